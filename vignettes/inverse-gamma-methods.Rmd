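---
title: "Inverse gamma analysis: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse gamma analysis: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igdose)
```

## The comparison problem

Patient-specific quality assurance compares a measured planar dose
distribution (the *evaluated* grid, typically from a detector array)
against the planning system's calculation (the *reference* grid). The gamma
index combines dose and spatial tolerance into one test: a reference point
at position $r_r$ with dose $D_r$ passes when some evaluated sample at
$r_e$ with dose $D_e$ satisfies

$$\Gamma(r_e, r_r) \;=\; \sqrt{\frac{\delta^2(r_e,r_r)}{\Delta D^2} +
\frac{r^2(r_e,r_r)}{\Delta d^2}} \;\le\; 1,
\qquad \gamma(r_r) = \min_{r_e} \Gamma(r_e, r_r),$$

with $\delta = D_e - D_r$, $r$ the 2D Euclidean distance in mm, $\Delta D$
the dose criterion and $\Delta d$ the distance-to-agreement criterion. The
comparison to 1 is inclusive: a uniform $+\Delta D$ offset passes exactly
on the boundary. Under global normalization $\Delta D$ is a percentage of
the global maximum dose; this package takes that maximum from the
*reference* grid, since the reference is the planned, ground-truth
distribution (an override argument exists for centres that normalize to
the measurement). Points below the lower dose threshold (LDT, default 5%
of the normalization dose, compared inclusively and on the reference dose
only) are excluded from analysis. The gamma agreement index (GAI) is the
percentage of analysed points with $\gamma \le 1$.

The inverse gamma (IG) method turns the dial the other way: given a target
GAI, it reports the smallest criteria that reach it. Three modes are
supported — minimum $\Delta d$ at fixed $\Delta D$, minimum $\Delta D$ at
fixed $\Delta d$, and the minimum ratio-linked pair with $\Delta D /
\Delta d$ fixed. The iterative search raises the free criterion from 0 in
fixed increments (0.1 mm, or 0.1% for the dose search) and stops at the
first value whose *pass count* reaches
$m = \lceil \mathrm{target}/100 \cdot N \rceil$; the count-based rule keeps
"95% of 53 points" unambiguous instead of letting floating-point round-off
of a percentage decide convergence.

## Per-point requirement maps and the quantile identity

For each analysed point the smallest passing criterion has a closed form.
At fixed $\Delta D$, over evaluated samples within dose tolerance
($|\delta| \le \Delta D_{abs}$), the minimum distance criterion is

$$\mathrm{req}(r_r) = \min_{r_e}\; \frac{r}{\sqrt{1 - \delta^2/\Delta D_{abs}^2}},$$

with co-located in-tolerance samples giving 0 and no in-tolerance sample
(or a requirement beyond the search cap) giving the unreachable sentinel
$\infty$. Analogous forms exist for the fixed-$\Delta d$ mode
($100|\delta| / (D_{norm}\sqrt{1 - r^2/\Delta d^2})$ over samples strictly
inside the disc) and the fixed-ratio mode
($\sqrt{(100\delta/(k D_{norm}))^2 + r^2}$). A point passes at a criterion
value $c$ exactly when its requirement is $\le c$, so the iterative search
answer equals the $m$-th smallest requirement rounded up to the step —
`quantile_fast_path()`. The test suite asserts this identity exactly, on
random fields, for all three modes and targets from 90% to 100%; it is the
package's primary correctness oracle for the search, alongside a
brute-force double-loop gamma oracle for the engine itself. The
`accelerate = TRUE` argument of `ig_search()` uses the map route as an
optimization; the iterative route is the default and the reference
behaviour.

Two boundary conventions matter and are applied consistently on both
routes:

* In the fixed-$\Delta d$ mode the closed form divides by
  $\sqrt{1 - r^2/\Delta d^2}$, so samples at exactly $r = \Delta d$ pass
  only with $\delta = 0$ (then $\Gamma = 1$ at any $\Delta D$, requirement
  0). Dose equality is tested with a relative tolerance of $10^{-9}$ of
  the normalization dose.
* $\Delta d = 0$ (the first iterate) degenerates to a pure
  dose-difference test against co-located samples, "co-located" meaning
  within $10^{-9}$ mm to absorb floating-point position arithmetic.

## Interpolation and the candidate search

The gamma minimum is taken over *discrete* evaluated samples, so the
evaluated spacing limits the spatial resolution of the search. The
evaluated grid is therefore bilinearly resampled onto a lattice with
spacing at most `interp_step_mm` (default 0.2 mm, twice as fine as the
0.1 mm search step; configurable) before any candidate search; requirement
maps are computed on the same resampled lattice as the iterative search so
the quantile identity holds exactly. The discretization biases distances
by at most one resampled cell, which is why the shift-recovery test brackets
the found $\Delta d$ for a true shift $s$ in
$[s - \mathtt{interp\_step}, s + \mathtt{step}]$.

For pass/fail decisions candidates need only be searched within a disc of
radius $\Delta d$: any farther sample has $r/\Delta d > 1$ and hence
$\Gamma > 1$. When full gamma *values* are reported, the disc is enlarged
to `radius_factor` $\times\,\Delta d$ (default 3), so values up to 3 are
exact and larger ones are lower bounds flagged in `censored_mask` — a
bounded-cost compromise that never misstates pass/fail and never presents
a bound as exact. Because $\gamma$ is pointwise non-increasing in either
criterion, the iterative search re-evaluates only points that have not yet
passed; the result is identical to re-evaluating everything.

Search caps default to 20 mm and 20%: generous relative to any criterion a
clinic would accept, while bounding the worst case (an unreachable point
otherwise iterates forever). A search that hits the cap returns status
`cap_reached` with the cap's GAI, and the CLI exits with code 2.

## The synthetic study conditions

No public planar PSQA measurements accompany the method, so validation
runs on synthetic fields with analytically known ground truth:

* `square_field()` — the classic validation geometry: a separable plateau
  with an erf penumbra, default 60 mm width, 3 mm penumbra scale, 1 mm
  sampling over an 80 mm plane, normalized to 100. These defaults mirror a
  single modulated-arc planar measurement at clinical scale (detector
  arrays sample at 5–10 mm; planning systems export at 1–2.5 mm; 1 mm is
  used so that resampling, not the fixture, limits accuracy).
* `shift_field()` — translations evaluated from the analytic form, never
  by interpolating the discrete grid, so shift fixtures carry no
  resampling error and any deviation in a recovered shift is attributable
  to the engine alone.
* `add_noise()` (seeded Gaussian noise as a percent of the maximum dose,
  matching the global normalization of $\Delta D$; default study condition
  1%), `scale_dose()`, and `corrupt_pixel()` for single dead/noisy
  detector elements.

What these fixtures do *not* emulate: realistic VMAT fluence modulation,
detector spatial response, the cylindrical geometry of helical diode
arrays, or setup uncertainty beyond rigid shifts. Passing tests therefore
demonstrate the correctness of the gamma/IG computation on planar grids,
not clinical performance of any specific detector.

A deliberate property of the single-pixel corruption condition: the
corrupted element must sit on the *reference* grid. A spike on the
evaluated grid is smeared by bilinear resampling, which creates
in-tolerance doses a fraction of a millimetre away — the search then
correctly converges at a small $\Delta d$. Only a reference-side outlier
facing a smooth evaluated field is truly unreachable, which is what makes
a 100% GAI target fragile: one such pixel drives the search to its cap,
while a 99.5% target on a 400-point grid converges at 0 mm. This is why
the CLI recommends targets of 99–99.5% over 100%.

## Degenerate inputs and conventions

* All-zero reference: no normalization dose, an error.
* Empty inclusion mask (LDT above every dose): an error, not a 0% GAI.
* Disjoint grids: `validate_pair()` rejects them ("no spatial overlap").
* Excluded points carry `NA` in every map; unreachable points carry
  `Inf`. The two sentinels are never conflated, and exported grids encode
  both as −1 only in the sidecar-documented CLI output.
* Ties in the candidate minimum are irrelevant (a minimum over a finite
  set); no tie-breaking is needed.
* $\Delta D_{abs}$ is computed as `dd_pct * norm / 100` in that order,
  which is exact in floating point for the common norm-100 cases and keeps
  boundary examples (uniform +3% at $\Delta D = 3\%$) exactly on
  $\gamma = 1$.

## Problem sizes

The test suite runs identity and boundary cases on ~10–30 point-per-side
grids, the brute-force oracle on 50 random pairs up to 30×30, the
search–quantile identity on 30 random pairs × 5 targets × 3 modes, and
shift recovery on the full 81×81 clinical-scale field with 0.2 mm
resampling — sizes chosen so the whole suite completes in well under a
minute while still exercising every code path at clinical scale at least
once. The acceptance script runs the full clinical-scale condition
end-to-end.

## Known limitations

* 2D planar grids only; no 3D gamma, no cylindrical-array unrolling.
* Global normalization only (no local, point-by-point normalization).
* The joint ($\Delta D$, $\Delta d$) Pareto frontier is out of scope; the
  ratio-linked mode covers the one-parameter family instead.
* `read_rtdose()` handles uncompressed little-endian single/multi-frame
  RT Dose objects with axis-aligned orientation; it is a convenience
  ingestion path (flag-gated on the command line) and deliberately
  minimal.
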