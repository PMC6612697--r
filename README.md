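# igdose

Gamma index and inverse gamma analysis of planar dose distributions for
radiotherapy patient-specific quality assurance (PSQA).

Medical physicists verify modulated treatment plans (IMRT/VMAT) by
delivering them to a detector array and comparing the measured dose plane
against the treatment planning system's calculation. The standard
comparison is the gamma index: for each reference point
\(r_r\), the evaluated distribution is searched for the sample minimizing

    Γ(r_e, r_r) = sqrt( δ²(r_e, r_r)/ΔD²  +  r²(r_e, r_r)/Δd² ),
    γ(r_r)      = min over r_e of Γ(r_e, r_r)

where δ is the evaluated-minus-reference dose difference, ΔD the
dose-difference criterion (percent of the global maximum dose, "Van Dyk"
global normalization), r the 2D Euclidean distance in mm and Δd the
distance-to-agreement (DTA) criterion. The gamma agreement index (GAI, the
"pass rate") is the percentage of analysed points with γ ≤ 1; points below
a lower dose threshold (LDT, default 5% of the maximum) are excluded.

`igdose` additionally inverts this test. Instead of fixing (ΔD, Δd) and
reporting the GAI, the **inverse gamma** search fixes the target GAI and
reports the minimum criteria that achieve it, in three modes:

* minimum Δd at fixed ΔD (raising Δd from 0 in 0.1 mm steps),
* minimum ΔD at fixed Δd,
* the minimum ratio-linked pair (ΔD, Δd) with ΔD/Δd held constant.

The per-point requirement maps behind the search (the smallest criterion
each individual point needs) localize regions of geometric or dosimetric
disagreement, and their cumulative histogram reads off the criterion needed
for *any* target pass rate.

## Worked example

A 60 mm square field with a 3 mm penumbra, compared against the same field
shifted 2 mm with 1% Gaussian dose noise added:

```r
library(igdose)
ref <- square_field(extent_mm = 80, spacing_mm = 1, field_width_mm = 60,
                    penumbra_sigma_mm = 3, max_dose = 100)
ev  <- add_noise(shift_field(ref, 2, 0), sigma_pct_of_max = 1, seed = 2)

gamma_map(ref, ev, gamma_criteria(dd_pct = 3, dta_mm = 2, ldt_pct = 5))
#> gamma criteria: 3% / 2 mm, LDT 5% (global normalization)
#>   n_included: 4713, n_passed: 4098, GAI: 86.951%

ig_search(ref, ev, "fixed_dd", fixed_value = 3, target_gai_pct = 95)
#> inverse gamma search (fixed_dd), target GAI 95%
#>   fixed dd 3%; status: converged after 22 iterations
#>   found: dta 2.1 mm, dd 3%
#>   achieved GAI 98.833% (4478 of 4713 points needed)
```

The 3%/2 mm comparison fails (GAI 87%) because the 2 mm shift slightly
exceeds the 2 mm DTA tolerance once noise is added; the inverse search
reports that 2.1 mm — the true shift plus one 0.1 mm step — would have been
enough for 95% of points to pass. `per_point_min_dta()` returns the map of
each point's individual Δd requirement and `requirement_histogram()` its
cumulative form; here the last point passes at 2.31 mm, so even a 100%
target converges just beyond the applied shift.

A command-line wrapper with `gamma`, `inverse`, `synth` and `report`
subcommands is installed at `system.file("cli", "igdose", package =
"igdose")`; see `?ig_cli`.

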