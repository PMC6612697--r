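# Fixture builders shared across the suite. Everything is generated in code
# under fixed seeds; no files ship with the package.

# Smooth random dose field: a few Gaussian blobs scaled to max 100, plus an
# evaluated copy perturbed by iid Gaussian noise (in dose units; max is 100).
# Rectangular by default to catch axis-transposition mistakes.
smooth_pair <- function(seed, nx = 14, ny = 10, spacing = 1, noise = 1.5) {
  set.seed(seed)
  xs <- (seq_len(nx) - 1) * spacing
  ys <- (seq_len(ny) - 1) * spacing
  f <- matrix(0, nx, ny)
  for (b in seq_len(4)) {
    cx <- stats::runif(1, min(xs), max(xs))
    cy <- stats::runif(1, min(ys), max(ys))
    w <- stats::runif(1, 0.15, 0.45) * max(xs[length(xs)], ys[length(ys)])
    a <- stats::runif(1, 0.3, 1)
    f <- f + a * outer(exp(-(xs - cx)^2 / (2 * w^2)),
                       exp(-(ys - cy)^2 / (2 * w^2)))
  }
  vals <- 100 * f / max(f)
  ev <- pmax(vals + matrix(stats::rnorm(nx * ny, 0, noise), nx, ny), 0)
  list(ref = dose_grid(vals, spacing = c(spacing, spacing)),
       ev = dose_grid(ev, spacing = c(spacing, spacing)))
}

# settings that skip resampling for grids at native 1 mm spacing
native_settings <- function(spacing = 1, ...) {
  search_settings(interp_step_mm = spacing, ...)
}

# 1D row fixture as 3 x 1 grids at x = 0, 1, 2 mm
row_grid <- function(doses, spacing = 1) {
  dose_grid(matrix(doses, ncol = 1), spacing = c(spacing, spacing))
}
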