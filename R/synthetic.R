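#' Synthetic square dose field
#'
#' Generates the classic validation geometry for gamma comparisons: a
#' separable square field \eqn{D(x, y) = D_{max} P(x) P(y)} whose ideal
#' plateau edges are rolled off by a Gaussian-convolved (erf-based) penumbra,
#' \deqn{P(x) = \Phi((w/2 - x)/\sigma) + \Phi((w/2 + x)/\sigma) - 1,}
#' with \eqn{\Phi} the standard normal CDF, \eqn{w} the field width and
#' \eqn{\sigma} the penumbra scale. The profile is 0.5 of the plateau at the
#' field edge and reaches at least 99% of `max_dose` at the centre whenever
#' `field_width_mm >= 10 * penumbra_sigma_mm`. The analytic form is retained
#' on the object so that [shift_field()] can translate the field exactly,
#' without interpolation error.
#'
#' Defaults emulate a single modulated-arc planar measurement at clinical
#' scale: a 60 mm field with a 3 mm penumbra sampled every 1 mm over an
#' 80 mm square, normalized to 100 dose units.
#'
#' @param extent_mm side length of the sampled square region, mm; the grid
#'   is centred on the origin.
#' @param spacing_mm grid spacing, mm.
#' @param field_width_mm field width \eqn{w}, mm; must be smaller than the
#'   extent.
#' @param penumbra_sigma_mm penumbra scale \eqn{\sigma}, mm; > 0.
#' @param max_dose plateau dose (arbitrary units).
#' @return a [dose_grid()] carrying the analytic field description in its
#'   `analytic` element.
#' @examples
#' f <- square_field()
#' max(f$values)
#' @export
square_field <- function(extent_mm = 80, spacing_mm = 1, field_width_mm = 60,
                         penumbra_sigma_mm = 3, max_dose = 100) {
  if (extent_mm <= 0 || spacing_mm <= 0 || spacing_mm > extent_mm)
    stop("degenerate extent or spacing")
  if (field_width_mm >= extent_mm)
    stop("'field_width_mm' must be smaller than 'extent_mm'")
  if (penumbra_sigma_mm <= 0) stop("'penumbra_sigma_mm' must be > 0")
  n <- as.integer(round(extent_mm / spacing_mm)) + 1L
  origin <- -extent_mm / 2
  an <- list(type = "square_field", width = field_width_mm,
             sigma = penumbra_sigma_mm, max_dose = max_dose,
             shift = c(0, 0))
  g <- .eval_analytic(an, n, n, c(spacing_mm, spacing_mm), c(origin, origin))
  g
}

.square_profile <- function(x, width, sigma) {
  stats::pnorm((width / 2 - x) / sigma) + stats::pnorm((width / 2 + x) / sigma) - 1
}

.eval_analytic <- function(an, nx, ny, spacing, origin) {
  xs <- origin[1L] + (seq_len(nx) - 1) * spacing[1L]
  ys <- origin[2L] + (seq_len(ny) - 1) * spacing[2L]
  px <- .square_profile(xs - an$shift[1L], an$width, an$sigma)
  py <- .square_profile(ys - an$shift[2L], an$width, an$sigma)
  vals <- an$max_dose * pmax(outer(px, py), 0)
  g <- dose_grid(vals, spacing = spacing, origin = origin, unit = "rel")
  g$analytic <- an
  g
}

#' Shift an analytic field exactly
#'
#' Translates a [square_field()] by `(dx_mm, dy_mm)` by re-evaluating its
#' analytic form at the displaced positions — never by interpolating the
#' discrete grid — so the shift carries no resampling error and shifting
#' back recovers the original field to machine precision. The grid origin is
#' unchanged; only the dose pattern moves.
#'
#' @param grid a `dose_grid` produced by [square_field()] (or a previous
#'   shift of one).
#' @param dx_mm,dy_mm shift in mm along x and y.
#' @return the shifted `dose_grid`.
#' @export
shift_field <- function(grid, dx_mm, dy_mm = 0) {
  an <- grid$analytic
  if (is.null(an))
    stop("'grid' carries no analytic field description; only analytic fields can be shifted exactly")
  an$shift <- an$shift + c(dx_mm, dy_mm)
  .eval_analytic(an, nrow(grid$values), ncol(grid$values),
                 grid$spacing, grid$origin)
}

#' Dose perturbations for validation fixtures
#'
#' Deterministic perturbations with known ground truth: uniform
#' multiplicative scaling, additive Gaussian noise expressed as a percent of
#' the maximum dose (matching the global normalization of the dose
#' criterion), and single-pixel corruption emulating a dead or noisy
#' detector element. Noise and corruption invalidate the analytic field
#' description, so the result can no longer be shifted exactly.
#'
#' @param grid a [dose_grid()].
#' @param factor multiplicative scale factor; > 0.
#' @return a perturbed `dose_grid`.
#' @export
scale_dose <- function(grid, factor) {
  if (!is.numeric(factor) || factor <= 0) stop("'factor' must be > 0")
  g <- dose_grid(grid$values * factor, grid$spacing, grid$origin, grid$unit)
  if (!is.null(grid$analytic)) {
    g$analytic <- grid$analytic
    g$analytic$max_dose <- grid$analytic$max_dose * factor
  }
  g
}

#' @rdname scale_dose
#' @param sigma_pct_of_max noise standard deviation, percent of the grid's
#'   maximum dose; >= 0.
#' @param seed integer seed making the noise reproducible; the caller's RNG
#'   state is left untouched. Doses are clamped at zero afterwards.
#' @export
add_noise <- function(grid, sigma_pct_of_max, seed) {
  if (sigma_pct_of_max < 0) stop("'sigma_pct_of_max' must be >= 0")
  if (sigma_pct_of_max == 0) return(grid)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sd_abs <- sigma_pct_of_max / 100 * max(grid$values)
  vals <- pmax(grid$values +
                 matrix(stats::rnorm(length(grid$values), 0, sd_abs),
                        nrow(grid$values)), 0)
  dose_grid(vals, grid$spacing, grid$origin, grid$unit)
}

#' @rdname scale_dose
#' @param i,j element indices of the corrupted pixel.
#' @param delta_pct additive corruption, percent of the grid's maximum dose
#'   (negative values model under-response). The result is clamped at zero.
#' @export
corrupt_pixel <- function(grid, i, j, delta_pct) {
  nx <- nrow(grid$values); ny <- ncol(grid$values)
  if (!is.numeric(i) || !is.numeric(j) || i < 1 || i > nx || j < 1 || j > ny)
    stop("index out of range")
  vals <- grid$values
  vals[i, j] <- max(vals[i, j] + delta_pct / 100 * max(vals), 0)
  dose_grid(vals, grid$spacing, grid$origin, grid$unit)
}

#' Uniform dose field
#'
#' Convenience generator for a flat field: every element carries `dose`.
#' Useful for boundary-case fixtures where the dose difference is constant
#' everywhere and distance cannot help a failing point.
#'
#' @inheritParams square_field
#' @param dose the uniform dose value; > 0.
#' @return a [dose_grid()].
#' @export
uniform_field <- function(extent_mm = 19, spacing_mm = 1, dose = 100) {
  if (extent_mm <= 0 || spacing_mm <= 0 || spacing_mm > extent_mm)
    stop("degenerate extent or spacing")
  if (dose <= 0) stop("'dose' must be > 0")
  n <- as.integer(round(extent_mm / spacing_mm)) + 1L
  dose_grid(matrix(dose, n, n), spacing = c(spacing_mm, spacing_mm),
            origin = c(-extent_mm / 2, -extent_mm / 2), unit = "rel")
}
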