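#' Normalization dose
#'
#' Under global ("Van Dyk") normalization the dose-difference criterion is a
#' percentage of the global maximum dose; this returns that maximum from the
#' reference distribution (the planned, ground-truth dose). An all-zero
#' reference has no meaningful normalization and is an error.
#'
#' @param reference a [dose_grid()].
#' @return the maximum reference dose, a positive scalar.
#' @export
normalization_dose <- function(reference) {
  if (!.is_dose_grid(reference)) stop("'reference' must be a dose_grid")
  m <- max(reference$values)
  if (!is.finite(m) || m <= 0) stop("zero normalization dose")
  m
}

#' Lower-dose-threshold inclusion mask
#'
#' Logical grid marking the reference points analysed by the gamma
#' comparison: those with dose greater than or equal to
#' `ldt_pct/100 * norm_dose`. The comparison is inclusive, so points exactly
#' at the threshold (and every point of a uniform field) are analysed.
#'
#' @param reference a [dose_grid()].
#' @param criteria a [gamma_criteria()] supplying `ldt_pct`.
#' @param norm_dose normalization dose; defaults to
#'   [normalization_dose()] of the reference.
#' @return logical matrix with the reference grid's shape.
#' @export
inclusion_mask <- function(reference, criteria = gamma_criteria(),
                           norm_dose = NULL) {
  if (is.null(norm_dose)) norm_dose <- normalization_dose(reference)
  reference$values >= criteria$ldt_pct * norm_dose / 100
}

#' Resample the evaluated grid
#'
#' Bilinearly resamples the evaluated distribution onto a finer regular grid
#' covering the same extent, with spacing at most `interp_step_mm` per axis.
#' The gamma minimum is taken over discrete evaluated samples, so the
#' evaluated spacing bounds the spatial resolution of the search; resampling
#' well below the distance criterion keeps the discretization error small.
#' When `interp_step_mm` equals the native spacing the input is returned
#' unchanged.
#'
#' @param evaluated a [dose_grid()].
#' @param settings a [search_settings()]; only `interp_step_mm` is used.
#' @return a `dose_grid` on the refined lattice.
#' @export
resample_evaluated <- function(evaluated, settings = search_settings()) {
  step <- settings$interp_step_mm
  sp <- evaluated$spacing
  if (isTRUE(all.equal(step, sp[1L])) && isTRUE(all.equal(step, sp[2L])))
    return(evaluated)
  if (step > min(sp) * (1 + 1e-9))
    stop("interp_step_mm must not exceed the native evaluated spacing")
  ax <- .axis_resample(nrow(evaluated$values), sp[1L], step)
  ay <- .axis_resample(ncol(evaluated$values), sp[2L], step)
  vals <- ax$W %*% evaluated$values %*% t(ay$W)
  dose_grid(vals, spacing = c(ax$d, ay$d), origin = evaluated$origin,
            unit = evaluated$unit)
}

# 1D bilinear weight matrix for refining one axis: n samples at spacing d
# onto m samples at spacing <= step over the same extent.
.axis_resample <- function(n, d, step) {
  if (n == 1L) return(list(W = matrix(1, 1L, 1L), d = d))
  len <- (n - 1) * d
  m <- as.integer(ceiling(len / step - 1e-9)) + 1L
  nd <- len / (m - 1)
  t <- (seq_len(m) - 1) * nd / d              # position in units of old cells
  i0 <- pmin(pmax(floor(t + 1e-12), 0), n - 2)
  w <- t - i0
  W <- matrix(0, m, n)
  W[cbind(seq_len(m), i0 + 1)] <- 1 - w
  W[cbind(seq_len(m), i0 + 2)] <- W[cbind(seq_len(m), i0 + 2)] + w
  list(W = W, d = nd)
}

# Precomputed lookup for candidate searches.
.ev_cache <- function(grid) {
  list(v = grid$values, xs = grid_x(grid), ys = grid_y(grid))
}

# Evaluated samples within a disc of `radius` mm around (x, y).
# radius = 0 means "co-located" (within 1e-9 mm). The boundary is included
# with a small relative slack; samples admitted just beyond the boundary
# have Gamma > 1 and can never flip a pass decision.
.disc_window <- function(ev, x, y, radius) {
  r <- radius + 1e-9
  ix <- which(ev$xs >= x - r & ev$xs <= x + r)
  if (!length(ix)) return(NULL)
  iy <- which(ev$ys >= y - r & ev$ys <= y + r)
  if (!length(iy)) return(NULL)
  r2 <- outer((ev$xs[ix] - x)^2, (ev$ys[iy] - y)^2, `+`)
  keep <- r2 <= radius * radius * (1 + 1e-9) + 1e-18
  if (!any(keep)) return(NULL)
  list(v = ev$v[ix, iy, drop = FALSE][keep], r2 = r2[keep])
}

# Minimum Gamma over a candidate window. dd_abs = 0 and dta_mm = 0 degenerate
# to exact dose match / co-location tests.
.gamma_min <- function(win, ref_dose, dd_abs, dta_mm, dose_tol) {
  if (is.null(win)) return(Inf)
  delta <- win$v - ref_dose
  u2 <- if (dd_abs > 0) (delta / dd_abs)^2 else
    ifelse(abs(delta) <= dose_tol, 0, Inf)
  v2 <- if (dta_mm > 0) win$r2 / (dta_mm * dta_mm) else
    ifelse(win$r2 <= 1e-18, 0, Inf)
  sqrt(min(u2 + v2))
}

.dose_tol <- function(norm_dose) 1e-9 * max(1, norm_dose)

#' Gamma index at a single reference point
#'
#' The gamma value at one reference point: the minimum over evaluated
#' samples within `radius_mm` of
#' \deqn{\Gamma = \sqrt{\delta^2/\Delta D^2 + r^2/\Delta d^2},}
#' where \eqn{\delta} is the evaluated-minus-reference dose difference,
#' \eqn{\Delta D} the absolute dose criterion (`dd_pct`% of `norm_dose`),
#' \eqn{r} the 2D Euclidean distance in mm and \eqn{\Delta d} the distance
#' criterion. Returns `Inf` when no evaluated sample lies within
#' `radius_mm`. With `dta_mm = 0` the test degenerates to
#' \eqn{|\delta|/\Delta D} over co-located samples only.
#'
#' @param ref_pos numeric `(x, y)` position of the reference point, mm.
#' @param ref_dose reference dose at that point.
#' @param evaluated evaluated [dose_grid()], already resampled as desired.
#' @param criteria a [gamma_criteria()].
#' @param norm_dose normalization dose (global maximum).
#' @param radius_mm candidate search radius, mm; must be at least
#'   `criteria$dta_mm` for exact pass/fail.
#' @return the gamma value, a non-negative scalar (possibly `Inf`).
#' @export
gamma_point <- function(ref_pos, ref_dose, evaluated,
                        criteria = gamma_criteria(), norm_dose,
                        radius_mm = criteria$dta_mm) {
  ev <- .ev_cache(evaluated)
  dd_abs <- criteria$dd_pct * norm_dose / 100
  .gamma_min(.disc_window(ev, ref_pos[1L], ref_pos[2L], radius_mm),
             ref_dose, dd_abs, criteria$dta_mm, .dose_tol(norm_dose))
}

#' Gamma map and agreement index
#'
#' Full global gamma comparison of an evaluated against a reference dose
#' distribution. The evaluated grid is bilinearly resampled (see
#' [resample_evaluated()]), reference points below the lower dose threshold
#' are excluded, and each included point receives the minimum \eqn{\Gamma}
#' over evaluated samples within the candidate radius. The gamma agreement
#' index (GAI) is the percentage of included points with gamma `<= 1`
#' (inclusive).
#'
#' Candidates are searched to `radius_factor * dta_mm` by default, so
#' reported gamma values up to `radius_factor` are exact; larger values are
#' lower bounds, flagged in `censored_mask`. Pass/fail status and the GAI are
#' exact for any radius `>= dta_mm`, since farther candidates always have
#' \eqn{\Gamma > 1}.
#'
#' @inheritParams validate_pair
#' @param criteria a [gamma_criteria()].
#' @param settings a [search_settings()].
#' @param norm_dose override for the normalization dose; default is the
#'   reference grid's maximum.
#' @param radius_mm override for the candidate search radius (may be `Inf`
#'   for an uncapped search); default `radius_factor * dta_mm`.
#' @param resample if `FALSE`, use the evaluated grid as supplied.
#' @return an object of class `gamma_result`: list with `gamma` (matrix,
#'   `NA` at excluded points, `Inf` where no candidate exists),
#'   `included_mask`, `censored_mask`, `gai_pct`, `n_included`, `n_passed`,
#'   `criteria`, `settings`, `norm_dose`, `eval_spacing`.
#' @examples
#' ref <- square_field(extent_mm = 40, spacing_mm = 2, field_width_mm = 24)
#' res <- gamma_map(ref, ref, gamma_criteria(3, 2, 5))
#' res$gai_pct
#' @export
gamma_map <- function(reference, evaluated, criteria = gamma_criteria(),
                      settings = search_settings(), norm_dose = NULL,
                      radius_mm = NULL, resample = TRUE) {
  validate_pair(reference, evaluated)
  if (is.null(norm_dose)) norm_dose <- normalization_dose(reference)
  mask <- inclusion_mask(reference, criteria, norm_dose)
  if (!any(mask)) stop("no points above threshold")
  evg <- if (resample) resample_evaluated(evaluated, settings) else evaluated
  ev <- .ev_cache(evg)
  dta <- criteria$dta_mm
  dd_abs <- criteria$dd_pct * norm_dose / 100
  radius <- if (!is.null(radius_mm)) radius_mm else settings$radius_factor * dta
  bb_r <- .grid_bbox(reference); bb_e <- .grid_bbox(evg)
  if (!is.finite(radius))
    radius <- sqrt((max(bb_r[2L], bb_e[2L]) - min(bb_r[1L], bb_e[1L]))^2 +
                   (max(bb_r[4L], bb_e[4L]) - min(bb_r[3L], bb_e[3L]))^2) + dta
  tol <- .dose_tol(norm_dose)
  xs <- grid_x(reference); ys <- grid_y(reference)
  nx <- nrow(reference$values)
  gam <- matrix(NA_real_, nx, ncol(reference$values))
  for (k in which(mask)) {
    i <- (k - 1L) %% nx + 1L
    j <- (k - 1L) %/% nx + 1L
    gam[k] <- .gamma_min(.disc_window(ev, xs[i], ys[j], radius),
                         reference$values[k], dd_abs, dta, tol)
  }
  pass <- !is.na(gam) & gam <= criteria$pass_threshold
  n_inc <- sum(mask)
  n_pass <- sum(pass)
  censored <- !is.na(gam) & is.finite(gam) & dta > 0 & gam > radius / dta
  censored[is.na(gam)] <- FALSE
  structure(
    list(gamma = gam, included_mask = mask, censored_mask = censored,
         gai_pct = 100 * n_pass / n_inc, n_included = n_inc,
         n_passed = n_pass, criteria = criteria, settings = settings,
         norm_dose = norm_dose, eval_spacing = evg$spacing),
    class = "gamma_result")
}

#' Gamma agreement index
#'
#' Percentage of analysed points whose gamma value is less than or equal to
#' the pass threshold (inclusive); `Inf` sentinels (no candidate within the
#' search radius) count as failures.
#'
#' @param x a `gamma_result`, or a numeric matrix/vector of gamma values.
#' @param ... passed to methods.
#' @return the GAI, a percentage in `[0, 100]`.
#' @export
gai <- function(x, ...) UseMethod("gai")

#' @rdname gai
#' @export
gai.gamma_result <- function(x, ...) x$gai_pct

#' @rdname gai
#' @param included_mask optional logical mask selecting the analysed points;
#'   default: all non-`NA` entries.
#' @param pass_threshold gamma cutoff (1.0).
#' @export
gai.default <- function(x, included_mask = NULL, pass_threshold = 1.0, ...) {
  g <- as.numeric(x)
  inc <- if (is.null(included_mask)) !is.na(g) else as.logical(included_mask)
  n <- sum(inc)
  if (n == 0L) stop("no points above threshold")
  100 * sum(g[inc] <= pass_threshold, na.rm = TRUE) / n
}

#' @export
print.gamma_result <- function(x, ...) {
  print(x$criteria)
  cat(sprintf("  n_included: %d, n_passed: %d, GAI: %.3f%%\n",
              x$n_included, x$n_passed, x$gai_pct))
  if (any(x$censored_mask))
    cat(sprintf("  %d gamma values censored (lower bounds beyond the search radius)\n",
                sum(x$censored_mask)))
  invisible(x)
}

#' @export
plot.gamma_result <- function(x, ...) {
  z <- x$gamma
  z[!is.finite(z)] <- NA
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z,
                  col = grDevices::hcl.colors(64, "Spectral", rev = TRUE),
                  xlab = "i", ylab = "j",
                  main = sprintf("gamma map (GAI %.1f%%)", x$gai_pct),
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}
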