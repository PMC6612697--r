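#' @title Inverse gamma analysis
#' @description
#' The inverse gamma (IG) method turns the gamma comparison around: instead
#' of fixing the criteria and reporting the pass rate, it fixes the target
#' pass rate (GAI) and reports the minimum criteria that achieve it. Three
#' modes exist: the minimum distance-to-agreement at a fixed dose criterion,
#' the minimum dose criterion at a fixed distance, and the minimum
#' ratio-linked pair. [ig_search()] performs the iterative search;
#' [per_point_min_dta()] and friends give the closed-form per-point
#' requirement maps underlying it; [quantile_fast_path()] reads the search
#' answer directly off a requirement map and serves as the primary
#' cross-check of the iterative search.
#' @name inverse_gamma
NULL

# Shared setup for requirement maps and the iterative search: validation,
# normalization, LDT masking, evaluated-grid resampling, and flattened
# coordinates of the included reference points.
.ig_setup <- function(reference, evaluated, settings, ldt_pct, norm_dose) {
  validate_pair(reference, evaluated)
  if (is.null(norm_dose)) norm_dose <- normalization_dose(reference)
  mask <- reference$values >= ldt_pct * norm_dose / 100
  if (!any(mask)) stop("no points above threshold")
  evg <- resample_evaluated(evaluated, settings)
  idx <- which(mask)
  nx <- nrow(reference$values)
  i <- (idx - 1L) %% nx + 1L
  j <- (idx - 1L) %/% nx + 1L
  list(norm = norm_dose, mask = mask, ev = .ev_cache(evg),
       eval_spacing = evg$spacing, idx = idx,
       x = grid_x(reference)[i], y = grid_y(reference)[j],
       dose = reference$values[idx],
       shape = dim(reference$values), tol = .dose_tol(norm_dose))
}

.new_requirement_map <- function(kind, values, mask, fixed, settings,
                                 norm_dose, eval_spacing) {
  structure(
    list(kind = kind, values = values, included_mask = mask, fixed = fixed,
         settings = settings, norm_dose = norm_dose,
         eval_spacing = eval_spacing),
    class = "requirement_map")
}

#' Per-point minimum distance-to-agreement map
#'
#' For each analysed reference point, the smallest distance criterion
#' \eqn{\Delta d} at which the point would pass the gamma test with the dose
#' criterion fixed at `dd_pct`. In closed form, over evaluated samples whose
#' dose difference is within tolerance (\eqn{|\delta| \le \Delta D}), the
#' requirement is \eqn{r / \sqrt{1 - \delta^2/\Delta D^2}}; a co-located
#' in-tolerance sample gives 0. Points with no in-tolerance sample within
#' `max_dta_mm`, or whose requirement exceeds that cap, carry the
#' unreachable sentinel `Inf`. This is the distance-requirement map that the
#' fixed-\eqn{\Delta D} inverse search thresholds at each iteration.
#'
#' @inheritParams gamma_map
#' @param dd_pct fixed dose-difference criterion, percent of the
#'   normalization dose; > 0.
#' @param ldt_pct lower dose threshold, percent.
#' @return an object of class `requirement_map` (`kind = "min_dta_mm"`):
#'   matrix of requirements in mm, `NA` at excluded points, `Inf` where
#'   unreachable.
#' @export
per_point_min_dta <- function(reference, evaluated, dd_pct = 3,
                              settings = search_settings(), ldt_pct = 5,
                              norm_dose = NULL) {
  if (dd_pct <= 0) stop("'dd_pct' must be > 0")
  s <- .ig_setup(reference, evaluated, settings, ldt_pct, norm_dose)
  dd_abs <- dd_pct * s$norm / 100
  cap <- settings$max_dta_mm
  vals <- matrix(NA_real_, s$shape[1L], s$shape[2L])
  for (t in seq_along(s$idx)) {
    win <- .disc_window(s$ev, s$x[t], s$y[t], cap)
    req <- Inf
    if (!is.null(win)) {
      u2 <- ((win$v - s$dose[t]) / dd_abs)^2
      ok <- u2 <= 1
      if (any(ok)) {
        r2 <- win$r2[ok]
        req <- min(ifelse(r2 <= 1e-18, 0, sqrt(r2 / (1 - u2[ok]))))
        if (req > cap) req <- Inf
      }
    }
    vals[s$idx[t]] <- req
  }
  .new_requirement_map("min_dta_mm", vals, s$mask, dd_pct, settings,
                       s$norm, s$eval_spacing)
}

#' Per-point minimum dose-criterion map
#'
#' For each analysed reference point, the smallest dose criterion
#' \eqn{\Delta D} (percent of the normalization dose) at which the point
#' would pass with the distance criterion fixed at `dta_mm`. Over samples
#' strictly inside the distance tolerance (\eqn{r < \Delta d}) the
#' requirement is
#' \eqn{100\,|\delta| / (D_{norm}\sqrt{1 - r^2/\Delta d^2})}; a sample with
#' exactly matching dose passes at any \eqn{\Delta D} for \eqn{r \le \Delta
#' d} (boundary included) and contributes 0. Unreachable points (no sample
#' strictly inside the disc, or requirement beyond `max_dd_pct`) carry
#' `Inf`. With `dta_mm = 0` only co-located samples count and the
#' requirement is the plain dose difference.
#'
#' @inheritParams per_point_min_dta
#' @param dta_mm fixed distance-to-agreement criterion, mm; >= 0.
#' @return a `requirement_map` (`kind = "min_dd_pct"`), values in percent.
#' @export
per_point_min_dd <- function(reference, evaluated, dta_mm = 2,
                             settings = search_settings(), ldt_pct = 5,
                             norm_dose = NULL) {
  if (dta_mm < 0) stop("'dta_mm' must be >= 0")
  s <- .ig_setup(reference, evaluated, settings, ldt_pct, norm_dose)
  cap <- settings$max_dd_pct
  vals <- matrix(NA_real_, s$shape[1L], s$shape[2L])
  for (t in seq_along(s$idx)) {
    win <- .disc_window(s$ev, s$x[t], s$y[t], dta_mm)
    req <- Inf
    if (!is.null(win)) {
      delta <- abs(win$v - s$dose[t])
      if (any(delta <= s$tol)) {
        req <- 0
      } else if (dta_mm > 0) {
        str <- win$r2 < dta_mm * dta_mm
        if (any(str))
          req <- min(100 * delta[str] /
                       (s$norm * sqrt(1 - win$r2[str] / (dta_mm * dta_mm))))
      } else {
        req <- min(100 * delta / s$norm)
      }
      if (req > cap) req <- Inf
    }
    vals[s$idx[t]] <- req
  }
  .new_requirement_map("min_dd_pct", vals, s$mask, dta_mm, settings,
                       s$norm, s$eval_spacing)
}

#' Per-point minimum criteria-pair map at a fixed ratio
#'
#' For a fixed ratio \eqn{k = \Delta D / \Delta d} (percent per mm), the
#' smallest \eqn{\Delta d} such that the linked pair
#' \eqn{(\Delta D, \Delta d) = (k\,\Delta d, \Delta d)} lets the point pass.
#' The closed form is the minimum over candidates of
#' \eqn{\sqrt{(100\,\delta/(k\,D_{norm}))^2 + r^2}}: finite for every
#' candidate, but reported as unreachable (`Inf`) beyond the `max_dta_mm`
#' cap.
#'
#' @inheritParams per_point_min_dta
#' @param ratio_pct_per_mm the fixed ratio \eqn{k} in percent per mm; > 0.
#' @return a `requirement_map` (`kind = "min_scale"`), values in mm (the
#'   \eqn{\Delta d} of the pair; the paired \eqn{\Delta D} is `k` times it).
#' @export
per_point_min_scale <- function(reference, evaluated, ratio_pct_per_mm = 1.5,
                                settings = search_settings(), ldt_pct = 5,
                                norm_dose = NULL) {
  if (ratio_pct_per_mm <= 0) stop("'ratio_pct_per_mm' must be > 0")
  s <- .ig_setup(reference, evaluated, settings, ldt_pct, norm_dose)
  cap <- settings$max_dta_mm
  k <- ratio_pct_per_mm
  vals <- matrix(NA_real_, s$shape[1L], s$shape[2L])
  for (t in seq_along(s$idx)) {
    win <- .disc_window(s$ev, s$x[t], s$y[t], cap)
    req <- Inf
    if (!is.null(win)) {
      req <- min(sqrt((100 * (win$v - s$dose[t]) / (k * s$norm))^2 + win$r2))
      if (req > cap) req <- Inf
    }
    vals[s$idx[t]] <- req
  }
  .new_requirement_map("min_scale", vals, s$mask, k, settings,
                       s$norm, s$eval_spacing)
}

# Count-based convergence target: the number of points that must pass for a
# pass rate of target_pct. The 1e-9 slack keeps exact products such as
# 0.9 * 30 from ceiling up through floating-point round-off.
.target_count <- function(target_pct, n) {
  max(1L, as.integer(ceiling(target_pct * n / 100 - 1e-9)))
}

#' Iterative inverse-gamma search
#'
#' Finds the minimum criterion value achieving a target GAI by running full
#' global gamma evaluations with the free criterion raised from 0 in fixed
#' increments, stopping at the first value whose pass count reaches the
#' count-based target `ceiling(target_gai_pct/100 * n_included)`. Modes:
#'
#' * `"fixed_dd"`: \eqn{\Delta D} held at `fixed_value` (%), \eqn{\Delta d}
#'   searched in `dta_step_mm` increments up to `max_dta_mm`.
#' * `"fixed_dta"`: \eqn{\Delta d} held at `fixed_value` (mm), \eqn{\Delta D}
#'   searched in `dd_step_pct` increments up to `max_dd_pct`.
#' * `"fixed_ratio"`: \eqn{\Delta d} searched with \eqn{\Delta D =
#'   k\,\Delta d} linked through `fixed_value` = \eqn{k} (%/mm).
#'
#' If the cap is reached before the target, `status = "cap_reached"` and the
#' GAI at the cap is reported. Because gamma is pointwise non-increasing in
#' the growing criterion, points that pass at one iterate stay passing, so
#' only surviving points are re-evaluated — an internal optimization with
#' identical results. With `accelerate = TRUE` the same result (including
#' the iteration trace) is derived from the closed-form requirement map
#' instead of iterating.
#'
#' A target GAI of 100% is permitted but is very sensitive to single-pixel
#' noise; targets of 99–99.5% are more robust (the command line interface
#' warns about this).
#'
#' @inheritParams per_point_min_dta
#' @param mode one of `"fixed_dd"`, `"fixed_dta"`, `"fixed_ratio"`.
#' @param fixed_value the held-constant criterion (% for `fixed_dd`, mm for
#'   `fixed_dta`, %/mm for `fixed_ratio`); > 0.
#' @param target_gai_pct target GAI in `(0, 100]`.
#' @param accelerate derive the result from the requirement map instead of
#'   iterating (identical output, faster for large answers).
#' @return an object of class `ig_result`: list with `mode`,
#'   `target_gai_pct`, `fixed_value`, `found_dta_mm`, `found_dd_pct` (`NA`
#'   when the cap was reached), `achieved_gai_pct`, `status`
#'   (`"converged"` or `"cap_reached"`), `n_iterations`, `n_included`,
#'   `target_count`, and `trace` (data frame of criterion value vs GAI per
#'   iteration).
#' @examples
#' ref <- square_field(extent_mm = 40, spacing_mm = 2, field_width_mm = 24)
#' ig_search(ref, ref, "fixed_dd", 3, 100,
#'           settings = search_settings(interp_step_mm = 2))
#' @export
ig_search <- function(reference, evaluated,
                      mode = c("fixed_dd", "fixed_dta", "fixed_ratio"),
                      fixed_value, target_gai_pct,
                      settings = search_settings(), ldt_pct = 5,
                      norm_dose = NULL, accelerate = FALSE) {
  mode <- match.arg(mode)
  if (!is.numeric(fixed_value) || fixed_value <= 0)
    stop("'fixed_value' must be > 0")
  if (!is.numeric(target_gai_pct) || target_gai_pct <= 0 ||
      target_gai_pct > 100)
    stop("'target_gai_pct' must lie in (0, 100]")
  if (accelerate)
    return(.ig_search_fast(reference, evaluated, mode, fixed_value,
                           target_gai_pct, settings, ldt_pct, norm_dose))
  s <- .ig_setup(reference, evaluated, settings, ldt_pct, norm_dose)
  step <- if (mode == "fixed_dta") settings$dd_step_pct else settings$dta_step_mm
  cap <- if (mode == "fixed_dta") settings$max_dd_pct else settings$max_dta_mm
  n <- length(s$idx)
  m <- .target_count(target_gai_pct, n)

  surv <- seq_len(n)
  passed <- 0L
  trace_crit <- numeric(0)
  trace_gai <- numeric(0)
  status <- "cap_reached"
  found <- NA_real_
  iter <- 0L
  repeat {
    crit <- iter * step
    par <- switch(mode,
      fixed_dd = list(dd_abs = fixed_value * s$norm / 100, dta = crit),
      fixed_dta = list(dd_abs = crit * s$norm / 100, dta = fixed_value),
      fixed_ratio = list(dd_abs = fixed_value * crit * s$norm / 100,
                         dta = crit))
    now_pass <- vapply(surv, function(t) {
      .gamma_min(.disc_window(s$ev, s$x[t], s$y[t], par$dta),
                 s$dose[t], par$dd_abs, par$dta, s$tol) <= 1.0
    }, logical(1L))
    passed <- passed + sum(now_pass)
    surv <- surv[!now_pass]
    iter <- iter + 1L
    trace_crit <- c(trace_crit, crit)
    trace_gai <- c(trace_gai, 100 * passed / n)
    if (passed >= m) {
      status <- "converged"
      found <- crit
      break
    }
    if (crit >= cap - 1e-9) break
  }
  .new_ig_result(mode, target_gai_pct, fixed_value, found, status,
                 100 * passed / n, iter, n, m,
                 data.frame(criterion = trace_crit, gai_pct = trace_gai))
}

# Requirement-map fast path: identical result to the iterative search,
# including the per-iteration trace.
.ig_search_fast <- function(reference, evaluated, mode, fixed_value,
                            target_gai_pct, settings, ldt_pct, norm_dose) {
  req <- switch(mode,
    fixed_dd = per_point_min_dta(reference, evaluated, fixed_value,
                                 settings, ldt_pct, norm_dose),
    fixed_dta = per_point_min_dd(reference, evaluated, fixed_value,
                                 settings, ldt_pct, norm_dose),
    fixed_ratio = per_point_min_scale(reference, evaluated, fixed_value,
                                      settings, ldt_pct, norm_dose))
  step <- if (mode == "fixed_dta") settings$dd_step_pct else settings$dta_step_mm
  cap <- if (mode == "fixed_dta") settings$max_dd_pct else settings$max_dta_mm
  vals <- req$values[req$included_mask]
  n <- length(vals)
  m <- .target_count(target_gai_pct, n)
  found <- quantile_fast_path(req, target_gai_pct, step)
  n_iter <- if (is.finite(found)) as.integer(round(found / step)) + 1L else
    as.integer(floor(cap / step + 1e-9)) + 1L
  crit <- (seq_len(n_iter) - 1) * step
  gai_tr <- vapply(crit, function(cc) 100 * sum(vals <= cc + 1e-12) / n,
                   numeric(1L))
  status <- if (is.finite(found)) "converged" else "cap_reached"
  .new_ig_result(mode, target_gai_pct, fixed_value,
                 if (is.finite(found)) found else NA_real_, status,
                 gai_tr[n_iter], n_iter, n, m,
                 data.frame(criterion = crit, gai_pct = gai_tr))
}

.new_ig_result <- function(mode, target, fixed, found, status, achieved,
                           n_iter, n_inc, m, trace) {
  found_dta <- switch(mode, fixed_dd = found, fixed_ratio = found,
                      fixed_dta = fixed)
  found_dd <- switch(mode, fixed_dd = fixed, fixed_dta = found,
                     fixed_ratio = fixed * found)
  if (status == "cap_reached") {
    if (mode != "fixed_dta") found_dta <- NA_real_
    if (mode != "fixed_dd") found_dd <- NA_real_
  }
  structure(
    list(mode = mode, target_gai_pct = target, fixed_value = fixed,
         found_dta_mm = found_dta, found_dd_pct = found_dd,
         achieved_gai_pct = achieved, status = status,
         n_iterations = n_iter, n_included = n_inc, target_count = m,
         trace = trace),
    class = "ig_result")
}

#' Requirement-map quantile read-off
#'
#' Reads the inverse-search answer directly off a per-point requirement map:
#' the smallest multiple of `step` that is at least the m-th smallest
#' per-point requirement, where `m = ceiling(target_gai_pct/100 *
#' n_included)`. Unreachable sentinels sort last; if the m-th value is a
#' sentinel, the target cannot be met within the cap and `Inf` is returned.
#' For matching settings this equals the value found by the iterative
#' [ig_search()], which makes it the search's independent cross-check.
#'
#' @param req_map a `requirement_map` from [per_point_min_dta()],
#'   [per_point_min_dd()] or [per_point_min_scale()].
#' @param target_gai_pct target GAI in `(0, 100]`.
#' @param step the search increment the result is rounded up to.
#' @return the criterion value (same unit as the map), or `Inf` on cap
#'   failure.
#' @export
quantile_fast_path <- function(req_map, target_gai_pct, step = 0.1) {
  if (!inherits(req_map, "requirement_map"))
    stop("'req_map' must be a requirement_map")
  vals <- req_map$values[req_map$included_mask]
  if (!length(vals)) stop("empty requirement map")
  m <- .target_count(target_gai_pct, length(vals))
  v <- sort(vals)[m]
  if (!is.finite(v)) return(Inf)
  ceiling(v / step - 1e-9) * step
}

#' Requirement histogram
#'
#' Tabulates a per-point requirement map into sorted distinct requirement
#' values with counts and the cumulative GAI, so the criterion needed for
#' any target pass rate can be read off directly: the cumulative fraction at
#' value v equals the GAI a standard gamma comparison would report with the
#' free criterion set to v. Unreachable points never enter the cumulative
#' fraction, so it tops out below 100% when any point is unreachable.
#'
#' @param req_map a `requirement_map`.
#' @return a data frame with columns `value`, `count`, `cum_count`,
#'   `cum_gai_pct`, plus attributes `n_included` and `n_unreachable`.
#' @export
requirement_histogram <- function(req_map) {
  if (!inherits(req_map, "requirement_map"))
    stop("'req_map' must be a requirement_map")
  vals <- req_map$values[req_map$included_mask]
  if (!length(vals)) stop("empty requirement map")
  n <- length(vals)
  fin <- sort(vals[is.finite(vals)])
  if (length(fin)) {
    uv <- unique(fin)
    cnt <- as.integer(tabulate(match(fin, uv)))
    cum <- cumsum(cnt)
    out <- data.frame(value = uv, count = cnt, cum_count = cum,
                      cum_gai_pct = 100 * cum / n)
  } else {
    out <- data.frame(value = numeric(0), count = integer(0),
                      cum_count = integer(0), cum_gai_pct = numeric(0))
  }
  attr(out, "n_included") <- n
  attr(out, "n_unreachable") <- sum(!is.finite(vals))
  out
}

#' @export
print.requirement_map <- function(x, ...) {
  unit <- switch(x$kind, min_dta_mm = "mm", min_dd_pct = "%",
                 min_scale = "mm (ratio-linked)")
  vals <- x$values[x$included_mask]
  fin <- vals[is.finite(vals)]
  cat(sprintf("requirement map (%s), fixed value %g\n", x$kind, x$fixed))
  cat(sprintf("  %d included points, %d unreachable\n",
              length(vals), sum(!is.finite(vals))))
  if (length(fin))
    cat(sprintf("  requirement range [%.4g, %.4g] %s, median %.4g\n",
                min(fin), max(fin), unit, stats::median(fin)))
  invisible(x)
}

#' @export
plot.requirement_map <- function(x, ...) {
  z <- x$values
  z[!is.finite(z)] <- NA
  graphics::image(seq_len(nrow(z)), seq_len(ncol(z)), z,
                  col = grDevices::hcl.colors(64, "Spectral", rev = TRUE),
                  xlab = "i", ylab = "j",
                  main = sprintf("requirement map (%s)", x$kind),
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

#' @export
print.ig_result <- function(x, ...) {
  cat(sprintf("inverse gamma search (%s), target GAI %g%%\n",
              x$mode, x$target_gai_pct))
  lab <- switch(x$mode,
    fixed_dd = sprintf("fixed dd %g%%", x$fixed_value),
    fixed_dta = sprintf("fixed dta %g mm", x$fixed_value),
    fixed_ratio = sprintf("fixed ratio %g %%/mm", x$fixed_value))
  cat(sprintf("  %s; status: %s after %d iterations\n",
              lab, x$status, x$n_iterations))
  if (x$status == "converged") {
    cat(sprintf("  found: dta %.4g mm, dd %.4g%%\n",
                x$found_dta_mm, x$found_dd_pct))
  }
  cat(sprintf("  achieved GAI %.3f%% (%d of %d points needed)\n",
              x$achieved_gai_pct, x$target_count, x$n_included))
  invisible(x)
}
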