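#' Gamma acceptance criteria
#'
#' The parameters of a gamma comparison: the dose-difference criterion
#' \eqn{\Delta D} (percent of the normalization dose, global normalization),
#' the distance-to-agreement criterion \eqn{\Delta d} (mm), and the lower
#' dose threshold (LDT) below which reference points are excluded from
#' analysis. A point agrees when its gamma value is less than or equal to
#' `pass_threshold` (1.0, inclusive).
#'
#' @param dd_pct dose difference criterion \eqn{\Delta D}, percent of the
#'   normalization dose; must be > 0.
#' @param dta_mm distance-to-agreement criterion \eqn{\Delta d} in mm;
#'   must be >= 0. `dta_mm = 0` degenerates to a pure dose-difference test
#'   against co-located evaluated samples (the first iterate of the inverse
#'   gamma search).
#' @param ldt_pct lower dose threshold, percent of the normalization dose, in
#'   `[0, 100)`. Reference points with dose >= the threshold dose are
#'   included (inclusive comparison, so a uniform field is fully included).
#' @param normalization normalization mode; only `"global"` (percent of the
#'   global maximum dose) is supported.
#' @param pass_threshold gamma cutoff, fixed at 1.0.
#' @return an object of class `gamma_criteria`.
#' @examples
#' gamma_criteria(3, 2, 5)  # the common clinical 3%/2 mm, 5% LDT
#' @export
gamma_criteria <- function(dd_pct = 3, dta_mm = 2, ldt_pct = 5,
                           normalization = "global", pass_threshold = 1.0) {
  normalization <- match.arg(normalization, "global")
  if (!is.numeric(dd_pct) || length(dd_pct) != 1L || !is.finite(dd_pct) ||
      dd_pct <= 0)
    stop("'dd_pct' must be a single value > 0")
  if (!is.numeric(dta_mm) || length(dta_mm) != 1L || !is.finite(dta_mm) ||
      dta_mm < 0)
    stop("'dta_mm' must be a single value >= 0")
  if (!is.numeric(ldt_pct) || length(ldt_pct) != 1L || ldt_pct < 0 ||
      ldt_pct >= 100)
    stop("'ldt_pct' must lie in [0, 100)")
  if (!identical(as.numeric(pass_threshold), 1.0))
    stop("'pass_threshold' is fixed at 1.0")
  structure(
    list(dd_pct = as.numeric(dd_pct), dta_mm = as.numeric(dta_mm),
         ldt_pct = as.numeric(ldt_pct), normalization = normalization,
         pass_threshold = 1.0),
    class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("gamma criteria: %g%% / %g mm, LDT %g%% (%s normalization)\n",
              x$dd_pct, x$dta_mm, x$ldt_pct, x$normalization))
  invisible(x)
}

#' Search and interpolation settings
#'
#' Numerical settings shared by the gamma engine and the inverse-gamma
#' searches: the criterion increments, the search caps, the resampling step
#' for the evaluated grid, and the candidate-search radius factor used when
#' full gamma maps (not just pass/fail) are requested.
#'
#' @param dta_step_mm increment of the distance-to-agreement search, mm
#'   (default 0.1: the inverse search raises \eqn{\Delta d} from 0 in 0.1 mm
#'   steps).
#' @param dd_step_pct increment of the dose-criterion search, percent
#'   (default 0.1, by analogy with the 0.1 mm distance step).
#' @param max_dta_mm cap of the distance search, mm. Points whose requirement
#'   exceeds the cap are reported as unreachable; a search that hits the cap
#'   stops with status `cap_reached`.
#' @param max_dd_pct cap of the dose-criterion search, percent.
#' @param interp_step_mm target spacing, mm, onto which the evaluated grid is
#'   bilinearly resampled before the candidate search. Must not exceed the
#'   evaluated grid's native spacing; equal to it, the grid is left
#'   untouched.
#' @param radius_factor when full gamma values are reported, candidates are
#'   searched to `radius_factor * dta_mm`, so values up to `radius_factor`
#'   are exact and larger ones are censored lower bounds. Pass/fail and the
#'   GAI only ever need radius `dta_mm`.
#' @return an object of class `search_settings`.
#' @export
search_settings <- function(dta_step_mm = 0.1, dd_step_pct = 0.1,
                            max_dta_mm = 20, max_dd_pct = 20,
                            interp_step_mm = 0.2, radius_factor = 3) {
  vals <- c(dta_step_mm, dd_step_pct, max_dta_mm, max_dd_pct,
            interp_step_mm, radius_factor)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all search settings must be finite and > 0")
  if (max_dta_mm < dta_step_mm || max_dd_pct < dd_step_pct)
    stop("search caps must be at least one step")
  structure(
    list(dta_step_mm = dta_step_mm, dd_step_pct = dd_step_pct,
         max_dta_mm = max_dta_mm, max_dd_pct = max_dd_pct,
         interp_step_mm = interp_step_mm, radius_factor = radius_factor),
    class = "search_settings")
}

#' @export
print.search_settings <- function(x, ...) {
  cat(sprintf(paste0(
    "search settings: steps %g mm / %g%%, caps %g mm / %g%%, ",
    "interp %g mm, radius factor %g\n"),
    x$dta_step_mm, x$dd_step_pct, x$max_dta_mm, x$max_dd_pct,
    x$interp_step_mm, x$radius_factor))
  invisible(x)
}
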