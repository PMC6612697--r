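#' Planar dose grid
#'
#' A `dose_grid` holds a 2D scalar absorbed-dose field sampled on a regular
#' grid. Element `values[i, j]` sits at the physical position
#' `(origin[1] + (i - 1) * spacing[1], origin[2] + (j - 1) * spacing[2])`,
#' in mm; positions refer to element (detector / voxel) centres, so shifting
#' the origin is a pure spatial translation. Dose units are not interpreted:
#' under global normalization only ratios to the maximum dose matter, so any
#' consistent unit (Gy, cGy, relative) is accepted.
#'
#' @param values numeric matrix of doses; rows index x, columns index y.
#'   All values must be finite and non-negative.
#' @param spacing grid spacing `(dx, dy)` in mm, both > 0. A single value is
#'   recycled.
#' @param origin physical position `(x0, y0)` in mm of the centre of
#'   `values[1, 1]`.
#' @param unit free-text dose unit label (metadata only).
#' @param validate if `FALSE`, skip invariant checks (used internally to
#'   construct deliberately invalid grids for [validate_pair()] testing).
#'
#' @return an object of class `dose_grid`: a list with elements `values`,
#'   `spacing`, `origin`, `unit`.
#' @seealso [grid_x()], [validate_pair()], [read_dose_grid()]
#' @examples
#' g <- dose_grid(matrix(100, 5, 5), spacing = c(1, 1), origin = c(-2, -2))
#' grid_x(g)
#' @export
dose_grid <- function(values, spacing = c(1, 1), origin = c(0, 0),
                      unit = "Gy", validate = TRUE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  storage.mode(values) <- "double"
  spacing <- rep_len(as.numeric(spacing), 2L)
  origin <- rep_len(as.numeric(origin), 2L)
  g <- structure(
    list(values = values, spacing = spacing, origin = origin,
         unit = as.character(unit)[1L]),
    class = "dose_grid")
  if (validate) .check_grid(g)
  g
}

.check_grid <- function(g) {
  if (!all(is.finite(g$spacing)) || any(g$spacing <= 0))
    stop("invalid spacing: dx and dy must be finite and > 0")
  if (!all(is.finite(g$origin)))
    stop("invalid origin: must be finite")
  if (!all(is.finite(g$values)))
    stop("invalid dose value: all doses must be finite")
  if (any(g$values < 0))
    stop("invalid dose value: doses must be non-negative")
  invisible(g)
}

.is_dose_grid <- function(x) inherits(x, "dose_grid")

#' Grid axis positions
#'
#' Physical x (or y) coordinates, in mm, of the element centres of a
#' [dose_grid()].
#'
#' @param grid a `dose_grid`.
#' @return numeric vector of positions in mm.
#' @export
grid_x <- function(grid) {
  grid$origin[1L] + (seq_len(nrow(grid$values)) - 1) * grid$spacing[1L]
}

#' @rdname grid_x
#' @export
grid_y <- function(grid) {
  grid$origin[2L] + (seq_len(ncol(grid$values)) - 1) * grid$spacing[2L]
}

# bounding box c(xmin, xmax, ymin, ymax) of element centres
.grid_bbox <- function(grid) {
  xs <- grid_x(grid); ys <- grid_y(grid)
  c(xs[1L], xs[length(xs)], ys[1L], ys[length(ys)])
}

#' Validate a reference / evaluated grid pair
#'
#' Checks that the two distributions can be meaningfully compared: doses are
#' finite and the grids overlap spatially (their bounding boxes, the
#' evaluated one enlarged by `margin_mm`, intersect). Comparing disjoint
#' fields is always a setup error, not a 0% pass rate.
#'
#' @param reference,evaluated `dose_grid` objects.
#' @param margin_mm extra margin, in mm, added around the evaluated grid's
#'   bounding box before the overlap test.
#' @return invisibly, `list(reference, evaluated)` unchanged.
#' @export
validate_pair <- function(reference, evaluated, margin_mm = 0) {
  if (!.is_dose_grid(reference) || !.is_dose_grid(evaluated))
    stop("'reference' and 'evaluated' must be dose_grid objects")
  if (!all(is.finite(reference$values)) || !all(is.finite(evaluated$values)))
    stop("invalid dose value: non-finite dose in input grid")
  rb <- .grid_bbox(reference)
  eb <- .grid_bbox(evaluated) + c(-margin_mm, margin_mm, -margin_mm, margin_mm)
  if (rb[2L] < eb[1L] || rb[1L] > eb[2L] || rb[4L] < eb[3L] || rb[3L] > eb[4L])
    stop("no spatial overlap between reference and evaluated grids")
  invisible(list(reference = reference, evaluated = evaluated))
}

#' @export
print.dose_grid <- function(x, ...) {
  bb <- .grid_bbox(x)
  cat(sprintf("dose_grid: %d x %d, spacing %.4g x %.4g mm\n",
              nrow(x$values), ncol(x$values), x$spacing[1L], x$spacing[2L]))
  cat(sprintf("  extent x [%.4g, %.4g] mm, y [%.4g, %.4g] mm\n",
              bb[1L], bb[2L], bb[3L], bb[4L]))
  cat(sprintf("  dose range [%.6g, %.6g] %s\n",
              min(x$values), max(x$values), x$unit))
  invisible(x)
}

#' @export
plot.dose_grid <- function(x, main = "dose", ...) {
  graphics::image(grid_x(x), grid_y(x), x$values,
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (mm)", ylab = "y (mm)", main = main,
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}
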