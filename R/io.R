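#' Read and write the dose-grid TSV format
#'
#' A plain-text interchange format for planar dose grids: a header block of
#' `key<TAB>value` lines (`format_version`, `nx`, `ny`, `dx_mm`, `dy_mm`,
#' `origin_x_mm`, `origin_y_mm`, `dose_unit`), a blank line, then `ny` rows
#' of `nx` tab-separated dose values; row j holds constant y with x
#' increasing along the row. Values are written with 17 significant digits,
#' so a write/read round trip reproduces the grid bit-identically.
#'
#' @param path file path.
#' @return `read_dose_grid` returns a [dose_grid()]; `write_dose_grid`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' write_dose_grid(square_field(extent_mm = 20, field_width_mm = 12), f)
#' g <- read_dose_grid(f)
#' @export
read_dose_grid <- function(path) {
  lines <- readLines(path)
  blank <- which(lines == "")
  if (!length(blank)) stop("malformed grid file: no blank line after header")
  hend <- blank[1L]
  header <- lines[seq_len(hend - 1L)]
  parts <- strsplit(header, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != 2L)
  if (length(bad))
    stop(sprintf("malformed header at line %d: expected 'key<TAB>value'",
                 bad[1L]))
  keys <- vapply(parts, `[[`, "", 1L)
  vals <- vapply(parts, `[[`, "", 2L)
  need <- c("format_version", "nx", "ny", "dx_mm", "dy_mm",
            "origin_x_mm", "origin_y_mm", "dose_unit")
  missing_keys <- setdiff(need, keys)
  if (length(missing_keys))
    stop("missing header key(s): ", paste(missing_keys, collapse = ", "))
  h <- stats::setNames(as.list(vals), keys)
  num <- function(key) {
    v <- suppressWarnings(as.numeric(h[[key]]))
    if (is.na(v))
      stop(sprintf("non-numeric header value for '%s' (line %d)",
                   key, which(keys == key)[1L]))
    v
  }
  nx <- as.integer(num("nx")); ny <- as.integer(num("ny"))
  dx <- num("dx_mm"); dy <- num("dy_mm")
  if (!is.finite(dx) || !is.finite(dy) || dx <= 0 || dy <= 0)
    stop("invalid spacing in header: dx_mm and dy_mm must be > 0")
  if (nx < 1L || ny < 1L) stop("invalid dimensions in header")

  rows <- lines[seq.int(hend + 1L, length.out = length(lines) - hend)]
  while (length(rows) && rows[length(rows)] == "")   # tolerate trailing blanks
    rows <- rows[-length(rows)]
  if (length(rows) < ny)
    stop(sprintf("matrix row count mismatch: header declares ny = %d but only %d data rows found (after line %d)",
                 ny, length(rows), hend))
  vals_m <- matrix(NA_real_, nx, ny)
  for (j in seq_len(ny)) {
    cells <- strsplit(rows[j], "\t", fixed = TRUE)[[1L]]
    if (length(cells) != nx)
      stop(sprintf("matrix width mismatch at line %d: expected %d values, found %d",
                   hend + j, nx, length(cells)))
    v <- suppressWarnings(as.numeric(cells))
    if (anyNA(v))
      stop(sprintf("non-numeric dose value at line %d", hend + j))
    vals_m[, j] <- v
  }
  dose_grid(vals_m, spacing = c(dx, dy),
            origin = c(num("origin_x_mm"), num("origin_y_mm")),
            unit = h[["dose_unit"]])
}

#' @rdname read_dose_grid
#' @param grid a [dose_grid()] to serialize.
#' @export
write_dose_grid <- function(grid, path) {
  if (!.is_dose_grid(grid)) stop("'grid' must be a dose_grid")
  fmt <- function(x) sprintf("%.17g", x)
  header <- c(
    paste0("format_version\t1"),
    paste0("nx\t", nrow(grid$values)),
    paste0("ny\t", ncol(grid$values)),
    paste0("dx_mm\t", fmt(grid$spacing[1L])),
    paste0("dy_mm\t", fmt(grid$spacing[2L])),
    paste0("origin_x_mm\t", fmt(grid$origin[1L])),
    paste0("origin_y_mm\t", fmt(grid$origin[2L])),
    paste0("dose_unit\t", grid$unit))
  rows <- apply(grid$values, 2L, function(col) paste(fmt(col), collapse = "\t"))
  writeLines(c(header, "", rows), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Minimal DICOM RT Dose reader (little-endian explicit or implicit VR).
# Only the attributes needed to build a planar dose grid are interpreted;
# everything else, including sequences, is skipped.

.dcm_u16 <- function(raw) readBin(raw, "integer", length(raw) / 2, 2,
                                  signed = FALSE, endian = "little")
.dcm_u32 <- function(raw) {
  v <- readBin(raw, "integer", length(raw) / 4, 4, endian = "little")
  v[v < 0] <- v[v < 0] + 2^32
  v
}
.dcm_str <- function(raw) trimws(rawToChar(raw[raw != as.raw(0)]))

# read one element header; returns NULL at EOF
.dcm_elem <- function(con, explicit) {
  grp <- readBin(con, "integer", 1, 2, signed = FALSE, endian = "little")
  if (!length(grp)) return(NULL)
  ele <- readBin(con, "integer", 1, 2, signed = FALSE, endian = "little")
  vr <- ""
  if (explicit && grp != 0xFFFE) {
    vr <- rawToChar(readBin(con, "raw", 2))
    if (vr %in% c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")) {
      readBin(con, "raw", 2)
      len <- .dcm_u32(readBin(con, "raw", 4))
    } else {
      len <- readBin(con, "integer", 1, 2, signed = FALSE, endian = "little")
    }
  } else {
    len <- .dcm_u32(readBin(con, "raw", 4))
  }
  list(grp = grp, ele = ele, vr = vr, len = len)
}

# skip an undefined-length value (sequence or item) up to its delimiter
.dcm_skip_undef <- function(con, explicit, delim_ele) {
  repeat {
    e <- .dcm_elem(con, explicit)
    if (is.null(e)) stop("truncated DICOM sequence")
    if (e$grp == 0xFFFE && e$ele == delim_ele) return(invisible())
    if (e$len == 4294967295) {
      nested <- if (e$grp == 0xFFFE) 0xE00D else 0xE0DD
      .dcm_skip_undef(con, explicit, nested)
    } else if (e$len > 0) {
      readBin(con, "raw", e$len)
    }
  }
}

#' Read a DICOM RT Dose plane
#'
#' Extracts a planar dose distribution from a DICOM RT Dose object: pixel
#' data scaled by the dose grid scaling factor, spacing from the pixel
#' spacing and origin from the image position. Supports little-endian
#' explicit- and implicit-VR transfer syntaxes and uncompressed 16- or
#' 32-bit unsigned pixel data; the image is assumed axis-aligned.
#' Multi-frame objects require a `frame` index.
#'
#' @param path path to a DICOM RT Dose file.
#' @param frame frame index (1-based) for multi-frame dose objects.
#' @return a [dose_grid()].
#' @export
read_rtdose <- function(path, frame = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  pre <- readBin(con, "raw", 132)
  if (length(pre) < 132 || rawToChar(pre[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker)")

  ts <- "1.2.840.10008.1.2.1"
  repeat {
    e <- .dcm_elem(con, explicit = TRUE)
    if (is.null(e)) stop("truncated DICOM file meta header")
    if (e$grp != 0x0002) {
      # first dataset element read with the wrong assumption; rewind it
      seek(con, -ifelse(e$vr %in% c("OB", "OW", "OF", "OD", "OL", "SQ",
                                    "UC", "UR", "UT", "UN"), 12L, 8L),
           origin = "current")
      break
    }
    val <- readBin(con, "raw", e$len)
    if (e$ele == 0x0010) ts <- .dcm_str(val)
  }
  explicit <- switch(ts,
    "1.2.840.10008.1.2.1" = TRUE,
    "1.2.840.10008.1.2" = FALSE,
    stop("unsupported DICOM transfer syntax: ", ts))

  att <- list(bits = 16L, nframes = 1L)
  repeat {
    e <- .dcm_elem(con, explicit)
    if (is.null(e)) break
    tag <- sprintf("%04X%04X", e$grp, e$ele)
    if (e$len == 4294967295) {
      .dcm_skip_undef(con, explicit, 0xE0DD)
      next
    }
    val <- if (e$len > 0) readBin(con, "raw", e$len) else raw(0)
    switch(tag,
      "00080060" = att$modality <- .dcm_str(val),
      "00200032" = att$ipp <- as.numeric(strsplit(.dcm_str(val), "\\\\")[[1L]]),
      "00280008" = att$nframes <- as.integer(.dcm_str(val)),
      "00280010" = att$rows <- .dcm_u16(val),
      "00280011" = att$cols <- .dcm_u16(val),
      "00280030" = att$spacing <- as.numeric(strsplit(.dcm_str(val), "\\\\")[[1L]]),
      "00280100" = att$bits <- .dcm_u16(val),
      "3004000E" = att$scaling <- as.numeric(.dcm_str(val)),
      "7FE00010" = att$pixels <- val,
      NULL)
  }
  if (is.null(att$modality) || !identical(att$modality, "RTDOSE"))
    stop("not an RT Dose object (modality: ",
         if (is.null(att$modality)) "absent" else att$modality, ")")
  for (k in c("rows", "cols", "spacing", "scaling", "pixels"))
    if (is.null(att[[k]]))
      stop("missing required RT Dose attribute: ", k)
  px <- if (att$bits == 16L) .dcm_u16(att$pixels) else
    if (att$bits == 32L) .dcm_u32(att$pixels) else
      stop("unsupported bits allocated: ", att$bits)
  per_frame <- att$rows * att$cols
  if (att$nframes > 1L) {
    if (is.null(frame))
      stop("multi-frame RT Dose: supply a frame index (--frame)")
    if (frame < 1L || frame > att$nframes) stop("frame index out of range")
    px <- px[seq.int((frame - 1L) * per_frame + 1L, length.out = per_frame)]
  } else {
    px <- px[seq_len(per_frame)]
  }
  # pixel data is row-major over image rows (y); columns index x
  vals <- matrix(px * att$scaling, nrow = att$cols)
  origin <- if (!is.null(att$ipp)) att$ipp[1:2] else c(0, 0)
  # PixelSpacing is (row spacing, column spacing) = (dy, dx)
  dose_grid(vals, spacing = c(att$spacing[2L], att$spacing[1L]),
            origin = origin, unit = "Gy")
}
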