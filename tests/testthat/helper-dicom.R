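# Builds a minimal synthetic DICOM RT Dose byte stream (explicit VR little
# endian, 16-bit unsigned pixels) for exercising read_rtdose(). Synthetic:
# contains only the attributes the reader needs, in ascending tag order.
write_min_rtdose <- function(path, values, spacing = c(1, 1),
                             origin = c(0, 0), scaling = 1e-3,
                             modality = "RTDOSE", nframes = 1L) {
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                              endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                              endian = "little")
  pad_even <- function(s) if (nchar(s) %% 2) paste0(s, " ") else s
  elem_str <- function(grp, ele, vr, s) {
    s <- pad_even(s)
    c(u16(grp), u16(ele), charToRaw(vr), u16(nchar(s)), charToRaw(s))
  }
  elem_us <- function(grp, ele, v)
    c(u16(grp), u16(ele), charToRaw("US"), u16(2L), u16(v))
  elem_ow <- function(grp, ele, raw_payload)
    c(u16(grp), u16(ele), charToRaw("OW"), as.raw(c(0, 0)),
      u32(length(raw_payload)), raw_payload)

  nx <- nrow(values)  # columns of the image (x)
  ny <- ncol(values)  # rows of the image (y)
  # pixel data: row-major over image rows (y); one frame repeated if needed
  px_int <- as.integer(round(as.vector(values) / scaling))
  stopifnot(all(px_int >= 0), all(px_int < 65536))
  payload <- do.call(c, replicate(nframes, u16(px_int), simplify = FALSE))

  meta_body <- elem_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  meta <- c(u16(0x0002), u16(0x0000), charToRaw("UL"), u16(4L),
            u32(length(meta_body)), meta_body)

  ds <- c(
    elem_str(0x0008, 0x0060, "CS", modality),
    elem_str(0x0020, 0x0032, "DS",
             sprintf("%.6f\\%.6f\\0.0", origin[1], origin[2])))
  if (nframes > 1L)
    ds <- c(ds, elem_str(0x0028, 0x0008, "IS", as.character(nframes)))
  ds <- c(ds,
    elem_us(0x0028, 0x0010, ny),                       # Rows (y)
    elem_us(0x0028, 0x0011, nx),                       # Columns (x)
    elem_str(0x0028, 0x0030, "DS",
             sprintf("%.6f\\%.6f", spacing[2], spacing[1])),  # row\col = dy\dx
    elem_us(0x0028, 0x0100, 16L),                      # BitsAllocated
    elem_us(0x0028, 0x0103, 0L),                       # PixelRepresentation
    elem_str(0x3004, 0x000E, "DS", sprintf("%.9g", scaling)),
    elem_ow(0x7FE0, 0x0010, payload))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
  invisible(path)
}
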