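# Test-only minimal DICOM slice writer (explicit VR little endian) used
# to build series fixtures for the reader; the package itself never
# writes DICOM.

write_test_dicom_slice <- function(path, pixels, ipp, iop,
                                   pixel_spacing = c(1, 1)) {
  stopifnot(is.matrix(pixels))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, nchars = 4, eos = NULL)
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  elem_str <- function(group, element, vr, value) {
    value <- as.character(value)
    if (nchar(value) %% 2 == 1) value <- paste0(value, " ")
    w16(group); w16(element)
    writeChar(vr, con, nchars = 2, eos = NULL)
    w16(nchar(value))
    writeChar(value, con, nchars = nchar(value), eos = NULL)
  }
  elem_us <- function(group, element, value) {
    w16(group); w16(element)
    writeChar("US", con, nchars = 2, eos = NULL)
    w16(2); w16(value)
  }
  # elements must appear in increasing tag order
  elem_str(0x0020, 0x0032, "DS", paste(ipp, collapse = "\\"))
  elem_str(0x0020, 0x0037, "DS", paste(iop, collapse = "\\"))
  elem_us(0x0028, 0x0010, nrow(t(pixels)))        # Rows
  elem_us(0x0028, 0x0011, nrow(pixels))           # Columns
  elem_str(0x0028, 0x0030, "DS",
           paste(rev(pixel_spacing), collapse = "\\"))
  elem_us(0x0028, 0x0100, 16)                     # BitsAllocated
  elem_us(0x0028, 0x0103, 0)                      # unsigned
  # PixelData, OW with 4-byte length
  w16(0x7FE0); w16(0x0010)
  writeChar("OW", con, nchars = 2, eos = NULL)
  w16(0)
  writeBin(as.integer(2 * length(pixels)), con, size = 4, endian = "little")
  # row-major stream: columns fastest; pixels is (x = col, y = row)
  writeBin(as.integer(as.vector(pixels)), con, size = 2, endian = "little")
  invisible(path)
}

# write a small synthetic axial series; returns the directory
write_test_dicom_series <- function(dir, nx = 8, ny = 6, nz = 4,
                                    spacing = c(2, 3), zsp = 4,
                                    shuffle = FALSE, break_orient = FALSE,
                                    break_spacing = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vals <- array(seq_len(nx * ny * nz) %% 4000L, c(nx, ny, nz))
  ord <- seq_len(nz)
  if (shuffle) ord <- rev(ord)
  for (pos in seq_len(nz)) {
    k <- ord[pos]
    iop <- c(1, 0, 0, 0, 1, 0)
    if (break_orient && k == 2) iop <- c(0, 1, 0, -1, 0, 0)
    z <- (k - 1) * zsp
    if (break_spacing && k == nz) z <- z + 1.5
    write_test_dicom_slice(file.path(dir, sprintf("sl%02d.dcm", pos)),
                           vals[, , k], ipp = c(0, 0, z), iop = iop,
                           pixel_spacing = spacing)
  }
  attr(dir, "truth") <- vals
  dir
}
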