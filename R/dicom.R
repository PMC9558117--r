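# Minimal DICOM series reader (read-only).
#
# Supports single-frame axial series in explicit-VR little-endian transfer
# syntax with unsigned 16-bit pixels, which covers exported MR series.
# Only the geometry and pixel tags needed to assemble a volume are
# interpreted; everything else is skipped structurally.

dicom_tag <- function(group, element) sprintf("%04X,%04X", group, element)

DICOM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one DICOM file into a named list of the tags we care about.
parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  out <- list()
  u16 <- function(at) readBin(raw[at:(at + 1)], "integer", size = 2,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(raw[at:(at + 3)], "integer", size = 4,
                              endian = "little")
  wanted <- c("0020,0032", "0020,0037", "0028,0010", "0028,0011",
              "0028,0030", "0028,0100", "0028,0103", "0028,1052",
              "0028,1053", "7FE0,0010")
  while (pos + 7 <= length(raw)) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported (implicit VR?) DICOM encoding in ", path)
    if (vr %in% DICOM_LONG_VRS) {
      len <- u32(pos + 8L); vstart <- pos + 12L
    } else {
      len <- u16(pos + 6L); vstart <- pos + 8L
    }
    if (len < 0) stop("undefined-length DICOM element unsupported in ", path)
    tag <- dicom_tag(group, element)
    if (tag %in% wanted) {
      bytes <- if (len > 0) raw[vstart:(vstart + len - 1L)] else raw(0)
      out[[tag]] <- list(vr = vr, bytes = bytes)
    }
    pos <- vstart + len
    if (tag == "7FE0,0010") break
  }
  out
}

dicom_numeric <- function(el) {
  if (is.null(el)) return(NULL)
  if (el$vr %in% c("DS", "IS"))
    as.numeric(strsplit(trimws(rawToChar(el$bytes)), "\\\\")[[1]])
  else if (el$vr == "US")
    readBin(el$bytes, "integer", n = length(el$bytes) / 2, size = 2,
            signed = FALSE, endian = "little")
  else stop("unexpected VR ", el$vr)
}

#' Read a DICOM series as a volume
#'
#' Assembles the single-frame files in `dir` into one `volume_grid`.
#' Slices are sorted by their position along the slice normal (the cross
#' product of the row and column direction cosines), so shuffled file
#' names still yield a monotone, correctly ordered stack.  Mixed in-plane
#' orientations or inconsistent slice spacing abort with an error.
#'
#' @param dir directory containing one DICOM series.
#' @return a `volume_grid`.
#' @export
read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory: ", dir)
  slices <- lapply(files, parse_dicom_file)
  iop <- lapply(slices, function(s) dicom_numeric(s[["0020,0037"]]))
  ipp <- lapply(slices, function(s) dicom_numeric(s[["0020,0032"]]))
  if (any(vapply(iop, is.null, TRUE)) || any(vapply(ipp, is.null, TRUE)))
    stop("DICOM series lacks geometry tags (0020,0032 / 0020,0037)")
  iop0 <- iop[[1]]
  for (o in iop)
    if (max(abs(o - iop0)) > 1e-4)
      stop("mixed-orientation DICOM series rejected")
  rowdir <- iop0[1:3]; coldir <- iop0[4:6]
  normal <- c(rowdir[2] * coldir[3] - rowdir[3] * coldir[2],
              rowdir[3] * coldir[1] - rowdir[1] * coldir[3],
              rowdir[1] * coldir[2] - rowdir[2] * coldir[1])
  proj <- vapply(ipp, function(p) sum(p * normal), 0.0)
  ord <- order(proj)
  slices <- slices[ord]; ipp <- ipp[ord]; proj <- proj[ord]
  if (length(slices) > 1) {
    dz <- diff(proj)
    if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-3)
      stop("inconsistent slice spacing in DICOM series")
    zsp <- mean(dz)
  } else zsp <- 1
  s1 <- slices[[1]]
  rows <- dicom_numeric(s1[["0028,0010"]])
  cols <- dicom_numeric(s1[["0028,0011"]])
  ps <- dicom_numeric(s1[["0028,0030"]])  # (row spacing, column spacing)
  bits <- dicom_numeric(s1[["0028,0100"]])
  if (is.null(bits) || bits != 16) stop("only 16-bit DICOM pixels supported")
  slope <- dicom_numeric(s1[["0028,1053"]]); if (is.null(slope)) slope <- 1
  inter <- dicom_numeric(s1[["0028,1052"]]); if (is.null(inter)) inter <- 0
  data <- array(0, c(cols, rows, length(slices)))
  for (k in seq_along(slices)) {
    px <- slices[[k]][["7FE0,0010"]]
    if (is.null(px)) stop("missing pixel data in DICOM slice ", k)
    v <- readBin(px$bytes, "integer", n = rows * cols, size = 2,
                 signed = FALSE, endian = "little")
    # pixel stream is row-major (columns fastest) -> dim1 = column index
    data[, , k] <- matrix(as.double(v) * slope + inter, nrow = cols)
  }
  direction <- cbind(rowdir, coldir, normal)
  volume_grid(data, spacing = c(ps[2], ps[1], zsp), origin = ipp[[1]],
              direction = direction)
}
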