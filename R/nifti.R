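# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package is assumed to be available, so the fixed 348-byte
# NIfTI-1 header is read and written directly.  Voxel data are stored as
# float64 so that write -> read round trips are bit exact.  Geometry is
# carried in the sform rows.  Files ending in .gz are transparently
# (de)compressed.  Little-endian and byte-swapped files are both read.

NIFTI_TYPES <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                    `4` = list(what = "integer", size = 2, signed = TRUE),
                    `8` = list(what = "integer", size = 4, signed = TRUE),
                    `16` = list(what = "double", size = 4, signed = TRUE),
                    `64` = list(what = "double", size = 8, signed = TRUE))

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a volume as NIfTI-1
#'
#' @param grid a `volume_grid`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(grid, path) {
  stopifnot(is_volume_grid(grid))
  con <- tryCatch(nifti_connection(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  d <- dim(grid$data)
  A <- grid_affine(grid)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x, size = 4) writeBin(as.numeric(x), con, size = size, endian = "little")
  wc <- function(n) writeBin(raw(n), con)
  wi(348, 4)                      # sizeof_hdr
  wc(10 + 18 + 4 + 2 + 1 + 1)     # data_type..dim_info
  wi(c(3, d, 1, 1, 1, 1), 2)      # dim[8]
  wf(c(0, 0, 0))                  # intent_p1..p3
  wi(0, 2)                        # intent_code
  wi(64, 2)                       # datatype: float64
  wi(64, 2)                       # bitpix
  wi(0, 2)                        # slice_start
  wf(c(1, grid$spacing, 0, 0, 0, 0))  # pixdim[8], qfac = 1
  wf(352)                         # vox_offset
  wf(1)                           # scl_slope
  wf(0)                           # scl_inter
  wi(0, 2)                        # slice_end
  wc(1)                           # slice_code
  writeBin(as.raw(2L), con)       # xyzt_units: mm
  wf(c(0, 0, 0, 0))               # cal_max, cal_min, slice_duration, toffset
  wi(c(0, 0), 4)                  # glmax, glmin
  wc(80 + 24)                     # descrip, aux_file
  wi(0, 2)                        # qform_code
  wi(1, 2)                        # sform_code
  wf(c(0, 0, 0, 0, 0, 0))        # quaternion fields (unused)
  wf(A[1, ])                      # srow_x
  wf(A[2, ])                      # srow_y
  wf(A[3, ])                      # srow_z
  wc(16)                          # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  wc(1)
  wf(0)                           # 4-byte extension flag (no extensions)
  writeBin(as.numeric(grid$data), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a `volume_grid`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("not a NIfTI-1 file (truncated header): ", path)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sz != 348) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (sz != 348) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  ri <- function(off, n, size) readBin(hdr[(off + 1):(off + n * size)],
                                       "integer", n = n, size = size,
                                       endian = endian)
  rf <- function(off, n) readBin(hdr[(off + 1):(off + n * 4)], "double",
                                 n = n, size = 4, endian = endian)
  dim8 <- ri(40, 8, 2)
  if (dim8[1] < 3) dim8[(dim8[1] + 2):8] <- 1
  d <- dim8[2:4]
  datatype <- ri(70, 1, 2)
  ty <- NIFTI_TYPES[[as.character(datatype)]]
  if (is.null(ty)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108, 1)
  scl_slope <- rf(112, 1)
  scl_inter <- rf(116, 1)
  sform_code <- ri(254, 1, 2)
  srow <- matrix(rf(280, 12), nrow = 3, byrow = TRUE)
  nt <- max(1L, prod(dim8[5:(dim8[1] + 1)][dim8[5:(dim8[1] + 1)] > 0], 1L))
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  nvox <- prod(d) * nt
  vals <- readBin(con, ty$what, n = nvox, size = ty$size,
                  signed = ty$signed, endian = endian)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  if (nt > 1) vals <- vals[seq_len(prod(d))]  # first volume only
  spacing <- pixdim[2:4]
  if (any(spacing <= 0)) spacing[spacing <= 0] <- 1
  if (sform_code > 0) {
    spacing <- sqrt(colSums(srow[, 1:3]^2))
    direction <- sweep(srow[, 1:3], 2, spacing, "/")
    origin <- srow[, 4]
  } else {
    direction <- diag(3)
    origin <- c(0, 0, 0)
  }
  volume_grid(array(vals, d), spacing = spacing, origin = origin,
              direction = direction)
}
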