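#' @useDynLib prostacad, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm pnorm qnorm rnorm runif kmeans optim pbinom pchisq qbeta rbinom sd
#' @importFrom utils modifyList
NULL

# ---------------------------------------------------------------------------
# VolumeGrid: a 3D scalar image with geometry.
#
# Array convention (used consistently across the package):
#   dim 1 (i / x): in-plane, +x is the patient's LEFT
#   dim 2 (j / y): in-plane, +y is POSTERIOR
#   dim 3 (k / z): axial slice index; slices are ordered cranial -> caudal,
#                  so a SMALLER slice index is MORE CRANIAL (closer to the
#                  prostate base, which sits superiorly under the bladder).
# World coordinates are voxel-center based: world = origin + direction %*%
# diag(spacing) %*% (index - 1)  with 1-based indices.
# ---------------------------------------------------------------------------

#' Construct a volume grid
#'
#' A `volume_grid` bundles a 3D voxel array with its geometry (voxel
#' spacing in mm, world origin of the first voxel center, and a 3x3
#' direction matrix whose columns are the world directions of the voxel
#' axes).  One `volume_grid` holds one MRI sequence or one mask.
#'
#' @param data numeric 3D array, dim `(nx, ny, nz)`.
#' @param spacing numeric length-3, voxel spacing in mm along (x, y, z).
#' @param origin numeric length-3, world coordinates (mm) of voxel (1,1,1).
#' @param direction 3x3 matrix of unit column vectors (defaults to identity).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing, origin = c(0, 0, 0),
                        direction = diag(3)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("volume data must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive numbers")
  origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  if (!all(dim(direction) == c(3L, 3L)))
    stop("direction must be a 3x3 matrix")
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "volume_grid")
}

#' @export
is_volume_grid <- function(x) inherits(x, "volume_grid")

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid", paste(dim(x$data), collapse = " x "),
      "| spacing", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' Voxel-to-world affine of a grid
#'
#' @param grid a `volume_grid`.
#' @return 4x4 matrix mapping 0-based voxel indices (homogeneous) to world mm.
#' @export
grid_affine <- function(grid) {
  A <- diag(4)
  A[1:3, 1:3] <- grid$direction %*% diag(grid$spacing)
  A[1:3, 4] <- grid$origin
  A
}

#' Do two grids share the same geometry?
#'
#' @param a,b `volume_grid` objects.
#' @param tol numeric tolerance on affine entries (mm).
#' @export
same_geometry <- function(a, b, tol = 1e-4) {
  all(dim(a$data) == dim(b$data)) &&
    max(abs(grid_affine(a) - grid_affine(b))) < tol
}

#' Replace the voxel data of a grid, keeping its geometry
#' @param grid a `volume_grid`.
#' @param data replacement array of identical dimensions.
#' @export
with_data <- function(grid, data) {
  data <- as.array(data)
  stopifnot(all(dim(data) == dim(grid$data)))
  grid$data <- data
  grid
}

#' Coerce voxel data to a strict 0/1 mask
#' @param grid a `volume_grid` holding approximately binary values.
#' @export
as_mask <- function(grid) {
  with_data(grid, array(as.double(grid$data > 0.5), dim(grid$data)))
}

#' Volume of one voxel in mm^3
#' @param grid a `volume_grid`.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

# World coordinate arrays of all voxel centers.  Because the affine is
# linear, each coordinate separates into three per-axis vectors, which keeps
# this cheap even for rotated (deranged) grids.
world_coordinate_arrays <- function(grid) {
  A <- grid_affine(grid)
  d <- dim(grid$data)
  ii <- seq_len(d[1]) - 1
  jj <- seq_len(d[2]) - 1
  kk <- seq_len(d[3]) - 1
  coord <- function(r) {
    v <- outer(A[r, 1] * ii, A[r, 2] * jj, "+")
    arr <- array(v, d) # recycled along z
    arr + rep(A[r, 3] * kk + A[r, 4], each = d[1] * d[2])
  }
  list(x = coord(1), y = coord(2), z = coord(3))
}

# Bounding box of a nonzero mask: list(lo, hi) of 1-based index triples.
mask_bbox <- function(mask_data) {
  w <- which(mask_data > 0.5, arr.ind = TRUE)
  if (nrow(w) == 0L) return(NULL)
  list(lo = apply(w, 2, min), hi = apply(w, 2, max))
}
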