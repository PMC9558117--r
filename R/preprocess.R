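# Preprocessing chain: header-based rigid registration (resampling onto the
# ADC/DWI grid), K-means prostate localization on high-b DWI, in-plane
# cropping to a fixed patch, [0,1] normalization, and training-time
# augmentation (mirror / small rotation / additive noise).

#' Registration specification
#'
#' Describes how one volume is resampled onto the grid of another using
#' the rigid world transforms stored in the image headers.  Images use
#' third-order B-spline interpolation; binary masks use Gaussian label
#' interpolation (Gaussian smoothing of the indicator, linear resampling,
#' then thresholding), which keeps the result binary.
#'
#' @param source,target `volume_grid` objects; the output lies on
#'   `target`'s grid.
#' @param order interpolation order for images: 0, 1 or 3 (default 3).
#' @param label_sigma Gaussian smoothing width for masks (voxels).
#' @param label_threshold relabel threshold after smoothing.
#' @return An object of class `registration_spec`.
#' @export
registration_spec <- function(source, target, order = 3L,
                              label_sigma = 0.5, label_threshold = 0.5) {
  stopifnot(is_volume_grid(source), is_volume_grid(target), order >= 0)
  src_aff <- grid_affine(source)
  tgt_aff <- grid_affine(target)
  if (abs(det(src_aff)) < 1e-12 || abs(det(tgt_aff)) < 1e-12)
    stop("non-invertible grid transform")
  structure(list(source_affine = src_aff, target_affine = tgt_aff,
                 target_dim = dim(target$data),
                 target_spacing = target$spacing,
                 target_origin = target$origin,
                 target_direction = target$direction,
                 order = as.integer(order), label_sigma = label_sigma,
                 label_threshold = label_threshold),
            class = "registration_spec")
}

#' Resample a volume onto a target grid
#'
#' @param source a `volume_grid` sharing `spec`'s source geometry.
#' @param spec a `registration_spec`.
#' @param is_label resample as a binary mask (Gaussian label interpolation)?
#' @return a `volume_grid` on the target grid.
#' @export
resample_to_grid <- function(source, spec, is_label = FALSE) {
  stopifnot(inherits(spec, "registration_spec"))
  # voxel(target, 0-based) -> world -> voxel(source, 0-based)
  M <- solve(spec$source_affine) %*% spec$target_affine
  arr <- source$data
  if (is_label) {
    arr <- .cpp_gaussian3d(array(as.double(arr > 0.5), dim(arr)),
                           rep(spec$label_sigma, 3))
    out <- .cpp_resample3d(arr, M, as.integer(spec$target_dim), 1L, 0)
    out <- array(as.double(out > spec$label_threshold), spec$target_dim)
  } else {
    if (spec$order == 3L) arr <- .cpp_bspline_prefilter3d(arr)
    out <- .cpp_resample3d(arr, M, as.integer(spec$target_dim),
                           spec$order, 0)
  }
  volume_grid(out, spacing = spec$target_spacing,
              origin = spec$target_origin,
              direction = spec$target_direction)
}

#' Localizer configuration
#'
#' Parameters of the coarse K-means prostate localizer run on high-b DWI.
#'
#' @param k number of intensity clusters (>= 2).
#' @param max_iter,tol K-means iteration controls.
#' @param open_radius morphological opening radius (voxels).
#' @param patch_size in-plane crop size in pixels.
#' @param margin_mm bounding-box dilation in mm.
#' @param seed RNG seed for centroid initialization.
#' @return An object of class `localizer_config`.
#' @export
localizer_config <- function(k = 2L, max_iter = 50L, tol = 1e-6,
                             open_radius = 1L, patch_size = 128L,
                             margin_mm = 5, seed = 1L) {
  stopifnot(k >= 2, patch_size > 0)
  structure(list(k = as.integer(k), max_iter = as.integer(max_iter),
                 tol = tol, open_radius = as.integer(open_radius),
                 patch_size = as.integer(patch_size), margin_mm = margin_mm,
                 seed = as.integer(seed)),
            class = "localizer_config")
}

#' Coarse prostate localization by K-means on high-b DWI
#'
#' Clusters voxel intensities (restricted to the central half of the field
#' of view, where the prostate sits) into `k` groups, keeps the brightest
#' cluster, cleans it with a morphological opening, retains the largest
#' 26-connected component and returns its bounding box dilated by the
#' configured margin, together with the coarse mask.
#'
#' @param high_b `volume_grid` of the high-b-value DWI.
#' @param cfg a `localizer_config`.
#' @return list with `box` (list `lo`, `hi`, 1-based voxel indices) and
#'   `mask` (a `volume_grid`).
#' @export
localize_prostate <- function(high_b, cfg = localizer_config()) {
  arr <- high_b$data
  d <- dim(arr)
  if (max(arr) - min(arr) < 1e-12)
    stop("localization failed: constant volume")
  cx <- seq.int(floor(d[1] / 4) + 1, ceiling(3 * d[1] / 4))
  cy <- seq.int(floor(d[2] / 4) + 1, ceiling(3 * d[2] / 4))
  central <- array(FALSE, d)
  central[cx, cy, ] <- TRUE
  vals <- arr[central]
  if (max(vals) - min(vals) < 1e-12)
    stop("localization failed: constant central region")
  set.seed(cfg$seed)
  km <- kmeans(vals, centers = cfg$k, iter.max = cfg$max_iter, nstart = 3)
  bright <- which.max(km$centers)
  mask <- array(0L, d)
  mask[central][km$cluster == bright] <- 1L
  if (cfg$open_radius > 0) {
    mask <- .cpp_morph3d(mask, cfg$open_radius, 0L)
    mask <- .cpp_morph3d(mask, cfg$open_radius, 1L)
  }
  if (sum(mask) == 0L)
    stop("localization failed: bright cluster empty after cleanup")
  lab <- .cpp_cc3d(mask, 26L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  comp <- array(as.double(lab == keep), d)
  bb <- mask_bbox(comp)
  margin_vox <- ceiling(cfg$margin_mm / high_b$spacing)
  bb$lo <- pmax(bb$lo - margin_vox, 1)
  bb$hi <- pmin(bb$hi + margin_vox, d)
  list(box = bb, mask = with_data(high_b, comp))
}

#' Crop an in-plane patch around a bounding box
#'
#' Extracts, from every axial slice, a `size` x `size` patch centered on
#' the in-plane centroid of `box`, zero-padding outside the volume.  The
#' inverse placement is recorded so patch-space predictions can be mapped
#' back to the original grid losslessly with [uncrop_patch()].
#'
#' @param volume a `volume_grid`.
#' @param box bounding box as returned by [localize_prostate()].
#' @param size patch edge length in pixels.
#' @return a `volume_grid` of dim `(size, size, nz)` with attribute
#'   `placement`.
#' @export
crop_patch <- function(volume, box, size = 128L) {
  d <- dim(volume$data)
  cx <- floor((box$lo[1] + box$hi[1]) / 2)
  cy <- floor((box$lo[2] + box$hi[2]) / 2)
  x0 <- cx - size %/% 2L + 1L   # first original x index inside the patch
  y0 <- cy - size %/% 2L + 1L
  out <- array(0, c(size, size, d[3]))
  sx <- max(x0, 1L):min(x0 + size - 1L, d[1])
  sy <- max(y0, 1L):min(y0 + size - 1L, d[2])
  out[sx - x0 + 1L, sy - y0 + 1L, ] <- volume$data[sx, sy, ]
  placement <- list(x0 = x0, y0 = y0, size = as.integer(size),
                    orig_dim = d, spacing = volume$spacing,
                    origin = volume$origin, direction = volume$direction)
  new_origin <- as.numeric(grid_affine(volume) %*%
                             c(x0 - 1, y0 - 1, 0, 1))[1:3]
  g <- volume_grid(out, spacing = volume$spacing, origin = new_origin,
                   direction = volume$direction)
  attr(g, "placement") <- placement
  g
}

#' Map a patch-space volume back onto the original grid
#'
#' @param patch a `volume_grid` (or plain array) in patch space.
#' @param placement the `placement` attribute recorded by [crop_patch()].
#' @return a `volume_grid` on the original grid (zero outside the patch
#'   footprint).
#' @export
uncrop_patch <- function(patch, placement) {
  arr <- if (is_volume_grid(patch)) patch$data else patch
  d <- placement$orig_dim
  size <- placement$size
  out <- array(0, d)
  sx <- max(placement$x0, 1L):min(placement$x0 + size - 1L, d[1])
  sy <- max(placement$y0, 1L):min(placement$y0 + size - 1L, d[2])
  out[sx, sy, ] <- arr[sx - placement$x0 + 1L, sy - placement$y0 + 1L, ]
  volume_grid(out, spacing = placement$spacing, origin = placement$origin,
              direction = placement$direction)
}

#' Min-max normalize a patch into [0, 1]
#'
#' Per-patient, per-sequence scaling over the cropped region.  A constant
#' patch maps to all zeros (guarded division).
#'
#' @param patch a `volume_grid`.
#' @return a `volume_grid` with values in `[0, 1]`.
#' @export
normalize_patch <- function(patch) {
  arr <- patch$data
  lo <- min(arr); hi <- max(arr)
  if (hi - lo < 1e-12) return(with_data(patch, array(0, dim(arr))))
  with_data(patch, (arr - lo) / (hi - lo))
}

#' Augmentation configuration
#'
#' @param mirror_prob probability of a left-right mirror.
#' @param rotation_deg rotation bound in degrees (angle drawn uniformly in
#'   `[-rotation_deg, +rotation_deg]`).
#' @param noise_bound additive-noise bound as an intensity fraction; each
#'   pixel fluctuates uniformly within this amount.
#' @param seed optional RNG seed.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(mirror_prob = 0.5, rotation_deg = 10,
                           noise_bound = 0.001, seed = NULL) {
  stopifnot(rotation_deg >= 0, noise_bound >= 0)
  structure(list(mirror_prob = mirror_prob, rotation_deg = rotation_deg,
                 noise_bound = noise_bound, seed = seed),
            class = "augment_config")
}

rotate_slices <- function(arr, angle_deg, order) {
  d <- dim(arr)
  theta <- angle_deg * pi / 180
  cx <- (d[1] - 1) / 2
  cy <- (d[2] - 1) / 2
  # target voxel -> source voxel: rotate about the patch center
  M <- diag(4)
  M[1, 1] <- cos(theta); M[1, 2] <- -sin(theta)
  M[2, 1] <- sin(theta); M[2, 2] <- cos(theta)
  M[1, 4] <- cx - M[1, 1] * cx - M[1, 2] * cy
  M[2, 4] <- cy - M[2, 1] * cx - M[2, 2] * cy
  src <- if (order == 3L) .cpp_bspline_prefilter3d(arr) else arr
  .cpp_resample3d(src, M, as.integer(d), as.integer(order), 0)
}

#' Augment an image stack and its masks identically
#'
#' Applies one random draw of (mirror, rotation) to all images and masks,
#' and adds bounded uniform noise to the images only.  Masks are rotated
#' with nearest-neighbour interpolation and therefore stay binary.
#'
#' @param images list of `volume_grid`s (or arrays) already normalized.
#' @param masks list of binary `volume_grid`s (or arrays), may be empty.
#' @param cfg an `augment_config`.
#' @param force optional list overriding the random draw
#'   (`mirror` logical, `angle` degrees) for reproducibility in tests.
#' @return list with `images`, `masks` (same container types as input) and
#'   the realized `draw`.
#' @export
augment_pair <- function(images, masks, cfg = augment_config(),
                         force = NULL) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  draw <- list(
    mirror = if (!is.null(force$mirror)) force$mirror
             else runif(1) < cfg$mirror_prob,
    angle = if (!is.null(force$angle)) force$angle
            else runif(1, -cfg$rotation_deg, cfg$rotation_deg))
  tf_arr <- function(x, is_mask) {
    arr <- if (is_volume_grid(x)) x$data else x
    if (draw$mirror) arr <- arr[rev(seq_len(dim(arr)[1])), , , drop = FALSE]
    if (abs(draw$angle) > 1e-12)
      arr <- rotate_slices(arr, draw$angle, if (is_mask) 0L else 3L)
    if (is_mask) arr <- array(as.double(arr > 0.5), dim(arr))
    else if (cfg$noise_bound > 0)
      arr <- arr + runif(length(arr), -cfg$noise_bound, cfg$noise_bound)
    if (is_volume_grid(x)) with_data(x, arr) else arr
  }
  list(images = lapply(images, tf_arr, is_mask = FALSE),
       masks = lapply(masks, tf_arr, is_mask = TRUE),
       draw = draw)
}

#' Preprocess one patient case
#'
#' Full chain: (1) resample T2WI onto the ADC grid using the header
#' transforms, (2) localize the prostate on high-b DWI, (3) crop all
#' sequences and masks to the in-plane patch, (4) normalize images into
#' [0, 1].  Ground-truth masks are cropped with plain indexing (no
#' resampling: they already live on the ADC grid).
#'
#' @param case a `patient_case`.
#' @param loc_cfg a `localizer_config`.
#' @return the case with added fields `adc_p`, `t2_p`, `hb_p` (normalized
#'   patches), cropped masks (`gland_p`, `pz_p`, `cg_p`, per-lesion), the
#'   crop `placement`, and the localizer output.
#' @export
preprocess_case <- function(case, loc_cfg = localizer_config()) {
  reg <- registration_spec(case$t2, case$adc)
  t2_reg <- if (same_geometry(case$t2, case$adc)) case$t2
            else resample_to_grid(case$t2, reg, is_label = FALSE)
  loc <- localize_prostate(case$hb, loc_cfg)
  size <- loc_cfg$patch_size
  crop <- function(vol) crop_patch(vol, loc$box, size)
  adc_p <- crop(case$adc)
  placement <- attr(adc_p, "placement")
  case$adc_p <- normalize_patch(adc_p)
  case$t2_p <- normalize_patch(crop(t2_reg))
  case$hb_p <- normalize_patch(crop(case$hb))
  case$gland_p <- as_mask(crop(case$gland))
  case$pz_p <- as_mask(crop(case$pz))
  case$cg_p <- as_mask(crop(case$cg))
  case$lesions_p <- lapply(case$lesions, function(l) as_mask(crop(l$mask)))
  case$placement <- placement
  case$localizer <- loc
  case
}
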