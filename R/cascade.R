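# The three-stage cascade: gland -> peripheral zone -> lesion.
#
# Stage 1 segments the whole gland from the image channels; stage 2 takes
# the images plus the gland mask and segments the PZ (clipped to the
# gland); the central gland is the set difference CG = gland \ PZ; stage 3
# takes the images plus both zone masks and segments the lesion.  The
# ADC-only and biparametric variants differ only in the image channel
# stack.

#' Cascade specification
#'
#' @param variant `"bp"` (ADC + T2WI) or `"adc"` (ADC only).
#' @param net_specs list of three `network_spec`s (stage 1..3); their
#'   `in_channels` are overridden to match the variant and stage.
#' @param threshold pixel classification threshold on the probability
#'   maps (default 0.5).
#' @param constrain_to_gland intersect predicted lesions with the
#'   predicted gland mask?
#' @param min_lesion_volume smallest retained lesion component (mm^3).
#' @return An object of class `cascade_spec`.
#' @export
cascade_spec <- function(variant = c("bp", "adc"),
                         net_specs = NULL,
                         threshold = 0.5,
                         constrain_to_gland = TRUE,
                         min_lesion_volume = 25) {
  variant <- match.arg(variant)
  if (is.null(net_specs))
    net_specs <- lapply(1:3, function(i) network_spec(1L, depth = 4L,
                                                      base_width = 32L))
  stopifnot(length(net_specs) == 3L)
  structure(list(variant = variant, net_specs = net_specs,
                 threshold = threshold,
                 constrain_to_gland = constrain_to_gland,
                 min_lesion_volume = min_lesion_volume),
            class = "cascade_spec")
}

#' Input channel count of a cascade stage
#'
#' Image channels (2 for biparametric, 1 for ADC-only) plus the
#' conditioning mask channels: none for stage 1, the gland mask for
#' stage 2, and the PZ + CG masks for stage 3.
#'
#' @param spec a `cascade_spec`.
#' @param stage 1, 2 or 3.
#' @export
stage_in_channels <- function(spec, stage) {
  n_img <- if (spec$variant == "bp") 2L else 1L
  n_img + c(0L, 1L, 2L)[stage]
}

#' Train all three stages of the cascade
#'
#' @param cases,val_cases preprocessed training/validation cases.
#' @param spec a `cascade_spec`.
#' @param cfg a `train_config`.
#' @return list of three stage results (see [train_stage()]).
#' @export
train_cascade <- function(cases, spec, cfg = train_config(),
                          val_cases = NULL) {
  lapply(1:3, function(stage)
    train_stage(stage, cases, spec, cfg, val_cases = val_cases))
}

slices_forward <- function(net, chans, threshold) {
  d <- dim(chans[[1]])
  x <- array(0, c(d[1], d[2], length(chans), d[3]))
  for (c in seq_along(chans)) x[, , c, ] <- chans[[c]]
  p <- forward_network(net, x, training = FALSE)$p
  array(p[, , 1, ], d)
}

#' Run the cascade on one preprocessed case
#'
#' Produces gland, PZ and CG masks and the csPCa probability map /
#' thresholded lesion mask, applies the configured post-filters
#' (gland intersection, minimum component volume) and maps everything
#' back onto the original ADC grid through the recorded crop placement.
#'
#' @param case a preprocessed `patient_case` (see [preprocess_case()]).
#' @param nets list of three trained `resunet`s (or a checkpoint
#'   directory written by [save_checkpoint()] with stems `stage1..3`).
#' @param spec the `cascade_spec` used in training.
#' @return list with patch-space masks (`gland`, `pz`, `cg`, `lesion`,
#'   `prob`), full-grid volumes (`gland_full`, ..., `prob_full`),
#'   `components` (lesion components on the ADC grid) and
#'   `patient_positive`.
#' @export
infer_case <- function(case, nets, spec) {
  if (is.character(nets)) {
    dirn <- nets
    nets <- lapply(1:3, function(s) {
      stem <- file.path(dirn, sprintf("stage%d", s))
      load_checkpoint(stem, expect_channels = stage_in_channels(spec, s))
    })
  }
  if (length(nets) != 3L || any(vapply(nets, is.null, TRUE)))
    stop("cascade inference needs checkpoints for stages 1, 2 and 3")
  thr <- spec$threshold
  imgs <- if (spec$variant == "bp") list(case$adc_p$data, case$t2_p$data)
          else list(case$adc_p$data)
  gland_p <- slices_forward(nets[[1]], imgs, thr)
  gland <- array(as.double(gland_p > thr), dim(gland_p))
  pz_p <- slices_forward(nets[[2]], c(imgs, list(gland)), thr)
  pz <- array(as.double(pz_p > thr), dim(pz_p)) * gland  # PZ within gland
  cg <- gland * (1 - pz)                                  # CG = gland \ PZ
  les_p <- slices_forward(nets[[3]], c(imgs, list(pz), list(cg)), thr)
  lesion <- array(as.double(les_p > thr), dim(les_p))
  if (isTRUE(spec$constrain_to_gland)) lesion <- lesion * gland
  pl <- case$placement
  to_full <- function(arr) uncrop_patch(arr, pl)
  lesion_full <- to_full(lesion)
  comps <- extract_components(lesion_full, connectivity = 26L,
                              min_volume = spec$min_lesion_volume)
  # rebuild the filtered lesion mask from the retained components
  keep <- array(0, dim(lesion_full$data))
  for (cmp in comps) keep[cmp$voxels] <- 1
  lesion_full <- with_data(lesion_full, keep)
  list(gland = gland, pz = pz, cg = cg, lesion = lesion, prob = les_p,
       gland_full = to_full(gland), pz_full = to_full(pz),
       cg_full = to_full(cg), lesion_full = lesion_full,
       prob_full = to_full(les_p),
       components = comps,
       patient_positive = length(comps) > 0)
}

#' Extract 3D lesion components from a binary mask
#'
#' Labels the mask (26-connectivity by default), discards components
#' below the minimum physical volume, and summarizes each survivor.
#'
#' @param mask a `volume_grid` holding a 0/1 mask, or a plain array (then
#'   `spacing` must be given).
#' @param connectivity 6 or 26.
#' @param min_volume minimum component volume in mm^3.
#' @param spacing voxel spacing when `mask` is a plain array.
#' @return list of components, each with `voxels` (linear indices),
#'   `n_vox`, `volume_mm3`, `bbox` (`lo`/`hi` index triples),
#'   `slice_areas` (voxel counts per axial slice), `dim` and `spacing`.
#' @export
extract_components <- function(mask, connectivity = 26L, min_volume = 0,
                               spacing = NULL) {
  if (is_volume_grid(mask)) {
    spacing <- mask$spacing
    arr <- mask$data
  } else arr <- mask
  if (is.null(spacing)) stop("spacing required for a plain-array mask")
  stopifnot(connectivity %in% c(6L, 26L))
  d <- dim(arr)
  lab <- .cpp_cc3d(array(as.integer(arr > 0.5), d), as.integer(connectivity))
  nlab <- max(lab)
  vv <- prod(spacing)
  out <- list()
  for (l in seq_len(nlab)) {
    vox <- which(lab == l)
    vol <- length(vox) * vv
    if (vol < min_volume) next
    ar <- arrayInd(vox, d)
    areas <- table(factor(ar[, 3], levels = seq_len(d[3])))
    out[[length(out) + 1L]] <- list(
      voxels = vox, n_vox = length(vox), volume_mm3 = vol,
      bbox = list(lo = apply(ar, 2, min), hi = apply(ar, 2, max)),
      slice_areas = as.integer(areas), dim = d, spacing = spacing)
  }
  out
}
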