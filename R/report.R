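# Structured-report output: sextant partitioning of the gland, lesion
# sextant localization, 3D diameters, key image selection, and a
# machine-readable JSON report.

SEXTANT_LABELS <- c("left-base", "left-mid", "left-apex",
                    "right-base", "right-mid", "right-apex")

#' Partition a gland mask into six sextants
#'
#' Standard sextant scheme: a left/right split by the sagittal plane
#' through the gland centroid, crossed with base/mid/apex bands dividing
#' the gland's occupied craniocaudal span into three equal-thickness
#' slabs.  Slices are stored cranial-first, so the base (superior) band
#' has the smallest slice indices.
#'
#' @param gland a `volume_grid` holding the gland mask.
#' @return An object of class `sextant_map`: `masks` (list of six
#'   `volume_grid`s), `labels`, `voxel_counts`.
#' @export
partition_sextants <- function(gland) {
  arr <- gland$data
  d <- dim(arr)
  w <- which(arr > 0.5, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("empty gland mask")
  zs <- sort(unique(w[, 3]))
  if (length(zs) < 3L)
    stop("gland occupies fewer than 3 slices; cannot form sextant bands")
  cx <- mean(w[, 1])
  # +x is patient left; band 1 = base (most cranial = smallest indices)
  z0 <- min(zs); z1 <- max(zs)
  band_of <- function(z) pmin(3L, 1L + ((z - z0) * 3L) %/% (z1 - z0 + 1L))
  masks <- list(); counts <- integer(0)
  for (lat in c("left", "right")) for (bd in 1:3) {
    sel <- if (lat == "left") w[, 1] > cx else w[, 1] <= cx
    sel <- sel & band_of(w[, 3]) == bd
    m <- array(0, d)
    m[w[sel, , drop = FALSE]] <- 1
    lbl <- paste0(lat, "-", c("base", "mid", "apex")[bd])
    masks[[lbl]] <- with_data(gland, m)
    counts[lbl] <- sum(sel)
  }
  masks <- masks[SEXTANT_LABELS]
  structure(list(masks = masks, labels = SEXTANT_LABELS,
                 voxel_counts = counts[SEXTANT_LABELS]),
            class = "sextant_map")
}

#' Validate that a sextant map partitions the gland
#' @param sm a `sextant_map`.
#' @export
validate_sextant_map <- function(sm) {
  stopifnot(inherits(sm, "sextant_map"), length(sm$masks) == 6L)
  tot <- Reduce(`+`, lapply(sm$masks, function(m) m$data))
  if (any(tot > 1)) stop("sextants overlap")
  invisible(TRUE)
}

#' Axis-aligned 3D diameters of a mask
#'
#' Extents of the mask's bounding box in mm along the three anatomical
#' axes: left-right, anterior-posterior, craniocaudal.  Each extent is
#' `(index span + 1) * spacing` so a single voxel reports one voxel's
#' footprint.
#'
#' @param mask a `volume_grid` 0/1 mask (or component from
#'   [extract_components()]).
#' @return named numeric: `lr`, `ap`, `cc`, `greatest` (mm).
#' @export
diameters_3d <- function(mask) {
  if (is_volume_grid(mask)) {
    bb <- mask_bbox(mask$data)
    spacing <- mask$spacing
  } else {
    bb <- mask$bbox
    spacing <- mask$spacing
  }
  if (is.null(bb)) stop("empty mask has no diameters")
  ext <- (bb$hi - bb$lo + 1) * spacing
  c(lr = unname(ext[1]), ap = unname(ext[2]), cc = unname(ext[3]),
    greatest = max(ext))
}

#' Select the key image slice of a lesion
#'
#' The axial slice with maximal lesion cross-sectional area; ties break
#' toward the more cranial slice (smaller index, cranial-first storage).
#' The raster is the ADC slice with the lesion's boundary voxels marked.
#'
#' @param adc the ADC `volume_grid`.
#' @param comp a lesion component from [extract_components()].
#' @return list with `slice` (index), `raster` (2D matrix), `contour`
#'   (2D 0/1 matrix of boundary pixels in the slice).
#' @export
select_key_image <- function(adc, comp) {
  areas <- comp$slice_areas
  if (all(areas == 0)) stop("empty lesion")
  slice <- which.max(areas)  # which.max takes the first (most cranial) tie
  d <- comp$dim
  mask2d <- matrix(0, d[1], d[2])
  onk <- comp$voxels[(comp$voxels - 1) %/% (d[1] * d[2]) + 1 == slice]
  ij <- arrayInd(onk, d)
  mask2d[ij[, 1:2]] <- 1
  # boundary: lesion pixels with at least one 4-neighbour outside
  pad <- matrix(0, d[1] + 2, d[2] + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1)] <- mask2d
  nb <- pad[1:d[1], 2:(d[2] + 1)] * pad[3:(d[1] + 2), 2:(d[2] + 1)] *
    pad[2:(d[1] + 1), 1:d[2]] * pad[2:(d[1] + 1), 3:(d[2] + 2)]
  contour <- mask2d * (nb == 0)
  list(slice = slice, raster = adc$data[, , slice], contour = contour)
}

#' Build the structured report for one case
#'
#' Machine-readable summary of the cascade output: patient status
#' ("csPCa" / "non-csPCa"), gland 3D diameters, and per-lesion diameters,
#' volume, sextant labels (via the sextant containment rule, so report
#' and metrics never disagree) and key-image slice, plus a sector map of
#' six booleans.
#'
#' @param case the (preprocessed) `patient_case`.
#' @param inference output of [infer_case()].
#' @param sextant_map a `sextant_map` on the predicted gland (built if
#'   `NULL`).
#' @param cfg a `match_rule_config` for the sextant rule.
#' @return An object of class `structured_report` (a list that
#'   serializes to schema-valid JSON via [write_report()]).
#' @export
build_report <- function(case, inference, sextant_map = NULL,
                         cfg = match_rule_config()) {
  if (is.null(sextant_map))
    sextant_map <- partition_sextants(inference$gland_full)
  comps <- inference$components
  status <- if (length(comps) > 0) "csPCa" else "non-csPCa"
  gland_d <- diameters_3d(inference$gland_full)
  sector <- stats::setNames(rep(FALSE, 6L), sextant_map$labels)
  lesions <- lapply(seq_along(comps), function(i) {
    cmp <- comps[[i]]
    hits <- sextant_hits(cmp, sextant_map, cfg)
    if (!any(hits)) {
      # degenerate tiny lesion: fall back to the sextant holding most of it
      ov <- vapply(sextant_map$masks, function(sx)
        length(intersect(cmp$voxels, which(sx$data > 0.5))), 0L)
      hits[which.max(ov)] <- TRUE
    }
    sector[hits] <<- TRUE
    key <- select_key_image(case$adc, cmp)
    dm <- diameters_3d(cmp)
    list(index = i,
         diameters_mm = as.list(dm[c("lr", "ap", "cc")]),
         greatest_dimension_mm = unname(dm[["greatest"]]),
         volume_mm3 = cmp$volume_mm3,
         sextants = sextant_map$labels[hits],
         key_slice = key$slice)
  })
  rep <- structure(list(
    patient_id = case$id,
    status = status,
    gland_diameters_mm = as.list(gland_d[c("lr", "ap", "cc")]),
    lesions = lesions,
    sector_map = as.list(sector)), class = "structured_report")
  validate_report(rep)
  rep
}

#' Validate a structured report against its schema
#' @param rep a `structured_report`.
#' @export
validate_report <- function(rep) {
  if (!all(c("patient_id", "status", "gland_diameters_mm", "lesions",
             "sector_map") %in% names(rep)))
    stop("report missing required fields")
  if (!rep$status %in% c("csPCa", "non-csPCa"))
    stop("invalid status: ", rep$status)
  if (rep$status == "non-csPCa" && length(rep$lesions) > 0)
    stop("non-csPCa report must have an empty lesion list")
  if (!identical(sort(names(rep$sector_map)), sort(SEXTANT_LABELS)))
    stop("sector map must carry exactly the six sextant labels")
  for (l in rep$lesions)
    if (length(l$sextants) < 1) stop("lesion without sextant label")
  invisible(TRUE)
}

#' Write / read a structured report as JSON
#'
#' @param rep a `structured_report`.
#' @param path output JSON path.
#' @export
write_report <- function(rep, path) {
  validate_report(rep)
  jsonlite::write_json(unclass(rep), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path)
  rep$lesions <- lapply(rep$lesions, function(l) {
    l$sextants <- as.character(unlist(l$sextants))
    l
  })
  structure(rep, class = "structured_report")
}

#' Write a key image as a plain-text PGM raster
#'
#' Portable graymap (P2, ASCII) with the lesion contour burned in at
#' maximum intensity; text-only so it travels anywhere.
#'
#' @param key output of [select_key_image()].
#' @param path output path (`.pgm`).
#' @export
write_key_image <- function(key, path) {
  r <- key$raster
  lo <- min(r); hi <- max(r)
  g <- if (hi > lo) round(254 * (r - lo) / (hi - lo)) else r * 0
  g[key$contour > 0.5] <- 255
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(nrow(g), ncol(g)), "255"), con)
  # PGM is row-major top-to-bottom; write y as rows
  for (j in seq_len(ncol(g)))
    writeLines(paste(g[, j], collapse = " "), con)
  invisible(path)
}
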