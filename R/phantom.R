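# Synthetic biparametric prostate MRI phantom generator.
#
# Each phantom is an analytic scene -- a superellipsoidal gland split into a
# posterior peripheral-zone (PZ) shell and a central gland (CG), carrying
# 0-4 ellipsoidal lesions -- rendered onto voxel grids by evaluating the
# scene at voxel-center world coordinates.  Because the scene is analytic,
# the same patient can be rendered consistently on deliberately mismatched
# grids, which is how the registration stage is exercised.
#
# All defaults describe the cohort the package is calibrated to: 0.75 mm
# in-plane resolution (240 mm FOV / 320 matrix), 4 mm slices, per-patient
# lesion multiplicities 173:49:10:3 among positives (112/347 patients
# lesion-free), 212/313 of lesions in the PZ, and lesion greatest dimension
# 1.6 +/- 0.7 cm truncated below at 0.4 cm.

#' Phantom generator configuration
#'
#' Builds the configuration of the synthetic cohort generator.  Every
#' argument has a default describing the calibrated cohort; pass a smaller
#' `shape`/coarser `spacing` for fast test-scale phantoms.
#'
#' The lesion-size sampler is a truncated normal.  `lesion_dim_mean` and
#' `lesion_dim_sd` are the moments of the *truncated* distribution (the
#' quantity a cohort table reports); the underlying normal parameters are
#' solved for by moment matching at construction time.
#'
#' @param shape integer length-3 voxel counts `(nx, ny, nz)`.
#' @param spacing voxel spacing in mm.
#' @param gland_semiaxes_mean,gland_semiaxes_sd mm, per axis (x, y, z).
#' @param gland_exponent superellipsoid exponent (2 = ellipsoid).
#' @param pz_thickness_frac thickness of the posterior PZ shell as a
#'   fraction of the gland radius.
#' @param lesion_count_probs probabilities of 0..4 lesions per patient.
#' @param lesion_zone_p_pz probability that a lesion sits in the PZ.
#' @param lesion_dim_mean,lesion_dim_sd,lesion_dim_min greatest-dimension
#'   distribution in cm (truncated normal).
#' @param intensities named list per sequence (`adc`, `t2`, `hb`) of tissue
#'   means for `background`, `pz`, `cg`, `lesion` (arbitrary units).
#' @param noise_sd named additive Gaussian noise sd per sequence.
#' @param max_retries placement retries before giving up on a lesion.
#' @param seed integer seed fixing the full cohort.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(320, 320, 24),
                           spacing = c(0.75, 0.75, 4),
                           gland_semiaxes_mean = c(22, 17, 19),
                           gland_semiaxes_sd = c(2, 1.5, 2),
                           gland_exponent = 2.5,
                           pz_thickness_frac = 0.4,
                           lesion_count_probs = c(112, 173, 49, 10, 3) / 347,
                           lesion_zone_p_pz = 212 / 313,
                           lesion_dim_mean = 1.6,
                           lesion_dim_sd = 0.7,
                           lesion_dim_min = 0.4,
                           intensities = list(
                             adc = c(background = 400, pz = 1500, cg = 1150, lesion = 700),
                             t2  = c(background = 120, pz = 420, cg = 260, lesion = 190),
                             hb  = c(background = 60, pz = 190, cg = 165, lesion = 420)),
                           noise_sd = c(adc = 80, t2 = 25, hb = 15),
                           max_retries = 40L,
                           seed = 20220929L) {
  lesion_count_probs <- as.numeric(lesion_count_probs)
  if (length(lesion_count_probs) != 5L || any(lesion_count_probs < 0) ||
      abs(sum(lesion_count_probs) - 1) > 1e-8)
    stop("lesion_count_probs must be 5 non-negative values summing to 1")
  if (any(spacing <= 0) || any(gland_semiaxes_mean <= 0))
    stop("spacings and gland semi-axes must be strictly positive")
  if (lesion_zone_p_pz < 0 || lesion_zone_p_pz > 1)
    stop("lesion_zone_p_pz must be a probability")
  tn <- solve_truncnorm(lesion_dim_mean, lesion_dim_sd, lesion_dim_min)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 gland_semiaxes_mean = gland_semiaxes_mean,
                 gland_semiaxes_sd = gland_semiaxes_sd,
                 gland_exponent = gland_exponent,
                 pz_thickness_frac = pz_thickness_frac,
                 lesion_count_probs = lesion_count_probs,
                 lesion_zone_p_pz = lesion_zone_p_pz,
                 lesion_dim_mean = lesion_dim_mean,
                 lesion_dim_sd = lesion_dim_sd,
                 lesion_dim_min = lesion_dim_min,
                 lesion_dim_mu = tn$mu, lesion_dim_sigma = tn$sigma,
                 intensities = intensities, noise_sd = noise_sd,
                 max_retries = as.integer(max_retries),
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Solve for (mu, sigma) of a normal truncated below at `a` whose truncated
# moments are (m, s).  Closed-form truncated moments + BFGS.
solve_truncnorm <- function(m, s, a) {
  moments <- function(mu, sigma) {
    alpha <- (a - mu) / sigma
    lam <- dnorm(alpha) / (1 - pnorm(alpha))
    mean_t <- mu + sigma * lam
    var_t <- sigma^2 * (1 + alpha * lam - lam^2)
    c(mean_t, sqrt(max(var_t, 1e-12)))
  }
  obj <- function(p) {
    mo <- moments(p[1], exp(p[2]))
    (mo[1] - m)^2 + (mo[2] - s)^2
  }
  fit <- optim(c(m, log(s)), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  if (fit$value > 1e-8)
    stop("could not match truncated-normal moments for the lesion sizes")
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Sample lesion greatest dimensions (cm)
#'
#' Draws from the truncated normal lesion-size law of a `phantom_config`
#' (rejection sampling below the truncation point).
#'
#' @param n number of draws.
#' @param config a `phantom_config`.
#' @return numeric vector of `n` diameters in cm.
#' @export
sample_lesion_dims <- function(n, config) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- rnorm(n, config$lesion_dim_mu, config$lesion_dim_sigma)
    out <- c(out, d[d >= config$lesion_dim_min])
  }
  out[seq_len(n)]
}

# Superellipsoid "radius" of world points relative to a gland.
superellipsoid_rho <- function(xyz, center, semi, p) {
  ((abs(xyz$x - center[1]) / semi[1])^p +
   (abs(xyz$y - center[2]) / semi[2])^p +
   (abs(xyz$z - center[3]) / semi[3])^p)^(1 / p)
}

# Build the default (ADC-frame) grid of a config, centered on the origin.
config_grid <- function(config, data = NULL, origin_shift = c(0, 0, 0),
                        rotation_deg = 0) {
  d <- config$shape
  if (is.null(data)) data <- array(0, d)
  theta <- rotation_deg * pi / 180
  direction <- rbind(c(cos(theta), -sin(theta), 0),
                     c(sin(theta), cos(theta), 0),
                     c(0, 0, 1))
  extent <- (d - 1) * config$spacing
  origin <- -extent / 2 + origin_shift
  volume_grid(data, spacing = config$spacing, origin = origin,
              direction = direction)
}

# Analytic scene: gland geometry + lesion list (world-space ellipsoids).
# Renders a tissue label array on any grid: 0 bg, 1 CG, 2 PZ; lesions are
# rendered separately so multiplicity is preserved.
render_labels <- function(scene, grid) {
  xyz <- world_coordinate_arrays(grid)
  rho <- superellipsoid_rho(xyz, scene$center, scene$semi, scene$p)
  gland <- rho <= 1
  pz <- gland & rho >= (1 - scene$pz_frac) & (xyz$y - scene$center[2]) >
    -0.15 * scene$semi[2]
  lab <- array(0, dim(grid$data))
  lab[gland] <- 1
  lab[pz] <- 2
  lab
}

render_lesion <- function(lesion, grid) {
  xyz <- world_coordinate_arrays(grid)
  u <- xyz$x - lesion$center[1]
  v <- xyz$y - lesion$center[2]
  w <- xyz$z - lesion$center[3]
  ct <- cos(lesion$theta); st <- sin(lesion$theta)
  a1 <- ct * u + st * v      # major axis, in-plane
  a2 <- -st * u + ct * v
  inside <- (a1 / lesion$semi[1])^2 + (a2 / lesion$semi[2])^2 +
    (w / lesion$semi[3])^2 <= 1
  array(as.double(inside), dim(grid$data))
}

#' Render a single lesion as a standalone mask
#'
#' Renders an ellipsoidal lesion of greatest (in-plane) dimension `d_cm`
#' on a fresh grid just large enough to hold it; used to study how
#' voxelization affects measured diameters.
#'
#' @param d_cm greatest dimension in cm (major axis, oriented along x).
#' @param spacing voxel spacing in mm.
#' @param axis_ratios minor/major semi-axis ratios (in-plane, through-plane).
#' @return a `volume_grid` holding a 0/1 mask.
#' @export
render_lesion_mask <- function(d_cm, spacing = c(0.75, 0.75, 4),
                               axis_ratios = c(0.7, 0.55)) {
  stopifnot(d_cm > 0)
  semi <- c(d_cm * 10 / 2, d_cm * 10 / 2 * axis_ratios[1],
            d_cm * 10 / 2 * axis_ratios[2])
  d <- pmax(3L, as.integer(ceiling(2 * semi / spacing)) + 4L)
  d <- d + (1L - d %% 2L)  # odd sizes put a voxel center at the origin
  extent <- (d - 1) * spacing
  grid <- volume_grid(array(0, d), spacing = spacing, origin = -extent / 2)
  lesion <- list(center = c(0, 0, 0), semi = semi, theta = 0)
  with_data(grid, render_lesion(lesion, grid))
}

# Sample one lesion (zone, size, placement) inside the gland.  Placement
# candidates are drawn from the rendered zone mask; a candidate is accepted
# when the rendered lesion lies entirely inside the gland.
sample_lesion <- function(config, scene, gland_arr, zone_arr, grid) {
  zone_is_pz <- runif(1) < config$lesion_zone_p_pz
  target <- if (zone_is_pz) zone_arr == 2 else zone_arr == 1
  cand <- which(target)
  if (length(cand) == 0L) stop("requested lesion zone is empty")
  d_cm <- sample_lesion_dims(1, config)
  A <- grid_affine(grid)
  for (attempt in seq_len(config$max_retries)) {
    if (attempt > 1 && attempt %% 8 == 0) d_cm <- sample_lesion_dims(1, config)
    idx <- cand[[sample.int(length(cand), 1)]]
    d3 <- dim(grid$data)
    i <- (idx - 1) %% d3[1]
    j <- ((idx - 1) %/% d3[1]) %% d3[2]
    k <- (idx - 1) %/% (d3[1] * d3[2])
    center <- as.numeric(A %*% c(i, j, k, 1))[1:3]
    semi <- c(d_cm * 10 / 2, d_cm * 10 / 2 * 0.7, d_cm * 10 / 2 * 0.55)
    lesion <- list(center = center, semi = semi, theta = runif(1, 0, pi),
                   zone = if (zone_is_pz) "PZ" else "TZ", d_cm = d_cm)
    mask <- render_lesion(lesion, grid)
    if (sum(mask) >= 2 && all(gland_arr[mask > 0.5] > 0)) {
      lesion$mask <- mask
      return(lesion)
    }
  }
  stop("could not place a lesion of ", signif(d_cm, 3),
       " cm inside the gland after ", config$max_retries, " attempts")
}

#' Generate one synthetic patient
#'
#' Renders one complete biparametric case: T2WI, ADC and high-b DWI
#' volumes plus ground-truth gland / PZ / CG / lesion masks.  With
#' `deranged_geometry = TRUE` the T2WI is rendered on a shifted and
#' rotated grid so that header-based rigid registration has real work to
#' do; all masks always live on the ADC grid.
#'
#' @param config a `phantom_config`.
#' @param with_lesions if `FALSE`, force a lesion-free (non-csPCa) case.
#' @param deranged_geometry render T2WI on a mismatched grid.
#' @param id patient identifier.
#' @param n_lesions optional lesion-count override (otherwise drawn from
#'   `config$lesion_count_probs`).
#' @param seed optional seed; when given, the case is a deterministic
#'   function of `(config, seed)`.  When `NULL` the ambient RNG stream is
#'   used (as [sample_cohort()] does after seeding once).
#' @return An object of class `patient_case`.
#' @export
generate_patient <- function(config, with_lesions = TRUE,
                             deranged_geometry = FALSE, id = "pt0001",
                             n_lesions = NULL, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(seed)) set.seed(seed)
  semi <- pmax(rnorm(3, config$gland_semiaxes_mean, config$gland_semiaxes_sd),
               config$gland_semiaxes_mean * 0.6)
  scene <- list(center = c(0, 0, 0), semi = semi, p = config$gland_exponent,
                pz_frac = config$pz_thickness_frac)
  adc_grid <- config_grid(config)
  labels <- render_labels(scene, adc_grid)
  gland_arr <- array(as.double(labels > 0), dim(labels))
  if (!any(gland_arr > 0)) stop("gland fell outside the grid")
  if (is.null(n_lesions)) {
    n_lesions <- if (with_lesions)
      sample(0:4, 1, prob = config$lesion_count_probs) else 0L
  }
  if (!with_lesions) n_lesions <- 0L
  lesions <- vector("list", n_lesions)
  for (l in seq_len(n_lesions))
    lesions[[l]] <- sample_lesion(config, scene, gland_arr, labels, adc_grid)
  lesion_union <- array(0, dim(labels))
  for (l in lesions) lesion_union <- pmax(lesion_union, l$mask)

  t2_grid <- if (deranged_geometry)
    config_grid(config, origin_shift = c(3.2, -2.4, 0), rotation_deg = 4)
  else adc_grid

  render_sequence <- function(seqname, grid) {
    lab <- render_labels(scene, grid)
    les <- array(0, dim(grid$data))
    for (l in lesions) les <- pmax(les, render_lesion(l, grid))
    mu <- config$intensities[[seqname]]
    img <- array(mu[["background"]], dim(grid$data))
    img[lab == 1] <- mu[["cg"]]
    img[lab == 2] <- mu[["pz"]]
    img[les > 0.5] <- mu[["lesion"]]
    img <- img + rnorm(length(img), 0, config$noise_sd[[seqname]])
    with_data(grid, img)
  }

  case <- structure(list(
    id = id,
    adc = render_sequence("adc", adc_grid),
    t2 = render_sequence("t2", t2_grid),
    hb = render_sequence("hb", adc_grid),
    gland = with_data(adc_grid, gland_arr),
    pz = with_data(adc_grid, array(as.double(labels == 2), dim(labels))),
    cg = with_data(adc_grid, array(as.double(labels == 1), dim(labels))),
    lesions = lapply(lesions, function(l)
      list(mask = with_data(adc_grid, l$mask), zone = l$zone,
           d_cm = l$d_cm, center = l$center, semi = l$semi,
           theta = l$theta)),
    cspca = n_lesions > 0,
    gland_semiaxes = semi), class = "patient_case")
  case
}

#' Validate the structural invariants of a patient case
#'
#' Checks the zone partition (PZ and CG disjoint, union = gland), lesion
#' containment in the gland, and the consistency of the csPCa flag.
#'
#' @param case a `patient_case`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_patient_case <- function(case) {
  pz <- case$pz$data; cg <- case$cg$data; gl <- case$gland$data
  if (any(pz * cg > 0)) stop("PZ and CG overlap")
  if (!all((pz + cg > 0) == (gl > 0))) stop("PZ union CG != gland")
  for (l in case$lesions)
    if (!all(gl[l$mask$data > 0.5] > 0)) stop("lesion exceeds gland")
  if (case$cspca != (length(case$lesions) > 0))
    stop("csPCa flag inconsistent with lesion list")
  invisible(TRUE)
}

#' Generate a synthetic cohort
#'
#' Draws `n_pos` csPCa cases (at least one lesion each, multiplicity from
#' the positive part of `config$lesion_count_probs`) and `n_neg`
#' lesion-free cases.  The whole cohort is a deterministic function of
#' `config$seed`.
#'
#' @param config a `phantom_config`.
#' @param n_pos,n_neg case counts.
#' @param deranged_geometry passed through to [generate_patient()].
#' @return list of `patient_case` objects (positives first).
#' @export
sample_cohort <- function(config, n_pos, n_neg, deranged_geometry = FALSE) {
  stopifnot(n_pos >= 0, n_neg >= 0)
  set.seed(config$seed)
  pos_probs <- config$lesion_count_probs[2:5]
  pos_probs <- pos_probs / sum(pos_probs)
  cases <- vector("list", n_pos + n_neg)
  for (i in seq_len(n_pos)) {
    n_les <- sample(1:4, 1, prob = pos_probs)
    cases[[i]] <- generate_patient(config, with_lesions = TRUE,
                                   deranged_geometry = deranged_geometry,
                                   id = sprintf("pt%04d", i),
                                   n_lesions = n_les)
  }
  for (i in seq_len(n_neg)) {
    cases[[n_pos + i]] <- generate_patient(
      config, with_lesions = FALSE, deranged_geometry = deranged_geometry,
      id = sprintf("pt%04d", n_pos + i))
  }
  cases
}

#' Write a cohort to disk
#'
#' One NIfTI file per sequence and mask per patient plus a JSON manifest.
#'
#' @param cases list of `patient_case` objects.
#' @param dir output directory (created if needed).
#' @return manifest as a list (also written to `dir/manifest.json`).
#' @export
write_cohort <- function(cases, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create cohort directory: ", dir)
  entries <- lapply(cases, function(case) {
    paths <- list()
    for (field in c("adc", "t2", "hb", "gland", "pz", "cg")) {
      p <- file.path(dir, sprintf("%s_%s.nii.gz", case$id, field))
      write_nifti(case[[field]], p)
      paths[[field]] <- basename(p)
    }
    lesion_files <- character(0)
    zones <- character(0)
    for (l in seq_along(case$lesions)) {
      p <- file.path(dir, sprintf("%s_lesion%02d.nii.gz", case$id, l))
      write_nifti(case$lesions[[l]]$mask, p)
      lesion_files <- c(lesion_files, basename(p))
      zones <- c(zones, case$lesions[[l]]$zone)
    }
    list(id = case$id, cspca = case$cspca, paths = paths,
         lesions = as.list(lesion_files), lesion_zones = as.list(zones))
  })
  manifest <- list(n_cases = length(cases), cases = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return list of `patient_case` objects.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lapply(manifest$cases, function(e) {
    case <- list(id = e$id)
    for (field in c("adc", "t2", "hb", "gland", "pz", "cg"))
      case[[field]] <- read_nifti(file.path(dir, e$paths[[field]]))
    case$lesions <- lapply(seq_along(e$lesions), function(l)
      list(mask = read_nifti(file.path(dir, e$lesions[[l]])),
           zone = e$lesion_zones[[l]]))
    case$cspca <- isTRUE(e$cspca)
    structure(case, class = "patient_case")
  })
}
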