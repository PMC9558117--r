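test_that("resampling onto the same grid is the identity", {
  set.seed(2)
  arr <- array(rnorm(12 * 10 * 6), c(12, 10, 6))
  g <- volume_grid(arr, spacing = c(1, 1.5, 4))
  out <- resample_to_grid(g, registration_spec(g, g))
  expect_equal(out$data, arr, tolerance = 1e-10)
})

test_that("a one-voxel origin shift shifts the voxel lattice exactly", {
  set.seed(3)
  arr <- array(rnorm(16 * 12 * 6), c(16, 12, 6))
  g <- volume_grid(arr, spacing = c(2, 2, 4))
  shifted <- volume_grid(array(0, dim(arr)), spacing = c(2, 2, 4),
                         origin = c(2, 0, 0))  # +1 voxel along x
  out <- resample_to_grid(g, registration_spec(g, shifted))
  expect_equal(out$data[1:15, , ], arr[2:16, , ], tolerance = 1e-10)
})

test_that("label resampling stays binary and non-invertible transforms fail", {
  m <- array(0, c(12, 12, 5)); m[4:8, 5:9, 2:4] <- 1
  g <- volume_grid(m, spacing = c(1, 1, 2))
  tgt <- volume_grid(array(0, c(12, 12, 5)), spacing = c(1, 1, 2),
                     origin = c(0.4, -0.3, 0.5))
  out <- resample_to_grid(g, registration_spec(g, tgt), is_label = TRUE)
  expect_true(all(out$data %in% c(0, 1)))
  expect_gt(sum(out$data), 0)
  bad <- g; bad$direction <- matrix(0, 3, 3)
  expect_error(registration_spec(bad, g), "invertible")
})

test_that("registration sanity loop: deranged T2 truth returns with high DSC", {
  # a well-resolved lesion (>= 2 cm at 1 mm in-plane): the >= 0.95 bound
  # is a statement about registration fidelity, not about voxelization of
  # sub-resolution lesions
  cfg <- toy_config(shape = c(96, 96, 10), spacing = c(1, 1, 4),
                    lesion_dim_mean = 2.5, lesion_dim_sd = 0.2,
                    lesion_dim_min = 2.0)
  case <- generate_patient(cfg, n_lesions = 1L, seed = 21,
                           deranged_geometry = TRUE)
  # render the lesion on the deranged T2 grid, register it back to ADC
  lesion_adc <- case$lesions[[1]]$mask
  spec <- registration_spec(case$t2, case$adc)
  # analytic re-render on the t2 grid via the generator's own machinery
  rl <- getFromNamespace("render_lesion", "prostacad")
  l1 <- case$lesions[[1]]
  lesion_t2 <- with_data(case$t2, rl(
    list(center = l1$center, semi = l1$semi, theta = l1$theta), case$t2))
  expect_gt(sum(lesion_t2$data), 0)
  back <- resample_to_grid(lesion_t2, spec, is_label = TRUE)
  expect_gte(dsc(back$data, lesion_adc$data), 0.95)
})

test_that("K-means localizer finds the gland and rejects degenerate input", {
  cfg <- toy_config(shape = c(64, 64, 10), spacing = c(2, 2, 4))
  case <- generate_patient(cfg, seed = 4)
  loc <- localize_prostate(case$hb, toy_localizer())
  bb <- mask_bbox <- which(case$gland$data > 0.5, arr.ind = TRUE)
  expect_true(all(apply(bb, 2, min) >= loc$box$lo))
  expect_true(all(apply(bb, 2, max) <= loc$box$hi))
  flat <- with_data(case$hb, array(3, dim(case$hb$data)))
  expect_error(localize_prostate(flat, toy_localizer()), "constant")
})

test_that("localizer picks the larger of two bright blobs", {
  d <- c(64, 64, 6)
  arr <- array(rnorm(prod(d), 10, 1), d)
  arr[20:29, 25:34, 2:5] <- 100   # large blob: 10x10x4
  arr[40:44, 40:44, 3:4] <- 100   # small blob: 5x5x2
  g <- volume_grid(arr, spacing = c(2, 2, 4))
  loc <- localize_prostate(g, toy_localizer())
  ctr <- (loc$box$lo + loc$box$hi) / 2
  expect_true(ctr[1] < 35 && ctr[2] < 38)  # around the large blob
})

test_that("crop / uncrop round-trips indices exactly", {
  set.seed(5)
  arr <- array(rnorm(40 * 40 * 6), c(40, 40, 6))
  g <- volume_grid(arr, spacing = c(2, 2, 4))
  # centered box
  box <- list(lo = c(13, 13, 2), hi = c(28, 28, 5))
  patch <- crop_patch(g, box, size = 16L)
  expect_equal(dim(patch$data), c(16, 16, 6))
  pl <- attr(patch, "placement")
  expect_equal(patch$data, arr[pl$x0:(pl$x0 + 15), pl$y0:(pl$y0 + 15), ])
  # corner box gets zero padding; un-crop re-inserts at original indices
  box2 <- list(lo = c(1, 1, 1), hi = c(6, 6, 3))
  patch2 <- crop_patch(g, box2, size = 16L)
  pl2 <- attr(patch2, "placement")
  expect_true(pl2$x0 < 1)
  back <- uncrop_patch(patch2, pl2)
  inb <- max(pl2$x0, 1):(pl2$x0 + 15)
  expect_equal(back$data[inb, inb, ], arr[inb, inb, ])
  # all-ones patch un-crops to exactly the in-bounds patch footprint
  ones <- uncrop_patch(array(1, c(16, 16, 6)), pl)
  expect_equal(sum(ones$data), 16 * 16 * 6)
  ones2 <- uncrop_patch(array(1, c(16, 16, 6)), pl2)
  expect_equal(sum(ones2$data), length(inb)^2 * 6)
})

test_that("normalize_patch maps to [0,1] with the closed form", {
  v <- volume_grid(array(c(100, 200, 300, 100, 100, 300), c(1, 2, 3)),
                   c(1, 1, 1))
  out <- normalize_patch(v)
  expect_equal(as.vector(out$data), c(0, 0.5, 1, 0, 0, 1))
  flat <- volume_grid(array(7, c(2, 2, 2)), c(1, 1, 1))
  expect_equal(normalize_patch(flat)$data, array(0, c(2, 2, 2)))
  set.seed(1)
  r <- normalize_patch(volume_grid(array(rnorm(64), c(4, 4, 4)), c(1, 1, 1)))
  expect_equal(range(r$data), c(0, 1))
})

test_that("augmentation respects its bounds and involution", {
  set.seed(6)
  img <- array(runif(16 * 16 * 4), c(16, 16, 4))
  mk <- array(0, c(16, 16, 4)); mk[6:10, 6:10, 2:3] <- 1
  cfg0 <- augment_config(mirror_prob = 1, rotation_deg = 0, noise_bound = 0)
  once <- augment_pair(list(img), list(mk), cfg0)
  twice <- augment_pair(once$images, once$masks, cfg0)
  expect_equal(twice$images[[1]], img)
  expect_equal(twice$masks[[1]], mk)
  # bounds
  cfgb <- augment_config(mirror_prob = 0, rotation_deg = 0, noise_bound = 1e-3)
  noisy <- augment_pair(list(img), list(), cfgb)
  expect_lte(max(abs(noisy$images[[1]] - img)), 1e-3)
  for (i in 1:20) {
    d <- augment_pair(list(img), list(mk), augment_config())$draw
    expect_lte(abs(d$angle), 10)
  }
})

test_that("rotating a centered disk changes it little; pairs stay aligned", {
  d <- c(32, 32, 1)
  xy <- expand.grid(x = 1:32, y = 1:32)
  disk <- array(as.double((xy$x - 16.5)^2 + (xy$y - 16.5)^2 <= 100), d)
  img <- disk
  out <- augment_pair(list(img), list(disk),
                      augment_config(mirror_prob = 0, noise_bound = 0),
                      force = list(mirror = FALSE, angle = 7.3))
  expect_gte(dsc(out$masks[[1]], disk), 0.95)
  # image (binary content, cubic) and mask (nearest) stay aligned
  cm <- function(a) colMeans(which(a > 0.5, arr.ind = TRUE))[1:2]
  expect_lt(max(abs(cm(out$images[[1]]) - cm(out$masks[[1]]))), 1)
})
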