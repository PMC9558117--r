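test_that("sextant partition is a six-way partition of the gland", {
  cfg <- toy_config(shape = c(48, 48, 12), spacing = c(2, 2, 4))
  for (s in 1:5) {
    case <- generate_patient(cfg, with_lesions = FALSE, seed = 100 + s)
    sm <- partition_sextants(case$gland)
    expect_length(sm$masks, 6)
    expect_true(validate_sextant_map(sm))
    tot <- Reduce(`+`, lapply(sm$masks, function(m) m$data))
    expect_equal(tot, case$gland$data)  # exact cover, no overlap
  }
})

test_that("left and right sextant volumes balance for a symmetric gland", {
  # symmetric superellipsoid, no noise dependence: build the mask directly
  d <- c(41, 41, 9)
  g <- volume_grid(array(0, d), spacing = c(2, 2, 4),
                   origin = -c(40, 40, 32) / 2 * c(1, 1, 1))
  xyz <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  A <- grid_affine(g)
  wx <- A[1, 1] * (xyz$x - 1) + A[1, 4]
  wy <- A[2, 2] * (xyz$y - 1) + A[2, 4]
  wz <- A[3, 3] * (xyz$z - 1) + A[3, 4]
  inside <- (abs(wx) / 30)^2 + (abs(wy) / 24)^2 + (abs(wz) / 14)^2 <= 1
  gl <- with_data(g, array(as.double(inside), d))
  sm <- partition_sextants(gl)
  left <- sum(vapply(sm$masks[c("left-base", "left-mid", "left-apex")],
                     function(m) sum(m$data), 0))
  right <- sum(vapply(sm$masks[c("right-base", "right-mid", "right-apex")],
                      function(m) sum(m$data), 0))
  # equal up to one sagittal voxel layer
  layer <- max(vapply(seq_len(d[1]), function(i) sum(gl$data[i, , ]), 0))
  expect_lte(abs(left - right), layer)
})

test_that("partition is invariant to array padding and needs 3 slices", {
  cfg <- toy_config(shape = c(40, 40, 10), spacing = c(2, 2, 4))
  case <- generate_patient(cfg, with_lesions = FALSE, seed = 110)
  sm1 <- partition_sextants(case$gland)
  # pad by 4 voxels on every side
  d <- dim(case$gland$data)
  pad <- array(0, d + 8)
  pad[5:(d[1] + 4), 5:(d[2] + 4), 5:(d[3] + 4)] <- case$gland$data
  gp <- volume_grid(pad, spacing = case$gland$spacing,
                    origin = case$gland$origin - 4 * case$gland$spacing)
  sm2 <- partition_sextants(gp)
  expect_equal(unname(sm2$voxel_counts), unname(sm1$voxel_counts))
  thin <- volume_grid(array(1, c(5, 5, 2)), c(1, 1, 1))
  expect_error(partition_sextants(thin), "3 slices")
  expect_error(partition_sextants(volume_grid(array(0, c(5, 5, 5)),
                                              c(1, 1, 1))), "empty")
})

test_that("a 140-patient cohort yields 840 sextant units", {
  cfg <- toy_config(shape = c(32, 32, 9), spacing = c(3, 3, 4))
  set.seed(120)
  n_sextants <- 0
  for (i in 1:140) {
    case <- generate_patient(cfg, with_lesions = FALSE)
    sm <- partition_sextants(case$gland)
    n_sextants <- n_sextants + length(sm$masks)
  }
  expect_equal(n_sextants, 840)
})

test_that("diameters_3d applies (span + 1) * spacing per axis", {
  d <- c(30, 30, 8)
  one <- array(0, d); one[5, 7, 3] <- 1
  g <- volume_grid(one, spacing = c(0.75, 0.75, 4))
  expect_equal(unname(diameters_3d(g)[c("lr", "ap", "cc")]),
               c(0.75, 0.75, 4.0))
  blk <- array(0, d); blk[3:22, 4:23, 2:5] <- 1
  gb <- volume_grid(blk, spacing = c(0.75, 0.75, 4))
  expect_equal(unname(diameters_3d(gb)[c("lr", "ap", "cc")]),
               c(15, 15, 16))
  expect_equal(diameters_3d(gb)[["greatest"]], 16)
  expect_error(diameters_3d(volume_grid(array(0, d), c(1, 1, 1))), "empty")
})

test_that("phantom lesion diameters match the generator's ground truth", {
  m <- render_lesion_mask(1.6, spacing = c(0.75, 0.75, 4))
  expect_lt(abs(diameters_3d(m)[["greatest"]] - 16), 0.76)
})

test_that("key image selection takes max area with cranial tie-break", {
  d <- c(12, 12, 8)
  arr <- array(0, d)
  # areas 10, 30, 30, 5 on slices 4..7 -> slice 5 wins the tie
  arr[1:5, 1:2, 4] <- 1                 # 10
  arr[1:6, 1:5, 5] <- 1                 # 30
  arr[1:6, 1:5, 6] <- 1                 # 30
  arr[1:5, 1, 7] <- 1                   # 5
  comp <- extract_components(volume_grid(arr, c(1, 1, 1)))[[1]]
  adc <- volume_grid(array(rnorm(prod(d)), d), c(1, 1, 1))
  key <- select_key_image(adc, comp)
  expect_equal(key$slice, 5L)
  # single-slice lesion: that slice
  arr1 <- array(0, d); arr1[4:6, 4:6, 3] <- 1
  comp1 <- extract_components(volume_grid(arr1, c(1, 1, 1)))[[1]]
  expect_equal(select_key_image(adc, comp1)$slice, 3L)
  # contour: boundary pixels only (interior removed)
  k2 <- select_key_image(adc, comp1)
  expect_equal(sum(k2$contour), 8)  # 3x3 square boundary
  # raster writes as text PGM
  p <- tempfile(fileext = ".pgm")
  write_key_image(k2, p)
  expect_equal(readLines(p, n = 1), "P2")
  unlink(p)
})

test_that("structured reports validate, serialize and round-trip", {
  cfg <- toy_config(shape = c(48, 48, 10), spacing = c(2, 2, 4))
  case <- preprocess_case(generate_patient(cfg, n_lesions = 1L, seed = 130),
                          toy_localizer(32L))
  # build a faux inference output from the ground truth itself
  comps <- extract_components(case$lesions[[1]]$mask, min_volume = 0)
  inf <- list(gland_full = case$gland, components = comps)
  rp <- build_report(case, inf)
  expect_equal(rp$status, "csPCa")
  expect_length(rp$lesions, 1)
  expect_gte(length(rp$lesions[[1]]$sextants), 1)
  expect_equal(sum(unlist(rp$sector_map)),
               length(rp$lesions[[1]]$sextants))
  # gland at least as large as its lesions
  expect_gte(max(unlist(rp$gland_diameters_mm)),
             rp$lesions[[1]]$greatest_dimension_mm)
  path <- tempfile(fileext = ".json")
  write_report(rp, path)
  back <- read_report(path)
  expect_equal(back$status, rp$status)
  expect_equal(back$patient_id, rp$patient_id)
  expect_equal(back$lesions[[1]]$sextants, rp$lesions[[1]]$sextants)
  expect_equal(unlist(back$sector_map), unlist(rp$sector_map))
  unlink(path)
  # a negative case keeps gland diameters but no lesions
  neg <- preprocess_case(generate_patient(cfg, with_lesions = FALSE,
                                          seed = 131), toy_localizer(32L))
  inf0 <- list(gland_full = neg$gland, components = list())
  rp0 <- build_report(neg, inf0)
  expect_equal(rp0$status, "non-csPCa")
  expect_length(rp0$lesions, 0)
  expect_false(any(unlist(rp0$sector_map)))
  expect_equal(length(rp0$gland_diameters_mm), 3)
  # schema violations are rejected before write
  bad <- rp; bad$status <- "maybe"
  expect_error(validate_report(bad), "status")
})
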