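make_comp_mask <- function(d, ...) {
  arr <- array(0, d)
  for (box in list(...)) arr[box[[1]], box[[2]], box[[3]]] <- 1
  arr
}

comps_of <- function(arr, spacing = c(1, 1, 1), min_volume = 0)
  extract_components(volume_grid(arr, spacing), min_volume = min_volume)

test_that("dsc follows its closed form, symmetry and guards", {
  d <- c(8, 8, 4)
  x <- array(0, d); x[1:2, 1:2, 1] <- 1          # |X| = 4
  y <- array(0, d)                                # |Y| = 6, overlap 3
  y[1, 1:2, 1] <- 1; y[2, 1, 1] <- 1             # 3 shared with X
  y[3, 1:2, 1] <- 1; y[4, 1, 1] <- 1             # 3 outside X
  expect_equal(sum(x), 4); expect_equal(sum(y), 6)
  expect_equal(sum(x * y), 3)
  expect_equal(dsc(x, y), 0.6)
  expect_equal(dsc(y, x), 0.6)
  expect_equal(dsc(x, x), 1.0)
  expect_equal(dsc(x, array(0, d)), 0.0)
  both <- dsc(array(0, d), array(0, d))
  expect_equal(as.numeric(both), 1.0)
  expect_true(isTRUE(attr(both, "both_empty")))
  g1 <- volume_grid(x, c(1, 1, 1))
  g2 <- volume_grid(y, c(2, 1, 1))
  expect_error(dsc(g1, g2), "share one grid")
})

test_that("dsc is monotone in the intersection for fixed mask sizes", {
  d <- c(10, 10, 1)
  prev <- -1
  for (ov in 0:5) {
    x <- array(0, d); x[1:5, 1, 1] <- 1
    y <- array(0, d); y[6:10, 2, 1] <- 1
    if (ov > 0) { y[seq_len(ov), 1, 1] <- 1; y[5 + seq_len(ov), 2, 1] <- 0 }
    v <- dsc(x, y)
    expect_gt(v, prev)
    prev <- v
  }
})

test_that("lesion matching implements the boundary-inclusive slice rule", {
  d <- c(10, 10, 4)
  truth <- make_comp_mask(d, list(3:6, 3:6, 2))          # 16 px on slice 2
  # prediction covering exactly 50% of the truth's area on that slice
  pred50 <- make_comp_mask(d, list(3:6, 3:4, 2))          # 8 of 16
  m <- match_lesions(comps_of(pred50), comps_of(truth))
  expect_equal(m$counts$tp, 1L)
  expect_equal(m$counts$fn, 0L)
  # prediction covering 40% on every slice -> FP and FN
  truth2 <- make_comp_mask(d, list(1:5, 1:2, 1:3))        # 10 px per slice
  pred40 <- make_comp_mask(d, list(1:4, 1, 1:3))          # 4 of 10 per slice
  m2 <- match_lesions(comps_of(pred40), comps_of(truth2))
  expect_equal(m2$counts$tp, 0L)
  expect_equal(m2$counts$fp, 1L)
  expect_equal(m2$counts$fn, 1L)
  # identical prediction: all TP
  m3 <- match_lesions(comps_of(truth), comps_of(truth))
  expect_equal(m3$counts$tp, 1L)
  expect_equal(m3$counts$fp, 0L)
  expect_equal(m3$counts$fn, 0L)
  expect_equal(m3$lesion_dsc, 1.0)
})

test_that("lesion/sextant matching agrees with brute-force oracles", {
  set.seed(30)
  n_trials <- 200
  for (trial in seq_len(n_trials)) {
    d <- c(sample(6:16, 1), sample(6:16, 1), sample(2:5, 1))
    pred_arr <- random_mask(d, runif(1, 0.05, 0.3))
    truth_arr <- random_mask(d, runif(1, 0.05, 0.3))
    pred <- comps_of(pred_arr)
    truth <- comps_of(truth_arr)
    m <- match_lesions(pred, truth)
    # oracle works on per-component arrays
    to_arrs <- function(comps, d) lapply(comps, function(cmp) {
      a <- array(0, d); a[cmp$voxels] <- 1; a
    })
    o <- oracle_match_lesions(to_arrs(pred, d), to_arrs(truth, d))
    expect_equal(m$counts$tp, o$tp)
    expect_equal(m$counts$fp, o$fp)
    expect_equal(m$counts$fn, o$fn)
    # bookkeeping identity: TP(truth side) + FN = number of truth lesions
    expect_equal(sum(apply(o$pair[, seq_along(truth), drop = FALSE], 2,
                           any) & length(pred) > 0) + m$counts$fn,
                 length(truth))
  }
})

test_that("sextant rule: containment, split, and tiny-lesion clauses", {
  cfg <- toy_config(shape = c(48, 48, 12), spacing = c(2, 2, 4))
  case <- generate_patient(cfg, with_lesions = FALSE, seed = 40)
  sm <- partition_sextants(case$gland)
  d <- dim(case$gland$data)
  # lesion entirely inside one sextant
  one <- sm$masks[["left-mid"]]$data
  w <- which(one > 0.5, arr.ind = TRUE)
  ctr <- round(colMeans(w))
  les <- array(0, d); les[ctr[1], ctr[2], ctr[3]] <- 1
  hits <- match_sextants(comps_of(les, c(2, 2, 4)), list(), sm)
  expect_equal(unname(hits$pred_positive), sm$labels == "left-mid")
  # oracle agreement on random lesions
  set.seed(41)
  sx_arrs <- lapply(sm$masks, function(m) m$data)
  for (i in 1:20) {
    les <- array(0, d)
    c0 <- w[sample(nrow(w), 1), ]
    les[max(1, c0[1] - 2):min(d[1], c0[1] + 2),
        max(1, c0[2] - 2):min(d[2], c0[2] + 2),
        max(1, c0[3] - 1):min(d[3], c0[3] + 1)] <- 1
    ms <- match_sextants(comps_of(les, c(2, 2, 4)), list(), sm)
    o <- oracle_sextant_positive(list(les), sx_arrs)
    expect_equal(unname(ms$pred_positive), o)
  }
})

test_that("sextant counts tally to six per patient", {
  cfg <- toy_config(shape = c(48, 48, 12), spacing = c(2, 2, 4))
  for (s in c(50, 51)) {
    case <- generate_patient(cfg, n_lesions = 1L, seed = s)
    sm <- partition_sextants(case$gland)
    truth <- comps_of(case$lesions[[1]]$mask$data, c(2, 2, 4))
    ms <- match_sextants(truth, truth, sm)
    ct <- ms$counts
    expect_equal(ct$tp + ct$fp + ct$fn + ct$tn, 6L)
    expect_equal(ct$fp + ct$fn, 0L)  # identical sets
  }
})

test_that("patient-level rules follow the at-least-one conventions", {
  d <- c(8, 8, 2)
  truth <- comps_of(make_comp_mask(d, list(1:4, 1:4, 1),
                                   list(6:8, 6:8, 2)))
  # only one of the lesions detected -> still patient TP
  pred <- comps_of(make_comp_mask(d, list(1:4, 1:4, 1)))
  lm <- match_lesions(pred, truth)
  expect_equal(patient_outcome(lm, length(pred), TRUE), "TP")
  # negative patient with any prediction -> FP; with none -> TN
  expect_equal(patient_outcome(NULL, 1L, FALSE), "FP")
  expect_equal(patient_outcome(NULL, 0L, FALSE), "TN")
  # positive patient with nothing detected -> FN
  lm0 <- match_lesions(list(), truth)
  expect_equal(patient_outcome(lm0, 0L, TRUE), "FN")
  pl <- patient_level(c("TP", "FP", "FN", "TN", "TP"))
  expect_equal(pl$tp, 2L); expect_equal(pl$n_pos, 3L)
})

test_that("Clopper-Pearson intervals reproduce printed table values", {
  ci <- clopper_pearson(84, 88)
  expect_equal(round(100 * ci[["lower"]], 1), 88.8)
  ci2 <- clopper_pearson(46, 71)
  expect_equal(round(100 * ci2[["lower"]], 1), 52.5)
  expect_equal(round(100 * ci2[["upper"]], 1), 75.8)
  # closures
  expect_equal(clopper_pearson(5, 5)[["upper"]], 1)
  expect_equal(clopper_pearson(0, 5)[["lower"]], 0)
})

test_that("rates_with_ci computes the three rates as percentages", {
  ct <- confusion_counts("sextant", tp = 108, fp = 62, fn = 5, tn = 665,
                         n_pos = 113, n_neg = 727)
  r <- rates_with_ci(ct)
  expect_equal(r$percent[r$metric == "sensitivity"], 100 * 108 / 113)
  expect_equal(r$percent[r$metric == "specificity"], 100 * 665 / 727)
  expect_equal(r$percent[r$metric == "accuracy"], 100 * 773 / 840)
  expect_true(all(r$ci_lower <= r$percent & r$percent <= r$ci_upper))
  # TP = n, FN = 0 -> sensitivity 100 with upper bound 100
  ct2 <- confusion_counts("patient", tp = 7, fp = 0, fn = 0, tn = 3,
                          n_pos = 7, n_neg = 3)
  r2 <- rates_with_ci(ct2)
  expect_equal(r2$percent[1], 100)
  expect_equal(r2$ci_upper[1], 100)
  # lesion level: specificity undefined, flagged not fabricated
  ct3 <- confusion_counts("lesion", tp = 4, fp = 1, fn = 2, tn = NA,
                          n_pos = 6, n_neg = NA)
  r3 <- rates_with_ci(ct3)
  expect_true(is.na(r3$percent[r3$metric == "specificity"]))
})

test_that("Clopper-Pearson coverage at p = 0.9, n = 88", {
  set.seed(60)
  n <- 88; p <- 0.9; reps <- 10000
  x <- rbinom(reps, n, p)
  lo <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
  hi <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
  cover <- mean(lo <= p & p <= hi)
  expect_gte(cover, 0.95 - 0.006)  # exact interval: conservative coverage
})

test_that("McNemar test reproduces exact and asymptotic arithmetic", {
  # b = c = 5: perfect symmetry
  a <- c(rep(TRUE, 5), rep(FALSE, 5), TRUE)
  b <- c(rep(FALSE, 5), rep(TRUE, 5), TRUE)
  expect_equal(mcnemar_test(a, b)$p_value, 1.0)
  # b = 10, c = 2 -> exact p = 158/4096
  a2 <- c(rep(TRUE, 10), rep(FALSE, 2), rep(TRUE, 3))
  b2 <- c(rep(FALSE, 10), rep(TRUE, 2), rep(TRUE, 3))
  r2 <- mcnemar_test(a2, b2)
  expect_equal(r2$method, "exact")
  expect_equal(r2$p_value, 158 / 4096)
  # b = 60, c = 20 -> chi-square with continuity correction = 19.0125
  a3 <- c(rep(TRUE, 60), rep(FALSE, 20))
  b3 <- c(rep(FALSE, 60), rep(TRUE, 20))
  r3 <- mcnemar_test(a3, b3)
  expect_equal(r3$statistic, (abs(60 - 20) - 1)^2 / 80)
  expect_lt(r3$p_value, 0.001)
  # no discordance
  r4 <- mcnemar_test(c(TRUE, FALSE), c(TRUE, FALSE))
  expect_equal(r4$p_value, 1.0)
  expect_match(r4$note, "discordant")
})
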