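# Evaluation framework: Dice similarity, per-lesion / per-sextant /
# per-patient matching rules, diagnostic rates with exact Clopper-Pearson
# confidence intervals, and McNemar paired comparisons.

#' Matching-rule configuration
#'
#' The three 50% rules of the evaluation framework:
#' * a predicted lesion is a true positive when it covers at least
#'   `lesion_overlap` of a ground-truth lesion's area on at least one
#'   axial slice;
#' * a sextant contains a lesion when the sextant holds at least
#'   `sextant_coverage` of the lesion's volume, or the lesion occupies at
#'   least `sextant_occupancy` of the sextant.
#'
#' @param lesion_overlap slice-overlap fraction (default 0.5).
#' @param sextant_coverage lesion-coverage fraction (default 0.5).
#' @param sextant_occupancy sextant-occupancy fraction (default 0.5).
#' @return An object of class `match_rule_config`.
#' @export
match_rule_config <- function(lesion_overlap = 0.5,
                              sextant_coverage = 0.5,
                              sextant_occupancy = 0.5) {
  v <- c(lesion_overlap, sextant_coverage, sextant_occupancy)
  if (any(v <= 0) || any(v > 1))
    stop("all matching fractions must lie in (0, 1]")
  structure(list(lesion_overlap = lesion_overlap,
                 sextant_coverage = sextant_coverage,
                 sextant_occupancy = sextant_occupancy),
            class = "match_rule_config")
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |X intersect Y| / (|X| + |Y|)`.  Two empty masks give 1.0
#' (flagged with attribute `both_empty`); one empty mask gives 0.0.
#'
#' @param x,y `volume_grid` masks on the same grid, or plain arrays of
#'   identical dimension.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(x, y) {
  if (is_volume_grid(x) && is_volume_grid(y) && !same_geometry(x, y))
    stop("dsc: masks must share one grid")
  ax <- if (is_volume_grid(x)) x$data else x
  ay <- if (is_volume_grid(y)) y$data else y
  stopifnot(all(dim(ax) == dim(ay)))
  nx <- sum(ax > 0.5); ny <- sum(ay > 0.5)
  if (nx + ny == 0) return(structure(1.0, both_empty = TRUE))
  2 * sum(ax > 0.5 & ay > 0.5) / (nx + ny)
}

# per-slice voxel index sets of a component
component_slice_sets <- function(comp) {
  d <- comp$dim
  k <- (comp$voxels - 1) %/% (d[1] * d[2]) + 1
  split(comp$voxels, factor(k, levels = seq_len(d[3])))
}

#' Match predicted lesions against ground truth
#'
#' A predicted component is a true positive when there is a ground-truth
#' component and an axial slice on which the prediction covers at least
#' the configured fraction (default >= 50%) of the truth's area on that
#' slice.  Unmatched predictions are false positives; undetected
#' ground-truth lesions are false negatives.  A ground-truth lesion
#' counts as detected at most once; one truth lesion may be matched by
#' several predicted components, in which case the per-lesion DSC is
#' computed against their union.
#'
#' @param pred,truth component lists from [extract_components()], on the
#'   same grid.
#' @param cfg a `match_rule_config`.
#' @return list with `counts` (`confusion_counts`, level `"lesion"`, TN
#'   undefined), `matches` (data.frame pred x truth), and `lesion_dsc`
#'   (per detected truth lesion).
#' @export
match_lesions <- function(pred, truth, cfg = match_rule_config()) {
  for (p in pred) for (g in truth)
    if (!all(p$dim == g$dim)) stop("components live on different grids")
  nd <- length(pred); ng <- length(truth)
  pair <- matrix(FALSE, nrow = max(nd, 1), ncol = max(ng, 1))
  truth_slices <- lapply(truth, component_slice_sets)
  pred_slices <- lapply(pred, component_slice_sets)
  for (ip in seq_len(nd)) for (ig in seq_len(ng)) {
    ts <- truth_slices[[ig]]; ps <- pred_slices[[ip]]
    for (k in seq_along(ts)) {
      ta <- length(ts[[k]])
      if (ta == 0L) next
      ov <- length(intersect(ps[[k]], ts[[k]]))
      if (ov / ta >= cfg$lesion_overlap) { pair[ip, ig] <- TRUE; break }
    }
  }
  pred_tp <- if (nd > 0) apply(pair[seq_len(nd), , drop = FALSE], 1, any) &
    ng > 0 else logical(0)
  truth_hit <- if (ng > 0) apply(pair[, seq_len(ng), drop = FALSE], 2, any) &
    nd > 0 else logical(0)
  lesion_dsc <- rep(NA_real_, ng)
  for (ig in seq_len(ng)) {
    if (!isTRUE(truth_hit[ig])) next
    u <- unique(unlist(lapply(which(pair[, ig]), function(ip)
      pred[[ip]]$voxels)))
    tvox <- truth[[ig]]$voxels
    lesion_dsc[ig] <- 2 * length(intersect(u, tvox)) /
      (length(u) + length(tvox))
  }
  counts <- confusion_counts("lesion",
                             tp = sum(pred_tp), fp = sum(!pred_tp),
                             fn = sum(!truth_hit), tn = NA_integer_,
                             n_pos = ng, n_neg = NA_integer_)
  matches <- if (nd > 0 && ng > 0)
    data.frame(pred = rep(seq_len(nd), ng),
               truth = rep(seq_len(ng), each = nd),
               matched = as.vector(pair[seq_len(nd), seq_len(ng)]))
  else data.frame(pred = integer(0), truth = integer(0),
                  matched = logical(0))
  list(counts = counts, matches = matches, lesion_dsc = lesion_dsc)
}

# Which sextants "contain" a lesion under the two-clause 50% rule.
sextant_hits <- function(comp, sextant_map, cfg) {
  vapply(sextant_map$masks, function(sx) {
    svox <- which(sx$data > 0.5)
    ov <- length(intersect(comp$voxels, svox))
    ov / comp$n_vox >= cfg$sextant_coverage ||
      (length(svox) > 0 && ov / length(svox) >= cfg$sextant_occupancy)
  }, TRUE)
}

#' Sextant-level confusion counts
#'
#' Applies the sextant containment rule identically to predicted and
#' ground-truth lesion components, then tallies TP/FP/FN/TN over the six
#' sextants.
#'
#' @param pred,truth component lists from [extract_components()].
#' @param sextant_map a `sextant_map` from [partition_sextants()].
#' @param cfg a `match_rule_config`.
#' @return `confusion_counts` at level `"sextant"` plus the two positive
#'   sets as named logical vectors.
#' @export
match_sextants <- function(pred, truth, sextant_map,
                           cfg = match_rule_config()) {
  validate_sextant_map(sextant_map)
  pos_set <- function(comps) {
    hit <- rep(FALSE, 6L)
    for (cmp in comps) hit <- hit | sextant_hits(cmp, sextant_map, cfg)
    names(hit) <- sextant_map$labels
    hit
  }
  p <- pos_set(pred)
  g <- pos_set(truth)
  counts <- confusion_counts("sextant",
                             tp = sum(p & g), fp = sum(p & !g),
                             fn = sum(!p & g), tn = sum(!p & !g),
                             n_pos = sum(g), n_neg = sum(!g))
  list(counts = counts, pred_positive = p, truth_positive = g)
}

#' Patient-level outcome of one case
#'
#' A positive patient with at least one matched lesion is a TP; a
#' negative patient with any predicted component is an FP.
#'
#' @param lesion_match result of [match_lesions()] for the case (may be
#'   `NULL` for a negative patient).
#' @param n_pred number of predicted components.
#' @param truth_positive ground-truth csPCa status.
#' @return one of `"TP"`, `"FP"`, `"FN"`, `"TN"`.
#' @export
patient_outcome <- function(lesion_match, n_pred, truth_positive) {
  if (truth_positive) {
    hit <- !is.null(lesion_match) && lesion_match$counts$tp > 0
    if (hit) "TP" else "FN"
  } else {
    if (n_pred > 0) "FP" else "TN"
  }
}

#' Patient-level confusion counts for a cohort
#'
#' @param outcomes character vector of per-patient outcomes from
#'   [patient_outcome()].
#' @return `confusion_counts` at level `"patient"`.
#' @export
patient_level <- function(outcomes) {
  tab <- table(factor(outcomes, levels = c("TP", "FP", "FN", "TN")))
  confusion_counts("patient", tp = tab[["TP"]], fp = tab[["FP"]],
                   fn = tab[["FN"]], tn = tab[["TN"]],
                   n_pos = tab[["TP"]] + tab[["FN"]],
                   n_neg = tab[["TN"]] + tab[["FP"]])
}

#' Confusion counts container
#'
#' @param level `"lesion"`, `"sextant"` or `"patient"`.
#' @param tp,fp,fn,tn counts (`tn` is undefined at lesion level).
#' @param n_pos,n_neg cohort sizes.
#' @export
confusion_counts <- function(level, tp, fp, fn, tn, n_pos, n_neg) {
  x <- list(level = level, tp = as.integer(tp), fp = as.integer(fp),
            fn = as.integer(fn), tn = as.integer(tn),
            n_pos = as.integer(n_pos), n_neg = as.integer(n_neg))
  ok <- function(v) is.na(v) || v >= 0
  if (!all(vapply(x[c("tp", "fp", "fn", "tn")], ok, TRUE)))
    stop("negative confusion count")
  structure(x, class = "confusion_counts")
}

#' Combine confusion counts across patients
#' @param lst list of `confusion_counts` at one level.
#' @export
sum_counts <- function(lst) {
  stopifnot(length(lst) > 0)
  level <- lst[[1]]$level
  add <- function(f) {
    v <- vapply(lst, function(x) as.numeric(x[[f]]), 0.0)
    if (all(is.na(v))) NA_integer_ else sum(v, na.rm = TRUE)
  }
  confusion_counts(level, add("tp"), add("fp"), add("fn"), add("tn"),
                   add("n_pos"), add("n_neg"))
}

#' Exact Clopper-Pearson confidence interval
#'
#' Two-sided exact binomial interval in its beta-quantile form:
#' lower `qbeta(alpha/2, x, n - x + 1)`, upper
#' `qbeta(1 - alpha/2, x + 1, n - x)`, with the conventional closures at
#' `x = 0` and `x = n`.
#'
#' @param x successes, `n` trials.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return `c(lower, upper)` as proportions.
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  a <- (1 - conf) / 2
  lo <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  c(lower = lo, upper = hi)
}

#' Diagnostic rates with exact confidence intervals
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and accuracy
#' `(TP+TN)/total` as percentages, each with its exact Clopper-Pearson
#' 95% CI.  Rates with a zero denominator (or undefined TN at lesion
#' level) are returned as `NA`, not fabricated.
#'
#' @param counts a `confusion_counts`.
#' @return data.frame with one row per defined rate: `metric`,
#'   `numerator`, `denominator`, `percent`, `ci_lower`, `ci_upper`
#'   (percent, all at full precision; round for display).
#' @export
rates_with_ci <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rows <- list()
  push <- function(metric, x, n) {
    if (is.na(x) || is.na(n) || n == 0) {
      rows[[length(rows) + 1L]] <<- data.frame(
        metric = metric, numerator = NA_integer_, denominator = NA_integer_,
        percent = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_)
      return(invisible())
    }
    ci <- clopper_pearson(x, n)
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, numerator = x, denominator = n,
      percent = 100 * x / n, ci_lower = 100 * ci[["lower"]],
      ci_upper = 100 * ci[["upper"]])
  }
  with(counts, {
    push("sensitivity", tp, tp + fn)
    push("specificity", tn, tn + fp)
    total <- sum(c(tp, fp, fn, tn), na.rm = FALSE)
    push("accuracy", if (is.na(tn)) NA else tp + tn, total)
  })
  out <- do.call(rbind, rows)
  out$level <- counts$level
  out
}

#' McNemar paired comparison of two detectors
#'
#' Given per-unit correctness of two detectors on the same units, tests
#' symmetry of the discordant counts `b` (A correct, B wrong) and `c`
#' (A wrong, B correct): exact two-sided binomial test when `b + c < 25`,
#' chi-square with continuity correction otherwise.
#'
#' @param correct_a,correct_b logical vectors over the same units.
#' @return list with `b`, `c`, `method`, `p_value` (and `statistic` for
#'   the asymptotic branch).  `b + c == 0` returns p = 1 with a note.
#' @export
mcnemar_test <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  n <- b + cc
  if (n == 0)
    return(list(b = b, c = cc, method = "none",
                p_value = 1.0, note = "no discordant pairs"))
  if (n < 25) {
    p <- min(1, 2 * pbinom(min(b, cc), n, 0.5))
    list(b = b, c = cc, method = "exact", p_value = p)
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    list(b = b, c = cc, method = "chi-square (continuity corrected)",
         statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
  }
}

#' Evaluate a cohort of predictions at all three levels
#'
#' @param results list per patient: `components` (predictions),
#'   `truth_components`, `truth_positive`, and optionally `sextant_map`.
#' @param cfg a `match_rule_config`.
#' @return list of `confusion_counts` per level plus per-lesion DSC
#'   summary and per-patient outcome/correctness vectors.
#' @export
evaluate_cohort <- function(results, cfg = match_rule_config()) {
  lesion_counts <- list(); sextant_counts <- list()
  outcomes <- character(0); dscs <- numeric(0)
  for (r in results) {
    lm <- match_lesions(r$components, r$truth_components, cfg)
    lesion_counts[[length(lesion_counts) + 1L]] <- lm$counts
    dscs <- c(dscs, lm$lesion_dsc[!is.na(lm$lesion_dsc)])
    if (!is.null(r$sextant_map)) {
      sm <- match_sextants(r$components, r$truth_components,
                           r$sextant_map, cfg)
      sextant_counts[[length(sextant_counts) + 1L]] <- sm$counts
    }
    outcomes <- c(outcomes, patient_outcome(lm, length(r$components),
                                            r$truth_positive))
  }
  out <- list(lesion = sum_counts(lesion_counts),
              patient = patient_level(outcomes),
              outcomes = outcomes,
              lesion_dsc_mean = if (length(dscs)) mean(dscs) else NA_real_,
              lesion_dsc_sd = if (length(dscs) > 1) sd(dscs) else NA_real_)
  if (length(sextant_counts) > 0) out$sextant <- sum_counts(sextant_counts)
  out
}
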