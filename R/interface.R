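# Shared plumbing: format dispatch, run configuration, the end-to-end
# pipeline driver and a small command-line interface.

#' Read a volume from NIfTI or a DICOM series directory
#'
#' @param path a `.nii` / `.nii.gz` file or a directory holding one
#'   DICOM series.
#' @return a `volume_grid`.
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (grepl("\\.nii(\\.gz)?$", path)) return(read_nifti(path))
  stop("unsupported volume format: ", path)
}

#' Default run configuration
#'
#' Bundles every stage configuration with the defaults of the reference
#' training setup (batch 20, learning rate 1e-4, 120 epochs, threshold
#' 0.5, 128 patch, 10 degree rotations, 0.001 noise, 50% matching rules).
#' Any field can be overridden with a nested list, e.g.
#' `run_config(train = list(epochs = 5))`.
#'
#' @param ... nested overrides per section (`phantom`, `localizer`,
#'   `augment`, `cascade`, `train`, `match`, `seed`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  base <- list(phantom = list(), localizer = list(), augment = list(),
               cascade = list(), train = list(), match = list(), seed = 1L)
  for (nm in names(over)) {
    if (nm == "seed") base$seed <- over$seed
    else base[[nm]] <- modifyList(base[[nm]], over[[nm]])
  }
  cfg <- list(
    phantom = do.call(phantom_config, base$phantom),
    localizer = do.call(localizer_config, base$localizer),
    augment = do.call(augment_config, base$augment),
    cascade = do.call(cascade_spec, base$cascade),
    train = do.call(train_config, base$train),
    match = do.call(match_rule_config, base$match),
    seed = as.integer(base$seed))
  structure(cfg, class = "run_config")
}

# preprocess a stored cohort with the run's localizer settings
load_preprocessed <- function(config, cohort_dir) {
  lapply(read_cohort(cohort_dir), preprocess_case,
         loc_cfg = config$localizer)
}

train_and_save <- function(config, pp, out_dir) {
  stages <- train_cascade(pp, config$cascade, config$train)
  ckpt_dir <- file.path(out_dir, "ckpt")
  dir.create(ckpt_dir, showWarnings = FALSE, recursive = TRUE)
  hist <- list()
  for (s in 1:3) {
    save_checkpoint(stages[[s]]$net,
                    file.path(ckpt_dir, sprintf("stage%d", s)))
    h <- stages[[s]]$history
    h$stage <- s
    hist[[s]] <- h
  }
  utils::write.csv(do.call(rbind, hist),
                   file.path(ckpt_dir, "history.csv"), row.names = FALSE)
  list(stages = stages, ckpt_dir = ckpt_dir)
}

infer_and_save <- function(config, pp, nets, out_dir) {
  pred_dir <- file.path(out_dir, "pred")
  dir.create(pred_dir, showWarnings = FALSE, recursive = TRUE)
  infs <- list()
  for (case in pp) {
    inf <- infer_case(case, nets, config$cascade)
    for (f in c("gland_full", "pz_full", "cg_full", "lesion_full",
                "prob_full"))
      write_nifti(inf[[f]], file.path(
        pred_dir, sprintf("%s_%s.nii.gz", case$id, sub("_full", "", f))))
    infs[[case$id]] <- inf
  }
  list(pred_dir = pred_dir, infs = infs)
}

evaluate_and_save <- function(config, pp, infs, out_dir) {
  results <- list()
  for (case in pp) {
    truth_comps <- list()
    for (l in case$lesions)
      truth_comps <- c(truth_comps,
                       extract_components(l$mask, min_volume = 0))
    sm <- tryCatch(partition_sextants(case$gland),
                   error = function(e) NULL)
    results[[case$id]] <- list(components = infs[[case$id]]$components,
                               truth_components = truth_comps,
                               truth_positive = case$cspca,
                               sextant_map = sm)
  }
  ev <- evaluate_cohort(results, config$match)
  metrics <- do.call(rbind, lapply(
    Filter(Negate(is.null),
           list(ev$lesion, ev$sextant, ev$patient)), rates_with_ci))
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(metrics = metrics, lesion_dsc_mean = ev$lesion_dsc_mean,
         lesion_dsc_sd = ev$lesion_dsc_sd, seed = config$seed),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  list(evaluation = ev, metrics = metrics)
}

report_and_save <- function(config, pp, infs, out_dir) {
  rep_dir <- file.path(out_dir, "reports")
  dir.create(rep_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- list()
  for (case in pp) {
    rp <- tryCatch(build_report(case, infs[[case$id]], cfg = config$match),
                   error = function(e) {
                     warning("no report for ", case$id, ": ",
                             conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (is.null(rp)) next
    write_report(rp, file.path(rep_dir, paste0(case$id, ".json")))
    if (length(infs[[case$id]]$components) > 0) {
      key <- select_key_image(case$adc, infs[[case$id]]$components[[1]])
      write_key_image(key, file.path(rep_dir,
                                     paste0(case$id, "_key.pgm")))
    }
    reports[[case$id]] <- rp
  }
  reports
}

load_nets <- function(config, ckpt_dir) {
  lapply(1:3, function(s)
    load_checkpoint(file.path(ckpt_dir, sprintf("stage%d", s)),
                    expect_channels = stage_in_channels(config$cascade, s)))
}

#' Run the pipeline
#'
#' `command = "all"` simulates a cohort, preprocesses it, trains the
#' three cascade stages, runs inference on held-out cases, evaluates at
#' all three levels, and writes metrics (CSV + JSON), structured reports
#' and key images under `out_dir`.  The individual commands expose the
#' stages separately on a stored cohort: `simulate` writes a cohort,
#' `preprocess` materializes registered/cropped/normalized patches,
#' `train` fits the cascade and saves checkpoints, `infer` writes
#' predicted masks and probability maps, `evaluate` writes metrics, and
#' `report` writes structured reports.
#'
#' @param config a `run_config`.
#' @param command one of `"all"`, `"simulate"`, `"preprocess"`,
#'   `"train"`, `"infer"`, `"evaluate"`, `"report"`.
#' @param out_dir output directory.
#' @param n_pos,n_neg training-cohort composition for `simulate`/`all`.
#' @param n_test_pos,n_test_neg held-out test composition for `all`.
#' @param cohort_dir cohort directory (commands other than
#'   `simulate`/`all`).
#' @param ckpt_dir checkpoint directory (for `infer` when trained
#'   elsewhere; defaults to `out_dir/ckpt`).
#' @return list of artifacts (invisible); files under `out_dir`.
#' @export
run_pipeline <- function(config,
                         command = c("all", "simulate", "preprocess",
                                     "train", "infer", "evaluate",
                                     "report"),
                         out_dir, n_pos = 20L, n_neg = 10L,
                         n_test_pos = 6L, n_test_neg = 6L,
                         cohort_dir = NULL, ckpt_dir = NULL) {
  command <- match.arg(command)
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ph <- config$phantom
  ph$seed <- config$seed
  if (command == "simulate") {
    manifest <- write_cohort(sample_cohort(ph, n_pos, n_neg),
                             file.path(out_dir, "cohort"))
    return(invisible(list(manifest = manifest)))
  }
  if (command %in% c("preprocess", "train", "infer", "evaluate",
                     "report")) {
    if (is.null(cohort_dir)) stop(command, " needs a cohort_dir")
    pp <- load_preprocessed(config, cohort_dir)
    if (command == "preprocess") {
      pre_dir <- file.path(out_dir, "preprocessed")
      dir.create(pre_dir, showWarnings = FALSE, recursive = TRUE)
      for (case in pp) {
        for (f in c("adc_p", "t2_p", "hb_p", "gland_p", "pz_p", "cg_p"))
          write_nifti(case[[f]],
                      file.path(pre_dir, sprintf("%s_%s.nii.gz",
                                                 case$id, f)))
        jsonlite::write_json(case$placement[c("x0", "y0", "size",
                                              "orig_dim")],
                             file.path(pre_dir,
                                       paste0(case$id, "_placement.json")),
                             auto_unbox = TRUE)
      }
      return(invisible(list(preprocessed = pre_dir)))
    }
    if (command == "train") {
      tr <- train_and_save(config, pp, out_dir)
      return(invisible(list(checkpoints = tr$ckpt_dir)))
    }
    if (is.null(ckpt_dir)) ckpt_dir <- file.path(out_dir, "ckpt")
    nets <- load_nets(config, ckpt_dir)
    io <- infer_and_save(config, pp, nets, out_dir)
    if (command == "infer")
      return(invisible(list(pred = io$pred_dir)))
    if (command == "evaluate")
      return(invisible(evaluate_and_save(config, pp, io$infs, out_dir)))
    return(invisible(list(reports = report_and_save(config, pp, io$infs,
                                                    out_dir))))
  }
  # command == "all": synthetic end-to-end run
  cohort <- sample_cohort(ph, n_pos, n_neg)
  ph_test <- ph
  ph_test$seed <- config$seed + 1000L
  test_cohort <- sample_cohort(ph_test, n_test_pos, n_test_neg)
  pp <- lapply(cohort, preprocess_case, loc_cfg = config$localizer)
  pp_test <- lapply(test_cohort, preprocess_case,
                    loc_cfg = config$localizer)
  tr <- train_and_save(config, pp, out_dir)
  nets <- lapply(tr$stages, `[[`, "net")
  io <- infer_and_save(config, pp_test, nets, out_dir)
  ev <- evaluate_and_save(config, pp_test, io$infs, out_dir)
  reports <- report_and_save(config, pp_test, io$infs, out_dir)
  invisible(list(evaluation = ev$evaluation, metrics = ev$metrics,
                 reports = reports, checkpoints = tr$ckpt_dir,
                 pred = io$pred_dir))
}

#' Command-line entry point
#'
#' `prostacad_main(c("simulate", "--out", dir, "--n-pos", "4", ...))`.
#' Commands: `simulate`, `all`.  An executable wrapper lives in
#' `inst/cli/prostacad`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status (0 on success), invisibly.
#' @export
prostacad_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    message("usage: prostacad <simulate|preprocess|train|infer|evaluate|",
            "report|all> --out DIR [--cohort DIR] [--ckpt DIR] [--seed S] ",
            "[--n-pos N] [--n-neg M] [--shape X,Y,Z] [--epochs E]")
    return(invisible(1L))
  }
  command <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  out <- opt("--out", "prostacad-out")
  seed <- as.integer(opt("--seed", "1"))
  n_pos <- as.integer(opt("--n-pos", "8"))
  n_neg <- as.integer(opt("--n-neg", "4"))
  shape <- as.integer(strsplit(opt("--shape", "64,64,12"), ",")[[1]])
  spacing <- as.numeric(strsplit(opt("--spacing", "2,2,4"), ",")[[1]])
  epochs <- as.integer(opt("--epochs", "10"))
  status <- tryCatch({
    cfg <- run_config(
      seed = seed,
      phantom = list(shape = shape, spacing = spacing,
                     gland_semiaxes_mean = c(22, 17, 19) *
                       min(1, shape[1] * spacing[1] / 90)),
      localizer = list(patch_size = min(128L, 2L^floor(log2(shape[1])))),
      cascade = list(net_specs = lapply(1:3, function(i)
        network_spec(1L, depth = 2L, base_width = 8L))),
      train = list(epochs = epochs, batch = 20L, seed = seed))
    run_pipeline(cfg, command, out_dir = out, n_pos = n_pos, n_neg = n_neg,
                 cohort_dir = opt("--cohort"), ckpt_dir = opt("--ckpt"))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
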