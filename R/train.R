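# Training: soft-Dice / binary cross-entropy losses, Adam, and the
# per-stage training loop of the cascade.

#' Soft Dice loss and its gradient
#'
#' `L = 1 - (2 * sum(w p y) + eps) / (sum(w p) + sum(w y) + eps)`,
#' matching the Dice evaluation metric.  With `per_sample = TRUE`
#' (the training default) the soft Dice is computed per batch item and
#' averaged, which stops large lesions from drowning out the gradient of
#' small ones; `FALSE` applies the formula over the pooled batch.
#' `weight` is an optional per-pixel loss-weight map (uniform by
#' default).
#'
#' @param p probability tensor `(H, W, 1, N)`.
#' @param y binary target tensor of the same shape.
#' @param weight optional weight tensor.
#' @param eps smoothing constant.
#' @param per_sample average one soft Dice per batch item?
#' @return list with `value` and `dlogits` (gradient through the
#'   logistic output).
#' @export
dice_loss <- function(p, y, weight = NULL, eps = 1, per_sample = FALSE) {
  w <- if (is.null(weight)) array(1, dim(p)) else weight
  if (!per_sample) {
    num <- 2 * sum(w * p * y) + eps
    den <- sum(w * p) + sum(w * y) + eps
    dp <- -(2 * w * y * den - num * w) / den^2
    return(list(value = 1 - num / den, dlogits = dp * p * (1 - p)))
  }
  d <- dim(p)
  N <- d[4]
  m <- prod(d[1:3])
  pm <- matrix(w * p, nrow = m)
  ym <- matrix(w * y, nrow = m)
  wm <- matrix(w, nrow = m)
  num <- 2 * colSums(matrix(w * p * y, nrow = m)) + eps
  den <- colSums(pm) + colSums(ym) + eps
  dp_m <- -(sweep(2 * ym, 2, den, "*") - sweep(wm, 2, num, "*")) / N
  dp_m <- sweep(dp_m, 2, den^2, "/")
  dp <- array(dp_m, d)
  list(value = mean(1 - num / den), dlogits = dp * p * (1 - p))
}

#' Binary cross-entropy loss and its gradient
#'
#' @inheritParams dice_loss
#' @export
bce_loss <- function(p, y, weight = NULL, eps = 1e-7) {
  w <- if (is.null(weight)) 1 else weight
  pc <- pmin(pmax(p, eps), 1 - eps)
  value <- -mean(w * (y * log(pc) + (1 - y) * log(1 - pc)))
  list(value = value, dlogits = w * (pc - y) / length(p))
}

#' Combined soft-Dice + weighted cross-entropy loss
#'
#' Per-sample soft Dice plus binary cross-entropy in which positive
#' pixels carry `pos_weight`.  The cross-entropy term keeps per-pixel
#' gradients alive when the sigmoid saturates, which prevents the
#' well-known all-background collapse of a pure Dice loss on very sparse
#' targets (lesions occupy ~1% of a prostate patch).
#'
#' @inheritParams dice_loss
#' @param pos_weight multiplicative weight of positive pixels in the
#'   cross-entropy term.
#' @export
dice_bce_loss <- function(p, y, weight = NULL, pos_weight = 10) {
  dl <- dice_loss(p, y, weight, per_sample = TRUE)
  w <- 1 + (pos_weight - 1) * y
  if (!is.null(weight)) w <- w * weight
  bl <- bce_loss(p, y, weight = w)
  list(value = dl$value + bl$value, dlogits = dl$dlogits + bl$dlogits)
}

loss_fn <- function(name, pos_weight = 10) {
  switch(name,
         dice_bce = function(p, y, weight = NULL)
           dice_bce_loss(p, y, weight, pos_weight = pos_weight),
         dice = function(p, y, weight = NULL)
           dice_loss(p, y, weight, per_sample = TRUE),
         dice_global = dice_loss,
         bce = bce_loss,
         stop("unknown loss: ", name))
}

#' Training configuration
#'
#' Defaults follow the reference training setup: batch size 20, learning
#' rate 1e-4, 120 epochs, Adam.
#'
#' @param batch minibatch size (slices).
#' @param lr learning rate.
#' @param epochs training epochs.
#' @param loss `"dice_bce"` (default: per-sample soft Dice plus weighted
#'   cross-entropy, see [dice_bce_loss()]), `"dice"`, `"dice_global"`, or
#'   `"bce"`.
#' @param pos_weight positive-pixel weight of the cross-entropy term.
#' @param augment apply mirror/rotation/noise augmentation to training
#'   batches?
#' @param val_frac fraction of cases held out for validation when no
#'   explicit validation set is given.
#' @param seed RNG seed covering initialization, shuffling and
#'   augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch = 20L, lr = 1e-4, epochs = 120L,
                         loss = "dice_bce", pos_weight = 10,
                         augment = TRUE, val_frac = 0.2, seed = 1L) {
  stopifnot(batch >= 1, lr > 0, epochs >= 1)
  structure(list(batch = as.integer(batch), lr = lr,
                 epochs = as.integer(epochs), loss = loss,
                 pos_weight = pos_weight,
                 augment = augment, val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, st = st)
}

# Stage targets and input channel stacks ----------------------------------

stage_target <- function(case, stage) {
  if (stage == 1L) return(case$gland_p$data)
  if (stage == 2L) return(case$pz_p$data)
  les <- array(0, dim(case$gland_p$data))
  for (m in case$lesions_p) les <- pmax(les, m$data)
  les
}

stage_inputs <- function(case, stage, variant,
                         gland = NULL, pz = NULL, cg = NULL) {
  imgs <- if (variant == "bp") list(case$adc_p$data, case$t2_p$data)
          else list(case$adc_p$data)
  if (stage == 2L)
    imgs <- c(imgs, list(if (is.null(gland)) case$gland_p$data else gland))
  if (stage == 3L) {
    imgs <- c(imgs, list(if (is.null(pz)) case$pz_p$data else pz),
              list(if (is.null(cg)) case$cg_p$data else cg))
  }
  imgs
}

# Build the slice dataset of a stage: x (H, W, C, N), y (H, W, 1, N).
# Slices containing gland are kept; stage 1 additionally keeps two
# gland-free slices per case so the network learns the empty background.
# Stage 3 balances its heavy class skew: every lesion-bearing slice plus
# at most an equal number of lesion-free gland slices per case.
make_stage_dataset <- function(cases, stage, variant) {
  xs <- list(); ys <- list()
  for (case in cases) {
    chans <- stage_inputs(case, stage, variant)
    tgt <- stage_target(case, stage)
    gl <- case$gland_p$data
    nz <- dim(gl)[3]
    keep <- which(apply(gl, 3, sum) > 0)
    if (stage == 1L) {
      empty <- setdiff(seq_len(nz), keep)
      if (length(empty) > 0)
        keep <- sort(c(keep, empty[unique(round(seq(1, length(empty),
                                                    length.out = 2)))]))
    }
    if (stage == 3L) {
      pos <- keep[vapply(keep, function(k) sum(tgt[, , k]) > 0, TRUE)]
      neg <- setdiff(keep, pos)
      if (length(pos) > 0 && length(neg) > length(pos))
        neg <- neg[unique(round(seq(1, length(neg),
                                    length.out = length(pos))))]
      keep <- sort(c(pos, neg))
    }
    for (k in keep) {
      xs[[length(xs) + 1L]] <-
        vapply(chans, function(ch) ch[, , k], chans[[1]][, , 1])
      ys[[length(ys) + 1L]] <- tgt[, , k]
    }
  }
  if (length(xs) == 0L) stop("empty cohort: no usable slices")
  d <- dim(xs[[1]])
  x <- array(unlist(xs), c(d[1], d[2], d[3], length(xs)))
  y <- array(unlist(ys), c(d[1], d[2], 1L, length(ys)))
  list(x = x, y = y)
}

augment_batch <- function(xb, yb, cfg_aug) {
  for (n in seq_len(dim(xb)[4])) {
    mirror <- runif(1) < cfg_aug$mirror_prob
    angle <- runif(1, -cfg_aug$rotation_deg, cfg_aug$rotation_deg)
    if (mirror) {
      xb[, , , n] <- xb[rev(seq_len(dim(xb)[1])), , , n]
      yb[, , , n] <- yb[rev(seq_len(dim(yb)[1])), , , n]
    }
    if (abs(angle) > 1e-9) {
      xb[, , , n] <- rotate_slices(array(xb[, , , n], dim(xb)[1:3]),
                                   angle, 1L)
      ym <- rotate_slices(array(yb[, , , n], dim(yb)[1:3]), angle, 0L)
      yb[, , , n] <- as.double(ym > 0.5)
    }
  }
  if (cfg_aug$noise_bound > 0)
    xb <- xb + runif(length(xb), -cfg_aug$noise_bound, cfg_aug$noise_bound)
  list(x = xb, y = yb)
}

batch_dsc <- function(p, y, threshold = 0.5) {
  pb <- p > threshold
  yb <- y > 0.5
  inter <- sum(pb & yb)
  if (sum(pb) + sum(yb) == 0) return(1)
  2 * inter / (sum(pb) + sum(yb))
}

#' Train one cascade stage
#'
#' Trains the stage network on ground-truth conditioning masks (teacher
#' forcing), tracking validation DSC per epoch and returning the
#' best-validation checkpoint.  Fully deterministic under `cfg$seed`.
#'
#' @param stage 1 (gland), 2 (PZ) or 3 (lesion).
#' @param cases list of preprocessed `patient_case`s (training).
#' @param spec a `cascade_spec`.
#' @param cfg a `train_config`.
#' @param val_cases optional preprocessed validation cases; when `NULL`, a
#'   `cfg$val_frac` tail split of `cases` is used.
#' @return list with `net` (best checkpoint), `history` (data.frame of
#'   epoch, mean training loss, validation DSC) and `best_epoch`.
#' @export
train_stage <- function(stage, cases, spec, cfg = train_config(),
                        val_cases = NULL) {
  stopifnot(stage %in% 1:3, inherits(spec, "cascade_spec"))
  if (length(cases) == 0L) stop("empty training cohort")
  set.seed(cfg$seed + stage)
  if (is.null(val_cases)) {
    n_val <- max(1L, round(length(cases) * cfg$val_frac))
    if (length(cases) <= n_val) stop("cohort too small to split")
    # random (seeded) split: cohorts are often ordered by status, so a
    # tail split would give a degenerate single-class validation set
    vid <- sample(length(cases), n_val)
    val_cases <- cases[vid]
    cases <- cases[-vid]
  }
  variant <- spec$variant
  tr <- make_stage_dataset(cases, stage, variant)
  va <- make_stage_dataset(val_cases, stage, variant)
  nspec <- spec$net_specs[[stage]]
  nspec$in_channels <- stage_in_channels(spec, stage)
  net <- build_network(network_spec(nspec$in_channels, nspec$depth,
                                    nspec$base_width, nspec$loss_weight))
  opt <- adam_init(net$params)
  lf <- loss_fn(cfg$loss, pos_weight = if (is.null(cfg$pos_weight)) 10 else cfg$pos_weight)
  n_tr <- dim(tr$x)[4]
  aug_cfg <- augment_config(seed = NULL)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_dsc = numeric(0))
  best <- list(dsc = -Inf, net = net, epoch = 0L)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n_tr)
    losses <- c()
    for (start in seq(1, n_tr, by = cfg$batch)) {
      take <- ord[start:min(start + cfg$batch - 1, n_tr)]
      xb <- tr$x[, , , take, drop = FALSE]
      yb <- tr$y[, , , take, drop = FALSE]
      if (isTRUE(cfg$augment)) {
        ab <- augment_batch(xb, yb, aug_cfg)
        xb <- ab$x; yb <- ab$y
      }
      fw <- forward_network(net, xb, training = TRUE)
      net <- fw$net
      ls <- lf(fw$p, yb, weight = nspec$loss_weight)
      grads <- backward_network(net, fw$cache, ls$dlogits)
      upd <- adam_step(net$params, grads, opt, cfg$lr)
      net$params <- upd$params
      opt <- upd$st
      losses <- c(losses, ls$value)
    }
    pv <- forward_network(net, va$x, training = FALSE)$p
    vdsc <- batch_dsc(pv, va$y, spec$threshold)
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = mean(losses),
                                         val_dsc = vdsc))
    if (vdsc > best$dsc) best <- list(dsc = vdsc, net = net, epoch = epoch)
  }
  list(net = best$net, history = history, best_epoch = best$epoch)
}

#' Save a network checkpoint
#'
#' Writes the weights (`<path>.rds`) plus a JSON sidecar embedding the
#' network specification, so that inference can validate channel
#' compatibility before loading.
#'
#' @param net a `resunet`.
#' @param path checkpoint path stem.
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(net, paste0(path, ".rds"))
  sc <- net$spec
  jsonlite::write_json(list(in_channels = sc$in_channels, depth = sc$depth,
                            base_width = sc$base_width),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path checkpoint path stem as given to [save_checkpoint()].
#' @param expect_channels optional input-channel count to validate
#'   against the JSON sidecar.
#' @export
load_checkpoint <- function(path, expect_channels = NULL) {
  side <- paste0(path, ".json")
  if (!file.exists(paste0(path, ".rds")))
    stop("missing checkpoint: ", path, ".rds")
  if (file.exists(side) && !is.null(expect_channels)) {
    meta <- jsonlite::read_json(side)
    if (meta$in_channels != expect_channels)
      stop("checkpoint expects ", meta$in_channels,
           " input channels, pipeline provides ", expect_channels)
  }
  readRDS(paste0(path, ".rds"))
}
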