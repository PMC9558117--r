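test_that("network output has the right shape, range and determinism", {
  set.seed(10)
  net <- build_network(network_spec(2L, depth = 4L, base_width = 4L))
  x <- array(runif(32 * 32 * 2 * 2), c(32, 32, 2, 2))
  p1 <- forward_network(net, x)$p
  expect_equal(dim(p1), c(32, 32, 1, 2))
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, forward_network(net, x)$p)
  # thresholding at 0.5 yields a binary mask
  expect_true(all((p1 > 0.5) %in% c(TRUE, FALSE)))
  # shape errors
  expect_error(forward_network(net, array(0, c(30, 30, 2, 1))), "divisible")
  expect_error(forward_network(net, array(0, c(32, 32, 3, 1))), "channels")
  expect_error(network_spec(2L, depth = 1L), "depth")
})

test_that("parameter count grows with base width", {
  n1 <- n_parameters(build_network(network_spec(1L, 2L, 4L)))
  n2 <- n_parameters(build_network(network_spec(1L, 2L, 8L)))
  n3 <- n_parameters(build_network(network_spec(1L, 2L, 16L)))
  expect_true(n1 < n2 && n2 < n3)
})

test_that("zeroed main path reduces a block to the rectified shortcut", {
  bf <- getFromNamespace("block_fwd", "prostacad")
  ib <- getFromNamespace("init_block", "prostacad")
  ibs <- getFromNamespace("init_block_state", "prostacad")
  set.seed(11)
  p <- ib(2L, 3L); names(p) <- paste0("b.", names(p))
  s <- ibs(3L); names(s) <- paste0("b.", names(s))
  # zero the main path (conv weights and BN affine)
  for (nm in c("b.conv1.w", "b.conv2.w", "b.bn1.gamma", "b.bn2.gamma",
               "b.bn1.beta", "b.bn2.beta", "b.conv1.b", "b.conv2.b"))
    p[[nm]] <- p[[nm]] * 0
  net <- list(params = p, state = s, bn_momentum = 0.1, bn_eps = 1e-5)
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  out <- bf(x, "b", net, FALSE, list())$y
  sc <- prostacad:::.cpp_conv2d_fwd(x, p$b.proj.w, p$b.proj.b)
  expect_equal(out, sc * (sc > 0))
})

test_that("all-zero input yields a spatially constant interior response", {
  set.seed(12)
  net <- build_network(network_spec(1L, depth = 2L, base_width = 4L))
  x <- array(0, c(16, 16, 1, 1))
  p <- forward_network(net, x)$p
  interior <- p[5:12, 5:12, 1, 1]
  expect_lt(max(interior) - min(interior), 1e-10)
})

test_that("analytic block gradients match finite differences", {
  bf <- getFromNamespace("block_fwd", "prostacad")
  bb <- getFromNamespace("block_bwd", "prostacad")
  ib <- getFromNamespace("init_block", "prostacad")
  ibs <- getFromNamespace("init_block_state", "prostacad")
  set.seed(13)
  p <- ib(2L, 3L); names(p) <- paste0("b.", names(p))
  s <- ibs(3L); names(s) <- paste0("b.", names(s))
  net <- list(params = p, state = s, bn_momentum = 0.1, bn_eps = 1e-5)
  x <- array(runif(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  R <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  loss_of <- function(net) sum(bf(x, "b", net, TRUE, list())$y * R)
  f <- bf(x, "b", net, TRUE, list())
  g <- bb(R, f$cache, "b", net, list())$grads
  eps <- 1e-6
  set.seed(14)
  for (nm in names(p)) {
    # gradient must exist for every parameter (no dead shortcut)
    expect_false(is.null(g[[nm]]), info = nm)
    for (i in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      np <- net; np$params[[nm]][i] <- np$params[[nm]][i] + eps
      nm2 <- net; nm2$params[[nm]][i] <- nm2$params[[nm]][i] - eps
      fd <- (loss_of(np) - loss_of(nm2)) / (2 * eps)
      denom <- max(abs(fd), abs(g[[nm]][i]), 1)
      expect_lt(abs(fd - g[[nm]][i]) / denom, 1e-4,
                label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("full-network gradients match finite differences", {
  set.seed(15)
  net <- build_network(network_spec(2L, depth = 2L, base_width = 3L))
  # tiny bias perturbation moves merge pre-activations off the exact
  # ReLU kink that zero-init biases create at dead-feature pixels
  for (nm in grep("\\.b$|beta", names(net$params), value = TRUE))
    net$params[[nm]] <- net$params[[nm]] + rnorm(length(net$params[[nm]]),
                                                 0, 1e-2)
  x <- array(runif(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  y <- array(as.double(runif(8 * 8 * 2) > 0.7), c(8, 8, 1, 2))
  loss_of <- function(net) {
    fw <- forward_network(net, x, training = TRUE)
    dice_loss(fw$p, y)$value
  }
  fw <- forward_network(net, x, training = TRUE)
  ls <- dice_loss(fw$p, y)
  grads <- backward_network(fw$net, fw$cache, ls$dlogits)
  eps <- 1e-6
  set.seed(16)
  for (nm in c("enc1.conv1.w", "enc2.proj.w", "up1.w", "dec1.conv2.w",
               "dec1.proj.w", "final.w", "dec1.bn2.gamma")) {
    for (i in sample(length(net$params[[nm]]),
                     min(2, length(net$params[[nm]])))) {
      np <- net; np$params[[nm]][i] <- np$params[[nm]][i] + eps
      nm2 <- net; nm2$params[[nm]][i] <- nm2$params[[nm]][i] - eps
      fd <- (loss_of(np) - loss_of(nm2)) / (2 * eps)
      denom <- max(abs(fd), abs(grads[[nm]][i]), 1e-3)
      expect_lt(abs(fd - grads[[nm]][i]) / denom, 1e-3,
                label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("loss gradients are consistent with their values", {
  set.seed(17)
  p <- array(runif(8 * 8 * 1 * 3, 0.05, 0.95), c(8, 8, 1, 3))
  y <- array(as.double(runif(8 * 8 * 3) > 0.6), c(8, 8, 1, 3))
  z <- log(p / (1 - p))
  for (fn in list(function(p, y) dice_loss(p, y),
                  function(p, y) dice_loss(p, y, per_sample = TRUE),
                  function(p, y) bce_loss(p, y))) {
    l0 <- fn(p, y)
    eps <- 1e-6
    set.seed(18)
    for (i in sample(length(z), 5)) {
      zp <- z; zp[i] <- zp[i] + eps
      zm <- z; zm[i] <- zm[i] - eps
      fd <- (fn(1 / (1 + exp(-zp)), y)$value -
               fn(1 / (1 + exp(-zm)), y)$value) / (2 * eps)
      expect_equal(fd, l0$dlogits[i], tolerance = 1e-5)
    }
  }
})

test_that("a tiny network overfits a handful of phantom slices", {
  cfg <- toy_config(shape = c(48, 48, 10), spacing = c(2, 2, 4))
  set.seed(19)
  cases <- lapply(1:4, function(i)
    preprocess_case(generate_patient(cfg, id = sprintf("p%d", i)),
                    toy_localizer(32L)))
  ds <- getFromNamespace("make_stage_dataset", "prostacad")(cases, 1L, "adc")
  take <- seq_len(min(20, dim(ds$x)[4]))
  x <- ds$x[, , , take, drop = FALSE]
  y <- ds$y[, , , take, drop = FALSE]
  set.seed(20)
  net <- build_network(network_spec(1L, depth = 2L, base_width = 8L))
  ai <- getFromNamespace("adam_init", "prostacad")
  as_ <- getFromNamespace("adam_step", "prostacad")
  opt <- ai(net$params)
  for (step in 1:200) {
    fw <- forward_network(net, x, training = TRUE)
    net <- fw$net
    ls <- dice_loss(fw$p, y, per_sample = TRUE)
    g <- backward_network(net, fw$cache, ls$dlogits)
    upd <- as_(net$params, g, opt, 1e-3)
    net$params <- upd$params
    opt <- upd$st
  }
  p <- forward_network(net, x, training = FALSE)$p
  d <- 2 * sum(p > 0.5 & y > 0.5) / (sum(p > 0.5) + sum(y > 0.5))
  expect_gte(d, 0.9)
})
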