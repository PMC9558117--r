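# Residual U-Net.
#
# A 2D encoder-decoder with long skip connections in which every
# resolution level is a residual block:
#   main path:  [3x3 conv -> batch norm -> ReLU] x 2
#   shortcut:   1x1 conv projection
#   merge:      addition, then ReLU
# Downsampling is 2x2 max pooling, upsampling is nearest-neighbour
# doubling followed by a 3x3 conv, and the head is a 1x1 conv with a
# logistic output.  Forward and backward passes are written out by hand
# over the compiled conv/pool/upsample kernels; no external deep-learning
# runtime is involved.  Network tensors are (H, W, C, N) arrays.

#' Network specification
#'
#' @param in_channels input channel count (1-4; image channels plus any
#'   conditioning mask channels of the cascade stage).
#' @param depth number of resolution levels (>= 2).
#' @param base_width feature channels at the finest level; widths double
#'   at each deeper level.
#' @param loss_weight optional per-pixel loss-weight map (applied by the
#'   training loss; `NULL` means uniform weighting).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(in_channels, depth = 4L, base_width = 32L,
                         loss_weight = NULL) {
  stopifnot(depth >= 2, in_channels >= 1, in_channels <= 4)
  widths <- as.integer(base_width * 2^(seq_len(depth) - 1))
  structure(list(in_channels = as.integer(in_channels),
                 depth = as.integer(depth),
                 base_width = as.integer(base_width),
                 widths = widths, loss_weight = loss_weight),
            class = "network_spec")
}

he_init <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

block_param_names <- function() c("conv1", "conv2", "proj")

init_block <- function(cin, cout, k = 3L) {
  list(conv1.w = he_init(k, k, cin, cout), conv1.b = numeric(cout),
       bn1.gamma = rep(1, cout), bn1.beta = numeric(cout),
       conv2.w = he_init(k, k, cout, cout), conv2.b = numeric(cout),
       bn2.gamma = rep(1, cout), bn2.beta = numeric(cout),
       proj.w = he_init(1L, 1L, cin, cout), proj.b = numeric(cout))
}

init_block_state <- function(cout) {
  list(bn1.mean = numeric(cout), bn1.var = rep(1, cout),
       bn2.mean = numeric(cout), bn2.var = rep(1, cout))
}

#' Build a residual U-Net
#'
#' Initializes all parameters (He initialization, seeded by the ambient
#' RNG stream) for the architecture described by `spec`.
#'
#' @param spec a `network_spec`.
#' @return An object of class `resunet` holding `spec`, flat parameter
#'   list `params`, and batch-norm running statistics `state`.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  w <- spec$widths
  params <- list()
  state <- list()
  add <- function(prefix, lst) {
    names(lst) <- paste0(prefix, ".", names(lst))
    lst
  }
  cin <- spec$in_channels
  for (l in seq_len(spec$depth)) {
    params <- c(params, add(sprintf("enc%d", l), init_block(cin, w[l])))
    state <- c(state, add(sprintf("enc%d", l), init_block_state(w[l])))
    cin <- w[l]
  }
  for (l in seq.int(spec$depth - 1, 1)) {
    params <- c(params, add(sprintf("up%d", l), list(
      w = he_init(3L, 3L, w[l + 1], w[l]), b = numeric(w[l]))))
    params <- c(params, add(sprintf("dec%d", l), init_block(2L * w[l], w[l])))
    state <- c(state, add(sprintf("dec%d", l), init_block_state(w[l])))
  }
  # head bias starts at a low-foreground prior so sparse-target training
  # does not begin with a violent all-background correction
  params <- c(params, list(final.w = he_init(1L, 1L, w[1], 1L),
                           final.b = -2))
  structure(list(spec = spec, params = params, state = state,
                 bn_momentum = 0.1, bn_eps = 1e-5),
            class = "resunet")
}

#' Number of trainable parameters
#' @param net a `resunet`.
#' @export
n_parameters <- function(net) sum(vapply(net$params, length, 0L))

# --- batch norm over (H, W, N) per channel -------------------------------

bn_broadcast <- function(v, d) rep(rep(v, each = d[1] * d[2]), times = d[4])

bn_channel_stats <- function(x) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1] * d[2])          # columns are (c, n) pairs
  cs <- rowSums(matrix(colSums(xm), nrow = d[3]))
  cs2 <- rowSums(matrix(colSums(xm^2), nrow = d[3]))
  m <- d[1] * d[2] * d[4]
  mu <- cs / m
  list(mu = mu, var = pmax(cs2 / m - mu^2, 0), m = m)
}

bn_fwd <- function(x, gamma, beta, run_mean, run_var, training,
                   momentum, eps) {
  d <- dim(x)
  if (training) {
    st <- bn_channel_stats(x)
    mu <- st$mu; va <- st$var
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * va
  } else {
    mu <- run_mean; va <- run_var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- (x - bn_broadcast(mu, d)) * bn_broadcast(invstd, d)
  y <- xhat * bn_broadcast(gamma, d) + bn_broadcast(beta, d)
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                           d = d),
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dy, cache) {
  d <- cache$d
  m <- d[1] * d[2] * d[4]
  per_channel_sum <- function(a) {
    rowSums(matrix(colSums(matrix(a, nrow = d[1] * d[2])), nrow = d[3]))
  }
  dbeta <- per_channel_sum(dy)
  dgamma <- per_channel_sum(dy * cache$xhat)
  coef <- bn_broadcast(cache$gamma * cache$invstd / m, d)
  dx <- coef * (m * dy - bn_broadcast(dbeta, d) -
                  cache$xhat * bn_broadcast(dgamma, d))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- conv -> BN -> ReLU --------------------------------------------------

cbr_fwd <- function(x, p, s, prefix, cidx, net, training) {
  w <- p[[sprintf("%s.conv%d.w", prefix, cidx)]]
  b <- p[[sprintf("%s.conv%d.b", prefix, cidx)]]
  z <- .cpp_conv2d_fwd(x, w, b)
  bn <- bn_fwd(z, p[[sprintf("%s.bn%d.gamma", prefix, cidx)]],
               p[[sprintf("%s.bn%d.beta", prefix, cidx)]],
               s[[sprintf("%s.bn%d.mean", prefix, cidx)]],
               s[[sprintf("%s.bn%d.var", prefix, cidx)]],
               training, net$bn_momentum, net$bn_eps)
  y <- bn$y * (bn$y > 0)
  list(y = y, cache = list(x = x, z = z, bn = bn$cache, relu = bn$y > 0),
       run = list(mean = bn$run_mean, var = bn$run_var))
}

cbr_bwd <- function(dy, cache, p, prefix, cidx, grads) {
  dz_bn <- dy * cache$relu
  bnb <- bn_bwd(dz_bn, cache$bn)
  w <- p[[sprintf("%s.conv%d.w", prefix, cidx)]]
  cv <- .cpp_conv2d_bwd(cache$x, w, bnb$dx)
  grads[[sprintf("%s.conv%d.w", prefix, cidx)]] <- cv$dw
  grads[[sprintf("%s.conv%d.b", prefix, cidx)]] <- cv$db
  grads[[sprintf("%s.bn%d.gamma", prefix, cidx)]] <- bnb$dgamma
  grads[[sprintf("%s.bn%d.beta", prefix, cidx)]] <- bnb$dbeta
  list(dx = cv$dx, grads = grads)
}

block_fwd <- function(x, prefix, net, training, runs) {
  p <- net$params
  c1 <- cbr_fwd(x, p, net$state, prefix, 1L, net, training)
  c2 <- cbr_fwd(c1$y, p, net$state, prefix, 2L, net, training)
  sc <- .cpp_conv2d_fwd(x, p[[paste0(prefix, ".proj.w")]],
                        p[[paste0(prefix, ".proj.b")]])
  pre <- c2$y + sc
  y <- pre * (pre > 0)
  if (training) {
    runs[[paste0(prefix, ".bn1")]] <- c1$run
    runs[[paste0(prefix, ".bn2")]] <- c2$run
  }
  list(y = y, cache = list(x = x, c1 = c1$cache, c2 = c2$cache,
                           relu = pre > 0), runs = runs)
}

block_bwd <- function(dy, cache, prefix, net, grads) {
  p <- net$params
  dpre <- dy * cache$relu
  # shortcut branch
  sc <- .cpp_conv2d_bwd(cache$x, p[[paste0(prefix, ".proj.w")]], dpre)
  grads[[paste0(prefix, ".proj.w")]] <- sc$dw
  grads[[paste0(prefix, ".proj.b")]] <- sc$db
  # main branch
  b2 <- cbr_bwd(dpre, cache$c2, p, prefix, 2L, grads)
  grads <- b2$grads
  b1 <- cbr_bwd(b2$dx, cache$c1, p, prefix, 1L, grads)
  grads <- b1$grads
  list(dx = b1$dx + sc$dx, grads = grads)
}

concat_c <- function(a, b) {
  d <- dim(a)
  db <- dim(b)
  out <- array(0, c(d[1], d[2], d[3] + db[3], d[4]))
  out[, , seq_len(d[3]), ] <- a
  out[, , d[3] + seq_len(db[3]), ] <- b
  out
}

#' Forward pass of a residual U-Net
#'
#' @param net a `resunet`.
#' @param x input tensor, numeric array `(H, W, C, N)` with `C` equal to
#'   `net$spec$in_channels`; `H` and `W` must be divisible by
#'   `2^(depth-1)`.
#' @param training use batch statistics (and keep caches for
#'   [backward_network()])?  Inference mode is deterministic for fixed
#'   weights.
#' @return list with `p` (per-pixel probabilities `(H, W, 1, N)`), and in
#'   training mode `cache`; in training mode the returned `net` carries
#'   updated running statistics.
#' @export
forward_network <- function(net, x, training = FALSE) {
  spec <- net$spec
  d <- dim(x)
  if (length(d) != 4L || d[3] != spec$in_channels)
    stop("input has ", if (length(d) == 4) d[3] else "?",
         " channels; network expects ", spec$in_channels)
  if (d[1] %% 2^(spec$depth - 1) != 0 || d[2] %% 2^(spec$depth - 1) != 0)
    stop("spatial size must be divisible by 2^(depth-1)")
  runs <- list()
  caches <- list()
  skips <- list()
  h <- x
  for (l in seq_len(spec$depth)) {
    bf <- block_fwd(h, sprintf("enc%d", l), net, training, runs)
    runs <- bf$runs
    caches[[sprintf("enc%d", l)]] <- bf$cache
    h <- bf$y
    if (l < spec$depth) {
      skips[[l]] <- h
      mp <- .cpp_maxpool2_fwd(h)
      caches[[sprintf("pool%d", l)]] <- list(arg = mp$arg, xdim = dim(h))
      h <- mp$y
    }
  }
  for (l in seq.int(spec$depth - 1, 1)) {
    hin_dim <- dim(h)
    up <- .cpp_upsample2_fwd(h)
    uw <- net$params[[sprintf("up%d.w", l)]]
    uz <- .cpp_conv2d_fwd(up, uw, net$params[[sprintf("up%d.b", l)]])
    urelu <- uz > 0
    uy <- uz * urelu
    caches[[sprintf("up%d", l)]] <- list(hin_dim = hin_dim, up = up,
                                         relu = urelu)
    h <- concat_c(skips[[l]], uy)
    caches[[sprintf("cat%d", l)]] <- dim(skips[[l]])[3]
    bf <- block_fwd(h, sprintf("dec%d", l), net, training, runs)
    runs <- bf$runs
    caches[[sprintf("dec%d", l)]] <- bf$cache
    h <- bf$y
  }
  logits <- .cpp_conv2d_fwd(h, net$params$final.w, net$params$final.b)
  p <- 1 / (1 + exp(-logits))
  caches$head <- list(x = h, p = p)
  if (training) {
    for (nm in names(runs)) {
      net$state[[paste0(nm, ".mean")]] <- runs[[nm]]$mean
      net$state[[paste0(nm, ".var")]] <- runs[[nm]]$var
    }
    list(p = p, cache = caches, net = net)
  } else list(p = p)
}

#' Backward pass: gradients of a loss through the network
#'
#' @param net the `resunet` used in the forward pass.
#' @param cache the `cache` returned by [forward_network()] with
#'   `training = TRUE`.
#' @param dlogits gradient of the loss with respect to the pre-sigmoid
#'   logits (same shape as the probability map).
#' @return flat named list of parameter gradients.
#' @export
backward_network <- function(net, cache, dlogits) {
  spec <- net$spec
  D <- spec$depth
  grads <- list()
  hv <- .cpp_conv2d_bwd(cache$head$x, net$params$final.w, dlogits)
  grads$final.w <- hv$dw
  grads$final.b <- hv$db
  dh <- hv$dx
  dskips <- vector("list", D - 1)
  # decoder, in reverse of the forward order (forward ran l = D-1 .. 1)
  for (l in seq_len(D - 1)) {
    bb <- block_bwd(dh, cache[[sprintf("dec%d", l)]], sprintf("dec%d", l),
                    net, grads)
    grads <- bb$grads
    nskip <- cache[[sprintf("cat%d", l)]]
    dskips[[l]] <- bb$dx[, , seq_len(nskip), , drop = FALSE]
    duy <- bb$dx[, , nskip + seq_len(dim(bb$dx)[3] - nskip), , drop = FALSE]
    upc <- cache[[sprintf("up%d", l)]]
    duz <- duy * upc$relu
    uv <- .cpp_conv2d_bwd(upc$up, net$params[[sprintf("up%d.w", l)]], duz)
    grads[[sprintf("up%d.w", l)]] <- uv$dw
    grads[[sprintf("up%d.b", l)]] <- uv$db
    dh <- .cpp_upsample2_bwd(uv$dx)  # grad wrt the deeper decoder output
  }
  # encoder, deepest level first; skip gradients join below each pooling
  for (l in seq.int(D, 1)) {
    bb <- block_bwd(dh, cache[[sprintf("enc%d", l)]], sprintf("enc%d", l),
                    net, grads)
    grads <- bb$grads
    dh <- bb$dx
    if (l > 1) {
      mp <- cache[[sprintf("pool%d", l - 1)]]
      dh <- .cpp_maxpool2_bwd(dh, mp$arg, as.integer(mp$xdim)) +
        dskips[[l - 1]]
    }
  }
  grads
}
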