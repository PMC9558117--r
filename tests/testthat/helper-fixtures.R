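# Shared fixtures: small phantom configurations and brute-force oracles
# kept deliberately independent of the package's own counting code.

toy_config <- function(seed = 11L, shape = c(64, 64, 12),
                       spacing = c(2, 2, 4), ...) {
  phantom_config(shape = shape, spacing = spacing, seed = seed, ...)
}

toy_localizer <- function(patch = 32L) localizer_config(patch_size = patch)

toy_net_specs <- function(width = 8L)
  lapply(1:3, function(i) network_spec(1L, depth = 2L, base_width = width))

# random small binary mask on a tiny grid
random_mask <- function(d, p = 0.2) array(as.double(runif(prod(d)) < p), d)

# Brute-force lesion matching oracle: plain loops over slices and voxel
# arrays, no component bookkeeping shared with the package.
oracle_match_lesions <- function(pred_arrs, truth_arrs, frac = 0.5) {
  np <- length(pred_arrs); ng <- length(truth_arrs)
  pair <- matrix(FALSE, max(np, 1), max(ng, 1))
  for (ip in seq_len(np)) for (ig in seq_len(ng)) {
    P <- pred_arrs[[ip]]; G <- truth_arrs[[ig]]
    for (k in seq_len(dim(G)[3])) {
      ta <- sum(G[, , k])
      if (ta == 0) next
      if (sum(P[, , k] * G[, , k]) / ta >= frac) {
        pair[ip, ig] <- TRUE
        break
      }
    }
  }
  tp <- 0; fp <- 0
  for (ip in seq_len(np)) {
    if (ng > 0 && any(pair[ip, seq_len(ng)])) tp <- tp + 1 else fp <- fp + 1
  }
  fn <- 0
  for (ig in seq_len(ng))
    if (np == 0 || !any(pair[seq_len(np), ig])) fn <- fn + 1
  list(tp = tp, fp = fp, fn = fn, pair = pair)
}

# Brute-force sextant containment oracle.
oracle_sextant_positive <- function(lesion_arrs, sextant_arrs,
                                    cov = 0.5, occ = 0.5) {
  hit <- rep(FALSE, length(sextant_arrs))
  for (L in lesion_arrs) {
    nl <- sum(L)
    for (s in seq_along(sextant_arrs)) {
      S <- sextant_arrs[[s]]
      ov <- sum(L * S)
      if ((nl > 0 && ov / nl >= cov) || (sum(S) > 0 && ov / sum(S) >= occ))
        hit[s] <- TRUE
    }
  }
  hit
}

# split an array into per-component arrays with a naive flood fill (6-conn)
oracle_components6 <- function(arr) {
  d <- dim(arr)
  seen <- array(FALSE, d)
  comps <- list()
  idx <- which(arr > 0.5)
  for (start in idx) {
    if (seen[start]) next
    stack <- start
    mem <- c()
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[cur]) next
      seen[cur] <- TRUE
      mem <- c(mem, cur)
      ai <- arrayInd(cur, d)
      for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))) {
        nb <- ai + off
        if (all(nb >= 1) && all(nb <= d)) {
          ni <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
          if (arr[ni] > 0.5 && !seen[ni]) stack <- c(stack, ni)
        }
      }
    }
    m <- array(0, d); m[mem] <- 1
    comps[[length(comps) + 1L]] <- m
  }
  comps
}
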