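# Independent brute-force oracles: scalar loops and full enumerations,
# deliberately written without reusing any package internals.

oracle_dice <- function(pred, ref) {
  np <- 0L; nr <- 0L; ni <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] != 0
    r <- ref[i] != 0
    np <- np + p
    nr <- nr + r
    ni <- ni + (p && r)
  }
  if (np + nr == 0) 1 else 2 * ni / (np + nr)
}

oracle_ratio_map <- function(t1n, t2n, mask, alpha) {
  out <- array(0, dim = dim(t1n))
  for (i in seq_along(t1n)) {
    if (mask[i] != 0) out[i] <- t1n[i] / (t2n[i] + alpha)
  }
  out
}

oracle_combined_map <- function(t1w, t2w, beta, mask) {
  out <- array(0, dim = dim(t1w))
  for (i in seq_along(t1w)) {
    if (mask[i] != 0) {
      den <- t1w[i] + beta * t2w[i]
      out[i] <- if (den == 0) 0 else (t1w[i] - beta * t2w[i]) / den
    }
  }
  out
}

# per-voxel Gaussian posterior argmax, via dnorm at each voxel
oracle_predict <- function(model, channels, mask) {
  d <- dim(mask)
  out <- array(0L, dim = d)
  for (i in seq_along(mask)) {
    if (mask[i] == 0) next
    x <- vapply(channels, function(v) v[i], numeric(1))
    best_ll <- -Inf; best_k <- 0L
    for (k in 1:5) {
      if (!is.finite(model$log_priors[k])) next
      ll <- model$log_priors[k] +
        sum(dnorm(x, model$means[k, ], sqrt(model$vars[k, ]), log = TRUE))
      if (ll > best_ll) { best_ll <- ll; best_k <- k - 1L }
    }
    out[i] <- best_k
  }
  out
}

# full 2^n sign-assignment enumeration of the one-tailed signed-rank null;
# returns P(W >= W_obs) and the point mass P(W = W_obs)
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  ws <- apply(signs, 1, function(s) sum(r[s]))
  list(W = w_obs,
       p = mean(ws >= w_obs - 1e-9),
       point_mass = mean(abs(ws - w_obs) < 1e-9))
}

# small helper: a case-like list with constant per-class channel intensities
make_constant_case <- function(labels, class_means, brain_mask = NULL) {
  d <- dim(labels)
  if (is.null(brain_mask)) brain_mask <- array(1L, dim = d)
  channels <- lapply(seq_len(ncol(class_means)), function(ch)
    array(class_means[labels + 1L, ch], dim = d))
  names(channels) <- paste0("ch", seq_len(ncol(class_means)))
  list(channels = channels, labels = labels, brain_mask = brain_mask)
}

small_spec <- function(...) {
  phantom_spec(grid_shape = c(32L, 32L, 32L), ...)
}
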