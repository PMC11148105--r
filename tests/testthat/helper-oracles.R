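# Independent straight-loop oracles and small fixture builders shared by
# the test files. The oracles deliberately avoid every code path of the
# package's own operators: plain nested loops over kernel footprints and
# per-pixel tallies.

# Brute-force dilated "same"-padded 2-D convolution, layout (H, W, C, N).
oracle_conv2d <- function(x, w, b, d) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]; N <- dim(x)[4]
  k <- dim(w)[1]; O <- dim(w)[4]; half <- (k - 1) / 2
  y <- array(0, c(H, W, O, N))
  for (n in seq_len(N)) for (o in seq_len(O)) for (h in seq_len(H)) {
    for (wi in seq_len(W)) {
      s <- b[o]
      for (c in seq_len(C)) for (ki in seq_len(k)) for (kj in seq_len(k)) {
        hh <- h + (ki - 1 - half) * d
        ww <- wi + (kj - 1 - half) * d
        if (hh >= 1 && hh <= H && ww >= 1 && ww <= W) {
          s <- s + x[hh, ww, c, n] * w[ki, kj, c, o]
        }
      }
      y[h, wi, o, n] <- s
    }
  }
  y
}

# Oracle for the conv unit in eval mode with fresh statistics: the batch
# norm reduces to x / sqrt(1 + eps), then ReLU, then the dilated conv.
oracle_conv_unit <- function(x, params, d, eps = 1e-5) {
  h <- x / sqrt(1 + eps)
  h <- h * (h > 0)
  oracle_conv2d(h, params$w, params$b, d)
}

# Straight-loop spatial attention: per-pixel channel mean and max, 2-channel
# 7x7 convolution, sigmoid.
oracle_spatial_attention <- function(x, params) {
  d <- dim(x)
  cat2 <- array(0, c(d[1], d[2], 2, d[4]))
  for (n in seq_len(d[4])) for (h in seq_len(d[1])) for (w in seq_len(d[2])) {
    cat2[h, w, 1, n] <- mean(x[h, w, , n])
    cat2[h, w, 2, n] <- max(x[h, w, , n])
  }
  z <- oracle_conv2d(cat2, params$sconv, params$sbias, 1)
  1 / (1 + exp(-z))
}

# Closed-form channel attention (no hidden ReLU assumption handled by flag).
oracle_channel_attention <- function(x, params, hidden_relu = TRUE) {
  d <- dim(x)
  out <- array(0, c(1, 1, d[3], d[4]))
  for (n in seq_len(d[4])) {
    avg <- vapply(seq_len(d[3]), function(c) mean(x[, , c, n]), numeric(1))
    mx <- vapply(seq_len(d[3]), function(c) max(x[, , c, n]), numeric(1))
    mlp <- function(v) {
      h <- as.numeric(params$w0 %*% v + params$b0)
      if (hidden_relu) h <- pmax(h, 0)
      as.numeric(params$w1 %*% h + params$b1)
    }
    out[1, 1, , n] <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))))
  }
  out
}

# Per-pixel confusion tally by explicit loop.
oracle_confusion <- function(gt, pr) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(gt)) {
    if (gt[i] == 1 && pr[i] == 1) tp <- tp + 1L
    if (gt[i] == 0 && pr[i] == 0) tn <- tn + 1L
    if (gt[i] == 0 && pr[i] == 1) fp <- fp + 1L
    if (gt[i] == 1 && pr[i] == 0) fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Scalar-loop cross-entropy oracles.
oracle_bce <- function(p, q, eps = 1e-7) {
  s <- 0
  for (i in seq_along(p)) {
    pi <- min(max(p[i], eps), 1 - eps)
    s <- s + q[i] * log(pi) + (1 - q[i]) * log(1 - pi)
  }
  -s / length(p)
}

# Zero every conv weight / bias inside a (nested) parameter list while
# keeping batch-norm scales.
zero_conv_params <- function(p) {
  if (is.list(p)) {
    out <- lapply(p, zero_conv_params)
    attributes(out) <- attributes(p)
    return(out)
  }
  p
}

zero_block_weights <- function(block) {
  block$branches <- lapply(block$branches, function(br) {
    lapply(br, function(u) {
      u$w[] <- 0
      u$b[] <- 0
      u
    })
  })
  block
}

zero_all <- function(p) {
  out <- lapply(p, function(a) if (is.list(a)) zero_all(a) else a * 0)
  attributes(out) <- attributes(p)
  out
}

tiny_config <- function(num_classes = 1, in_channels = 1, input_size = 64) {
  madrnet_config(in_channels = in_channels, num_classes = num_classes,
                 input_size = input_size,
                 channel_progression = c(4, 8, 16, 32, 64, 128))
}

random_feature_map <- function(h, w, c, n, seed = 1) {
  withr::with_seed(seed, array(rnorm(h * w * c * n), c(h, w, c, n)))
}

random_mask_pair <- function(h = 8, w = 8, seed = 1) {
  withr::with_seed(seed, list(gt = matrix(rbinom(h * w, 1, 0.4), h, w),
                              pr = matrix(rbinom(h * w, 1, 0.4), h, w)))
}
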