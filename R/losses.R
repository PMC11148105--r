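# Training losses: binary / categorical cross-entropy, soft dice, focal
# Tversky, and their hybrid combination. All losses take probability maps
# `p` and hard targets `q` as (H, W, M, N) arrays (M = 1 for binary) and
# return a scalar. Analytic gradients with respect to `p` back the autodiff
# loss nodes.

CLIP_EPS <- 1e-7

check_pq <- function(p, q) {
  if (!identical(dim(p), dim(q))) abort("`p` and `q` must have equal shapes")
  if (length(p) == 0) abort("empty prediction/target arrays")
  invisible(NULL)
}

clip01 <- function(p) pmin(pmax(p, CLIP_EPS), 1 - CLIP_EPS)

#' Loss configuration
#'
#' Holds the focal-Tversky asymmetry weights (`alpha` penalises false
#' positives, `beta` false negatives; the published choice is
#' `alpha = 0.7`, `beta = 0.3` to favour recall under class imbalance), the
#' focusing exponent `gamma` (the loss raises `1 - TI` to `1 / gamma`;
#' `gamma = 1.33` gives exponent ~0.752), and the weights of the hybrid
#' combination (cross-entropy, dice, focal Tversky; default equal weights).
#'
#' @param alpha,beta,gamma focal-Tversky parameters; `gamma > 0`.
#' @param w_ce,w_dice,w_ft non-negative hybrid weights, not all zero.
#' @param mode `"binary"` (BCE cross-entropy term) or `"multiclass"` (CCE).
#' @return an object of class `madrnet_loss_config`.
#' @export
loss_config <- function(alpha = 0.7, beta = 0.3, gamma = 1.33,
                        w_ce = 1, w_dice = 1, w_ft = 1,
                        mode = c("binary", "multiclass")) {
  mode <- match.arg(mode)
  if (gamma <= 0) abort("`gamma` must be positive")
  if (any(c(w_ce, w_dice, w_ft) < 0) || w_ce + w_dice + w_ft == 0) {
    abort("hybrid weights must be non-negative and not all zero")
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 w_ce = w_ce, w_dice = w_dice, w_ft = w_ft, mode = mode),
            class = "madrnet_loss_config")
}

#' Binary cross-entropy loss
#'
#' `-(1/N) * sum(q log p + (1 - q) log(1 - p))` over all `N` output
#' elements, with `p` clipped to `[1e-7, 1 - 1e-7]` so gradients stay
#' finite at hard predictions.
#'
#' @param p probability array; `q` hard target array of the same shape with
#'   values in {0, 1}.
#' @param q target array.
#' @return non-negative scalar.
#' @export
bce_loss <- function(p, q) {
  check_pq(p, q)
  pc <- clip01(p)
  -mean(q * log(pc) + (1 - q) * log(1 - pc))
}

grad_bce <- function(p, q) {
  pc <- clip01(p)
  inside <- (p > CLIP_EPS & p < 1 - CLIP_EPS)
  (-q / pc + (1 - q) / (1 - pc)) * inside / length(p)
}

#' Categorical cross-entropy loss
#'
#' `-(1/N) * sum_m sum_i q[i, m] log p[i, m]` where `N` is the number of
#' pixels and `q` is one-hot over the `M` channel classes.
#'
#' @param p probability array `(H, W, M, N)` summing to 1 over channels.
#' @param q one-hot target array of the same shape.
#' @return non-negative scalar.
#' @export
cce_loss <- function(p, q) {
  check_pq(p, q)
  if (!all(q %in% c(0, 1)) ||
      max(abs(apply(q, c(1, 2, 4), sum) - 1)) > 1e-8) {
    abort("`q` must be one-hot over the channel axis")
  }
  n_pix <- length(q) / dim(q)[3]
  -sum(q * log(clip01(p))) / n_pix
}

grad_cce <- function(p, q) {
  n_pix <- length(q) / dim(q)[3]
  pc <- clip01(p)
  inside <- (p > CLIP_EPS)
  -q / pc * inside / n_pix
}

#' Soft dice loss
#'
#' `1 - (2 sum(p q) + s) / (sum(p) + sum(q) + s)`. The default smoothing
#' `s = 1` keeps the loss differentiable on empty masks; `smooth = 0` gives
#' exactly `1 - DSC` on hard masks.
#'
#' @inheritParams bce_loss
#' @param smooth smoothing constant `s`.
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(p, q, smooth = 1) {
  check_pq(p, q)
  1 - (2 * sum(p * q) + smooth) / (sum(p) + sum(q) + smooth)
}

grad_dice <- function(p, q, smooth = 1) {
  a <- 2 * sum(p * q) + smooth
  b <- sum(p) + sum(q) + smooth
  -(2 * q * b - a) / b^2
}

#' Focal Tversky loss
#'
#' Per class `m`, the Tversky index
#' `TI_m = sum(p0 q0) / (sum(p0 q0) + alpha sum(p0 q1) + beta sum(p1 q0))`
#' uses the soft foreground probability `p0` of class `m` (`p1 = 1 - p0`)
#' and the hard indicators `q0`, `q1 = 1 - q0`. The loss is
#' `sum_m (1 - TI_m)^(1/gamma)`: 0 for a perfect hard prediction and exactly
#' `M` for a completely wrong one. With `alpha = beta = 0.5`, `gamma = 1` it
#' coincides with the unsmoothed dice loss per class.
#'
#' @inheritParams bce_loss
#' @param alpha,beta,gamma see [loss_config()].
#' @return scalar in `[0, M]`.
#' @export
focal_tversky_loss <- function(p, q, alpha = 0.7, beta = 0.3, gamma = 1.33) {
  check_pq(p, q)
  if (gamma <= 0) abort("`gamma` must be positive")
  M <- dim(p)[3]
  total <- 0
  for (m in seq_len(M)) {
    p0 <- p[, , m, , drop = FALSE]
    q0 <- q[, , m, , drop = FALSE]
    ti <- tversky_index(p0, q0, alpha, beta)
    total <- total + (1 - ti)^(1 / gamma)
  }
  total
}

tversky_index <- function(p0, q0, alpha, beta) {
  num <- sum(p0 * q0)
  den <- num + alpha * sum(p0 * (1 - q0)) + beta * sum((1 - p0) * q0)
  if (den == 0) 1 else num / den
}

grad_ft <- function(p, q, alpha, beta, gamma) {
  M <- dim(p)[3]
  g <- array(0, dim(p))
  for (m in seq_len(M)) {
    p0 <- p[, , m, , drop = FALSE]
    q0 <- q[, , m, , drop = FALSE]
    num <- sum(p0 * q0)
    den <- num + alpha * sum(p0 * (1 - q0)) + beta * sum((1 - p0) * q0)
    if (den == 0) next
    ti <- num / den
    dden <- q0 + alpha * (1 - q0) - beta * q0
    dti <- (q0 * den - num * dden) / den^2
    outer_g <- -(1 / gamma) * max(1 - ti, 1e-6)^(1 / gamma - 1)
    g[, , m, ] <- outer_g * dti
  }
  g
}

#' Hybrid segmentation loss
#'
#' Weighted sum of a cross-entropy term (BCE in binary mode, CCE in
#' multiclass mode), the soft dice loss, and the focal Tversky loss:
#' `w_ce * l_CE + w_dice * l_DSC + w_ft * l_FT`, default weights (1, 1, 1).
#'
#' @inheritParams bce_loss
#' @param config a [loss_config()].
#' @param smooth dice smoothing constant.
#' @return scalar.
#' @export
hybrid_loss <- function(p, q, config = loss_config(), smooth = 1) {
  check_pq(p, q)
  ce <- if (config$mode == "binary") bce_loss(p, q) else cce_loss(p, q)
  config$w_ce * ce + config$w_dice * dice_loss(p, q, smooth) +
    config$w_ft * focal_tversky_loss(p, q, config$alpha, config$beta,
                                     config$gamma)
}

# ---- tape-level loss nodes -------------------------------------------------

op_loss <- function(tape, p, q, value_fn, grad_fn) {
  tape_node(tape, value_fn(p$v, q), p$id,
            function(g) list(g * grad_fn(p$v, q)))
}

# Hybrid loss on the tape; returns list of scalar nodes (total + components).
fwd_hybrid_loss <- function(tape, p, q, config, smooth = 1) {
  ce <- if (config$mode == "binary") {
    op_loss(tape, p, q, bce_loss, grad_bce)
  } else {
    op_loss(tape, p, q, cce_loss, grad_cce)
  }
  dl <- op_loss(tape, p, q, function(pv, qv) dice_loss(pv, qv, smooth),
                function(pv, qv) grad_dice(pv, qv, smooth))
  ft <- op_loss(tape, p, q,
                function(pv, qv) focal_tversky_loss(pv, qv, config$alpha,
                                                    config$beta, config$gamma),
                function(pv, qv) grad_ft(pv, qv, config$alpha, config$beta,
                                         config$gamma))
  total <- op_wsum(tape, list(ce, dl, ft),
                   c(config$w_ce, config$w_dice, config$w_ft))
  list(total = total, ce = ce$v, dice = dl$v, ft = ft$v)
}

#' One-hot encode an integer label mask
#'
#' @param mask array `(H, W, 1, N)` with labels in `0..M-1`.
#' @param num_classes number of classes M.
#' @return array `(H, W, M, N)` of 0/1 indicators.
#' @export
mask_to_onehot <- function(mask, num_classes) {
  d <- dim(mask)
  if (any(mask < 0) || any(mask > num_classes - 1)) {
    abort("mask labels out of range")
  }
  out <- array(0, c(d[1], d[2], num_classes, d[4]))
  for (m in seq_len(num_classes)) {
    out[, , m, ] <- (mask[, , 1, ] == m - 1)
  }
  out
}
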