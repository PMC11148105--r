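# Core computational blocks: dilated conv units, the multi-dilated residual
# block, ASPP, and the channel-spatial attention module. Each block exists
# in two forms: a tape-level forward (fwd_*) used inside the network, and an
# exported array-in/array-out wrapper for direct use and testing.

#' Effective kernel size of a dilated convolution
#'
#' A `k x k` kernel with dilation rate `d` spaces its taps `d` pixels apart,
#' so it covers `k + (k - 1) (d - 1)` pixels per side without adding
#' parameters. A 3x3 kernel therefore covers 3 pixels at `d = 1` and 11 at
#' `d = 5`; 1x1 kernels are dilation-invariant.
#'
#' @param kernel_size odd positive integer, kernel side length in pixels.
#' @param dilation positive integer dilation rate.
#' @return integer effective side length in pixels (vectorised).
#' @examples
#' effective_kernel_size(3, 1)
#' effective_kernel_size(3, 5)
#' @export
effective_kernel_size <- function(kernel_size, dilation) {
  if (length(kernel_size) == 0 || length(dilation) == 0 ||
      any(!is.finite(kernel_size)) || any(!is.finite(dilation)) ||
      any(kernel_size < 1) || any(dilation < 1) ||
      any(kernel_size != as.integer(kernel_size)) ||
      any(dilation != as.integer(dilation))) {
    abort("`kernel_size` and `dilation` must be positive integers")
  }
  as.integer(kernel_size + (kernel_size - 1) * (dilation - 1))
}

check_feature_map <- function(x, arg = "x") {
  if (!is.array(x) || length(dim(x)) != 4) {
    abort(sprintf("`%s` must be a 4-D (H, W, C, N) array", arg))
  }
  if (any(!is.finite(x))) abort(sprintf("`%s` contains non-finite values", arg))
  invisible(x)
}

# ---- parameter initialisers ------------------------------------------------

he_conv <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

#' @rdname conv_unit
#' @param in_channels,out_channels channel counts of the unit.
#' @param kernel_size kernel side length (odd).
#' @export
init_conv_unit <- function(in_channels, out_channels, kernel_size = 3) {
  list(gamma = rep(1, in_channels), beta = rep(0, in_channels),
       w = he_conv(kernel_size, in_channels, out_channels),
       b = rep(0, out_channels))
}

#' @rdname multi_dilated_residual_block
#' @export
init_mdr_block <- function(in_channels, out_channels, rates = c(1, 3, 5, 11),
                           branch_depth = 1, kernel_size = 3) {
  if (length(rates) < 1) abort("`rates` must be non-empty")
  branches <- lapply(sort(rates), function(r) {
    units <- vector("list", branch_depth)
    cin <- in_channels
    for (t in seq_len(branch_depth)) {
      units[[t]] <- init_conv_unit(cin, out_channels, kernel_size)
      cin <- out_channels
    }
    units
  })
  p <- list(branches = branches)
  if (in_channels != out_channels) {
    p$proj <- list(w = he_conv(1, in_channels, out_channels),
                   b = rep(0, out_channels))
  }
  attr(p, "rates") <- sort(rates)
  p
}

#' @rdname aspp
#' @export
init_aspp <- function(in_channels, out_channels, rates = c(6, 12, 18)) {
  branch_width <- out_channels
  dilated <- lapply(rates, function(r) init_conv_unit(in_channels, branch_width, 3))
  p <- list(
    c1x1 = init_conv_unit(in_channels, branch_width, 1),
    dilated = dilated,
    pool = list(w = he_conv(1, in_channels, branch_width),
                b = rep(0, branch_width)),
    fuse = init_conv_unit((length(rates) + 2) * branch_width, out_channels, 1)
  )
  attr(p, "rates") <- rates
  p
}

#' @rdname channel_attention
#' @param channels number of channels `C` of the gated feature map.
#' @param reduction_ratio positive integer `r` with `C / r >= 1`; width of the
#'   perceptron hidden layer is `C / r`.
#' @param spatial_kernel side length of the spatial-attention convolution.
#' @export
init_csam <- function(channels, reduction_ratio = 16, spatial_kernel = 7) {
  if (channels %% reduction_ratio != 0 && channels > reduction_ratio) {
    abort("`channels` must be divisible by `reduction_ratio`")
  }
  # hidden width C/r, floored at min(C, 4): a one-unit hidden layer can die
  # at initialisation (zero attention gradients), a four-unit one cannot in
  # practice
  hidden <- min(channels, max(4L, channels %/% reduction_ratio))
  list(
    w0 = matrix(rnorm(hidden * channels, sd = sqrt(2 / channels)), hidden, channels),
    # small positive bias keeps narrow hidden layers active at init, so
    # attention gradients flow from the first step
    b0 = rep(0.1, hidden),
    w1 = matrix(rnorm(channels * hidden, sd = sqrt(2 / hidden)), channels, hidden),
    b1 = rep(0, channels),
    sconv = he_conv(spatial_kernel, 2, 1),
    sbias = 0
  )
}

# ---- tape-level forwards ---------------------------------------------------

# Wrap every array in a (nested) parameter list as a named tape leaf.
params_to_nodes <- function(tape, p, prefix = "p") {
  if (is.list(p)) {
    out <- lapply(seq_along(p), function(i) {
      nm <- names(p)[i] %||% as.character(i)
      params_to_nodes(tape, p[[i]], paste(prefix, nm, sep = "."))
    })
    names(out) <- names(p)
    out
  } else if (is.numeric(p)) {
    leaf(tape, p, name = prefix)
  } else {
    p  # e.g. stored rates
  }
}

fwd_conv_unit <- function(tape, x, pn, dilation, training, state, key) {
  h <- op_batchnorm(tape, x, pn$gamma, pn$beta, training, state, key)
  h <- op_relu(tape, h)
  op_conv2d(tape, h, pn$w, pn$b, dilation)
}

fwd_mdr_block <- function(tape, x, pn, rates, training, state, key) {
  acc <- NULL
  for (i in seq_along(rates)) {
    h <- x
    for (t in seq_along(pn$branches[[i]])) {
      h <- fwd_conv_unit(tape, h, pn$branches[[i]][[t]], rates[i],
                         training, state, sprintf("%s.br%d.u%d", key, i, t))
    }
    acc <- if (is.null(acc)) h else op_add(tape, acc, h)
  }
  res <- if (!is.null(pn$proj)) {
    op_conv2d(tape, x, pn$proj$w, pn$proj$b, 1L)
  } else {
    if (dim(x$v)[3] != dim(acc$v)[3]) {
      abort("channel mismatch in residual path and no projection configured")
    }
    x
  }
  op_add(tape, res, acc)
}

fwd_aspp <- function(tape, x, pn, rates, training, state, key) {
  d <- dim(x$v)
  branches <- list(fwd_conv_unit(tape, x, pn$c1x1, 1L, training, state,
                                 paste0(key, ".c1x1")))
  for (i in seq_along(rates)) {
    branches[[length(branches) + 1]] <-
      fwd_conv_unit(tape, x, pn$dilated[[i]], rates[i], training, state,
                    sprintf("%s.d%d", key, i))
  }
  pooled <- op_gap(tape, x)
  pooled <- op_conv2d(tape, pooled, pn$pool$w, pn$pool$b, 1L)
  branches[[length(branches) + 1]] <- op_bcast_hw(tape, pooled, d[1], d[2])
  cat_ <- op_concat_c(tape, branches)
  fwd_conv_unit(tape, cat_, pn$fuse, 1L, training, state, paste0(key, ".fuse"))
}

fwd_channel_attention <- function(tape, x, pn, hidden_relu = TRUE) {
  mlp <- function(desc) {
    h <- op_linear(tape, op_squeeze_hw(tape, desc), pn$w0, pn$b0)
    if (hidden_relu) h <- op_relu(tape, h)
    op_linear(tape, h, pn$w1, pn$b1)
  }
  s <- op_add(tape, mlp(op_gap(tape, x)), mlp(op_gmp(tape, x)))
  op_sigmoid(tape, op_unsqueeze_hw(tape, s))
}

fwd_spatial_attention <- function(tape, x, pn) {
  cat_ <- op_concat_c(tape, list(op_cmean(tape, x), op_cmax(tape, x)))
  op_sigmoid(tape, op_conv2d(tape, cat_, pn$sconv, pn$sbias, 1L))
}

fwd_csam <- function(tape, x, pn, hidden_relu = TRUE) {
  f1 <- op_mul_gate(tape, x, fwd_channel_attention(tape, x, pn, hidden_relu))
  op_mul_gate(tape, f1, fwd_spatial_attention(tape, f1, pn))
}

# ---- exported array-level wrappers ----------------------------------------

run_block <- function(x, params, fn) {
  check_feature_map(x)
  tape <- new_tape()
  pn <- params_to_nodes(tape, params)
  fn(tape, leaf(tape, x), pn)$v
}

#' Batch-normalised dilated convolution unit
#'
#' The elementary unit of MADR-Net: batch normalisation, then ReLU, then a
#' dilated 2-D convolution with zero "same" padding (pre-activation order),
#' so spatial dimensions are always preserved. With the default fresh
#' normalisation statistics (mean 0, variance 1) the unit reduces to
#' `conv(relu(x))` up to the epsilon in the variance term.
#'
#' @param x numeric array of dim `(H, W, C, N)`.
#' @param params parameter list from [init_conv_unit()].
#' @param dilation dilation rate `d`.
#' @param training if `TRUE`, normalise with batch statistics.
#' @return array of dim `(H, W, out_channels, N)`.
#' @export
conv_unit <- function(x, params, dilation = 1, training = FALSE) {
  k <- dim(params$w)[1]
  if (effective_kernel_size(k, dilation) %% 2 == 0) {
    abort("effective kernel size must be odd for symmetric same padding")
  }
  check_feature_map(x)
  tape <- new_tape()
  state <- new.env(parent = emptyenv())
  pn <- params_to_nodes(tape, params)
  fwd_conv_unit(tape, leaf(tape, x), pn, dilation, training, state, "u")$v
}

#' Multi-dilated residual block
#'
#' Parallel branches of conv units at several dilation rates (default 1, 3,
#' 5, 11) whose outputs are summed element-wise, plus a residual path: the
#' identity when input and output channel counts match, otherwise a 1x1
#' projection convolution. With all branch weights zero and matched
#' channels the block is exactly the identity.
#'
#' @inheritParams conv_unit
#' @param params parameter list from [init_mdr_block()].
#' @param rates dilation rates of the parallel branches (ascending).
#' @param branch_depth number of stacked conv units per branch.
#' @param in_channels,out_channels,kernel_size see [init_mdr_block()].
#' @return array of dim `(H, W, out_channels, N)`.
#' @export
multi_dilated_residual_block <- function(x, params, training = FALSE) {
  rates <- attr(params, "rates") %||% c(1, 3, 5, 11)
  run_block(x, params, function(tape, xn, pn) {
    fwd_mdr_block(tape, xn, pn, rates, training, new.env(), "blk")
  })
}

#' Atrous spatial pyramid pooling block
#'
#' Five parallel branches: a 1x1 convolution, one 3x3 dilated convolution
#' per rate (default 6, 12, 18), and an image-pooling branch (global average
#' pool, 1x1 convolution, broadcast back to `H x W`). Branch outputs are
#' concatenated along channels and fused by a final 1x1 convolution. Zero
#' "same" padding keeps the block well defined even when `H`, `W` are
#' smaller than the largest effective kernel.
#'
#' @inheritParams conv_unit
#' @param params parameter list from [init_aspp()].
#' @param rates dilation rates of the 3x3 branches.
#' @return array of dim `(H, W, out_channels, N)`.
#' @export
aspp <- function(x, params, training = FALSE) {
  rates <- attr(params, "rates") %||% c(6, 12, 18)
  run_block(x, params, function(tape, xn, pn) {
    fwd_aspp(tape, xn, pn, rates, training, new.env(), "aspp")
  })
}

#' Channel-spatial attention module (CSAM)
#'
#' Sequential channel-then-spatial gating. The channel gate is
#' `sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))` with a shared two-layer
#' perceptron of hidden width `C / r`, shaped `(1, 1, C, N)`. The spatial
#' gate concatenates the per-pixel channel mean and maximum (2 channels) and
#' convolves them with a 7x7 kernel before a sigmoid, shaped
#' `(H, W, 1, N)`. `csam()` applies both: `F2 = Ws(F1) * F1` with
#' `F1 = Wc(F) * F`. With all attention weights zero both gates are exactly
#' 0.5 and `csam(F) = 0.25 * F`.
#'
#' @inheritParams conv_unit
#' @param params parameter list from [init_csam()].
#' @param hidden_relu apply a ReLU after the perceptron's hidden layer.
#' @return `channel_attention()`: array `(1, 1, C, N)` in (0, 1);
#'   `spatial_attention()`: array `(H, W, 1, N)` in (0, 1);
#'   `csam()`: array with the shape of `x`.
#' @export
channel_attention <- function(x, params, hidden_relu = TRUE) {
  check_feature_map(x)
  tape <- new_tape()
  pn <- params_to_nodes(tape, params)
  fwd_channel_attention(tape, leaf(tape, x), pn, hidden_relu)$v
}

#' @rdname channel_attention
#' @export
spatial_attention <- function(x, params) {
  check_feature_map(x)
  tape <- new_tape()
  pn <- params_to_nodes(tape, params)
  fwd_spatial_attention(tape, leaf(tape, x), pn)$v
}

#' @rdname channel_attention
#' @export
csam <- function(x, params, hidden_relu = TRUE) {
  check_feature_map(x)
  tape <- new_tape()
  pn <- params_to_nodes(tape, params)
  fwd_csam(tape, leaf(tape, x), pn, hidden_relu)$v
}
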