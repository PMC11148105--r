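# Assembly of the full MADR-Net: configuration, parameter initialisation,
# the L1..L37 layer registry, forward inference, and checkpoint I/O.
#
# Registry convention (documented in the role tags, depth D = 5 default):
#   encoder (2D + 2 = 12 entries): L1 stem 1x1 conv; then per stage a
#     multi-dilated residual block (L2, L4, ..., L10) and a 2x2 max-pool
#     (L3, L5, ..., L11); L12 the bottleneck ASPP, counted with the encoder
#     path as its 12th layer.
#   decoder (4D + 3 = 23 entries): per stage a 2x2 transposed convolution,
#     a channel-spatial attention gate on the coupled encoder feature, the
#     channel concatenation, and a residual block (L13..L32); then the head
#     group L33 attention on L1, L34 concatenation with L1, L35 head ASPP.
#   head (2 entries): L36 1x1 classifier convolution, L37 activation.
# Total 6D + 7 = 37; attention entries sit at L14, L18, L22, L26, L30 and
# couple to encoder blocks L10, L8, L6, L4, L2.

#' Model configuration for MADR-Net
#'
#' Collects every architectural knob. The channel progression follows the
#' classic U-Net doubling `1 -> 32 -> 64 -> 128 -> 256 -> 512 -> 1024`: the
#' stem 1x1 convolution outputs the first width, each encoder stage doubles
#' after pooling, and the last entry is the ASPP bottleneck width.
#'
#' @param in_channels 1 (grayscale) or 3 (RGB).
#' @param num_classes number of output classes M (1 for binary).
#' @param input_size square input side in pixels; must be divisible by
#'   `2^depth` where `depth = length(channel_progression) - 1`.
#' @param channel_progression strictly increasing channel widths; the
#'   default doubles from 32 to 1024 over five pooling stages.
#' @param block_rates dilation rates of the multi-dilated residual blocks.
#' @param aspp_rates dilation rates of the ASPP 3x3 branches.
#' @param branch_depth conv units stacked per residual-block branch. The
#'   default 1 reproduces the published 56M-parameter budget; 2 gives the
#'   deeper pre-activation pairing.
#' @param reduction_ratio channel-attention bottleneck ratio `r`.
#' @param spatial_kernel spatial-attention kernel side (7).
#' @param hidden_relu ReLU after the attention perceptron's hidden layer.
#' @param head_activation `"sigmoid"` or `"softmax"`; defaults to sigmoid
#'   for one class and softmax otherwise.
#' @param head_combine how the final decoder feature meets the L1 feature:
#'   `"concat"` (default) or `"add"`.
#' @return an object of class `madrnet_config`.
#' @export
madrnet_config <- function(in_channels = 3,
                           num_classes = 1,
                           input_size = 128,
                           channel_progression = c(32, 64, 128, 256, 512, 1024),
                           block_rates = c(1, 3, 5, 11),
                           aspp_rates = c(6, 12, 18),
                           branch_depth = 1,
                           reduction_ratio = 16,
                           spatial_kernel = 7,
                           hidden_relu = TRUE,
                           head_activation = if (num_classes == 1) "sigmoid" else "softmax",
                           head_combine = c("concat", "add")) {
  head_combine <- match.arg(head_combine)
  if (!in_channels %in% c(1, 3)) abort("`in_channels` must be 1 or 3")
  if (num_classes < 1) abort("`num_classes` must be >= 1")
  depth <- length(channel_progression) - 1
  if (depth < 1) abort("`channel_progression` needs at least two entries")
  if (any(diff(channel_progression) <= 0)) {
    abort("`channel_progression` must be strictly increasing")
  }
  if (input_size %% 2^depth != 0) {
    abort(sprintf("`input_size` must be divisible by 2^%d for %d poolings",
                  depth, depth))
  }
  if (!head_activation %in% c("sigmoid", "softmax")) {
    abort('`head_activation` must be "sigmoid" or "softmax"')
  }
  if (head_activation == "sigmoid" && num_classes != 1) {
    abort("sigmoid head requires `num_classes = 1`")
  }
  structure(list(in_channels = in_channels, num_classes = num_classes,
                 input_size = input_size,
                 channel_progression = channel_progression,
                 block_rates = sort(block_rates), aspp_rates = aspp_rates,
                 branch_depth = branch_depth,
                 reduction_ratio = reduction_ratio,
                 spatial_kernel = spatial_kernel, hidden_relu = hidden_relu,
                 head_activation = head_activation,
                 head_combine = head_combine, depth = depth),
            class = "madrnet_config")
}

# Per-stage channel widths: block i maps enc_in(i) -> enc_out(i).
enc_channels <- function(cfg) {
  cp <- cfg$channel_progression
  D <- cfg$depth
  list(stem = cp[1],
       block_in = c(cp[1], cp[seq_len(D - 1)]),
       block_out = cp[seq_len(D)],
       bott_in = cp[D], bott_out = cp[D + 1])
}

#' Decoder-encoder skip couplings
#'
#' Returns the layer-index pairs at which the decoder attends to encoder
#' features: the attention entries advance by 4 per decoder stage while the
#' coupled encoder blocks step back by 2, giving `(L14, L10), (L18, L8),
#' (L22, L6), (L26, L4), (L30, L2)` at the default depth.
#'
#' @param config a [madrnet_config()].
#' @return tibble with columns `decoder_index`, `encoder_index`.
#' @export
decoder_skip_map <- function(config) {
  D <- config$depth
  tibble::tibble(decoder_index = 2 * D + 4 + 4 * (seq_len(D) - 1),
                 encoder_index = 2 * D - 2 * (seq_len(D) - 1))
}

build_registry <- function(cfg) {
  D <- cfg$depth
  ch <- enc_channels(cfg)
  sz <- cfg$input_size
  rows <- list()
  add <- function(role, path, channels, size) {
    rows[[length(rows) + 1]] <<- list(role = role, path = path,
                                      channels = channels, size = size)
  }
  add("stem_conv1x1", "encoder", ch$stem, sz)
  s <- sz
  for (i in seq_len(D)) {
    add(sprintf("mdr_block_enc%d", i), "encoder", ch$block_out[i], s)
    s <- s / 2
    add(sprintf("maxpool%d", i), "encoder", ch$block_out[i], s)
  }
  add("bottleneck_aspp", "encoder", ch$bott_out, s)
  for (j in seq_len(D)) {
    s <- s * 2
    w <- ch$block_out[D + 1 - j]
    add(sprintf("upconv%d", j), "decoder", w, s)
    add(sprintf("attention%d", j), "decoder", w, s)
    add(sprintf("concat%d", j), "decoder", 2 * w, s)
    add(sprintf("mdr_block_dec%d", j), "decoder", w, s)
  }
  add("attention_head", "decoder", ch$stem, sz)
  head_c <- if (cfg$head_combine == "concat") 2 * ch$stem else ch$stem
  add("concat_head", "decoder", head_c, sz)
  add("head_aspp", "decoder", ch$stem, sz)
  add("classifier_conv1x1", "head", cfg$num_classes, sz)
  add(paste0("activation_", cfg$head_activation), "head", cfg$num_classes, sz)
  tibble::tibble(
    index = seq_along(rows),
    layer = paste0("L", seq_along(rows)),
    role = vapply(rows, `[[`, "", "role"),
    path = vapply(rows, `[[`, "", "path"),
    channels = vapply(rows, function(r) as.numeric(r$channels), numeric(1)),
    size = vapply(rows, function(r) as.numeric(r$size), numeric(1))
  )
}

init_convt <- function(cin, cout) {
  list(w = array(rnorm(4 * cin * cout, sd = sqrt(2 / (4 * cin))),
                 c(2, 2, cin, cout)),
       b = rep(0, cout))
}

#' Build a MADR-Net model
#'
#' Initialises every trainable array of the network described by `config`
#' (He-normal convolution weights, unit batch-norm scales) and assembles the
#' layer registry.
#'
#' @param config a [madrnet_config()].
#' @param seed optional integer; when given, initialisation is performed
#'   under this seed and the caller's RNG state is left untouched.
#' @return an object of class `madrnet_model` with fields `config`,
#'   `params`, `state` (batch-norm running moments) and `registry`.
#' @export
build_madrnet <- function(config, seed = NULL) {
  stopifnot(inherits(config, "madrnet_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  cfg <- config
  D <- cfg$depth
  ch <- enc_channels(cfg)
  r <- cfg$reduction_ratio
  params <- list(
    stem = list(w = he_conv(1, cfg$in_channels, ch$stem), b = rep(0, ch$stem)),
    enc = lapply(seq_len(D), function(i) {
      init_mdr_block(ch$block_in[i], ch$block_out[i], cfg$block_rates,
                     cfg$branch_depth)
    }),
    bott = init_aspp(ch$bott_in, ch$bott_out, cfg$aspp_rates),
    up = lapply(seq_len(D), function(j) {
      cin <- if (j == 1) ch$bott_out else ch$block_out[D + 2 - j]
      init_convt(cin, ch$block_out[D + 1 - j])
    }),
    att = lapply(seq_len(D), function(j) {
      init_csam(ch$block_out[D + 1 - j], r, cfg$spatial_kernel)
    }),
    dec = lapply(seq_len(D), function(j) {
      w <- ch$block_out[D + 1 - j]
      init_mdr_block(2 * w, w, cfg$block_rates, cfg$branch_depth)
    }),
    att_head = init_csam(ch$stem, r, cfg$spatial_kernel),
    head_aspp = init_aspp(if (cfg$head_combine == "concat") 2 * ch$stem else ch$stem,
                          ch$stem, cfg$aspp_rates),
    cls = list(w = he_conv(1, ch$stem, cfg$num_classes),
               b = rep(0, cfg$num_classes))
  )
  structure(list(config = cfg, params = params,
                 state = new.env(parent = emptyenv()),
                 registry = build_registry(cfg)),
            class = "madrnet_model")
}

#' Layer registry of a built model
#'
#' @param model a `madrnet_model`.
#' @return tibble with one row per named layer (`index`, `layer`, `role`,
#'   `path`, `channels`, `size`).
#' @export
layer_registry <- function(model) {
  stopifnot(inherits(model, "madrnet_model"))
  model$registry
}

#' Count trainable parameters
#'
#' Exact integer sum of the lengths of every learnable array (convolution
#' kernels and biases, batch-norm scales and shifts, attention perceptron
#' weights). Batch-norm running moments are state, not parameters.
#'
#' @param model a `madrnet_model`.
#' @return integer-valued double.
#' @export
count_trainable_parameters <- function(model) {
  stopifnot(inherits(model, "madrnet_model"))
  count_leaves <- function(p) {
    if (is.list(p)) sum(vapply(p, count_leaves, numeric(1)))
    else if (is.numeric(p)) length(p)
    else 0
  }
  count_leaves(model$params)
}

# Forward pass recorded on a tape; returns the probability-map node.
model_forward_node <- function(tape, model, xn, training = FALSE) {
  cfg <- model$config
  st <- model$state
  D <- cfg$depth
  pn <- params_to_nodes(tape, model$params)
  h <- op_conv2d(tape, xn, pn$stem$w, pn$stem$b, 1L)
  l1 <- h
  skips <- vector("list", D)
  for (i in seq_len(D)) {
    h <- fwd_mdr_block(tape, h, pn$enc[[i]], cfg$block_rates, training, st,
                       sprintf("enc%d", i))
    skips[[i]] <- h
    h <- op_maxpool2(tape, h)
  }
  h <- fwd_aspp(tape, h, pn$bott, cfg$aspp_rates, training, st, "bott")
  for (j in seq_len(D)) {
    h <- op_convt2(tape, h, pn$up[[j]]$w, pn$up[[j]]$b)
    gated <- fwd_csam(tape, skips[[D + 1 - j]], pn$att[[j]], cfg$hidden_relu)
    h <- op_concat_c(tape, list(h, gated))
    h <- fwd_mdr_block(tape, h, pn$dec[[j]], cfg$block_rates, training, st,
                       sprintf("dec%d", j))
  }
  gated <- fwd_csam(tape, l1, pn$att_head, cfg$hidden_relu)
  h <- if (cfg$head_combine == "concat") {
    op_concat_c(tape, list(h, gated))
  } else {
    op_add(tape, h, gated)
  }
  h <- fwd_aspp(tape, h, pn$head_aspp, cfg$aspp_rates, training, st, "head")
  h <- op_conv2d(tape, h, pn$cls$w, pn$cls$b, 1L)
  if (cfg$head_activation == "sigmoid") {
    op_sigmoid(tape, h)
  } else {
    op_softmax_c(tape, h)
  }
}

#' Run MADR-Net forward
#'
#' @param model a `madrnet_model`.
#' @param x image batch, array `(H, W, C, N)` with `H = W = input_size` and
#'   values in `[0, 1]`.
#' @param training use batch statistics (and update running moments) in the
#'   normalisation layers.
#' @return probability maps, array `(H, W, M, N)`: in `(0, 1)` for the
#'   sigmoid head; channel-summing to 1 at every pixel for the softmax head.
#' @export
madrnet_forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "madrnet_model"))
  check_feature_map(x)
  cfg <- model$config
  d <- dim(x)
  if (d[1] != cfg$input_size || d[2] != cfg$input_size) {
    abort(sprintf("input must be %dx%d, got %dx%d",
                  cfg$input_size, cfg$input_size, d[1], d[2]))
  }
  if (d[3] != cfg$in_channels) {
    abort(sprintf("input must have %d channel(s), got %d",
                  cfg$in_channels, d[3]))
  }
  tape <- new_tape()
  model_forward_node(tape, model, leaf(tape, x), training)$v
}

#' @export
print.madrnet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<madrnet_model> %dx%dx%d -> %d class(es), %s head\n",
              cfg$input_size, cfg$input_size, cfg$in_channels,
              cfg$num_classes, cfg$head_activation))
  cat(sprintf("  layers: %d (%d encoder / %d decoder / %d head)\n",
              nrow(x$registry), sum(x$registry$path == "encoder"),
              sum(x$registry$path == "decoder"), sum(x$registry$path == "head")))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_trainable_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
print.madrnet_config <- function(x, ...) {
  cat("<madrnet_config>\n")
  cat(sprintf("  input: %dx%dx%d, classes: %d (%s)\n", x$input_size,
              x$input_size, x$in_channels, x$num_classes, x$head_activation))
  cat(sprintf("  channels: %s\n", paste(x$channel_progression, collapse = " -> ")))
  cat(sprintf("  block rates: %s | ASPP rates: %s | branch depth: %d\n",
              paste(x$block_rates, collapse = ","),
              paste(x$aspp_rates, collapse = ","), x$branch_depth))
  invisible(x)
}

#' Tidy a MADR-Net model into its layer registry
#'
#' @param x a `madrnet_model`.
#' @param ... unused.
#' @return the layer registry tibble (see [layer_registry()]).
#' @export
tidy.madrnet_model <- function(x, ...) layer_registry(x)

#' One-row model summary
#'
#' @param x a `madrnet_model`.
#' @param ... unused.
#' @return tibble with layer counts and the exact parameter total.
#' @export
glance.madrnet_model <- function(x, ...) {
  reg <- x$registry
  tibble::tibble(
    n_layers = nrow(reg),
    n_encoder = sum(reg$path == "encoder"),
    n_decoder = sum(reg$path == "decoder"),
    n_parameters = count_trainable_parameters(x),
    input_size = x$config$input_size,
    num_classes = x$config$num_classes
  )
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint is an RDS file holding the configuration, all parameter
#' arrays, the batch-norm running moments, and (when supplied by the
#' trainer) the optimizer and RNG state, plus a self-describing JSON sidecar
#' (`<path>.json`) with the configuration and layer registry.
#'
#' @param model a `madrnet_model`.
#' @param path file path for the RDS checkpoint.
#' @param extra optional list merged into the checkpoint (optimizer state,
#'   epoch counters, RNG state).
#' @return `save_checkpoint()` the path, invisibly; `load_checkpoint()` a
#'   list with `model` plus any extra fields.
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  stopifnot(inherits(model, "madrnet_model"))
  payload <- c(list(config = unclass(model$config), params = model$params,
                    state = as.list(model$state)), extra)
  saveRDS(payload, path)
  sidecar <- list(config = unclass(model$config),
                  registry = as.data.frame(model$registry),
                  n_parameters = count_trainable_parameters(model))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  cfg <- do.call(madrnet_config, payload$config[setdiff(names(payload$config), "depth")])
  model <- structure(list(config = cfg, params = payload$params,
                          state = list2env(payload$state, parent = emptyenv()),
                          registry = build_registry(cfg)),
                     class = "madrnet_model")
  extras <- payload[setdiff(names(payload), c("config", "params", "state"))]
  c(list(model = model), extras)
}
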