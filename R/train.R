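# Training workflow: Adam optimisation of the hybrid loss with per-epoch
# logging, validation dice tracking, reduce-on-plateau scheduling, best
# checkpoint retention and bit-reproducible resumption.

# ---- parameter-tree utilities ---------------------------------------------

# Apply f(leaf, path) over every numeric leaf; paths match the tape leaf
# names produced by params_to_nodes() (prefix "p").
map_params <- function(p, f, prefix = "p") {
  if (is.list(p)) {
    out <- lapply(seq_along(p), function(i) {
      nm <- names(p)[i] %||% as.character(i)
      map_params(p[[i]], f, paste(prefix, nm, sep = "."))
    })
    names(out) <- names(p)
    attributes(out) <- attributes(p)
    out
  } else if (is.numeric(p)) {
    f(p, prefix)
  } else {
    p
  }
}

flatten_params <- function(p) {
  out <- list()
  map_params(p, function(a, path) {
    out[[path]] <<- a
    a
  })
  out
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- map_params(params, function(a, path) a * 0)
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  mf <- flatten_params(opt$m)
  vf <- flatten_params(opt$v)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  new_params <- map_params(params, function(a, path) {
    g <- grads[[path]]
    if (is.null(g)) return(a)
    m <- beta1 * mf[[path]] + (1 - beta1) * g
    v <- beta2 * vf[[path]] + (1 - beta2) * g * g
    mf[[path]] <<- m
    vf[[path]] <<- v
    a - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  })
  opt$m <- map_params(opt$m, function(a, path) mf[[path]])
  opt$v <- map_params(opt$v, function(a, path) vf[[path]])
  list(params = new_params, opt = opt)
}

# ---- gradient access -------------------------------------------------------

#' Gradients of the hybrid loss for one batch
#'
#' Runs a training-mode forward/backward pass and returns the gradient of
#' the hybrid loss with respect to every trainable array, keyed by
#' parameter path. Useful for gradient-flow diagnostics: after one pass on
#' a random batch every parameter should receive a non-zero gradient.
#'
#' @param model a `madrnet_model`.
#' @param images batch array `(H, W, C, N)`.
#' @param masks label array `(H, W, 1, N)`.
#' @param loss a [loss_config()].
#' @return named list of gradient arrays.
#' @export
madrnet_gradients <- function(model, images, masks, loss = loss_config()) {
  q <- target_tensor(masks, model$config)
  tape <- new_tape()
  p <- model_forward_node(tape, model, leaf(tape, images), training = TRUE)
  lo <- fwd_hybrid_loss(tape, p, q, loss)
  backprop(tape, lo$total)
}

target_tensor <- function(masks, cfg) {
  if (cfg$num_classes == 1) {
    if (!all(masks %in% c(0, 1))) abort("binary task requires 0/1 masks")
    masks
  } else {
    mask_to_onehot(masks, cfg$num_classes)
  }
}

# ---- training --------------------------------------------------------------

#' Train MADR-Net
#'
#' Adam optimisation of the hybrid loss with the published protocol as
#' defaults: learning rate 1e-3, batch size 16, up to 500 epochs, with an
#' optional reduce-on-plateau schedule (factor 0.5, patience 20) standing
#' in for the "reduced learning rate". Each epoch logs the loss components
#' and train/validation dice; the parameters with the best validation dice
#' (or lowest training loss when no validation set is given) are retained
#' in the returned fit. A non-finite loss aborts with a diagnostic.
#'
#' @param model a `madrnet_model` (modified copy returned in the fit).
#' @param images,masks training arrays, `(H, W, C, N)` and `(H, W, 1, N)`.
#' @param val_images,val_masks optional validation arrays.
#' @param epochs number of epochs; with `batch_size >= N` one epoch is one
#'   optimizer step.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param loss a [loss_config()].
#' @param seed integer seed controlling shuffling (and any augmentation).
#' @param reduce_on_plateau halve the learning rate after `patience` epochs
#'   without improvement.
#' @param patience plateau patience in epochs.
#' @param threshold decision threshold for the dice tracking.
#' @param log_path optional CSV path for the per-epoch log.
#' @param checkpoint_path optional RDS path; the best checkpoint (with
#'   optimizer and RNG state) is kept there.
#' @param resume_from optional checkpoint path to resume from.
#' @param verbose print a line per epoch.
#' @return an object of class `madrnet_fit`: `model` (best parameters),
#'   `history` tibble, `best` (epoch and metric), `loss` config.
#' @export
train_madrnet <- function(model, images, masks,
                          val_images = NULL, val_masks = NULL,
                          epochs = 500, batch_size = 16,
                          learning_rate = 1e-3, loss = loss_config(),
                          seed = 1, reduce_on_plateau = FALSE,
                          patience = 20, threshold = 0.5,
                          log_path = NULL, checkpoint_path = NULL,
                          resume_from = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "madrnet_model"))
  cfg <- model$config
  n <- dim(images)[4]
  history <- list()
  lr <- learning_rate
  opt <- adam_init(model$params)
  start_epoch <- 1L
  if (!is.null(resume_from)) {
    ck <- load_checkpoint(resume_from)
    model <- ck$model
    if (!is.null(ck$opt)) opt <- ck$opt
    if (!is.null(ck$lr)) lr <- ck$lr
    if (!is.null(ck$epoch)) start_epoch <- ck$epoch + 1L
    if (!is.null(ck$rng)) assign(".Random.seed", ck$rng, globalenv())
  } else {
    set.seed(seed)
  }
  best_metric <- -Inf
  best_params <- model$params
  best_state <- as.list(model$state)
  best_epoch <- 0L
  since_best <- 0L
  for (epoch in seq.int(start_epoch, epochs)) {
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / batch_size))
    comp <- c(total = 0, ce = 0, dice = 0, ft = 0)
    train_dice <- numeric(0)
    for (b in batches) {
      xb <- images[, , , b, drop = FALSE]
      mb <- masks[, , , b, drop = FALSE]
      qb <- target_tensor(mb, cfg)
      tape <- new_tape()
      pnode <- model_forward_node(tape, model, leaf(tape, xb), training = TRUE)
      lo <- fwd_hybrid_loss(tape, pnode, qb, loss)
      if (!is.finite(lo$total$v)) {
        abort(sprintf("training diverged: non-finite loss at epoch %d", epoch))
      }
      grads <- backprop(tape, lo$total)
      upd <- adam_step(model$params, grads, opt, lr)
      model$params <- upd$params
      opt <- upd$opt
      comp <- comp + c(lo$total$v, lo$ce, lo$dice, lo$ft) * length(b)
      train_dice <- c(train_dice, batch_dice(pnode$v, mb, cfg, threshold))
    }
    comp <- comp / n
    val_dice <- NA_real_
    if (!is.null(val_images)) {
      vp <- predict_prob(model, val_images, batch_size)
      val_dice <- mean_dice(vp, val_masks, cfg, threshold)
    }
    metric <- if (!is.null(val_images)) val_dice else -comp["total"]
    if (metric > best_metric) {
      best_metric <- metric
      best_params <- model$params
      best_state <- as.list(model$state)
      best_epoch <- epoch
      since_best <- 0L
      if (!is.null(checkpoint_path)) {
        save_checkpoint(model, checkpoint_path,
                        extra = list(opt = opt, epoch = epoch, lr = lr,
                                     rng = get(".Random.seed", globalenv())))
      }
    } else {
      since_best <- since_best + 1L
      if (reduce_on_plateau && since_best >= patience) {
        lr <- lr * 0.5
        since_best <- 0L
      }
    }
    history[[length(history) + 1]] <- tibble::tibble(
      epoch = epoch, loss = comp[["total"]], ce = comp[["ce"]],
      dice_loss = comp[["dice"]], focal_tversky = comp[["ft"]],
      train_dice = mean(train_dice), val_dice = val_dice, lr = lr)
    if (verbose) {
      message(sprintf("epoch %d loss %.4f train dice %.4f val dice %s",
                      epoch, comp[["total"]], mean(train_dice),
                      ifelse(is.na(val_dice), "-", sprintf("%.4f", val_dice))))
    }
  }
  history <- dplyr::bind_rows(history)
  if (!is.null(log_path)) write.csv(history, log_path, row.names = FALSE)
  best_model <- model
  best_model$params <- best_params
  best_model$state <- list2env(best_state, parent = emptyenv())
  structure(list(model = best_model, final_model = model, history = history,
                 best = list(epoch = best_epoch, metric = best_metric),
                 loss = loss),
            class = "madrnet_fit")
}

# Mean per-image dice of a probability batch against label masks.
mean_dice <- function(prob, masks, cfg, threshold = 0.5) {
  mean(batch_dice(prob, masks, cfg, threshold))
}

batch_dice <- function(prob, masks, cfg, threshold = 0.5) {
  n <- dim(prob)[4]
  vapply(seq_len(n), function(i) {
    if (cfg$num_classes == 1) {
      pr <- threshold_mask(prob[, , , i, drop = FALSE], threshold)
      dsc(confusion_counts(masks[, , 1, i], pr[, , 1, 1]))
    } else {
      pr <- argmax_mask(prob[, , , i, drop = FALSE])
      rep_i <- multiclass_report(masks[, , 1, i], pr[, , 1, 1],
                                 cfg$num_classes, include_background = FALSE)
      rep_i$dice[rep_i$class == "macro"]
    }
  }, numeric(1))
}

# Forward in chunks to bound tape memory.
predict_prob <- function(model, images, batch_size = 16) {
  n <- dim(images)[4]
  out <- NULL
  for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    p <- madrnet_forward(model, images[, , , b, drop = FALSE])
    if (is.null(out)) {
      d <- dim(p)
      out <- array(0, c(d[1], d[2], d[3], n))
    }
    out[, , , b] <- p
  }
  out
}

#' Evaluate a model on a labelled dataset
#'
#' Runs inference and produces the per-image metrics report (one row per
#' image plus a summary row) in the reporting convention of the evaluation
#' tables: accuracy, precision, recall, dice, Jaccard, with per-class dice
#' for multi-class tasks available via [multiclass_report()].
#'
#' @param model a `madrnet_model` or `madrnet_fit`.
#' @param images,masks evaluation arrays.
#' @param threshold decision threshold (sigmoid head).
#' @param batch_size inference chunk size.
#' @param ... passed to [evaluate_predictions()].
#' @return tibble report.
#' @export
evaluate_madrnet <- function(model, images, masks, threshold = 0.5,
                             batch_size = 16, ...) {
  if (inherits(model, "madrnet_fit")) model <- model$model
  prob <- predict_prob(model, images, batch_size)
  evaluate_predictions(prob, masks, threshold, ...)
}

#' Predict label masks for new images
#'
#' Binary heads threshold the sigmoid output (default 0.5); softmax heads
#' take the per-pixel argmax.
#'
#' @param model a `madrnet_model` or `madrnet_fit`.
#' @param images array `(H, W, C, N)`.
#' @param threshold sigmoid decision threshold.
#' @param batch_size inference chunk size.
#' @return label array `(H, W, 1, N)`.
#' @export
predict_madrnet <- function(model, images, threshold = 0.5, batch_size = 16) {
  if (inherits(model, "madrnet_fit")) model <- model$model
  prob <- predict_prob(model, images, batch_size)
  if (model$config$num_classes == 1) {
    threshold_mask(prob, threshold)
  } else {
    argmax_mask(prob)
  }
}

# ---- fit methods -----------------------------------------------------------

#' @export
print.madrnet_fit <- function(x, ...) {
  cat(sprintf("<madrnet_fit> %d epoch(s); best at epoch %d (metric %.4f)\n",
              nrow(x$history), x$best$epoch, x$best$metric))
  invisible(x)
}

#' Tidy a fit into its training history
#'
#' @param x a `madrnet_fit`.
#' @param ... unused.
#' @return the per-epoch history tibble (loss components, train/validation
#'   dice, learning rate).
#' @export
tidy.madrnet_fit <- function(x, ...) x$history

#' One-row fit summary
#'
#' @param x a `madrnet_fit`.
#' @param ... unused.
#' @return tibble with final/best metrics.
#' @export
glance.madrnet_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    final_loss = h$loss[nrow(h)],
    final_train_dice = h$train_dice[nrow(h)],
    best_epoch = x$best$epoch,
    best_metric = x$best$metric,
    n_parameters = count_trainable_parameters(x$model)
  )
}
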