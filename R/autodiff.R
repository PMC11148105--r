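# Reverse-mode automatic differentiation on a dynamic tape.
#
# The network forward pass records one node per primitive operation; each
# node keeps its value, the tape ids of its parents, and a closure that maps
# the incoming gradient to per-parent gradients. backprop() sweeps the tape
# once in reverse creation order, so any DAG (skips, parallel branches,
# shared weights) differentiates correctly.
#
# Values are numeric arrays of dim (H, W, C, N), plain matrices (for the
# attention perceptron) or scalars (losses). Heavy primitives (dilated
# convolution, transposed convolution, max-pooling) call into C++.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tape_node <- function(tape, value, parents = integer(0), backward = NULL,
                      name = NULL) {
  # force the arguments before claiming an id: argument expressions may
  # themselves create tape nodes, which must precede this one on the tape
  force(value)
  force(parents)
  force(backward)
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$n <- n
  nd <- list(id = n, v = value, parents = parents, backward = backward,
             name = name)
  tape$nodes[[n]] <- nd
  nd
}

# Wrap a raw array as a leaf; named leaves are trainable parameters whose
# gradients backprop() returns.
leaf <- function(tape, value, name = NULL) tape_node(tape, value, name = name)

is_node <- function(x) is.list(x) && !is.null(x$id) && !is.null(x$v)

as_node <- function(tape, x) if (is_node(x)) x else leaf(tape, x)

# Backpropagate from a scalar node; returns a named list of gradients for
# every named leaf reached by the sweep.
backprop <- function(tape, from) {
  grads <- vector("list", tape$n)
  grads[[from$id]] <- 1
  out <- list()
  for (i in seq.int(tape$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tape$nodes[[i]]
    if (!is.null(nd$name)) out[[nd$name]] <- g
    if (is.null(nd$backward)) next
    pg <- nd$backward(g)
    for (j in seq_along(nd$parents)) {
      gj <- pg[[j]]
      if (is.null(gj)) next
      pid <- nd$parents[[j]]
      grads[[pid]] <- if (is.null(grads[[pid]])) gj else grads[[pid]] + gj
    }
    grads[[i]] <- NULL
  }
  out
}

# ---- primitive ops ---------------------------------------------------------

op_conv2d <- function(tape, x, w, b, dilation = 1L) {
  xv <- x$v; wv <- w$v; bv <- b$v
  y <- cpp_conv2d_fw(xv, wv, bv, as.integer(dilation))
  tape_node(tape, y, c(x$id, w$id, b$id), function(g) {
    bw <- cpp_conv2d_bw(xv, wv, as.integer(dilation), g)
    list(bw$gx, bw$gw, bw$gb)
  })
}

op_convt2 <- function(tape, x, w, b) {
  xv <- x$v; wv <- w$v
  y <- cpp_convt2_fw(xv, wv, b$v)
  tape_node(tape, y, c(x$id, w$id, b$id), function(g) {
    bw <- cpp_convt2_bw(xv, wv, g)
    list(bw$gx, bw$gw, bw$gb)
  })
}

op_maxpool2 <- function(tape, x) {
  d <- dim(x$v)
  fw <- cpp_maxpool2_fw(x$v)
  tape_node(tape, fw$y, x$id, function(g) {
    list(cpp_maxpool2_bw(fw$idx, g, d[1], d[2]))
  })
}

op_relu <- function(tape, x) {
  m <- x$v > 0
  tape_node(tape, x$v * m, x$id, function(g) list(g * m))
}

op_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$v))
  tape_node(tape, s, x$id, function(g) list(g * s * (1 - s)))
}

# Softmax over the channel axis of an (H, W, C, N) array.
op_softmax_c <- function(tape, x) {
  v <- x$v
  d <- dim(v)
  mx <- over_c(v, d, function(m) do.call(pmax, asplit(m, 2)))
  e <- exp(v - rep_c(array(mx, c(d[1], d[2], d[4])), d[3]))
  s <- over_c(e, d, rowSums)
  p <- e / rep_c(array(s, c(d[1], d[2], d[4])), d[3])
  tape_node(tape, p, x$id, function(g) {
    dot <- over_c(g * p, d, rowSums)
    list(p * (g - rep_c(array(dot, c(d[1], d[2], d[4])), d[3])))
  })
}

# Replicate an (H, W, N) array across a channel axis -> (H, W, C, N).
# Column trick: as an (H*W, N) matrix, column n must appear C consecutive
# times; matrix column indexing keeps everything in C code.
rep_c <- function(a, C) {
  d <- dim(a)
  m <- matrix(a, d[1] * d[2], d[3])
  array(m[, rep.int(seq_len(d[3]), rep.int(C, d[3])), drop = FALSE],
        c(d[1], d[2], C, d[3]))
}

# Per-channel vector (length C) -> full (H, W, C, N) array values.
rep_chan <- function(v, d) {
  rep.int(rep.int(v, rep.int(d[1] * d[2], d[3])), d[4])
}

# Per-channel reduction over (H, W, N): returns length-C vector of means.
chan_mean <- function(x, d) {
  rowMeans(matrix(.colMeans(x, d[1] * d[2], d[3] * d[4]), d[3], d[4]))
}

chan_sum <- function(x, d) {
  rowSums(matrix(.colSums(x, d[1] * d[2], d[3] * d[4]), d[3], d[4]))
}

# Reduction over the channel axis -> (H, W, 1, N) values as (H*W x N).
over_c <- function(x, d, f2) {
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  out <- matrix(0, d[1] * d[2], d[4])
  for (n in seq_len(d[4])) {
    out[, n] <- f2(m[, (n - 1) * d[3] + seq_len(d[3]), drop = FALSE])
  }
  out
}

op_add <- function(tape, x, y) {
  tape_node(tape, x$v + y$v, c(x$id, y$id), function(g) list(g, g))
}

# Elementwise product with broadcasting: gate is (1,1,C,N) (channel gate)
# or (H,W,1,N) (spatial gate), x is (H,W,C,N).
op_mul_gate <- function(tape, x, gate) {
  dx <- dim(x$v); dg <- dim(gate$v)
  gv <- gate$v
  if (all(dg == dx)) {
    xv <- x$v
    return(tape_node(tape, xv * gv, c(x$id, gate$id),
                     function(g) list(g * gv, g * xv)))
  }
  if (dg[1] == 1 && dg[2] == 1 && dg[3] == dx[3]) {   # channel gate
    big <- bcast_channel_gate(gv, dx)
    xv <- x$v
    tape_node(tape, xv * big, c(x$id, gate$id), function(g) {
      gg <- .colSums(g * xv, dx[1] * dx[2], dx[3] * dx[4])
      list(g * big, array(gg, dg))
    })
  } else if (dg[3] == 1) {               # spatial gate
    big <- rep_c(array(gv, c(dx[1], dx[2], dx[4])), dx[3])
    xv <- x$v
    tape_node(tape, xv * big, c(x$id, gate$id), function(g) {
      gg <- over_c(g * xv, dx, rowSums)
      list(g * big, array(gg, dg))
    })
  } else {
    abort("unsupported gate shape")
  }
}

# (1,1,C,N) gate -> full (H,W,C,N) array: each (c,n) scalar fills one
# H*W block, and blocks are already in (c, n) order.
bcast_channel_gate <- function(gv, dx) {
  array(rep.int(as.vector(gv), rep.int(dx[1] * dx[2], dx[3] * dx[4])), dx)
}

op_concat_c <- function(tape, xs) {
  vs <- lapply(xs, function(x) x$v)
  ds <- vapply(vs, function(v) dim(v)[3], numeric(1))
  d1 <- dim(vs[[1]])
  y <- array(0, c(d1[1], d1[2], sum(ds), d1[4]))
  at <- 0L
  for (v in vs) {
    y[, , at + seq_len(dim(v)[3]), ] <- v
    at <- at + dim(v)[3]
  }
  tape_node(tape, y, vapply(xs, function(x) x$id, integer(1)), function(g) {
    out <- vector("list", length(ds))
    at <- 0L
    for (j in seq_along(ds)) {
      out[[j]] <- g[, , at + seq_len(ds[j]), , drop = FALSE]
      at <- at + ds[j]
    }
    out
  })
}

# Global average pool over H, W -> (1, 1, C, N).
op_gap <- function(tape, x) {
  d <- dim(x$v)
  m <- .colMeans(x$v, d[1] * d[2], d[3] * d[4])
  tape_node(tape, array(m, c(1, 1, d[3], d[4])), x$id, function(g) {
    list(bcast_channel_gate(g, d) / (d[1] * d[2]))
  })
}

# Global max pool over H, W -> (1, 1, C, N), argmax-routed backward.
op_gmp <- function(tape, x) {
  d <- dim(x$v)
  flat <- matrix(x$v, d[1] * d[2], d[3] * d[4])
  idx <- max.col(t(flat), ties.method = "first")
  mx <- flat[cbind(idx, seq_len(d[3] * d[4]))]
  tape_node(tape, array(mx, c(1, 1, d[3], d[4])), x$id, function(g) {
    gx <- matrix(0, d[1] * d[2], d[3] * d[4])
    gx[cbind(idx, seq_len(d[3] * d[4]))] <- as.vector(g)
    list(array(gx, d))
  })
}

# Mean / max over the channel axis -> (H, W, 1, N).
op_cmean <- function(tape, x) {
  d <- dim(x$v)
  m <- over_c(x$v, d, rowMeans)
  tape_node(tape, array(m, c(d[1], d[2], 1, d[4])), x$id, function(g) {
    list(rep_c(array(g, c(d[1], d[2], d[4])), d[3]) / d[3])
  })
}

op_cmax <- function(tape, x) {
  d <- dim(x$v)
  mx <- array(over_c(x$v, d, function(m) do.call(pmax, asplit(m, 2))),
              c(d[1], d[2], d[4]))
  big <- rep_c(mx, d[3])
  mask <- (x$v == big)
  # split gradient across ties to keep backward deterministic
  nt <- rep_c(array(over_c(mask, d, rowSums), c(d[1], d[2], d[4])), d[3])
  tape_node(tape, array(mx, c(d[1], d[2], 1, d[4])), x$id, function(g) {
    list(rep_c(array(g, c(d[1], d[2], d[4])), d[3]) * mask / nt)
  })
}

# Broadcast a (1, 1, C, N) tensor to (H, W, C, N).
op_bcast_hw <- function(tape, x, H, W) {
  dg <- dim(x$v)
  d <- c(H, W, dg[3], dg[4])
  tape_node(tape, bcast_channel_gate(x$v, d), x$id, function(g) {
    list(array(.colSums(g, H * W, dg[3] * dg[4]), dg))
  })
}

# Dense layer on a (C, N) matrix: y = W x + b.
op_linear <- function(tape, x, w, b) {
  xv <- x$v; wv <- w$v
  y <- wv %*% xv + b$v
  tape_node(tape, y, c(x$id, w$id, b$id), function(g) {
    list(crossprod(wv, g), tcrossprod(g, xv), rowSums(g))
  })
}

# (1, 1, C, N) <-> (C, N) reshapes for the attention perceptron.
op_squeeze_hw <- function(tape, x) {
  d <- dim(x$v)
  tape_node(tape, array(x$v, c(d[3], d[4])), x$id,
            function(g) list(array(g, d)))
}

op_unsqueeze_hw <- function(tape, x) {
  d <- dim(x$v)
  tape_node(tape, array(x$v, c(1, 1, d[1], d[2])), x$id,
            function(g) list(array(g, d)))
}

# Batch normalization over (H, W, N) per channel; pre-activation usage.
# `state` is an environment holding running moments keyed by `key`.
op_batchnorm <- function(tape, x, gamma, beta, training, state, key,
                         momentum = 0.1, eps = 1e-5) {
  d <- dim(x$v)
  C <- d[3]
  gv <- as.numeric(gamma$v)
  bv <- as.numeric(beta$v)
  if (training) {
    mu <- chan_mean(x$v, d)
    xc <- x$v - rep_chan(mu, d)
    va <- chan_mean(xc * xc, d)
    iv <- 1 / sqrt(va + eps)
    xhat <- xc * rep_chan(iv, d)
    y <- xhat * rep_chan(gv, d) + rep_chan(bv, d)
    rm0 <- state[[key]]$mean %||% rep(0, C)
    rv0 <- state[[key]]$var %||% rep(1, C)
    m <- d[1] * d[2] * d[4]
    ub <- if (m > 1) va * m / (m - 1) else va
    state[[key]] <- list(mean = (1 - momentum) * rm0 + momentum * mu,
                         var  = (1 - momentum) * rv0 + momentum * ub)
    tape_node(tape, y, c(x$id, gamma$id, beta$id), function(g) {
      ggamma <- chan_sum(g * xhat, d)
      gbeta <- chan_sum(g, d)
      gxh <- g * rep_chan(gv, d)
      t1 <- chan_mean(gxh, d)
      t2 <- chan_mean(gxh * xhat, d)
      gx <- (gxh - xhat * rep_chan(t2, d) - rep_chan(t1, d)) *
        rep_chan(iv, d)
      list(gx, as.numeric(ggamma), as.numeric(gbeta))
    })
  } else {
    rm0 <- state[[key]]$mean %||% rep(0, C)
    rv0 <- state[[key]]$var %||% rep(1, C)
    iv <- 1 / sqrt(rv0 + eps)
    xhat <- (x$v - rep_chan(rm0, d)) * rep_chan(iv, d)
    y <- xhat * rep_chan(gv, d) + rep_chan(bv, d)
    tape_node(tape, y, c(x$id, gamma$id, beta$id), function(g) {
      list(g * rep_chan(gv * iv, d),
           as.numeric(chan_sum(g * xhat, d)),
           as.numeric(chan_sum(g, d)))
    })
  }
}

# Weighted sum of scalar nodes (loss combination).
op_wsum <- function(tape, xs, ws) {
  v <- sum(vapply(seq_along(xs), function(i) ws[i] * xs[[i]]$v, numeric(1)))
  tape_node(tape, v, vapply(xs, function(x) x$id, integer(1)),
            function(g) lapply(ws, function(w) g * w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
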