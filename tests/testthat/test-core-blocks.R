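# Core blocks: dilated kernel arithmetic, conv units, multi-dilated
# residual blocks, ASPP, and the channel-spatial attention module.

test_that("effective kernel size follows the amplification formula", {
  expect_identical(effective_kernel_size(3, 1), 3L)
  expect_identical(effective_kernel_size(3, 5), 11L)
  expect_identical(effective_kernel_size(1, 7), 1L)
  expect_identical(effective_kernel_size(3, 3), 7L)
  expect_identical(effective_kernel_size(5, 2), 9L)
  # strictly increasing in d for k >= 2, constant for k = 1
  for (k in c(3, 5, 7)) {
    sizes <- effective_kernel_size(k, 1:6)
    expect_true(all(diff(sizes) > 0))
    expect_identical(sizes[1], as.integer(k))
  }
  expect_true(all(effective_kernel_size(1, 1:6) == 1L))
  expect_error(effective_kernel_size(0, 1), "positive")
  expect_error(effective_kernel_size(3, 0), "positive")
  expect_error(effective_kernel_size(3, 1.5), "positive")
})

test_that("conv unit preserves spatial dims and sets channel count", {
  withr::with_seed(11, {
    x <- array(rnorm(2 * 8 * 16 * 16), c(16, 16, 8, 2))
    p <- init_conv_unit(8, 16)
    y <- conv_unit(x, p, dilation = 3)
    expect_identical(dim(y), c(16L, 16L, 16L, 2L))
  })
})

test_that("conv unit with zero weights returns zero", {
  withr::with_seed(12, {
    x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
    p <- init_conv_unit(3, 4)
    p$w[] <- 0
    p$b[] <- 0
    expect_equal(max(abs(conv_unit(x, p, dilation = 2))), 0)
  })
})

test_that("conv unit matches the straight-loop oracle", {
  withr::with_seed(13, {
    x <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
    for (d in c(1, 2, 3)) {
      p <- init_conv_unit(3, 5)
      expect_equal(conv_unit(x, p, dilation = d), oracle_conv_unit(x, p, d),
                   tolerance = 1e-10)
    }
  })
})

test_that("conv unit rejects non-finite input", {
  p <- init_conv_unit(1, 1)
  x <- array(NaN, c(4, 4, 1, 1))
  expect_error(conv_unit(x, p), "non-finite")
})

test_that("residual block: shape contract and zero-weight identity", {
  withr::with_seed(21, {
    x <- array(rnorm(12 * 12 * 8 * 2), c(12, 12, 8, 2))
    p <- init_mdr_block(8, 16)
    y <- multi_dilated_residual_block(x, p)
    expect_identical(dim(y), c(12L, 12L, 16L, 2L))
    # channel-matched zero-weight block is exactly the identity
    pid <- zero_block_weights(init_mdr_block(8, 8))
    expect_identical(multi_dilated_residual_block(x, pid), x)
  })
})

test_that("degenerate single-branch block equals a composed conv-unit oracle", {
  withr::with_seed(22, {
    x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
    p <- init_mdr_block(4, 4, rates = 1, branch_depth = 2)
    got <- multi_dilated_residual_block(x, p)
    # pre-activation residual oracle: two stacked conv units plus identity
    h <- oracle_conv_unit(x, p$branches[[1]][[1]], 1)
    h <- oracle_conv_unit(h, p$branches[[1]][[2]], 1)
    expect_equal(got, x + h, tolerance = 1e-10)
  })
})

test_that("residual block branch summation over rates matches sum of units", {
  withr::with_seed(23, {
    x <- array(rnorm(9 * 9 * 3 * 1), c(9, 9, 3, 1))
    rates <- c(1, 3, 5, 11)
    p <- init_mdr_block(3, 6, rates = rates)
    got <- multi_dilated_residual_block(x, p)
    acc <- oracle_conv2d(x, p$proj$w, p$proj$b, 1)
    for (i in seq_along(rates)) {
      acc <- acc + oracle_conv_unit(x, p$branches[[i]][[1]], rates[i])
    }
    expect_equal(got, acc, tolerance = 1e-10)
  })
})

test_that("aspp preserves shape, handles tiny inputs, and matches its oracle", {
  withr::with_seed(31, {
    x <- array(rnorm(4 * 4 * 8), c(4, 4, 8, 1))
    p <- init_aspp(8, 8)
    y <- aspp(x, p)
    expect_identical(dim(y), c(4L, 4L, 8L, 1L))
    # H, W far smaller than the largest effective kernel (37) must still work
    x1 <- array(rnorm(2 * 2 * 4), c(2, 2, 4, 1))
    expect_identical(dim(aspp(x1, init_aspp(4, 6))), c(2L, 2L, 6L, 1L))
  })
})

test_that("aspp with zero weights maps any input to zero", {
  withr::with_seed(32, {
    x <- array(1, c(5, 5, 3, 2))
    p <- zero_all(init_aspp(3, 4))
    p$c1x1$gamma <- rep(1, 3)
    expect_equal(max(abs(aspp(x, p))), 0)
  })
})

test_that("aspp concatenates len(rates) + 2 branches before fusion", {
  p <- init_aspp(4, 8, rates = c(6, 12, 18))
  # fusion input width encodes the branch count x branch width
  expect_identical(dim(p$fuse$w)[3], 5L * 8L)
  p2 <- init_aspp(4, 8, rates = c(2, 4))
  expect_identical(dim(p2$fuse$w)[3], 4L * 8L)
})

test_that("aspp agrees with an independent branch-by-branch oracle", {
  withr::with_seed(33, {
    x <- array(rnorm(6 * 6 * 4), c(6, 6, 4, 1))
    rates <- c(2, 3)
    p <- init_aspp(4, 4, rates = rates)
    got <- aspp(x, p)
    branches <- list(oracle_conv_unit(x, p$c1x1, 1))
    for (i in seq_along(rates)) {
      branches[[i + 1]] <- oracle_conv_unit(x, p$dilated[[i]], rates[i])
    }
    pooled <- apply(x, c(3, 4), mean)
    pv <- array(0, dim(x))
    for (c_out in seq_len(4)) {
      pv[, , c_out, 1] <- sum(pooled[, 1] * p$pool$w[1, 1, , c_out]) +
        p$pool$b[c_out]
    }
    branches[[length(branches) + 1]] <- pv
    cat_ <- array(0, c(6, 6, 4 * length(branches), 1))
    for (j in seq_along(branches)) {
      cat_[, , (j - 1) * 4 + 1:4, ] <- branches[[j]]
    }
    want <- oracle_conv_unit(cat_, p$fuse, 1)
    expect_equal(got, want, tolerance = 1e-10)
  })
})

test_that("channel attention: shape, zero-weight value, constant-input identity", {
  withr::with_seed(41, {
    x <- array(rnorm(7 * 7 * 8 * 3), c(7, 7, 8, 3))
    p <- init_csam(8, 4)
    wc <- channel_attention(x, p)
    expect_identical(dim(wc), c(1L, 1L, 8L, 3L))
    expect_true(all(wc > 0 & wc < 1))
    # zero weights -> sigma(0) = 0.5 everywhere
    expect_equal(as.vector(channel_attention(x, zero_all(p))),
                 rep(0.5, 8 * 3))
    # spatially constant input: avg and max descriptors coincide, so the
    # gate is sigma(2 * MLP(c)) in closed form
    xc <- array(rep(rnorm(8), each = 49), c(7, 7, 8, 1))
    got <- channel_attention(xc, p)
    cvec <- xc[1, 1, , 1]
    mlp <- as.numeric(p$w1 %*% pmax(p$w0 %*% cvec + p$b0, 0) + p$b1)
    expect_equal(as.vector(got), 1 / (1 + exp(-2 * mlp)), tolerance = 1e-12)
  })
})

test_that("spatial attention: shape, zero-weight value, oracle agreement", {
  withr::with_seed(42, {
    x <- array(rnorm(8 * 8 * 5 * 2), c(8, 8, 5, 2))
    p <- init_csam(5, 1)
    ws <- spatial_attention(x, p)
    expect_identical(dim(ws), c(8L, 8L, 1L, 2L))
    expect_true(all(ws > 0 & ws < 1))
    expect_equal(as.vector(spatial_attention(x, zero_all(p))),
                 rep(0.5, 8 * 8 * 2))
    expect_equal(ws, oracle_spatial_attention(x, p), tolerance = 1e-10)
  })
})

test_that("csam composes channel-then-spatial gating", {
  withr::with_seed(43, {
    x <- array(rnorm(6 * 6 * 4 * 2), c(6, 6, 4, 2))
    p <- init_csam(4, 2)
    got <- csam(x, p)
    expect_identical(dim(got), dim(x))
    # zero attention weights: two 0.5 gates compose to 0.25 exactly
    expect_identical(csam(x, zero_all(p)), 0.25 * x)
    # independent composition of the two attention oracles
    wc <- oracle_channel_attention(x, p)
    f1 <- x
    for (n in 1:2) for (c in 1:4) f1[, , c, n] <- x[, , c, n] * wc[1, 1, c, n]
    ws <- oracle_spatial_attention(f1, p)
    f2 <- f1
    for (n in 1:2) for (c in 1:4) f2[, , c, n] <- f1[, , c, n] * ws[, , 1, n]
    expect_equal(got, f2, tolerance = 1e-10)
    # gates <= 1 bound the output magnitude elementwise
    expect_true(all(abs(got) <= abs(x) + 1e-12))
  })
})

test_that("every block preserves arbitrary spatial dimensions", {
  withr::with_seed(44, {
    for (hw in list(c(1, 1), c(3, 5), c(7, 4), c(10, 10))) {
      x <- array(rnorm(hw[1] * hw[2] * 4 * 2), c(hw[1], hw[2], 4, 2))
      expect_identical(dim(conv_unit(x, init_conv_unit(4, 6), 3))[1:2],
                       as.integer(hw))
      expect_identical(dim(multi_dilated_residual_block(x, init_mdr_block(4, 4)))[1:2],
                       as.integer(hw))
      expect_identical(dim(aspp(x, init_aspp(4, 4)))[1:2], as.integer(hw))
      expect_identical(dim(csam(x, init_csam(4, 2)))[1:2], as.integer(hw))
    }
  })
})
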