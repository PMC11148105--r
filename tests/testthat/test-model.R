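# Model assembly: registry structure, skip couplings, parameter counting,
# forward contracts, determinism, and construction scaling.

test_that("default build matches the printed layer accounting", {
  cfg <- madrnet_config()
  model <- build_madrnet(cfg, seed = 1)
  reg <- layer_registry(model)
  expect_identical(nrow(reg), 37L)
  expect_identical(sum(reg$path == "encoder"), 12L)
  expect_identical(sum(reg$path == "decoder"), 23L)
  sk <- decoder_skip_map(cfg)
  expect_identical(sk$decoder_index, c(14, 18, 22, 26, 30))
  expect_identical(sk$encoder_index, c(10, 8, 6, 4, 2))
  # couplings reference attention entries and encoder blocks in the registry
  expect_true(all(grepl("attention", reg$role[sk$decoder_index])))
  expect_true(all(grepl("mdr_block_enc", reg$role[sk$encoder_index])))
  # resolutions of coupled entries agree
  expect_identical(reg$size[sk$decoder_index], reg$size[sk$encoder_index])
})

test_that("default parameter count rounds to the published 56 million", {
  model <- build_madrnet(madrnet_config(), seed = 1)
  n <- count_trainable_parameters(model)
  expect_identical(round(n / 1e6), 56)
})

test_that("parameter counting is an exact sum over learnable arrays", {
  # a single 1x1 conv, 3 -> 32 channels with bias
  p <- list(w = array(0, c(1, 1, 3, 32)), b = rep(0, 32))
  m <- structure(list(params = p), class = "madrnet_model")
  expect_identical(count_trainable_parameters(m), 3 * 32 + 32)
})

test_that("tiny config count equals an independent shape-by-shape tally", {
  cfg <- madrnet_config(in_channels = 1, num_classes = 1, input_size = 32,
                        channel_progression = c(2, 4),
                        block_rates = c(1, 3), aspp_rates = c(2),
                        reduction_ratio = 1, spatial_kernel = 3)
  model <- build_madrnet(cfg, seed = 1)
  # hand tally (depth 1): stem 1x1 (1->2); one encoder block 2->2 with two
  # branches of one conv unit each (BN(2) + 3x3 conv 2->2); bottleneck ASPP
  # 2->4 (branch width 4: 1x1 unit, one 3x3 unit, pool conv, fuse over 12
  # channels); upconv 4->2; attention on 2 channels (hidden width
  # min(2, max(4, 2)) = 2, spatial 3x3 over 2 channels); decoder block
  # 4->2; head attention on 2; head ASPP 4->2; classifier 2->1.
  unit <- function(cin, cout, k) 2 * cin + k * k * cin * cout + cout
  conv <- function(cin, cout, k) k * k * cin * cout + cout
  block <- function(cin, cout, nb) {
    nb * unit(cin, cout, 3) + if (cin != cout) conv(cin, cout, 1) else 0
  }
  aspp_n <- function(cin, cout) {
    unit(cin, cout, 1) + unit(cin, cout, 3) + conv(cin, cout, 1) +
      unit(3 * cout, cout, 1)
  }
  att <- function(C, hidden, sk) {
    hidden * C + hidden + C * hidden + C + sk * sk * 2 + 1
  }
  want <- conv(1, 2, 1) + block(2, 2, 2) + aspp_n(2, 4) +
    (2 * 2 * 4 * 2 + 2) + att(2, 2, 3) + block(4, 2, 2) + att(2, 2, 3) +
    aspp_n(4, 2) + conv(2, 1, 1)
  expect_identical(count_trainable_parameters(model), want)
})

test_that("halving channel widths roughly quarters the parameter count", {
  n_full <- count_trainable_parameters(
    build_madrnet(madrnet_config(in_channels = 1, input_size = 64,
                                 channel_progression = c(8, 16, 32, 64, 128, 256)),
                  seed = 1))
  n_half <- count_trainable_parameters(
    build_madrnet(madrnet_config(in_channels = 1, input_size = 64,
                                 channel_progression = c(4, 8, 16, 32, 64, 128)),
                  seed = 1))
  expect_gt(n_full / n_half, 3.5)
  expect_lt(n_full / n_half, 4.5)
})

test_that("forward pass honours the output contracts", {
  m1 <- build_madrnet(tiny_config(), seed = 2)
  x <- random_feature_map(64, 64, 1, 2, seed = 5)
  x <- (x - min(x)) / diff(range(x))
  p <- madrnet_forward(m1, x)
  expect_identical(dim(p), c(64L, 64L, 1L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  # with batch-normalised activations the sigmoid output is strictly
  # interior; the untrained eval-mode pass above may saturate in double
  # precision because fresh running moments do not normalise anything
  pt <- madrnet_forward(build_madrnet(tiny_config(), seed = 2), x,
                        training = TRUE)
  expect_true(all(pt > 0 & pt < 1))
  # softmax head: per-pixel channel sums equal 1
  m4 <- build_madrnet(tiny_config(num_classes = 4), seed = 2)
  p4 <- madrnet_forward(m4, x)
  expect_identical(dim(p4), c(64L, 64L, 4L, 2L))
  expect_lt(max(abs(apply(p4, c(1, 2, 4), sum) - 1)), 1e-6)
  # wrong input size is a shape error
  expect_error(madrnet_forward(m1, x[1:32, 1:32, , , drop = FALSE]), "input")
})

test_that("two forward passes on identical input are bit-identical", {
  m <- build_madrnet(tiny_config(), seed = 9)
  x <- random_feature_map(64, 64, 1, 1, seed = 6)
  expect_identical(madrnet_forward(m, x), madrnet_forward(m, x))
})

test_that("skip-map pattern generalises to other depths", {
  cfg2 <- madrnet_config(in_channels = 1, input_size = 16,
                         channel_progression = c(4, 8, 16))
  sk <- decoder_skip_map(cfg2)
  expect_identical(sk$decoder_index, c(8, 12))
  expect_identical(sk$encoder_index, c(4, 2))
  model <- build_madrnet(cfg2, seed = 1)
  reg <- layer_registry(model)
  expect_identical(nrow(reg), 6L * 2L + 7L)
  expect_true(all(sk$decoder_index <= nrow(reg)))
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  expect_identical(dim(madrnet_forward(model, x)), c(16L, 16L, 1L, 1L))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(madrnet_config(input_size = 100), "divisible")
  expect_error(madrnet_config(channel_progression = c(32, 16, 64)),
               "increasing")
  expect_error(madrnet_config(num_classes = 3, head_activation = "sigmoid"),
               "sigmoid")
})

test_that("checkpoints round-trip the model and forward outputs", {
  m <- build_madrnet(tiny_config(), seed = 4)
  x <- random_feature_map(64, 64, 1, 1, seed = 8)
  p0 <- madrnet_forward(m, x)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path, extra = list(epoch = 3L))
  ck <- load_checkpoint(path)
  expect_identical(ck$epoch, 3L)
  expect_identical(madrnet_forward(ck$model, x), p0)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_identical(length(side$registry$layer), 37L)
})

test_that("tidy and glance expose registry and totals", {
  m <- build_madrnet(tiny_config(), seed = 1)
  expect_identical(tidy(m), layer_registry(m))
  g <- glance(m)
  expect_identical(g$n_layers, 37L)
  expect_identical(g$n_parameters, count_trainable_parameters(m))
})
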