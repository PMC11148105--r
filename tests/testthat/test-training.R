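# Training workflow: loss descent, logging, reproducibility, checkpoint
# resume, evaluation and prediction plumbing, and the loss-ablation
# mechanism. Runs use a reduced-depth configuration so each fits in
# seconds; the full overfit-capacity experiment lives in the acceptance
# suite.

shallow_config <- function(num_classes = 1) {
  madrnet_config(in_channels = 1, num_classes = num_classes, input_size = 32,
                 channel_progression = c(4, 8, 16))
}

shallow_data <- function(n = 4, seed = 31) {
  d <- generate_binary(synthetic_spec(n_images = n, image_size = 32,
                                      task = "binary", seed = seed))
  d
}

test_that("a short training run reduces the hybrid loss and logs components", {
  d <- shallow_data()
  m <- build_madrnet(shallow_config(), seed = 1)
  log_file <- withr::local_tempfile(fileext = ".csv")
  fit <- train_madrnet(m, d$images, d$masks, epochs = 25, batch_size = 8,
                       seed = 1, log_path = log_file)
  h <- tidy(fit)
  expect_identical(nrow(h), 25L)
  expect_true(all(c("loss", "ce", "dice_loss", "focal_tversky",
                    "train_dice", "val_dice", "lr") %in% names(h)))
  expect_lt(h$loss[25], h$loss[1])
  expect_true(file.exists(log_file))
  expect_identical(nrow(read.csv(log_file)), 25L)
  expect_s3_class(autoplot(fit), "ggplot")
  g <- glance(fit)
  expect_identical(g$epochs, 25L)
})

test_that("training is reproducible under identical seed and config", {
  d <- shallow_data()
  f1 <- train_madrnet(build_madrnet(shallow_config(), seed = 2),
                      d$images, d$masks, epochs = 5, batch_size = 2, seed = 9)
  f2 <- train_madrnet(build_madrnet(shallow_config(), seed = 2),
                      d$images, d$masks, epochs = 5, batch_size = 2, seed = 9)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("resuming from a checkpoint reproduces the continued run exactly", {
  d <- shallow_data()
  ckpt <- withr::local_tempfile(fileext = ".rds")
  # uninterrupted 6-epoch run
  full <- train_madrnet(build_madrnet(shallow_config(), seed = 3),
                        d$images, d$masks, epochs = 6, batch_size = 8,
                        seed = 4)
  # 3 epochs, checkpoint, then resume for the remaining 3
  part <- train_madrnet(build_madrnet(shallow_config(), seed = 3),
                        d$images, d$masks, epochs = 3, batch_size = 8,
                        seed = 4, checkpoint_path = ckpt)
  resumed <- train_madrnet(build_madrnet(shallow_config(), seed = 3),
                           d$images, d$masks, epochs = 6, batch_size = 8,
                           seed = 4, resume_from = ckpt)
  expect_equal(resumed$history$loss,
               full$history$loss[4:6], tolerance = 1e-12)
})

test_that("untrained-model validation dice sits at the chance floor", {
  d <- shallow_data(n = 6, seed = 37)
  m <- build_madrnet(shallow_config(), seed = 5)
  rep_ <- evaluate_madrnet(m, d$images, d$masks)
  # an untrained sigmoid model thresholded at 0.5 yields near-constant
  # maps; dice stays near the level of a constant guess, far below a
  # trained model
  expect_lt(rep_$dice[nrow(rep_)], 0.6)
})

test_that("evaluation report has one row per image plus a summary", {
  d <- shallow_data(n = 5, seed = 41)
  m <- build_madrnet(shallow_config(), seed = 6)
  rep_ <- evaluate_madrnet(m, d$images, d$masks)
  expect_identical(nrow(rep_), 6L)
  expect_identical(rep_$image[6], "summary")
  expect_identical(colnames(rep_)[1], "image")
})

test_that("multiclass evaluation macro dice equals the hand aggregation", {
  spec <- synthetic_spec(n_images = 2, image_size = 32, task = "multiclass3",
                         seed = 43)
  d <- generate_multiclass3(spec)
  m <- build_madrnet(shallow_config(num_classes = 4), seed = 7)
  prob <- madrnet_forward(m, d$images)
  rep_ <- evaluate_predictions(prob, d$masks, include_background = TRUE)
  pred <- argmax_mask(prob)
  hand <- multiclass_report(d$masks[, , 1, 1], pred[, , 1, 1], 4)
  per_class <- hand$dice[hand$class != "macro"]
  expect_equal(rep_$dice[1], mean(per_class), tolerance = 1e-12)
})

test_that("prediction thresholds behave at the extremes", {
  d <- shallow_data(n = 2, seed = 47)
  m <- build_madrnet(shallow_config(), seed = 8)
  expect_true(all(predict_madrnet(m, d$images, threshold = 0) == 1))
  expect_true(all(predict_madrnet(m, d$images, threshold = 1 + 1e-9) == 0))
  m4 <- build_madrnet(shallow_config(num_classes = 4), seed = 8)
  lab <- predict_madrnet(m4, d$images)
  expect_true(all(lab %in% 0:3))
})

test_that("the loss-ablation mechanism runs under each single-term loss", {
  d <- shallow_data(n = 4, seed = 53)
  losses <- list(
    ce_only = loss_config(w_ce = 1, w_dice = 0, w_ft = 0),
    dice_only = loss_config(w_ce = 0, w_dice = 1, w_ft = 0),
    ft_only = loss_config(w_ce = 0, w_dice = 0, w_ft = 1),
    hybrid = loss_config()
  )
  curves <- lapply(losses, function(lc) {
    fit <- train_madrnet(build_madrnet(shallow_config(), seed = 11),
                         d$images, d$masks, epochs = 8, batch_size = 8,
                         seed = 12, loss = lc)
    fit$history$train_dice
  })
  expect_identical(lengths(curves), c(ce_only = 8L, dice_only = 8L,
                                      ft_only = 8L, hybrid = 8L))
  expect_true(all(vapply(curves, function(x) all(is.finite(x)), logical(1))))
})

test_that("the command-line workflow wires gen-data, train, eval and predict", {
  dir <- withr::local_tempdir()
  data_dir <- file.path(dir, "data")
  expect_invisible(madrnet_cli(c("gen-data", "--task", "binary", "--n", "12",
                                 "--input-size", "32", "--seed", "3",
                                 "--out", data_dir)))
  expect_identical(length(list.files(data_dir, "^img_")), 12L)
  ckpt <- file.path(dir, "model.rds")
  log_csv <- file.path(dir, "log.csv")
  suppressMessages(madrnet_cli(c("train", "--data", data_dir, "--epochs", "2",
                                 "--batch-size", "8", "--seed", "1",
                                 "--base-width", "4",
                                 "--out", ckpt, "--log", log_csv)))
  expect_true(file.exists(ckpt))
  expect_true(file.exists(log_csv))
  report_stub <- file.path(dir, "report")
  suppressMessages(madrnet_cli(c("eval", "--checkpoint", ckpt,
                                 "--data", data_dir,
                                 "--out", report_stub)))
  expect_true(file.exists(paste0(report_stub, ".csv")))
  pred_dir <- file.path(dir, "pred")
  suppressMessages(madrnet_cli(c("predict", "--checkpoint", ckpt,
                                 "--data", data_dir, "--out", pred_dir)))
  expect_identical(length(list.files(pred_dir, "_mask\\.png$")), 12L)
})
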