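test_that("pretraining reduces the reconstruction loss and is deterministic", {
  ds <- tiny_dataset(n = 16, len = c(32, 44), seed = 14)
  b1 <- pretrain_backbone(ds, pretrain_epochs = 5, seed = 14)
  expect_length(b1$history, 5)
  expect_lt(b1$history[5], b1$history[1])

  b2 <- pretrain_backbone(ds, pretrain_epochs = 5, seed = 14)
  expect_identical(b1$params, b2$params)
  b3 <- pretrain_backbone(ds, pretrain_epochs = 5, seed = 15)
  expect_false(identical(b1$params$W1, b3$params$W1))
})

test_that("pretraining never reads labels", {
  ds <- tiny_dataset(n = 12, len = c(32, 40), seed = 16)
  stripped <- ds
  stripped$labels <- NULL
  b_lab <- pretrain_backbone(ds, pretrain_epochs = 3, seed = 16)
  b_none <- pretrain_backbone(stripped, pretrain_epochs = 3, seed = 16)
  expect_identical(b_lab$params, b_none$params)
})

test_that("empty training split errors out", {
  ds <- tiny_dataset(n = 6, len = c(20, 25), seed = 17)
  ds$split[] <- "validation"
  expect_error(pretrain_backbone(ds, pretrain_epochs = 1), "no clips")
  empty <- list(x = list(), y = matrix(numeric(0), 0, 6))
  expect_error(train_emotion_model(emotion_model(seed = 1), empty), "empty")
})

test_that("fine-tuning trains only the head and leaves the backbone bitwise intact", {
  ds <- tiny_dataset(n = 16, len = c(32, 40), seed = 18)
  b <- pretrain_backbone(ds, pretrain_epochs = 2, seed = 18)
  before <- b$params
  lab <- labeled_clips(ds, split = "train")
  m <- finetune_head(b, lab, epochs = 8, seed = 18)
  expect_identical(m$backbone$params, before)
  expect_length(m$history, 8)
  expect_lt(m$history[8], m$history[1])

  m2 <- finetune_head(b, lab, epochs = 8, seed = 18)
  expect_identical(m$head, m2$head)
})

test_that("all-zero labels drive the head toward zero output", {
  ds <- tiny_dataset(n = 12, len = c(32, 40), seed = 19)
  lab <- labeled_clips(ds, split = "train")
  lab$y[] <- 0
  b <- random_backbone(seed = 19)
  m <- finetune_head(b, lab, epochs = 60, seed = 19)
  preds <- predict(m, lab$x)
  expect_lt(mean(abs(preds)), 0.05)
})

test_that("the baseline trains the identical architecture end to end", {
  ds <- tiny_dataset(n = 12, len = c(32, 40), seed = 20)
  lab <- labeled_clips(ds, split = "train")
  m <- train_baseline(lab, epochs = 3, seed = 20)
  expect_false(m$frozen)
  expect_length(m$history, 3)
  expect_lt(m$history[3], m$history[1])

  # parameter inventory matches the pretrained-model inventory exactly
  ssl <- emotion_model(random_backbone(seed = 20), seed = 20)
  expect_identical(lapply(c(m$backbone$params, m$head), dim),
                   lapply(c(ssl$backbone$params, ssl$head), dim))

  # joint training moves backbone parameters
  init <- emotion_model(seed = 20)
  expect_false(identical(m$backbone$params$W1, init$backbone$params$W1))

  m2 <- train_baseline(lab, epochs = 3, seed = 20)
  expect_identical(m$head, m2$head)
  expect_identical(m$backbone$params, m2$backbone$params)
})

test_that("training leaves the caller's RNG state untouched", {
  ds <- tiny_dataset(n = 8, len = c(20, 30), seed = 21)
  set.seed(999)
  expected <- runif(3)
  set.seed(999)
  invisible(pretrain_backbone(ds, pretrain_epochs = 1, seed = 3))
  expect_identical(runif(3), expected)
})

test_that("pretraining lowers held-out masked reconstruction error", {
  ds <- tiny_dataset(n = 20, len = c(32, 44), seed = 22)
  b <- pretrain_backbone(ds, pretrain_epochs = 6, seed = 22)
  val <- sslser:::split_clips(ds, "validation")
  trained <- reconstruction_error(b, val, seed = 5)
  untrained <- reconstruction_error(random_backbone(seed = 23), val, seed = 5)
  expect_lt(trained, untrained)
})
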