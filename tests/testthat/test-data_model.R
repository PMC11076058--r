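test_that("dataset round-trips through the on-disk CSV layout", {
  ds <- generate_emotion_dataset(3, length_range = c(10, 15), seed = 3,
                                 standardize = FALSE)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- load_dataset(dir)
  expect_identical(names(ds2$clips), names(ds$clips))
  for (id in names(ds$clips)) {
    expect_equal(unname(ds2$clips[[id]]), unname(ds$clips[[id]]),
                 tolerance = 1e-12)
  }
  expect_equal(unname(ds2$labels), unname(ds$labels), tolerance = 1e-12)
})

test_that("loading keeps unlabeled clips and rejects malformed input", {
  ds <- generate_emotion_dataset(3, length_range = c(8, 10), seed = 4,
                                 standardize = FALSE)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  # drop one label row: clip stays, label count drops
  lab <- read.csv(file.path(dir, "labels.csv"))
  write.csv(lab[-2, ], file.path(dir, "labels.csv"), row.names = FALSE)
  ds2 <- load_dataset(dir)
  expect_length(ds2$clips, 3)
  expect_equal(nrow(ds2$labels), 2)

  # wrong feature count names the offending file
  bad <- matrix(rnorm(5 * 73), 5, 73)
  colnames(bad) <- sprintf("f%02d", 1:73)
  write.csv(bad, file.path(dir, "clips", "zz_bad.csv"), row.names = FALSE)
  expect_error(load_dataset(dir), "zz_bad.*73|73.*zz_bad")
  unlink(file.path(dir, "clips", "zz_bad.csv"))

  # empty directory errors
  empty <- withr::local_tempdir()
  dir.create(file.path(empty, "clips"))
  expect_error(load_dataset(empty), "empty")
})

test_that("standardization z-scores with training statistics only", {
  # hand-built clip: one feature column with mean 10, SD 2 across timesteps
  x <- matrix(0, 5, 74)
  x[, 1] <- c(8, 9, 10, 11, 14)
  stats <- standardization_stats(mean = c(10, rep(0, 73)),
                                 sd = c(2, rep(1, 73)))
  ds <- ser_dataset(list(a = x))
  out <- standardize_dataset(ds, stats = stats)
  expect_equal(out$clips$a[5, 1], 2)  # (14 - 10) / 2
  expect_equal(out$clips$a[3, 1], 0)

  # fitted path: training columns end up mean 0, SD 1; validation transformed
  # with the training stats
  ds2 <- tiny_dataset(n = 12, len = c(20, 30), seed = 5)
  pooled <- do.call(rbind, sslser:::split_clips(ds2, "train"))
  expect_equal(max(abs(colMeans(pooled))), 0, tolerance = 1e-10)
  expect_equal(max(abs(apply(pooled, 2, sd) - 1)), 0, tolerance = 1e-10)
})

test_that("zero-variance features are flagged and mapped to zero", {
  clips <- list(a = matrix(rnorm(20 * 74), 20, 74),
                b = matrix(rnorm(25 * 74), 25, 74))
  clips$a[, 7] <- 3.3
  clips$b[, 7] <- 3.3
  ds <- standardize_dataset(ser_dataset(clips))
  expect_true(ds$stats$zero_variance[7])
  expect_true(all(ds$clips$a[, 7] == 0))
  expect_equal(ds$stats$sd[7], 1)
})

test_that("non-finite raw entries become zero after standardization", {
  clips <- list(a = matrix(rnorm(30 * 74), 30, 74))
  clips$a[3, 5] <- NaN
  clips$a[4, 6] <- Inf
  ds <- standardize_dataset(ser_dataset(clips))
  expect_true(all(is.finite(ds$clips$a)))
  expect_equal(ds$clips$a[3, 5], 0)
  expect_equal(ds$clips$a[4, 6], 0)
})

test_that("standardization is invertible given the statistics", {
  ds <- generate_emotion_dataset(4, length_range = c(15, 20), seed = 6,
                                 standardize = FALSE)
  raw <- ds$clips
  std <- standardize_dataset(ds)
  back <- unstandardize_matrix(std$clips[[2]], std$stats)
  expect_equal(back, raw[[2]], tolerance = 1e-10)
})

test_that("the split is a reproducible partition with the right shares", {
  ds <- generate_emotion_dataset(100, length_range = c(5, 8), seed = 8,
                                 standardize = FALSE)
  s1 <- split_dataset(ds, 0.8, seed = 42)
  expect_equal(sum(s1$split == "train"), 80)
  expect_equal(sum(s1$split == "validation"), 20)
  expect_setequal(names(s1$split), names(ds$clips))

  s2 <- split_dataset(ds, 0.8, seed = 42)
  expect_identical(s1$split, s2$split)
  s3 <- split_dataset(ds, 0.8, seed = 43)
  expect_false(identical(s1$split, s3$split))

  expect_error(split_dataset(ds, 1.0), "between 0 and 1")
  one <- ser_dataset(ds$clips[1])
  expect_error(split_dataset(one, 0.8), "at least 2")
})

test_that("label validation enforces the 0-3 intensity range", {
  clips <- list(a = matrix(0, 5, 74))
  bad <- matrix(3.5, 1, 6, dimnames = list("a", NULL))
  expect_error(ser_dataset(clips, labels = bad), "\\[0, 3\\]")
})
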