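# A small shared experiment keeps these tests fast; scientific direction
# checks at realistic scale live in the acceptance tests.
small_curve <- function() {
  ds <- tiny_dataset(n = 30, len = c(32, 44), seed = 24)
  run_label_curve(ds, label_grid = c(4L, 8L), repeats = 2L, base_seed = 24L,
                  epochs = 2L, pretrain_epochs = 2L)
}

test_that("subset sampling is uniform, train-only and reproducible", {
  ds <- tiny_dataset(n = 40, len = c(10, 15), seed = 25)
  sub <- sample_labeled_subset(ds, 8, seed = 1)
  expect_length(sub$ids, 8)
  expect_false(anyDuplicated(sub$ids) > 0)
  expect_true(all(ds$split[sub$ids] == "train"))
  expect_identical(sample_labeled_subset(ds, 8, seed = 1)$ids, sub$ids)
  expect_false(identical(sample_labeled_subset(ds, 8, seed = 2)$ids, sub$ids))

  n_train <- sum(ds$split == "train" & names(ds$split) %in% rownames(ds$labels))
  whole <- sample_labeled_subset(ds, n_train, seed = 3)
  expect_setequal(whole$ids, labeled_clips(ds, split = "train")$ids)
  expect_error(sample_labeled_subset(ds, n_train + 1, seed = 3), "available")
})

test_that("cell seeds are stable and distinct across the grid", {
  s1 <- sslser:::cell_seed(7, 20, 1)
  expect_identical(s1, sslser:::cell_seed(7, 20, 1))
  cells <- expand.grid(n = c(20, 35, 50, 400), rep = 1:3)
  seeds <- mapply(function(n, r) sslser:::cell_seed(7, n, r),
                  cells$n, cells$rep)
  expect_false(anyDuplicated(seeds) > 0)
  expect_true(all(seeds >= 0 & seeds < 2^31))
})

test_that("the curve produces exactly |grid| x repeats x 2 paired records", {
  cr <- small_curve()
  expect_s3_class(cr, "ser_curve")
  expect_equal(nrow(cr$records), 2 * 2 * 2)
  expect_setequal(unique(cr$records$model), c("ssl", "baseline"))

  # paired subsets: both arms share the cell seed within each (n, repeat)
  rec <- cr$records
  for (n in c(4, 8)) {
    for (r in 1:2) {
      cell <- rec[rec$n_labels == n & rec$rep == r, ]
      expect_equal(nrow(cell), 2)
      expect_equal(length(unique(cell$seed)), 1)
    }
  }

  # aggregate has mean and sd for every metric and cell
  n_metrics <- 2 + 3 * 6
  expect_equal(nrow(cr$aggregate), n_metrics * 2 * 2)
  expect_true(all(is.finite(cr$aggregate$mean)))
})

test_that("repeats = 1 aggregates with zero standard deviation", {
  ds <- tiny_dataset(n = 20, len = c(32, 40), seed = 26)
  cr <- run_label_curve(ds, label_grid = 4L, repeats = 1L, base_seed = 26L,
                        epochs = 1L, pretrain_epochs = 1L)
  expect_true(all(cr$aggregate$sd == 0))
})

test_that("experiments are exactly reproducible from the base seed", {
  ds <- tiny_dataset(n = 24, len = c(32, 40), seed = 27)
  cr1 <- run_label_curve(ds, label_grid = 4L, repeats = 1L, base_seed = 9L,
                         epochs = 2L, pretrain_epochs = 2L)
  cr2 <- run_label_curve(ds, label_grid = 4L, repeats = 1L, base_seed = 9L,
                         epochs = 2L, pretrain_epochs = 2L)
  expect_identical(cr1$records, cr2$records)
})

test_that("a pretrained backbone is reused frozen across cells", {
  ds <- tiny_dataset(n = 24, len = c(32, 40), seed = 28)
  b <- pretrain_backbone(ds, pretrain_epochs = 2, seed = 28)
  before <- b$params
  cr <- run_label_curve(ds, label_grid = c(4L, 6L), repeats = 1L,
                        base_seed = 28L, backbone = b, epochs = 1L)
  expect_identical(cr$backbone$params, before)
})

test_that("report_curve writes tidy records, aggregates and plots", {
  cr <- small_curve()
  out <- withr::local_tempdir()
  files <- report_curve(cr, out)
  expect_true(file.exists(file.path(out, "records.csv")))
  expect_true(file.exists(file.path(out, "aggregate.csv")))
  rec <- read.csv(file.path(out, "records.csv"))
  expect_equal(nrow(rec), nrow(cr$records))
  pngs <- list.files(out, pattern = "^curve_.*\\.png$")
  expect_length(pngs, 14)  # overall accuracy + MAE, 6 per-emotion each
})

test_that("grid values beyond the labeled pool are rejected", {
  ds <- tiny_dataset(n = 10, len = c(20, 30), seed = 29)
  expect_error(run_label_curve(ds, label_grid = 1000L, repeats = 1L),
               "exceeds")
})
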