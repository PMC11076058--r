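test_that("rounding floors below .5 and rounds ties up", {
  expect_equal(round_intensity(1.4), 1)
  expect_equal(round_intensity(1.5), 2)
  expect_equal(round_intensity(0), 0)
  expect_equal(round_intensity(c(0.5, 2.5, 2.49999)), c(1, 3, 2))
  expect_error(round_intensity(NaN), "finite")
  expect_error(round_intensity(Inf), "finite")
})

test_that("4-class accuracy matches hand-derived cases", {
  t2 <- rbind(rep(0, 6), rep(1, 6))
  expect_equal(four_class_accuracy(t2, t2), 1)
  expect_equal(four_class_accuracy(matrix(0, 2, 6), t2), 0.5)

  # +0.4 on integer-valued truth rounds back to the truth everywhere,
  # including at 3 where clamping keeps the class in range
  tr <- matrix(sample(0:3, 60, replace = TRUE), 10, 6)
  expect_equal(four_class_accuracy(tr + 0.4, tr), 1)

  # single cell, both round to 3
  p1 <- matrix(c(2.6, 0, 0, 0, 0, 0), 1, 6)
  t1 <- matrix(c(3, 0, 0, 0, 0, 0), 1, 6)
  expect_equal(four_class_accuracy_per_emotion(p1, t1, 1), 1)

  expect_error(four_class_accuracy(matrix(0, 2, 6), matrix(0, 3, 6)),
               "identical shape")
  expect_error(four_class_accuracy_per_emotion(t2, t2, 7), "1\\.\\.6")
})

test_that("per-emotion accuracies average to the overall accuracy", {
  s <- random_scores(40, seed = 21)
  per <- vapply(1:6, function(j)
    four_class_accuracy_per_emotion(s$pred, s$true, j), numeric(1))
  expect_equal(mean(per), four_class_accuracy(s$pred, s$true),
               tolerance = 1e-12)
})

test_that("MAE is computed on raw floats without clamping", {
  s <- random_scores(15, seed = 22)
  expect_equal(emotion_mae(s$true, s$true), 0)
  expect_equal(emotion_mae(s$true + 0.25, s$true), 0.25, tolerance = 1e-12)
  signs <- matrix(rep_len(c(0.1, -0.1), 15 * 6), 15, 6)
  expect_equal(emotion_mae(s$true + signs, s$true), 0.1, tolerance = 1e-12)
  # out-of-range predictions contribute their full error (no clamping)
  p <- s$true
  p[1, 1] <- s$true[1, 1] + 10
  expect_gt(emotion_mae(p, s$true, j = 1), 10 / 15 - 1e-9)
})

test_that("F1 handles its conventions and a hand-computed case", {
  # TP=2, FP=1, FN=1 in column 1 -> P = R = 2/3 -> F1 = 2/3
  tr <- matrix(0, 5, 6); pr <- matrix(0, 5, 6)
  tr[, 1] <- c(1, 2, 0, 1, 0)
  pr[, 1] <- c(1, 1, 1, 0, 0)
  expect_equal(f1_per_emotion(pr, tr, 1), 2 / 3, tolerance = 1e-12)

  # perfect agreement with at least one positive
  expect_equal(f1_per_emotion(tr, tr, 1), 1)
  # no predicted positives but true positives -> recall 0 -> F1 0
  expect_equal(f1_per_emotion(matrix(0, 5, 6), tr, 1), 0)
  # no positives anywhere -> defined as 1
  expect_equal(f1_per_emotion(matrix(0, 5, 6), matrix(0, 5, 6), 1), 1)
  # raw binarization counts sub-threshold intensities as present
  tr2 <- matrix(0, 2, 6); pr2 <- matrix(0, 2, 6)
  tr2[, 2] <- c(0.3, 0); pr2[, 2] <- c(0.3, 0)
  expect_equal(f1_per_emotion(pr2, tr2, 2), 1)  # both round to absent
  expect_equal(f1_per_emotion(pr2, tr2, 2, presence = "raw"), 1)
})

test_that("vectorized metrics equal the scalar-loop oracles", {
  for (case in 1:25) {
    s <- random_scores(sample(1:50, 1), seed = 100 + case)
    expect_equal(four_class_accuracy(s$pred, s$true),
                 oracle_accuracy(s$pred, s$true), tolerance = 1e-12)
    j <- sample(1:6, 1)
    expect_equal(four_class_accuracy_per_emotion(s$pred, s$true, j),
                 oracle_accuracy_emotion(s$pred, s$true, j),
                 tolerance = 1e-12)
    expect_equal(emotion_mae(s$pred, s$true),
                 oracle_mae(s$pred, s$true), tolerance = 1e-12)
    expect_equal(emotion_mae(s$pred, s$true, j),
                 oracle_mae(s$pred, s$true, j), tolerance = 1e-12)
    expect_equal(f1_per_emotion(s$pred, s$true, j),
                 oracle_f1(s$pred, s$true, j), tolerance = 1e-12)
  }
})

test_that("per-emotion metrics are permutation-consistent", {
  s <- random_scores(30, seed = 31)
  perm <- c(3, 1, 6, 2, 5, 4)
  for (j in 1:6) {
    expect_equal(
      four_class_accuracy_per_emotion(s$pred[, perm], s$true[, perm], j),
      four_class_accuracy_per_emotion(s$pred, s$true, perm[j]))
    expect_equal(f1_per_emotion(s$pred[, perm], s$true[, perm], j),
                 f1_per_emotion(s$pred, s$true, perm[j]))
  }
})

test_that("the aggregated report carries every metric with bounds", {
  s <- random_scores(25, seed = 41)
  rep <- evaluate_predictions(s$pred, s$true)
  expect_s3_class(rep, "ser_metrics")
  expect_true(rep$overall_accuracy >= 0 && rep$overall_accuracy <= 1)
  expect_true(all(rep$per_emotion_accuracy >= 0 & rep$per_emotion_accuracy <= 1))
  expect_true(rep$overall_mae >= 0)
  expect_true(all(rep$per_emotion_f1 >= 0 & rep$per_emotion_f1 <= 1))
  expect_named(rep$per_emotion_mae, emotion_names())
  row <- sslser:::metrics_row(rep)
  expect_length(row, 2 + 3 * 6)
})
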