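# Evaluation surface: nearest-integer rounding with ties up, 4-class
# accuracy (overall and per emotion), mean absolute error on the raw
# floats, and a presence/absence F1 per emotion. Predictions are clamped
# to [0, 3] before rounding inside accuracy and F1 so the class set stays
# {0, 1, 2, 3}; MAE is never clamped.

#' Round an intensity to the nearest integer, ties up
#'
#' `floor(x)` when the fractional part is below 0.5, `ceiling(x)` when it
#' is 0.5 or more, so `1.5` rounds to 2 (unlike base R's round-half-even).
#'
#' @param x Numeric vector of finite values.
#' @return Integer-valued numeric vector.
#' @export
#' @examples
#' round_intensity(c(1.4, 1.5, 0))
round_intensity <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("round_intensity requires finite numeric input", call. = FALSE)
  }
  floor(x + 0.5)
}

clamp03 <- function(x) pmin(pmax(x, 0), 3)

check_score_pair <- function(pred, true) {
  pred <- as.matrix(pred)
  true <- as.matrix(true)
  if (!all(dim(pred) == dim(true))) {
    stop("prediction and truth matrices must have identical shape",
         call. = FALSE)
  }
  if (ncol(pred) != 6L) stop("score matrices must have 6 emotion columns",
                             call. = FALSE)
  if (nrow(pred) < 1L) stop("score matrices must have at least one row",
                            call. = FALSE)
  list(pred = pred, true = true)
}

check_emotion_index <- function(j) {
  if (length(j) != 1L || is.na(j) || j < 1L || j > 6L) {
    stop("emotion index must lie in 1..6", call. = FALSE)
  }
  as.integer(j)
}

#' 4-class accuracy over all six emotions
#'
#' Both matrices are clamped to `[0, 3]` and rounded with
#' [round_intensity()]; the accuracy is the fraction of the `6n` cells
#' where the rounded classes agree.
#'
#' @param pred,true Numeric `n` x 6 matrices of predicted and true
#'   intensities.
#' @return Accuracy in `[0, 1]`.
#' @export
four_class_accuracy <- function(pred, true) {
  m <- check_score_pair(pred, true)
  mean(round_intensity(clamp03(m$pred)) == round_intensity(clamp03(m$true)))
}

#' @rdname four_class_accuracy
#' @param j Emotion column (1-based, in [emotion_names()] order); the
#'   per-emotion variant restricts the count to that column.
#' @export
four_class_accuracy_per_emotion <- function(pred, true, j) {
  m <- check_score_pair(pred, true)
  j <- check_emotion_index(j)
  mean(round_intensity(clamp03(m$pred[, j])) ==
         round_intensity(clamp03(m$true[, j])))
}

#' Mean absolute error on intensity scores
#'
#' Standard MAE on the raw floating-point values (no clamping, no
#' rounding), over all six columns or over one emotion column.
#'
#' @param pred,true Numeric `n` x 6 matrices.
#' @param j Optional emotion column (1-based); default uses all cells.
#' @return Non-negative scalar.
#' @export
emotion_mae <- function(pred, true, j = NULL) {
  m <- check_score_pair(pred, true)
  if (is.null(j)) return(mean(abs(m$pred - m$true)))
  j <- check_emotion_index(j)
  mean(abs(m$pred[, j] - m$true[, j]))
}

#' Presence/absence F1 score for one emotion
#'
#' An emotion counts as present when its clamped, rounded intensity is at
#' least 1 (configurable to `raw value > 0`). F1 is `2PR / (P + R)` on that
#' binarization; it is defined as 1 when there are neither true nor
#' predicted positives, and 0 when precision and recall are both undefined
#' or zero otherwise.
#'
#' @param pred,true Numeric `n` x 6 matrices.
#' @param j Emotion column (1-based).
#' @param presence `"rounded"` (default: rounded clamped value >= 1) or
#'   `"raw"` (value > 0).
#' @return F1 in `[0, 1]`.
#' @export
f1_per_emotion <- function(pred, true, j, presence = c("rounded", "raw")) {
  m <- check_score_pair(pred, true)
  j <- check_emotion_index(j)
  presence <- match.arg(presence)
  binarize <- function(x) {
    if (presence == "rounded") round_intensity(clamp03(x)) >= 1 else x > 0
  }
  p <- binarize(m$pred[, j])
  t <- binarize(m$true[, j])
  tp <- sum(p & t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  if (tp == 0 && fp == 0 && fn == 0) return(1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

#' Full evaluation report
#'
#' Computes every metric the package reports: overall and per-emotion
#' 4-class accuracy, overall and per-emotion MAE, and per-emotion F1.
#'
#' @param pred,true Numeric `n` x 6 matrices.
#' @param presence F1 binarization rule, see [f1_per_emotion()].
#' @return An object of class `ser_metrics`: a list with elements
#'   `overall_accuracy`, `per_emotion_accuracy`, `overall_mae`,
#'   `per_emotion_mae` and `per_emotion_f1`.
#' @export
evaluate_predictions <- function(pred, true, presence = "rounded") {
  m <- check_score_pair(pred, true)
  per_acc <- vapply(1:6, function(j)
    four_class_accuracy_per_emotion(m$pred, m$true, j), numeric(1))
  per_mae <- vapply(1:6, function(j)
    emotion_mae(m$pred, m$true, j), numeric(1))
  per_f1 <- vapply(1:6, function(j)
    f1_per_emotion(m$pred, m$true, j, presence = presence), numeric(1))
  names(per_acc) <- names(per_mae) <- names(per_f1) <- emotion_names()
  structure(
    list(overall_accuracy = four_class_accuracy(m$pred, m$true),
         per_emotion_accuracy = per_acc,
         overall_mae = emotion_mae(m$pred, m$true),
         per_emotion_mae = per_mae,
         per_emotion_f1 = per_f1,
         n = nrow(m$pred)),
    class = "ser_metrics"
  )
}

#' @export
print.ser_metrics <- function(x, digits = 4, ...) {
  cat("Emotion-intensity evaluation on", x$n, "clips\n")
  cat("  4-class overall accuracy:", round(x$overall_accuracy, digits), "\n")
  cat("  overall MAE:             ", round(x$overall_mae, digits), "\n")
  tab <- rbind(accuracy = x$per_emotion_accuracy,
               mae = x$per_emotion_mae,
               f1 = x$per_emotion_f1)
  print(round(tab, digits))
  invisible(x)
}

# Flatten a report into a named numeric vector (used by the experiment
# harness when assembling tidy records).
metrics_row <- function(rep) {
  c(overall_accuracy = rep$overall_accuracy,
    setNames(rep$per_emotion_accuracy,
             paste0("accuracy_", emotion_names())),
    overall_mae = rep$overall_mae,
    setNames(rep$per_emotion_mae, paste0("mae_", emotion_names())),
    setNames(rep$per_emotion_f1, paste0("f1_", emotion_names())))
}
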