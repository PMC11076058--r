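# Independent scalar-loop oracles for the evaluation metrics. These follow
# the metric definitions cell by cell with no vectorization and no shared
# code with the package implementation.

oracle_round <- function(x) {
  if (x - floor(x) < 0.5) floor(x) else ceiling(x)
}

oracle_clamp <- function(x) min(max(x, 0), 3)

oracle_accuracy <- function(pred, true) {
  n <- nrow(pred)
  hits <- 0
  for (k in seq_len(n)) {
    for (i in 1:6) {
      if (oracle_round(oracle_clamp(pred[k, i])) ==
          oracle_round(oracle_clamp(true[k, i]))) {
        hits <- hits + 1
      }
    }
  }
  hits / (6 * n)
}

oracle_accuracy_emotion <- function(pred, true, j) {
  n <- nrow(pred)
  hits <- 0
  for (k in seq_len(n)) {
    if (oracle_round(oracle_clamp(pred[k, j])) ==
        oracle_round(oracle_clamp(true[k, j]))) {
      hits <- hits + 1
    }
  }
  hits / n
}

oracle_mae <- function(pred, true, j = NULL) {
  cols <- if (is.null(j)) 1:6 else j
  total <- 0
  cells <- 0
  for (k in seq_len(nrow(pred))) {
    for (i in cols) {
      total <- total + abs(pred[k, i] - true[k, i])
      cells <- cells + 1
    }
  }
  total / cells
}

oracle_f1 <- function(pred, true, j) {
  tp <- fp <- fn <- 0
  for (k in seq_len(nrow(pred))) {
    p <- oracle_round(oracle_clamp(pred[k, j])) >= 1
    t <- oracle_round(oracle_clamp(true[k, j])) >= 1
    if (p && t) tp <- tp + 1
    if (p && !t) fp <- fp + 1
    if (!p && t) fn <- fn + 1
  }
  if (tp + fp + fn == 0) return(1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}
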