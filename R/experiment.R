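# Label-efficiency harness: for each label budget n and repeat, draw a
# labeled subset of the training split, fine-tune the (frozen) pretrained
# model and train the baseline from scratch on the same subset, evaluate
# both on the untouched validation split, and aggregate mean/SD over
# repeats.

#' Default label-budget grid
#'
#' 20 to 200 in steps of 15, then 400 to 1200 in steps of 200 -- the grid
#' at which label efficiency is conventionally monitored here.
#' @return Integer vector.
#' @export
default_label_grid <- function() {
  c(seq(20L, 200L, by = 15L), seq(400L, 1200L, by = 200L))
}

#' Sample a labeled subset of the training split
#'
#' Uniform draw without replacement from the labeled clips carrying the
#' `train` split tag; reproducible for a fixed seed.
#'
#' @param ds A split, labeled [ser_dataset()].
#' @param n Subset size; must not exceed the number of labeled training
#'   clips.
#' @param seed Integer seed.
#' @return A list as returned by [labeled_clips()].
#' @export
sample_labeled_subset <- function(ds, n, seed = 1L) {
  stopifnot(inherits(ds, "ser_dataset"))
  pool <- labeled_clips(ds, split = if (is.null(ds$split)) NULL else "train")
  if (n > length(pool$ids)) {
    stop("requested ", n, " labeled clips but only ", length(pool$ids),
         " are available in the training split", call. = FALSE)
  }
  ids <- with_seed(seed, sample(pool$ids, n))
  labeled_clips(ds, ids = ids)
}

# Deterministic per-cell seed: stable arithmetic on (base_seed, n, repeat)
# so adding grid points never perturbs existing cells. Kept below 2^31.
cell_seed <- function(base_seed, n, rep) {
  as.integer((as.double(base_seed) %% 97777L + 1) * 10007 +
               as.double(n) * 131 + as.double(rep) * 7919) %% 2147483647L
}

#' Run the label-efficiency experiment
#'
#' The backbone is pretrained exactly once on the unlabeled training split
#' (unless one is supplied) and shared, frozen, across every cell. For each
#' `(n, repeat)` cell, one labeled subset is drawn and given to both arms:
#' the fine-tuned head on the frozen pretrained backbone (`ssl`) and an
#' identically architected model trained from scratch (`baseline`). Both
#' are evaluated on the validation split, which no training stage ever
#' touches.
#'
#' @param ds A standardized, split, labeled [ser_dataset()].
#' @param label_grid Integer vector of label budgets; see
#'   [default_label_grid()].
#' @param repeats Repeats per budget (independent subset draws); default 3.
#' @param base_seed Base seed from which every cell seed is derived.
#' @param backbone Optional pretrained `ser_backbone` to reuse; when `NULL`
#'   one is pretrained here with `pretrain_epochs`.
#' @param epochs Supervised epochs per arm (default 30).
#' @param pretrain_epochs Pretraining epochs when `backbone` is `NULL`.
#' @param batch_size,learning_rate Optimizer settings for both arms.
#' @param verbose Print per-cell progress?
#' @return An object of class `ser_curve`: list with `records` (one row per
#'   cell and arm, all metrics), `aggregate` (mean and SD over repeats per
#'   budget, arm and metric), the grid, and the backbone used.
#' @export
run_label_curve <- function(ds, label_grid = default_label_grid(),
                            repeats = 3L, base_seed = 1L, backbone = NULL,
                            epochs = 30L, pretrain_epochs = 30L,
                            batch_size = 32L, learning_rate = 1e-3,
                            verbose = FALSE) {
  stopifnot(inherits(ds, "ser_dataset"), repeats >= 1L)
  if (is.null(ds$split)) stop("dataset must be split first", call. = FALSE)
  if (is.null(ds$labels)) stop("dataset carries no labels", call. = FALSE)
  n_train_labeled <- length(labeled_clips(ds, split = "train")$ids)
  if (any(label_grid > n_train_labeled)) {
    stop("label_grid exceeds the ", n_train_labeled,
         " labeled training clips", call. = FALSE)
  }

  if (is.null(backbone)) {
    if (verbose) message("pretraining backbone on the unlabeled training split")
    backbone <- pretrain_backbone(ds, pretrain_epochs = pretrain_epochs,
                                  batch_size = batch_size,
                                  learning_rate = learning_rate,
                                  seed = base_seed, verbose = verbose)
  }
  stopifnot(inherits(backbone, "ser_backbone"))

  val <- labeled_clips(ds, split = "validation")
  records <- list()
  for (n in label_grid) {
    for (r in seq_len(repeats)) {
      seed <- cell_seed(base_seed, n, r)
      subset <- sample_labeled_subset(ds, n, seed = seed)
      if (verbose) message(sprintf("cell n=%d repeat=%d (seed %d)", n, r, seed))

      ssl <- finetune_head(backbone, subset, epochs = epochs,
                           batch_size = batch_size,
                           learning_rate = learning_rate, seed = seed)
      base <- train_baseline(subset, epochs = epochs,
                             batch_size = batch_size,
                             learning_rate = learning_rate, seed = seed)
      for (arm in c("ssl", "baseline")) {
        model <- if (arm == "ssl") ssl else base
        rep_metrics <- evaluate_predictions(predict(model, val$x), val$y)
        records[[length(records) + 1L]] <- data.frame(
          n_labels = n, rep = r, model = arm, seed = seed,
          t(metrics_row(rep_metrics)))
      }
    }
  }
  records <- do.call(rbind, records)
  structure(
    list(records = records, aggregate = aggregate_curve(records),
         label_grid = label_grid, repeats = repeats, base_seed = base_seed,
         backbone = backbone),
    class = "ser_curve"
  )
}

aggregate_curve <- function(records) {
  metric_cols <- setdiff(names(records), c("n_labels", "rep", "model", "seed"))
  out <- list()
  for (m in metric_cols) {
    agg_mean <- stats::aggregate(records[[m]],
                                 by = records[c("n_labels", "model")], mean)
    agg_sd <- stats::aggregate(records[[m]],
                               by = records[c("n_labels", "model")],
                               function(v) if (length(v) > 1) sd(v) else 0)
    out[[m]] <- data.frame(metric = m, n_labels = agg_mean$n_labels,
                           model = agg_mean$model, mean = agg_mean$x,
                           sd = agg_sd$x)
  }
  agg <- do.call(rbind, out)
  rownames(agg) <- NULL
  agg[order(agg$metric, agg$model, agg$n_labels), ]
}

#' @export
print.ser_curve <- function(x, ...) {
  cat("<ser_curve> label-efficiency experiment\n")
  cat("  grid:    ", paste(x$label_grid, collapse = ", "), "\n", sep = "")
  cat("  repeats: ", x$repeats, " (", nrow(x$records), " records)\n",
      sep = "")
  ov <- x$aggregate[x$aggregate$metric == "overall_mae", ]
  cat("  overall MAE (mean over repeats):\n")
  tab <- stats::reshape(ov[, c("n_labels", "model", "mean")],
                        idvar = "n_labels", timevar = "model",
                        direction = "wide")
  names(tab) <- sub("^mean\\.", "", names(tab))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.ser_curve <- function(object, ...) {
  agg <- object$aggregate
  for (m in c("overall_accuracy", "overall_mae")) {
    cat("==", m, "==\n")
    ov <- agg[agg$metric == m, ]
    tab <- stats::reshape(ov[, c("n_labels", "model", "mean", "sd")],
                          idvar = "n_labels", timevar = "model",
                          direction = "wide")
    print(tab, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' Plot a label-efficiency curve
#'
#' Mean over repeats with a shaded +/- one SD band, one line per arm,
#' against the number of labeled clips.
#'
#' @param x A `ser_curve`.
#' @param metric Metric column to plot (default `"overall_mae"`).
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.ser_curve <- function(x, metric = "overall_mae", ...) {
  agg <- x$aggregate[x$aggregate$metric == metric, ]
  if (!nrow(agg)) stop("unknown metric '", metric, "'", call. = FALSE)
  cols <- c(ssl = "#1b7837", baseline = "#762a83")
  ylim <- range(agg$mean - agg$sd, agg$mean + agg$sd)
  graphics::plot(NA, xlim = range(agg$n_labels), ylim = ylim,
                 xlab = "labeled clips", ylab = metric,
                 main = paste("Label efficiency:", metric), ...)
  for (arm in c("ssl", "baseline")) {
    a <- agg[agg$model == arm, ]
    a <- a[order(a$n_labels), ]
    graphics::polygon(c(a$n_labels, rev(a$n_labels)),
                      c(a$mean - a$sd, rev(a$mean + a$sd)),
                      col = grDevices::adjustcolor(cols[[arm]], 0.15),
                      border = NA)
    graphics::lines(a$n_labels, a$mean, col = cols[[arm]], lwd = 2)
    graphics::points(a$n_labels, a$mean, col = cols[[arm]], pch = 19)
  }
  graphics::legend("topright", legend = names(cols), col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Write experiment outputs to disk
#'
#' Writes `records.csv` (one row per cell and arm with every metric),
#' `aggregate.csv` (mean/SD over repeats) and one PNG per reported curve:
#' overall accuracy, overall MAE, and per-emotion accuracy and MAE.
#'
#' @param cr A `ser_curve`.
#' @param outdir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
report_curve <- function(cr, outdir) {
  stopifnot(inherits(cr, "ser_curve"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- c(file.path(outdir, "records.csv"),
             file.path(outdir, "aggregate.csv"))
  write.csv(cr$records, files[1], row.names = FALSE)
  write.csv(cr$aggregate, files[2], row.names = FALSE)
  metrics <- c("overall_accuracy", "overall_mae",
               paste0("accuracy_", emotion_names()),
               paste0("mae_", emotion_names()))
  for (m in metrics) {
    f <- file.path(outdir, paste0("curve_", m, ".png"))
    grDevices::png(f, width = 900, height = 600)
    plot(cr, metric = m)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}
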