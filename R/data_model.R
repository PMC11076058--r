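#' Construct a dataset of feature sequences
#'
#' Bundles per-clip feature matrices, optional emotion-intensity labels and
#' an optional train/validation split tag into the container used throughout
#' the package. Clips are stored in lexicographic clip-id order.
#'
#' @param clips Named list of numeric matrices, one per clip, each of
#'   dimension `T_i` x 74 (timesteps by features). Names are clip ids.
#' @param labels Optional numeric matrix with one row per labeled clip
#'   (rownames are clip ids) and the 6 emotion columns in
#'   [emotion_names()] order; intensities must lie in `[0, 3]`.
#' @param split Optional named character vector mapping clip ids to
#'   `"train"` or `"validation"`.
#' @param standardized Logical; whether the clips are already standardized.
#' @param stats Optional [standardization_stats()] used to standardize.
#' @return An object of class `ser_dataset`.
#' @seealso [load_dataset()], [standardize_dataset()], [split_dataset()]
#' @export
ser_dataset <- function(clips, labels = NULL, split = NULL,
                        standardized = FALSE, stats = NULL) {
  if (!length(clips)) stop("dataset contains no clips", call. = FALSE)
  if (is.null(names(clips)) || anyDuplicated(names(clips))) {
    stop("clips must be uniquely named by clip_id", call. = FALSE)
  }
  clips <- clips[order(names(clips))]
  for (id in names(clips)) {
    m <- clips[[id]]
    if (!is.matrix(m) || !is.numeric(m)) {
      stop("clip '", id, "' is not a numeric matrix", call. = FALSE)
    }
    if (ncol(m) != N_FEATURES) {
      stop("clip '", id, "' has ", ncol(m), " feature columns; expected ",
           N_FEATURES, call. = FALSE)
    }
    if (nrow(m) < 1L) stop("clip '", id, "' has no timesteps", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.matrix(labels)
    if (ncol(labels) != 6L) stop("labels must have 6 columns", call. = FALSE)
    colnames(labels) <- emotion_names()
    if (is.null(rownames(labels))) {
      stop("labels must have clip_id rownames", call. = FALSE)
    }
    missing_ids <- setdiff(rownames(labels), names(clips))
    if (length(missing_ids)) {
      stop("labels refer to unknown clip ids: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    if (anyNA(labels) || any(labels < 0) || any(labels > 3)) {
      stop("emotion intensities must lie in [0, 3]", call. = FALSE)
    }
    labels <- labels[order(rownames(labels)), , drop = FALSE]
  }
  if (!is.null(split)) {
    if (!all(split %in% c("train", "validation"))) {
      stop("split tags must be 'train' or 'validation'", call. = FALSE)
    }
    split <- split[names(clips)]
  }
  structure(
    list(clips = clips, labels = labels, split = split,
         standardized = standardized, stats = stats),
    class = "ser_dataset"
  )
}

#' @export
print.ser_dataset <- function(x, ...) {
  n <- length(x$clips)
  tl <- range(vapply(x$clips, nrow, integer(1)))
  cat("<ser_dataset> ", n, " clips (", tl[1], "-", tl[2], " timesteps x ",
      N_FEATURES, " features)\n", sep = "")
  cat("  labeled:      ", if (is.null(x$labels)) 0L else nrow(x$labels), "\n",
      sep = "")
  if (!is.null(x$split)) {
    cat("  split:        ", sum(x$split == "train"), " train / ",
        sum(x$split == "validation"), " validation\n", sep = "")
  }
  cat("  standardized: ", x$standardized, "\n", sep = "")
  invisible(x)
}

#' @export
summary.ser_dataset <- function(object, ...) {
  lens <- vapply(object$clips, nrow, integer(1))
  out <- list(
    n_clips = length(object$clips),
    n_labeled = if (is.null(object$labels)) 0L else nrow(object$labels),
    length_summary = summary(lens),
    label_means = if (is.null(object$labels)) NULL else colMeans(object$labels),
    standardized = object$standardized
  )
  class(out) <- "summary.ser_dataset"
  out
}

#' @export
print.summary.ser_dataset <- function(x, ...) {
  cat("Dataset of", x$n_clips, "clips,", x$n_labeled, "labeled\n")
  cat("Clip lengths:\n")
  print(x$length_summary)
  if (!is.null(x$label_means)) {
    cat("Mean intensity per emotion:\n")
    print(round(x$label_means, 3))
  }
  invisible(x)
}

#' Read a dataset from its on-disk layout
#'
#' The layout is a directory containing `clips/<clip_id>.csv` (one numeric
#' CSV per clip, `T` rows by 74 named feature columns with a header row) and
#' an optional `labels.csv` with columns `clip_id` plus the six emotions in
#' [emotion_names()] order. Clips without a label row are kept as unlabeled.
#'
#' @param path Directory containing `clips/` and optionally `labels.csv`.
#' @return A [ser_dataset()].
#' @export
load_dataset <- function(path) {
  clip_dir <- file.path(path, "clips")
  if (!dir.exists(clip_dir)) {
    stop("no clips/ directory under '", path, "'", call. = FALSE)
  }
  files <- sort(list.files(clip_dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop("empty dataset: no clip files in '", clip_dir, "'",
                           call. = FALSE)
  clips <- lapply(files, function(f) {
    df <- read.csv(f, check.names = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) {
      stop("non-numeric cells in clip file '", basename(f), "'", call. = FALSE)
    }
    if (ncol(m) != N_FEATURES) {
      stop("clip file '", basename(f), "' has ", ncol(m),
           " feature columns; expected ", N_FEATURES, call. = FALSE)
    }
    m
  })
  names(clips) <- sub("\\.csv$", "", basename(files))

  labels <- NULL
  label_file <- file.path(path, "labels.csv")
  if (file.exists(label_file)) {
    lab <- read.csv(label_file, check.names = FALSE)
    need <- c("clip_id", emotion_names())
    if (!all(need %in% names(lab))) {
      stop("labels.csv is missing columns: ",
           paste(setdiff(need, names(lab)), collapse = ", "), call. = FALSE)
    }
    labels <- as.matrix(lab[, emotion_names(), drop = FALSE])
    if (!is.numeric(labels)) {
      stop("non-numeric cells in labels.csv", call. = FALSE)
    }
    rownames(labels) <- lab$clip_id
  }
  ser_dataset(clips, labels = labels)
}

#' Write a dataset to the on-disk layout read by [load_dataset()]
#'
#' @param ds A [ser_dataset()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "ser_dataset"))
  clip_dir <- file.path(path, "clips")
  dir.create(clip_dir, recursive = TRUE, showWarnings = FALSE)
  feat_names <- sprintf("f%02d", seq_len(N_FEATURES))
  for (id in names(ds$clips)) {
    m <- ds$clips[[id]]
    colnames(m) <- feat_names
    write.csv(m, file.path(clip_dir, paste0(id, ".csv")), row.names = FALSE)
  }
  if (!is.null(ds$labels)) {
    lab <- data.frame(clip_id = rownames(ds$labels), ds$labels,
                      check.names = FALSE)
    write.csv(lab, file.path(path, "labels.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Standardization statistics
#'
#' Per-feature means and standard deviations estimated on the training
#' split. Features whose training-sample standard deviation is zero are
#' flagged and given unit scale, which maps them to exactly zero after
#' centering.
#'
#' @param mean,sd Numeric vectors of length 74.
#' @param zero_variance Logical vector flagging degenerate features.
#' @return An object of class `ser_standardization`.
#' @export
standardization_stats <- function(mean, sd, zero_variance = sd == 0) {
  stopifnot(length(mean) == N_FEATURES, length(sd) == N_FEATURES)
  sd[zero_variance] <- 1
  if (any(sd <= 0)) stop("standard deviations must be positive", call. = FALSE)
  structure(list(mean = mean, sd = sd, zero_variance = zero_variance),
            class = "ser_standardization")
}

#' Standardize a dataset with training-split statistics
#'
#' Per-feature z-scoring: statistics are fit on the training clips only
#' (pooling all their timesteps) and applied to every clip. Non-finite raw
#' entries are replaced by zero after the transform, so that all finite
#' standardized values stay in a bounded range well clear of the mask
#' sentinel of -30.
#'
#' @param ds A [ser_dataset()]. If it carries no split, all clips are
#'   treated as training clips for fitting.
#' @param stats Optional precomputed [standardization_stats()]; when given,
#'   no fitting is done (used to transform held-out data consistently).
#' @return The standardized dataset, with the statistics stored in
#'   `$stats`.
#' @export
standardize_dataset <- function(ds, stats = NULL) {
  stopifnot(inherits(ds, "ser_dataset"))
  if (is.null(stats)) {
    train_ids <- if (is.null(ds$split)) names(ds$clips) else
      names(ds$split)[ds$split == "train"]
    if (!length(train_ids)) {
      stop("training split is empty; cannot fit standardization", call. = FALSE)
    }
    pooled <- do.call(rbind, ds$clips[train_ids])
    pooled[!is.finite(pooled)] <- NA
    mu <- colMeans(pooled, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    sdv <- apply(pooled, 2, sd, na.rm = TRUE)
    sdv[is.na(sdv)] <- 0
    stats <- standardization_stats(mu, sdv)
  }
  ds$clips <- lapply(ds$clips, function(m) {
    z <- sweep(sweep(m, 2, stats$mean, "-"), 2, stats$sd, "/")
    z[, stats$zero_variance] <- 0
    z[!is.finite(z)] <- 0
    z
  })
  ds$standardized <- TRUE
  ds$stats <- stats
  ds
}

#' Invert standardization
#'
#' Reconstructs raw feature values from a standardized matrix given the
#' statistics used to standardize it. Zero-variance features recover their
#' (constant) training mean.
#'
#' @param m Standardized numeric matrix (`T` x 74).
#' @param stats A [standardization_stats()].
#' @return Matrix of raw-scale values.
#' @export
unstandardize_matrix <- function(m, stats) {
  stopifnot(inherits(stats, "ser_standardization"))
  sweep(sweep(m, 2, stats$sd, "*"), 2, stats$mean, "+")
}

#' Random clip-level train/validation split
#'
#' @param ds A [ser_dataset()].
#' @param fraction Training fraction in `(0, 1)`; default 0.8 for the
#'   conventional 80/20 split.
#' @param seed Integer seed; the same seed always yields the same split.
#' @return The dataset with `$split` assigned.
#' @export
split_dataset <- function(ds, fraction = 0.8, seed = 1L) {
  stopifnot(inherits(ds, "ser_dataset"))
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  ids <- names(ds$clips)
  n <- length(ids)
  if (n < 2L) stop("need at least 2 clips to split", call. = FALSE)
  n_train <- max(1L, min(n - 1L, round(fraction * n)))
  train_ids <- with_seed(seed, sample(ids, n_train))
  split <- setNames(rep("validation", n), ids)
  split[train_ids] <- "train"
  ds$split <- split
  ds
}

#' Extract labeled clips as (sequence, label) pairs
#'
#' @param ds A [ser_dataset()].
#' @param ids Clip ids to extract; defaults to all labeled clips (optionally
#'   restricted to a split).
#' @param split Optional split tag to restrict to (`"train"` or
#'   `"validation"`).
#' @return List with elements `x` (list of matrices), `y` (matrix n x 6) and
#'   `ids`.
#' @export
labeled_clips <- function(ds, ids = NULL, split = NULL) {
  stopifnot(inherits(ds, "ser_dataset"))
  if (is.null(ds$labels)) stop("dataset has no labels", call. = FALSE)
  pool <- rownames(ds$labels)
  if (!is.null(split)) {
    if (is.null(ds$split)) stop("dataset has no split tags", call. = FALSE)
    pool <- intersect(pool, names(ds$split)[ds$split == split])
  }
  if (is.null(ids)) ids <- pool else {
    bad <- setdiff(ids, pool)
    if (length(bad)) {
      stop("ids not in the labeled pool: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  ids <- sort(ids)
  list(x = ds$clips[ids], y = ds$labels[ids, , drop = FALSE], ids = ids)
}

# Clips belonging to one split, as a plain list of matrices.
split_clips <- function(ds, split = "train") {
  if (is.null(ds$split)) return(ds$clips)
  ds$clips[names(ds$split)[ds$split == split]]
}
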