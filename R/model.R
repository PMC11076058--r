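# Backbone architecture: two stacked GRU layers (256 units each) returning
# per-timestep outputs, followed by a 74-unit per-timestep dense projection.
# The emotion head is a single 6-unit dense layer applied to the temporal
# mean of the projection. Gate order inside the stacked 3h rows is r, z, n.

HIDDEN_UNITS <- 256L

# Uniform fan-in initialization (bound 1/sqrt(fan_in)), drawn from the
# caller-controlled R RNG stream.
runif_mat <- function(nr, nc, bound) {
  matrix(runif(nr * nc, -bound, bound), nr, nc)
}

init_backbone_params <- function(input_dim = N_FEATURES,
                                 hidden = HIDDEN_UNITS) {
  k <- 1 / sqrt(hidden)
  list(
    W1 = runif_mat(3L * hidden, input_dim, k),
    U1 = runif_mat(3L * hidden, hidden, k),
    b1i = runif(3L * hidden, -k, k),
    b1h = runif(3L * hidden, -k, k),
    W2 = runif_mat(3L * hidden, hidden, k),
    U2 = runif_mat(3L * hidden, hidden, k),
    b2i = runif(3L * hidden, -k, k),
    b2h = runif(3L * hidden, -k, k),
    Wd = runif_mat(input_dim, hidden, k),
    bd = runif(input_dim, -k, k)
  )
}

init_head_params <- function(input_dim = N_FEATURES, n_out = 6L) {
  k <- 1 / sqrt(input_dim)
  list(Wh = runif_mat(n_out, input_dim, k), bh = runif(n_out, -k, k))
}

count_params <- function(p) sum(vapply(p, length, numeric(1)))

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    # bias gradients arrive from the kernels as n x 1 matrices
    if (is.null(dim(params[[nm]]))) g <- as.vector(g)
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- Backbone object --------------------------------------------------

new_backbone <- function(params, history = NULL, config = list()) {
  structure(
    list(params = params, history = history, config = config,
         n_params = count_params(params)),
    class = "ser_backbone"
  )
}

#' Create an untrained backbone
#'
#' Randomly initialized two-layer recurrent encoder with a 74-unit
#' per-timestep dense projection, as used both for pretraining and as the
#' baseline's trunk. Initialization is a uniform fan-in scheme seeded from
#' `seed`.
#'
#' @param seed Integer seed for the initialization.
#' @return An object of class `ser_backbone`.
#' @export
random_backbone <- function(seed = 1L) {
  params <- with_seed(seed, init_backbone_params())
  new_backbone(params, config = list(seed = seed, trained = FALSE))
}

#' @export
print.ser_backbone <- function(x, ...) {
  cat("<ser_backbone> 2 x ", HIDDEN_UNITS, "-unit GRU + ", N_FEATURES,
      "-unit dense projection (", format(x$n_params, big.mark = ","),
      " parameters)\n", sep = "")
  if (!is.null(x$history)) {
    h <- x$history
    cat("  pretrained ", length(h), " epochs; reconstruction MSE ",
        signif(h[1], 4), " -> ", signif(h[length(h)], 4), "\n", sep = "")
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}

# Run clips through the backbone (and head, if present) in fixed-size
# chunks so padding overhead stays bounded.
model_forward <- function(params, clips, return_sequences = FALSE,
                          chunk_size = 64L) {
  stopifnot(length(clips) >= 1L)
  idx <- split(seq_along(clips), ceiling(seq_along(clips) / chunk_size))
  pooled <- NULL
  preds <- NULL
  seqs <- list()
  for (ii in idx) {
    out <- cpp_forward(params, clips[ii], return_sequences)
    pooled <- rbind(pooled, out$pooled)
    if (!is.null(out$predictions)) preds <- rbind(preds, out$predictions)
    if (return_sequences) seqs <- c(seqs, out$sequences)
  }
  rownames(pooled) <- names(clips)
  if (!is.null(preds)) {
    rownames(preds) <- names(clips)
    colnames(preds) <- emotion_names()
  }
  if (return_sequences) names(seqs) <- names(clips)
  list(pooled = pooled, predictions = preds, sequences = seqs)
}

#' Predict with a backbone: reconstructions or pooled features
#'
#' @param object A `ser_backbone`.
#' @param newdata A [ser_dataset()], a list of clip matrices, or a single
#'   `T` x 74 matrix.
#' @param type `"reconstruction"` for per-timestep `T` x 74 outputs,
#'   `"features"` for the temporal-mean pooled 74-dim summary per clip.
#' @param ... Unused.
#' @return For `"reconstruction"`, a list of matrices (or a single matrix if
#'   `newdata` was one); for `"features"`, an `n` x 74 matrix.
#' @export
predict.ser_backbone <- function(object, newdata,
                                 type = c("reconstruction", "features"),
                                 ...) {
  type <- match.arg(type)
  single <- is.matrix(newdata)
  clips <- as_clip_list(newdata)
  out <- model_forward(object$params, clips,
                       return_sequences = type == "reconstruction")
  if (type == "features") return(out$pooled)
  if (single) out$sequences[[1]] else out$sequences
}

as_clip_list <- function(newdata) {
  if (inherits(newdata, "ser_dataset")) return(newdata$clips)
  if (is.matrix(newdata)) return(list(clip = newdata))
  stopifnot(is.list(newdata))
  newdata
}

# ---- Emotion model ----------------------------------------------------

#' Assemble an emotion model from a backbone and a fresh head
#'
#' Attaches a randomly initialized 6-unit dense head to a backbone. When a
#' (typically pretrained) backbone is supplied the model starts frozen:
#' training updates only the head's 450 parameters. When `backbone` is
#' `NULL` a randomly initialized backbone is created and the model starts
#' unfrozen, which is the baseline configuration.
#'
#' @param backbone A `ser_backbone`, or `NULL` for a random one.
#' @param seed Seed for head (and, if needed, backbone) initialization.
#' @return An object of class `ser_model`.
#' @seealso [freeze_backbone()], [train_emotion_model()]
#' @export
emotion_model <- function(backbone = NULL, seed = 1L) {
  frozen <- !is.null(backbone)
  if (is.null(backbone)) backbone <- random_backbone(seed)
  stopifnot(inherits(backbone, "ser_backbone"))
  head <- with_seed(seed + 1L, init_head_params())
  structure(
    list(backbone = backbone, head = head, frozen = frozen,
         pretrained = isTRUE(backbone$config$trained), history = NULL),
    class = "ser_model"
  )
}

#' Freeze or unfreeze a model's backbone
#'
#' A frozen backbone receives no parameter updates during
#' [train_emotion_model()]; only the 6-unit head (450 parameters) is
#' trainable. Unfreezing restores gradient flow to every parameter.
#'
#' @param model A `ser_model`.
#' @return The model with its freeze flag set.
#' @export
freeze_backbone <- function(model) {
  stopifnot(inherits(model, "ser_model"))
  model$frozen <- TRUE
  model
}

#' @rdname freeze_backbone
#' @export
unfreeze_backbone <- function(model) {
  stopifnot(inherits(model, "ser_model"))
  model$frozen <- FALSE
  model
}

#' Number of trainable parameters of a model
#'
#' @param model A `ser_model`.
#' @return Integer count; 450 when the backbone is frozen.
#' @export
n_trainable <- function(model) {
  stopifnot(inherits(model, "ser_model"))
  n <- count_params(model$head)
  if (!model$frozen) n <- n + count_params(model$backbone$params)
  as.integer(n)
}

#' @export
print.ser_model <- function(x, ...) {
  cat("<ser_model> backbone (", if (x$pretrained) "pretrained" else
    "random init", ", ", if (x$frozen) "frozen" else "trainable",
    ") + 6-unit emotion head\n", sep = "")
  cat("  trainable parameters: ", format(n_trainable(x), big.mark = ","),
      "\n", sep = "")
  if (!is.null(x$history)) {
    h <- x$history
    cat("  trained ", length(h), " epochs; MSE ", signif(h[1], 4), " -> ",
        signif(h[length(h)], 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.ser_model <- function(object, ...) {
  cat("Emotion-intensity regression model\n")
  print(object)
  cat("  backbone parameters: ",
      format(count_params(object$backbone$params), big.mark = ","), "\n",
      sep = "")
  cat("  head parameters:     ", count_params(object$head), "\n", sep = "")
  invisible(object)
}

#' @export
coef.ser_model <- function(object, ...) {
  w <- cbind(object$head$bh, object$head$Wh)
  rownames(w) <- emotion_names()
  colnames(w) <- c("(bias)", sprintf("f%02d", seq_len(N_FEATURES)))
  w
}

#' Predict emotion intensities
#'
#' Runs clips through the backbone, averages the per-timestep 74-dim output
#' over (valid) timesteps and applies the 6-unit head. No output activation
#' is applied; predictions are unconstrained reals on the intensity scale.
#'
#' @param object A `ser_model`.
#' @param newdata A [ser_dataset()], list of clip matrices, or single
#'   matrix.
#' @param ... Unused.
#' @return An `n` x 6 matrix of predicted intensities.
#' @export
predict.ser_model <- function(object, newdata, ...) {
  clips <- as_clip_list(newdata)
  params <- c(object$backbone$params, object$head)
  model_forward(params, clips)$predictions
}

# ---- Checkpoints ------------------------------------------------------

#' Save and restore model checkpoints
#'
#' Checkpoints include all parameters, any attached standardization
#' statistics and a structural fingerprint; loading verifies the
#' fingerprint so a checkpoint cannot be silently applied to a different
#' architecture. Round-tripping reproduces predictions bitwise.
#'
#' @param object A `ser_backbone` or `ser_model`.
#' @param path File path for the checkpoint.
#' @param stats Optional [standardization_stats()] to store alongside.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the restored object with any stored stats in
#'   `attr(, "stats")`.
#' @export
save_checkpoint <- function(object, path, stats = NULL) {
  stopifnot(inherits(object, c("ser_backbone", "ser_model")))
  fp <- checkpoint_fingerprint(object)
  saveRDS(list(object = object, stats = stats, fingerprint = fp,
               package_version = as.character(utils::packageVersion("sslser"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$fingerprint, checkpoint_fingerprint(ck$object))) {
    stop("checkpoint fingerprint mismatch: file is corrupt or was written ",
         "for a different architecture", call. = FALSE)
  }
  obj <- ck$object
  attr(obj, "stats") <- ck$stats
  obj
}

checkpoint_fingerprint <- function(object) {
  params <- if (inherits(object, "ser_model")) {
    c(object$backbone$params, object$head)
  } else {
    object$params
  }
  list(class = class(object),
       shapes = lapply(params, function(p) as.integer(dim(p) %||% length(p))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
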