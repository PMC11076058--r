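# Training loops: masked-reconstruction pretraining of the backbone, and
# supervised training of the emotion model (head-only when frozen, all
# parameters for the baseline). Optimizer is Adam (lr 0.001) with MSE loss
# and a 30-epoch default budget throughout. All randomness (initialization,
# batch order, mask draws) derives from the function's seed argument and
# the caller's RNG state is left untouched.

#' Pretrain the backbone by masked-timestep reconstruction
#'
#' The self-supervised pretext task: every epoch, each training clip gets a
#' freshly drawn contiguous mask (see [mask_clip()]) and the backbone is
#' trained to reproduce the original clip from the masked input by
#' minimizing mean squared error. Labels are never read -- the function only
#' sees feature matrices.
#'
#' @param ds A standardized [ser_dataset()]; only its training-split clips
#'   are used (all clips when the dataset carries no split).
#' @param pretrain_epochs Number of passes over the unlabeled clips.
#' @param batch_size Clips per optimizer step; variable-length clips are
#'   zero-padded per batch and padded rows are excluded from the loss.
#' @param learning_rate Adam learning rate.
#' @param mask_len,sentinel Masking parameters, see [mask_clip()].
#' @param loss_on `"all"` computes the reconstruction loss over every
#'   (valid) timestep of the clip, masked or not; `"masked"` restricts it to
#'   the masked block.
#' @param seed Integer seed controlling initialization, batch order and
#'   mask draws.
#' @param verbose Print per-epoch losses?
#' @return A trained `ser_backbone`; `$history` holds the per-epoch mean
#'   training loss.
#' @export
pretrain_backbone <- function(ds, pretrain_epochs = 30L, batch_size = 32L,
                              learning_rate = 1e-3, mask_len = 30L,
                              sentinel = MASK_SENTINEL, loss_on = c("all", "masked"),
                              seed = 1L, verbose = FALSE) {
  stopifnot(inherits(ds, "ser_dataset"), pretrain_epochs >= 1,
            learning_rate > 0)
  loss_on <- match.arg(loss_on)
  clips <- split_clips(ds, "train")
  if (!length(clips)) stop("training split has no clips", call. = FALSE)
  if (!ds$standardized) {
    warning("pretraining on non-standardized data; the mask sentinel may ",
            "not be out of range", call. = FALSE)
  }

  n <- length(clips)
  history <- numeric(pretrain_epochs)
  params <- NULL
  with_seed(seed, {
    params <- init_backbone_params()
    state <- adam_init(params)
    for (epoch in seq_len(pretrain_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        ids <- batches[[bi]]
        pairs <- lapply(clips[ids], mask_clip, mask_len = mask_len,
                        sentinel = sentinel)
        res <- cpp_recon_grad(
          params,
          lapply(pairs, `[[`, "input"),
          lapply(pairs, `[[`, "target"),
          loss_on == "masked",
          vapply(pairs, `[[`, integer(1), "mask_start"),
          vapply(pairs, `[[`, integer(1), "mask_len"))
        st <- adam_step(params, res$grads, state, lr = learning_rate)
        params <- st$params
        state <- st$state
        losses[bi] <- res$loss
      }
      history[epoch] <- mean(losses)
      if (verbose) {
        message(sprintf("pretrain epoch %d/%d: loss %.5f", epoch,
                        pretrain_epochs, history[epoch]))
      }
    }
  })
  new_backbone(params, history = history,
               config = list(seed = seed, trained = TRUE,
                             pretrain_epochs = pretrain_epochs,
                             mask_len = mask_len, sentinel = sentinel,
                             loss_on = loss_on))
}

#' Train an emotion model on labeled clips
#'
#' Minimizes mean squared error between the model's 6-dim predictions and
#' the emotion-intensity labels with Adam. When the model's backbone is
#' frozen (the fine-tuning protocol) only the 450 head parameters are
#' updated and the backbone features are computed once up front; otherwise
#' every parameter trains jointly (the baseline protocol).
#'
#' @param model A `ser_model` from [emotion_model()].
#' @param labeled Either a [ser_dataset()] (its labeled training clips are
#'   used) or a list as returned by [labeled_clips()].
#' @param epochs,batch_size,learning_rate Optimizer settings; defaults 30,
#'   32 and 0.001.
#' @param seed Seed controlling batch order.
#' @param verbose Print per-epoch losses?
#' @return The trained `ser_model` with `$history` filled in.
#' @export
train_emotion_model <- function(model, labeled, epochs = 30L,
                                batch_size = 32L, learning_rate = 1e-3,
                                seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "ser_model"), epochs >= 1, learning_rate > 0)
  lab <- as_labeled(labeled)
  n <- length(lab$x)
  if (!n) stop("labeled set is empty", call. = FALSE)

  if (model$frozen) {
    feats <- model_forward(model$backbone$params, lab$x)$pooled
    res <- with_seed(seed, train_head(model$head, feats, lab$y, epochs,
                                      batch_size, learning_rate, verbose))
    model$head <- res$head
    model$history <- res$history
    return(model)
  }

  params <- c(model$backbone$params, model$head)
  history <- numeric(epochs)
  with_seed(seed, {
    state <- adam_init(params)
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        ids <- batches[[bi]]
        res <- cpp_emotion_grad(params, unname(lab$x[ids]),
                                t(lab$y[ids, , drop = FALSE]))
        st <- adam_step(params, res$grads, state, lr = learning_rate)
        params <- st$params
        state <- st$state
        losses[bi] <- res$loss
      }
      history[epoch] <- mean(losses)
      if (verbose) {
        message(sprintf("train epoch %d/%d: loss %.5f", epoch, epochs,
                        history[epoch]))
      }
    }
  })
  backbone_names <- names(model$backbone$params)
  model$backbone$params <- params[backbone_names]
  model$head <- params[c("Wh", "bh")]
  model$history <- history
  model
}

# Head-only optimization on precomputed pooled features (frozen backbone).
# Runs under the caller's seeded RNG.
train_head <- function(head, feats, y, epochs, batch_size, learning_rate,
                       verbose = FALSE) {
  n <- nrow(feats)
  state <- adam_init(head)
  history <- numeric(epochs)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      ids <- batches[[bi]]
      Xb <- feats[ids, , drop = FALSE]
      Yb <- y[ids, , drop = FALSE]
      pred <- Xb %*% t(head$Wh)
      pred <- sweep(pred, 2, head$bh, "+")
      diff <- pred - Yb
      nc <- length(diff)
      losses[bi] <- sum(diff^2) / nc
      dpred <- 2 * diff / nc
      grads <- list(Wh = t(dpred) %*% Xb, bh = colSums(dpred))
      st <- adam_step(head, grads, state, lr = learning_rate)
      head <- st$params
      state <- st$state
    }
    history[epoch] <- mean(losses)
    if (verbose) {
      message(sprintf("head epoch %d/%d: loss %.5f", epoch, epochs,
                      history[epoch]))
    }
  }
  list(head = head, history = history)
}

#' Fine-tune a 6-unit head on a frozen pretrained backbone
#'
#' Convenience wrapper: attaches a fresh head to `backbone`, freezes the
#' backbone and trains the head on the labeled clips. The backbone's
#' parameters are bitwise unchanged afterwards.
#'
#' @param backbone A (pretrained) `ser_backbone`.
#' @param labeled Labeled clips, as for [train_emotion_model()].
#' @param ... Passed to [train_emotion_model()].
#' @param seed Seed for head initialization and batch order.
#' @return A trained, frozen `ser_model`.
#' @export
finetune_head <- function(backbone, labeled, ..., seed = 1L) {
  model <- emotion_model(backbone, seed = seed)
  train_emotion_model(model, labeled, ..., seed = seed)
}

#' Train the no-pretraining baseline
#'
#' Identical architecture to the pretrained-plus-head model, with every
#' parameter trained from random initialization on the labeled clips only.
#'
#' @param labeled Labeled clips, as for [train_emotion_model()].
#' @param ... Passed to [train_emotion_model()].
#' @param seed Seed for initialization and batch order.
#' @return A trained, unfrozen `ser_model`.
#' @export
train_baseline <- function(labeled, ..., seed = 1L) {
  model <- unfreeze_backbone(emotion_model(NULL, seed = seed))
  train_emotion_model(model, labeled, ..., seed = seed)
}

#' Masked-reconstruction error on held-out clips
#'
#' Draws one seeded mask per clip and returns the mean squared error of the
#' backbone's reconstruction, on the same cells the pretraining loss would
#' use. Comparing a pretrained backbone against [random_backbone()] on the
#' same clips and seed quantifies how much the pretext task was learned.
#'
#' @param backbone A `ser_backbone`.
#' @param clips A [ser_dataset()] (validation split if tagged) or list of
#'   standardized clip matrices.
#' @param mask_len,sentinel,loss_on As in [pretrain_backbone()].
#' @param seed Seed for the mask draws.
#' @param chunk_size Clips per forward pass.
#' @return Mean squared reconstruction error (scalar).
#' @export
reconstruction_error <- function(backbone, clips, mask_len = 30L,
                                 sentinel = MASK_SENTINEL,
                                 loss_on = c("all", "masked"), seed = 1L,
                                 chunk_size = 64L) {
  loss_on <- match.arg(loss_on)
  if (inherits(clips, "ser_dataset")) {
    clips <- if (is.null(clips$split)) clips$clips else
      split_clips(clips, "validation")
  }
  stopifnot(length(clips) >= 1L)
  pairs <- with_seed(seed, lapply(clips, mask_clip, mask_len = mask_len,
                                  sentinel = sentinel))
  idx <- split(seq_along(pairs), ceiling(seq_along(pairs) / chunk_size))
  sse <- 0
  ncell <- 0
  for (ii in idx) {
    pp <- pairs[ii]
    cells <- sum(vapply(pp, function(p) {
      if (loss_on == "masked") p$mask_len else nrow(p$target)
    }, numeric(1))) * N_FEATURES
    loss <- cpp_recon_loss(
      backbone$params,
      lapply(pp, `[[`, "input"),
      lapply(pp, `[[`, "target"),
      loss_on == "masked",
      vapply(pp, `[[`, integer(1), "mask_start"),
      vapply(pp, `[[`, integer(1), "mask_len"))
    sse <- sse + loss * cells
    ncell <- ncell + cells
  }
  sse / ncell
}

as_labeled <- function(labeled) {
  if (inherits(labeled, "ser_dataset")) {
    split <- if (is.null(labeled$split)) NULL else "train"
    return(labeled_clips(labeled, split = split))
  }
  stopifnot(is.list(labeled), !is.null(labeled$x), !is.null(labeled$y))
  labeled
}

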