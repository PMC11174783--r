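#' Train the classifier on a manifest
#'
#' Mini-batch Adam training with the hybrid focal loss. Images are loaded
#' once, augmented per epoch (random resized crop + horizontal flip), and the
#' test manifest — when given — is evaluated after every epoch; the state with
#' the best test accuracy is kept.
#'
#' @param train_manifest Manifest tibble (`path`, `class_id`).
#' @param test_manifest Optional test manifest for per-epoch evaluation.
#' @param model An [nn_amwnet()] module, or `NULL` to build one from
#'   `model_cfg`.
#' @param model_cfg An [amwnet_config()] used when `model` is `NULL`.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param loss_cfg A [wfr_config()]; `class_weights = NULL` derives them from
#'   the training-set class proportions.
#' @param aug_cfg An [augmentation_config()]; defaults to a crop size equal to
#'   `model_cfg$input_size`.
#' @param seed RNG seed covering initialisation, shuffling and augmentation.
#' @param resume A previous `amwnet_fit` to continue from (epoch numbering and
#'   optimizer state carry on).
#' @param verbose Print one line per epoch.
#' @return An object of class `amwnet_fit`: the trained `model`, per-epoch
#'   `history` tibble, `best` (state dict + accuracy) and the configs.
#' @export
train_amwnet <- function(train_manifest, test_manifest = NULL, model = NULL,
                         model_cfg = amwnet_config(), epochs = 15L,
                         batch_size = 32L, learning_rate = 1e-3,
                         loss_cfg = wfr_config(), aug_cfg = NULL,
                         seed = NULL, resume = NULL, verbose = TRUE) {
  if (!is.null(seed)) withr::local_seed(seed)
  if (!is.null(resume)) {
    model <- resume$model
    model_cfg <- resume$model_cfg
  }
  if (is.null(model)) model <- nn_amwnet(model_cfg)
  cfg <- model$meta$cfg %||% model_cfg
  if (is.null(aug_cfg)) {
    # evaluation uses the conventional resize-then-centre-crop with an 8/7
    # zoom (256 -> 224 at full scale), matching the scale statistics of the
    # random resized training crops
    aug_cfg <- augmentation_config(crop_size = cfg$input_size,
                                   resize_side = as.integer(round(cfg$input_size * 8 / 7)))
  }
  if (is.null(loss_cfg$class_weights)) {
    prop <- as.numeric(table(factor(train_manifest$class_id,
                                    levels = 0:(cfg$num_classes - 1))))
    loss_cfg$class_weights <- class_weights_from_proportions(prop / sum(prop))
  }

  imgs <- lapply(train_manifest$path, load_image)
  labels <- train_manifest$class_id
  n <- length(imgs)
  params <- nn_parameters(model)
  opt <- if (!is.null(resume)) resume$optimizer else adam_state(params)
  hist_rows <- if (!is.null(resume)) resume$history else NULL
  epoch0 <- if (!is.null(resume)) max(resume$history$epoch) else 0L
  best <- if (!is.null(resume)) resume$best else list(accuracy = -Inf,
                                                      state = NULL)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    tot_loss <- 0
    tot_correct <- 0
    for (b0 in seq(1, n, by = batch_size)) {
      idx <- ord[b0:min(b0 + batch_size - 1, n)]
      B <- length(idx)
      xb <- array(0, c(B, 3L, aug_cfg$crop_size, aug_cfg$crop_size))
      for (j in seq_len(B)) xb[j, , , ] <- augment_train(imgs[[idx[j]]], aug_cfg)
      yb <- labels[idx]
      tp <- ad_tape()
      logits <- model$forward(ad_const(tp, xb), training = TRUE)
      lw <- ad_wfr_loss(logits, yb, loss_cfg)
      loss_val <- lw$loss$value
      if (loss_cfg$l2_mode == "weights" && loss_cfg$beta > 0) {
        loss_val <- loss_val +
          l2_penalty(lapply(params, function(p) p$value), loss_cfg$beta)
      }
      ad_backward(lw$loss)
      if (loss_cfg$l2_mode == "weights" && loss_cfg$beta > 0) {
        for (p in params) {
          g <- 2 * loss_cfg$beta * p$value
          p$grad <- if (is.null(p$grad)) g else p$grad + g
        }
      }
      adam_step(opt, learning_rate)
      zero_grads(params)
      tot_loss <- tot_loss + loss_val * B
      tot_correct <- tot_correct + sum(max.col(lw$probs) - 1L == yb)
    }
    train_loss <- tot_loss / n
    train_acc <- tot_correct / n
    test_acc <- NA_real_
    if (!is.null(test_manifest)) {
      rpt <- evaluate_amwnet(model, test_manifest, aug_cfg = aug_cfg,
                             batch_size = batch_size)
      test_acc <- rpt$macro$accuracy
      if (test_acc >= best$accuracy) {
        best <- list(accuracy = test_acc, state = nn_state_dict(model),
                     epoch = epoch0 + ep)
      }
    }
    hist_rows <- dplyr::bind_rows(
      hist_rows,
      tibble::tibble(epoch = epoch0 + ep, train_loss = train_loss,
                     train_accuracy = train_acc, test_accuracy = test_acc))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  train acc %.3f  test acc %s",
                      epoch0 + ep, train_loss, train_acc,
                      ifelse(is.na(test_acc), "-", sprintf("%.3f", test_acc))))
    }
  }
  structure(list(model = model, history = hist_rows, best = best,
                 optimizer = opt, model_cfg = cfg, loss_cfg = loss_cfg,
                 aug_cfg = aug_cfg),
            class = "amwnet_fit")
}

#' Predict class probabilities for a manifest
#'
#' @param model Trained module.
#' @param manifest Manifest tibble with `path`.
#' @param aug_cfg Evaluation preprocessing config.
#' @param batch_size Forward batch size.
#' @return Tibble with `path`, `predicted` class id and per-class probability
#'   columns `p0..p{K-1}`.
#' @export
predict_amwnet <- function(model, manifest, aug_cfg = NULL, batch_size = 32L) {
  cfg <- model$meta$cfg
  if (is.null(aug_cfg)) {
    aug_cfg <- augmentation_config(
      crop_size = cfg$input_size,
      resize_side = as.integer(round(cfg$input_size * 8 / 7)))
  }
  n <- nrow(manifest)
  probs <- matrix(0, n, cfg$num_classes)
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, n)
    xb <- array(0, c(length(idx), 3L, aug_cfg$crop_size, aug_cfg$crop_size))
    for (j in seq_along(idx)) {
      xb[j, , , ] <- preprocess_eval(load_image(manifest$path[idx[j]]), aug_cfg)
    }
    logits <- amwnet_forward(xb, model, training = FALSE)
    probs[idx, ] <- softmax_rows_value(logits)
  }
  out <- tibble::tibble(path = manifest$path,
                        predicted = max.col(probs) - 1L)
  colnames(probs) <- paste0("p", 0:(cfg$num_classes - 1))
  dplyr::bind_cols(out, tibble::as_tibble(probs))
}

#' Evaluate a model on a manifest
#'
#' @inheritParams predict_amwnet
#' @return A [classification_report()].
#' @export
evaluate_amwnet <- function(model, manifest, aug_cfg = NULL,
                            batch_size = 32L) {
  pred <- predict_amwnet(model, manifest, aug_cfg, batch_size)
  classification_report(manifest$class_id, pred$predicted,
                        model$meta$cfg$num_classes)
}

#' Save / load checkpoints
#'
#' A checkpoint stores the network configuration and the full state (weights
#' plus batch-norm running statistics); loading rebuilds the module.
#'
#' @param model A module or `amwnet_fit`.
#' @param path File path.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "amwnet_fit")) model <- model$model
  saveRDS(list(cfg = model$meta$cfg, state = nn_state_dict(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the rebuilt module.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- nn_amwnet(ck$cfg)
  nn_load_state_dict(model, ck$state)
  model
}

#' @export
print.amwnet_fit <- function(x, ...) {
  cat("amwnet fit:", nrow(x$history), "epochs; best test accuracy",
      format(x$best$accuracy, digits = 4), "\n")
  invisible(x)
}
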