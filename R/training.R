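#' Training configuration
#'
#' Adam optimisation of the multivariate loss with early stopping on the
#' validation loss. Defaults follow the reference recipe: learning rate
#' 1e-4, beta1 0.9, beta2 0.999, decay 1e-4, batch size 8, at most 60
#' epochs, patience 10.
#'
#' @param lr Learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param decay Decay constant; with `decay_mode = "lr"` (default) it is the
#'   legacy per-update learning-rate decay `lr / (1 + decay * step)`, with
#'   `"l2"` it is an L2 weight penalty added to the gradient.
#' @param decay_mode `"lr"` or `"l2"`.
#' @param batch_size Mini-batch size (>= 1).
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience in epochs (must be
#'   `< max_epochs`): training stops once the validation loss has failed to
#'   improve for this many consecutive epochs.
#' @param seed Integer seed controlling data order (weight init is seeded by
#'   the model config).
#' @param loss A [lossConfig()].
#' @return A `adffnet_train_config` list.
#' @export
trainConfig <- function(lr = 1e-4, beta1 = 0.9, beta2 = 0.999, decay = 1e-4,
                        decay_mode = c("lr", "l2"), batch_size = 8L,
                        max_epochs = 60L, patience = 10L, seed = 1L,
                        loss = lossConfig()) {
  decay_mode <- match.arg(decay_mode)
  stopifnot(batch_size >= 1, patience < max_epochs, patience >= 1)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, decay = decay,
                 decay_mode = decay_mode, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 loss = loss),
            class = "adffnet_train_config")
}

#' Early-stopping epoch for a validation-loss trace
#'
#' Returns the epoch after which training stops: the first epoch at which
#' the validation loss has not strictly improved for `patience` consecutive
#' epochs, or `length(val_losses)` if the trace never exhausts the patience.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param patience Positive integer.
#' @return Integer epoch index.
#' @examples
#' stoppingEpoch(rep(1, 60), patience = 10)   # flat: stops at epoch 11
#' @export
stoppingEpoch <- function(val_losses, patience) {
  best <- Inf
  bad <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) return(e)
    }
  }
  length(val_losses)
}

samplesToArrays <- function(samples) {
  n <- length(samples)
  d <- dim(samples[[1]]$image)
  x <- array(0, c(d[1], d[2], 3L, n))
  t <- array(0, c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- samples[[i]]$image
    t[, , 1, i] <- samples[[i]]$mask
  }
  list(x = x, t = t)
}

snapshotParams <- function(model) {
  list(params = lapply(model$params, function(p) p$val),
       bn_mean = model$layers$dff$bn$state$running_mean,
       bn_var = model$layers$dff$bn$state$running_var)
}

restoreParams <- function(model, snap) {
  for (nm in names(snap$params)) model$params[[nm]]$val <- snap$params[[nm]]
  model$layers$dff$bn$state$running_mean <- snap$bn_mean
  model$layers$dff$bn$state$running_var <- snap$bn_var
  invisible(model)
}

batchLoss <- function(model, x, t, lossCfg, training) {
  out <- modelForwardNode(model, agConst(x), training = training)
  c(agTotalLoss(out$p, t, lossCfg), list(p = out$p))
}

#' Train the segmentation model
#'
#' Adam optimisation of the multivariate loss with per-epoch validation,
#' Dice-coefficient monitoring, and early stopping on the validation loss.
#' The best-epoch parameters (argmin of validation loss) are restored into
#' the returned model. Fully reproducible given the model seed (weights)
#' and `cfg$seed` (data order).
#'
#' @param model An `adffnet` model from [assembleADFFNet()].
#' @param data List with `train` and `val` elements, each a list of
#'   `list(image, mask)` pairs (e.g. from [generateSamples()]).
#' @param cfg A [trainConfig()].
#' @param checkpoint Optional path; the best model is saved there.
#' @param verbose Print one line per epoch.
#' @return List with `history` (one row per epoch: loss components,
#'   validation loss and Dice, wall-clock seconds), `best_epoch`,
#'   `best_val_loss`, and `model`.
#' @export
trainModel <- function(model, data, cfg = trainConfig(), checkpoint = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(model, "adffnet"), inherits(cfg, "adffnet_train_config"))
  if (!length(data$train) || !length(data$val)) {
    stop("train and val splits must be nonempty", call. = FALSE)
  }
  tr <- samplesToArrays(data$train)
  va <- samplesToArrays(data$val)
  ntr <- dim(tr$x)[4]
  params <- model$params
  mState <- lapply(params, function(p) p$val * 0)
  vState <- mState
  step <- 0L
  set.seed(cfg$seed)
  hist <- list()
  best <- Inf
  bestEpoch <- 0L
  bad <- 0L
  snap <- snapshotParams(model)
  for (epoch in seq_len(cfg$max_epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- sample.int(ntr)
    comp <- c(total = 0, l_e = 0, l_bce = 0, l_dice = 0)
    nb <- 0L
    for (start in seq(1L, ntr, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, ntr)]
      xb <- tr$x[, , , idx, drop = FALSE]
      tb <- tr$t[, , , idx, drop = FALSE]
      res <- batchLoss(model, xb, tb, cfg$loss, training = TRUE)
      if (!is.finite(res$total$val)) {
        stop("non-finite training loss at epoch ", epoch, ", batch starting ",
             start, " (samples ", paste(idx, collapse = ","), ")",
             call. = FALSE)
      }
      grads <- agBackward(res$total, params)
      step <- step + 1L
      lr <- if (cfg$decay_mode == "lr") cfg$lr / (1 + cfg$decay * step)
            else cfg$lr
      for (k in seq_along(params)) {
        g <- grads[[k]]
        if (cfg$decay_mode == "l2") g <- g + cfg$decay * params[[k]]$val
        mState[[k]] <- cfg$beta1 * mState[[k]] + (1 - cfg$beta1) * g
        vState[[k]] <- cfg$beta2 * vState[[k]] + (1 - cfg$beta2) * g^2
        mh <- mState[[k]] / (1 - cfg$beta1^step)
        vh <- vState[[k]] / (1 - cfg$beta2^step)
        params[[k]]$val <- params[[k]]$val - lr * mh / (sqrt(vh) + 1e-8)
      }
      comp <- comp + c(res$total$val, res$l_e$val, res$l_bce$val,
                       res$l_dice$val)
      nb <- nb + 1L
    }
    comp <- comp / nb
    # validation
    nva <- dim(va$x)[4]
    vloss <- 0
    vdice <- 0
    nvb <- 0L
    for (start in seq(1L, nva, by = cfg$batch_size)) {
      idx <- start:min(start + cfg$batch_size - 1L, nva)
      res <- batchLoss(model, va$x[, , , idx, drop = FALSE],
                       va$t[, , , idx, drop = FALSE], cfg$loss,
                       training = FALSE)
      vloss <- vloss + res$total$val * length(idx)
      for (i in seq_along(idx)) {
        vdice <- vdice + diceCoefficient(res$p$val[, , , i],
                                         va$t[, , , idx[i]])
      }
      nvb <- nvb + length(idx)
    }
    vloss <- vloss / nvb
    vdice <- vdice / nvb
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_total = comp[["total"]], train_l_e = comp[["l_e"]],
      train_l_bce = comp[["l_bce"]], train_l_dice = comp[["l_dice"]],
      val_loss = vloss, val_dice = vdice,
      seconds = proc.time()[["elapsed"]] - t0)
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  dice %.4f",
                      epoch, comp[["total"]], vloss, vdice))
    }
    if (vloss < best) {
      best <- vloss
      bestEpoch <- epoch
      bad <- 0L
      snap <- snapshotParams(model)
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
    }
  }
  restoreParams(model, snap)
  if (!is.null(checkpoint)) saveModel(model, checkpoint)
  history <- do.call(rbind, hist)
  attr(history, "best_epoch") <- bestEpoch
  list(history = history, best_epoch = bestEpoch, best_val_loss = best,
       model = model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a model on labelled samples
#'
#' Runs the model over the samples, pools pixels (or averages per image)
#' and reports the six segmentation metrics plus ROC/AUC.
#'
#' @param model An `adffnet` model.
#' @param samples List of `list(image, mask)` pairs.
#' @param threshold Binarisation threshold, default 0.5.
#' @param mode `"pooled"` (default; metrics from pooled confusion counts)
#'   or `"per_image"` (metrics averaged over images).
#' @param batch_size Prediction batch size.
#' @return List with `metrics`, `counts`, `auc` and `roc` (curve points).
#' @export
evaluateModel <- function(model, samples, threshold = 0.5,
                          mode = c("pooled", "per_image"), batch_size = 8L) {
  mode <- match.arg(mode)
  arr <- samplesToArrays(samples)
  n <- dim(arr$x)[4]
  probs <- array(0, dim(arr$t))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    probs[, , , idx] <- adffnetPredict(model, arr$x[, , , idx, drop = FALSE])
  }
  counts <- confusionCounts(probs, arr$t, threshold)
  metrics <- if (mode == "pooled") {
    segmentationMetrics(counts)
  } else {
    per <- vapply(seq_len(n), function(i) {
      segmentationMetrics(confusionCounts(probs[, , , i], arr$t[, , , i],
                                          threshold))
    }, numeric(6))
    rowMeans(per, na.rm = TRUE)
  }
  roc <- rocAuc(probs, arr$t)
  list(metrics = metrics, counts = counts, auc = roc$auc, roc = roc$curve,
       probs = probs)
}

#' Run an ablation grid
#'
#' Trains one model per module combination at the configured scale and
#' reports the test Jaccard similarity per row, mirroring the usual
#' ablation-table structure (baseline with no module, single modules,
#' cumulative combinations, full model).
#'
#' @param grid List of character vectors, each a subset of
#'   `c("BR", "MCIE", "FS", "DFF")`.
#' @param data List with `train`, `val`, `test` sample lists.
#' @param model_config Base [modelConfig()]; its `modules` field is replaced
#'   per row.
#' @param train_config A [trainConfig()].
#' @param verbose Print a line per row.
#' @return data.frame with logical columns BR, MCIE, FS, DFF and the test
#'   `js` per configuration.
#' @export
runAblation <- function(grid, data, model_config, train_config,
                        verbose = FALSE) {
  rows <- lapply(grid, function(mods) {
    cfg <- model_config
    cfg$modules <- mods
    model <- assembleADFFNet(cfg)
    fit <- trainModel(model, data, train_config)
    ev <- evaluateModel(fit$model, data$test)
    if (verbose) {
      message(sprintf("[%s] test JS %.4f",
                      paste(mods, collapse = "+"), ev$metrics[["js"]]))
    }
    data.frame(BR = "BR" %in% mods, MCIE = "MCIE" %in% mods,
               FS = "FS" %in% mods, DFF = "DFF" %in% mods,
               js = ev$metrics[["js"]])
  })
  do.call(rbind, rows)
}
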