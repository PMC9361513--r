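# Training: binary cross-entropy on soft or hard labels, optimized with
# Adam, with random-translation augmentation on the training partition only.

#' Training configuration
#'
#' Defaults follow the full-scale protocol: Adam with learning rate 1e-5,
#' beta1 = 0.9, beta2 = 0.99, epsilon = 1e-7, 100 epochs, batch size 64.
#' Scaled-down experiments override the rate/epochs/batch explicitly.
#'
#' @param learning_rate Adam step size.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer.
#' @param epochs number of passes over the training partition.
#' @param batch_size minibatch size (gradients are averaged per batch).
#' @param label_mode `"soft"` (sigmoid-of-score targets) or `"hard"` (0/1).
#' @param cutoff,center MoCA cutoff / sigmoid center for the labels.
#' @param augment_shift maximum translation (px) of the train-time
#'   augmentation; 0 disables it.
#' @param select checkpoint selection: `"best_auc"` (epoch with best
#'   validation AUC) or `"final"`.
#' @param seed integer seed driving shuffling and augmentation.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, beta1 = 0.9, beta2 = 0.99,
                         epsilon = 1e-7, epochs = 100, batch_size = 64,
                         label_mode = c("soft", "hard"), cutoff = 25,
                         center = 24.5, augment_shift = 12,
                         select = c("best_auc", "final"), seed = 1L) {
  label_mode <- match.arg(label_mode)
  select <- match.arg(select)
  stopifnot(learning_rate > 0, beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1,
            epsilon > 0, is_count(epochs), epochs >= 1,
            is_count(batch_size), batch_size >= 1, augment_shift >= 0)
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), label_mode = label_mode,
                 cutoff = cutoff, center = center,
                 augment_shift = augment_shift, select = select,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Binary cross-entropy loss
#'
#' `L = -mean(y log p + (1 - y) log(1 - p))` with predictions clamped to
#' `[clamp, 1 - clamp]` for numerical stability.  Targets may be soft
#' (in \[0, 1\]); as a function of `p` the loss is minimized exactly at
#' `p = y`.
#'
#' @param y targets in \[0, 1\].
#' @param p predicted MCI probabilities.
#' @param clamp clamping bound (default 1e-7).
#' @return nonnegative scalar loss.
#' @export
bce_loss <- function(y, p, clamp = 1e-7) {
  if (length(y) != length(p))
    stop("targets and predictions differ in length")
  if (any(y < 0 | y > 1)) stop("targets must lie in [0, 1]")
  p <- pmin(1 - clamp, pmax(clamp, p))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# one Adam step over a parameter tree; state carries first/second moments
# and the step counter
adam_step <- function(params, grads, state, tc) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) tc$beta1 * m + (1 - tc$beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) tc$beta2 * v + (1 - tc$beta2) * g * g,
                       state$v, grads)
  c1 <- 1 - tc$beta1^state$t
  c2 <- 1 - tc$beta2^state$t
  lr <- tc$learning_rate
  upd <- function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + tc$epsilon)
  rec <- function(p, m, v) {
    if (is.list(p)) {
      out <- vector("list", length(p)); names(out) <- names(p)
      for (i in seq_along(p)) out[[i]] <- rec(p[[i]], m[[i]], v[[i]])
      out
    } else upd(p, m, v)
  }
  list(params = rec(params, state$m, state$v), state = state)
}

#' Fit a multi-input drawing-classification model
#'
#' The main fitting function: builds the configured model, loads and
#' resizes every subject's images, and trains with minibatch Adam on the
#' binary cross-entropy between the predicted MCI probability and the
#' (soft or hard) label.  Random-translation augmentation is applied to
#' training images only; validation and test images are used as-is.
#' Per-epoch train/validation losses and validation AUC are logged, and the
#' returned fit carries the parameters of the selected checkpoint.
#'
#' @param records subject records from [load_manifest()].
#' @param split a split assignment from [stratified_split()]; when `NULL`
#'   a 70/15/15 stratified split is drawn using the training seed.
#' @param config model architecture, a [conv_att_config()].
#' @param training optimization settings, a [train_config()].
#' @param verbose print one line per epoch.
#' @return object of class `conv_att` with elements `model`, `history`
#'   (data frame: epoch, train_loss, val_loss, val_auc), `split`, `config`,
#'   `training`, `records`.
#' @export
conv_att <- function(records, split = NULL, config = conv_att_config(),
                     training = train_config(), verbose = FALSE) {
  stopifnot(inherits(config, "conv_att_config"),
            inherits(training, "train_config"))
  if (is.null(split))
    split <- stratified_split(records, seed = training$seed,
                              cutoff = training$cutoff)
  idx_train <- partition_indices(records, split, "train")
  idx_val <- partition_indices(records, split, "validation")
  if (!length(idx_train)) stop("training partition is empty")
  if (!length(idx_val)) stop("validation partition is empty")
  y <- subject_labels(records, training$label_mode, training$cutoff,
                      training$center)
  yhard <- hard_label(vapply(records, function(r) r$moca_score, numeric(1)),
                      training$cutoff)
  images <- lapply(records, load_and_resize, size = config$input_size)
  model <- new_conv_att_model(config)
  params <- model_params(model)
  state <- list(m = tree_zero(params), v = tree_zero(params), t = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_auc = numeric())
  best <- list(auc = -Inf, params = params)
  eval_probs <- function(model, idx) {
    vapply(idx, function(i) model_forward(model, images[[i]])$prob,
           numeric(1))
  }
  with_seed(training$seed, {
    for (epoch in seq_len(training$epochs)) {
      ord <- sample(idx_train)
      batch_starts <- seq(1L, length(ord), by = training$batch_size)
      losses <- numeric(0)
      for (b in batch_starts) {
        bidx <- ord[b:min(b + training$batch_size - 1L, length(ord))]
        gsum <- NULL
        bl <- 0
        for (i in bidx) {
          imgs <- images[[i]]
          if (training$augment_shift > 0) {
            imgs <- lapply(imgs, augment_translate,
                           max_shift = training$augment_shift)
          }
          fw <- model_forward(model, imgs[config$inputs], keep_cache = TRUE)
          bl <- bl + bce_loss(y[i], fw$prob)
          g <- model_backward(model, fw, y[i])
          gsum <- if (is.null(gsum)) g else tree_map2(`+`, gsum, g)
        }
        gavg <- tree_map(function(x) x / length(bidx), gsum)
        st <- adam_step(params, gavg, state, training)
        params <- st$params
        state <- st$state
        model <- model_set_params(model, params)
        losses <- c(losses, bl / length(bidx))
      }
      pv <- eval_probs(model, idx_val)
      vl <- bce_loss(y[idx_val], pv)
      va <- if (length(unique(yhard[idx_val])) == 2L)
        rank_auc(pv, yhard[idx_val]) else NA_real_
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = mean(losses), val_loss = vl,
        val_auc = va))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  auc %s", epoch,
                        mean(losses), vl,
                        ifelse(is.na(va), "NA", sprintf("%.3f", va))))
      if (!is.na(va) && va > best$auc) best <- list(auc = va, params = params)
    }
  })
  final_params <- if (training$select == "best_auc" && is.finite(best$auc))
    best$params else params
  model <- model_set_params(model, final_params)
  structure(list(model = model, history = history, split = split,
                 config = config, training = training, records = records),
            class = "conv_att")
}

#' Predicted MCI probabilities
#'
#' Deterministic inference (no augmentation) on a set of subject records.
#'
#' @param object a fitted `conv_att`.
#' @param records subject records; defaults to the fit's records.
#' @return numeric vector of per-subject MCI probabilities in \[0, 1\].
#' @export
predict_proba <- function(object, records = object$records) {
  stopifnot(inherits(object, "conv_att"))
  size <- object$config$input_size
  vapply(records, function(r) {
    imgs <- load_and_resize(r, size = size)
    model_forward(object$model, imgs[object$config$inputs])$prob
  }, numeric(1))
}
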