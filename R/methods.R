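# S3 methods for fitted models.

#' @export
print.conv_att <- function(x, ...) {
  cfg <- x$config
  cat("Multi-input drawing classifier (", cfg$variant, ")\n", sep = "")
  cat("  inputs   :", paste(cfg$inputs, collapse = ", "), "\n")
  cat("  backbone : ", cfg$backbone, ", input ", cfg$input_size, "x",
      cfg$input_size, "\n", sep = "")
  if (cfg$variant == "conv_att")
    cat("  attention:", cfg$n_layers, "layer(s), D =", cfg$hidden_dim,
        ", ffn =", cfg$ffn_dim, "\n")
  cat("  labels   :", x$training$label_mode, "(cutoff", x$training$cutoff,
      ")\n")
  h <- x$history
  if (nrow(h)) {
    cat(sprintf("  trained  : %d epoch(s); final val loss %.4f, val AUC %s\n",
                nrow(h), h$val_loss[nrow(h)],
                ifelse(is.na(h$val_auc[nrow(h)]), "NA",
                       sprintf("%.3f", h$val_auc[nrow(h)]))))
  }
  invisible(x)
}

#' @export
summary.conv_att <- function(object, ...) {
  n_par <- length(tree_flatten(model_params(object$model)))
  h <- object$history
  best <- if (all(is.na(h$val_auc))) NA_real_ else max(h$val_auc, na.rm = TRUE)
  out <- list(config = object$config, training = object$training,
              n_parameters = n_par, epochs = nrow(h),
              best_val_auc = best, history = h,
              split_sizes = table(object$split$partition))
  class(out) <- "summary.conv_att"
  out
}

#' @export
print.summary.conv_att <- function(x, ...) {
  cat("Fitted drawing classifier:", x$config$variant, "with",
      length(x$config$inputs), "input(s)\n")
  cat("  parameters      :", x$n_parameters, "\n")
  cat("  split sizes     :", paste(names(x$split_sizes), x$split_sizes,
                                   sep = "=", collapse = ", "), "\n")
  cat("  epochs          :", x$epochs, "\n")
  cat("  best val AUC    :", ifelse(is.na(x$best_val_auc), "NA",
                                    sprintf("%.3f", x$best_val_auc)), "\n")
  invisible(x)
}

#' Predict from a fitted drawing classifier
#'
#' @param object fitted `conv_att`.
#' @param newdata subject records (default: the fit's records).
#' @param type `"prob"` for MCI probabilities, `"class"` for thresholded
#'   0/1 labels (p >= 0.5 classified as MCI).
#' @param ... unused.
#' @export
predict.conv_att <- function(object, newdata = object$records,
                             type = c("prob", "class"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "class") as.integer(p >= 0.5) else p
}

#' @export
plot.conv_att <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"),
                    xlab = "epoch", ylab = "BCE loss", ...)
  graphics::legend("topright", legend = c("train", "validation"),
                   col = c("black", "red3"), lty = 1, bty = "n")
  invisible(x)
}

#' @export
coef.conv_att <- function(object, ...) model_params(object$model)

#' @export
residuals.conv_att <- function(object, ...) {
  y <- subject_labels(object$records, object$training$label_mode,
                      object$training$cutoff, object$training$center)
  y - predict_proba(object)
}

#' @export
simulate.conv_att <- function(object, nsim = 1, seed = NULL, ...) {
  p <- predict_proba(object)
  out <- with_seed(seed, replicate(nsim, as.integer(runif(length(p)) < p)))
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- vapply(object$records, function(r) r$subject_id,
                          character(1))
  out
}
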