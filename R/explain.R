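# Visual explanation: attention rollout for the conv-att variant, Grad-CAM
# for the pooling baseline, and top-k binarization of heat maps.

check_row_stochastic <- function(W, tol = 1e-6) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("attention matrix must be square")
  if (any(W < -tol) || any(abs(rowSums(W) - 1) > 1e-4))
    stop("attention matrix must be row-stochastic")
  invisible(W)
}

#' Residual-corrected raw attention
#'
#' Because each encoder layer adds its attention output back onto the
#' residual stream (`V_{l+1} = V_l + W_att V_l`), the attention actually
#' mixing tokens is the average of the weight matrix with the identity:
#' `A = 0.5 W_att + 0.5 I`.
#'
#' @param W_att square row-stochastic attention weight matrix.
#' @return the raw attention `A`, also row-stochastic.
#' @export
raw_attention <- function(W_att) {
  check_row_stochastic(W_att)
  0.5 * W_att + 0.5 * diag(nrow(W_att))
}

#' Attention rollout across layers
#'
#' Recursively left-multiplies the residual-corrected attentions:
#' `rollout(l_i) = A(l_i) %*% rollout(l_{i-1})` for `i > j`, with
#' `rollout(l_j) = A(l_j)`.  The result traces how attention propagates
#' from the final layer back to the input tokens and stays row-stochastic.
#'
#' @param trace list of per-layer attention weight matrices (`W_att`),
#'   ordered first to last layer (as returned by [encoder_forward()]).
#' @param from_layer,to_layer layer span (defaults: all layers).
#' @return rollout matrix of the same dimension as the attentions.
#' @export
attention_rollout <- function(trace, from_layer = 1L,
                              to_layer = length(trace)) {
  if (!length(trace)) stop("empty attention trace")
  if (from_layer > to_layer) stop("from_layer must not exceed to_layer")
  if (to_layer > length(trace) || from_layer < 1L)
    stop("layer indices out of range")
  R <- raw_attention(trace[[from_layer]])
  if (to_layer > from_layer) {
    for (l in (from_layer + 1L):to_layer) {
      R <- raw_attention(trace[[l]]) %*% R
    }
  }
  R
}

#' CLS heat map from a rollout matrix
#'
#' Takes the CLS row of the rollout (how the final CLS representation
#' weights every token), drops the CLS column, reshapes the remaining `HL`
#' weights row-major back onto the `H x L` feature grid (the exact inverse
#' of [tokenize()]'s pixel-to-token indexing), and upsamples bilinearly to
#' the input resolution.
#'
#' @param rollout `(HL+1) x (HL+1)` rollout matrix.
#' @param grid_shape feature-grid dimensions `c(H, L)`.
#' @param input_size output side length in pixels.
#' @return `input_size` x `input_size` nonnegative matrix with attribute
#'   `source = "rollout"`.
#' @export
cls_heatmap <- function(rollout, grid_shape, input_size) {
  H <- grid_shape[1]; L <- grid_shape[2]
  if (nrow(rollout) != H * L + 1)
    stop("rollout dimension does not match grid_shape")
  v <- rollout[1, -1]
  hm <- resize_bilinear(vector_to_grid(v, H, L), input_size, input_size)
  hm <- pmax(hm, 0)
  attr(hm, "source") <- "rollout"
  hm
}

#' Rollout heat maps for a fitted conv-att model
#'
#' Runs the forward pass on one subject's images and converts each task
#' pathway's attention trace into a CLS heat map spanning all layers.
#'
#' @param object a fitted `conv_att` (attention variant).
#' @param images named list of input arrays (see [load_and_resize()]).
#' @return named list of heat-map matrices, one per input task.
#' @export
rollout_heatmaps <- function(object, images) {
  stopifnot(inherits(object, "conv_att"))
  if (object$config$variant != "conv_att")
    stop("rollout requires the conv_att variant; use grad_cam() for the ",
         "pooling baseline")
  fw <- model_forward(object$model, images[object$config$inputs])
  out <- lapply(fw$trace, function(tr)
    cls_heatmap(attention_rollout(tr), attr(tr, "grid_shape"),
                object$config$input_size))
  names(out) <- names(fw$trace)
  out
}

# core Grad-CAM combination: channel weights are the spatial means of the
# class-logit gradients; the map is the rectified weighted channel sum
grad_cam_map <- function(feature_map, feature_grad, input_size) {
  alpha <- apply(feature_grad, 3L, mean)
  raw <- matrix(0, dim(feature_map)[1], dim(feature_map)[2])
  for (c in seq_along(alpha)) raw <- raw + alpha[c] * feature_map[, , c]
  hm <- pmax(resize_bilinear(pmax(raw, 0), input_size, input_size), 0)
  attr(hm, "source") <- "grad_cam"
  hm
}

#' Grad-CAM heat maps for the pooling baseline
#'
#' Gradient-weighted class-activation mapping on the last convolutional
#' feature map of each pathway: channel weights are the spatially averaged
#' gradients of the target-class logit, and the weighted channel sum is
#' rectified and upsampled to the input size.  With global average pooling
#' and a linear classifier, the logit gradient with respect to feature
#' pixel `(h, w, c)` is the classifier weight for channel `c` divided by
#' the number of feature pixels; the gradients are computed that way here.
#'
#' @param object a fitted `conv_att` with the pooling variant.
#' @param images named list of input arrays.
#' @param target_class class whose logit is explained (default `"mci"`).
#' @return named list of heat-map matrices, one per input task.
#' @export
grad_cam <- function(object, images, target_class = c("mci", "healthy")) {
  stopifnot(inherits(object, "conv_att"))
  target_class <- match.arg(target_class)
  if (object$config$variant != "pooling")
    stop("grad_cam applies to the pooling baseline; the conv_att variant ",
         "is explained by attention rollout")
  fw <- model_forward(object$model, images[object$config$inputs])
  ti <- if (target_class == "mci") 2L else 1L
  inputs <- object$config$inputs
  out <- list()
  for (k in seq_along(inputs)) {
    feat <- fw$feature_maps[[inputs[k]]]
    d <- dim(feat)
    wseg <- object$model$classifier$W[ti, (k - 1) * d[3] + seq_len(d[3])]
    grad <- array(rep(wseg, each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
    out[[inputs[k]]] <- grad_cam_map(feat, grad, object$config$input_size)
  }
  out
}

#' Binarize a heat map by top-k percent
#'
#' Assigns 1 to the `round(k/100 * n_pixels)` pixels with the highest
#' values and 0 elsewhere.  Ties are broken deterministically by linear
#' (column-major) pixel index.
#'
#' @param heatmap numeric matrix.
#' @param k_percent percentage of pixels to keep, in (0, 100\].
#' @return binary (logical) matrix of the same shape.
#' @export
binarize_topk <- function(heatmap, k_percent) {
  if (!is.numeric(k_percent) || length(k_percent) != 1L ||
      k_percent <= 0 || k_percent > 100)
    stop("k_percent must lie in (0, 100]")
  n <- length(heatmap)
  k <- round_half_up(k_percent / 100 * n)
  out <- matrix(FALSE, nrow(heatmap), ncol(heatmap))
  if (k > 0) {
    ord <- order(-as.numeric(heatmap), seq_len(n))
    out[ord[seq_len(k)]] <- TRUE
  }
  out
}

# write a heat map as a plain-text grid and as a PNG overlay on a drawing
write_heatmap <- function(hm, path_txt, path_png = NULL, drawing = NULL) {
  write.table(format(hm, digits = 8), path_txt, row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  if (!is.null(path_png)) {
    hmn <- hm / max(hm, 1e-12)
    base <- if (is.null(drawing)) matrix(1, nrow(hm), ncol(hm)) else
      resize_bilinear(drawing, nrow(hm), ncol(hm))
    rgb <- array(0, dim = c(nrow(hm), ncol(hm), 3))
    rgb[, , 1] <- pmin(1, base * (1 - hmn) + hmn)       # red overlay
    rgb[, , 2] <- base * (1 - hmn)
    rgb[, , 3] <- base * (1 - hmn)
    png::writePNG(rgb, path_png)
  }
  invisible(path_txt)
}
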