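# Multi-input model assembly.
#
# Each configured input task gets its own pathway: a convolutional backbone
# followed, in the conv-att variant, by a 1 x 1 projection to the attention
# hidden dimension, a CLS token, and a stack of single-head self-attention
# layers; or, in the pooling variant, by global average pooling.  The
# per-task representations are concatenated and classified by a two-node
# softmax layer.  The MCI probability is the model output p.

#' Model configuration
#'
#' @param variant `"conv_att"` (CLS-token self-attention aggregation) or
#'   `"pooling"` (global average pooling baseline).
#' @param inputs subset of `c("clock", "cube", "trail")`; a single task
#'   gives the corresponding single-input model.
#' @param backbone `"vgg16"` or `"toy"` (see [make_backbone()]).
#' @param input_size input image side in pixels (default 256).
#' @param n_layers number of stacked self-attention layers (default 2).
#' @param hidden_dim attention hidden dimension D (default 128).
#' @param ffn_dim feed-forward sublayer width (default 512).
#' @param seed integer seed for all weight initialization, including the
#'   random CLS vector.
#' @return object of class `conv_att_config`.
#' @export
conv_att_config <- function(variant = c("conv_att", "pooling"),
                            inputs = c("clock", "cube", "trail"),
                            backbone = c("vgg16", "toy"),
                            input_size = 256, n_layers = 2,
                            hidden_dim = 128, ffn_dim = 512, seed = 1L) {
  variant <- match.arg(variant)
  backbone <- match.arg(backbone)
  inputs <- match.arg(inputs, TASKS, several.ok = TRUE)
  stopifnot(is_count(input_size), is_count(n_layers), n_layers >= 1,
            is_count(hidden_dim), hidden_dim >= 1,
            is_count(ffn_dim), ffn_dim >= 1)
  stride <- backbone_spec(backbone)$stride
  if (input_size %% stride != 0)
    stop("input_size must be a multiple of the backbone stride (", stride, ")")
  structure(list(variant = variant, inputs = inputs, backbone = backbone,
                 input_size = as.integer(input_size),
                 n_layers = as.integer(n_layers),
                 hidden_dim = as.integer(hidden_dim),
                 ffn_dim = as.integer(ffn_dim), seed = as.integer(seed)),
            class = "conv_att_config")
}

new_encoder_layer <- function(D, Fd) {
  sd_qkv <- sqrt(1 / D)
  list(Wq = matrix(rnorm(D * D, 0, sd_qkv), D, D),
       Wk = matrix(rnorm(D * D, 0, sd_qkv), D, D),
       Wv = matrix(rnorm(D * D, 0, sd_qkv), D, D),
       ln1_g = rep(1, D), ln1_b = rep(0, D),
       W1 = matrix(rnorm(Fd * D, 0, sqrt(2 / D)), Fd, D),
       b1 = rep(0, Fd),
       W2 = matrix(rnorm(D * Fd, 0, sqrt(2 / Fd)), D, Fd),
       b2 = rep(0, D),
       ln2_g = rep(1, D), ln2_b = rep(0, D))
}

#' Build a (untrained) multi-input model
#'
#' @param config a [conv_att_config()].
#' @return object of class `conv_att_model` holding per-pathway parameters
#'   (backbone, projection, CLS vector, encoder layers) and the two-node
#'   classifier.
#' @export
new_conv_att_model <- function(config) {
  stopifnot(inherits(config, "conv_att_config"))
  D <- config$hidden_dim
  pathways <- list()
  with_seed(config$seed, {
    for (task in config$inputs) {
      bb <- make_backbone(config$backbone,
                          seed = derive_seed(config$seed, task, "backbone"))
      C <- backbone_out_channels(bb)
      pw <- list(backbone = bb)
      if (config$variant == "conv_att") {
        pw$proj <- list(W = matrix(rnorm(D * C, 0, sqrt(1 / C)), D, C),
                        b = rep(0, D))
        pw$cls <- rnorm(D, 0, 0.02)
        pw$layers <- lapply(seq_len(config$n_layers), function(l)
          new_encoder_layer(D, config$ffn_dim))
      }
      pathways[[task]] <- pw
    }
    rep_dim <- if (config$variant == "conv_att") D else
      backbone_spec(config$backbone)$channels[
        length(backbone_spec(config$backbone)$channels)]
    W <- matrix(rnorm(2 * rep_dim * length(config$inputs), 0, 0.01),
                2, rep_dim * length(config$inputs))
    classifier <- list(W = W, b = rep(0, 2))
  })
  structure(list(pathways = pathways, classifier = classifier,
                 config = config),
            class = "conv_att_model")
}

# image (ink scale, [0,1]) -> centered backbone input
prep_input <- function(img) 2 * img - 1

# full forward pass on one subject's images; returns probabilities, the
# attention trace (conv_att), pooled/CLS vectors, and optional caches
model_forward <- function(model, images, keep_cache = FALSE) {
  cfg <- model$config
  reps <- list(); traces <- list(); caches <- list(); feats <- list()
  for (task in cfg$inputs) {
    img <- images[[task]]
    if (is.null(img)) stop("missing image for input task '", task, "'")
    pw <- model$pathways[[task]]
    x <- prep_input(img)
    feat <- backbone_forward(pw$backbone, x, keep_cache = keep_cache)
    cache <- list(feat = feat, bb_cache = attr(feat, "cache"))
    attr(feat, "cache") <- NULL
    if (cfg$variant == "conv_att") {
      tok <- tokenize(feat, pw$proj, pw$cls)
      trace <- vector("list", cfg$n_layers)
      lcaches <- vector("list", cfg$n_layers)
      X <- tok
      for (l in seq_len(cfg$n_layers)) {
        r <- encoder_layer_fwd(X, pw$layers[[l]])
        trace[[l]] <- r$A
        lcaches[[l]] <- c(r$cache, list(X_in = X))
        X <- r$out
      }
      reps[[task]] <- X[1, ]
      attr(trace, "grid_shape") <- attr(tok, "grid_shape")
      traces[[task]] <- trace
      cache$tok <- tok
      cache$lcaches <- lcaches
    } else {
      reps[[task]] <- apply(feat, 3L, mean)
    }
    feats[[task]] <- feat
    if (keep_cache) caches[[task]] <- cache
  }
  u <- unlist(reps, use.names = FALSE)
  logits <- as.numeric(model$classifier$W %*% u + model$classifier$b)
  p <- softmax_probs(logits)
  names(p) <- c("healthy", "mci")
  list(p = p, prob = unname(p["mci"]), reps = reps, trace = traces,
       feature_maps = feats, u = u,
       caches = if (keep_cache) caches else NULL)
}

# backward pass for one subject given target y in [0,1] (probability of
# MCI); returns gradients in the same tree shape as the model parameters
model_backward <- function(model, fw, y) {
  cfg <- model$config
  p <- fw$p
  dz <- c(p[1] - (1 - y), p[2] - y)           # softmax + BCE
  dW_cls <- outer(dz, fw$u)
  db_cls <- dz
  du <- as.numeric(t(model$classifier$W) %*% dz)
  rep_dim <- length(fw$u) / length(cfg$inputs)
  gpaths <- list()
  for (k in seq_along(cfg$inputs)) {
    task <- cfg$inputs[k]
    pw <- model$pathways[[task]]
    cache <- fw$caches[[task]]
    drep <- du[(k - 1) * rep_dim + seq_len(rep_dim)]
    if (cfg$variant == "conv_att") {
      X_final_d <- matrix(0, nrow(cache$tok), cfg$hidden_dim)
      X_final_d[1, ] <- drep
      dX <- X_final_d
      lay_grads <- vector("list", cfg$n_layers)
      for (l in rev(seq_len(cfg$n_layers))) {
        bw <- encoder_layer_bwd(cache$lcaches[[l]], pw$layers[[l]], dX)
        lay_grads[[l]] <- bw$grads
        dX <- bw$dX
      }
      tb <- tokenize_bwd(cache$feat, pw$proj, dX)
      bbg <- backbone_backward(pw$backbone, cache$bb_cache, tb$dX)
      gpaths[[task]] <- list(backbone = list(convs = bbg),
                             proj = list(W = tb$dW, b = tb$db),
                             cls = tb$dcls, layers = lay_grads)
    } else {
      d <- dim(cache$feat)
      dfeat <- array(rep(drep, each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
      bbg <- backbone_backward(pw$backbone, cache$bb_cache, dfeat)
      gpaths[[task]] <- list(backbone = list(convs = bbg))
    }
  }
  list(pathways = gpaths, classifier = list(W = dW_cls, b = db_cls))
}

# the trainable parameter tree of a model (same shape as gradients)
model_params <- function(model) {
  lapply_named <- function(x, f) { out <- lapply(x, f); names(out) <- names(x); out }
  list(pathways = lapply_named(model$pathways, function(pw) {
    out <- list(backbone = list(convs = pw$backbone$convs))
    if (!is.null(pw$proj)) {
      out$proj <- pw$proj
      out$cls <- pw$cls
      out$layers <- pw$layers
    }
    out
  }), classifier = model$classifier)
}

# write a parameter tree back into a model
model_set_params <- function(model, params) {
  for (task in names(model$pathways)) {
    model$pathways[[task]]$backbone$convs <-
      params$pathways[[task]]$backbone$convs
    if (!is.null(model$pathways[[task]]$proj)) {
      model$pathways[[task]]$proj <- params$pathways[[task]]$proj
      model$pathways[[task]]$cls <- params$pathways[[task]]$cls
      model$pathways[[task]]$layers <- params$pathways[[task]]$layers
    }
  }
  model$classifier <- params$classifier
  model
}

#' Pooling-baseline forward pass
#'
#' Runs the global-average-pooling variant on one subject: per-task
#' backbone, average pooling over the `H x L` feature grid, concatenation,
#' and the two-node softmax classifier.
#'
#' @param model a `conv_att_model` with `variant = "pooling"`.
#' @param images named list of input arrays (ink scale), one per configured
#'   input task.
#' @return named probability vector `c(healthy, mci)`.
#' @export
pooling_baseline_forward <- function(model, images) {
  stopifnot(inherits(model, "conv_att_model"))
  if (model$config$variant != "pooling")
    stop("model is not a pooling-baseline variant")
  model_forward(model, images)$p
}
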