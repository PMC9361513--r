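# Convolutional backbones.
#
# Two architectures are provided behind one interface: the 16-layer VGG
# configuration (13 conv layers in five pooled stages, downsampling by 32,
# 512 output channels -- 8 x 8 x 512 at a 256 x 256 input) and a small
# 4-conv-block "toy" backbone (three pooled stages, downsampling by 8, 32
# output channels) for desk-scale experiments.  Weights are He-initialized;
# a list of pretrained weights of matching shapes can be supplied but is
# never required.  All convolutions are 3 x 3 with same padding, all pools
# 2 x 2 max.

backbone_spec <- function(kind) {
  switch(kind,
    toy = list(channels = c(8, 16, 32, 32),
               pool_after = c(TRUE, TRUE, TRUE, FALSE), stride = 8L),
    vgg16 = list(channels = c(64, 64, 128, 128, 256, 256, 256,
                              512, 512, 512, 512, 512, 512),
                 pool_after = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE,
                                FALSE, FALSE, TRUE, FALSE, FALSE, TRUE),
                 stride = 32L),
    stop("unknown backbone kind: ", kind, " (use 'toy' or 'vgg16')"))
}

#' Construct a convolutional backbone
#'
#' @param kind `"vgg16"` (the default full-scale architecture) or `"toy"`
#'   (a 4-conv-block backbone for small experiments).
#' @param seed integer seed for the He-normal weight initialization.
#' @param in_channels input channel count (3 for replicated grayscale).
#' @param weights optional list of `list(w, b)` per conv layer (e.g.
#'   pretrained values) with shapes matching the architecture.
#' @return object of class `conv_backbone`.
#' @export
make_backbone <- function(kind = c("vgg16", "toy"), seed = 1L,
                          in_channels = 3L, weights = NULL) {
  kind <- match.arg(kind)
  spec <- backbone_spec(kind)
  convs <- vector("list", length(spec$channels))
  cin <- in_channels
  with_seed(seed, {
    for (i in seq_along(spec$channels)) {
      cout <- spec$channels[i]
      convs[[i]] <- list(
        w = matrix(rnorm(cout * 9 * cin, 0, sqrt(2 / (9 * cin))),
                   cout, 9 * cin),
        b = rep(0, cout))
      cin <- cout
    }
  })
  if (!is.null(weights)) {
    if (length(weights) != length(convs))
      stop("supplied weights do not match the architecture depth")
    for (i in seq_along(convs)) {
      if (!identical(dim(weights[[i]]$w), dim(convs[[i]]$w)))
        stop("weight shape mismatch in conv layer ", i)
      convs[[i]] <- list(w = weights[[i]]$w, b = as.numeric(weights[[i]]$b))
    }
  }
  structure(list(kind = kind, convs = convs, pool_after = spec$pool_after,
                 stride = spec$stride, in_channels = in_channels),
            class = "conv_backbone")
}

#' Backbone forward pass
#'
#' Runs an image through the convolutional stages and returns the last
#' convolutional feature map.  With the default (`vgg16`) backbone the
#' spatial side shrinks by a factor of 32, so a 256 x 256 input yields an
#' 8 x 8 x 512 map and a 64 x 64 input a 2 x 2 x 512 map.
#'
#' @param backbone a `conv_backbone` from [make_backbone()].
#' @param image `N x N x C_in` numeric array, `N` divisible by the
#'   backbone's downsampling stride.
#' @param keep_cache retain intermediate activations (needed for the
#'   backward pass during training).
#' @return `H x L x C` feature map; with `keep_cache = TRUE`, attribute
#'   `cache` holds the per-layer activations.
#' @export
backbone_forward <- function(backbone, image, keep_cache = FALSE) {
  stopifnot(inherits(backbone, "conv_backbone"))
  d <- dim(image)
  if (length(d) != 3L || d[1] != d[2] || d[3] != backbone$in_channels)
    stop("expected a square H x W x ", backbone$in_channels, " input array")
  if (d[1] %% backbone$stride != 0 || d[1] < backbone$stride)
    stop("input side must be a positive multiple of ", backbone$stride)
  x <- image
  cache <- if (keep_cache) vector("list", length(backbone$convs)) else NULL
  for (i in seq_along(backbone$convs)) {
    p <- backbone$convs[[i]]
    y <- .cv_conv3_fwd(x, p$w, p$b)
    a <- pmax(y, 0)
    st <- list(x = x, relu_mask = y > 0)
    if (backbone$pool_after[i]) {
      pl <- .cv_maxpool2_fwd(a)
      st$pool_idx <- pl$idx
      st$pre_pool_dim <- dim(a)
      a <- pl$y
    }
    if (keep_cache) cache[[i]] <- st
    x <- a
  }
  if (keep_cache) attr(x, "cache") <- cache
  x
}

# backward pass: gradients w.r.t. every conv weight (input gradient is not
# needed -- images are leaves)
backbone_backward <- function(backbone, cache, dfeat) {
  n <- length(backbone$convs)
  grads <- vector("list", n)
  dy <- dfeat
  for (i in rev(seq_len(n))) {
    st <- cache[[i]]
    if (backbone$pool_after[i]) {
      dy <- .cv_maxpool2_bwd(st$pool_idx, dy,
                             st$pre_pool_dim[1], st$pre_pool_dim[2])
    }
    dy <- dy * st$relu_mask
    g <- .cv_conv3_bwd(st$x, backbone$convs[[i]]$w, dy)
    grads[[i]] <- list(w = g$dw, b = as.numeric(g$db))
    dy <- g$dx
  }
  grads
}

backbone_params <- function(backbone) backbone$convs

backbone_out_channels <- function(backbone) {
  spec <- backbone_spec(backbone$kind)
  spec$channels[length(spec$channels)]
}
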