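# Dense neural-network primitives with explicit forward/backward passes.
#
# Everything is double precision.  Token matrices are N x D with row 1
# reserved for the CLS token; attention layers use a single head.  The
# encoder block is pre-normalization: each sublayer reads a layer-normalized
# copy of its input and adds its output back onto the raw residual stream,
# so the residual path through a layer is an exact identity -- consistent
# with the residual view of attention that the rollout correction
# A = 0.5 W_att + 0.5 I compensates for.

softmax_rows <- function(S) {
  e <- exp(S - apply(S, 1L, max))
  e / rowSums(e)
}

#' Two-node softmax
#'
#' `f_i(x) = exp(x_i) / sum_j exp(x_j)`, invariant under adding a constant
#' to all logits.
#'
#' @param logits numeric vector of logits.
#' @return probabilities summing to 1.
#' @export
softmax_probs <- function(logits) {
  e <- exp(logits - max(logits))
  e / sum(e)
}

relu <- function(x) pmax(x, 0)

# ---- layer norm -----------------------------------------------------------

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(y = sweep(xhat * g[col(xhat)], 2L, b, "+"),
       xhat = xhat, inv = inv, g = g)
}

layernorm_bwd <- function(cache, dy) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxh <- dy * cache$g[col(dy)]
  dx <- cache$inv * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
  list(dx = dx, dg = dg, db = db)
}

# ---- single-head scaled dot-product attention ----------------------------

#' Scaled dot-product self-attention
#'
#' `Attn(Q, K, V) = softmax(Q K' / sqrt(D)) V` with the softmax taken over
#' each query's row of logits, so every output row is a convex combination
#' of the rows of `V`.  The row-stochastic weight matrix is returned for
#' attention rollout.
#'
#' @param Q,K,V numeric matrices with equal row counts and `D` columns.
#' @return list with `output` (same shape as `V`) and `weights` (the
#'   attention matrix `W_att`).
#' @export
self_attention <- function(Q, K, V) {
  if (!is.matrix(Q) || !is.matrix(K) || !is.matrix(V))
    stop("Q, K, V must be matrices")
  if (nrow(Q) != nrow(K) || nrow(K) != nrow(V) ||
      ncol(Q) != ncol(K))
    stop("Q, K, V dimensions are inconsistent")
  A <- softmax_rows(Q %*% t(K) / sqrt(ncol(Q)))
  list(output = A %*% V, weights = A)
}

attention_fwd <- function(X, p) {
  Q <- X %*% t(p$Wq); K <- X %*% t(p$Wk); V <- X %*% t(p$Wv)
  at <- self_attention(Q, K, V)
  list(O = at$output, A = at$weights, Q = Q, K = K, V = V, X = X)
}

attention_bwd <- function(cache, p, dO) {
  A <- cache$A; sc <- sqrt(ncol(cache$Q))
  dA <- dO %*% t(cache$V)
  dV <- t(A) %*% dO
  dS <- A * (dA - rowSums(dA * A))
  dQ <- dS %*% cache$K / sc
  dK <- t(dS) %*% cache$Q / sc
  dX <- dQ %*% p$Wq + dK %*% p$Wk + dV %*% p$Wv
  list(dX = dX,
       dWq = t(dQ) %*% cache$X,
       dWk = t(dK) %*% cache$X,
       dWv = t(dV) %*% cache$X)
}

# ---- encoder layer (pre-LN residual block) -------------------------------

encoder_layer_fwd <- function(X, p) {
  ln1 <- layernorm_fwd(X, p$ln1_g, p$ln1_b)
  at <- attention_fwd(ln1$y, p)
  X2 <- X + at$O
  ln2 <- layernorm_fwd(X2, p$ln2_g, p$ln2_b)
  z1 <- sweep(ln2$y %*% t(p$W1), 2L, p$b1, "+")
  a1 <- relu(z1)
  f <- sweep(a1 %*% t(p$W2), 2L, p$b2, "+")
  list(out = X2 + f, A = at$A,
       cache = list(ln1 = ln1, at = at, ln2 = ln2, z1 = z1, a1 = a1))
}

encoder_layer_bwd <- function(cache, p, dout) {
  df <- dout
  da1 <- df %*% p$W2
  dW2 <- t(df) %*% cache$a1
  db2 <- colSums(df)
  dz1 <- da1 * (cache$z1 > 0)
  dh2 <- dz1 %*% p$W1
  dW1 <- t(dz1) %*% cache$ln2$y
  db1 <- colSums(dz1)
  ln2b <- layernorm_bwd(cache$ln2, dh2)
  dX2 <- dout + ln2b$dx
  atb <- attention_bwd(cache$at, p, dX2)
  ln1b <- layernorm_bwd(cache$ln1, atb$dX)
  list(dX = dX2 + ln1b$dx,
       grads = list(Wq = atb$dWq, Wk = atb$dWk, Wv = atb$dWv,
                    ln1_g = ln1b$dg, ln1_b = ln1b$db,
                    W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    ln2_g = ln2b$dg, ln2_b = ln2b$db))
}

#' Run a stack of self-attention encoder layers
#'
#' Applies `length(layer_params)` single-head encoder layers (attention +
#' residual + feed-forward sublayer) to a token matrix and records each
#' layer's row-stochastic attention matrix for rollout.
#'
#' @param tokens `(HL+1) x D` token matrix, CLS token in row 1 (see
#'   [tokenize()]).
#' @param layer_params list of per-layer parameter lists (fields `Wq`,
#'   `Wk`, `Wv`, `ln1_g`, `ln1_b`, `W1`, `b1`, `W2`, `b2`, `ln2_g`,
#'   `ln2_b`).
#' @return list with `tokens` (final token matrix) and `trace` (list of
#'   attention weight matrices, first to last layer).
#' @export
encoder_forward <- function(tokens, layer_params) {
  if (!length(layer_params)) stop("at least one encoder layer is required")
  trace <- vector("list", length(layer_params))
  X <- tokens
  for (l in seq_along(layer_params)) {
    r <- encoder_layer_fwd(X, layer_params[[l]])
    X <- r$out
    trace[[l]] <- r$A
  }
  attr(trace, "grid_shape") <- attr(tokens, "grid_shape")
  list(tokens = X, trace = trace)
}

# ---- tokenization --------------------------------------------------------

# feature map (H x L x C) -> row-major HL x C matrix; row (r-1)*L + c is
# feature pixel (r, c)
feature_to_rows <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(2, 1, 3)), d[1] * d[2], d[3])
}

rows_to_feature <- function(M, H, L) {
  aperm(array(M, dim = c(L, H, ncol(M))), c(2, 1, 3))
}

# length-HL row-major vector -> H x L grid (inverse of the token indexing)
vector_to_grid <- function(v, H, L) t(matrix(v, L, H))

#' Tokenize a convolutional feature map
#'
#' Applies a 1 x 1 convolution (a per-pixel linear map `C -> D`) to the
#' backbone's feature map, flattens the `H x L` grid row-major into `HL`
#' tokens, and prepends the learned CLS token, giving the `(HL+1) x D`
#' matrix consumed by the encoder.  Token `1 + (r-1)*L + c` corresponds to
#' feature pixel `(r, c)`; heat-map reshaping inverts exactly this mapping.
#'
#' @param X `H x L x C` feature map.
#' @param proj list with `W` (`D x C`) and `b` (length `D`): the 1 x 1
#'   projection.
#' @param cls length-`D` CLS vector.
#' @return `(HL+1) x D` token matrix with attribute `grid_shape = c(H, L)`.
#' @export
tokenize <- function(X, proj, cls) {
  d <- dim(X)
  if (length(d) != 3L) stop("feature map must be H x L x C")
  if (ncol(proj$W) != d[3]) stop("projection does not match channel count")
  Tm <- sweep(feature_to_rows(X) %*% t(proj$W), 2L, proj$b, "+")
  out <- rbind(matrix(cls, nrow = 1), Tm)
  attr(out, "grid_shape") <- c(H = d[1], L = d[2])
  out
}

tokenize_bwd <- function(X, proj, dtokens) {
  d <- dim(X)
  dcls <- dtokens[1, ]
  dT <- dtokens[-1, , drop = FALSE]
  Xr <- feature_to_rows(X)
  list(dX = rows_to_feature(dT %*% proj$W, d[1], d[2]),
       dW = t(dT) %*% Xr,
       db = colSums(dT),
       dcls = dcls)
}

#' Fuse pathway representations and classify
#'
#' Concatenates the per-task CLS vectors (or pooled feature vectors), maps
#' them through a two-node fully connected layer and applies the softmax,
#' returning `(p_healthy, p_MCI)`.
#'
#' @param cls_vectors list of numeric vectors, one per input pathway.
#' @param weights `2 x sum(lengths)` weight matrix.
#' @param bias length-2 bias.
#' @return named probability vector `c(healthy, mci)` summing to 1.
#' @export
aggregate_and_classify <- function(cls_vectors, weights, bias) {
  u <- unlist(cls_vectors, use.names = FALSE)
  if (ncol(weights) != length(u))
    stop("classifier weights do not match concatenated representation")
  p <- softmax_probs(as.numeric(weights %*% u + bias))
  names(p) <- c("healthy", "mci")
  p
}

# ---- parameter-tree helpers ----------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zero <- function(a) tree_map(function(x) x * 0, a)

tree_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, tree_flatten), use.names = FALSE)
  else as.numeric(a)
}

tree_unflatten <- function(a, v) {
  pos <- 0L
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    n <- length(x)
    out <- x
    out[] <- v[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  rec(a)
}
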