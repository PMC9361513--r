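# Model architecture: backbone shapes, tokenization conventions, attention
# algebra, encoder behavior, fusion/classification, and gradient
# correctness of the hand-written backward pass.

test_that("backbone feature-map shapes follow the stride arithmetic", {
  toy <- make_backbone("toy", seed = 1)
  f <- backbone_forward(toy, array(0.1, c(64, 64, 3)))
  expect_equal(dim(f), c(8, 8, 32))
  expect_true(all(is.finite(backbone_forward(
    toy, array(0, c(64, 64, 3))))))
  vgg <- make_backbone("vgg16", seed = 1)
  expect_equal(dim(backbone_forward(vgg, array(0.05, c(64, 64, 3)))),
               c(2, 2, 512))
  expect_equal(dim(backbone_forward(vgg, array(0.05, c(256, 256, 3)))),
               c(8, 8, 512))
  expect_error(backbone_forward(toy, array(0, c(60, 60, 3))), "multiple")
  expect_error(backbone_forward(toy, matrix(0, 64, 64)), "input array")
})

test_that("tokenization is row-major with CLS in row 1", {
  X <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  proj <- list(W = diag(4), b = rep(0, 4))
  cls <- rnorm(4)
  tok <- tokenize(X, proj, cls)
  expect_equal(dim(tok), c(7, 4))
  expect_equal(tok[1, ], cls)
  # pixel (r, c) (1-based) sits in token row 1 + (r-1)*L + c
  expect_equal(tok[1 + (2 - 1) * 3 + 3, ], X[2, 3, ])
  expect_equal(tok[1 + (1 - 1) * 3 + 2, ], X[1, 2, ])
  # identity projection reproduces the flattened map
  for (r in 1:2) for (cc in 1:3)
    expect_equal(tok[1 + (r - 1) * 3 + cc, ], X[r, cc, ])
  X1 <- array(rnorm(5), c(1, 1, 5))
  expect_equal(nrow(tokenize(X1, list(W = diag(5), b = rep(0, 5)),
                             rnorm(5))), 2)
})

test_that("self-attention matches a brute-force evaluation", {
  withr::with_seed(8, {
    Q <- matrix(rnorm(12), 4, 3)
    K <- matrix(rnorm(12), 4, 3)
    V <- matrix(rnorm(12), 4, 3)
  })
  got <- self_attention(Q, K, V)
  want <- brute_attention(Q, K, V)
  expect_lt(max(abs(got$output - want$output)), 1e-6)
  expect_lt(max(abs(got$weights - want$weights)), 1e-6)
  # singleton: softmax over one key is 1
  s <- self_attention(Q[1, , drop = FALSE], K[1, , drop = FALSE],
                      V[1, , drop = FALSE])
  expect_equal(s$output, V[1, , drop = FALSE])
  # zero queries: uniform weights, rows become column means of V
  z <- self_attention(matrix(0, 4, 3), K, V)
  expect_equal(unname(z$output[2, ]), unname(colMeans(V)))
  expect_true(all(abs(z$weights - 0.25) < 1e-12))
  expect_error(self_attention(Q, K[1:2, ], V), "inconsistent")
})

make_layer <- function(D, Fd) {
  list(Wq = matrix(rnorm(D * D, 0, 0.3), D, D),
       Wk = matrix(rnorm(D * D, 0, 0.3), D, D),
       Wv = matrix(rnorm(D * D, 0, 0.3), D, D),
       ln1_g = rep(1, D), ln1_b = rep(0, D),
       W1 = matrix(rnorm(Fd * D, 0, 0.3), Fd, D), b1 = rep(0, Fd),
       W2 = matrix(rnorm(D * Fd, 0, 0.3), D, Fd), b2 = rep(0, D),
       ln2_g = rep(1, D), ln2_b = rep(0, D))
}

test_that("the encoder records one row-stochastic attention per layer", {
  withr::with_seed(2, {
    tok <- matrix(rnorm(6 * 4), 6, 4)
    layers <- list(make_layer(4, 8), make_layer(4, 8), make_layer(4, 8))
  })
  one <- encoder_forward(tok, layers[1])
  expect_length(one$trace, 1)
  out <- encoder_forward(tok, layers)
  expect_length(out$trace, 3)
  for (A in out$trace) {
    expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-6)
    expect_true(all(A >= 0))
  }
  expect_error(encoder_forward(tok, list()), "at least one")
})

test_that("zeroed attention values and feed-forward give a pure residual", {
  withr::with_seed(3, tok <- matrix(rnorm(5 * 4), 5, 4))
  lay <- make_layer(4, 8)
  lay$Wv <- matrix(0, 4, 4)
  lay$W2 <- matrix(0, 4, 8)
  out <- encoder_forward(tok, list(lay))
  expect_equal(out$tokens, tok, ignore_attr = TRUE)
})

test_that("fusion concatenates and the softmax classifier normalizes", {
  expect_equal(softmax_probs(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax_probs(c(1, 0)), c(0.73106, 0.26894),
               tolerance = 1e-4)
  expect_equal(softmax_probs(c(2, -1)), softmax_probs(c(7, 4)))
  cls <- list(rnorm(3), rnorm(3), rnorm(3))
  W <- matrix(rnorm(18), 2, 9)
  p <- aggregate_and_classify(cls, W, c(0, 0))
  expect_equal(sum(p), 1)
  expect_named(p, c("healthy", "mci"))
  p0 <- aggregate_and_classify(cls, matrix(0, 2, 9), c(0, 0))
  expect_equal(unname(p0), c(0.5, 0.5))
  expect_error(aggregate_and_classify(cls, matrix(0, 2, 5), c(0, 0)),
               "match")
})

test_that("pooling baseline averages features and concatenates pathways", {
  cfg <- conv_att_config(variant = "pooling", inputs = c("clock", "cube",
                                                         "trail"),
                         backbone = "toy", input_size = 32, seed = 5)
  m <- new_conv_att_model(cfg)
  imgs <- lapply(stats::setNames(1:3, c("clock", "cube", "trail")),
                 function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  fw <- convatt:::model_forward(m, imgs)
  expect_length(fw$u, 3 * 32)            # 3 pathways x C channels
  expect_equal(sum(fw$p), 1)
  expect_equal(fw$reps$clock,
               apply(fw$feature_maps$clock, 3, mean))
  p <- pooling_baseline_forward(m, imgs)
  expect_equal(p, fw$p)

  cfg1 <- conv_att_config(variant = "pooling", inputs = "cube",
                          backbone = "toy", input_size = 32, seed = 5)
  m1 <- new_conv_att_model(cfg1)
  expect_silent(pooling_baseline_forward(m1, imgs["cube"]))
  expect_error(convatt:::model_forward(m1, imgs["clock"]), "cube")
})

test_that("forward is deterministic and invariant to pathway relabeling", {
  cfg <- conv_att_config(variant = "conv_att", backbone = "toy",
                         input_size = 32, n_layers = 2, hidden_dim = 16,
                         ffn_dim = 24, seed = 9)
  m <- new_conv_att_model(cfg)
  imgs <- lapply(stats::setNames(1:3, c("clock", "cube", "trail")),
                 function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  f1 <- convatt:::model_forward(m, imgs)
  f2 <- convatt:::model_forward(m, imgs)
  expect_identical(f1$p, f2$p)
  # swap the clock and trail pathways together with their inputs and the
  # matching classifier blocks: the output must not change
  m2 <- m
  m2$pathways <- m$pathways[c("trail", "cube", "clock")]
  names(m2$pathways) <- c("clock", "cube", "trail")
  D <- cfg$hidden_dim
  blocks <- list(1:D, D + 1:D, 2 * D + 1:D)
  m2$classifier$W <- m$classifier$W[, c(blocks[[3]], blocks[[2]],
                                        blocks[[1]])]
  imgs2 <- imgs[c("trail", "cube", "clock")]
  names(imgs2) <- c("clock", "cube", "trail")
  f3 <- convatt:::model_forward(m2, imgs2)
  expect_equal(f3$p, f1$p, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  cfg <- conv_att_config(variant = "conv_att", backbone = "toy",
                         input_size = 16, n_layers = 2, hidden_dim = 8,
                         ffn_dim = 12, seed = 7)
  model <- new_conv_att_model(cfg)
  imgs <- withr::with_seed(42, lapply(
    stats::setNames(1:3, c("clock", "cube", "trail")),
    function(i) array(runif(16 * 16 * 3), c(16, 16, 3))))
  y <- 0.3
  fw <- convatt:::model_forward(model, imgs, keep_cache = TRUE)
  gr <- convatt:::model_backward(model, fw, y)
  params <- convatt:::model_params(model)
  pf <- convatt:::tree_flatten(params)
  gf <- convatt:::tree_flatten(gr)
  lossfn <- function(v) {
    m <- convatt:::model_set_params(model,
                                    convatt:::tree_unflatten(params, v))
    bce_loss(y, convatt:::model_forward(m, imgs)$prob)
  }
  eps <- 1e-5
  idx <- withr::with_seed(1, sort(sample(length(pf), 25)))
  num <- vapply(idx, function(i) {
    v1 <- pf; v2 <- pf
    v1[i] <- v1[i] + eps; v2[i] <- v2[i] - eps
    (lossfn(v1) - lossfn(v2)) / (2 * eps)
  }, numeric(1))
  rel <- abs(num - gf[idx]) / pmax(1e-8, abs(num) + abs(gf[idx]))
  expect_lt(max(rel), 1e-4)
})
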