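# Attention rollout, Grad-CAM, and heat-map binarization.

test_that("raw attention averages the weights with the identity", {
  I4 <- diag(4)
  expect_equal(raw_attention(I4), I4)
  W <- matrix(0.5, 2, 2)
  expect_equal(raw_attention(W), matrix(c(0.75, 0.25, 0.25, 0.75), 2, 2))
  withr::with_seed(1, W5 <- rand_row_stochastic(5))
  A <- raw_attention(W5)
  expect_equal(rowSums(A), rep(1, 5), tolerance = 1e-12)
  expect_error(raw_attention(matrix(0.5, 2, 3)), "square")
  expect_error(raw_attention(matrix(2, 2, 2)), "stochastic")
})

test_that("rollout equals the explicit ordered product of raw attentions", {
  withr::with_seed(4, trace <- lapply(1:3, function(i)
    rand_row_stochastic(5)))
  expect_equal(attention_rollout(trace, 2, 2), raw_attention(trace[[2]]))
  explicit <- raw_attention(trace[[3]]) %*% raw_attention(trace[[2]]) %*%
    raw_attention(trace[[1]])
  expect_lt(max(abs(attention_rollout(trace) - explicit)), 1e-6)
  expect_equal(rowSums(attention_rollout(trace)), rep(1, 5),
               tolerance = 1e-6)
  id_trace <- lapply(1:4, function(i) diag(6))
  expect_equal(attention_rollout(id_trace), diag(6))
  expect_error(attention_rollout(trace, 3, 1), "from_layer")
  expect_error(attention_rollout(list()), "empty")
})

test_that("CLS heat maps invert the tokenization grid indexing", {
  # H = L = 2, CLS row (0.1, 0.2, 0.3, 0.4) over pixel tokens
  R <- diag(5)
  R[1, ] <- c(0, 0.1, 0.2, 0.3, 0.4)
  hm <- cls_heatmap(R, c(2, 2), 2)
  expect_equal(unclass(hm), matrix(c(0.1, 0.3, 0.2, 0.4), 2, 2),
               ignore_attr = TRUE)
  # uniform CLS mass gives a constant map after upsampling
  Ru <- diag(5); Ru[1, ] <- c(0, rep(0.25, 4))
  hu <- cls_heatmap(Ru, c(2, 2), 16)
  expect_lt(diff(range(hu)), 1e-12)
  # all mass on pixel (1, 1): maximum stays in the top-left region
  R1 <- diag(5); R1[1, ] <- c(0, 1, 0, 0, 0)
  h1 <- cls_heatmap(R1, c(2, 2), 16)
  w <- which(h1 == max(h1), arr.ind = TRUE)
  expect_true(all(w[1, ] <= 8))
  expect_error(cls_heatmap(R, c(3, 2), 8), "grid_shape")
})

test_that("token indexing round-trips through the heat-map reshape", {
  X <- array(seq_len(12), c(3, 4, 1))
  rows <- convatt:::feature_to_rows(X)
  for (r in 1:3) for (cc in 1:4)
    expect_equal(rows[(r - 1) * 4 + cc, 1], X[r, cc, 1])
  back <- convatt:::vector_to_grid(rows[, 1], 3, 4)
  expect_equal(back, X[, , 1])
})

test_that("Grad-CAM matches a hand-computed weighted channel sum", {
  feat <- array(0, c(2, 2, 2))
  feat[, , 1] <- matrix(c(1, -2, 3, 4), 2, 2)
  feat[, , 2] <- matrix(c(0, 1, -1, 2), 2, 2)
  grad <- array(0, c(2, 2, 2))
  grad[, , 1] <- 0.5       # alpha_1 = 0.5
  grad[, , 2] <- -1        # alpha_2 = -1
  hm <- convatt:::grad_cam_map(feat, grad, 2)
  want <- pmax(0.5 * feat[, , 1] - 1 * feat[, , 2], 0)
  expect_equal(unclass(hm), want, ignore_attr = TRUE)
  expect_true(all(hm >= 0))
  # zero gradients: all-zero map
  hz <- convatt:::grad_cam_map(feat, array(0, c(2, 2, 2)), 4)
  expect_true(all(hz == 0))
})

test_that("explanation methods are tied to their model variants", {
  imgs <- lapply(stats::setNames(1:3, c("clock", "cube", "trail")),
                 function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  cfg_att <- conv_att_config(variant = "conv_att", backbone = "toy",
                             input_size = 32, hidden_dim = 8, ffn_dim = 12,
                             seed = 2)
  fit_att <- structure(list(model = new_conv_att_model(cfg_att),
                            config = cfg_att), class = "conv_att")
  hms <- rollout_heatmaps(fit_att, imgs)
  expect_named(hms, c("clock", "cube", "trail"))
  expect_true(all(vapply(hms, function(h) all(h >= 0) &&
                           all(dim(h) == 32), logical(1))))
  expect_error(grad_cam(fit_att, imgs), "pooling")

  cfg_gap <- conv_att_config(variant = "pooling", backbone = "toy",
                             input_size = 32, seed = 2)
  fit_gap <- structure(list(model = new_conv_att_model(cfg_gap),
                            config = cfg_gap), class = "conv_att")
  cams <- grad_cam(fit_gap, imgs)
  expect_true(all(vapply(cams, function(h) all(h >= 0), logical(1))))
  expect_error(rollout_heatmaps(fit_gap, imgs), "rollout")
})

test_that("top-k binarization selects the exact pixel count with stable ties", {
  hm <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_true(all(binarize_topk(hm, 100)))
  m50 <- binarize_topk(hm, 50)
  expect_equal(sum(m50), 2)
  expect_true(m50[2, 2] && m50[1, 2])     # values 4 and 3
  cst <- matrix(1, 4, 4)
  m25 <- binarize_topk(cst, 25)
  expect_equal(sum(m25), 4)
  expect_true(all(which(m25) == 1:4))     # tie-break by linear index
  for (k in c(10, 33.3, 50, 80)) {
    for (n in c(5, 8, 13)) {
      hm2 <- matrix(runif(n * n), n, n)
      expect_equal(sum(binarize_topk(hm2, k)),
                   floor(k / 100 * n * n + 0.5))
    }
  }
  expect_error(binarize_topk(hm, 0), "k_percent")
  expect_error(binarize_topk(hm, 101), "k_percent")
})
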