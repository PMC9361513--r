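# Loss, optimizer, and the training loop.

test_that("binary cross-entropy has the stated closed forms and minimum", {
  expect_equal(bce_loss(0.5, 0.5), log(2), tolerance = 1e-6)
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-6)
  expect_equal(bce_loss(c(1, 0), c(1, 0)), 0, tolerance = 1e-5)
  expect_gte(bce_loss(runif(10), runif(10)), 0)
  # grid-search oracle: for y = 0.3 the loss over p is minimized at 0.3
  grid <- seq(0.01, 0.99, by = 0.001)
  vals <- vapply(grid, function(p) bce_loss(0.3, p), numeric(1))
  expect_equal(grid[which.min(vals)], 0.3, tolerance = 2e-3)
  expect_error(bce_loss(c(0.1, 0.2), 0.5), "length")
  expect_error(bce_loss(1.2, 0.5), "0, 1")
})

test_that("the Adam step reproduces the hand-evaluated recurrences", {
  # 1-parameter problem f(w) = w^2, gradient 2w, three steps
  tc <- train_config(learning_rate = 0.1, beta1 = 0.9, beta2 = 0.99,
                     epsilon = 1e-7, epochs = 1, batch_size = 1)
  params <- list(w = 1)
  state <- list(m = list(w = 0), v = list(w = 0), t = 0L)
  got <- numeric(3)
  for (i in 1:3) {
    st <- convatt:::adam_step(params, list(w = 2 * params$w), state, tc)
    params <- st$params; state <- st$state
    got[i] <- params$w
  }
  # independent evaluation of the update rule
  w <- 1; m <- 0; v <- 0; want <- numeric(3)
  for (t in 1:3) {
    g <- 2 * w
    m <- 0.9 * m + 0.1 * g
    v <- 0.99 * v + 0.01 * g^2
    w <- w - 0.1 * (m / (1 - 0.9^t)) / (sqrt(v / (1 - 0.99^t)) + 1e-7)
    want[t] <- w
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("label mode changes the training targets as specified", {
  recs <- score_records(c(24, 25, 30, 10))
  expect_equal(convatt:::subject_labels(recs, "hard"), c(1, 0, 0, 1))
  soft <- convatt:::subject_labels(recs, "soft")
  expect_equal(soft[1], 0.62246, tolerance = 1e-4)
  expect_equal(soft[2], 0.37754, tolerance = 1e-4)
  expect_false(identical(soft, convatt:::subject_labels(recs, "hard")))
})

toy_fit <- local({
  cache <- new.env()
  function() {
    if (is.null(cache$fit)) {
      d <- cohort_dir(n = 16, seed = 13, canvas = 64, noise_sd = 0,
                      severities = rep(c(0.1, 0.9), 8))
      recs <- load_manifest(file.path(d, "manifest.csv"))
      split <- stratified_split(recs, fractions = c(0.5, 0.25, 0.25),
                                seed = 2)
      cfg <- conv_att_config(variant = "conv_att", backbone = "toy",
                             input_size = 32, n_layers = 2,
                             hidden_dim = 16, ffn_dim = 24, seed = 3)
      tc <- train_config(learning_rate = 1e-3, epochs = 30,
                         batch_size = 8, label_mode = "hard",
                         augment_shift = 2, seed = 4)
      cache$fit <- conv_att(recs, split, cfg, tc)
      cache$recs <- recs
    }
    list(fit = cache$fit, recs = cache$recs)
  }
})

test_that("training reduces the loss on a small synthetic cohort", {
  tf <- toy_fit()
  h <- tf$fit$history
  expect_equal(nrow(h), 30)
  expect_lt(h$train_loss[30], h$train_loss[1])
  expect_true(all(is.finite(h$val_loss)))
})

test_that("a one-epoch run emits exactly one history row", {
  d <- cohort_dir(n = 8, seed = 14, canvas = 64, noise_sd = 0,
                  severities = rep(c(0, 1), 4))
  recs <- load_manifest(file.path(d, "manifest.csv"))
  split <- stratified_split(recs, fractions = c(0.5, 0.25, 0.25), seed = 1)
  cfg <- conv_att_config(variant = "conv_att", backbone = "toy",
                         input_size = 32, n_layers = 1, hidden_dim = 8,
                         ffn_dim = 12, seed = 1)
  tc <- train_config(learning_rate = 1e-3, epochs = 1, batch_size = 4,
                     seed = 1)
  fit <- conv_att(recs, split, cfg, tc)
  expect_equal(nrow(fit$history), 1)
  empty_split <- split
  empty_split$partition[empty_split$partition == "validation"] <- "train"
  expect_error(conv_att(recs, empty_split, cfg, tc), "validation")
})

test_that("inference is deterministic, normalized and augmentation-free", {
  tf <- toy_fit()
  p1 <- predict_proba(tf$fit, tf$recs)
  p2 <- predict_proba(tf$fit, tf$recs)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  imgs <- load_and_resize(tf$recs[[1]], 32)
  fw <- convatt:::model_forward(tf$fit$model, imgs)
  expect_equal(sum(fw$p), 1, tolerance = 1e-12)
  expect_equal(unname(fw$p["mci"]), p1[1])
})

test_that("fit methods expose the usual modelling interface", {
  tf <- toy_fit()
  expect_output(print(tf$fit), "conv_att")
  s <- summary(tf$fit)
  expect_gt(s$n_parameters, 1000)
  expect_output(print(s), "parameters")
  cls <- predict(tf$fit, tf$recs[1:4], type = "class")
  expect_true(all(cls %in% 0:1))
  r <- residuals(tf$fit)
  expect_length(r, length(tf$recs))
  expect_true(all(abs(r) <= 1))
  sim <- simulate(tf$fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(length(tf$recs), 2))
  expect_identical(sim, simulate(tf$fit, nsim = 2, seed = 1))
})
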