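# Independent oracles used across tests: these deliberately re-derive
# quantities by enumeration or brute force, not via the package internals.

# connected components of a binary matrix under 4-connectivity (flood fill)
flood_count <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j] || seen[i, j]) next
      n <- n + 1L
      queue <- list(c(i, j))
      seen[i, j] <- TRUE
      while (length(queue)) {
        p <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
              q[2] <= ncol(mask) && mask[q[1], q[2]] && !seen[q[1], q[2]]) {
            seen[q[1], q[2]] <- TRUE
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  n
}

# confusion-matrix metrics + pairwise AUC by explicit enumeration
enum_metrics <- function(p, labels) {
  pred <- ifelse(p >= 0.5, 1, 0)
  acc <- mean(pred == labels)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  pos <- p[labels == 1]; neg <- p[labels == 0]
  cmp <- 0
  for (a in pos) for (b in neg)
    cmp <- cmp + if (a > b) 1 else if (a == b) 0.5 else 0
  c(accuracy = acc, f1 = f1, auc = cmp / (length(pos) * length(neg)))
}

# step-by-step scaled dot-product attention
brute_attention <- function(Q, K, V) {
  n <- nrow(Q); D <- ncol(Q)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    logits <- sapply(seq_len(n), function(j) sum(Q[i, ] * K[j, ]) / sqrt(D))
    e <- exp(logits - max(logits))
    W[i, ] <- e / sum(e)
  }
  list(output = W %*% V, weights = W)
}

rand_row_stochastic <- function(n) {
  m <- matrix(runif(n * n), n, n)
  m / rowSums(m)
}

# minimal in-memory subject records with given MoCA scores (no images);
# enough for splitting/labeling tests
score_records <- function(scores) {
  lapply(seq_along(scores), function(i)
    list(subject_id = sprintf("X%04d", i), image_paths = NULL,
         moca_score = as.integer(scores[i]), mask_paths = NULL))
}

# small synthetic cohort on disk, cached per test session
cohort_dir <- local({
  cache <- new.env()
  function(n = 12, seed = 7, canvas = 64, noise_sd = 0,
           severities = NULL) {
    key <- paste(n, seed, canvas, noise_sd,
                 paste(severities, collapse = ","), sep = "_")
    if (is.null(cache[[key]])) {
      d <- file.path(tempdir(), paste0("cohort_", key))
      sev <- if (is.null(severities)) stats::runif else severities
      generate_cohort(n, sev, d, rng_seed = seed, canvas_size = canvas,
                      noise_sd = noise_sd)
      cache[[key]] <- d
    }
    cache[[key]]
  }
})
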