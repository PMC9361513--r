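# Evaluation: thresholded classification metrics with rank-based AUC,
# repeated-split reporting, ROI construction, and IoU scoring of heat maps.

rank_auc <- function(p, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(p, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from predicted probabilities
#'
#' Subjects with `p >= 0.5` are classified as MCI (the boundary counts as
#' MCI).  Accuracy and F1 (MCI as the positive class) come from the
#' thresholded confusion matrix; AUC is the rank-based (Mann-Whitney)
#' statistic with ties counted one half.
#'
#' @param p predicted MCI probabilities.
#' @param labels hard labels (1 = MCI, 0 = healthy); both classes must be
#'   present for the AUC.
#' @return named vector `c(accuracy, f1, auc)`.
#' @export
classification_metrics <- function(p, labels) {
  if (length(p) != length(labels)) stop("p and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("AUC undefined: only one class present")
  pred <- as.integer(p >= 0.5)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  c(accuracy = mean(pred == labels), f1 = f1, auc = rank_auc(p, labels))
}

#' Metrics over repeated random splits
#'
#' Repeats the full cycle -- stratified split, training, test-set
#' evaluation -- once per seed and reports the per-split metrics with their
#' mean and standard deviation.
#'
#' @param records subject records.
#' @param config model configuration ([conv_att_config()]).
#' @param training training configuration ([train_config()]).
#' @param n_repeats number of repetitions (default 5).
#' @param seeds distinct integer seeds, one per repetition (default
#'   `1:n_repeats`).
#' @return object of class `metrics_report`: list with `per_split` (data
#'   frame seed/accuracy/f1/auc) and `summary` (mean and sd per metric).
#' @export
repeated_splits_report <- function(records, config = conv_att_config(),
                                   training = train_config(),
                                   n_repeats = 5, seeds = seq_len(n_repeats)) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (length(seeds) != n_repeats) stop("need one seed per repetition")
  if (anyDuplicated(seeds)) stop("split seeds must be distinct")
  rows <- lapply(seeds, function(s) {
    split <- stratified_split(records, seed = s, cutoff = training$cutoff)
    tr <- training
    tr$seed <- derive_seed(s, "train")
    fit <- conv_att(records, split, config, tr)
    idx_test <- partition_indices(records, split, "test")
    p <- predict_proba(fit, records[idx_test])
    labs <- hard_label(vapply(records[idx_test], function(r) r$moca_score,
                              numeric(1)), training$cutoff)
    m <- classification_metrics(p, labs)
    data.frame(seed = s, accuracy = m["accuracy"], f1 = m["f1"],
               auc = m["auc"], row.names = NULL)
  })
  per_split <- do.call(rbind, rows)
  sd0 <- function(x) if (length(x) < 2L) 0 else sd(x)
  summary <- data.frame(
    metric = c("accuracy", "f1", "auc"),
    mean = c(mean(per_split$accuracy), mean(per_split$f1),
             mean(per_split$auc)),
    sd = c(sd0(per_split$accuracy), sd0(per_split$f1), sd0(per_split$auc)))
  structure(list(per_split = per_split, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Metrics over", nrow(x$per_split), "split(s):\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-8s %.4f +/- %.4f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}

# ---- enclosing shapes ----------------------------------------------------

# minimal enclosing circle (incremental Welzl); pts is n x 2 (x, y)
min_circle <- function(pts) {
  circ2 <- function(a, b) {
    c(cx = (a[1] + b[1]) / 2, cy = (a[2] + b[2]) / 2,
      r = sqrt(sum((a - b)^2)) / 2)
  }
  circ3 <- function(a, b, c3) {
    ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c3[1]; cy <- c3[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(cx = ux, cy = uy, r = sqrt((ax - ux)^2 + (ay - uy)^2))
  }
  inside <- function(circ, p) {
    !is.null(circ) && sqrt((p[1] - circ[1])^2 + (p[2] - circ[2])^2) <=
      circ[3] + 1e-7
  }
  n <- nrow(pts)
  D <- c(cx = pts[1, 1], cy = pts[1, 2], r = 0)
  for (i in seq_len(n)) {
    if (inside(D, pts[i, ])) next
    D <- c(cx = pts[i, 1], cy = pts[i, 2], r = 0)
    for (j in seq_len(i - 1L)) {
      if (inside(D, pts[j, ])) next
      D <- circ2(pts[i, ], pts[j, ])
      for (k in seq_len(j - 1L)) {
        if (inside(D, pts[k, ])) next
        cand <- circ3(pts[i, ], pts[j, ], pts[k, ])
        if (is.null(cand)) {
          # collinear triple: take the widest pairwise circle
          cand <- circ2(pts[i, ], pts[k, ])
          for (pr in list(list(pts[i, ], pts[j, ]), list(pts[j, ], pts[k, ]))) {
            cc <- circ2(pr[[1]], pr[[2]])
            if (cc[3] > cand[3]) cand <- cc
          }
        }
        D <- cand
      }
    }
  }
  D
}

# minimum-volume enclosing ellipse via Khachiyan's algorithm; returns
# center c (x, y) and shape matrix A with (p - c)' A (p - c) <= 1
min_ellipse <- function(pts, tol = 1e-3, maxit = 500L) {
  P <- t(pts)                      # 2 x n
  n <- ncol(P)
  Q <- rbind(P, 1)
  u <- rep(1 / n, n)
  for (it in seq_len(maxit)) {
    Xm <- Q %*% (u * t(Q))
    M <- colSums(Q * solve(Xm, Q))
    j <- which.max(M)
    if (M[j] - 3 < tol) break
    step <- (M[j] - 3) / (3 * (M[j] - 1))
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  ctr <- as.numeric(P %*% u)
  A <- solve(P %*% (u * t(P)) - ctr %*% t(ctr)) / 2
  list(center = ctr, A = A)
}

#' Whole-drawing region of interest
#'
#' Fits the smallest simple shape (circle, ellipse, or convex polygon)
#' enclosing every ink pixel of a white-background drawing (ink = intensity
#' below `ink_threshold`), then enlarges it by `margin_px` pixels of
#' Euclidean dilation.
#'
#' @param image grayscale matrix in \[0, 1\], dark strokes on white.
#' @param shape_kind `"circle"`, `"ellipse"` or `"polygon"` (convex hull).
#' @param margin_px dilation margin in pixels (default 5).
#' @param ink_threshold intensity below which a pixel counts as ink.
#' @return logical mask of the same shape, covering all ink pixels, with
#'   attribute `roi_type = "whole_drawing"`.
#' @export
whole_drawing_roi <- function(image, shape_kind = c("circle", "ellipse",
                                                    "polygon"),
                              margin_px = 5, ink_threshold = 0.5) {
  shape_kind <- match.arg(shape_kind)
  ink <- which(image < ink_threshold, arr.ind = TRUE)
  if (!nrow(ink)) stop("blank image: no ink pixels below the threshold")
  pts <- cbind(x = ink[, 2], y = ink[, 1])
  H <- nrow(image); W <- ncol(image)
  gx <- rep(seq_len(W), each = H)
  gy <- rep(seq_len(H), times = W)
  hull <- unique(pts[chull(pts[, 1], pts[, 2]), , drop = FALSE])
  member <- switch(shape_kind,
    circle = {
      D <- min_circle(hull)
      (gx - D[1])^2 + (gy - D[2])^2 <= (D[3] + 1e-7)^2
    },
    ellipse = {
      if (nrow(hull) < 3L) {
        D <- min_circle(hull)
        (gx - D[1])^2 + (gy - D[2])^2 <= (D[3] + 1e-7)^2
      } else {
        el <- tryCatch(min_ellipse(hull), error = function(e) NULL)
        if (is.null(el)) {
          D <- min_circle(hull)
          (gx - D[1])^2 + (gy - D[2])^2 <= (D[3] + 1e-7)^2
        } else {
          dx <- gx - el$center[1]; dy <- gy - el$center[2]
          el$A[1, 1] * dx^2 + 2 * el$A[1, 2] * dx * dy +
            el$A[2, 2] * dy^2 <= 1 + 1e-6
        }
      }
    },
    polygon = {
      if (nrow(hull) < 3L) rep(FALSE, length(gx)) else
        mgcv::in.out(rbind(hull, hull[1, ]), cbind(gx, gy))
    })
  mask <- matrix(member, H, W)
  mask[image < ink_threshold] <- TRUE   # enclosure is exact for ink pixels
  if (margin_px > 0) {
    dd <- as.matrix(EBImage::distmap(1 - mask))
    mask <- dd <= margin_px
  }
  attr(mask, "roi_type") <- "whole_drawing"
  mask
}

#' Intersection over union of two binary masks
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both masks are empty.
#'
#' @param mask_a,mask_b binary (logical or 0/1) matrices of equal shape.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks differ in shape")
  a <- mask_a > 0.5; b <- mask_b > 0.5
  un <- sum(a | b)
  if (un == 0) return(0)
  sum(a & b) / un
}

#' Mean IoU as a function of the binarization percentage
#'
#' For each `k`, binarizes every heat map to its top `k` percent of pixels
#' and averages the IoU against the paired ROI mask.
#'
#' @param heatmaps list of heat-map matrices.
#' @param roi_masks list of binary ROI masks, paired with `heatmaps`.
#' @param k_values percentages to evaluate (default 10, 20, ..., 80).
#' @return data frame with columns `k`, `mean_iou`, `sd_iou`.
#' @export
iou_curve <- function(heatmaps, roi_masks, k_values = seq(10, 80, by = 10)) {
  if (!length(heatmaps) || length(heatmaps) != length(roi_masks))
    stop("heatmaps and roi_masks must be nonempty and paired")
  rows <- lapply(k_values, function(k) {
    vals <- mapply(function(hm, roi) iou(binarize_topk(hm, k), roi),
                   heatmaps, roi_masks)
    data.frame(k = k, mean_iou = mean(vals),
               sd_iou = if (length(vals) < 2L) 0 else sd(vals))
  })
  do.call(rbind, rows)
}

#' Paired IoU comparison against spatially permuted heat maps
#'
#' Localization check used on synthetic cohorts: for every record whose
#' anomaly mask is nonempty, the top-`k_percent` rollout heat map of each
#' task is scored by IoU against the anomaly (expert-type) ROI and compared
#' with the same heat map after a random permutation of its feature-grid
#' cells (which preserves the value distribution but destroys
#' localization).
#'
#' @param object a fitted conv-att model.
#' @param records subject records carrying mask paths.
#' @param k_percent binarization percentage (default 20).
#' @param seed seed for the grid permutations.
#' @return data frame with one row per scored task image: `subject_id`,
#'   `task`, `iou_own`, `iou_permuted`.
#' @export
rollout_permutation_iou <- function(object, records, k_percent = 20,
                                    seed = 1L) {
  stopifnot(inherits(object, "conv_att"))
  size <- object$config$input_size
  rows <- list()
  for (r in records) {
    masks <- load_masks(r, size)
    if (is.null(masks)) next
    images <- load_and_resize(r, size)
    fw <- model_forward(object$model, images[object$config$inputs])
    for (task in object$config$inputs) {
      mask <- masks[[task]]
      if (is.null(mask) || !any(mask)) next
      tr <- fw$trace[[task]]
      gs <- attr(tr, "grid_shape")
      v <- attention_rollout(tr)[1, -1]
      vperm <- with_seed(derive_seed(seed, r$subject_id, task), sample(v))
      hm_own <- resize_bilinear(vector_to_grid(v, gs[1], gs[2]), size, size)
      hm_perm <- resize_bilinear(vector_to_grid(vperm, gs[1], gs[2]),
                                 size, size)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = r$subject_id, task = task,
        iou_own = iou(binarize_topk(hm_own, k_percent), mask),
        iou_permuted = iou(binarize_topk(hm_perm, k_percent), mask))
    }
  }
  if (!length(rows)) stop("no records with nonempty anomaly masks")
  do.call(rbind, rows)
}
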