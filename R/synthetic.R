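# Synthetic drawing-task generator.
#
# Emulates the three pen-drawing screening tasks (clock drawing, cube
# copying, trail making) as anti-aliased dark strokes on a white canvas,
# injects enumerated, mask-annotated "abnormalities" whose number and size
# grow with a severity parameter in [0, 1], and links severity to a
# MoCA-like 0-30 score.  Every operation is deterministic under its seed,
# so generated cohorts serve as reproducible fixtures for the full
# classification + interpretability pipeline.

# ---- soft rasterizer ------------------------------------------------------
# Ink images are matrices (rows = y, cols = x) with ink intensity in [0, 1];
# a finished drawing is 1 - ink (white background, dark strokes).  Strokes
# get a ~1 px soft edge from the distance transform, mimicking anti-aliased
# tablet capture.

ink_blank <- function(S) matrix(0, S, S)

soft_edge <- function(d, half_w) pmin(1, pmax(0, half_w + 0.5 - d))

ink_disc <- function(S, cx, cy, r) {
  xr <- max(1L, floor(cx - r - 1)):min(S, ceiling(cx + r + 1))
  yr <- max(1L, floor(cy - r - 1)):min(S, ceiling(cy + r + 1))
  if (!length(xr) || !length(yr)) return(ink_blank(S))
  d <- sqrt(outer((yr - cy)^2, (xr - cx)^2, "+"))
  out <- ink_blank(S)
  out[yr, xr] <- pmin(1, pmax(0, r + 0.5 - d))
  out
}

ink_ring <- function(S, cx, cy, r, w) {
  xr <- max(1L, floor(cx - r - w)):min(S, ceiling(cx + r + w))
  yr <- max(1L, floor(cy - r - w)):min(S, ceiling(cy + r + w))
  d <- abs(sqrt(outer((yr - cy)^2, (xr - cx)^2, "+")) - r)
  out <- ink_blank(S)
  out[yr, xr] <- soft_edge(d, w / 2)
  out
}

ink_segment <- function(S, x0, y0, x1, y1, w) {
  pad <- w + 1
  xr <- max(1L, floor(min(x0, x1) - pad)):min(S, ceiling(max(x0, x1) + pad))
  yr <- max(1L, floor(min(y0, y1) - pad)):min(S, ceiling(max(y0, y1) + pad))
  px <- rep(xr, each = length(yr))
  py <- rep(yr, times = length(xr))
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx * vx + vy * vy
  t <- if (len2 == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - x0) * vx + (py - y0) * vy) / len2))
  d <- sqrt((px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2)
  out <- ink_blank(S)
  out[yr, xr] <- matrix(soft_edge(d, w / 2), nrow = length(yr))
  out
}

render_element <- function(S, el) {
  switch(el$kind,
    ring = ink_ring(S, el$cx, el$cy, el$r, el$w),
    disc = ink_disc(S, el$cx, el$cy, el$r),
    seg  = ink_segment(S, el$x0, el$y0, el$x1, el$y1, el$w),
    stop("unknown element kind: ", el$kind)
  )
}

# binary locus of an element (or ink matrix): where it leaves visible ink
ink_locus <- function(ink) ink > 0.02

default_stroke_params <- function(canvas_size, stroke_params = list()) {
  defaults <- list(
    stroke_width  = max(1.2, 0.010 * canvas_size),
    jitter_sd     = 0.005 * canvas_size,
    n_trail_nodes = 8L,
    # class-independent normal variation, emulating healthy inter-subject
    # variability: per-drawing pen-width variation (global, so no single
    # image region is spuriously informative) and, optionally, faint
    # specks/smudges of tablet capture (off by default: they add local
    # structure unrelated to the drawing)
    width_jitter  = 0.2,
    speck_rate    = 0,
    speck_max_intensity = 0.55
  )
  unknown <- setdiff(names(stroke_params), names(defaults))
  if (length(unknown))
    stop("unknown stroke parameter(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, stroke_params)
}

# ---- task geometry --------------------------------------------------------
# Idealized layouts in canvas fractions; per-drawing jitter is applied to
# positions when a drawing is rendered.  The same geometry drives anomaly
# injection, so omission masks can cover "where the element should be".

task_geometry <- function(task_kind, canvas_size, params, jitter_sd = 0) {
  check_task_kind(task_kind)
  S <- canvas_size
  w <- params$stroke_width *
    runif(1, 1 - params$width_jitter, 1 + params$width_jitter)
  params$stroke_width <- w      # anomaly strokes match the drawing's pen
  jit <- function(n = 1L) rnorm(n, 0, jitter_sd)
  els <- list()
  if (task_kind == "clock") {
    cx <- 0.5 * S + jit(); cy <- 0.5 * S + jit(); r <- 0.42 * S
    els[[length(els) + 1L]] <- list(kind = "ring", role = "face",
                                    cx = cx, cy = cy, r = r, w = w)
    for (h in 1:12) {
      th <- (h * 30 - 90) * pi / 180
      els[[length(els) + 1L]] <- list(
        kind = "disc", role = "digit", index = h,
        cx = cx + 0.34 * S * cos(th) + jit(),
        cy = cy + 0.34 * S * sin(th) + jit(),
        r = 0.020 * S)
    }
    # hands drawn at "ten past eleven"
    for (hand in c("hour", "minute")) {
      ang <- if (hand == "hour") ((11 + 10 / 60) * 30 - 90) else (10 * 6 - 90)
      ang <- (ang + rnorm(1, 0, jitter_sd)) * pi / 180
      len <- if (hand == "hour") 0.18 * S else 0.30 * S
      els[[length(els) + 1L]] <- list(
        kind = "seg", role = "hand", which = hand,
        x0 = cx, y0 = cy,
        x1 = cx + len * cos(ang), y1 = cy + len * sin(ang), w = 1.3 * w)
    }
  } else if (task_kind == "cube") {
    fx <- c(0.28, 0.60, 0.60, 0.28) * S + jit(4)
    fy <- c(0.36, 0.36, 0.68, 0.68) * S + jit(4)
    bx <- fx + 0.14 * S + jit(4); by <- fy - 0.14 * S + jit(4)
    vx <- c(fx, bx); vy <- c(fy, by)
    edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                   c(5, 6), c(6, 7), c(7, 8), c(8, 5),
                   c(1, 5), c(2, 6), c(3, 7), c(4, 8))
    for (e in seq_len(nrow(edges))) {
      i <- edges[e, 1]; j <- edges[e, 2]
      els[[length(els) + 1L]] <- list(
        kind = "seg", role = "edge", index = e,
        x0 = vx[i], y0 = vy[i], x1 = vx[j], y1 = vy[j], w = w)
    }
    attr(els, "vertices") <- cbind(x = vx, y = vy)
  } else { # trail
    layout <- rbind(
      c(0.15, 0.20), c(0.55, 0.12), c(0.85, 0.30), c(0.65, 0.55),
      c(0.88, 0.82), c(0.45, 0.85), c(0.15, 0.75), c(0.30, 0.45))
    labels <- c("1", "A", "2", "B", "3", "C", "4", "D")
    n <- min(params$n_trail_nodes, nrow(layout))
    px <- layout[seq_len(n), 1] * S + jit(n)
    py <- layout[seq_len(n), 2] * S + jit(n)
    for (i in seq_len(n)) {
      els[[length(els) + 1L]] <- list(
        kind = "disc", role = "node", index = i, label = labels[i],
        cx = px[i], cy = py[i], r = 0.035 * S)
    }
    node_r <- 0.035 * S
    for (i in seq_len(n - 1)) {
      # connection segments trimmed back so nodes stay visually distinct
      dx <- px[i + 1] - px[i]; dy <- py[i + 1] - py[i]
      len <- sqrt(dx^2 + dy^2); ux <- dx / len; uy <- dy / len
      els[[length(els) + 1L]] <- list(
        kind = "seg", role = "connection", index = i,
        x0 = px[i] + ux * node_r * 1.3, y0 = py[i] + uy * node_r * 1.3,
        x1 = px[i + 1] - ux * node_r * 1.3, y1 = py[i + 1] - uy * node_r * 1.3,
        w = w)
    }
    attr(els, "nodes") <- cbind(x = px, y = py)
  }
  structure(list(task_kind = task_kind, canvas_size = S, params = params,
                 elements = els), class = "task_geometry")
}

# faint class-independent clutter: specks and short light strokes, drawn
# from the current RNG stream
render_clutter <- function(S, params) {
  ink <- ink_blank(S)
  n_specks <- rpois(1, params$speck_rate)
  for (i in seq_len(n_specks)) {
    ink <- pmax(ink, runif(1, 0.25, params$speck_max_intensity) *
                  ink_disc(S, runif(1, 0.05, 0.95) * S,
                           runif(1, 0.05, 0.95) * S,
                           runif(1, 0.003, 0.008) * S))
  }
  n_smudge <- rpois(1, params$speck_rate / 4)
  for (i in seq_len(n_smudge)) {
    x0 <- runif(1, 0.1, 0.9) * S; y0 <- runif(1, 0.1, 0.9) * S
    ang <- runif(1, 0, 2 * pi); len <- runif(1, 0.03, 0.08) * S
    ink <- pmax(ink, runif(1, 0.3, 0.5) *
                  ink_segment(S, x0, y0, x0 + len * cos(ang),
                              y0 + len * sin(ang),
                              0.6 * params$stroke_width))
  }
  ink
}

render_geometry <- function(geo) {
  S <- geo$canvas_size
  total <- ink_blank(S)
  layers <- list()
  for (el in geo$elements) {
    ink <- render_element(S, el)
    total <- pmax(total, ink)
    layers[[el$role]] <- if (is.null(layers[[el$role]])) ink
                         else pmax(layers[[el$role]], ink)
  }
  list(ink = total, layers = layers)
}

# ---- exported generator operations ---------------------------------------

#' Render an idealized drawing-task image
#'
#' Draws a defect-free clock face (circle, 12 digit blobs, hour and minute
#' hands), a Necker-cube wireframe (12 edges), or a trail-making sheet
#' (labeled node blobs connected in the correct 1-A-2-B-... order) as dark
#' anti-aliased strokes on a white canvas.  Small positional jitter (seeded)
#' makes repeated subjects distinct while keeping the layout canonical.
#'
#' @param task_kind one of `"clock"`, `"cube"`, `"trail"`.
#' @param canvas_size side length in pixels (>= 64).
#' @param stroke_params optional list overriding `stroke_width` (px),
#'   `jitter_sd` (px), `n_trail_nodes`, `width_jitter` (relative
#'   per-drawing pen-width variation), `speck_rate` (mean count of faint
#'   specks), `speck_max_intensity`.  The variation entries emulate
#'   class-independent differences between subjects' normal drawings.
#' @param rng_seed integer seed; identical seeds give bit-identical images.
#' @return a `canvas_size` x `canvas_size` matrix in \[0, 1\] (1 = white
#'   background), with attributes `task_kind`, `geometry` (element layout)
#'   and `layers` (per-role binary ink masks, e.g. `nodes` for trail).
#' @export
make_base_drawing <- function(task_kind, canvas_size = 256,
                              stroke_params = list(), rng_seed = 1L) {
  check_task_kind(task_kind)
  if (!is_count(canvas_size) || canvas_size < 64)
    stop("canvas_size must be an integer >= 64")
  params <- default_stroke_params(canvas_size, stroke_params)
  rendered <- with_seed(rng_seed, {
    geo <- task_geometry(task_kind, canvas_size, params,
                         jitter_sd = params$jitter_sd)
    r <- render_geometry(geo)
    r$ink <- pmax(r$ink, render_clutter(canvas_size, geo$params))
    list(geo = geo, r = r)
  })
  geo <- rendered$geo; r <- rendered$r
  img <- 1 - pmin(r$ink, 1)
  attr(img, "task_kind") <- task_kind
  attr(img, "geometry") <- geo
  attr(img, "layers") <- lapply(r$layers, ink_locus)
  img
}

# one anomaly entry: returns list(ink = ink to draw or NULL,
#                                 erase = binary locus to blank or NULL,
#                                 mask  = binary annotation mask,
#                                 kind  = anomaly_kind)
anomaly_catalog <- function(task_kind) {
  switch(task_kind,
    clock = c("hand_misplaced", "digit_missing", "digit_duplicated",
              "stray_stroke"),
    cube  = c("edge_broken", "edge_extra", "corner_gap", "stray_stroke"),
    trail = c("connection_wrong", "connection_omitted", "node_duplicated",
              "stray_stroke"))
}

pick_element <- function(geo, role) {
  idx <- which(vapply(geo$elements, function(e) identical(e$role, role),
                      logical(1)))
  geo$elements[[idx[sample.int(length(idx), 1L)]]]
}

apply_one_anomaly <- function(kind, geo, severity) {
  S <- geo$canvas_size
  w <- geo$params$stroke_width
  mag <- 0.5 + 0.5 * severity       # defect extent grows with severity
  draw <- NULL; erase <- NULL
  if (kind == "hand_misplaced") {
    el <- pick_element(geo, "hand")
    erase <- ink_locus(render_element(S, el))
    ang <- atan2(el$y1 - el$y0, el$x1 - el$x0) +
      (pi / 2 + runif(1, -0.4, 0.4)) * sample(c(-1, 1), 1)
    len <- sqrt((el$x1 - el$x0)^2 + (el$y1 - el$y0)^2) * mag
    draw <- ink_segment(S, el$x0, el$y0, el$x0 + len * cos(ang),
                        el$y0 + len * sin(ang), el$w)
  } else if (kind == "digit_missing") {
    el <- pick_element(geo, "digit")
    erase <- ink_locus(ink_disc(S, el$cx, el$cy, el$r * 2))
  } else if (kind == "digit_duplicated") {
    el <- pick_element(geo, "digit")
    ang <- runif(1, 0, 2 * pi)
    off <- 0.07 * S * mag
    draw <- ink_disc(S, el$cx + off * cos(ang), el$cy + off * sin(ang), el$r)
  } else if (kind == "edge_broken") {
    el <- pick_element(geo, "edge")
    f0 <- runif(1, 0.2, 0.5); f1 <- min(0.95, f0 + 0.25 * mag)
    gx0 <- el$x0 + f0 * (el$x1 - el$x0); gy0 <- el$y0 + f0 * (el$y1 - el$y0)
    gx1 <- el$x0 + f1 * (el$x1 - el$x0); gy1 <- el$y0 + f1 * (el$y1 - el$y0)
    erase <- ink_locus(ink_segment(S, gx0, gy0, gx1, gy1, 2.5 * el$w))
  } else if (kind == "edge_extra") {
    v <- attr(geo$elements, "vertices")
    ij <- sample.int(nrow(v), 2L)
    draw <- ink_segment(S, v[ij[1], 1], v[ij[1], 2],
                        v[ij[2], 1], v[ij[2], 2], w)
  } else if (kind == "corner_gap") {
    v <- attr(geo$elements, "vertices")
    i <- sample.int(nrow(v), 1L)
    erase <- ink_locus(ink_disc(S, v[i, 1], v[i, 2], 0.05 * S * mag))
  } else if (kind == "connection_wrong") {
    nd <- attr(geo$elements, "nodes")
    n <- nrow(nd)
    repeat {
      ij <- sort(sample.int(n, 2L))
      if (ij[2] - ij[1] > 1) break
    }
    draw <- ink_segment(S, nd[ij[1], 1], nd[ij[1], 2],
                        nd[ij[2], 1], nd[ij[2], 2], w)
  } else if (kind == "connection_omitted") {
    el <- pick_element(geo, "connection")
    erase <- ink_locus(ink_segment(S, el$x0, el$y0, el$x1, el$y1, 2 * el$w))
  } else if (kind == "node_duplicated") {
    el <- pick_element(geo, "node")
    ang <- runif(1, 0, 2 * pi)
    off <- 0.09 * S * mag
    draw <- ink_disc(S, el$cx + off * cos(ang), el$cy + off * sin(ang), el$r)
  } else if (kind == "stray_stroke") {
    x0 <- runif(1, 0.2, 0.8) * S; y0 <- runif(1, 0.2, 0.8) * S
    ang <- runif(1, 0, 2 * pi)
    len <- (0.08 + 0.15 * severity) * S
    x1 <- min(S - 1, max(2, x0 + len * cos(ang)))
    y1 <- min(S - 1, max(2, y0 + len * sin(ang)))
    draw <- ink_segment(S, x0, y0, x1, y1, w)
  } else stop("unknown anomaly kind: ", kind)
  mask <- matrix(FALSE, S, S)
  if (!is.null(draw)) mask <- mask | ink_locus(draw)
  if (!is.null(erase)) mask <- mask | erase
  list(kind = kind, draw = draw, erase = erase, mask = mask)
}

#' Inject severity-scaled drawing abnormalities
#'
#' Applies defects from a fixed per-task catalog (e.g. misplaced clock
#' hands, missing/duplicated digits, broken cube edges, wrong or omitted
#' trail connections, stray strokes).  Each catalog entry is applied
#' independently with probability `severity`, and defect extent also grows
#' with severity, so the expected abnormal area is monotone in severity.
#' Masks of omission defects cover the locus where the erased element should
#' have been drawn.
#'
#' @param image a drawing from [make_base_drawing()] (white background).
#' @param task_kind task of the drawing (used when the image carries no
#'   geometry attribute).
#' @param severity real in \[0, 1\]; 0 returns the input untouched.
#' @param rng_seed integer seed.
#' @return list with `image` (modified drawing), `mask` (binary matrix
#'   covering all modified or omitted pixels) and `applied_specs` (one
#'   record per injected defect: `task_kind`, `anomaly_kind`, `location`
#'   bounding box `c(xmin, ymin, xmax, ymax)`, `severity_weight`).
#' @export
inject_anomalies <- function(image, task_kind, severity, rng_seed = 1L) {
  check_task_kind(task_kind)
  if (!is.numeric(severity) || length(severity) != 1L || is.na(severity) ||
      severity < 0 || severity > 1)
    stop("severity must be a single number in [0, 1]")
  S <- nrow(image)
  mask <- matrix(FALSE, S, S)
  if (severity == 0)
    return(list(image = image, mask = mask, applied_specs = list()))
  geo <- attr(image, "geometry")
  if (is.null(geo)) {
    params <- default_stroke_params(S)
    geo <- task_geometry(task_kind, S, params, jitter_sd = 0)
  }
  img <- image
  specs <- list()
  with_seed(rng_seed, {
    catalog <- anomaly_catalog(task_kind)
    apply_flags <- runif(length(catalog)) < severity
    for (k in seq_along(catalog)) {
      if (!apply_flags[k]) next
      a <- apply_one_anomaly(catalog[k], geo, severity)
      if (!is.null(a$erase)) img[a$erase] <- 1
      if (!is.null(a$draw)) img <- pmin(img, 1 - a$draw)
      mask <- mask | a$mask
      loc <- which(a$mask, arr.ind = TRUE)
      specs[[length(specs) + 1L]] <- list(
        task_kind = task_kind, anomaly_kind = a$kind,
        location = c(xmin = min(loc[, 2]), ymin = min(loc[, 1]),
                     xmax = max(loc[, 2]), ymax = max(loc[, 1])),
        severity_weight = severity)
    }
  })
  attributes(img) <- attributes(image)
  list(image = img, mask = mask, applied_specs = specs)
}

#' Map drawing severity to a MoCA-like screening score
#'
#' `score = clip(round(30 - 12 * severity + e), 0, 30)` with
#' `e ~ Normal(0, noise_sd)`.  The slope of 12 places severity 0.5 at score
#' 24, just below the usual impairment cutoff of 25, so mid-range severities
#' probe the decision boundary.  With `noise_sd = 0` the mapping is
#' deterministic and nonincreasing in severity.
#'
#' @param severity numeric vector in \[0, 1\].
#' @param noise_sd standard deviation of the additive score noise (>= 0).
#' @param rng_seed optional integer seed for the noise draws.
#' @return integer scores in 0..30.
#' @export
severity_to_moca <- function(severity, noise_sd = 1, rng_seed = NULL) {
  if (!is.numeric(severity) || any(is.na(severity)) ||
      any(severity < 0 | severity > 1))
    stop("severity must lie in [0, 1]")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("noise_sd must be >= 0")
  eps <- if (noise_sd == 0) rep(0, length(severity))
         else with_seed(rng_seed, rnorm(length(severity), 0, noise_sd))
  as.integer(pmin(30, pmax(0, round(30 - 12 * severity + eps))))
}

#' Generate a synthetic cohort on disk
#'
#' Draws a severity per subject, renders the three task images with injected
#' anomalies and their masks, scores each subject, and writes everything
#' under `out_dir` together with a manifest CSV (columns `subject_id`,
#' `clock_path`, `cube_path`, `trail_path`, `clock_mask_path`,
#' `cube_mask_path`, `trail_mask_path`, `moca_score`, `severity`).
#' Re-running with identical arguments reproduces byte-identical files.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param severity_distribution function `n -> severities` in \[0, 1\]
#'   (default uniform), or a numeric vector recycled to `n_subjects`.
#' @param out_dir output directory (created if needed).
#' @param rng_seed integer master seed; per-subject/task seeds are derived
#'   from it.
#' @param canvas_size image side length in pixels.
#' @param noise_sd score-noise standard deviation passed to
#'   [severity_to_moca()].
#' @param stroke_params forwarded to [make_base_drawing()].
#' @return the manifest as a data frame (invisibly), with attribute
#'   `out_dir`; also written as `manifest.csv` in `out_dir`.
#' @export
generate_cohort <- function(n_subjects, severity_distribution = stats::runif,
                            out_dir, rng_seed = 1L, canvas_size = 256,
                            noise_sd = 1, stroke_params = list()) {
  if (!is_count(n_subjects) || n_subjects < 1)
    stop("n_subjects must be an integer >= 1")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  sev <- if (is.function(severity_distribution)) {
    with_seed(derive_seed(rng_seed, "severity"),
              severity_distribution(n_subjects))
  } else rep_len(as.numeric(severity_distribution), n_subjects)
  if (any(is.na(sev)) || any(sev < 0 | sev > 1))
    stop("severities must lie in [0, 1]")
  scores <- severity_to_moca(sev, noise_sd,
                             rng_seed = derive_seed(rng_seed, "score"))
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    id <- sprintf("S%04d", i)
    paths <- character(0)
    for (task in TASKS) {
      img <- make_base_drawing(task, canvas_size, stroke_params,
                               rng_seed = derive_seed(rng_seed, id, task, "base"))
      inj <- inject_anomalies(img, task, sev[i],
                              rng_seed = derive_seed(rng_seed, id, task, "anom"))
      ipath <- sprintf("%s_%s.png", id, task)
      mpath <- sprintf("%s_%s_mask.png", id, task)
      png::writePNG(pmin(pmax(inj$image, 0), 1), file.path(out_dir, ipath))
      png::writePNG(inj$mask * 1.0, file.path(out_dir, mpath))
      paths[paste0(task, "_path")] <- ipath
      paths[paste0(task, "_mask_path")] <- mpath
    }
    rows[[i]] <- data.frame(subject_id = id,
                            clock_path = paths[["clock_path"]],
                            cube_path = paths[["cube_path"]],
                            trail_path = paths[["trail_path"]],
                            clock_mask_path = paths[["clock_mask_path"]],
                            cube_mask_path = paths[["cube_mask_path"]],
                            trail_mask_path = paths[["trail_mask_path"]],
                            moca_score = scores[i],
                            severity = sev[i],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "out_dir") <- out_dir
  invisible(manifest)
}
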