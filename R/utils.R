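# Shared internal helpers: seeded evaluation, seed fan-out, bilinear
# resampling, and small validation utilities.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  All stochastic operations in the
# package route through this so that a single integer seed makes any
# operation reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministically derive a child seed from a parent seed and a stream
# label; keeps results independent across stages without seed collisions.
# Result is always a valid 32-bit integer seed.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(parts)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

# Bilinear resize of a numeric matrix (rows = y, cols = x).
resize_bilinear <- function(m, out_h, out_w) {
  stopifnot(is.matrix(m))
  if (nrow(m) == out_h && ncol(m) == out_w) return(m)
  # EBImage stores images as (x, y); transpose in and out.
  r <- EBImage::resize(EBImage::Image(t(m)), w = out_w, h = out_h)
  t(EBImage::imageData(r))
}

# Nearest-neighbour resize, used for binary masks where interpolation would
# produce fractional values.
resize_nearest <- function(m, out_h, out_w) {
  stopifnot(is.matrix(m))
  if (nrow(m) == out_h && ncol(m) == out_w) return(m)
  ri <- pmin(nrow(m), pmax(1L, round((seq_len(out_h) - 0.5) * nrow(m) / out_h + 0.5)))
  ci <- pmin(ncol(m), pmax(1L, round((seq_len(out_w) - 0.5) * ncol(m) / out_w + 0.5)))
  m[ri, ci, drop = FALSE]
}

# round-half-up to the nearest integer (base round() rounds halves to even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == floor(x)

TASKS <- c("clock", "cube", "trail")

check_task_kind <- function(task_kind) {
  if (!is.character(task_kind) || length(task_kind) != 1L ||
      !task_kind %in% TASKS) {
    stop("unknown task_kind; valid kinds are: ", paste(TASKS, collapse = ", "),
         call. = FALSE)
  }
  task_kind
}
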