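# Dataset plumbing: manifest parsing, image loading and resizing,
# train-time translation augmentation, and stratified splitting.

MANIFEST_COLS <- c("subject_id", "clock_path", "cube_path", "trail_path",
                   "moca_score")
MASK_COLS <- c("clock_mask_path", "cube_mask_path", "trail_mask_path")

#' Load a cohort manifest
#'
#' Reads a manifest CSV (one subject per row; columns `subject_id`,
#' `clock_path`, `cube_path`, `trail_path`, `moca_score`, plus optional
#' `*_mask_path` columns) and validates each row: scores must be integers in
#' 0..30 and every referenced image file must exist (paths are resolved
#' relative to the manifest's directory).
#'
#' @param path path to the manifest CSV.
#' @return list of subject records, each a list with `subject_id`,
#'   `image_paths` (named by task, absolute), `moca_score`, and
#'   `mask_paths` (named by task, or `NULL`).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(MANIFEST_COLS, names(df))
  if (length(missing))
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  root <- dirname(normalizePath(path))
  has_masks <- all(MASK_COLS %in% names(df))
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    id <- as.character(df$subject_id[i])
    m <- suppressWarnings(as.numeric(df$moca_score[i]))
    if (is.na(m) || m != floor(m) || m < 0 || m > 30)
      stop("row ", i, " (subject ", id, "): moca_score '", df$moca_score[i],
           "' is not an integer in 0..30")
    ip <- vapply(TASKS, function(task) {
      p <- df[[paste0(task, "_path")]][i]
      p <- if (file.exists(p)) p else file.path(root, p)
      if (!file.exists(p))
        stop("row ", i, " (subject ", id, "): missing image file for task '",
             task, "': ", df[[paste0(task, "_path")]][i])
      p
    }, character(1))
    mp <- NULL
    if (has_masks) {
      mp <- vapply(TASKS, function(task) {
        p <- df[[paste0(task, "_mask_path")]][i]
        if (is.na(p) || !nzchar(p)) return(NA_character_)
        if (file.exists(p)) p else file.path(root, p)
      }, character(1))
    }
    records[[i]] <- list(subject_id = id, image_paths = ip,
                         moca_score = as.integer(m), mask_paths = mp,
                         severity = if ("severity" %in% names(df))
                           df$severity[i] else NA_real_)
  }
  records
}

# read an image file as a grayscale matrix in [0, 1] (1 = white)
read_gray <- function(path) {
  img <- tryCatch(png::readPNG(path),
                  error = function(e) stop("cannot read image ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3) 0.299 * img[, , 1] + 0.587 * img[, , 2] +
      0.114 * img[, , 3] else img[, , 1]
  }
  img
}

# grayscale white-background matrix -> 3-channel ink-intensity array
to_ink_array <- function(gray, size) {
  ink <- resize_bilinear(1 - gray, size, size)
  ink <- pmin(1, pmax(0, ink))
  array(ink, dim = c(size, size, 3))
}

#' Load and resize a subject's three drawings
#'
#' Reads the clock, cube and trail images of one record, converts them to
#' ink-intensity maps (0 = blank page, 1 = full ink; drawings are dark on
#' white so this is `1 - gray`), resizes to `size` x `size` by bilinear
#' interpolation, and replicates the single channel to three so the arrays
#' feed a backbone that expects color input.  Scaling to the backbone's
#' centered input range happens inside the model's forward pass.
#'
#' @param record a subject record from [load_manifest()].
#' @param size target side length (default 256).
#' @return named list (clock/cube/trail) of `size` x `size` x 3 arrays.
#' @export
load_and_resize <- function(record, size = 256) {
  stopifnot(is.list(record), !is.null(record$image_paths))
  out <- lapply(record$image_paths[TASKS], function(p)
    to_ink_array(read_gray(p), size))
  names(out) <- TASKS
  out
}

# load a record's anomaly masks at a given resolution (nearest neighbour)
load_masks <- function(record, size) {
  if (is.null(record$mask_paths)) return(NULL)
  out <- lapply(TASKS, function(task) {
    p <- record$mask_paths[[task]]
    if (is.na(p) || !file.exists(p)) return(NULL)
    resize_nearest(read_gray(p) > 0.5, size, size)
  })
  names(out) <- TASKS
  out
}

#' Random-translation augmentation
#'
#' Mirrors the zero-pad-then-random-crop scheme used at train time: the
#' image is conceptually zero-padded by `max_shift` pixels on every side and
#' cropped back to its original size with the crop center at a random
#' location, which amounts to a translation by at most `max_shift` pixels
#' per axis with zero fill at the borders.  With the default shift of 12 and
#' 256 x 256 inputs this is exactly a 280 x 280 pad + 256 x 256 random crop.
#' Inputs must be on the ink scale (0 = background) so the zero fill adds no
#' spurious content.
#'
#' @param image a square matrix or H x W x C array.
#' @param max_shift maximum absolute translation per axis (px).
#' @param shift optional fixed integer `c(dy, dx)`; when `NULL` both
#'   offsets are drawn uniformly from `-max_shift..max_shift`.
#' @return translated image of identical shape.
#' @export
augment_translate <- function(image, max_shift = 12, shift = NULL) {
  d <- dim(image)
  if (is.null(d) || length(d) < 2L || d[1] != d[2])
    stop("augment_translate expects a square image")
  if (d[1] <= 2 * max_shift)
    stop("image side must exceed twice the maximum shift")
  if (is.null(shift))
    shift <- sample.int(2L * max_shift + 1L, 2L, replace = TRUE) -
      (max_shift + 1L)
  dy <- shift[1]; dx <- shift[2]
  n <- d[1]
  out <- array(0, dim = d)
  src_r <- max(1, 1 - dy):min(n, n - dy)
  src_c <- max(1, 1 - dx):min(n, n - dx)
  if (length(d) == 2L) {
    out[src_r + dy, src_c + dx] <- image[src_r, src_c]
  } else {
    out[src_r + dy, src_c + dx, ] <- image[src_r, src_c, , drop = FALSE]
  }
  out
}

#' Stratified train/validation/test split
#'
#' Splits subjects into train/validation/test within each diagnostic class
#' (hard label at the given cutoff).  Per class, the test and validation
#' sizes are the round-half-up nearest integers of `class size x fraction`
#' and train receives the remainder, so e.g. 651 healthy + 267 MCI subjects
#' at 15% yield a 98 + 40 = 138-subject test set.
#'
#' @param records list of subject records.
#' @param fractions train/validation/test proportions summing to 1.
#' @param seed integer seed controlling the within-class shuffle.
#' @param cutoff MoCA cutoff used for the stratification label.
#' @return data frame (`subject_id`, `partition`) with attribute `seed`;
#'   `partition` is a factor with levels train/validation/test.
#' @export
stratified_split <- function(records, fractions = c(0.70, 0.15, 0.15),
                             seed = 1L, cutoff = 25) {
  if (!length(records)) stop("records must be nonempty")
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three nonnegative numbers summing to 1")
  ids <- vapply(records, function(r) r$subject_id, character(1))
  labs <- hard_label(vapply(records, function(r) r$moca_score, numeric(1)),
                     cutoff)
  part <- character(length(records))
  for (cl in unique(labs)) {
    idx <- which(labs == cl)
    if (length(idx) < 3L)
      stop("class ", cl, " has fewer than 3 members; cannot populate all ",
           "partitions")
    n_test <- round_half_up(length(idx) * fractions[3])
    n_val <- round_half_up(length(idx) * fractions[2])
    if (n_test + n_val > length(idx))
      stop("fractions leave no training subjects for class ", cl)
    idx <- with_seed(derive_seed(seed, "split", cl), sample(idx))
    part[idx[seq_len(n_test)]] <- "test"
    part[idx[n_test + seq_len(n_val)]] <- "validation"
    rest <- idx[setdiff(seq_along(idx), seq_len(n_test + n_val))]
    part[rest] <- "train"
  }
  out <- data.frame(subject_id = ids,
                    partition = factor(part, levels = c("train", "validation",
                                                        "test")),
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  out
}

# index records by partition
partition_indices <- function(records, split, partition) {
  ids <- vapply(records, function(r) r$subject_id, character(1))
  which(ids %in% split$subject_id[split$partition == partition])
}
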