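# Diagnostic labels from MoCA screening scores.
#
# The clinical convention labels a subject as MCI when the score falls
# below a cutoff (25 by default).  The soft label replaces the hard 0/1
# target with a sigmoid of the score centered between the two integer
# scores adjacent to the cutoff (24.5), so that a score of 24 maps to 0.622
# and 25 to 0.378: label uncertainty is largest exactly where the clinical
# cutoff is most debatable.

#' Hard diagnostic label from a MoCA score
#'
#' @param m integer score(s) in 0..30.
#' @param cutoff scores strictly below this are labeled MCI (default 25).
#' @return integer vector: 1 = MCI, 0 = healthy control.
#' @export
hard_label <- function(m, cutoff = 25) {
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0 | m > 30))
    stop("MoCA scores must lie in [0, 30]")
  as.integer(m < cutoff)
}

#' Soft diagnostic label from a MoCA score
#'
#' `y = 1 - sigmoid(m - center)`, strictly decreasing in the score, equal to
#' 0.5 at the center and consistent with [hard_label()] in sign for every
#' integer score.
#'
#' @param m numeric score(s).
#' @param center sigmoid center (default 24.5, between the hard cutoff's
#'   two adjacent integer scores).
#' @return soft labels in (0, 1).
#' @export
soft_label <- function(m, center = 24.5) {
  if (!is.numeric(m) || any(is.na(m))) stop("scores must be numeric")
  1 - plogis(m - center)
}

# resolve labels for a set of records under a labeling mode
subject_labels <- function(records, mode = c("soft", "hard"),
                           cutoff = 25, center = 24.5) {
  mode <- match.arg(mode)
  m <- vapply(records, function(r) r$moca_score, numeric(1))
  if (mode == "hard") as.numeric(hard_label(m, cutoff)) else
    soft_label(m, center)
}
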