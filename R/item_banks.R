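#' Item banks for the reasoning tasks
#'
#' Constructors for the item designs of the analogical reasoning task (ART),
#' the deductive reasoning task (DRT) and the perceptual-matching baseline
#' task.
#'
#' The ART bank holds 24 test items: 12 follow the Progression rule (a
#' monotone change in numerical value, colour intensity or size) and 12 the
#' odd-one-out (OOU) rule; orthogonally, 12 are intra-dimensional (the rule
#' applies to the same stimulus feature in source and target) and 12
#' cross-dimensional. The rule feature (number / colour / size) is balanced
#' 8/8/8 across the bank. The DRT bank holds 24 relational deduction items:
#' 12 logically valid and 12 invalid; all valid items are determinate, and
#' the invalid items split into 6 determinate and 6 indeterminate, so the
#' bank has 18 determinate and 6 indeterminate items. The baseline bank
#' holds 12 perceptual-matching items with no analogy rule.
#'
#' Item difficulties are on the same 0-1 scale as \code{score/100} in
#' \code{\link{simulate_responses}}. Defaults order cross-dimensional above
#' intra-dimensional and indeterminate above determinate, matching the
#' reported difficulty ordering of those subtypes; the exact values are
#' arguments.
#'
#' @param difficulty_intra,difficulty_cross ART difficulties by
#'   dimensionality.
#' @param difficulty_det,difficulty_indet DRT difficulties by determinacy.
#' @param difficulty baseline item difficulty.
#' @return data frame of class \code{item_bank} with columns
#'   \code{item_id}, \code{task}, \code{rule}, \code{dimensionality},
#'   \code{feature}, \code{validity}, \code{determinacy},
#'   \code{difficulty_q}.
#' @name item_bank
NULL

.bank <- function(df) {
  df$item_id <- sprintf("%s_%02d", df$task, seq_len(nrow(df)))
  class(df) <- c("item_bank", "data.frame")
  df
}

#' @rdname item_bank
#' @export
art_item_bank <- function(difficulty_intra = 0.45, difficulty_cross = 0.60) {
  rule <- rep(c("progression", "odd_one_out"), each = 12L)
  dimensionality <- rep(rep(c("intra", "cross"), each = 6L), 2L)
  feature <- rep_len(c("number", "colour", "size"), 24L)
  .bank(data.frame(
    task = "ART", rule = rule, dimensionality = dimensionality,
    feature = feature, validity = "none", determinacy = "none",
    difficulty_q = ifelse(dimensionality == "intra",
                          difficulty_intra, difficulty_cross),
    stringsAsFactors = FALSE
  ))
}

#' @rdname item_bank
#' @export
drt_item_bank <- function(difficulty_det = 0.45, difficulty_indet = 0.65) {
  validity <- rep(c("valid", "invalid"), each = 12L)
  determinacy <- c(rep("determinate", 12L),
                   rep(c("determinate", "indeterminate"), each = 6L))
  .bank(data.frame(
    task = "DRT", rule = "none", dimensionality = "none", feature = "none",
    validity = validity, determinacy = determinacy,
    difficulty_q = ifelse(determinacy == "determinate",
                          difficulty_det, difficulty_indet),
    stringsAsFactors = FALSE
  ))
}

#' @rdname item_bank
#' @export
baseline_item_bank <- function(difficulty = 0.30) {
  .bank(data.frame(
    task = rep("baseline", 12L), rule = "none", dimensionality = "none",
    feature = "none", validity = "none", determinacy = "none",
    difficulty_q = difficulty, stringsAsFactors = FALSE
  ))
}

#' Percent-correct scoring
#'
#' Per-participant percentage of correct responses over the items selected
#' by \code{subset_filter}: number correct / number of questions x 100.
#' Every participant in the log must have answered every selected item
#' exactly once.
#'
#' @param log response log (\code{participant_id}, \code{item_id},
#'   \code{correct}).
#' @param bank the \code{\link{item_bank}} the log was administered from.
#' @param subset_filter \code{NULL} for all items, or a predicate taking the
#'   bank data frame and returning a logical vector (e.g.
#'   \code{function(it) it$determinacy == "indeterminate"}).
#' @return named numeric vector of percentages in [0, 100], one per
#'   participant.
#' @export
percent_correct <- function(log, bank, subset_filter = NULL) {
  keep <- if (is.null(subset_filter)) rep(TRUE, nrow(bank))
          else subset_filter(bank)
  items <- bank$item_id[keep]
  if (length(items) == 0L) stop("filter error: no items match the filter")
  if (!all(log$item_id %in% bank$item_id))
    stop("response log contains items absent from the bank")
  sub <- log[log$item_id %in% items, , drop = FALSE]
  counts <- table(sub$participant_id)
  if (any(counts != length(items)))
    stop("completeness error: some participants did not answer every ",
         "selected item exactly once")
  agg <- tapply(sub$correct, sub$participant_id, sum)
  out <- 100 * as.numeric(agg) / length(items)
  names(out) <- names(agg)
  out
}
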