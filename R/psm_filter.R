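#' Target-decoy FDR annotation of scored PSMs
#'
#' Estimates, at every distinct score threshold s, the false discovery rate
#' among target PSMs scoring at least s by the concatenated-search convention
#' FDR(s) = #decoys(score >= s) / max(1, #targets(score >= s)), capped at 1,
#' and converts it to a q-value: the minimum FDR over all thresholds at which
#' the PSM would still be accepted (i.e. thresholds <= its score). q-values
#' are therefore nonincreasing in score. Tied scores share one threshold, so
#' a decoy tied with a target counts against it (conservative).
#'
#' @param psms tibble with at least `score` (finite, higher is better) and
#'   `is_decoy` (logical) columns; typically a PSM table from
#'   [generate_dataset()] or [read_psm_tsv()].
#' @param plus_one if `TRUE`, use the (#decoys + 1) variant of the estimator.
#' @return the input with `fdr_at_score` (FDR at the PSM's own score used as
#'   threshold) and `q_value` columns appended.
#' @export
compute_fdr <- function(psms, plus_one = FALSE) {
  stopifnot(is.data.frame(psms), all(c("score", "is_decoy") %in% names(psms)))
  if (!all(is.finite(psms$score))) stop("non-finite PSM scores", call. = FALSE)
  if (!any(!psms$is_decoy)) {
    stop("FDR undefined: table contains no target PSMs", call. = FALSE)
  }

  ## distinct thresholds, descending; counts of rows with score >= threshold
  thr <- sort(unique(psms$score), decreasing = TRUE)
  n_tgt <- cumsum_by_threshold(psms$score[!psms$is_decoy], thr)
  n_dec <- cumsum_by_threshold(psms$score[psms$is_decoy], thr)
  fdr <- pmin(1, (n_dec + as.numeric(plus_one)) / pmax(1, n_tgt))
  ## q(s_i) = min FDR over thresholds <= s_i (all j >= i in descending order)
  qv <- rev(cummin(rev(fdr)))

  pos <- match(psms$score, thr)
  psms$fdr_at_score <- fdr[pos]
  psms$q_value <- qv[pos]
  psms
}

## number of `scores` >= each threshold; thresholds must be sorted descending
cumsum_by_threshold <- function(scores, thr_desc) {
  counts <- tabulate(match(scores, thr_desc), nbins = length(thr_desc))
  cumsum(counts)
}

#' Retain target PSMs passing an FDR threshold
#'
#' Keeps non-decoy PSMs with `q_value` strictly below `threshold` (the
#' q-value route, default) or with `fdr_at_score` strictly below it. Decoys
#' never pass.
#'
#' @param psms an FDR-annotated table from [compute_fdr()].
#' @param threshold FDR cutoff in (0, 1]; default 0.01.
#' @param use `"q_value"` (default) or `"fdr"` (raw threshold FDR).
#' @return the retained target PSM rows.
#' @export
filter_fdr <- function(psms, threshold = 0.01, use = c("q_value", "fdr")) {
  use <- match.arg(use)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  if (!all(c("fdr_at_score", "q_value") %in% names(psms))) {
    stop("run compute_fdr() first", call. = FALSE)
  }
  stat <- if (use == "q_value") psms$q_value else psms$fdr_at_score
  psms[!psms$is_decoy & stat < threshold, , drop = FALSE]
}
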