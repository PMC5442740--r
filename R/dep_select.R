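#' Selection thresholds for DEP calling
#'
#' Defaults mirror the printed analysis settings: raw p < 0.1, at least two
#' nonredundant peptides, and fold-changes above the 90th percentile of the
#' fold-change magnitude distribution (and likewise for the normalized
#' 2-month/1-day fold-change). No multiple-testing correction is applied at
#' this stage; the p threshold is a raw per-protein significance level.
#'
#' @param p_cut significance level in (0, 1); default 0.1.
#' @param min_peptides minimum nonredundant peptide support; default 2.
#' @param fc_percentile,norm_fc_percentile percentile rank in (0, 100) of the
#'   fold-change magnitude distribution used as adaptive cutoff; default 90.
#' @param percentile_method `"nearest_rank"` (default, order-statistic exact)
#'   or `"interpolated"` (type-7 quantile).
#' @return validated `selection_thresholds` list.
#' @export
selection_thresholds <- function(p_cut = 0.1, min_peptides = 2L,
                                 fc_percentile = 90, norm_fc_percentile = 90,
                                 percentile_method = c("nearest_rank", "interpolated")) {
  percentile_method <- match.arg(percentile_method)
  if (p_cut <= 0 || p_cut >= 1) stop("p_cut must be in (0, 1)", call. = FALSE)
  for (q in c(fc_percentile, norm_fc_percentile)) {
    if (q <= 0 || q >= 100) stop("percentiles must be in (0, 100)", call. = FALSE)
  }
  structure(list(p_cut = p_cut, min_peptides = as.integer(min_peptides),
                 fc_percentile = fc_percentile,
                 norm_fc_percentile = norm_fc_percentile,
                 percentile_method = percentile_method),
            class = "selection_thresholds")
}

#' One-sample Student's t test with a documented degenerate-variance policy
#'
#' Two-sided p-value for the mean of `values` against `null_mean`, with n - 1
#' degrees of freedom. Replicate log2 abundances occasionally have zero
#' sample variance (e.g. noise-free simulations); the t statistic is then
#' undefined and the p-value is reported as 1 if the mean equals the null and
#' 0 otherwise, with a warning.
#'
#' @param values numeric, length >= 2, finite.
#' @param null_mean null hypothesis mean; default 0.
#' @return two-sided p-value.
#' @export
one_sample_t <- function(values, null_mean = 0) {
  if (length(values) < 2L) stop("need >= 2 values for a one-sample t test", call. = FALSE)
  if (!all(is.finite(values))) stop("non-finite values", call. = FALSE)
  if (stats::sd(values) == 0) {
    warning("zero variance: degenerate p-value reported", call. = FALSE)
    return(if (mean(values) == null_mean) 1 else 0)
  }
  stats::t.test(values, mu = null_mean)$p.value
}

#' Two-sample pooled-variance Student's t test with degenerate policy
#'
#' Two-sided p-value for a difference in means, pooled variance, with
#' nA + nB - 2 degrees of freedom. Zero pooled variance triggers the same
#' degenerate policy as [one_sample_t()].
#'
#' @param group_a,group_b numeric vectors, each length >= 2, finite.
#' @return two-sided p-value.
#' @export
two_sample_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("need >= 2 values per group", call. = FALSE)
  }
  if (!all(is.finite(group_a)) || !all(is.finite(group_b))) {
    stop("non-finite values", call. = FALSE)
  }
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    warning("zero pooled variance: degenerate p-value reported", call. = FALSE)
    return(if (mean(group_a) == mean(group_b)) 1 else 0)
  }
  stats::t.test(group_a, group_b, var.equal = TRUE)$p.value
}

#' Nearest-rank percentile cutoff
#'
#' The k-th smallest value with k = ceiling(q/100 * n): deterministic,
#' order-statistic exact, and well behaved at small n. The interpolated
#' variant uses the conventional type-7 quantile.
#'
#' @param values nonempty numeric vector.
#' @param q percentile rank in (0, 100).
#' @param method `"nearest_rank"` (default) or `"interpolated"`.
#' @return the cutoff value.
#' @export
percentile_cutoff <- function(values, q, method = c("nearest_rank", "interpolated")) {
  method <- match.arg(method)
  if (length(values) == 0L) stop("empty value list", call. = FALSE)
  if (method == "nearest_rank") {
    unname(stats::quantile(values, q / 100, type = 1))
  } else {
    unname(stats::quantile(values, q / 100, type = 7))
  }
}

#' Select differentially expressed proteins at 1 day, 2 months, and 2m/1d
#'
#' Implements the three-class DEP selection. Per protein and timepoint the
#' mean log2 fold-change over replicates, a one-sample t p-value, and the
#' fold-change magnitude `2^|mean log2fc|` are computed; a protein is a
#' timepoint DEP when p < `p_cut`, it has at least `min_peptides`
#' nonredundant peptides, and its fold-change magnitude strictly exceeds the
#' `fc_percentile` cutoff of the magnitude distribution over all quantified
#' proteins at that timepoint (the bulk, mostly-null population defines the
#' adaptive cutoff). Among the 2-month DEPs, the late-change class
#' additionally requires a two-sample t test between the per-replicate 1-day
#' and 2-month log2 fold-changes at p < `p_cut` and a normalized fold-change
#' (2-month fold-change divided by 1-day fold-change, folded to magnitude
#' scale) strictly above its own percentile cutoff, so the late class is a
#' subset of the 2-month class by construction.
#'
#' @param protein_ratios table from [aggregate_proteins()] /
#'   [quantify_proteins()].
#' @param thresholds a [selection_thresholds()] object.
#' @param incomplete `"error"` (default) to reject proteins quantified in
#'   only some replicates, or `"drop"` to discard them with a message.
#' @return tibble with one row per protein: means, p-values, fold-change
#'   magnitudes, normalized fold-change, peptide support, DEP flags and
#'   directions, plus attributes `fc_cutoff_1day`, `fc_cutoff_2month`,
#'   `norm_fc_cutoff` holding the realized adaptive cutoffs.
#' @export
select_deps <- function(protein_ratios, thresholds = selection_thresholds(),
                        incomplete = c("error", "drop")) {
  incomplete <- match.arg(incomplete)
  stopifnot(inherits(thresholds, "selection_thresholds"))
  th <- thresholds

  counts <- table(protein_ratios$protein)
  n_rep <- max(counts)
  if (any(counts < n_rep)) {
    bad <- names(counts)[counts < n_rep]
    if (incomplete == "error") {
      stop("replicate mismatch: ", length(bad),
           " protein(s) not quantified in every replicate", call. = FALSE)
    }
    message("dropping ", length(bad), " protein(s) with incomplete replicates")
    protein_ratios <- protein_ratios[!protein_ratios$protein %in% bad, , drop = FALSE]
  }
  if (length(unique(protein_ratios$protein)) < 10L) {
    stop("fewer than 10 proteins: percentile cutoffs are not meaningful", call. = FALSE)
  }

  per_protein <- protein_ratios |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(
      mean_log2fc_1day = mean(.data$log2_abundance_1day),
      mean_log2fc_2month = mean(.data$log2_abundance_2month),
      p_1day = suppressWarnings(one_sample_t(.data$log2_abundance_1day)),
      p_2month = suppressWarnings(one_sample_t(.data$log2_abundance_2month)),
      p_2m_vs_1d = suppressWarnings(
        two_sample_t(.data$log2_abundance_2month, .data$log2_abundance_1day)),
      n_nonredundant_peptides = .data$n_nonredundant_peptides[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fc_mag_1day = 2^abs(.data$mean_log2fc_1day),
      fc_mag_2month = 2^abs(.data$mean_log2fc_2month),
      norm_fc = 2^(.data$mean_log2fc_2month - .data$mean_log2fc_1day),
      norm_fc_mag = pmax(.data$norm_fc, 1 / .data$norm_fc),
      direction_1day = ifelse(.data$mean_log2fc_1day >= 0, "up", "down"),
      direction_2month = ifelse(.data$mean_log2fc_2month >= 0, "up", "down")
    )

  cut_1d <- percentile_cutoff(per_protein$fc_mag_1day, th$fc_percentile,
                              th$percentile_method)
  cut_2m <- percentile_cutoff(per_protein$fc_mag_2month, th$fc_percentile,
                              th$percentile_method)
  cut_nf <- percentile_cutoff(per_protein$norm_fc_mag, th$norm_fc_percentile,
                              th$percentile_method)

  out <- per_protein |>
    dplyr::mutate(
      is_dep_1day = .data$p_1day < th$p_cut &
        .data$n_nonredundant_peptides >= th$min_peptides &
        .data$fc_mag_1day > cut_1d,
      is_dep_2month = .data$p_2month < th$p_cut &
        .data$n_nonredundant_peptides >= th$min_peptides &
        .data$fc_mag_2month > cut_2m,
      is_dep_2m_over_1d = .data$is_dep_2month &
        .data$p_2m_vs_1d < th$p_cut &
        .data$norm_fc_mag > cut_nf
    )
  attr(out, "fc_cutoff_1day") <- cut_1d
  attr(out, "fc_cutoff_2month") <- cut_2m
  attr(out, "norm_fc_cutoff") <- cut_nf
  out
}
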