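#' Build the peptide-level reporter-intensity matrix
#'
#' Collapses retained PSMs to one row per (protein, peptide) and one column
#' per channel x replicate (4R columns, `i114_1` ... `i117_R`), summing raw
#' reporter intensities when the same peptide was matched by several spectra
#' in a replicate, then log2-transforming. Zero intensities become missing;
#' rows with any missing entry are dropped (no imputation) so that the
#' normalization step sees a complete finite matrix. The number of dropped
#' rows is reported via the `"n_dropped_incomplete"` attribute.
#'
#' @param psms retained target PSM rows (see [filter_fdr()]).
#' @return tibble: `protein`, `peptide`, then 4R log2-intensity columns.
#' @export
reporter_matrix <- function(psms) {
  stopifnot(all(c("peptide", "protein", "replicate",
                  "i114", "i115", "i116", "i117") %in% names(psms)))
  if (nrow(psms) == 0L) stop("empty PSM table: nothing to quantify", call. = FALSE)
  if (any(psms$is_decoy)) stop("decoy PSMs must be filtered out first", call. = FALSE)

  long <- psms |>
    dplyr::group_by(.data$protein, .data$peptide, .data$replicate) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c("i114", "i115", "i116", "i117")), sum),
                     .groups = "drop") |>
    tidyr::pivot_longer(dplyr::all_of(c("i114", "i115", "i116", "i117")),
                        names_to = "channel", values_to = "intensity") |>
    dplyr::mutate(
      log2_intensity = ifelse(.data$intensity > 0, log2(.data$intensity), NA_real_),
      column = paste0(.data$channel, "_", .data$replicate)
    )

  wide <- long |>
    dplyr::select(dplyr::all_of(c("protein", "peptide", "column", "log2_intensity"))) |>
    tidyr::pivot_wider(names_from = "column", values_from = "log2_intensity")

  value_cols <- setdiff(names(wide), c("protein", "peptide"))
  complete <- stats::complete.cases(wide[value_cols])
  out <- wide[complete, , drop = FALSE]
  attr(out, "n_dropped_incomplete") <- sum(!complete)
  out
}

#' Quantile-normalize reporter intensity columns
#'
#' Forces every intensity column to share one reference distribution (the
#' row means of the column-sorted matrix) while preserving within-column
#' ranks; ties within a column receive the mean of the reference values they
#' span. Normalization is applied jointly across all 4 channels x R
#' replicates by default, treating the whole multiplexed experiment as one
#' batch; `scope = "per_replicate"` normalizes each replicate's 4 channels
#' separately.
#'
#' @param x a reporter tibble from [reporter_matrix()] or a numeric matrix.
#' @param scope `"joint"` (default) or `"per_replicate"` (tibble input only).
#' @return object of the same shape with normalized values.
#' @export
quantile_normalize <- function(x, scope = c("joint", "per_replicate")) {
  scope <- match.arg(scope)
  if (is.matrix(x)) return(qn_matrix(x))
  value_cols <- setdiff(names(x), c("protein", "peptide"))
  m <- as.matrix(x[value_cols])
  if (scope == "joint") {
    m <- qn_matrix(m)
  } else {
    reps <- unique(sub("^i11[4-7]_", "", value_cols))
    for (r in reps) {
      cols <- grep(paste0("_", r, "$"), value_cols, value = TRUE)
      m[, cols] <- qn_matrix(m[, cols, drop = FALSE])
    }
  }
  x[value_cols] <- as.data.frame(m)
  x
}

qn_matrix <- function(m) {
  if (!all(is.finite(m))) {
    stop("non-finite entries: apply the missing-data policy before normalizing",
         call. = FALSE)
  }
  if (nrow(m) < 2L) stop("need >= 2 rows to quantile-normalize", call. = FALSE)
  if (ncol(m) == 1L) return(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Per-peptide condition ratios at the two timepoints
#'
#' From the (normalized) log2 reporter matrix, computes per peptide and
#' replicate the treatment/vehicle log2 ratios at 1 day (channel 116 minus
#' 114) and 2 months (channel 117 minus 115).
#'
#' @param mat reporter tibble (see [reporter_matrix()]), normally after
#'   [quantile_normalize()].
#' @return tibble: `peptide`, `protein`, `replicate`, `log2_ratio_1day`,
#'   `log2_ratio_2month`.
#' @export
peptide_ratios <- function(mat) {
  value_cols <- setdiff(names(mat), c("protein", "peptide"))
  reps <- sort(unique(as.integer(sub("^i11[4-7]_", "", value_cols))))
  out <- purrr::map(reps, function(r) {
    tibble::tibble(
      peptide = mat$peptide,
      protein = mat$protein,
      replicate = r,
      log2_ratio_1day = mat[[paste0("i116_", r)]] - mat[[paste0("i114_", r)]],
      log2_ratio_2month = mat[[paste0("i117_", r)]] - mat[[paste0("i115_", r)]]
    )
  })
  out <- dplyr::bind_rows(out)
  if (any(!is.finite(out$log2_ratio_1day) & !is.na(out$log2_ratio_1day)) ||
      any(!is.finite(out$log2_ratio_2month) & !is.na(out$log2_ratio_2month))) {
    stop("non-finite peptide ratio: zero intensity survived the floor policy",
         call. = FALSE)
  }
  out
}

#' L1-optimal protein log2 ratio from peptide ratios
#'
#' Returns the value rho minimizing the L1 objective sum_i |r_i - rho| over
#' the peptide log2 ratios r_i — a one-dimensional linear program whose
#' closed-form solution is the sample median. For an even number of ratios
#' the optimum is the flat interval between the two central order statistics;
#' the documented tie policy returns its midpoint.
#'
#' @param ratios numeric vector of finite log2 ratios (NAs dropped).
#' @return the L1-optimal log2 ratio.
#' @export
lp_protein_ratio <- function(ratios) {
  r <- ratios[!is.na(ratios)]
  if (length(r) == 0L) stop("no finite peptide ratios", call. = FALSE)
  if (!all(is.finite(r))) stop("non-finite peptide ratios", call. = FALSE)
  stats::median(r)
}

#' Aggregate peptide ratios to protein relative abundances
#'
#' Rolls peptide-level log2 ratios up to one protein-level log2 relative
#' abundance per (protein, replicate, timepoint) via [lp_protein_ratio()].
#' Peptide sequences mapping to more than one protein are excluded before the
#' roll-up (unique-peptide parsimony); `n_nonredundant_peptides` counts
#' distinct peptide sequences supporting the protein (maximum over
#' replicates). Protein x replicate combinations with no usable peptide are
#' omitted.
#'
#' @param ratios a peptide ratio table from [peptide_ratios()].
#' @return tibble: `protein`, `replicate`, `log2_abundance_1day`,
#'   `log2_abundance_2month`, `n_nonredundant_peptides`.
#' @export
aggregate_proteins <- function(ratios) {
  if (nrow(ratios) == 0L) stop("empty peptide ratio table", call. = FALSE)

  shared <- ratios |>
    dplyr::distinct(.data$peptide, .data$protein) |>
    dplyr::count(.data$peptide) |>
    dplyr::filter(.data$n > 1L)
  usable <- ratios[!ratios$peptide %in% shared$peptide, , drop = FALSE]
  if (nrow(usable) == 0L) stop("no peptides left after shared-peptide exclusion",
                               call. = FALSE)

  per_rep <- usable |>
    dplyr::group_by(.data$protein, .data$replicate) |>
    dplyr::summarise(
      log2_abundance_1day = lp_protein_ratio(.data$log2_ratio_1day),
      log2_abundance_2month = lp_protein_ratio(.data$log2_ratio_2month),
      n_pep_rep = dplyr::n_distinct(.data$peptide),
      .groups = "drop"
    )
  support <- per_rep |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(n_nonredundant_peptides = max(.data$n_pep_rep), .groups = "drop")

  per_rep |>
    dplyr::select(-dplyr::all_of("n_pep_rep")) |>
    dplyr::left_join(support, by = "protein") |>
    dplyr::arrange(.data$protein, .data$replicate)
}

#' Full quantification stage: retained PSMs to protein ratio table
#'
#' Convenience wrapper chaining [reporter_matrix()], [quantile_normalize()]
#' (unless `normalize = "none"`), [peptide_ratios()] and
#' [aggregate_proteins()].
#'
#' @param psms retained target PSMs.
#' @param normalize `"joint"` (default), `"per_replicate"`, or `"none"`.
#' @return protein ratio tibble (see [aggregate_proteins()]).
#' @export
quantify_proteins <- function(psms, normalize = c("joint", "per_replicate", "none")) {
  normalize <- match.arg(normalize)
  mat <- reporter_matrix(psms)
  if (normalize != "none") mat <- quantile_normalize(mat, scope = normalize)
  aggregate_proteins(peptide_ratios(mat))
}
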