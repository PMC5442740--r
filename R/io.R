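#' @importFrom dplyr .data
NULL

psm_cols <- c("psm_id", "peptide", "protein", "is_decoy", "score", "replicate",
              "i114", "i115", "i116", "i117")

#' Read / write the PSM TSV dialect
#'
#' Tab-separated, header required, UTF-8, LF line endings; columns
#' `psm_id, peptide, protein, is_decoy, score, replicate, i114, i115, i116,
#' i117` (FDR-annotated files append `fdr_at_score` and `q_value`).
#' Malformed files are rejected with the offending line number.
#'
#' @param path file path.
#' @rdname psm_tsv
#' @return `read_psm_tsv`: the PSM tibble.
#' @export
read_psm_tsv <- function(path) {
  raw <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    psm_id = readr::col_character(), peptide = readr::col_character(),
    protein = readr::col_character(), is_decoy = readr::col_logical(),
    score = readr::col_double(), replicate = readr::col_integer(),
    i114 = readr::col_double(), i115 = readr::col_double(),
    i116 = readr::col_double(), i117 = readr::col_double(),
    .default = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0L) {
    stop("malformed PSM TSV at line ", probs$row[1], ": expected ",
         probs$expected[1], ", got ", probs$actual[1], call. = FALSE)
  }
  missing <- setdiff(psm_cols, names(raw))
  if (length(missing) > 0L) {
    stop("PSM TSV missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(raw$i114 < 0 | raw$i115 < 0 | raw$i116 < 0 | raw$i117 < 0)
  if (length(bad) > 0L) {
    stop("negative intensity at line ", bad[1] + 1L, call. = FALSE)
  }
  raw
}

#' @param psms PSM tibble.
#' @rdname psm_tsv
#' @export
write_psm_tsv <- function(psms, path) {
  check_no_tabs(psms, c("psm_id", "peptide", "protein"))
  readr::write_tsv(psms, path, progress = FALSE)
  invisible(path)
}

#' Read / write a planted-truth table
#'
#' TSV with one row per simulated protein: the planted log2 fold-changes at
#' both timepoints, DEP flags, and cell-type membership. Round-trips
#' losslessly.
#'
#' @param truth truth tibble from [generate_dataset()].
#' @param path file path.
#' @rdname truth_tsv
#' @export
write_truth <- function(truth, path) {
  if (nrow(truth) == 0L) stop("empty truth table", call. = FALSE)
  check_no_tabs(truth, c("protein_id", "cell_type_membership"))
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}

#' @rdname truth_tsv
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    true_log2fc_1day = readr::col_double(),
    true_log2fc_2month = readr::col_double(),
    is_dep_1day = readr::col_logical(),
    is_dep_2month = readr::col_logical(),
    cell_type_membership = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
}

check_no_tabs <- function(tbl, cols) {
  for (cl in intersect(cols, names(tbl))) {
    if (any(grepl("[\t\n]", tbl[[cl]]))) {
      stop("format error: column `", cl, "` contains tab or newline characters",
           call. = FALSE)
    }
  }
  invisible(tbl)
}

#' Read / write gene sets in GMT format
#'
#' Standard GMT: one set per line, `set_name<TAB>description<TAB>member...`.
#' Duplicate set names and lines with fewer than three fields are rejected
#' with their line number.
#'
#' @param path GMT file path.
#' @param universe optional universe; defaults to the union of all members.
#' @rdname gmt
#' @return `read_gmt`: a [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: no gene sets", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop("malformed GMT at line ", short[1], ": fewer than 3 tab-separated fields",
         call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  dup <- which(duplicated(nm))
  if (length(dup) > 0L) {
    stop("duplicate set name '", nm[dup[1]], "' at line ", dup[1], call. = FALSE)
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, universe = if (is.null(universe)) unique(unlist(sets)) else universe)
}

#' @param collection a [gene_set_collection()].
#' @param descriptions optional named character of set descriptions.
#' @rdname gmt
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  nm <- names(collection$sets)
  desc <- if (is.null(descriptions)) rep("na", length(nm)) else descriptions[nm]
  lines <- vapply(seq_along(nm), function(i) {
    paste(c(nm[i], desc[i], collection$sets[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write / read the protein ratio and DEP tables
#'
#' Plain TSV mirrors of the tibbles produced by [aggregate_proteins()] and
#' [select_deps()]; the DEP writer preserves the realized adaptive cutoffs
#' as a JSON sidecar-free reload is not needed (cutoffs are re-derivable).
#'
#' @param tbl the table.
#' @param path file path.
#' @rdname table_tsv
#' @export
write_table_tsv <- function(tbl, path) {
  readr::write_tsv(tibble::as_tibble(tbl), path, progress = FALSE)
  invisible(path)
}

#' @rdname table_tsv
#' @export
read_table_tsv <- function(path) {
  readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
}
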