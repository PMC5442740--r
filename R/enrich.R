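#' Gene-set collection over a gene-symbol universe
#'
#' @param sets named list of character vectors (set name -> member symbols);
#'   names must be unique, sets nonempty after deduplication.
#' @param universe character vector of symbols eligible for testing; sets are
#'   intersected with the universe before any test.
#' @return `gene_set_collection` list.
#' @export
gene_set_collection <- function(sets, universe) {
  if (length(sets) == 0L) stop("empty gene-set collection", call. = FALSE)
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(names(sets) == "")) {
    stop("gene sets must have unique nonempty names", call. = FALSE)
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) < 1L)) stop("gene sets must have >= 1 member", call. = FALSE)
  structure(list(sets = sets, universe = unique(as.character(universe))),
            class = "gene_set_collection")
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' P(X >= overlap) for X ~ Hypergeometric(universe_size, set_size,
#' query_size): the probability of drawing at least the observed overlap
#' when `query_size` genes are sampled without replacement from a universe
#' containing `set_size` set members. The observed overlap is included in
#' the tail (standard over-representation convention), so overlap 0 gives
#' p = 1 exactly.
#'
#' @param overlap observed overlap count.
#' @param query_size number of genes in the query list.
#' @param set_size number of set members in the universe.
#' @param universe_size total genes in the universe.
#' @return upper-tail p-value in (0, 1].
#' @export
hypergeom_upper_tail <- function(overlap, query_size, set_size, universe_size) {
  k <- overlap; n <- query_size; K <- set_size; N <- universe_size
  if (any(c(k, n, K, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation of DEP classes in gene sets
#'
#' For every DEP class x direction x gene set, tests whether the query (the
#' DEPs of that class and direction) overlaps the set more than expected by
#' chance. The universe is the set of quantified proteins present in the
#' collection's namespace (background-corrected enrichment); each set is
#' intersected with the universe before testing. A result passes when
#' p < `p_cut` and the overlap is at least `min_overlap`; no multiple-testing
#' correction enters the pass rule, but a Benjamini-Hochberg column is
#' emitted for information.
#'
#' @param deps DEP table from [select_deps()].
#' @param collection a [gene_set_collection()].
#' @param p_cut raw significance level for `passes`; default 0.1.
#' @param min_overlap minimum DEP overlap for `passes`; default 3.
#' @param directions which direction strata to test; default up and down,
#'   `"all"` pools both.
#' @return tibble sorted by p ascending: class, direction, set_name,
#'   overlap/query/set/universe counts, p_value, p_bh, neg_log10_p, passes.
#' @export
enrich_sets <- function(deps, collection, p_cut = 0.1, min_overlap = 3L,
                        directions = c("up", "down")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (nrow(deps) == 0L) stop("empty DEP table", call. = FALSE)
  if (length(collection$universe) == 0L) stop("empty universe", call. = FALSE)

  universe <- intersect(deps$protein, collection$universe)
  unmapped <- setdiff(deps$protein, collection$universe)
  if (length(unmapped) > 0L) {
    warning(length(unmapped), " quantified protein(s) absent from the collection universe",
            call. = FALSE)
  }
  if (length(universe) == 0L) stop("no quantified protein maps to the universe",
                                   call. = FALSE)
  sets <- lapply(collection$sets, intersect, y = universe)

  classes <- list(
    "1day" = list(flag = deps$is_dep_1day, dir = deps$direction_1day),
    "2month" = list(flag = deps$is_dep_2month, dir = deps$direction_2month),
    "2m_over_1d" = list(flag = deps$is_dep_2m_over_1d, dir = deps$direction_2month)
  )

  rows <- list()
  for (cl in names(classes)) {
    for (dr in directions) {
      sel <- classes[[cl]]$flag &
        (if (dr == "all") TRUE else classes[[cl]]$dir == dr)
      query <- intersect(deps$protein[sel], universe)
      for (sn in names(sets)) {
        set <- sets[[sn]]
        ov <- length(intersect(query, set))
        p <- hypergeom_upper_tail(ov, length(query), length(set), length(universe))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          class = cl, direction = dr, set_name = sn,
          overlap_count = ov, query_size = length(query),
          set_size = length(set), universe_size = length(universe),
          p_value = p
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$class, .data$direction) |>
    dplyr::mutate(p_bh = stats::p.adjust(.data$p_value, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      neg_log10_p = -log10(.data$p_value),
      passes = .data$p_value < p_cut & .data$overlap_count >= min_overlap
    ) |>
    dplyr::arrange(.data$p_value)
  out
}

#' Cell-type attribution of DEP classes via marker-set enrichment
#'
#' Tests the neuron, astrocyte, and oligodendrocyte marker sets against each
#' DEP class, stratified by direction: 3 classes x 2 directions x 3 sets =
#' 18 results, flagged significant at p < `p_cut` (the conventional 0.05
#' reference line of a -log10(p) bar chart). No minimum-overlap rule is
#' applied here.
#'
#' @param deps DEP table from [select_deps()].
#' @param markers a [gene_set_collection()] containing exactly the sets
#'   `neuron`, `astrocyte`, `oligodendrocyte` (extra sets are ignored).
#' @param p_cut significance reference; default 0.05.
#' @return tibble of 18 enrichment results (see [enrich_sets()]).
#' @export
cell_type_profile <- function(deps, markers, p_cut = 0.05) {
  need <- c("neuron", "astrocyte", "oligodendrocyte")
  missing <- setdiff(need, names(markers$sets))
  if (length(missing) > 0L) {
    stop("missing marker set(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  marker_only <- gene_set_collection(markers$sets[need], markers$universe)
  enrich_sets(deps, marker_only, p_cut = p_cut, min_overlap = 0L,
              directions = c("up", "down"))
}
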