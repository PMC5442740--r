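#' End-to-end pipeline configuration
#'
#' Bundles the simulation configuration, the PSM FDR threshold, the
#' normalization scope, the DEP selection thresholds and the enrichment
#' settings. Defaults equal the printed analysis settings throughout:
#' PSM FDR < 0.01, p < 0.1, at least 2 nonredundant peptides, 90th-percentile
#' fold-change cutoffs, enrichment pass at p < 0.1 with >= 3 DEPs.
#'
#' @param sim a [simulation_config()].
#' @param fdr_threshold PSM q-value cutoff; default 0.01.
#' @param normalize `"joint"`, `"per_replicate"` or `"none"`.
#' @param thresholds a [selection_thresholds()].
#' @param enrich_p_cut,enrich_min_overlap pass rule for gene-set enrichment.
#' @param celltype_p_cut significance reference for the cell-type profile.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            fdr_threshold = 0.01,
                            normalize = c("joint", "per_replicate", "none"),
                            thresholds = selection_thresholds(),
                            enrich_p_cut = 0.1,
                            enrich_min_overlap = 3L,
                            celltype_p_cut = 0.05) {
  normalize <- match.arg(normalize)
  structure(list(sim = sim, fdr_threshold = fdr_threshold, normalize = normalize,
                 thresholds = thresholds, enrich_p_cut = enrich_p_cut,
                 enrich_min_overlap = as.integer(enrich_min_overlap),
                 celltype_p_cut = celltype_p_cut),
            class = "pipeline_config")
}

#' Run the full simulate -> filter -> quantify -> select -> enrich pipeline
#'
#' Executes every stage in order on a freshly generated synthetic dataset,
#' optionally persisting each intermediate table under `out_dir` (PSM TSV,
#' truth TSV, GMT, protein ratio TSV, DEP TSV, enrichment TSVs, and a JSON
#' run report). Identical config and seed give identical tables and report
#' (wall-clock fields aside).
#'
#' @param config a [pipeline_config()].
#' @param out_dir directory for persisted tables, or `NULL` to keep results
#'   in memory only.
#' @return list with every stage's table plus `report` (named counts,
#'   parameter echo and timings).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  stage_time <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    stage_time[[name]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  sim <- generate_dataset(config$sim)
  tick("simulate")

  annotated <- compute_fdr(sim$psms)
  passed <- filter_fdr(annotated, threshold = config$fdr_threshold)
  if (nrow(passed) == 0L) stop("pipeline stage 'filter' failed: no PSM passed FDR",
                               call. = FALSE)
  tick("filter")

  protein_ratios <- quantify_proteins(passed, normalize = config$normalize)
  tick("quantify")

  deps <- select_deps(protein_ratios, thresholds = config$thresholds,
                      incomplete = "drop")
  tick("deps")

  enrichment <- enrich_sets(deps, sim$gene_sets, p_cut = config$enrich_p_cut,
                            min_overlap = config$enrich_min_overlap)
  celltype <- cell_type_profile(deps, sim$gene_sets, p_cut = config$celltype_p_cut)
  tick("enrich")

  report <- list(
    seed = config$sim$seed,
    version = as.character(utils::packageVersion("itraqdep")),
    parameters = list(
      fdr_threshold = config$fdr_threshold,
      normalize = config$normalize,
      p_cut = config$thresholds$p_cut,
      min_peptides = config$thresholds$min_peptides,
      fc_percentile = config$thresholds$fc_percentile,
      norm_fc_percentile = config$thresholds$norm_fc_percentile,
      enrich_p_cut = config$enrich_p_cut,
      enrich_min_overlap = config$enrich_min_overlap
    ),
    counts = list(
      psms_in = nrow(sim$psms),
      psms_passed = nrow(passed),
      proteins_quantified = length(unique(protein_ratios$protein)),
      dep_1day = sum(deps$is_dep_1day),
      dep_2month = sum(deps$is_dep_2month),
      dep_2m_over_1d = sum(deps$is_dep_2m_over_1d),
      enrichment_passes = sum(enrichment$passes),
      celltype_significant = sum(celltype$passes)
    ),
    dep_containment_holds = all(!deps$is_dep_2m_over_1d | deps$is_dep_2month),
    fc_cutoffs = list(
      fc_1day = attr(deps, "fc_cutoff_1day"),
      fc_2month = attr(deps, "fc_cutoff_2month"),
      norm_fc = attr(deps, "norm_fc_cutoff")
    ),
    wall_clock_s = as.list(stage_time)
  )

  out <- list(psms = sim$psms, truth = sim$truth, gene_sets = sim$gene_sets,
              psms_passed = passed, protein_ratios = protein_ratios,
              deps = deps, enrichment = enrichment, celltype = celltype,
              report = report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_psm_tsv(sim$psms, file.path(out_dir, "psms.tsv"))
    write_truth(sim$truth, file.path(out_dir, "truth.tsv"))
    write_gmt(sim$gene_sets, file.path(out_dir, "gene_sets.gmt"))
    write_psm_tsv(passed, file.path(out_dir, "psms.passed.tsv"))
    write_table_tsv(protein_ratios, file.path(out_dir, "protein_ratios.tsv"))
    write_table_tsv(deps, file.path(out_dir, "deps.tsv"))
    write_table_tsv(enrichment, file.path(out_dir, "enrichment.tsv"))
    write_table_tsv(celltype, file.path(out_dir, "celltype_profile.tsv"))
    report_no_clock <- report[setdiff(names(report), "wall_clock_s")]
    jsonlite::write_json(report_no_clock, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
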