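#' Simulation configuration for a 4-plex iTRAQ experiment
#'
#' Defines the generative model for a synthetic peptide-spectrum-match (PSM)
#' table emulating a two-timepoint transplantation design: reporter channels
#' 114 and 115 carry the vehicle condition at 1 day and 2 months, channels
#' 116 and 117 the treatment condition at the same timepoints, measured in
#' replicate iTRAQ experiments. A configured fraction of proteins receives a
#' planted, sign-symmetric log2 fold-change at each timepoint; up-regulated
#' 2-month proteins are preferentially assigned to the oligodendrocyte marker
#' set so that downstream enrichment has a known positive control.
#'
#' @param n_proteins number of target proteins simulated.
#' @param peptides_per_protein integer length-2 vector `c(min, max)`; each
#'   protein draws a uniform peptide count in this range (min >= 1).
#' @param n_replicates number of replicate iTRAQ experiments (>= 2).
#' @param frac_dep_1day,frac_dep_2month proportion of proteins with a planted
#'   nonzero log2 fold-change at 1 day / 2 months.
#' @param log2_effect_mean,log2_effect_sd mean and sd of the planted effect
#'   magnitude on the log2 scale; the sign is symmetric (half up, half down).
#' @param peptide_noise_sd sd of per-PSM, per-channel measurement noise in
#'   log2-intensity units.
#' @param channel_bias length-4 vector of strictly positive multiplicative
#'   scale factors for channels 114/115/116/117 (what normalization removes).
#' @param baseline_log_intensity_mean,baseline_log_intensity_sd protein
#'   baseline log2 reporter intensity distribution.
#' @param decoy_fraction proportion of PSM rows that are decoys.
#' @param target_score_mean,target_score_sd,decoy_score_mean,decoy_score_sd
#'   normal search-score distribution parameters for target and decoy PSMs.
#' @param marker_set_sizes named integer vector with entries `neuron`,
#'   `astrocyte`, `oligodendrocyte`; default scales the reported
#'   1,441 / 1,489 / 1,371-gene marker lists (of a ~15,000-gene background)
#'   down to the simulated universe.
#' @param oligo_enrichment_factor relative odds that an up-regulated 2-month
#'   protein is drawn into the oligodendrocyte marker set.
#' @param n_pathway_sets,pathway_set_size_range number and size range of
#'   additional random pathway-style gene sets included in the collection.
#' @param dropout_rate per-PSM-channel probability of a missing (zero)
#'   intensity; off by default.
#' @param seed integer seed; the generator consumes a single pseudo-random
#'   stream seeded once, so identical configs give byte-identical output.
#' @return a `simulation_config` list, validated.
#' @export
simulation_config <- function(n_proteins = 1000L,
                              peptides_per_protein = c(5L, 10L),
                              n_replicates = 3L,
                              frac_dep_1day = 0.1,
                              frac_dep_2month = 0.1,
                              log2_effect_mean = 1.0,
                              log2_effect_sd = 0,
                              peptide_noise_sd = 0.2,
                              channel_bias = c(1.05, 0.92, 1.10, 0.96),
                              baseline_log_intensity_mean = 16,
                              baseline_log_intensity_sd = 2,
                              decoy_fraction = 0.2,
                              target_score_mean = 15,
                              target_score_sd = 3,
                              decoy_score_mean = 5,
                              decoy_score_sd = 3,
                              marker_set_sizes = NULL,
                              oligo_enrichment_factor = 5,
                              n_pathway_sets = 20L,
                              pathway_set_size_range = c(20L, 100L),
                              dropout_rate = 0,
                              seed = 1L) {
  if (is.null(marker_set_sizes)) {
    marker_set_sizes <- c(
      neuron          = max(1L, round(n_proteins * 1441 / 15000)),
      astrocyte       = max(1L, round(n_proteins * 1489 / 15000)),
      oligodendrocyte = max(1L, round(n_proteins * 1371 / 15000))
    )
  }
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    peptides_per_protein = as.integer(peptides_per_protein),
    n_replicates = as.integer(n_replicates),
    frac_dep_1day = frac_dep_1day,
    frac_dep_2month = frac_dep_2month,
    log2_effect_mean = log2_effect_mean,
    log2_effect_sd = log2_effect_sd,
    peptide_noise_sd = peptide_noise_sd,
    channel_bias = channel_bias,
    baseline_log_intensity_mean = baseline_log_intensity_mean,
    baseline_log_intensity_sd = baseline_log_intensity_sd,
    decoy_fraction = decoy_fraction,
    target_score_mean = target_score_mean,
    target_score_sd = target_score_sd,
    decoy_score_mean = decoy_score_mean,
    decoy_score_sd = decoy_score_sd,
    marker_set_sizes = marker_set_sizes,
    oligo_enrichment_factor = oligo_enrichment_factor,
    n_pathway_sets = as.integer(n_pathway_sets),
    pathway_set_size_range = as.integer(pathway_set_size_range),
    dropout_rate = dropout_rate,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  props <- c("frac_dep_1day", "frac_dep_2month", "decoy_fraction", "dropout_rate")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("config error: `", p, "` must be a proportion in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$n_proteins < 1L) stop("config error: n_proteins must be >= 1", call. = FALSE)
  if (cfg$n_replicates < 2L) stop("config error: n_replicates must be >= 2", call. = FALSE)
  if (length(cfg$peptides_per_protein) != 2L || cfg$peptides_per_protein[1] < 1L ||
      cfg$peptides_per_protein[2] < cfg$peptides_per_protein[1]) {
    stop("config error: peptides_per_protein must be c(min, max) with min >= 1", call. = FALSE)
  }
  if (length(cfg$channel_bias) != 4L || any(cfg$channel_bias <= 0)) {
    stop("config error: channel_bias must be 4 strictly positive scale factors", call. = FALSE)
  }
  for (s in c("log2_effect_sd", "peptide_noise_sd", "baseline_log_intensity_sd",
              "target_score_sd", "decoy_score_sd")) {
    if (cfg[[s]] < 0) stop("config error: `", s, "` must be nonnegative", call. = FALSE)
  }
  if (!all(c("neuron", "astrocyte", "oligodendrocyte") %in% names(cfg$marker_set_sizes))) {
    stop("config error: marker_set_sizes needs neuron, astrocyte, oligodendrocyte entries",
         call. = FALSE)
  }
  if (sum(cfg$marker_set_sizes) > cfg$n_proteins) {
    stop("sizing error: marker_set_sizes sum to more than n_proteins", call. = FALSE)
  }
  invisible(cfg)
}

#' Generate a seeded synthetic iTRAQ dataset with known ground truth
#'
#' Draws a PSM-level table, the planted truth per protein, and a gene-set
#' collection (three cell-type marker sets plus random pathway-style sets)
#' from a single pseudo-random stream seeded once with `config$seed`.
#'
#' The generative model: each protein receives a baseline log2 intensity
#' ~ Normal(baseline mean, sd); each of its peptides, in each replicate,
#' receives four channel intensities
#' `2^(baseline + peptide offset + log2(channel bias) + condition effect +
#' Normal(0, peptide_noise_sd))`, where the condition effect adds the 1-day
#' true log2 fold-change to channel 116 and the 2-month one to channel 117
#' and zero to 114/115. Decoy rows carry scores from the decoy distribution
#' and protein ids prefixed `REV_`. The gene-symbol namespace is the protein
#' id itself (identity mapping).
#'
#' @param config a [simulation_config()].
#' @return list with `psms` (tibble, one row per PSM), `truth` (tibble, one
#'   row per protein) and `gene_sets` (a [gene_set_collection()]).
#' @export
generate_dataset <- function(config) {
  validate_simulation_config(config)
  cfg <- config
  set.seed(cfg$seed)

  protein_id <- sprintf("PROT%05d", seq_len(cfg$n_proteins))

  ## draw order is fixed and documented: baselines, 1-day effects, 2-month
  ## effects, peptide counts, peptide offsets, peptide sequences, marker
  ## membership, pathway sets, target scores, decoys, intensity noise, dropout
  baseline <- stats::rnorm(cfg$n_proteins, cfg$baseline_log_intensity_mean,
                           cfg$baseline_log_intensity_sd)

  draw_effects <- function(frac) {
    fc <- numeric(cfg$n_proteins)
    n_dep <- round(frac * cfg$n_proteins)
    if (n_dep > 0) {
      idx <- sample.int(cfg$n_proteins, n_dep)
      mag <- stats::rnorm(n_dep, cfg$log2_effect_mean, cfg$log2_effect_sd)
      sgn <- rep_len(c(1, -1), n_dep)[sample.int(n_dep)]
      fc[idx] <- sgn * mag
    }
    fc
  }
  true_log2fc_1day <- draw_effects(cfg$frac_dep_1day)
  true_log2fc_2month <- draw_effects(cfg$frac_dep_2month)

  n_pep <- sample(seq(cfg$peptides_per_protein[1], cfg$peptides_per_protein[2]),
                  cfg$n_proteins, replace = TRUE)
  n_target_pep <- sum(n_pep)
  pep_offset <- stats::rnorm(n_target_pep, 0, 1)
  peptide <- random_peptides(n_target_pep)

  membership <- assign_marker_membership(
    protein_id, true_log2fc_2month, cfg$marker_set_sizes, cfg$oligo_enrichment_factor
  )

  pathway_sets <- list()
  if (cfg$n_pathway_sets > 0) {
    sizes <- sample(seq(cfg$pathway_set_size_range[1], cfg$pathway_set_size_range[2]),
                    cfg$n_pathway_sets, replace = TRUE)
    sizes <- pmin(sizes, cfg$n_proteins)
    pathway_sets <- lapply(sizes, function(sz) sample(protein_id, sz))
    names(pathway_sets) <- sprintf("PATHWAY_%03d", seq_len(cfg$n_pathway_sets))
  }

  ## expand to PSM level: one PSM per peptide x replicate
  pep_protein <- rep(seq_len(cfg$n_proteins), times = n_pep)
  reps <- seq_len(cfg$n_replicates)
  pep_idx <- rep(seq_len(n_target_pep), each = cfg$n_replicates)
  rep_lab <- rep(reps, times = n_target_pep)
  n_target_psm <- length(pep_idx)

  prot_of_psm <- pep_protein[pep_idx]
  mu <- baseline[prot_of_psm] + pep_offset[pep_idx]
  effect <- cbind(0, 0, true_log2fc_1day[prot_of_psm], true_log2fc_2month[prot_of_psm])
  bias <- matrix(log2(cfg$channel_bias), n_target_psm, 4, byrow = TRUE)
  target_scores <- stats::rnorm(n_target_psm, cfg$target_score_mean, cfg$target_score_sd)

  n_decoy <- if (cfg$decoy_fraction >= 1) {
    stop("config error: decoy_fraction must be < 1", call. = FALSE)
  } else {
    round(cfg$decoy_fraction * n_target_psm / (1 - cfg$decoy_fraction))
  }
  decoy_scores <- stats::rnorm(n_decoy, cfg$decoy_score_mean, cfg$decoy_score_sd)
  decoy_pep <- random_peptides(n_decoy)
  decoy_base <- stats::rnorm(n_decoy, cfg$baseline_log_intensity_mean,
                             cfg$baseline_log_intensity_sd)

  noise <- matrix(stats::rnorm(4L * n_target_psm, 0, cfg$peptide_noise_sd),
                  n_target_psm, 4)
  target_int <- 2^(mu + bias + effect + noise)

  decoy_noise <- matrix(stats::rnorm(4L * n_decoy, 0, cfg$peptide_noise_sd), n_decoy, 4)
  decoy_int <- 2^(decoy_base + matrix(log2(cfg$channel_bias), n_decoy, 4, byrow = TRUE) +
                    decoy_noise)

  if (cfg$dropout_rate > 0) {
    drop_t <- matrix(stats::runif(4L * n_target_psm) < cfg$dropout_rate, n_target_psm, 4)
    target_int[drop_t] <- 0
    if (n_decoy > 0) {
      drop_d <- matrix(stats::runif(4L * n_decoy) < cfg$dropout_rate, n_decoy, 4)
      decoy_int[drop_d] <- 0
    }
  }

  psms <- tibble::tibble(
    psm_id = sprintf("PSM%07d", seq_len(n_target_psm + n_decoy)),
    peptide = c(peptide[pep_idx], decoy_pep),
    protein = c(protein_id[prot_of_psm], sprintf("REV_DECOY%05d", seq_len(n_decoy))),
    is_decoy = rep(c(FALSE, TRUE), c(n_target_psm, n_decoy)),
    score = c(target_scores, decoy_scores),
    replicate = c(rep_lab, rep(1L, n_decoy)),
    i114 = c(target_int[, 1], decoy_int[, 1]),
    i115 = c(target_int[, 2], decoy_int[, 2]),
    i116 = c(target_int[, 3], decoy_int[, 3]),
    i117 = c(target_int[, 4], decoy_int[, 4])
  )
  if (n_decoy > 0) {
    psms$replicate[psms$is_decoy] <- sample(reps, n_decoy, replace = TRUE)
  }

  truth <- tibble::tibble(
    protein_id = protein_id,
    true_log2fc_1day = true_log2fc_1day,
    true_log2fc_2month = true_log2fc_2month,
    is_dep_1day = true_log2fc_1day != 0,
    is_dep_2month = true_log2fc_2month != 0,
    cell_type_membership = membership
  )

  marker_sets <- split(protein_id, membership)
  marker_sets <- marker_sets[setdiff(names(marker_sets), "none")]
  gene_sets <- gene_set_collection(c(marker_sets, pathway_sets), universe = protein_id)

  list(psms = psms, truth = truth, gene_sets = gene_sets)
}

## weighted draw of the oligodendrocyte set (up-regulated 2-month proteins get
## `factor` times the odds), then uniform fill of the neuron / astrocyte sets
assign_marker_membership <- function(protein_id, true_log2fc_2month,
                                     sizes, factor) {
  n <- length(protein_id)
  membership <- rep("none", n)
  w <- ifelse(true_log2fc_2month > 0, factor, 1)
  oligo <- sample.int(n, sizes[["oligodendrocyte"]], prob = w)
  membership[oligo] <- "oligodendrocyte"
  rest <- which(membership == "none")
  neuro <- sample(rest, sizes[["neuron"]])
  membership[neuro] <- "neuron"
  rest <- which(membership == "none")
  astro <- sample(rest, sizes[["astrocyte"]])
  membership[astro] <- "astrocyte"
  membership
}

random_peptides <- function(n, min_len = 8L, max_len = 15L) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  lens <- sample(seq(min_len, max_len), n, replace = TRUE)
  seqs <- vapply(lens, function(l) paste(sample(aa, l, replace = TRUE), collapse = ""),
                 character(1))
  ## suffix guarantees uniqueness without disturbing the look of a tryptic peptide
  paste0(seqs, "K", format_base26(seq_len(n)))
}

format_base26 <- function(i) {
  vapply(i, function(x) {
    out <- character(0)
    x <- x - 1L
    repeat {
      out <- c(LETTERS[x %% 26L + 1L], out)
      x <- x %/% 26L
      if (x == 0L) break
      x <- x - 1L
    }
    paste(out, collapse = "")
  }, character(1))
}
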