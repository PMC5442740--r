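test_that("quantile normalization reproduces the textbook two-column example", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  out <- quantile_normalize(m)
  expect_equal(unname(out), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))
})

test_that("quantile normalization fixes identical-multiset columns and single columns", {
  m <- cbind(c(3, 1, 2), c(1, 2, 3))  # same multiset, different order
  expect_equal(quantile_normalize(m), m)
  single <- matrix(c(5, 1, 7), ncol = 1)
  expect_equal(quantile_normalize(single), single)
})

test_that("after normalization all columns share one sorted value vector", {
  set.seed(1)
  m <- matrix(rnorm(40 * 12, 16, 2), 40, 12)
  out <- quantile_normalize(m)
  ref <- sort(out[, 1])
  for (j in 2:12) expect_equal(sort(out[, j]), ref)
  # ranks within each column preserved
  for (j in 1:12) expect_equal(rank(out[, j]), rank(m[, j]))
  # agrees with an independently hand-rolled implementation (tie-free input)
  expect_equal(unname(out), unname(qn_oracle(m)))
})

test_that("normalization rejects non-finite input and too-few rows", {
  m <- cbind(c(1, NA), c(2, 3))
  expect_error(quantile_normalize(m), "non-finite")
  expect_error(quantile_normalize(matrix(1:2, 1)), ">= 2 rows")
})

test_that("peptide ratios are the log2 channel differences per replicate", {
  psms <- make_psms(function(p, q, r) c(100, 50, 200, 50), "PROT1",
                    peptides_per_protein = 1L, replicates = 1:2)
  mat <- reporter_matrix(psms)
  rt <- peptide_ratios(mat)
  expect_equal(nrow(rt), 2)  # one peptide seen in two replicates
  expect_equal(rt$log2_ratio_1day, c(1, 1))   # 200 vs 100
  expect_equal(rt$log2_ratio_2month, c(0, 0)) # 50 vs 50
})

test_that("repeat PSMs for one peptide in a replicate are summed before log transform", {
  psms <- make_psms(function(p, q, r) c(100, 100, 100, 100), "PROT1",
                    peptides_per_protein = 1L, replicates = 1L)
  psms <- dplyr::bind_rows(psms, psms)  # the same peptide matched twice
  psms$psm_id <- c("A", "B")
  mat <- reporter_matrix(psms)
  expect_equal(nrow(mat), 1)
  expect_equal(mat$i114_1, log2(200))
})

test_that("rows with a zero intensity are dropped under the no-imputation policy", {
  psms <- make_psms(function(p, q, r) if (q == 1) c(0, 50, 100, 50) else c(100, 50, 100, 50),
                    "PROT1", peptides_per_protein = 2L, replicates = 1L)
  mat <- reporter_matrix(psms)
  expect_equal(nrow(mat), 1)
  expect_equal(attr(mat, "n_dropped_incomplete"), 1)
})

test_that("the L1 protein ratio matches the grid-search oracle and handles flat optima", {
  expect_equal(lp_protein_ratio(0.7), 0.7)
  expect_equal(lp_protein_ratio(c(0.2, 1.0, 1.2)), 1.0)
  expect_equal(l1_grid_oracle(c(0.2, 1.0, 1.2))$argmin, 1.0)
  # even n: optimum is flat on [0, 1]; documented tie policy returns midpoint
  expect_equal(lp_protein_ratio(c(0, 1)), 0.5)
  probe <- seq(0, 1, by = 0.1)
  objs <- vapply(probe, function(rho) l1_objective(c(0, 1), rho), numeric(1))
  expect_equal(objs, rep(1, length(probe)))
  expect_error(lp_protein_ratio(numeric(0)), "no finite")
})

test_that("the L1 ratio also agrees with a convex-optimization route", {
  set.seed(2)
  for (i in 1:50) {
    r <- rnorm(sample(1:9, 1))
    est <- lp_protein_ratio(r)
    opt <- optimize(function(rho) sum(abs(r - rho)),
                    c(min(r) - 1, max(r) + 1), tol = 1e-10)
    expect_lte(sum(abs(r - est)), opt$objective + 1e-7)
  }
})

test_that("shared peptides are excluded before the protein roll-up", {
  rt <- tibble::tibble(
    peptide = c("p1", "p2", "p3", "p3", "p4"),
    protein = c("A", "A", "A", "B", "B"),
    replicate = 1L,
    log2_ratio_1day = c(1, 1, 5, 5, 0),
    log2_ratio_2month = 0
  )
  out <- aggregate_proteins(rt)
  a <- out[out$protein == "A", ]
  expect_equal(a$n_nonredundant_peptides, 2)   # p3 shared with B, dropped
  expect_equal(a$log2_abundance_1day, 1)       # median of {1, 1}
})

test_that("protein aggregation is invariant to peptide row order", {
  set.seed(3)
  rt <- tibble::tibble(
    peptide = paste0("p", 1:30),
    protein = rep(c("A", "B", "C"), each = 10),
    replicate = rep(1:2, 15),
    log2_ratio_1day = rnorm(30),
    log2_ratio_2month = rnorm(30)
  )
  out1 <- aggregate_proteins(rt)
  out2 <- aggregate_proteins(rt[sample(30), ])
  expect_equal(out1, out2)
})

test_that("noise-free synthetic data is recovered exactly without normalization", {
  cfg <- simulation_config(n_proteins = 40L, peptides_per_protein = c(2L, 4L),
                           peptide_noise_sd = 0, channel_bias = c(1, 1, 1, 1),
                           seed = 9L)
  sim <- generate_dataset(cfg)
  targets <- sim$psms[!sim$psms$is_decoy, ]
  pr <- quantify_proteins(targets, normalize = "none")
  merged <- dplyr::left_join(pr, sim$truth, by = c(protein = "protein_id"))
  expect_equal(merged$log2_abundance_1day, merged$true_log2fc_1day)
  expect_equal(merged$log2_abundance_2month, merged$true_log2fc_2month)
})

test_that("joint quantile normalization undoes channel bias on null proteins", {
  cfg <- simulation_config(n_proteins = 300L, peptides_per_protein = c(3L, 5L),
                           frac_dep_1day = 0, frac_dep_2month = 0,
                           peptide_noise_sd = 0.1,
                           channel_bias = c(1.4, 0.7, 1.1, 0.9), seed = 13L)
  sim <- generate_dataset(cfg)
  pr <- quantify_proteins(sim$psms[!sim$psms$is_decoy, ], normalize = "joint")
  # all proteins null: mean log2 ratio should be ~0 despite strong channel bias
  expect_lt(abs(mean(pr$log2_abundance_1day)), 0.02)
  expect_lt(abs(mean(pr$log2_abundance_2month)), 0.02)
})
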