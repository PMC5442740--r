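# Independent oracles used to validate the package's implementations.
# Each is deliberately brute-force and shares no code with the package.

# grid-search minimizer of the L1 objective sum |r - rho|
l1_grid_oracle <- function(r, step = 1e-4, pad = 0.5) {
  lo <- floor((min(r) - pad) / step) * step
  hi <- ceiling((max(r) + pad) / step) * step
  grid <- seq(lo, hi, by = step)
  obj <- colSums(abs(outer(r, grid, "-")))
  list(argmin = grid[which.min(obj)], objmin = min(obj))
}

l1_objective <- function(r, rho) sum(abs(r - rho))

# per-PSM q-values by explicit scan over every candidate threshold
fdr_scan_oracle <- function(score, is_decoy) {
  thr <- unique(score)
  fdr_at <- vapply(thr, function(s) {
    d <- sum(is_decoy & score >= s)
    t <- sum(!is_decoy & score >= s)
    min(1, d / max(1, t))
  }, numeric(1))
  vapply(score, function(s) min(fdr_at[thr <= s]), numeric(1))
}

# exhaustive-enumeration hypergeometric upper tail: draw every possible
# query of size n from universe 1..N whose first K elements are the set
hyper_enum_oracle <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  ov <- colSums(draws <= K)
  mean(ov >= k)
}

# high-precision upper tail via log-space summation of the exact pmf
hyper_lchoose_oracle <- function(k, n, K, N) {
  kk <- seq(max(0, n - (N - K)), min(K, n))
  logp <- lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)
  sum(exp(logp[kk >= k]))
}

# hand-rolled quantile normalization (tie-free inputs only)
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) ref[rank(col, ties.method = "first")])
}

# two-sided t-test p-value through numerical integration of the t density
t_pvalue_integrate <- function(tstat, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  tail <- stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-12)$value
  2 * tail
}

# small deterministic PSM fixture used across filter tests: target scores
# {10, 9, 8, 7}, decoy scores {8.5, 6}
six_psm_fixture <- function() {
  tibble::tibble(
    psm_id = paste0("P", 1:6),
    peptide = paste0("PEPTIDE", LETTERS[1:6], "K"),
    protein = c("A", "B", "C", "D", "REV_X", "REV_Y"),
    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    score = c(10, 9, 8, 7, 8.5, 6),
    replicate = 1L,
    i114 = 100, i115 = 100, i116 = 100, i117 = 100
  )
}

# PSM table with chosen per-channel intensities, one protein/peptide grid
make_psms <- function(intensity_fun, proteins, peptides_per_protein = 2L,
                      replicates = 1:3) {
  rows <- list()
  id <- 0L
  for (p in seq_along(proteins)) {
    for (q in seq_len(peptides_per_protein)) {
      for (r in replicates) {
        id <- id + 1L
        ints <- intensity_fun(p, q, r)
        rows[[id]] <- tibble::tibble(
          psm_id = sprintf("PSM%04d", id),
          peptide = sprintf("PEP_%s_%02d", proteins[p], q),
          protein = proteins[p],
          is_decoy = FALSE, score = 20, replicate = as.integer(r),
          i114 = ints[1], i115 = ints[2], i116 = ints[3], i117 = ints[4]
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
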