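test_that("hypergeometric upper tail matches hand-computed and boundary cases", {
  expect_equal(hypergeom_upper_tail(0, 4, 5, 10), 1)
  expect_equal(hypergeom_upper_tail(4, 4, 5, 10), 5 / 210)
  expect_equal(hyper_enum_oracle(4, 4, 5, 10), 5 / 210)
  expect_equal(hypergeom_upper_tail(6, 6, 6, 6), 1)  # saturated draw
  expect_error(hypergeom_upper_tail(5, 4, 5, 10), "inconsistent")
  expect_error(hypergeom_upper_tail(2, 4, 5, 3), "inconsistent")
})

test_that("upper tail matches exhaustive enumeration for every small parameter triple", {
  for (N in c(6, 9, 12)) {
    for (n in seq(1, N, by = 2)) {
      draws <- utils::combn(N, n)
      for (K in seq(1, N, by = 3)) {
        ov <- colSums(draws <= K)
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_upper_tail(k, n, K, N), mean(ov >= k),
                       tolerance = 1e-14)
        }
      }
    }
  }
})

test_that("upper tail matches a log-space summation reference at realistic scale", {
  cases <- list(c(30, 100, 1371, 15000), c(3, 50, 91, 1000),
                c(10, 242, 1489, 9073), c(0, 40, 200, 5000),
                c(25, 143, 1441, 9073))
  for (cs in cases) {
    p <- hypergeom_upper_tail(cs[1], cs[2], cs[3], cs[4])
    ref <- hyper_lchoose_oracle(cs[1], cs[2], cs[3], cs[4])
    expect_equal(p, ref, tolerance = 1e-12)
  }
})

test_that("the hypergeometric pmf sums to one for random valid parameter triples", {
  set.seed(5)
  for (i in 1:25) {
    N <- sample(20:2000, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    support <- max(0, n - (N - K)):min(K, n)
    expect_equal(sum(dhyper(support, K, N - K, n)), 1, tolerance = 1e-12)
  }
})

make_dep_table <- function(universe, dep_1day = character(0),
                           dep_2month = character(0),
                           dep_2m1d = character(0),
                           direction = "up") {
  tibble::tibble(
    protein = universe,
    is_dep_1day = universe %in% dep_1day,
    is_dep_2month = universe %in% dep_2month,
    is_dep_2m_over_1d = universe %in% dep_2m1d,
    direction_1day = direction,
    direction_2month = direction
  )
}

test_that("marker sets sized like the published lists detect a planted overlap", {
  # 15,000-gene universe; neuron/astrocyte/oligodendrocyte marker sizes
  # 1,441 / 1,489 / 1,371; a 100-gene up-regulated query with 30 oligo markers
  genes <- sprintf("G%05d", 1:15000)
  sets <- list(neuron = genes[1:1441],
               astrocyte = genes[1442:2930],
               oligodendrocyte = genes[2931:4301])
  markers <- gene_set_collection(sets, genes)
  query <- c(genes[2931:2960], genes[14001:14070])  # 30 oligo + 70 background
  deps <- make_dep_table(genes, dep_2month = query)
  prof <- cell_type_profile(deps, markers)
  expect_equal(nrow(prof), 18)
  oligo_up <- prof[prof$set_name == "oligodendrocyte" & prof$class == "2month" &
                     prof$direction == "up", ]
  expect_equal(oligo_up$overlap_count, 30)
  expect_lt(oligo_up$p_value, 0.05)
  expect_equal(oligo_up$p_value,
               hyper_lchoose_oracle(30, 100, 1371, 15000), tolerance = 1e-12)
  # empty down-regulated query: p = 1 throughout
  down <- prof[prof$direction == "down", ]
  expect_equal(down$p_value, rep(1, nrow(down)))
  # purity: identical query tested twice gives identical results
  expect_equal(prof, cell_type_profile(deps, markers))
})

test_that("a query disjoint from every set passes nothing", {
  genes <- sprintf("G%03d", 1:200)
  coll <- gene_set_collection(list(s1 = genes[1:50], s2 = genes[51:100]), genes)
  deps <- make_dep_table(genes, dep_1day = genes[150:170])
  res <- enrich_sets(deps, coll)
  expect_false(any(res$passes))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
})

test_that("the minimum-overlap rule vetoes significant but tiny overlaps", {
  # set of 2, query of 2, both members hit: p is small but overlap < 3
  genes <- sprintf("G%03d", 1:200)
  coll <- gene_set_collection(list(tiny = genes[1:2]), genes)
  deps <- make_dep_table(genes, dep_1day = genes[1:2])
  res <- enrich_sets(deps, coll, p_cut = 0.1, min_overlap = 3L)
  hit <- res[res$class == "1day" & res$direction == "up", ]
  expect_lt(hit$p_value, 1e-3)
  expect_equal(hit$overlap_count, 2)
  expect_false(hit$passes)
})

test_that("enlarging the query with genes outside every set keeps p-values valid", {
  genes <- sprintf("G%03d", 1:300)
  coll <- gene_set_collection(list(s = genes[1:40]), genes)
  q1 <- genes[1:10]
  for (extra in c(0, 50, 150)) {
    deps <- make_dep_table(genes, dep_2month = c(q1, genes[101:(100 + extra)]))
    res <- enrich_sets(deps, coll)
    expect_true(all(res$p_value > 0 & res$p_value <= 1))
  }
})

test_that("missing marker sets and empty inputs are rejected", {
  genes <- sprintf("G%03d", 1:100)
  two_sets <- gene_set_collection(list(neuron = genes[1:10],
                                       astrocyte = genes[11:20]), genes)
  deps <- make_dep_table(genes)
  expect_error(cell_type_profile(deps, two_sets), "oligodendrocyte")
  expect_error(enrich_sets(deps[0, ], two_sets), "empty DEP")
  expect_error(gene_set_collection(list(), genes), "empty gene-set")
  expect_error(gene_set_collection(list(a = "g", a = "h"), genes), "unique")
})

test_that("planted oligodendrocyte enrichment propagates through the whole pipeline", {
  res <- run_pipeline(pipeline_config(
    sim = simulation_config(n_proteins = 600L, peptides_per_protein = c(4L, 6L),
                            seed = 17L)))
  prof <- res$celltype
  up2m <- prof[prof$class == "2month" & prof$direction == "up", ]
  expect_lt(up2m$p_value[up2m$set_name == "oligodendrocyte"], 0.05)
  expect_gt(min(up2m$p_value[up2m$set_name != "oligodendrocyte"]), 0.05)
})
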