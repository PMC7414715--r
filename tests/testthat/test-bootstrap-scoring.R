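test_that("bootstrap ensembles are seeded, deterministic and well-defined", {
  sim <- simulate_family(sim_config(seed = 9, n_columns = 150,
                                    n_diagnostic = 15))
  pairs <- extract_paralog_pairs(sim$alignment, sim$gene_map)

  ens0 <- bootstrap_fates(sim$alignment, pairs, n = 0)
  expect_equal(ens0$n, 0L)

  e1 <- bootstrap_fates(sim$alignment, pairs, n = 5, seed = 3)
  e2 <- bootstrap_fates(sim$alignment, pairs, n = 5, seed = 3)
  expect_identical(e1$replicates, e2$replicates)

  # a no-signal family has unstable replicate clusterings, so different
  # seeds must yield different ensembles
  simn <- simulate_family(sim_config(seed = 9, n_columns = 150,
                                     n_diagnostic = 0))
  pn <- extract_paralog_pairs(simn$alignment, simn$gene_map)
  n1 <- bootstrap_fates(simn$alignment, pn, n = 5, seed = 3)
  n3 <- bootstrap_fates(simn$alignment, pn, n = 5, seed = 4)
  expect_false(identical(n1$replicates, n3$replicates))
})

test_that("an alignment of identical columns bootstraps to its baseline", {
  # one informative column repeated: resampling cannot change anything
  col <- c(gA1 = "A", gA2 = "C", gB1 = "A", gB2 = "C",
           gC1 = "A", gC2 = "C")
  seqs <- vapply(col, function(ch) paste(rep(ch, 40), collapse = ""),
                 character(1))
  aln <- family_alignment(seqs, names(seqs))
  map <- c(gA1 = "spA", gA2 = "spA", gB1 = "spB", gB2 = "spB",
           gC1 = "spC", gC2 = "spC")
  pairs <- extract_paralog_pairs(aln, map)
  qt <- quartet_table(aln, pairs, mode = "parsimony")
  baseline <- markov_clustering(build_fate_network(qt))
  ens <- bootstrap_fates(aln, pairs, n = 20, seed = 1)
  for (rep_blocks in ens$replicates)
    expect_true(setequal(lapply(rep_blocks, sort),
                         lapply(baseline$blocks, sort)))
  rob <- jaccard_robust_clusters(baseline, ens)
  expect_equal(unname(rob$robustness), rep(1, length(rob$clusters)))
})

test_that("robustness is the mean best jaccard match over replicates", {
  baseline <- structure(list(
    membership = stats::setNames(c(1L, 1L, 2L, 2L), c("a", "b", "c", "d")),
    blocks = list(c("a", "b"), c("c", "d"))), class = "fate_clustering")
  ens <- structure(list(replicates = list(
    list(c("a", "b"), c("c", "d")),        # perfect
    list(c("a", "b", "c"), c("d")),        # jaccards 2/3 and 1/2
    list()), n = 3L, seed = NULL),         # empty replicate scores 0
    class = "bootstrap_ensemble")
  rob <- jaccard_robust_clusters(baseline, ens, min_robustness = 0)
  expect_equal(unname(rob$baseline_robustness),
               c(mean(c(1, 2 / 3, 0)), mean(c(1, 1 / 2, 0))))

  # a cluster never recovered is dropped at the default cutoff
  ens2 <- structure(list(replicates = list(list(c("a", "b"), c("x", "y"))),
                         n = 1L, seed = NULL), class = "bootstrap_ensemble")
  rob2 <- jaccard_robust_clusters(baseline, ens2, min_robustness = 0.5)
  expect_equal(length(rob2$clusters), 1L)
  expect_equal(rob2$clusters[["F1"]], c("a", "b"))

  # disabled bootstrap keeps everything at robustness 1
  ens0 <- structure(list(replicates = list(), n = 0L, seed = NULL),
                    class = "bootstrap_ensemble")
  expect_equal(unname(jaccard_robust_clusters(baseline, ens0)$robustness),
               c(1, 1))
})

test_that("pervasiveness counts duplications split across one fate pair", {
  pairs <- data.frame(
    species_id = paste0("sp", 1:6),
    gene_a = paste0("sp", 1:6, "_a"), gene_b = paste0("sp", 1:6, "_b"),
    stringsAsFactors = FALSE)
  dups <- manual_dups(list(c("sp1", "sp2"), c("sp3", "sp4"), c("sp5", "sp6")))
  fates <- manual_fates(list(paste0("sp", 1:6, "_a"), paste0("sp", 1:6, "_b")))
  pv <- pervasiveness(dups, fates, pairs)
  expect_equal(pv$P, 3L)
  expect_equal(pv$prevailing, c("F1", "F2"))

  # one block diverted to a third fate is excluded
  fates2 <- manual_fates(list(paste0("sp", 1:4, "_a"),
                              paste0("sp", 1:4, "_b"),
                              c(paste0("sp", 5:6, "_a"),
                                paste0("sp", 5:6, "_b"))))
  pv2 <- pervasiveness(dups, fates2, pairs)
  expect_equal(pv2$P, 2L)

  # a pair with both genes in one fate cannot support its block
  fates3 <- manual_fates(list(
    c(paste0("sp", 1:2, "_a"), "sp3_a", "sp3_b"),
    paste0("sp", 1:2, "_b")))
  pv3 <- pervasiveness(dups, fates3, pairs)
  expect_equal(pv3$P, 1L)

  # fewer than two robust fates: P = 0, flagged
  pv0 <- pervasiveness(dups, manual_fates(list(paste0("sp", 1:6, "_a"))),
                       pairs)
  expect_equal(pv0$P, 0L)
  expect_true(pv0$flagged)
})

test_that("P never increases when a duplication block's species are removed", {
  sim <- simulate_family(sim_config(seed = 17))
  rep_full <- analyze_family(sim$alignment, sim$gene_map,
                             mode = "parsimony", seed = 17)
  drop_sp <- c("sp01", "sp02", "sp03")
  keep <- !(sim$gene_map %in% drop_sp)
  seqs <- apply(sim$alignment$mat[keep, ], 1, paste, collapse = "")
  aln2 <- family_alignment(seqs, names(seqs))
  rep_small <- analyze_family(aln2, sim$gene_map[keep],
                              mode = "parsimony", seed = 17)
  expect_lte(rep_small$P, rep_full$P)
})

test_that("the family magnitude averages Z_F over qualifying quartets", {
  pairs <- data.frame(
    species_id = c("sp1", "sp2", "sp3"),
    gene_a = c("sp1_a", "sp2_a", "sp3_a"),
    gene_b = c("sp1_b", "sp2_b", "sp3_b"), stringsAsFactors = FALSE)
  dups <- manual_dups(list(c("sp1"), c("sp2"), c("sp3")))
  fates <- manual_fates(list(paste0("sp", 1:3, "_a"),
                             paste0("sp", 1:3, "_b")))
  qtab <- data.frame(
    species_x = c("sp1", "sp1", "sp2"), species_y = c("sp2", "sp3", "sp3"),
    gene_a = c("sp1_a", "sp1_a", "sp2_a"),
    gene_b = c("sp1_b", "sp1_b", "sp2_b"),
    gene_c = c("sp2_a", "sp3_a", "sp3_a"),
    gene_d = c("sp2_b", "sp3_b", "sp3_b"),
    Z_F = c(2, 4, 6), stringsAsFactors = FALSE)
  # restrict to the first two quartets by shrinking the fate pair coverage
  expect_equal(mean_fate_zscore(qtab, dups, fates, c("F1", "F2"), pairs),
               mean(c(2, 4, 6)))

  # P < 2: undefined
  dups1 <- manual_dups(list(c("sp1", "sp2", "sp3")))
  expect_true(is.na(mean_fate_zscore(qtab, dups1, fates, c("F1", "F2"),
                                     pairs)))
})

test_that("analyze_family rejects families with too few pairs", {
  aln <- make_aln(a1 = "ACDEFAAC", a2 = "ACDEFAAD", b1 = "ACDEFAAE")
  map <- c(a1 = "spA", a2 = "spA", b1 = "spB")
  expect_error(analyze_family(aln, map),
               class = "refates_insufficient_pairs")

  sim <- simulate_family(sim_config(seed = 3, n_columns = 200,
                                    n_diagnostic = 15))
  expect_error(analyze_family(sim$alignment, sim$gene_map,
                              mode = "parsimony", min_pairs = 12),
               class = "refates_insufficient_pairs")
})

test_that("reports round-trip through the written files", {
  sim <- simulate_family(sim_config(seed = 21, n_columns = 200,
                                    n_diagnostic = 20))
  rep <- analyze_family(sim$alignment, sim$gene_map, mode = "parsimony",
                        seed = 21, bootstrap_n = 10)
  dir <- file.path(tempdir(), "reptest")
  write_report(rep, dir)
  qt <- read_quartet_table(dir)
  expect_equal(nrow(qt), nrow(rep$quartets))
  expect_equal(qt$Z_F, rep$quartets$Z_F, tolerance = 1e-9)
  dups <- read_duplication_clusters(dir)
  expect_equal(dups$membership, rep$duplication$membership)
  fates <- read_robust_fates(dir)
  expect_equal(fates$clusters, rep$robust_fates$clusters)
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$P, rep$P)
  expect_equal(js$Zbar_F, rep$Zbar_F, tolerance = 1e-9)
})
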