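test_that("quartet subsampling caps the table deterministically", {
  qtab <- data.frame(i = 1:50)
  expect_identical(sample_quartets(qtab, max_n = 50), qtab)
  s1 <- sample_quartets(qtab, max_n = 10, seed = 4)
  s2 <- sample_quartets(qtab, max_n = 10, seed = 4)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 10L)
  expect_false(is.unsorted(s1$i))
})

test_that("quartets are categorized by blocks and WGD annotation", {
  qtab <- data.frame(
    species_x = c("spA", "spA", "spB"), species_y = c("spB", "spC", "spC"),
    gene_a = c("a1", "a1", "b1"), gene_b = c("a2", "a2", "b2"),
    gene_c = c("b1", "c1", "c1"), gene_d = c("b2", "c2", "c2"),
    stringsAsFactors = FALSE)
  dups <- manual_dups(list(c("spA", "spB"), "spC"))
  wgd <- data.frame(species = "spA", gene_a = "a1", gene_b = "a2",
                    label = "WGD", stringsAsFactors = FALSE)
  out <- categorize_quartets(qtab, dups, wgd)
  expect_equal(out$category,
               c("single_duplication_wgd", "independent_duplication",
                 "independent_duplication"))

  # without annotation: single duplications default to "other"
  out2 <- categorize_quartets(qtab, dups)
  expect_equal(out2$category[1], "single_duplication_other")

  # conflicting labels are flagged and excluded
  wgd2 <- rbind(wgd, data.frame(species = "spB", gene_a = "b1",
                                gene_b = "b2", label = "Other"))
  out3 <- categorize_quartets(qtab, dups, wgd2)
  expect_true(is.na(out3$category[1]))
  expect_true(out3$category_flagged[1])

  # simulated family: truth categories recovered exactly
  sim <- simulate_family(sim_config(seed = 6))
  pairs <- extract_paralog_pairs(sim$alignment, sim$gene_map)
  qt <- quartet_table(sim$alignment, pairs, mode = "parsimony")
  dupcl <- cluster_editing(build_duplication_network(qt))
  qt <- categorize_quartets(qt, dupcl)
  truth_blocks <- sim$truth$dup_block
  want <- ifelse(truth_blocks[qt$species_x] != truth_blocks[qt$species_y],
                 "independent_duplication", "single_duplication_other")
  expect_equal(qt$category, unname(want))
})

test_that("asymmetry summaries are exact proportions with exact SEs", {
  qtab <- data.frame(category = rep("independent_duplication", 12),
                     Z_F = c(rep(3, 10), 0.5, NA),
                     Z_A = c(rep(3, 9), 0.2, 5, NA))
  s <- asymmetry_summary(qtab)
  expect_equal(s$n_significant, 10L)
  expect_equal(s$fraction, 0.9)
  expect_equal(s$se, sqrt(0.9 * 0.1 / 10), tolerance = 1e-12)
  expect_equal(s$se, 0.095, tolerance = 1e-2)

  none <- asymmetry_summary(data.frame(category = "x", Z_F = 0.3, Z_A = 0.1))
  expect_true(is.na(none$fraction))

  # independent recount from a simulated quartet table
  sim <- simulate_family(sim_config(seed = 12, asymmetry_mode = "one_sided"))
  pairs <- extract_paralog_pairs(sim$alignment, sim$gene_map)
  qt <- quartet_table(sim$alignment, pairs, mode = "parsimony")
  qt <- categorize_quartets(qt, cluster_editing(build_duplication_network(qt)))
  s2 <- asymmetry_summary(qt)
  for (i in seq_len(nrow(s2))) {
    sub <- qt[qt$category == s2$category[i] & abs(qt$Z_F) > 1.96, ]
    sub <- sub[!is.na(sub$Z_F), ]
    expect_equal(s2$n_significant[i], nrow(sub))
    expect_equal(s2$fraction[i], mean(abs(sub$Z_A) > 1.96))
  }
})

test_that("localization configurations match their definitions", {
  expect_equal(refates:::classify_localization("Mito", "Cyto", "Mito",
                                               "Cyto", "R"), "consistent")
  expect_equal(refates:::classify_localization("Mito", "Cyto", "Cyto",
                                               "Mito", "R"), "inconsistent")
  expect_equal(refates:::classify_localization("Cyto", "Cyto", "Cyto",
                                               "Cyto", "R"), "uniform")
  expect_equal(refates:::classify_localization("Mito", "Cyto", "Cyto",
                                               "Cyto", "R"), "single_distinct")
  expect_equal(refates:::classify_localization("Mito", "Cyto", "Mito",
                                               "Chlo", "R"), "other")

  # the reliability filter is strict and excludes whole quartets
  qtab <- data.frame(species_x = "spX", species_y = "spY",
                     gene_a = "a", gene_b = "b", gene_c = "c", gene_d = "d",
                     pairing = "R", stringsAsFactors = FALSE)
  loc <- data.frame(gene_id = c("a", "b", "c", "d"),
                    compartment = c("Mito", "Cyto", "Mito", "Cyto"),
                    reliability_class = c(1L, 2L, 1L, 3L))
  out <- localization_configuration(qtab, loc)
  expect_true(is.na(out$loc_config))
  expect_equal(out$loc_excluded, "unreliable")
  loc$reliability_class[4] <- 2L
  expect_equal(localization_configuration(qtab, loc)$loc_config, "consistent")
})

test_that("localization tables parse the TargetP vocabulary", {
  p <- tempfile()
  writeLines(c("gene_id\tcompartment\treliability_class",
               "g1\tMito\t1", "g2\tother\t2", "g3\tSecr\t5"), p)
  tab <- read_localization_table(p)
  expect_equal(tab$compartment, c("Mito", "Cyto", "Secr"))
  writeLines("g1\tNucleus\t1", p)
  expect_error(read_localization_table(p), class = "refates_format_error")
})

test_that("column patterns color by fate support and contradiction", {
  # two species in different duplication blocks, one pair each; columns:
  # 1 = full fate match (ABAB), 2 = crossed (ABBA), 3 = one-sided support,
  # 4 = constant, 5 = shared gap block in fate 1 (support via absence)
  aln <- make_aln(x1 = "AAAC-", x2 = "CCGCD",
                  y1 = "ACACD", y2 = "CAGC-")
  # col1: r1=A r2=C s1=A s2=C -> symmetric support
  # col2: r1=A r2=C s1=C s2=A -> symmetric contradiction
  # col3: r1=A r2=G s1=A s2=G -> symmetric support
  # col4: constant -> uninformative
  # col5: r1=- r2=D s1=D s2=- -> crossed via gap: contradiction
  pairs <- data.frame(species_id = c("spX", "spY"),
                      gene_a = c("x1", "y1"), gene_b = c("x2", "y2"),
                      stringsAsFactors = FALSE)
  dups <- manual_dups(list("spX", "spY"))
  fates <- manual_fates(list(c("x1", "y1"), c("x2", "y2")))
  ann <- color_positions(aln, pairs, dups, fates)
  x <- ann[ann$species_id == "spX", ]
  expect_equal(x$color[1], "yellow")
  expect_equal(x$color[2], "blue")
  expect_equal(x$color[3], "yellow")
  expect_equal(x$color[4], "none")
  expect_equal(x$color[5], "blue")
  expect_equal(x$class[5], "symmetric_contradict")
})

test_that("logos aggregate pair annotations and ignore processing order", {
  sim <- simulate_family(sim_config(seed = 19, n_columns = 150,
                                    n_diagnostic = 12))
  rep <- analyze_family(sim$alignment, sim$gene_map, mode = "parsimony",
                        seed = 19, bootstrap_n = 0)
  ann <- color_positions(sim$alignment, rep$pairs, rep$duplication,
                         rep$robust_fates, rep$prevailing)
  logo <- build_logo(ann)
  expect_true(all(colSums(logo) <= 1 + 1e-9))
  expect_equal(ncol(logo), 150)

  # order invariance: shuffle the pairs
  perm <- c(7, 1, 12, 3, 9, 2, 11, 4, 10, 5, 8, 6)
  ann2 <- color_positions(sim$alignment, rep$pairs[perm, ], rep$duplication,
                          rep$robust_fates, rep$prevailing)
  logo2 <- build_logo(ann2)
  expect_equal(logo, logo2)

  # a single pair's logo is its own indicator pattern
  one <- ann[ann$species_id == ann$species_id[1], ]
  class(one) <- class(ann)
  l1 <- build_logo(one)
  inform <- one$class != "uninformative"
  expect_equal(unname(colSums(l1)[one$column[inform]]),
               rep(1, sum(inform)))
})
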