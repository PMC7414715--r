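# Synthetic gene families with known duplication events and fates.
#
# Sequences evolve along a species tree under an amino-acid substitution
# process.  At each configured duplication node the lineage forks into two
# copies that evolve independently through the subtree below; every species
# under a duplication therefore carries one paralog pair whose copies
# belong to fate 1 and fate 2.  Recurrence is injected through diagnostic
# columns: at each such column, every gene of the constrained fate — across
# all independent duplications — is set to the same residue, emulating a
# recurrently conserved motif, while the other fate evolves freely.
# Optionally, fate-2 copies gain an N-terminal extension block (gapped in
# all other rows), emulating a recurrently gained target peptide, together
# with per-fate subcellular localization labels.

.default_tree_text <- paste0(
  "(((((sp01:0.15,sp02:0.15):0.15,sp03:0.3)d1:0.5,",
  "((sp04:0.15,sp05:0.15):0.15,sp06:0.3)d2:0.5):0.3,",
  "(((sp07:0.15,sp08:0.15):0.15,sp09:0.3)d3:0.5,",
  "((sp10:0.15,sp11:0.15):0.15,sp12:0.3)d4:0.5):0.3):0.0);")

#' Default simulated species tree
#'
#' Twelve species in four clades of three; the clade ancestors carry node
#' labels `d1` .. `d4` and serve as the default independent duplication
#' placements.  Within-clade depth is 0.3 substitutions/site and clades are
#' separated by long internal branches, so paralog pairs stay alignable
#' while species from different clades are clearly diverged.
#'
#' @return An `ape` `phylo` object.
#' @export
default_species_tree <- function() {
  ape::read.tree(text = .default_tree_text)
}

#' Simulation configuration
#'
#' @param species_tree An `ape` `phylo`, a newick string, or a path to a
#'   newick file; defaults to [default_species_tree()].
#' @param duplication_placements Node (or tip) labels at which independent
#'   duplications occur; the subtrees below must be disjoint so each species
#'   has at most one duplication ancestor.
#' @param n_columns Core alignment columns (excluding any extension block).
#' @param n_diagnostic Diagnostic columns per fate.
#' @param asymmetry_mode `"symmetric"` (each fate conserves its own columns)
#'   or `"one_sided"` (all diagnostic columns constrain fate 1 only).
#' @param target_peptide_len Length of the N-terminal extension carried by
#'   fate-2 copies (0 disables it).
#' @param subst_model `"lg"` (default) or `"poisson_uniform"` (substitute to
#'   a uniformly chosen different residue).
#' @param gamma_shape Optional gamma shape for across-site rate variation
#'   (sites draw one of 10 discrete-gamma category rates); `NULL` gives
#'   rate homogeneity.
#' @param loc_labels Optional named compartments `c(f1 = ..., f2 = ...)`
#'   from `Mito`/`Chlo`/`Secr`/`Cyto`; emits a localization table.
#' @param reliability_class Reliability class for emitted localization rows.
#' @param seed Integer seed; the simulation is deterministic given the seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(species_tree = NULL,
                       duplication_placements = c("d1", "d2", "d3", "d4"),
                       n_columns = 500L, n_diagnostic = 30L,
                       asymmetry_mode = c("symmetric", "one_sided"),
                       target_peptide_len = 0L,
                       subst_model = c("lg", "poisson_uniform"),
                       gamma_shape = NULL, loc_labels = NULL,
                       reliability_class = 1L, seed = 1L) {
  asymmetry_mode <- match.arg(asymmetry_mode)
  subst_model <- match.arg(subst_model)
  tree <- if (is.null(species_tree)) default_species_tree()
  else if (inherits(species_tree, "phylo")) species_tree
  else if (is.character(species_tree) && file.exists(species_tree))
    ape::read.tree(species_tree)
  else if (is.character(species_tree))
    ape::read.tree(text = species_tree)
  else rf_stop("refates_config_error", "cannot interpret species_tree")
  if (is.null(tree) || is.null(tree$edge.length))
    rf_stop("refates_config_error", "species tree needs branch lengths")
  n_columns <- as.integer(n_columns)
  n_diagnostic <- as.integer(n_diagnostic)
  if (2L * n_diagnostic > n_columns)
    rf_stop("refates_config_error",
            "need 2 * n_diagnostic <= n_columns (%d > %d)",
            2L * n_diagnostic, n_columns)
  labels <- c(tree$tip.label, tree$node.label)
  bad <- setdiff(duplication_placements, labels)
  if (length(bad))
    rf_stop("refates_config_error",
            "duplication placements not in the tree: %s",
            paste(bad, collapse = ", "))
  tipsets <- lapply(duplication_placements, function(pl) .tips_below(tree, pl))
  if (length(tipsets) > 1L) {
    for (i in seq_along(tipsets)) for (j in seq_len(i - 1L))
      if (length(intersect(tipsets[[i]], tipsets[[j]])))
        rf_stop("refates_config_error",
                "duplication placements %s and %s overlap",
                duplication_placements[j], duplication_placements[i])
  }
  if (!is.null(loc_labels)) {
    stopifnot(length(loc_labels) == 2L)
    if (!all(loc_labels %in% LOC_COMPARTMENTS))
      rf_stop("refates_config_error", "loc_labels must be from %s",
              paste(LOC_COMPARTMENTS, collapse = "/"))
    if (is.null(names(loc_labels))) names(loc_labels) <- c("f1", "f2")
  }
  structure(list(tree = tree, duplication_placements = duplication_placements,
                 n_columns = n_columns, n_diagnostic = n_diagnostic,
                 asymmetry_mode = asymmetry_mode,
                 target_peptide_len = as.integer(target_peptide_len),
                 subst_model = subst_model, gamma_shape = gamma_shape,
                 loc_labels = loc_labels,
                 reliability_class = as.integer(reliability_class),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.tips_below <- function(tree, label) {
  nt <- length(tree$tip.label)
  if (label %in% tree$tip.label) return(label)
  node <- nt + match(label, tree$node.label)
  desc <- node
  repeat {
    children <- tree$edge[tree$edge[, 1L] %in% desc, 2L]
    new <- setdiff(children, desc)
    if (!length(new)) break
    desc <- c(desc, new)
  }
  tree$tip.label[desc[desc <= nt]]
}

# Evolve integer-coded residues (1..20) along one branch.
.evolve_branch <- function(seq, len, site_rates, model, subst_model) {
  out <- seq
  if (len <= 0) return(out)
  for (r in unique(site_rates)) {
    sites <- which(site_rates == r)
    if (subst_model == "lg") {
      P <- transition_matrix(model, len, r)
      for (p in unique(out[sites])) {
        ss <- sites[out[sites] == p]
        out[ss] <- sample.int(20L, length(ss), replace = TRUE, prob = P[p, ])
      }
    } else {
      hit <- sites[stats::runif(length(sites)) < 1 - exp(-len * r)]
      if (length(hit)) {
        shift <- sample.int(19L, length(hit), replace = TRUE)
        out[hit] <- 1L + (out[hit] - 1L + shift) %% 20L
      }
    }
  }
  out
}

#' Simulate a gene family with known duplications and fates
#'
#' @param cfg A [sim_config()].
#' @return Object of class `sim_family`: list with `alignment` (a
#'   [family_alignment()]), `gene_map` (named gene-to-species vector),
#'   `truth` (per-gene fate, per-species duplication block, diagnostic and
#'   extension column indices, 1-based in alignment coordinates),
#'   `localization` (data frame or `NULL`) and `config`.
#' @export
simulate_family <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, .simulate_family_impl(cfg))
}

.simulate_family_impl <- function(cfg) {
  tree <- cfg$tree
  nt <- length(tree$tip.label)
  model <- lg_model()
  L <- cfg$target_peptide_len + cfg$n_columns
  site_rates <- if (is.null(cfg$gamma_shape)) rep(1, L) else
    sample(discrete_gamma_rates(cfg$gamma_shape, 10L), L, replace = TRUE)
  node_label <- function(node)
    if (node <= nt) tree$tip.label[node] else tree$node.label[node - nt]

  genes <- list(); gene_sp <- character(); gene_fate <- character()
  emit <- function(tip, seq, fate) {
    sp <- tree$tip.label[tip]
    id <- paste0(sp, if (identical(fate, "f2")) "_b" else "_a")
    genes[[id]] <<- seq
    gene_sp[id] <<- sp
    gene_fate[id] <<- if (is.null(fate)) NA_character_ else fate
  }
  descend <- function(node, seq, fate) {
    kids <- which(tree$edge[, 1L] == node)
    for (e in kids) {
      child <- tree$edge[e, 2L]
      cseq <- .evolve_branch(seq, tree$edge.length[e], site_rates, model,
                             cfg$subst_model)
      visit(child, cseq, fate)
    }
  }
  visit <- function(node, seq, fate) {
    dup_here <- node_label(node) %in% cfg$duplication_placements &&
      is.null(fate)
    if (node <= nt) {
      if (dup_here) { emit(node, seq, "f1"); emit(node, seq, "f2") }
      else emit(node, seq, fate)
      return()
    }
    if (dup_here) { descend(node, seq, "f1"); descend(node, seq, "f2") }
    else descend(node, seq, fate)
  }
  root <- nt + 1L
  root_seq <- sample.int(20L, L, replace = TRUE, prob = model$frequencies)
  visit(root, root_seq, NULL)

  mat <- do.call(rbind, genes)
  rownames(mat) <- names(genes)

  # diagnostic columns (drawn from the core block, after any extension)
  core <- seq.int(cfg$target_peptide_len + 1L, L)
  diag_cols <- if (cfg$n_diagnostic > 0L)
    sample(core, 2L * cfg$n_diagnostic) else integer()
  d1 <- sort(diag_cols[seq_len(cfg$n_diagnostic)])
  d2 <- sort(diag_cols[-seq_len(cfg$n_diagnostic)])
  frozen <- sample.int(20L, length(diag_cols), replace = TRUE,
                       prob = model$frequencies)
  names(frozen) <- as.character(sort(c(d1, d2)))
  freeze <- function(fate, cols) {
    rows <- which(gene_fate[rownames(mat)] %in% fate)
    for (cc in cols) mat[rows, cc] <<- frozen[[as.character(cc)]]
  }
  if (cfg$n_diagnostic > 0L) {
    if (cfg$asymmetry_mode == "symmetric") {
      freeze("f1", d1); freeze("f2", d2)
    } else {
      freeze("f1", c(d1, d2))
    }
  }

  chars <- matrix(AA_ORDER[mat], nrow = nrow(mat),
                  dimnames = dimnames(mat))
  ext_cols <- seq_len(cfg$target_peptide_len)
  if (cfg$target_peptide_len > 0L) {
    not_f2 <- which(is.na(gene_fate[rownames(mat)]) |
                      gene_fate[rownames(mat)] != "f2")
    chars[not_f2, ext_cols] <- "-"
  }
  aln <- family_alignment(apply(chars, 1L, paste, collapse = ""),
                          rownames(chars))

  dup_block <- stats::setNames(rep(NA_character_, nt), tree$tip.label)
  for (pl in cfg$duplication_placements)
    dup_block[.tips_below(tree, pl)] <- pl

  localization <- NULL
  if (!is.null(cfg$loc_labels)) {
    fate_key <- ifelse(is.na(gene_fate), "f1", gene_fate)
    localization <- data.frame(
      gene_id = names(genes),
      compartment = unname(cfg$loc_labels[fate_key]),
      reliability_class = cfg$reliability_class,
      stringsAsFactors = FALSE)
  }
  truth <- list(fate = gene_fate, dup_block = dup_block,
                diagnostic_columns = list(f1 = d1, f2 = d2),
                extension_columns = as.integer(ext_cols),
                frozen_residues = AA_ORDER[frozen])
  structure(list(alignment = aln, gene_map = gene_sp, truth = truth,
                 localization = localization, config = cfg),
            class = "sim_family")
}

#' Simulate columns of a single quartet from a known topology
#'
#' Generates four sequences on the unrooted 4-taxon tree with the given
#' topology: two internal nodes joined by the internal branch, each bearing
#' two terminal branches.  Used to validate topology inference (the
#' duplication score D).
#'
#' @param topology `"Q"`, `"R"` or `"S"` — which gene pairs (of `a`, `b`
#'   from species X and `c`, `d` from species Y) are sisters.
#' @param n_columns Number of columns.
#' @param terminal_bl,internal_bl Branch lengths.
#' @param model Substitution model used for simulation.
#' @param gamma_shape Optional shape for across-site rate variation (sites
#'   draw one of 10 discrete-gamma category rates); `NULL` for homogeneity.
#' @param seed Integer seed.
#' @return Integer matrix 4 x `n_columns` (rows a, b, c, d; codes 1..20).
#' @export
simulate_quartet <- function(topology = c("Q", "R", "S"), n_columns = 200L,
                             terminal_bl = 0.3, internal_bl = 1.0,
                             model = lg_model(), gamma_shape = NULL,
                             seed = NULL) {
  topology <- match.arg(topology)
  with_local_seed(seed, {
    rates <- if (is.null(gamma_shape)) rep(1, n_columns) else
      sample(discrete_gamma_rates(gamma_shape, 10L), n_columns,
             replace = TRUE)
    anc1 <- sample.int(20L, n_columns, replace = TRUE,
                       prob = model$frequencies)
    anc2 <- .evolve_branch(anc1, internal_bl, rates, model, "lg")
    tips <- list(
      .evolve_branch(anc1, terminal_bl, rates, model, "lg"),
      .evolve_branch(anc1, terminal_bl, rates, model, "lg"),
      .evolve_branch(anc2, terminal_bl, rates, model, "lg"),
      .evolve_branch(anc2, terminal_bl, rates, model, "lg"))
    ord <- switch(topology,
                  Q = c(1L, 2L, 3L, 4L),   # (a,b) | (c,d)
                  R = c(1L, 3L, 2L, 4L),   # (a,c) | (b,d)
                  S = c(1L, 4L, 2L, 3L))   # (a,d) | (b,c)
    x <- do.call(rbind, tips)[order(ord), , drop = FALSE]
    rownames(x) <- c("a", "b", "c", "d")
    x
  })
}

#' Write simulation outputs as plain-text fixtures
#'
#' Emits `family.fasta`, `gene_species_map.tsv`, `truth.json`, optionally
#' `localization.tsv`, and `sim_config.json` into a directory.  Re-reading
#' the files reproduces the simulated objects exactly.
#'
#' @param sim A [simulate_family()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_family"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir))
    rf_stop("refates_io_error", "cannot create directory %s", dir)
  paths <- c(fasta = file.path(dir, "family.fasta"),
             map = file.path(dir, "gene_species_map.tsv"),
             truth = file.path(dir, "truth.json"),
             config = file.path(dir, "sim_config.json"))
  write_alignment(sim$alignment, paths[["fasta"]])
  utils::write.table(
    data.frame(gene_id = names(sim$gene_map), species_id = sim$gene_map),
    paths[["map"]], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = FALSE,
                       pretty = TRUE, digits = NA, na = "null")
  cfg <- sim$config
  cfg_json <- list(duplication_placements = cfg$duplication_placements,
                   n_columns = cfg$n_columns,
                   n_diagnostic = cfg$n_diagnostic,
                   asymmetry_mode = cfg$asymmetry_mode,
                   target_peptide_len = cfg$target_peptide_len,
                   subst_model = cfg$subst_model,
                   gamma_shape = cfg$gamma_shape,
                   loc_labels = cfg$loc_labels,
                   reliability_class = cfg$reliability_class,
                   seed = cfg$seed,
                   species_tree = ape::write.tree(cfg$tree))
  jsonlite::write_json(cfg_json, paths[["config"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  if (!is.null(sim$localization)) {
    paths[["localization"]] <- file.path(dir, "localization.tsv")
    utils::write.table(sim$localization, paths[["localization"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Vectors of cluster labels over the same items (named vectors
#'   are matched by name).
#' @return The adjusted Rand index (1 for identical partitions, about 0 for
#'   independent ones).
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
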