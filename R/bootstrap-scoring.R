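# Bootstrap-supported fate clusters and the family-level summary scores:
# pervasiveness P (number of independent duplications whose paralogs end up
# in the same two fates) and magnitude mean Z_F over the quartets that show
# recurrent sequence evolution.

#' Bootstrap the fate clustering
#'
#' Resamples alignment columns with replacement to the original length and
#' redoes the quartet pattern analysis and fate clustering for each
#' replicate.  The duplication clustering is held fixed from the full data:
#' only the fate side is bootstrapped, and recomputing likelihood weights per
#' replicate would be disproportionate for a column-resampling assessment.
#'
#' @param aln A [family_alignment()] (untrimmed; the fate path).
#' @param pairs Paralog pairs from [extract_paralog_pairs()].
#' @param n Number of bootstrap replicates (default 100); `n = 0` disables
#'   bootstrapping (all baseline clusters then count as fully robust).
#' @param seed Optional base seed; replicate `r` uses `seed + r`.
#' @param inflation,expansion Markov clustering parameters.
#' @return Object of class `bootstrap_ensemble`: list with `replicates` (one
#'   list of gene clusters per replicate; empty when a replicate had no
#'   informative columns), `n` and `seed`.
#' @export
bootstrap_fates <- function(aln, pairs, n = 100L, seed = NULL,
                            inflation = 10, expansion = 5) {
  stopifnot(inherits(aln, "family_alignment"))
  coded <- encode_alignment(aln)
  L <- ncol(coded)
  np <- nrow(pairs)
  idx <- if (np >= 2L) utils::combn(np, 2L) else matrix(integer(), 2L, 0L)
  replicates <- vector("list", n)
  for (r in seq_len(n)) {
    cols <- with_local_seed(if (is.null(seed)) NULL else seed + 7919L * r,
                            sample.int(L, L, replace = TRUE))
    sub <- coded[, cols, drop = FALSE]
    edges <- list()
    for (k in seq_len(ncol(idx))) {
      p1 <- pairs[idx[1L, k], ]; p2 <- pairs[idx[2L, k], ]
      cnt <- pattern_counts_coded(sub[p1$gene_a, ], sub[p1$gene_b, ],
                                  sub[p2$gene_a, ], sub[p2$gene_b, ])
      if (cnt$degenerate) next
      fs <- fate_similarity(cnt)
      if (fs$pairing == "tie") next
      e <- if (fs$pairing == "R")
        rbind(c(p1$gene_a, p2$gene_a), c(p1$gene_b, p2$gene_b))
      else
        rbind(c(p1$gene_a, p2$gene_b), c(p1$gene_b, p2$gene_a))
      edges[[length(edges) + 1L]] <- cbind(e, fs$F)
    }
    if (!length(edges)) { replicates[[r]] <- list(); next }
    em <- do.call(rbind, edges)
    genes <- sort(unique(c(em[, 1L], em[, 2L])))
    W <- matrix(0, length(genes), length(genes),
                dimnames = list(genes, genes))
    Nw <- W
    for (i in seq_len(nrow(em))) {
      g1 <- em[i, 1L]; g2 <- em[i, 2L]; w <- as.numeric(em[i, 3L])
      W[g1, g2] <- W[g1, g2] + w; W[g2, g1] <- W[g2, g1] + w
      Nw[g1, g2] <- Nw[g1, g2] + 1; Nw[g2, g1] <- Nw[g2, g1] + 1
    }
    W[Nw > 0] <- W[Nw > 0] / Nw[Nw > 0]
    cl <- suppressWarnings(markov_clustering(W, inflation = inflation,
                                             expansion = expansion))
    replicates[[r]] <- cl$blocks
  }
  structure(list(replicates = replicates, n = as.integer(n), seed = seed),
            class = "bootstrap_ensemble")
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Select robust, non-overlapping fate clusters
#'
#' The robustness of a baseline fate cluster is its mean best Jaccard match
#' over bootstrap replicates.  Baseline clusters are kept greedily by
#' descending robustness, skipping any that overlap an already-kept cluster,
#' and dropping those below `min_robustness` — filtering out fates that
#' depend on a few specific alignment positions.
#'
#' @param baseline A `fate_clustering` from [markov_clustering()].
#' @param ens A [bootstrap_fates()] ensemble.
#' @param min_robustness Minimum robustness for a cluster to be retained.
#' @return Object of class `robust_fate_set`: list with `clusters` (named
#'   list `F1`, `F2`, ... of gene vectors), `robustness` (per kept cluster),
#'   `baseline_robustness` (per baseline cluster) and `fate_of` (named
#'   gene-to-fate lookup).
#' @export
jaccard_robust_clusters <- function(baseline, ens, min_robustness = 0.5) {
  blocks <- baseline$blocks
  rob <- if (ens$n == 0L) rep(1, length(blocks)) else
    vapply(blocks, function(b) {
      mean(vapply(ens$replicates, function(rep_blocks) {
        if (!length(rep_blocks)) return(0)
        max(vapply(rep_blocks, jaccard, numeric(1L), a = b))
      }, numeric(1L)))
    }, numeric(1L))
  # deterministic order: robustness desc, then size desc, then first gene
  ord <- order(-rob,
               -lengths(blocks),
               vapply(blocks, function(b) sort(b)[1L], character(1L)))
  kept <- list(); kept_rob <- numeric(); used <- character()
  for (i in ord) {
    if (rob[i] < min_robustness) next
    if (length(intersect(blocks[[i]], used))) next
    kept[[length(kept) + 1L]] <- sort(blocks[[i]])
    kept_rob <- c(kept_rob, rob[i])
    used <- c(used, blocks[[i]])
  }
  names(kept) <- if (length(kept)) paste0("F", seq_along(kept)) else character()
  fate_of <- stats::setNames(rep(names(kept), lengths(kept)),
                             unlist(kept, use.names = FALSE))
  structure(list(clusters = kept, robustness = stats::setNames(kept_rob, names(kept)),
                 baseline_robustness = rob, fate_of = fate_of),
            class = "robust_fate_set")
}

# Which duplication blocks are fully split across the fate pair (f1, f2)?
.qualifying_blocks <- function(dups, fates, pairs, f1, f2) {
  fate_of <- fates$fate_of
  ok <- vapply(seq_along(dups$blocks), function(bi) {
    sp <- dups$blocks[[bi]]
    rows <- pairs[pairs$species_id %in% sp, , drop = FALSE]
    if (nrow(rows) == 0L) return(FALSE)
    all(vapply(seq_len(nrow(rows)), function(i) {
      fa <- fate_of[rows$gene_a[i]]; fb <- fate_of[rows$gene_b[i]]
      !is.na(fa) && !is.na(fb) && setequal(c(fa, fb), c(f1, f2)) && fa != fb
    }, logical(1L)))
  }, logical(1L))
  which(ok)
}

#' Pervasiveness of recurrent sequence evolution
#'
#' `P` is the number of duplication events (blocks of the duplication
#' clustering) for which every member species' paralog pair is split across
#' the same two robust fates.  The fate pair achieving the maximum is the
#' prevailing differentiation; ties are broken by the larger mean `Z_F`
#' (when a quartet table is supplied) and then lexicographically.
#'
#' @param dups A `duplication_clustering` from [cluster_editing()].
#' @param fates A `robust_fate_set` from [jaccard_robust_clusters()].
#' @param pairs Paralog pairs of the family.
#' @param qtab Optional quartet table, used only for tie-breaking.
#' @return List with `P`, `prevailing` (character vector of two fate ids, or
#'   `NULL`), `blocks` (indices of qualifying duplication blocks) and
#'   `flagged` (`TRUE` when no fate pair covers any duplication).
#' @export
pervasiveness <- function(dups, fates, pairs, qtab = NULL) {
  fate_ids <- names(fates$clusters)
  if (length(fate_ids) < 2L)
    return(list(P = 0L, prevailing = NULL, blocks = integer(), flagged = TRUE))
  cand <- utils::combn(sort(fate_ids), 2L)
  counts <- integer(ncol(cand))
  qual <- vector("list", ncol(cand))
  for (k in seq_len(ncol(cand))) {
    qual[[k]] <- .qualifying_blocks(dups, fates, pairs, cand[1L, k], cand[2L, k])
    counts[k] <- length(qual[[k]])
  }
  P <- max(counts)
  if (P == 0L)
    return(list(P = 0L, prevailing = NULL, blocks = integer(), flagged = TRUE))
  top <- which(counts == P)
  if (length(top) > 1L && !is.null(qtab)) {
    zb <- vapply(top, function(k) {
      z <- .zbar_for(qtab, dups, pairs, fates, cand[, k], qual[[k]])
      if (is.na(z)) -Inf else z
    }, numeric(1L))
    top <- top[zb == max(zb)]
  }
  k <- top[1L]                          # candidates are in lexicographic order
  list(P = as.integer(P), prevailing = cand[, k], blocks = qual[[k]],
       flagged = FALSE)
}

.zbar_for <- function(qtab, dups, pairs, fates, prevailing, blocks) {
  if (length(blocks) < 2L) return(NA_real_)
  sp_block <- dups$membership
  keep_sp <- names(sp_block)[sp_block %in% blocks]
  bx <- sp_block[qtab$species_x]; by <- sp_block[qtab$species_y]
  sel <- qtab$species_x %in% keep_sp & qtab$species_y %in% keep_sp & bx != by
  z <- qtab$Z_F[sel]
  if (!length(z)) return(NA_real_)
  mean(z, na.rm = TRUE)
}

#' Family magnitude of recurrent sequence evolution
#'
#' The mean `Z_F` over quartets whose two paralog pairs come from different
#' duplication blocks counted in `P` (independently duplicated pairs whose
#' genes fall in the prevailing fates).  Undefined (`NA`) when `P < 2`.
#'
#' @param qtab Quartet table.
#' @param dups Duplication clustering.
#' @param fates Robust fate set.
#' @param prevailing Character vector of the two prevailing fate ids.
#' @param pairs Paralog pairs of the family.
#' @return The mean `Z_F`, or `NA` when fewer than two duplications qualify.
#' @export
mean_fate_zscore <- function(qtab, dups, fates, prevailing, pairs) {
  if (is.null(prevailing) || length(prevailing) != 2L) return(NA_real_)
  blocks <- .qualifying_blocks(dups, fates, pairs, prevailing[1L], prevailing[2L])
  .zbar_for(qtab, dups, pairs, fates, prevailing, blocks)
}

#' Full recurrent-sequence-evolution analysis of one family
#'
#' Runs the whole pipeline: paralog-pair extraction, quartet scoring,
#' duplication clustering (cluster editing on `D`), fate clustering (Markov
#' clustering on `F`), alignment bootstrap of the fates, and the family
#' scores `P` and mean `Z_F`.
#'
#' @param aln A [family_alignment()].
#' @param gene_map Named gene-to-species vector.
#' @param mode `"ml"` (ELW duplication scores; reference) or `"parsimony"`
#'   (pattern-share screening).
#' @param model Substitution model for the likelihood route.
#' @param theta Cluster-editing threshold on `D`.
#' @param elw_replicates ELW resampling replicates per quartet.
#' @param bootstrap_n Alignment bootstrap replicates for fate robustness.
#' @param min_robustness Robustness cutoff for fate clusters.
#' @param min_pairs Require more than this many paralog pairs (input filter;
#'   0 disables it).
#' @param z_threshold Significance threshold used in summaries.
#' @param seed Integer seed governing every stochastic step.
#' @param max_gap_frac Gap trimming threshold for the duplication path.
#' @param estimate_shape Estimate the gamma shape per quartet (ml mode).
#' @return Object of class `rse_report`; see [write_report()] for the file
#'   layout.
#' @export
analyze_family <- function(aln, gene_map, mode = c("ml", "parsimony"),
                           model = lg_model(), theta = 0.6,
                           elw_replicates = 1000L, bootstrap_n = 100L,
                           min_robustness = 0.5, min_pairs = 0L,
                           z_threshold = 1.96, seed = NULL,
                           max_gap_frac = 0.5, estimate_shape = TRUE) {
  mode <- match.arg(mode)
  pairs <- extract_paralog_pairs(aln, gene_map)
  if (nrow(pairs) < 2L || nrow(pairs) <= min_pairs)
    rf_stop("refates_insufficient_pairs",
            "family has %d usable paralog pairs (need > %d and >= 2)",
            nrow(pairs), min_pairs)
  qtab <- quartet_table(aln, pairs, mode = mode, model = model,
                        B = elw_replicates, seed = seed,
                        max_gap_frac = max_gap_frac,
                        estimate_shape = estimate_shape)
  dup_net <- build_duplication_network(qtab, theta = theta)
  dups <- cluster_editing(dup_net, theta = theta)
  fate_net <- build_fate_network(qtab)
  baseline <- suppressWarnings(markov_clustering(fate_net))
  ens <- bootstrap_fates(aln, pairs, n = bootstrap_n,
                         seed = if (is.null(seed)) NULL else seed + 500000L)
  robust <- jaccard_robust_clusters(baseline, ens,
                                    min_robustness = min_robustness)
  perv <- pervasiveness(dups, robust, pairs, qtab)
  zbar <- if (perv$P >= 2L)
    mean_fate_zscore(qtab, dups, robust, perv$prevailing, pairs)
  else NA_real_
  structure(list(
    n_genes = length(aln$gene_ids), n_columns = aln$length,
    pairs = pairs, quartets = qtab,
    duplication_network = dup_net, duplication = dups,
    fate_network = fate_net, fate_baseline = baseline,
    bootstrap = ens, robust_fates = robust,
    P = perv$P, prevailing = perv$prevailing,
    qualifying_blocks = perv$blocks, P_flagged = perv$flagged,
    Zbar_F = zbar,
    params = list(mode = mode, model = model$name,
                  gamma_categories = model$n_categories, theta = theta,
                  elw_replicates = elw_replicates, bootstrap_n = bootstrap_n,
                  min_robustness = min_robustness, min_pairs = min_pairs,
                  z_threshold = z_threshold, seed = seed,
                  max_gap_frac = max_gap_frac,
                  estimate_shape = estimate_shape)),
    class = "rse_report")
}

#' @export
print.rse_report <- function(x, ...) {
  cat(sprintf("recurrent sequence evolution report\n"))
  cat(sprintf("  genes: %d  columns: %d  paralog pairs: %d  quartets: %d\n",
              x$n_genes, x$n_columns, nrow(x$pairs), nrow(x$quartets)))
  cat(sprintf("  duplication blocks: %d  robust fates: %d\n",
              length(x$duplication$blocks), length(x$robust_fates$clusters)))
  if (!is.null(x$prevailing))
    cat(sprintf("  prevailing fate pair: %s / %s\n",
                x$prevailing[1L], x$prevailing[2L]))
  cat(sprintf("  P = %d%s   Zbar_F = %s\n", x$P,
              if (x$P_flagged) " (no fate pair covers a duplication)" else "",
              if (is.na(x$Zbar_F)) "undefined (P < 2)"
              else sprintf("%.3f", x$Zbar_F)))
  invisible(x)
}
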