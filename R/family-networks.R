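# Family-level integration of quartet scores.
#
# Duplication side: a complete species graph weighted by D is partitioned by
# weighted cluster editing; species pairs with D above the threshold theta
# attract (they likely share the ancestral duplication), pairs below repel.
# Fate side: a gene graph weighted by F links paralogs of different species
# that share a fate under the quartet's resolved pairing; Markov clustering
# with strong inflation extracts the fates.  Both steps exploit the
# transitivity of shared-duplication and shared-fate relations.

#' Build the species duplication network
#'
#' @param qtab Quartet table from [quartet_table()].
#' @param theta Neutral weight given to edges of degenerate quartets (also
#'   the later cluster-editing threshold, so such edges neither attract nor
#'   repel).
#' @return Object of class `duplication_network`: list with `species` and
#'   the symmetric weight matrix `D` (no self-edges).
#' @export
build_duplication_network <- function(qtab, theta = 0.6) {
  species <- sort(unique(c(qtab$species_x, qtab$species_y)))
  if (length(species) < 2L)
    rf_stop("refates_network_error",
            "a duplication network needs at least two species")
  D <- matrix(NA_real_, length(species), length(species),
              dimnames = list(species, species))
  for (k in seq_len(nrow(qtab))) {
    d <- qtab$D[k]
    if (is.na(d)) d <- theta
    D[qtab$species_x[k], qtab$species_y[k]] <- d
    D[qtab$species_y[k], qtab$species_x[k]] <- d
  }
  miss <- which(is.na(D) & row(D) != col(D))
  if (length(miss)) D[miss] <- theta
  diag(D) <- NA_real_
  structure(list(species = species, D = D), class = "duplication_network")
}

#' Partition species into shared ancestral duplications by cluster editing
#'
#' Uses the signed similarity `s(i,j) = D(i,j) - theta`: species pairs with
#' high duplication support attract, others repel.  The editing cost of a
#' partition is the attraction lost between blocks plus the repulsion kept
#' within blocks; minimizing it is equivalent to maximizing the within-block
#' sum of `s`.  Small instances (up to 10 species) are solved exactly by
#' enumerating set partitions; larger ones use a deterministic greedy pivot
#' construction followed by single-node local moves.
#'
#' @param net A [build_duplication_network()] result.
#' @param theta Attraction/repulsion boundary on `D` (default 0.6).
#' @param method `"auto"` (exact up to 10 nodes), `"exact"`, or
#'   `"heuristic"`.
#' @return Object of class `duplication_clustering`: list with `membership`
#'   (named integer vector; blocks numbered by first species), `blocks`
#'   (list of species vectors), `cost` (editing cost achieved) and `method`.
#' @export
cluster_editing <- function(net, theta = 0.6,
                            method = c("auto", "exact", "heuristic")) {
  method <- match.arg(method)
  stopifnot(inherits(net, "duplication_network"))
  species <- sort(net$species)
  s <- net$D[species, species, drop = FALSE] - theta
  diag(s) <- 0
  n <- length(species)
  if (method == "auto") method <- if (n <= 10L) "exact" else "heuristic"
  membership <- if (method == "exact") .ce_exact(s) else .ce_heuristic(s)
  membership <- .canonical_membership(membership)
  names(membership) <- species
  blocks <- split(species, membership)
  structure(list(membership = membership, blocks = unname(blocks),
                 cost = cluster_editing_cost(s, membership), method = method),
            class = "duplication_clustering")
}

# Editing cost of a partition: sum over within-block pairs of max(-s, 0)
# plus between-block pairs of max(s, 0).
cluster_editing_cost <- function(s, membership) {
  same <- outer(membership, membership, "==")
  ut <- upper.tri(s)
  sum(pmax(-s[ut & same], 0)) + sum(pmax(s[ut & !same], 0))
}

# Renumber blocks in order of first appearance.
.canonical_membership <- function(m) {
  as.integer(factor(m, levels = unique(m)))
}

# Exhaustive search over set partitions (restricted growth strings),
# maximizing the within-block sum of s.
.ce_exact <- function(s) {
  n <- nrow(s)
  if (n == 1L) return(1L)
  parts <- list(1L)
  for (i in 2:n) {
    parts <- unlist(lapply(parts, function(p) {
      lapply(seq_len(max(p) + 1L), function(k) c(p, k))
    }), recursive = FALSE)
  }
  P <- matrix(unlist(parts, use.names = FALSE), nrow = n)
  score <- numeric(ncol(P))
  for (i in 1:(n - 1L)) for (j in (i + 1L):n)
    score <- score + s[i, j] * (P[i, ] == P[j, ])
  P[, which.max(score)]
}

# Greedy pivot construction + local search (single-node moves and block
# merges) to a local optimum.  Several deterministic starts are tried —
# pivot passes in lexicographic and attraction-strength order, plus the two
# trivial partitions — and the best local optimum is kept.
.ce_pivot <- function(s, order) {
  membership <- integer(nrow(s))
  blk <- 0L
  for (i in order) {
    if (membership[i] != 0L) next
    blk <- blk + 1L
    membership[i] <- blk
    open <- which(membership == 0L)
    membership[open[s[i, open] > 0]] <- blk
  }
  membership
}

.ce_heuristic <- function(s) {
  n <- nrow(s)
  strength <- rowSums(pmax(s, 0)) - diag(pmax(s, 0))
  starts <- list(
    .ce_pivot(s, seq_len(n)),
    .ce_pivot(s, order(-strength, seq_len(n))),
    seq_len(n),                        # all singletons
    rep(1L, n))                        # one block
  best <- NULL; best_cost <- Inf
  for (m0 in starts) {
    m <- .ce_local_search(s, m0)
    cost <- cluster_editing_cost(s, m)
    if (cost < best_cost - 1e-12) { best_cost <- cost; best <- m }
  }
  best
}

.ce_local_search <- function(s, membership) {
  n <- nrow(s)
  repeat {
    best_gain <- 0; best <- NULL
    nblk <- max(membership)
    for (i in seq_len(n)) {            # single-node relocations
      own <- sum(s[i, membership == membership[i]]) - s[i, i]
      for (b in seq_len(nblk + 1L)) {
        if (b == membership[i]) next
        gain <- (if (b > nblk) 0 else sum(s[i, membership == b])) - own
        if (gain > best_gain + 1e-12) {
          best_gain <- gain; best <- c(1L, i, b)
        }
      }
    }
    if (nblk > 1L) {                   # whole-block merges
      for (b1 in seq_len(nblk - 1L)) for (b2 in (b1 + 1L):nblk) {
        gain <- sum(s[membership == b1, membership == b2])
        if (gain > best_gain + 1e-12) {
          best_gain <- gain; best <- c(2L, b1, b2)
        }
      }
    }
    if (is.null(best)) break
    if (best[1L] == 1L) membership[best[2L]] <- best[3L]
    else membership[membership == best[3L]] <- best[2L]
    membership <- .canonical_membership(membership)
  }
  membership
}

#' Build the gene fate network
#'
#' For each quartet with a resolved pairing, two edges of weight `F` connect
#' the fate-matched genes of the two species (R pairing: a-c and b-d; S
#' pairing: a-d and b-c).  Tie quartets contribute nothing.  Repeated
#' contributions to the same gene pair are averaged.
#'
#' @param qtab Quartet table from [quartet_table()].
#' @return Object of class `fate_network`: list with `genes`, the symmetric
#'   averaged weight matrix `W`, and `n_obs` (contribution counts).
#' @export
build_fate_network <- function(qtab) {
  genes <- sort(unique(unlist(qtab[, c("gene_a", "gene_b", "gene_c", "gene_d")],
                              use.names = FALSE)))
  W <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  Nobs <- W
  add_edge <- function(g1, g2, w) {
    W[g1, g2] <<- W[g1, g2] + w; W[g2, g1] <<- W[g2, g1] + w
    Nobs[g1, g2] <<- Nobs[g1, g2] + 1; Nobs[g2, g1] <<- Nobs[g2, g1] + 1
  }
  for (k in seq_len(nrow(qtab))) {
    p <- qtab$pairing[k]
    if (is.na(p) || p == "tie") next
    f <- qtab$F[k]
    if (p == "R") {
      add_edge(qtab$gene_a[k], qtab$gene_c[k], f)
      add_edge(qtab$gene_b[k], qtab$gene_d[k], f)
    } else {
      add_edge(qtab$gene_a[k], qtab$gene_d[k], f)
      add_edge(qtab$gene_b[k], qtab$gene_c[k], f)
    }
  }
  W[Nobs > 0] <- W[Nobs > 0] / Nobs[Nobs > 0]
  structure(list(genes = genes, W = W, n_obs = Nobs), class = "fate_network")
}

#' Markov clustering of the fate network
#'
#' Canonical MCL on the weighted gene graph: a column-stochastic transition
#' matrix with self-loops (loop weight = maximum incident edge weight, at
#' least 1e-6) is alternately expanded (matrix power) and inflated
#' (entrywise power with column renormalization), pruning negligible
#' entries, until the matrix stabilizes.  Clusters are read off the limit
#' matrix through its attractors; a node attracted by several clusters joins
#' the one with the strongest attraction (ties broken lexicographically).
#'
#' @param net A [build_fate_network()] result, or a symmetric non-negative
#'   weight matrix with dimnames.
#' @param inflation Entrywise inflation exponent (default 10).
#' @param expansion Matrix power for expansion (default 5).
#' @param prune Entries below this value are zeroed each iteration.
#' @param tol Convergence threshold on the maximum entry change.
#' @param max_iter Iteration cap; non-convergence yields a warning and the
#'   current interpretation.
#' @return Object of class `fate_clustering`: list with `membership` (named
#'   integer vector over all nodes; edgeless nodes are singletons), `blocks`
#'   (list of gene vectors), `iterations` and `converged`.
#' @export
markov_clustering <- function(net, inflation = 10, expansion = 5,
                              prune = 1e-8, tol = 1e-6, max_iter = 200L) {
  W <- if (inherits(net, "fate_network")) net$W else as.matrix(net)
  stopifnot(nrow(W) == ncol(W), !is.null(rownames(W)))
  genes <- rownames(W)
  n <- nrow(W)
  if (n == 0L)
    rf_stop("refates_network_error", "empty fate network")
  isolated <- rowSums(W) == 0
  M <- W
  # Minimal self-loops only: under inflation this strong, a loop weight
  # comparable to the edges anchors every column on a local attractor and
  # fragments even a clean clique into sub-clusters.  The periodic limits
  # that loop-free chains can produce (a bare 2-cycle) are handled in the
  # interpretation step below.
  diag(M) <- pmax(diag(W), 1e-6)
  M <- sweep(M, 2L, colSums(M), "/")
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    old <- M
    for (e in seq_len(expansion - 1L)) M <- M %*% old  # M_old^expansion
    M <- M^inflation
    cs <- colSums(M)
    dead <- cs == 0
    if (any(dead)) { M[cbind(which(dead), which(dead))] <- 1; cs[dead] <- 1 }
    M <- sweep(M, 2L, cs, "/")
    M[M < prune] <- 0                  # prune on the normalized scale
    M <- sweep(M, 2L, colSums(M), "/")
    if (max(abs(M - old)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    rf_warn("refates_convergence_warning",
            "Markov clustering did not converge in %d iterations", max_iter)

  attractors <- which(diag(M) > tol)
  membership <- rep(NA_integer_, n)
  if (length(attractors)) {
    # group attractor systems: attractors that attract one another share a
    # cluster (union-find)
    parent <- seq_along(attractors)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (ai in seq_along(attractors)) for (aj in seq_along(attractors)) {
      if (ai < aj &&
          (M[attractors[ai], attractors[aj]] > tol ||
           M[attractors[aj], attractors[ai]] > tol)) {
        parent[find(aj)] <- find(ai)
      }
    }
    aroot <- vapply(seq_along(attractors), find, integer(1L))
    acl <- as.integer(factor(aroot, levels = unique(aroot)))
    for (j in seq_len(n)) {
      pull <- M[attractors, j]
      if (any(pull > 0)) {
        top <- which(pull == max(pull))
        membership[j] <- acl[top[order(genes[attractors[top]])[1L]]]
      }
    }
  }
  # Periodic limits (e.g. an isolated 2-cycle oscillating between its two
  # nodes) build no diagonal mass, so their nodes remain unassigned here;
  # group them by the weakly connected components of the limit matrix.
  una <- which(is.na(membership) & !isolated)
  if (length(una)) {
    G <- (M[una, una, drop = FALSE] > tol) |
      t(M[una, una, drop = FALSE] > tol)
    comp <- seq_along(una)
    repeat {
      changed <- FALSE
      for (i in seq_along(una)) {
        nb <- which(G[i, ])
        if (length(nb) && min(comp[nb], comp[i]) < comp[i]) {
          comp[i] <- min(comp[nb], comp[i]); changed <- TRUE
        }
        if (length(nb)) {
          upd <- comp[nb] > comp[i]
          if (any(upd)) { comp[nb[upd]] <- comp[i]; changed <- TRUE }
        }
      }
      if (!changed) break
    }
    base <- max(0L, membership, na.rm = TRUE)
    membership[una] <- base + as.integer(factor(comp, levels = unique(comp)))
  }
  # anything still unassigned (isolated or fully pruned) is a singleton
  nxt <- max(0L, membership, na.rm = TRUE)
  for (j in which(is.na(membership) | isolated)) {
    nxt <- nxt + 1L
    membership[j] <- nxt
  }
  membership <- .canonical_membership(membership)
  names(membership) <- genes
  structure(list(membership = membership,
                 blocks = unname(split(genes, membership)),
                 iterations = it, converged = converged),
            class = "fate_clustering")
}
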