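# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities by different routes than the
# package (enumeration, exhaustive summation, second implementations).

AAS <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

# Build a family alignment from raw sequence strings.
make_aln <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs))) names(seqs) <- paste0("g", seq_along(seqs))
  family_alignment(seqs, names(seqs))
}

# Classify one residue 4-tuple (characters, possibly "-"/"X") by literal
# enumeration of the definitions, independent of the package's vectorized
# counting.
brute_classify <- function(a, b, c, d) {
  if (any(c(a, b, c, d) %in% c("-", "X"))) return("unusable")
  cls <- character()
  if (a == b && c == d && a != c) cls <- c(cls, "Q")
  if (a == c && b == d && a != b) cls <- c(cls, "R")
  if (a == d && b == c && a != b) cls <- c(cls, "S")
  if (a == c && b != d && b != a && d != a) cls <- c(cls, "t_R")
  if (b == d && a != c && a != b && c != b) cls <- c(cls, "u_R")
  if (a == d && b != c && b != a && c != a) cls <- c(cls, "t_S")
  if (b == c && a != d && a != b && d != b) cls <- c(cls, "u_S")
  if (!length(cls)) "none" else cls
}

brute_pattern_counts <- function(rows) {
  classes <- unlist(lapply(seq_len(ncol(rows)), function(j)
    brute_classify(rows[1, j], rows[2, j], rows[3, j], rows[4, j])))
  list(n_Q = sum(classes == "Q"), n_R = sum(classes == "R"),
       n_S = sum(classes == "S"),
       t_R = sum(classes == "t_R"), u_R = sum(classes == "u_R"),
       t_S = sum(classes == "t_S"), u_S = sum(classes == "u_S"),
       l = sum(classes != "unusable"))
}

# Exhaustive 4-taxon site likelihood: explicit double sum over the two
# internal node states, per gamma category.
exhaustive_site_loglik <- function(x, bl, model) {
  pi <- model$frequencies
  rates <- model$category_rates
  vapply(seq_len(ncol(x)), function(s) {
    tot <- 0
    for (r in rates) {
      P <- lapply(bl, function(b) transition_matrix(model, b, r))
      acc <- 0
      for (i in 1:20) for (j in 1:20)
        acc <- acc + pi[i] * P[[1]][i, x[1, s]] * P[[2]][i, x[2, s]] *
          P[[5]][i, j] * P[[3]][j, x[3, s]] * P[[4]][j, x[4, s]]
      tot <- tot + acc
    }
    log(tot / length(rates))
  }, numeric(1))
}

# All set partitions of 1..n as a list of membership vectors, generated by
# assigning each element to an existing or new block (breadth-first, a
# different construction than the package's).
enumerate_partitions <- function(n) {
  acc <- list(1L)
  if (n == 1L) return(acc)
  for (i in 2:n) {
    acc <- do.call(c, lapply(acc, function(p) {
      lapply(seq_len(max(p) + 1L), function(k) c(p, k))
    }))
  }
  acc
}

# Editing cost straight from its definition.
ce_cost_direct <- function(D, membership, theta) {
  n <- nrow(D)
  cost <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- D[i, j] - theta
    if (membership[i] == membership[j] && s < 0) cost <- cost - s
    if (membership[i] != membership[j] && s > 0) cost <- cost + s
  }
  cost
}

ce_optimal_cost <- function(D, theta) {
  n <- nrow(D)
  min(vapply(enumerate_partitions(n), function(m)
    ce_cost_direct(D, m, theta), numeric(1)))
}

# Second RELL implementation: per replicate, draw L site indices and sum.
rell_reference <- function(S, B, seed) {
  L <- nrow(S)
  set.seed(seed)
  W <- stats::rmultinom(B, size = L, prob = rep(1 / L, L))
  reps <- t(W) %*% S
  w <- t(apply(reps, 1, function(r) {
    e <- exp(r - max(r)); e / sum(e)
  }))
  colMeans(w)
}

# Independent localization truth table built from multiset logic.
loc_truth <- function(la, lb, lc, ld, pairing) {
  v <- c(la, lb, lc, ld)
  counts <- sort(table(v), decreasing = TRUE)
  mate_a <- if (pairing == "R") lc else ld
  mate_b <- if (pairing == "R") ld else lc
  if (length(counts) == 1) return("uniform")
  if (la != lb && la == mate_a && lb == mate_b) return("consistent")
  swap_a <- if (pairing == "R") ld else lc
  swap_b <- if (pairing == "R") lc else ld
  if (la != lb && la == swap_a && lb == swap_b) return("inconsistent")
  if (length(counts) == 2 && counts[[2]] == 1) return("single_distinct")
  "other"
}

# Random duplication network for cluster-editing tests.
random_dup_network <- function(n) {
  D <- matrix(stats::runif(n * n), n, n)
  D <- (D + t(D)) / 2
  diag(D) <- NA
  rownames(D) <- colnames(D) <- sprintf("s%02d", seq_len(n))
  structure(list(species = rownames(D), D = D),
            class = "duplication_network")
}

# Manually assembled clustering containers for downstream tests.
manual_dups <- function(blocks) {
  membership <- stats::setNames(rep(seq_along(blocks), lengths(blocks)),
                                unlist(blocks))
  structure(list(membership = membership, blocks = blocks, cost = 0,
                 method = "manual"),
            class = "duplication_clustering")
}

manual_fates <- function(clusters) {
  names(clusters) <- paste0("F", seq_along(clusters))
  fate_of <- stats::setNames(rep(names(clusters), lengths(clusters)),
                             unlist(clusters))
  structure(list(clusters = clusters,
                 robustness = stats::setNames(rep(1, length(clusters)),
                                              names(clusters)),
                 baseline_robustness = rep(1, length(clusters)),
                 fate_of = fate_of),
            class = "robust_fate_set")
}
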