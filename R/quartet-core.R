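# Site-pattern counting and fate statistics for a quartet (two aligned
# paralog pairs from two species).
#
# For four residues (a, b) from species X and (c, d) from species Y, a
# column supports one of the three unrooted topologies when it shows a clean
# xxyy split:
#   Q: a=b, c=d, a!=c   (pairs group within species: independent duplications)
#   R: a=c, b=d, a!=b   (a~c / b~d correspondence across species)
#   S: a=d, b=c, a!=b   (crossed correspondence)
# One-sided patterns measure asymmetric divergence relative to a pairing:
# under the R pairing, t-columns (ABAC) conserve only the a~c side and
# u-columns (ABCB) only the b~d side.  Columns with a gap or ambiguous
# residue in any of the four sequences are unusable; all-identical columns
# are usable but uninformative.

#' Construct a quartet from two paralog pairs
#'
#' @param pair1,pair2 Single-row data frames (or lists) with `species_id`,
#'   `gene_a`, `gene_b`, as produced by [extract_paralog_pairs()].
#' @return Object of class `quartet` with fields `species_x`, `species_y`,
#'   `a`, `b` (paralogs of species X) and `c`, `d` (paralogs of species Y).
#' @export
quartet <- function(pair1, pair2) {
  p1 <- as.list(pair1); p2 <- as.list(pair2)
  if (identical(p1$species_id, p2$species_id))
    rf_stop("refates_identity_error",
            "a quartet needs paralog pairs from two different species")
  genes <- c(p1$gene_a, p1$gene_b, p2$gene_a, p2$gene_b)
  if (anyDuplicated(genes))
    rf_stop("refates_identity_error", "quartet genes must be distinct")
  structure(list(species_x = p1$species_id, species_y = p2$species_id,
                 a = p1$gene_a, b = p1$gene_b, c = p2$gene_a, d = p2$gene_b),
            class = "quartet")
}

# Core counting on integer-encoded residue vectors (NA or GAP_CODE =
# missing).  Returns counts for both possible pairings.
pattern_counts_coded <- function(xa, xb, xc, xd) {
  ok <- !(is.na(xa) | is.na(xb) | is.na(xc) | is.na(xd) |
            xa == GAP_CODE | xb == GAP_CODE | xc == GAP_CODE | xd == GAP_CODE)
  a <- xa[ok]; b <- xb[ok]; c <- xc[ok]; d <- xd[ok]
  l <- length(a)
  n_Q <- sum(a == b & c == d & a != c)
  n_R <- sum(a == c & b == d & a != b)
  n_S <- sum(a == d & b == c & a != b)
  t_R <- sum(a == c & b != d & b != a & d != a)
  u_R <- sum(b == d & a != c & a != b & c != b)
  t_S <- sum(a == d & b != c & b != a & c != a)
  u_S <- sum(b == c & a != d & a != b & d != b)
  list(n_Q = n_Q, n_R = n_R, n_S = n_S,
       t_R = t_R, u_R = u_R, t_S = t_S, u_S = u_S,
       l = l, usable = which(ok), degenerate = (l == 0L))
}

#' Count topology-supporting site patterns in a quartet
#'
#' @param aln A [family_alignment()].
#' @param q A [quartet()].
#' @return A list of class `pattern_counts` with elements `n_Q`, `n_R`, `n_S`
#'   (topology-supporting counts), `t_R`, `u_R`, `t_S`, `u_S` (one-sided
#'   counts under the R and S pairings), `l` (number of usable columns),
#'   `usable` (their 1-based column indices) and `degenerate` (`TRUE` when no
#'   column is usable, in which case all quartet scores are undefined).
#' @export
count_site_patterns <- function(aln, q) {
  stopifnot(inherits(aln, "family_alignment"), inherits(q, "quartet"))
  genes <- c(q$a, q$b, q$c, q$d)
  missing <- setdiff(genes, aln$gene_ids)
  if (length(missing))
    rf_stop("refates_identity_error", "quartet genes not in alignment: %s",
            paste(missing, collapse = ", "))
  coded <- encode_alignment(aln)
  out <- pattern_counts_coded(coded[q$a, ], coded[q$b, ], coded[q$c, ], coded[q$d, ])
  class(out) <- "pattern_counts"
  out
}

#' Variance of a count difference under the Bernoulli site-pattern model
#'
#' Treats the two pattern classes as multinomial outcomes along an alignment
#' of `l` usable columns with rates `x/l` and `y/l`; the variance of the
#' count difference is then `x(1 - x/l) + y(1 - y/l) + 2xy/l`, which is the
#' exact multinomial variance of `n_x - n_y`.
#'
#' @param x,y Non-negative pattern counts.
#' @param l Number of usable columns (`l >= max(x + y, 1)`).
#' @return The variance, a single non-negative number.
#' @export
bernoulli_variance <- function(x, y, l) {
  if (any(l <= 0))
    rf_stop("refates_domain_error", "alignment length l must be positive")
  if (any(x < 0) || any(y < 0) || any(x + y > l))
    rf_stop("refates_domain_error", "need 0 <= x, y and x + y <= l")
  x * (1 - x / l) + y * (1 - y / l) + 2 * x * y / l
}

#' Standard score of a count difference
#'
#' `|x - y| / sqrt(V)` with `V` from [bernoulli_variance()]; defined as 0
#' when the variance is 0 (no patterns of either class).
#'
#' @inheritParams bernoulli_variance
#' @return The non-negative standard score.
#' @export
z_score <- function(x, y, l) {
  v <- bernoulli_variance(x, y, l)
  ifelse(v > 0, abs(x - y) / sqrt(v), 0)
}

#' Fate similarity and its significance for a quartet
#'
#' The fate similarity is `F = |n_R - n_S| / (n_Q + n_R + n_S)`: the excess
#' of one cross-species correspondence over the other, as a fraction of all
#' topology-supporting columns.  The pairing is the correspondence with the
#' larger count (R: a~c, b~d; S: a~d, b~c); its significance `Z_F` is the
#' standard score of `dF = |n_R - n_S|`.
#'
#' @param counts A `pattern_counts` object from [count_site_patterns()].
#' @return A list with `F`, `dF`, `V_dF`, `Z_F` and `pairing` (one of
#'   `"R"`, `"S"`, `"tie"`).  When no column supports any topology, `F = 0`
#'   and the pairing is a tie.
#' @export
fate_similarity <- function(counts) {
  if (isTRUE(counts$degenerate))
    rf_stop("refates_degenerate_error", "quartet has no usable columns")
  tot <- counts$n_Q + counts$n_R + counts$n_S
  dF <- abs(counts$n_R - counts$n_S)
  Fval <- if (tot > 0) dF / tot else 0
  V <- bernoulli_variance(counts$n_R, counts$n_S, counts$l)
  ZF <- z_score(counts$n_R, counts$n_S, counts$l)
  pairing <- if (counts$n_R > counts$n_S) "R"
             else if (counts$n_S > counts$n_R) "S" else "tie"
  list(F = Fval, dF = dF, V_dF = V, Z_F = ZF, pairing = pairing)
}

#' One-sided asymmetry of a quartet's fate signal
#'
#' Under the resolved pairing, `t` counts columns where only the first
#' fate-matched side is conserved (ABAC under the R pairing) and `u` those
#' where only the second is (ABCB).  Their imbalance `dA = |t - u|` measures
#' asymmetric divergence of the two fates; `Z_A` is its standard score,
#' constructed exactly like `Z_F`.
#'
#' @param counts A `pattern_counts` object.
#' @param pairing `"R"` or `"S"`; a tie leaves the asymmetry undefined.
#' @return List with `t`, `u`, `dA`, `V_dA`, `Z_A`, or all-`NA` values with
#'   `flagged = TRUE` when the pairing is a tie.
#' @export
asymmetry_scores <- function(counts, pairing) {
  if (pairing == "tie" || is.na(pairing))
    return(list(t = NA_integer_, u = NA_integer_, dA = NA_real_,
                V_dA = NA_real_, Z_A = NA_real_, flagged = TRUE))
  t <- if (pairing == "R") counts$t_R else counts$t_S
  u <- if (pairing == "R") counts$u_R else counts$u_S
  list(t = t, u = u, dA = abs(t - u),
       V_dA = bernoulli_variance(t, u, counts$l),
       Z_A = z_score(t, u, counts$l), flagged = FALSE)
}
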