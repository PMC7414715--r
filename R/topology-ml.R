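# Likelihood support for the three quartet topologies and the duplication
# score D = 1 - w(Q).
#
# The three unrooted 4-taxon trees are all handled as ((1,2),(3,4)) with one
# internal branch, after permuting the taxa (a,b,c,d):
#   Q: ((a,b),(c,d))   R: ((a,c),(b,d))   S: ((a,d),(b,c))
# Site likelihoods come from Felsenstein pruning with the likelihood rooted
# at the first internal node, averaging over equal-prior discrete-gamma
# categories.  Branch lengths are fitted by coordinate ascent; topology
# support is summarized by expected likelihood weights (ELW) obtained from
# RELL resampling of the per-site log-likelihoods.

BL_MIN <- 1e-8
BL_MAX <- 10

.topo_perm <- function(label)
  switch(label, Q = c(1L, 2L, 3L, 4L), R = c(1L, 3L, 2L, 4L),
         S = c(1L, 4L, 2L, 3L),
         rf_stop("refates_model_error", "unknown topology label %s", label))

#' Construct a quartet topology
#'
#' @param label `"Q"`, `"R"` or `"S"`; determines which gene pairs are
#'   sisters (`(a,b)|(c,d)`, `(a,c)|(b,d)`, `(a,d)|(b,c)` respectively).
#' @param branch_lengths Five branch lengths (four terminal, in taxon order
#'   a, b, c, d, then the internal branch), each in `[1e-8, 10]`.
#' @return Object of class `quartet_topology`.
#' @export
quartet_topology <- function(label, branch_lengths = rep(0.1, 5)) {
  label <- match.arg(label, c("Q", "R", "S"))
  bl <- as.numeric(branch_lengths)
  stopifnot(length(bl) == 5L)
  if (any(bl < BL_MIN) || any(bl > BL_MAX))
    rf_stop("refates_model_error",
            "branch lengths must lie in [%g, %g]", BL_MIN, BL_MAX)
  structure(list(label = label, branch_lengths = bl),
            class = "quartet_topology")
}

# Tip conditionals: row l gives P[i, x_l] over internal states i (the
# probability of evolving from internal state i to the observed tip state);
# missing states are marginalized to all-ones.
.tip_mat <- function(P, x) {
  idx <- x
  idx[is.na(idx)] <- 1L
  M <- t(P)[idx, , drop = FALSE]
  if (anyNA(x)) M[is.na(x), ] <- 1
  M
}

# Per-site likelihood of ((1,2),(3,4)) for already-permuted coded columns
# x (4 x L, values 1..20 or NA), branch lengths bl (tips 1..4, internal 5).
.site_likelihood <- function(x, bl, model, rates = model$category_rates) {
  L <- ncol(x)
  pirep <- rep(model$frequencies, each = L)
  acc <- numeric(L)
  for (r in rates) {
    P5 <- transition_matrix(model, bl[5L], r)
    C1 <- .tip_mat(transition_matrix(model, bl[1L], r), x[1L, ]) *
          .tip_mat(transition_matrix(model, bl[2L], r), x[2L, ])
    C2 <- .tip_mat(transition_matrix(model, bl[3L], r), x[3L, ]) *
          .tip_mat(transition_matrix(model, bl[4L], r), x[4L, ])
    acc <- acc + rowSums((C1 * pirep) * (C2 %*% t(P5)))
  }
  acc / length(rates)
}

#' Per-site log-likelihoods of a quartet topology
#'
#' @param columns Integer matrix, 4 rows (taxa a, b, c, d) by L columns, with
#'   residues coded 1..20 in the order `ARNDCQEGHILKMFPSTWYV`; `NA` marks a
#'   missing residue, which is marginalized (all-ones tip conditional).
#' @param topo A [quartet_topology()].
#' @param model A [substitution_model()].
#' @return Numeric vector of natural-log site likelihoods (underflow-guarded).
#' @export
site_log_likelihoods <- function(columns, topo, model) {
  stopifnot(is.matrix(columns), nrow(columns) == 4L,
            inherits(topo, "quartet_topology"),
            inherits(model, "substitution_model"))
  x <- columns[.topo_perm(topo$label), , drop = FALSE]
  lik <- .site_likelihood(x, topo$branch_lengths, model)
  log(pmax(lik, 1e-320))
}

# Transposed transition matrices of all gamma categories, side by side:
# a 20 x (20 * ncat) block matrix.  Row s of block c holds P_c[i, s] over
# internal states i, so indexing rows by observed states yields the tip
# conditionals of every category in one operation.
.tp_blocks <- function(model, b, rates) {
  do.call(cbind, lapply(rates, function(r) t(transition_matrix(model, b, r))))
}

# Coordinate-ascent branch-length fit on permuted, pattern-compressed
# columns.  w holds pattern multiplicities.  Deterministic branch order:
# tips 1..4, then the internal branch.  Gamma categories are laid out as
# concatenated 20-column blocks so each likelihood evaluation is a handful
# of dense matrix operations.
.optimize_quartet_bl <- function(x, model, w = rep(1, ncol(x)),
                                 bl = rep(0.1, 5), tol = 1e-6,
                                 max_sweeps = 20L) {
  rates <- model$category_rates
  ncat <- length(rates)
  L <- ncol(x)
  nb <- 20L * ncat
  pim <- matrix(rep(model$frequencies, times = ncat), L, nb, byrow = TRUE)
  cat_idx <- lapply(seq_len(ncat), function(k) ((k - 1L) * 20L + 1L):(k * 20L))

  tiprows <- function(j, b) {
    xi <- x[j, ]
    idx <- xi
    idx[is.na(idx)] <- 1L
    M <- .tp_blocks(model, b, rates)[idx, , drop = FALSE]
    if (anyNA(xi)) M[is.na(xi), ] <- 1     # marginalize missing states
    M
  }
  Tm <- lapply(1:4, function(j) tiprows(j, bl[j]))   # L x nb each
  tP5 <- lapply(rates, function(r) t(transition_matrix(model, bl[5L], r)))

  # K = per-block (C2 %*% t(P5)); full site likelihood needs C1 * pi * K
  right_msg <- function(C2) {
    K <- matrix(0, L, nb)
    for (k in seq_len(ncat))
      K[, cat_idx[[k]]] <- C2[, cat_idx[[k]], drop = FALSE] %*% tP5[[k]]
    K
  }
  left_msg <- function(C1pi) {
    K <- matrix(0, L, nb)
    for (k in seq_len(ncat))
      K[, cat_idx[[k]]] <- C1pi[, cat_idx[[k]], drop = FALSE] %*% t(tP5[[k]])
    K
  }
  score <- function(acc) sum(w * log(pmax(acc / ncat, 1e-320)))
  total <- function()
    score(.rowSums(Tm[[1L]] * Tm[[2L]] * pim *
                     right_msg(Tm[[3L]] * Tm[[4L]]), L, nb))

  logL <- total()
  sweeps <- 0L
  converged <- FALSE
  repeat {
    sweeps <- sweeps + 1L
    before <- logL
    for (j in 1:5) {
      if (j <= 4L) {
        sib <- c(2L, 1L, 4L, 3L)[j]
        M <- if (j <= 2L)
          Tm[[sib]] * pim * right_msg(Tm[[3L]] * Tm[[4L]])
        else
          Tm[[sib]] * left_msg(Tm[[1L]] * Tm[[2L]] * pim)
        obj <- function(b) score(.rowSums(tiprows(j, b) * M, L, nb))
      } else {
        C1pi <- Tm[[1L]] * Tm[[2L]] * pim
        C2 <- Tm[[3L]] * Tm[[4L]]
        obj <- function(b) {
          acc <- numeric(L)
          for (k in seq_len(ncat))
            acc <- acc + .rowSums(
              C1pi[, cat_idx[[k]], drop = FALSE] *
                (C2[, cat_idx[[k]], drop = FALSE] %*%
                   t(transition_matrix(model, b, rates[k]))), L, 20L)
          score(acc)
        }
      }
      opt <- stats::optimize(obj, c(BL_MIN, BL_MAX), maximum = TRUE, tol = tol)
      if (opt$objective > logL) {       # monotone ascent only
        logL <- opt$objective
        bl[j] <- opt$maximum
        if (j <= 4L) Tm[[j]] <- tiprows(j, bl[j])
        else tP5 <- lapply(rates, function(r)
          t(transition_matrix(model, bl[5L], r)))
      }
    }
    if (logL - before < tol) { converged <- TRUE; break }
    if (sweeps >= max_sweeps) break
  }
  list(branch_lengths = bl, logL = logL, converged = converged,
       sweeps = sweeps)
}

#' Fit branch lengths of a quartet topology by maximum likelihood
#'
#' Coordinate ascent over the five branches (bounded scalar optimization per
#' branch, deterministic order: terminals a, b, c, d, then internal), with a
#' monotone non-decreasing total log-likelihood.
#'
#' @inheritParams site_log_likelihoods
#' @param tol Convergence tolerance on the total log-likelihood per sweep.
#' @param max_sweeps Maximum number of coordinate-ascent sweeps; a
#'   non-converged fit returns the best visited point with a warning.
#' @return The input [quartet_topology()] with fitted `branch_lengths`, plus
#'   attributes `logL`, `converged` and `sweeps`.
#' @export
optimize_branch_lengths <- function(columns, topo, model, tol = 1e-6,
                                    max_sweeps = 20L) {
  stopifnot(is.matrix(columns), nrow(columns) == 4L, ncol(columns) >= 1L)
  x <- columns[.topo_perm(topo$label), , drop = FALSE]
  cp <- .compress_patterns(x)
  fit <- .optimize_quartet_bl(cp$x, model, w = cp$w,
                              bl = topo$branch_lengths, tol = tol,
                              max_sweeps = max_sweeps)
  if (!fit$converged)
    rf_warn("refates_convergence_warning",
            "branch-length optimization did not converge in %d sweeps",
            max_sweeps)
  out <- quartet_topology(topo$label, fit$branch_lengths)
  attr(out, "logL") <- fit$logL
  attr(out, "converged") <- fit$converged
  attr(out, "sweeps") <- fit$sweeps
  out
}

# Collapse identical columns; x must already be permuted.  NA is treated as
# a 21st symbol for the purpose of pattern identity.
.compress_patterns <- function(x) {
  code <- x
  code[is.na(code)] <- 21L
  key <- ((code[1L, ] * 22L + code[2L, ]) * 22L + code[3L, ]) * 22L + code[4L, ]
  ux <- !duplicated(key)
  list(x = x[, ux, drop = FALSE],
       w = as.numeric(table(factor(key, levels = key[ux]))),
       index = match(key, key[ux]))
}

#' Estimate the gamma shape parameter for a quartet
#'
#' One-dimensional bounded maximum-likelihood search for the shape of the
#' discrete-gamma rate distribution, at fixed branch lengths.  The shape is
#' estimated once, on the highest-likelihood topology, and shared by all
#' three topologies of a quartet.
#'
#' @inheritParams site_log_likelihoods
#' @param interval Search bounds for the shape.
#' @param tol Optimization tolerance.
#' @param refit_branches Re-optimize branch lengths for every candidate
#'   shape (profile likelihood).  The default keeps the supplied branch
#'   lengths fixed, which is much faster and adequate once branches have
#'   been fitted under a nearby shape; the profile version is needed to
#'   resolve limit behavior (e.g. rate-homogeneous data driving the shape
#'   to the upper bound).
#' @return The estimated shape; attribute `boundary` is `TRUE` when the
#'   optimum sits at a search bound.
#' @export
estimate_gamma_shape <- function(columns, topo, model,
                                 interval = c(0.05, 20), tol = 1e-3,
                                 refit_branches = FALSE) {
  x <- columns[.topo_perm(topo$label), , drop = FALSE]
  cp <- .compress_patterns(x)
  obj <- function(shape) {
    m <- set_gamma_shape(model, shape)
    if (refit_branches)
      return(.optimize_quartet_bl(cp$x, m, w = cp$w,
                                  bl = topo$branch_lengths)$logL)
    lik <- .site_likelihood(cp$x, topo$branch_lengths, model,
                            m$category_rates)
    sum(cp$w * log(pmax(lik, 1e-320)))
  }
  opt <- stats::optimize(obj, interval, maximum = TRUE, tol = tol)
  shape <- opt$maximum
  boundary <- FALSE
  # A likelihood surface flat up to a search bound (e.g. rate-homogeneous
  # data, where any sufficiently large shape fits essentially equally well)
  # is a boundary solution even if golden search stops mid-plateau; half a
  # log-likelihood unit over the whole alignment counts as flat.
  for (b in c(interval[2L], interval[1L])) {
    if (obj(b) >= opt$objective - 0.5) {
      shape <- b
      boundary <- TRUE
      break
    }
  }
  structure(shape, boundary = boundary)
}

#' Expected likelihood weights by RELL resampling
#'
#' For each of `B` replicates, `L` sites are drawn with replacement, the
#' replicate log-likelihood of each topology is the weighted sum of its
#' per-site values, and replicate weights are the softmax of the three
#' totals.  The ELW of a topology is its mean weight over replicates; the
#' duplication score is `D = 1 - w_Q`.
#'
#' @param sitelogL_Q,sitelogL_R,sitelogL_S Per-site log-likelihood vectors of
#'   equal length `L >= 1`, as from [site_log_likelihoods()].
#' @param B Number of resampling replicates.
#' @param seed Optional integer seed for reproducible resampling.
#' @return Object of class `topology_weights`: list with `w` (named weights
#'   summing to 1), `D`, `B` and `L`.
#' @export
expected_likelihood_weights <- function(sitelogL_Q, sitelogL_R, sitelogL_S,
                                        B = 1000L, seed = NULL) {
  S <- cbind(Q = sitelogL_Q, R = sitelogL_R, S = sitelogL_S)
  L <- nrow(S)
  if (is.null(L) || L < 1L)
    rf_stop("refates_degenerate_error",
            "no usable sites for likelihood weighting")
  stopifnot(!anyNA(S), B >= 1L)
  W <- with_local_seed(seed,
                       stats::rmultinom(B, size = L, prob = rep(1 / L, L)))
  R <- crossprod(W, S)                              # B x 3 replicate logL
  E <- exp(R - apply(R, 1L, max))
  w <- colMeans(E / rowSums(E))
  structure(list(w = w / sum(w), D = unname(1 - (w / sum(w))["Q"]),
                 B = as.integer(B), L = L),
            class = "topology_weights")
}

#' Parsimony-style topology weights
#'
#' Fast screening alternative to the likelihood route: each topology is
#' weighted by its share of topology-supporting site patterns,
#' `w_i = n_i / (n_Q + n_R + n_S)`, and `D = 1 - w_Q`.
#'
#' @param counts A `pattern_counts` object from [count_site_patterns()].
#' @return A `topology_weights` object; with zero informative sites the
#'   weights and `D` are `NA` and the result is flagged degenerate.
#' @export
parsimony_weights <- function(counts) {
  tot <- counts$n_Q + counts$n_R + counts$n_S
  if (tot == 0)
    return(structure(list(w = c(Q = NA_real_, R = NA_real_, S = NA_real_),
                          D = NA_real_, degenerate = TRUE),
                     class = "topology_weights"))
  w <- c(Q = counts$n_Q, R = counts$n_R, S = counts$n_S) / tot
  structure(list(w = w, D = unname(1 - w["Q"]), degenerate = FALSE),
            class = "topology_weights")
}

#' Likelihood-based duplication score of one quartet
#'
#' Runs the full topology test for a quartet: usable columns (no gap or
#' ambiguous residue in any of the four sequences) are extracted, branch
#' lengths are fitted for the three topologies, the gamma shape is estimated
#' on the best topology and shared, per-site log-likelihoods are computed and
#' ELW resampling yields the topology weights and `D = 1 - w_Q`.
#'
#' @param aln A [family_alignment()]; for the duplication path this is
#'   typically the gap-trimmed alignment.
#' @param q A [quartet()].
#' @param model A [substitution_model()]; its `gamma_shape` is the starting
#'   value when `estimate_shape = TRUE`, or used as-is otherwise.
#' @param B ELW resampling replicates.
#' @param seed Optional seed for the resampling step.
#' @param estimate_shape Estimate the gamma shape per quartet (on the best
#'   topology) instead of using the model's fixed shape.
#' @param marginalize_missing Keep columns with a gap or ambiguous residue
#'   and marginalize the missing states, instead of excluding those columns
#'   (the default, which keeps the likelihood sample space identical to the
#'   pattern-counting one).
#' @return List with `D`, `w` (named ELW weights), `shape`, `logL` (named
#'   per-topology totals), `branch_lengths` (list per topology), `l` (usable
#'   columns) and `degenerate`.
#' @export
quartet_duplication_score <- function(aln, q, model = lg_model(),
                                      B = 1000L, seed = NULL,
                                      estimate_shape = TRUE,
                                      marginalize_missing = FALSE) {
  coded <- encode_alignment(aln)
  x <- rbind(coded[q$a, ], coded[q$b, ], coded[q$c, ], coded[q$d, ])
  x[which(x == GAP_CODE)] <- NA_integer_
  usable <- if (marginalize_missing) colSums(is.na(x)) < 4L
            else colSums(is.na(x)) == 0L
  x <- x[, usable, drop = FALSE]
  if (ncol(x) == 0L)
    return(list(D = NA_real_, w = NULL, shape = NA_real_, logL = NULL,
                branch_lengths = NULL, l = 0L, degenerate = TRUE))
  columns_elw_score(x, model = model, B = B, seed = seed,
                    estimate_shape = estimate_shape)
}

# Same computation on a prepared 4 x L coded matrix (no missing values
# required); shared by quartet_duplication_score and the simulator-driven
# validation paths.
columns_elw_score <- function(x, model = lg_model(), B = 1000L, seed = NULL,
                              estimate_shape = TRUE) {
  labels <- c("Q", "R", "S")
  fits <- list()
  for (lab in labels) {
    xp <- x[.topo_perm(lab), , drop = FALSE]
    cp <- .compress_patterns(xp)
    fits[[lab]] <- c(.optimize_quartet_bl(cp$x, model, w = cp$w), list(cp = cp))
  }
  logL <- vapply(fits, `[[`, numeric(1L), "logL")
  shape <- model$gamma_shape
  if (estimate_shape) {
    best <- labels[which.max(logL)]
    topo <- quartet_topology(best, fits[[best]]$branch_lengths)
    shape <- as.numeric(estimate_gamma_shape(x, topo, model))
    model <- set_gamma_shape(model, shape)
    for (lab in labels) {               # refit under the shared shape
      cp <- fits[[lab]]$cp
      fits[[lab]] <- c(.optimize_quartet_bl(cp$x, model, w = cp$w,
                                            bl = fits[[lab]]$branch_lengths),
                       list(cp = cp))
    }
    logL <- vapply(fits, `[[`, numeric(1L), "logL")
  }
  site <- lapply(labels, function(lab) {
    cp <- fits[[lab]]$cp
    lik <- .site_likelihood(cp$x, fits[[lab]]$branch_lengths, model)
    log(pmax(lik, 1e-320))[cp$index]
  })
  elw <- expected_likelihood_weights(site[[1L]], site[[2L]], site[[3L]],
                                     B = B, seed = seed)
  list(D = elw$D, w = elw$w, shape = shape, logL = logL,
       branch_lengths = lapply(fits, `[[`, "branch_lengths"),
       l = ncol(x), degenerate = FALSE)
}
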