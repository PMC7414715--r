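test_that("substitution models are valid reversible rate matrices", {
  m <- lg_model(gamma_shape = 0.6)
  expect_equal(sum(m$frequencies), 1, tolerance = 1e-12)
  expect_equal(mean(m$category_rates), 1, tolerance = 1e-9)
  expect_equal(rowSums(m$Q), rep(0, 20), tolerance = 1e-12,
               ignore_attr = TRUE)
  P <- transition_matrix(m, 0.37)
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-9, ignore_attr = TRUE)
  # detailed balance: pi_i P_ij = pi_j P_ji
  F <- m$frequencies * P
  expect_equal(F, t(F), tolerance = 1e-9)
  # homogeneity limit
  expect_equal(discrete_gamma_rates(Inf, 10), rep(1, 10))
  expect_error(substitution_model(matrix(1, 20, 20), rep(0.05, 20),
                                  gamma_shape = -1),
               class = "refates_model_error")
})

test_that("site log-likelihoods equal the exhaustive internal-state sum", {
  m <- lg_model(gamma_shape = 0.8)
  set.seed(12)
  x <- matrix(sample(1:20, 4 * 12, TRUE), nrow = 4)
  bl <- stats::runif(5, 0.05, 2)
  perms <- list(Q = 1:4, R = c(1, 3, 2, 4), S = c(1, 4, 2, 3))
  for (lab in names(perms)) {
    got <- site_log_likelihoods(x, quartet_topology(lab, bl), m)
    want <- exhaustive_site_loglik(x[perms[[lab]], , drop = FALSE], bl, m)
    expect_equal(got, want, tolerance = 1e-10, info = lab)
  }

  # zero-branch-length limits
  t0 <- quartet_topology("Q", rep(1e-8, 5))
  same <- matrix(rep(3L, 4), 4, 1)
  expect_equal(site_log_likelihoods(same, t0, m), log(m$frequencies[3]),
               tolerance = 1e-5)
  impossible <- matrix(c(1L, 1L, 1L, 17L), 4, 1)
  expect_lt(site_log_likelihoods(impossible, t0, m), -15)
  expect_true(is.finite(site_log_likelihoods(impossible, t0, m)))

  # missing residues marginalize to the three-sequence likelihood
  miss <- matrix(c(NA, 4L, 4L, 7L), 4, 1)
  expect_true(is.finite(site_log_likelihoods(miss, quartet_topology("Q"), m)))
})

test_that("total log-likelihood agrees with an independent ML engine", {
  skip_if_not_installed("phangorn")
  set.seed(27)
  x <- matrix(sample(1:20, 4 * 30, TRUE), nrow = 4)
  chars <- matrix(AAS[x], nrow = 4,
                  dimnames = list(c("a", "b", "c", "d"), NULL))
  dat <- phangorn::phyDat(chars, type = "AA")
  bl <- c(0.3, 0.25, 0.2, 0.35, 0.4)
  tr <- ape::read.tree(text = "((a:0.3,b:0.25):0.4,c:0.2,d:0.35);")
  fit <- phangorn::pml(tr, dat, model = "LG", k = 10, shape = 0.7)
  m <- lg_model(gamma_shape = 0.7)
  mine <- sum(site_log_likelihoods(x, quartet_topology("Q", bl), m))
  expect_equal(mine, fit$logLik, tolerance = 1e-9)
})

test_that("consistent taxon relabeling leaves the likelihood unchanged", {
  m <- lg_model()
  set.seed(33)
  for (rep in 1:3) {
    x <- matrix(sample(1:20, 4 * 30, TRUE), nrow = 4)
    bl <- stats::runif(5, 0.05, 1)
    # R on the original data equals Q on data re-ordered to (a,c,b,d)
    expect_equal(
      sum(site_log_likelihoods(x, quartet_topology("R", bl), m)),
      sum(site_log_likelihoods(x[c(1, 3, 2, 4), ], quartet_topology("Q", bl), m)),
      tolerance = 1e-9)
    expect_equal(
      sum(site_log_likelihoods(x, quartet_topology("S", bl), m)),
      sum(site_log_likelihoods(x[c(1, 4, 2, 3), ], quartet_topology("Q", bl), m)),
      tolerance = 1e-9)
  }
})

test_that("branch-length optimization ascends and matches expectations", {
  m <- lg_model()
  set.seed(14)
  # ascent property on random quartets
  for (rep in 1:5) {
    x <- matrix(sample(1:20, 4 * 40, TRUE), nrow = 4)
    init <- quartet_topology("Q")
    fit <- optimize_branch_lengths(x, init, m)
    expect_gte(attr(fit, "logL"),
               sum(site_log_likelihoods(x, init, m)))
  }

  # identical sister pairs, divergent across pairs: internal branch large
  x <- simulate_quartet("Q", n_columns = 150, terminal_bl = 0.01,
                        internal_bl = 1.5, seed = 41)
  fit <- optimize_branch_lengths(x, quartet_topology("Q"), m)
  bl <- fit$branch_lengths
  expect_gt(bl[5], 5 * max(bl[1:4]))

  # all sequences identical: every branch at the lower bound
  xc <- matrix(rep(sample(1:20, 30, TRUE), each = 4), nrow = 4)
  fit0 <- optimize_branch_lengths(xc, quartet_topology("Q"), m)
  expect_true(all(fit0$branch_lengths < 1e-4))
})

test_that("gamma shape estimation recovers simulated heterogeneity", {
  m <- lg_model()
  x <- simulate_quartet("Q", n_columns = 2000, gamma_shape = 0.5, seed = 3)
  topo <- optimize_branch_lengths(x, quartet_topology("Q"), m)
  sh <- estimate_gamma_shape(x, topo, m)
  expect_gt(as.numeric(sh), 0.3)
  expect_lt(as.numeric(sh), 0.8)
  expect_false(attr(sh, "boundary"))

  # rate-homogeneous data drives the profile estimate to the upper bound
  xh <- simulate_quartet("Q", n_columns = 400, seed = 4)
  th <- optimize_branch_lengths(xh, quartet_topology("Q"), m)
  shh <- estimate_gamma_shape(xh, th, m, refit_branches = TRUE)
  expect_true(attr(shh, "boundary"))
  expect_equal(as.numeric(shh), 20)

  # invariance to topology relabeling of the same data
  xr <- simulate_quartet("R", n_columns = 300, gamma_shape = 0.7, seed = 9)
  t1 <- optimize_branch_lengths(xr, quartet_topology("R"), m)
  s1 <- estimate_gamma_shape(xr, t1, m)
  xp <- xr[c(1, 3, 2, 4), ]
  t2 <- optimize_branch_lengths(xp, quartet_topology("Q"), m)
  s2 <- estimate_gamma_shape(xp, t2, m)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-6)
})

test_that("expected likelihood weights follow RELL resampling", {
  set.seed(6)
  s <- stats::rnorm(40)
  w <- expected_likelihood_weights(s, s, s, B = 200, seed = 2)
  expect_equal(unname(w$w), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(w$D, 2 / 3, tolerance = 1e-12)

  # dominance limit
  w2 <- expected_likelihood_weights(s + 50, s, s, B = 100, seed = 2)
  expect_gt(w2$w[["Q"]], 0.999)
  expect_lt(w2$D, 1e-3)

  # value-for-value agreement with an independent RELL implementation
  S <- matrix(stats::rnorm(30), 10, 3)
  got <- expected_likelihood_weights(S[, 1], S[, 2], S[, 3],
                                     B = 100, seed = 77)
  want <- rell_reference(S, B = 100, seed = 77)
  expect_equal(unname(got$w), unname(want), tolerance = 1e-12)
  expect_equal(sum(got$w), 1, tolerance = 1e-12)

  # stability in B on a simulated quartet
  m <- lg_model()
  x <- simulate_quartet("Q", n_columns = 120, seed = 51)
  topoQ <- optimize_branch_lengths(x, quartet_topology("Q"), m)
  topoR <- optimize_branch_lengths(x, quartet_topology("R"), m)
  topoS <- optimize_branch_lengths(x, quartet_topology("S"), m)
  sl <- lapply(list(topoQ, topoR, topoS), site_log_likelihoods,
               columns = x, model = m)
  d100 <- expected_likelihood_weights(sl[[1]], sl[[2]], sl[[3]],
                                      B = 100, seed = 1)$D
  d1000 <- expected_likelihood_weights(sl[[1]], sl[[2]], sl[[3]],
                                       B = 1000, seed = 1)$D
  expect_lt(abs(d100 - d1000), 0.05)

  expect_error(expected_likelihood_weights(numeric(), numeric(), numeric()),
               class = "refates_degenerate_error")
})

test_that("gappy columns are excluded by default, marginalized on request", {
  x <- simulate_quartet("Q", n_columns = 60, seed = 81)
  chars <- matrix(AAS[x], nrow = 4)
  chars[1, 1:10] <- "-"                     # gaps in taxon a
  seqs <- apply(chars, 1, paste, collapse = "")
  aln <- make_aln(gA = seqs[1], gB = seqs[2], gC = seqs[3], gD = seqs[4])
  q <- quartet(list(species_id = "spX", gene_a = "gA", gene_b = "gB"),
               list(species_id = "spY", gene_a = "gC", gene_b = "gD"))
  drop <- quartet_duplication_score(aln, q, B = 100, seed = 1,
                                    estimate_shape = FALSE)
  marg <- quartet_duplication_score(aln, q, B = 100, seed = 1,
                                    estimate_shape = FALSE,
                                    marginalize_missing = TRUE)
  expect_equal(drop$l, 50L)
  expect_equal(marg$l, 60L)
  expect_true(is.finite(marg$D))
})

test_that("parsimony weights are pattern shares", {
  cnt <- list(n_Q = 8L, n_R = 1L, n_S = 1L)
  expect_equal(parsimony_weights(cnt)$D, 0.2, tolerance = 1e-12)
  cnt2 <- list(n_Q = 0L, n_R = 5L, n_S = 5L)
  expect_equal(parsimony_weights(cnt2)$D, 1)
  cnt0 <- list(n_Q = 0L, n_R = 0L, n_S = 0L)
  pw <- parsimony_weights(cnt0)
  expect_true(pw$degenerate)
  expect_true(is.na(pw$D))
})

test_that("parsimony D ranks quartets like the likelihood D", {
  m <- lg_model()
  Dp <- De <- numeric(24)
  for (i in seq_along(Dp)) {
    topo <- c("Q", "R")[(i %% 2) + 1]
    x <- simulate_quartet(topo, n_columns = 150,
                          internal_bl = 0.1 + (i %% 6) * 0.2,
                          seed = 300 + i)
    cnt <- brute_pattern_counts(matrix(AAS[x], nrow = 4))
    Dp[i] <- parsimony_weights(cnt)$D
    De[i] <- refates:::columns_elw_score(x, m, B = 300, seed = i)$D
  }
  expect_gt(stats::cor(Dp, De, method = "spearman"), 0.8)
})
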