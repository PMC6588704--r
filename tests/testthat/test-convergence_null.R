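test_that("pruning likelihood matches exhaustive enumeration on small trees", {
  # single observed leaf (partner all-missing) marginalises to pi_a
  tr <- ape::read.tree(text = "(a:0.0,b:1.0);")
  m <- two_state_model(freq = c(0.7, 0.3))
  lab <- make_labels(c("a", "b"), 1)
  aln <- aln_from_strings(c(a = "0", b = "-"), lab, alphabet = c("0", "1"))
  ll <- prune_likelihood(aln, tr, m)
  expect_equal(as.numeric(ll), log(0.7), tolerance = 1e-12)

  # random small trees, 2 and 4 states, vs the enumeration oracle
  set.seed(8)
  for (rep in 1:5) {
    tr <- random_tree(4, seed = rep * 100, min_len = 0.05, max_len = 0.8)
    for (m in list(two_state_model(freq = c(0.6, 0.4)),
                   model_gtr(rates = runif(6, 0.5, 2),
                             freq = c(0.1, 0.2, 0.3, 0.4)))) {
      k <- length(m$alphabet)
      states <- sample(c(seq_len(k), NA), 4, replace = TRUE)
      chars <- ifelse(is.na(states), "-", m$alphabet[states])
      lab <- make_labels(tr$tip.label, 2)
      aln <- aln_from_strings(setNames(chars, tr$tip.label), lab,
                              alphabet = m$alphabet)
      ll <- prune_likelihood(aln, tr, m)
      oracle <- oracle_site_lik(tr, m, setNames(states, tr$tip.label))
      expect_equal(as.numeric(ll), log(oracle), tolerance = 1e-10)
    }
  }
})

test_that("gamma-mixture likelihood averages the category likelihoods", {
  tr <- random_tree(4, seed = 12, min_len = 0.1, max_len = 0.6)
  m <- two_state_model(gamma_shape = 0.7)
  lab <- make_labels(tr$tip.label, 2)
  states <- c(1L, 2L, 2L, 1L)
  aln <- aln_from_strings(setNames(m$alphabet[states], tr$tip.label), lab,
                          alphabet = m$alphabet)
  ll <- prune_likelihood(aln, tr, m)
  oracle <- oracle_site_lik_mix(tr, m, setNames(states, tr$tip.label))
  expect_equal(as.numeric(ll), log(oracle), tolerance = 1e-10)
})

test_that("infinitely long branches reduce to stationary products", {
  tr <- ape::read.tree(text = "((a:1e6,b:1e6):1e6,c:1e6);")
  m <- model_gtr(freq = c(0.1, 0.2, 0.3, 0.4))
  lab <- make_labels(c("a", "b", "c"), 1)
  aln <- aln_from_strings(c(a = "A", b = "C", c = "G"), lab)
  ll <- prune_likelihood(aln, tr, m)
  expect_equal(as.numeric(ll), log(0.1 * 0.2 * 0.3), tolerance = 1e-6)
})

test_that("marginal posteriors agree with brute-force Bayes and normalise", {
  set.seed(19)
  for (rep in 1:4) {
    tr <- random_tree(4, seed = rep * 7 + 1, min_len = 0.1, max_len = 0.7)
    m <- two_state_model(freq = c(0.65, 0.35))
    states <- sample(1:2, 4, replace = TRUE)
    lab <- make_labels(tr$tip.label, 2)
    aln <- aln_from_strings(setNames(m$alphabet[states], tr$tip.label), lab,
                            alphabet = m$alphabet)
    rec <- marginal_ancestral(aln, tr, m)
    for (v in 5:7) {
      expect_equal(sum(rec$posterior[[v]][, 1]), 1, tolerance = 1e-9)
      oracle <- oracle_posterior(tr, m, setNames(states, tr$tip.label), v)
      expect_equal(rec$posterior[[v]][, 1], oracle, tolerance = 1e-9)
    }
  }
})

test_that("reconstruction is invariant to leaf input order", {
  tr <- random_tree(6, seed = 23)
  m <- model_jc()
  lab <- labels_for_tree(tr, scatter_foreground(tr, 2))
  sim <- simulate_alignment(tr, m, lab, sites = 30, seed = 4)
  aln <- sim$alignment
  perm <- aln
  ord <- sample(nrow(aln$seq))
  perm$seq <- aln$seq[ord, , drop = FALSE]
  perm$groups <- aln$groups[ord, ]
  r1 <- marginal_ancestral(aln, tr, m)
  r2 <- marginal_ancestral(perm, tr, m)
  root <- length(tr$tip.label) + 1
  expect_equal(r1$posterior[[root]], r2$posterior[[root]], tolerance = 1e-12)
})

test_that("symmetric two-leaf disagreement gives a 50/50 root posterior", {
  tr <- ape::read.tree(text = "(a:0.4,b:0.4);")
  m <- two_state_model()
  lab <- make_labels(c("a", "b"), 1)
  aln <- aln_from_strings(c(a = "0", b = "1"), lab, alphabet = c("0", "1"))
  rec <- marginal_ancestral(aln, tr, m)
  expect_equal(rec$posterior[[3]][, 1], c(0.5, 0.5), tolerance = 1e-12)
  expect_true(rec$tie[3, 1])
})

test_that("uniform leaves make every ancestral posterior favour that state", {
  tr <- random_tree(6, seed = 3)
  m <- two_state_model()
  lab <- labels_for_tree(tr, scatter_foreground(tr, 2))
  mat <- matrix("0", 6, 1, dimnames = list(tr$tip.label, NULL))
  aln <- labeled_alignment(mat, lab, alphabet = m$alphabet)
  rec <- marginal_ancestral(aln, tr, m)
  for (v in 7:11) expect_gt(rec$posterior[[v]][1, 1], 0.5)
})

test_that("pair expectation equals the brute-force sum over (i, j, d)", {
  post <- c(0.9, 0.1)
  P <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, byrow = TRUE)
  # oracle: enumerate parent states i, j and derived d
  oracle <- 0
  for (d in 1:2) {
    q1 <- sum(vapply(setdiff(1:2, d), function(i) post[i] * P[i, d], 1))
    q2 <- sum(vapply(setdiff(1:2, d), function(j) post[j] * P[j, d], 1))
    oracle <- oracle + q1 * q2
  }
  expect_equal(pair_expectation(post, P, post, P), oracle, tolerance = 1e-14)
  expect_equal(oracle, 0.9 * 0.2 * 0.9 * 0.2 + 0.1 * 0.2 * 0.1 * 0.2)
})

test_that("expected convergence vanishes on zero-length branches and grows with length", {
  m <- model_jc()
  lab4 <- make_labels(c("a", "b", "c", "d"), 2)
  mk <- function(t1, t2) {
    ape::read.tree(text = sprintf("((a:%f,c:0.15):0.1,(b:%f,d:0.15):0.1);",
                                  t1, t2))
  }
  aln <- aln_from_strings(c(a = "G", b = "G", c = "A", d = "A"), lab4)
  exp_at <- function(t1, t2) {
    rec <- marginal_ancestral(aln, mk(t1, t2), m)
    as.numeric(expected_convergent_count(rec, c("a", "b")))
  }
  expect_equal(exp_at(0, 0.1), 0, tolerance = 1e-12)
  grid <- seq(0.02, 0.2, by = 0.03)
  vals <- vapply(grid, function(t) exp_at(t, t), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("single foreground branch yields no pairs and zero counts", {
  tr <- random_tree(5, seed = 2)
  pairs <- foreground_pairs(tr, tr$tip.label[1])
  expect_equal(nrow(pairs), 0)
  m <- model_jc()
  lab <- labels_for_tree(tr, tr$tip.label[1])
  sim <- simulate_alignment(tr, m, lab, sites = 10, seed = 1)
  rec <- marginal_ancestral(sim$alignment, tr, m)
  expect_equal(as.numeric(expected_convergent_count(rec, pairs)), 0)
  expect_equal(as.numeric(observed_convergent_count(rec, pairs)), 0)
})

test_that("nested branch pairs are rejected", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  # internal node 5 is ancestral to tips a (1) and b (2)
  expect_error(foreground_pairs(tr, c(1L, 5L)),
               class = "convflight_pair_error")
})

test_that("observed counts find simultaneous derived states in foreground tips", {
  # star-ish tree: two foreground tips share derived G; ancestral A elsewhere
  tr <- ape::read.tree(text = "((a:0.05,c:0.05):0.05,(b:0.05,d:0.05):0.05);")
  lab <- make_labels(c("a", "b", "c", "d"), 2)
  m <- model_jc()
  aln <- aln_from_strings(c(a = "GA", b = "GA", c = "AA", d = "AA"), lab)
  rec <- marginal_ancestral(aln, tr, m)
  obs <- observed_convergent_count(rec, c("a", "b"))
  expect_equal(as.numeric(obs), 1)      # site 1 only; site 2 has no change
  # missing data on one branch removes the pair-site
  aln2 <- aln_from_strings(c(a = "NA", b = "GA", c = "AA", d = "AA"), lab)
  rec2 <- marginal_ancestral(aln2, tr, m)
  expect_equal(as.numeric(observed_convergent_count(rec2, c("a", "b"))), 0)
})

test_that("planted convergence is counted once per planted site", {
  tr <- random_tree(10, seed = 77, min_len = 0.02, max_len = 0.08)
  fg <- scatter_foreground(tr, 2)
  lab <- labels_for_tree(tr, fg)
  m <- model_jc()
  k <- 4
  sim <- simulate_alignment(tr, m, lab, sites = 60,
                            planted = plant_spec(c(5, 15, 25, 35), "G",
                                                 list(fg, fg, fg, fg)),
                            seed = 31)
  # keep only plants that are genuine double substitutions in the realisation
  rec <- marginal_ancestral(sim$alignment, tr, m)
  obs <- observed_convergent_count(rec, fg)
  expect_gte(as.numeric(obs), sum(sim$truth$derived != sim$truth$ancestral) - 1)
  expect_lte(abs(as.numeric(obs) - k), 1)
})

test_that("Poisson tail probabilities match closed forms and are monotone", {
  expect_equal(poisson_significance(2, 0.1), 1 - exp(-0.1) * 1.1,
               tolerance = 1e-12)
  expect_equal(poisson_significance(0, 5), 1)
  expect_equal(poisson_significance(1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_warning(p0 <- poisson_significance(3, 0), "zero expectation")
  expect_equal(p0, 0)
  expect_error(poisson_significance(-1, 1), class = "convflight_domain_error")
  # non-increasing in observed, non-decreasing in expected
  ps <- vapply(0:6, poisson_significance, numeric(1), expected = 1.5)
  expect_true(all(diff(ps) <= 0))
  pe <- vapply(seq(0.1, 3, by = 0.3), function(e) poisson_significance(2, e),
               numeric(1))
  expect_true(all(diff(pe) >= 0))
})

test_that("tree-scale and gamma-shape fits recover sensible optima", {
  tr <- random_tree(8, seed = 41, min_len = 0.1, max_len = 0.3)
  m <- model_jc()
  lab <- labels_for_tree(tr, scatter_foreground(tr, 2))
  sim <- simulate_alignment(tr, m, lab, sites = 400, seed = 6)
  # likelihood at the true scale should beat badly wrong scales
  fit <- fit_tree_scale(sim$alignment, tr, m)
  expect_gt(fit$scale, 0.5)
  expect_lt(fit$scale, 2)
  half <- tr; half$edge.length <- half$edge.length * 0.25
  fit2 <- fit_tree_scale(sim$alignment, half, m)
  expect_equal(fit2$scale * 0.25, fit$scale * 1, tolerance = 0.05)
})
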