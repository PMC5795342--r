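test_that("Mk transition probabilities: identity, closed form, stationarity", {
  expect_equal(mk_transition_prob(1, 1, 0.3, 0, 7), 1)
  expect_equal(mk_transition_prob(1, 2, 0.3, 0, 7), 0)
  expect_equal(round(mk_transition_prob(2, 2, 0.1, 1, 7), 5), 0.56850)
  expect_equal(mk_transition_prob(2, 2, 0.1, 1, 7),
               1 / 7 + (6 / 7) * exp(-0.7), tolerance = 1e-12)
  expect_equal(mk_transition_prob(1, 1, 0.5, 1e6, 7), 1 / 7, tolerance = 1e-9)
  expect_equal(mk_transition_prob(1, 4, 0.5, 1e6, 7), 1 / 7, tolerance = 1e-9)
})

test_that("Mk transition rows sum to one over a parameter grid", {
  for (k in c(2, 3, 7)) {
    for (q in c(0, 0.05, 1, 10)) {
      for (t in c(0, 0.1, 2, 100)) {
        row <- vapply(1:k, function(j) mk_transition_prob(1, j, q, t, k),
                      numeric(1))
        expect_equal(sum(row), 1, tolerance = 1e-9)
        expect_true(all(row >= 0))
      }
    }
  }
})

test_that("two-tip Mk likelihood matches the closed form", {
  tr <- parse_newick("(A:0.5,B:0.5);")
  ll <- mk_log_likelihood(tr, c(A = 1L, B = 1L), q = 1, k = 2)
  expect_equal(exp(ll), 0.5 * (0.5 + 0.5 * exp(-2)), tolerance = 1e-12)
  expect_equal(round(ll, 4), -1.2594)
  # q = 0 with uniform tips: exactly 1/k
  expect_equal(exp(mk_log_likelihood(tr, c(A = 3L, B = 3L), 0, k = 7)), 1 / 7)
  expect_error(mk_log_likelihood(tr, c(A = 9L, B = 1L), 1, k = 7), "1..k")
})

test_that("Mk pruning equals exhaustive enumeration on 4-tip trees, k = 3", {
  set.seed(80)
  for (i in 1:5) {
    tr <- ape::rtree(4)
    st <- stats::setNames(sample.int(3, 4, replace = TRUE), tr$tip.label)
    for (q in c(0.1, 0.7)) {
      expect_equal(mk_log_likelihood(tr, st, q, k = 3),
                   enum_log_likelihood_mk(tr, st, q, 3), tolerance = 1e-10)
    }
  }
  # missing tip contributes an all-ones partial
  tr <- ape::rtree(4)
  st <- stats::setNames(c(1L, 2L, NA, 1L), tr$tip.label)
  expect_equal(mk_log_likelihood(tr, st, 0.4, k = 3),
               enum_log_likelihood_mk(tr, st, 0.4, 3), tolerance = 1e-10)
})

test_that("Mk likelihood is invariant under state relabelling", {
  set.seed(81)
  tr <- ape::rtree(6)
  st <- stats::setNames(sample.int(4, 6, replace = TRUE), tr$tip.label)
  perm <- sample(4)
  st_perm <- stats::setNames(perm[st], names(st))
  expect_equal(mk_log_likelihood(tr, st, 0.3, k = 4),
               mk_log_likelihood(tr, st_perm, 0.3, k = 4), tolerance = 1e-12)
})

test_that("rate fitting: lower bound on constant data, optimizer contract", {
  tr <- sim_species_tree(8, 1, seed = 82)
  flat <- stats::setNames(rep(2L, 8), tr$tip.label)
  expect_equal(fit_mk_rate(tr, flat, k = 7), 1e-8)
  ch <- evolve_discrete_character(tr, 0.5, k = 7, seed = 83)
  qhat <- fit_mk_rate(tr, ch, k = 7)
  ll <- function(q) mk_log_likelihood(tr, ch, q, k = 7)
  expect_gte(ll(qhat), ll(1e-8))
  expect_gte(ll(qhat), ll(100))
})

test_that("joint rate fitting recovers the generating rate", {
  tr <- sim_species_tree(16, 1, seed = 84)
  set.seed(85)
  chars <- replicate(200, evolve_discrete_character(tr, 0.3, k = 7))
  rownames(chars) <- tr$tip.label
  qhat <- fit_mk_rate(tr, chars, k = 7)
  expect_gte(qhat, 0.24)
  expect_lte(qhat, 0.36)
})

test_that("marginal reconstructions match enumeration and an independent engine", {
  # 3-tip brute force, k = 2
  tr <- parse_newick("((A:0.3,B:0.6):0.2,C:0.8);")
  st <- c(A = 1L, B = 1L, C = 2L)
  marg <- marginal_ancestral_states(tr, st, q = 0.5, k = 2)
  expect_equal(as.numeric(marg["4", ]), enum_root_posterior(tr, st, 0.5, 2),
               tolerance = 1e-9)
  expect_equal(rowSums(marg), stats::setNames(rep(1, nrow(marg)),
                                              rownames(marg)))
  # cross-check the full table against ape::ace on a larger tree
  tr8 <- sim_species_tree(8, 1, seed = 86)
  ch <- evolve_discrete_character(tr8, 0.4, k = 3, seed = 87)
  q <- fit_mk_rate(tr8, ch, k = 3)
  mm <- marginal_ancestral_states(tr8, ch, q, k = 3)
  ref <- ape::ace(factor(ch[tr8$tip.label], levels = 1:3), tr8,
                  type = "discrete", model = "ER")
  expect_equal(q, ref$rates, tolerance = 1e-4)
  expect_equal(unname(mm), unname(ref$lik.anc), tolerance = 1e-5)
})

test_that("marginal limits: certainty as q -> 0, uniformity on long branches", {
  tr <- sim_species_tree(6, 1, seed = 88)
  same <- stats::setNames(rep(4L, 6), tr$tip.label)
  marg0 <- marginal_ancestral_states(tr, same, q = 1e-9, k = 7)
  expect_true(all(marg0[, 4] > 1 - 1e-6))
  long <- tr
  long$edge.length <- long$edge.length * 1e5
  ch <- stats::setNames(c(1L, 2L, 3L, 4L, 5L, 6L), tr$tip.label)
  margI <- marginal_ancestral_states(long, ch, q = 1, k = 7)
  expect_true(all(abs(margI - 1 / 7) < 1e-6))
})

test_that("characters simulated without change reconstruct the root exactly", {
  for (seed in 1:5) {
    tr <- sim_species_tree(7, 1, seed = 500 + seed)
    ch <- evolve_discrete_character(tr, 0, k = 7, seed = 600 + seed)
    marg <- marginal_ancestral_states(tr, ch, q = 1e-8, k = 7)
    expect_equal(unname(which.max(marg["8", ])), unname(ch[[1]]))
  }
})

test_that("tracing over trees averages clade-wise with occupancy counts", {
  tr <- balanced_species_tree()
  ch <- evolve_discrete_character(tr, 0.3, k = 7, seed = 89)
  # identical trees: table equals the single-tree result, counts = n
  tabs <- trace_over_trees(replicate(5, tr, simplify = FALSE), ch)
  single_q <- fit_mk_rate(tr, ch, k = 7)
  single <- marginal_ancestral_states(tr, ch, single_q, k = 7)
  expect_true(all(tabs$count == 5L))
  root_key <- paste(sort(tr$tip.label), collapse = ",")
  expect_equal(as.numeric(tabs[tabs$clade == root_key,
                               annulus_states]),
               unname(single["8", ]), tolerance = 1e-9)
  probs <- as.matrix(tabs[, annulus_states])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(tabs)), tolerance = 1e-9)
  # mixed sample: a clade present in 2 of 3 trees averages over those 2
  alt <- parse_newick(paste0("(((S1:1,S3:1):1.5,(S2:1,S4:1):1.5):1.5,",
                             "((S5:1,S6:1):1.5,S7:2.5):1.5);"))
  mix <- list(tr, tr, alt)
  tab2 <- trace_over_trees(mix, ch)
  key12 <- "S1,S2"
  expect_equal(tab2$count[tab2$clade == key12], 2L)
  m1 <- marginal_ancestral_states(tr, ch, fit_mk_rate(tr, ch, k = 7), k = 7)
  # locate the S1,S2 node in `tr` and check the mean equals its vector
  tipsets <- lapply(8:13, function(nd) sort(ape::extract.clade(tr, nd)$tip.label))
  nd <- 7 + which(vapply(tipsets, function(s) identical(s, c("S1", "S2")),
                         logical(1)))
  expect_equal(as.numeric(tab2[tab2$clade == key12, annulus_states]),
               unname(m1[as.character(nd), ]), tolerance = 1e-9)
  expect_error(trace_over_trees(list(), ch), "empty")
})
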