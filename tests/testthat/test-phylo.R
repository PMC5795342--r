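test_that("JC distances invert the expected mismatch proportion", {
  taxa <- c("A", "B")
  mk_aln <- function(p, n = 1000) {
    diff <- round(p * n)
    rbind(A = rep("A", n),
          B = c(rep("C", diff), rep("A", n - diff)))
  }
  D <- jc_distance_matrix(mk_aln(0), "nt")
  expect_equal(D["A", "B"], 0)
  D <- jc_distance_matrix(mk_aln(0.1), "nt")
  expect_equal(D["A", "B"], -0.75 * log(1 - 0.4 / 3), tolerance = 1e-6)
  expect_equal(round(D["A", "B"], 6), 0.107326)
  # saturation capped
  D <- jc_distance_matrix(mk_aln(0.76), "nt")
  expect_equal(D["A", "B"], 5.0)
  # pairwise-complete columns only; all-gap overlap errors
  aln <- rbind(A = c("A", "-"), B = c("-", "A"))
  expect_error(jc_distance_matrix(aln, "nt"), "no comparable")
})

test_that("neighbor joining reconstructs additive distances exactly", {
  # ((A:1,B:2):1,(C:3,D:4))
  lab <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(lab, lab))
  tr <- neighbor_joining(D)
  expect_equal(rf_distance(tr, parse_newick("((A,B),(C,D));")), 0)
  expect_equal(sum(tr$edge.length), 11)      # 1+2+3+4 pendant + 1 internal
  recon <- ape::cophenetic.phylo(tr)[lab, lab]
  expect_equal(recon, D, tolerance = 1e-9)
  # ultrametric matrix: correct topology among the three alternatives
  DU <- matrix(c(0, 2, 8, 8,
                 2, 0, 8, 8,
                 8, 8, 0, 4,
                 8, 8, 4, 0), 4, 4, dimnames = list(lab, lab))
  expect_equal(rf_distance(neighbor_joining(DU),
                           parse_newick("((A,B),(C,D));")), 0)
  # n = 3: the unique unrooted tree with solved pendant lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(lab[1:3], lab[1:3]))
  t3 <- neighbor_joining(D3)
  expect_equal(ape::cophenetic.phylo(t3)[lab[1:3], lab[1:3]], D3)
  expect_error(neighbor_joining(matrix(NA_real_, 4, 4)), "NaN|NA")
})

test_that("two-taxon JC likelihood matches the closed form", {
  tr <- parse_newick("(A:0.05,B:0.05);")
  m <- substitution_model("JC69")
  ll <- log_likelihood(tr, rbind(A = "A", B = "A"), m)
  expect_equal(ll, log(0.25 * (0.25 + 0.75 * exp(-4 * 0.1 / 3))),
               tolerance = 1e-9)
  expect_equal(round(ll, 4), -1.4846)
})

test_that("pruning equals exhaustive state enumeration (nt, with gaps)", {
  set.seed(60)
  m_jc <- substitution_model("JC69")
  m_gtr <- substitution_model("GTR",
                              exchangeabilities = c(1, 2, 0.5, 1.2, 3, 1),
                              freqs = c(0.3, 0.2, 0.2, 0.3))
  for (n_taxa in 4:5) {
    tr <- ape::rtree(n_taxa)
    tr$tip.label <- paste0("t", seq_len(n_taxa))
    aln <- matrix(sample(c("A", "C", "G", "T"), n_taxa * 4, replace = TRUE),
                  n_taxa, 4, dimnames = list(tr$tip.label, NULL))
    aln[1, 2] <- "-"                         # one missing cell
    for (m in list(m_jc, m_gtr)) {
      expect_equal(log_likelihood(tr, aln, m),
                   enum_log_likelihood_nt(tr, aln, m), tolerance = 1e-9)
    }
  }
})

test_that("likelihood is invariant to rerooting (pulley principle)", {
  set.seed(61)
  m <- substitution_model("GTR", exchangeabilities = c(1, 2, 1, 1, 3, 1),
                          freqs = c(0.3, 0.2, 0.2, 0.3),
                          alpha = 0.7, gamma_categories = 4)
  tr <- ape::rtree(8)
  aln <- evolve_sequences(ape::rtree(8), substitution_model("JC69"), 40,
                          seed = 6)$nt
  rownames(aln) <- tr$tip.label
  ll <- log_likelihood(tr, aln, m)
  for (og in c(2, 5, 7)) {
    rerooted <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[og],
                          resolve.root = TRUE)
    expect_equal(log_likelihood(rerooted, aln, m), ll, tolerance = 1e-6)
  }
})

test_that("model limits: GTR collapses to JC, gamma collapses as alpha grows", {
  set.seed(62)
  tr <- ape::rtree(6)
  aln <- evolve_sequences(tr, substitution_model("JC69"), 50, seed = 7)$nt
  m_jc <- substitution_model("JC69")
  m_gtr1 <- substitution_model("GTR", exchangeabilities = rep(1, 6),
                               freqs = rep(0.25, 4))
  expect_equal(log_likelihood(tr, aln, m_gtr1), log_likelihood(tr, aln, m_jc),
               tolerance = 1e-9)
  m_g <- substitution_model("JC69", alpha = 1e6, gamma_categories = 4)
  expect_lt(abs(log_likelihood(tr, aln, m_g) - log_likelihood(tr, aln, m_jc)),
            1e-3)
})

test_that("invariant-sites mixture matches an independent implementation", {
  set.seed(63)
  tr <- ape::rtree(5)
  aln <- evolve_sequences(tr, substitution_model("JC69"), 60, seed = 8)$nt
  m <- substitution_model("GTR", exchangeabilities = c(1, 2, 1, 1, 3, 1),
                          freqs = c(0.28, 0.22, 0.24, 0.26),
                          alpha = 0.9, gamma_categories = 4, p_inv = 0.2)
  pd <- phangorn::phyDat(aln, type = "DNA")
  ref <- phangorn::pml(tr, pd, model = "GTR", k = 4, shape = 0.9, inv = 0.2,
                       Q = c(1, 2, 1, 1, 3, 1),
                       bf = c(0.28, 0.22, 0.24, 0.26))$logLik
  expect_equal(log_likelihood(tr, aln, m), ref, tolerance = 1e-6)
})

test_that("the empirical amino-acid model reproduces reference JTT likelihoods", {
  set.seed(64)
  tr <- ape::rtree(5)
  aa <- evolve_sequences(tr, substitution_model("JC69"), 60, seed = 9)$aa
  rownames(aa) <- tr$tip.label
  m <- substitution_model("EMPIRICAL")
  ref <- phangorn::pml(tr, phangorn::phyDat(aa, type = "AA"),
                       model = "JTT")$logLik
  expect_equal(log_likelihood(tr, aa, m), ref, tolerance = 1e-6)
  # +F: empirical frequencies re-normalise the same exchangeabilities
  mf <- substitution_model("EMPIRICAL", freqs = empirical_freqs(aa, "aa"))
  expect_true(is.finite(log_likelihood(tr, aa, mf)))
})

test_that("ML search recovers an easy 6-taxon topology and never regresses", {
  tru <- parse_newick(paste0("(((A:0.3,B:0.3):0.3,(C:0.3,D:0.3):0.3):0.3,",
                             "(E:0.3,F:0.3):0.3);"))
  m <- substitution_model("JC69")
  seqs <- evolve_sequences(tru, m, 500, seed = 10)
  fit <- ml_search(seqs$nt, m)
  expect_equal(rf_distance(fit$tree, tru), 0)
  # the search never leaves the true topology when started there
  fit2 <- ml_search(seqs$nt, m, start = ape::unroot(tru))
  expect_equal(rf_distance(fit2$tree, tru), 0)
  expect_gte(fit$loglik, optimize_branch_lengths(
    ape::unroot(neighbor_joining(jc_distance_matrix(seqs$nt, "nt"))),
    encode_alignment(seqs$nt, m), m)$loglik - 1e-6)
})

test_that("identical sequences give a topology-independent flat likelihood", {
  aln <- matrix("A", 5, 30, dimnames = list(paste0("t", 1:5), NULL))
  m <- substitution_model("JC69")
  t1 <- ape::rtree(5); t1$tip.label <- paste0("t", 1:5)
  t2 <- ape::rtree(5); t2$tip.label <- paste0("t", c(3, 1, 5, 2, 4))
  b1 <- optimize_branch_lengths(t1, encode_alignment(aln, m), m)
  b2 <- optimize_branch_lengths(t2, encode_alignment(aln, m), m)
  expect_equal(b1$loglik, b2$loglik, tolerance = 1e-6)
  expect_true(all(b1$tree$edge.length < 1e-6))
})

test_that("bootstrap support is reproducible and certain on easy data", {
  tru <- parse_newick("(((A:0.4,B:0.4):0.4,(C:0.4,D:0.4):0.4):0.4,E:0.4);")
  m <- substitution_model("JC69")
  seqs <- evolve_sequences(tru, m, 250, seed = 12)
  bs1 <- bootstrap_support(seqs$nt, m, n_reps = 20, seed = 5)
  bs2 <- bootstrap_support(seqs$nt, m, n_reps = 20, seed = 5)
  expect_identical(write_newick(bs1$tree), write_newick(bs2$tree))
  sup <- suppressWarnings(as.numeric(bs1$tree$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(all(sup >= 95))                # both true splits near-certain
})

test_that("Robinson-Foulds distance counts one-sided bipartitions", {
  t1 <- parse_newick("((A,B),(C,D),E);")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, parse_newick("((A,C),(B,D),E);")), 4)
  # maximum 2(n-3) for binary trees, here n = 5
  expect_equal(rf_distance(t1, parse_newick("((A,C),(B,E),D);")), 4)
  expect_error(rf_distance(t1, parse_newick("((A,B),(C,F),E);")), "mismatch")
})
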