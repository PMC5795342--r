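make_family <- function(id, species_copies) {
  # species_copies: named integer vector, species -> copy count
  members <- list()
  for (sp in names(species_copies)) {
    for (cp in seq_len(species_copies[[sp]])) {
      members[[length(members) + 1L]] <- seq_record(sp, as.character(cp), "ACGT")
    }
  }
  homolog_family(id, members)
}

test_that("species with more than max_copies lose all their sequences", {
  fam <- make_family("f1", c(X = 11L, Y = 3L))
  out <- drop_overrepresented_species(fam, max_copies = 10L)
  expect_false("X" %in% family_species(out))
  expect_equal(sum(family_species(out) == "Y"), 3L)
  # boundary: exactly 10 copies stay (strictly-greater rule)
  fam10 <- make_family("f2", c(X = 10L, Y = 1L))
  expect_equal(length(drop_overrepresented_species(fam10)$members), 11L)
  # untouched family passes through identically
  ok <- make_family("f3", c(X = 2L, Y = 1L))
  expect_identical(drop_overrepresented_species(ok), ok)
})

test_that("occupancy filter applies the round-half-up species threshold", {
  f35 <- make_family("a", stats::setNames(rep(1L, 35), paste0("s", 1:35)))
  f34 <- make_family("b", stats::setNames(rep(1L, 34), paste0("s", 1:34)))
  kept <- occupancy_filter(list(f35, f34), n_species_total = 69, fraction = 0.5)
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$id, "a")
  # fraction 1 keeps only complete families
  expect_length(occupancy_filter(list(f35), 35, 1.0), 1L)
  expect_length(occupancy_filter(list(f34), 35, 1.0), 0L)
  expect_length(occupancy_filter(list(), 69, 0.5), 0L)
})

test_that("paralog pruning keeps copy-clean trees unchanged", {
  tr <- parse_newick("((A.1,B.1),(C.1,D.1));")
  expect_identical(prune_to_ortholog(tr), tr)
})

test_that("paralog pruning picks the maximal copy-clean edge side", {
  # pendant-complement side {A.1,B.1,C.1} has 3 distinct species
  t1 <- parse_newick("((A.1,B.1),(C.1,A.2));")
  expect_setequal(prune_to_ortholog(t1)$tip.label, c("A.1", "B.1", "C.1"))
  # two 3-leaf sides tie on (species, leaves); lexicographic pick keeps A.1
  t2 <- parse_newick("((A.1,B.1),(A.2,C.1));")
  expect_setequal(prune_to_ortholog(t2)$tip.label, c("A.1", "B.1", "C.1"))
  # no side with >= 2 clean species -> discarded
  t3 <- parse_newick("((A.1,A.2),(A.3,A.4));")
  expect_null(prune_to_ortholog(t3))
})

test_that("pruning equals brute-force edge-side search on random 12-leaf trees", {
  for (seed in 1:40) {
    tr <- random_paralog_tree(12, 5, seed)
    got <- prune_to_ortholog(tr)
    want <- best_side_oracle(tr)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(sort(got$tip.label), want, info = paste("seed", seed))
      expect_false(anyDuplicated(label_species(got$tip.label)) > 0)
    }
  }
})

test_that("1-to-1 filter enforces single copies and the taxon floor", {
  trees <- list(
    good = parse_newick(paste0("(", paste(sprintf("s%d.1", 1:52), collapse = ","), ");")),
    dup  = parse_newick("((s1.1,s1.2),(s2.1,(s3.1,s4.1)));"),
    few  = parse_newick(paste0("(", paste(sprintf("s%d.1", 1:51), collapse = ","), ");"))
  )
  expect_equal(one_to_one_filter(trees, min_taxa = 52L), "good")
  # dup is excluded even at the lower floor because s1 has two copies
  expect_setequal(one_to_one_filter(trees, min_taxa = 4L), c("good", "few"))
  expect_equal(one_to_one_filter(trees["dup"], min_taxa = 4L), character(0))
})

test_that("raising min_taxa never increases retained groups", {
  set.seed(55)
  trees <- lapply(1:25, function(i) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- paste0("s", sample(seq_len(n + 2), n), ".1")
    tr
  })
  names(trees) <- paste0("t", seq_along(trees))
  counts <- vapply(4:12, function(mt) length(one_to_one_filter(trees, mt)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("alignment trimming drops gappy columns and ragged flanks", {
  taxa <- paste0("t", 1:5)
  aa <- matrix("M", 5, 8, dimnames = list(taxa, NULL))
  nt <- matrix("A", 5, 24, dimnames = list(taxa, NULL))
  out <- trim_alignment(aa, nt)
  expect_identical(out$aa, aa)               # conserved, gapless: unchanged
  expect_identical(out$nt, nt)
  # single 60%-gap column removed at the 0.5 threshold
  aa2 <- aa
  aa2[1:3, 4] <- "-"
  out2 <- trim_alignment(aa2, nt)
  expect_equal(out2$kept, setdiff(1:8, 4))
  expect_equal(ncol(out2$nt), 21L)
  expect_equal(ncol(out2$nt) %% 3L, 0L)
  # unconserved flanks are cut back to the first good run of 3
  aa3 <- aa
  aa3[, 1] <- c("M", "K", "L", "P", "F")
  out3 <- trim_alignment(aa3)
  expect_equal(out3$kept, 2:8)
  # nothing conserved enough -> empty alignment, flagged by length filter
  aa4 <- matrix(rep(c("M", "K", "L", "P", "F"), 8), 5, 8,
                dimnames = list(taxa, NULL))
  out4 <- trim_alignment(aa4)
  expect_equal(ncol(out4$aa), 0L)
  expect_false(length_filter(list(nt = out4$aa, aa = out4$aa)))
})

test_that("length filter is inclusive at 150 nt / 50 aa", {
  g <- function(nt_cols, aa_cols) list(nt = matrix("A", 2, nt_cols),
                                       aa = matrix("A", 2, aa_cols))
  expect_true(length_filter(g(150, 50)))
  expect_false(length_filter(g(149, 50)))
  expect_false(length_filter(g(150, 49)))
  expect_true(length_filter(g(300, 100)))
})

test_that("without duplication every simulated family survives as 1-to-1", {
  cfg <- default_config()$simulate
  cfg$n_species <- 6; cfg$n_genes <- 6; cfg$seq_length <- 60
  sim <- simulate_dataset(cfg, seed = 77)
  families <- lapply(sim$families, function(f) {
    list(id = f$id,
         nt = `rownames<-`(f$nt, sub("^[^|]+\\|", "", rownames(f$nt))),
         aa = `rownames<-`(f$aa, sub("^[^|]+\\|", "", rownames(f$aa))))
  })
  opts <- default_config()$ortholog
  opts$min_nt_length <- 90L; opts$min_aa_length <- 30L
  ex <- extract_ortholog_groups(families, cfg$n_species, opts)
  expect_equal(sort(names(ex$groups)), sort(names(sim$families)))
  expect_true(all(ex$audit$fate == "retained"))
  # pruning was the identity: every species present exactly once
  for (g in ex$groups) {
    expect_equal(sort(g$species), paste0("S", 1:6))
  }
})
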