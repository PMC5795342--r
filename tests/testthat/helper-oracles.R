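# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: likelihoods by exhaustive state enumeration,
# quartet scores by per-quartet subtree comparison, edge-side search via
# igraph component splitting, MCL by a standalone matrix iteration.

# exhaustive-summation likelihood of one site pattern (states 1..k, NA =
# missing, summed over); prior at the root node (ntip+1)
enum_site_likelihood <- function(tree, site, pmat_fun, prior) {
  k <- length(prior)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  free <- c(which(is.na(site)), ntip + seq_len(tree$Nnode))
  fixed <- rep(NA_integer_, nn)
  fixed[seq_len(ntip)] <- site
  grid <- expand.grid(rep(list(seq_len(k)), length(free)))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    st <- fixed
    st[free] <- as.integer(grid[r, ])
    p <- prior[st[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      P <- pmat_fun(tree$edge.length[e])
      p <- p * P[st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    tot <- tot + p
  }
  tot
}

enum_log_likelihood_nt <- function(tree, alignment, model) {
  stopifnot(model$gamma_categories == 1L, model$p_inv == 0)
  idx <- match(alignment, model$states)
  dim(idx) <- dim(alignment)
  rownames(idx) <- rownames(alignment)
  idx <- idx[tree$tip.label, , drop = FALSE]
  sum(vapply(seq_len(ncol(idx)), function(j) {
    log(enum_site_likelihood(tree, idx[, j],
                             function(t) transition_matrix(model, t),
                             model$freqs))
  }, numeric(1)))
}

enum_log_likelihood_mk <- function(tree, states, q, k) {
  st <- states[tree$tip.label]
  log(enum_site_likelihood(tree, st,
                           function(t) outer(1:k, 1:k, mk_transition_prob,
                                             q = q, t = t, k = k),
                           rep(1 / k, k)))
}

# brute-force root posterior: P(root state | tips) by enumeration
enum_root_posterior <- function(tree, states, q, k) {
  ntip <- length(tree$tip.label)
  st <- states[tree$tip.label]
  pm <- function(t) outer(1:k, 1:k, mk_transition_prob, q = q, t = t, k = k)
  joint <- vapply(seq_len(k), function(s) {
    prior <- rep(0, k); prior[s] <- 1 / k
    enum_site_likelihood(tree, st, pm, prior)
  }, numeric(1))
  joint / sum(joint)
}

# O(n^4) quartet score: drop to each 4-taxon subset and compare topologies
quartet_score_oracle <- function(species_tree, gene_trees) {
  taxa <- species_tree$tip.label
  quads <- utils::combn(taxa, 4, simplify = FALSE)
  total <- 0L
  for (quad in quads) {
    sp4 <- ape::unroot(ape::keep.tip(species_tree, quad))
    sp4$edge.length <- NULL
    for (gt in gene_trees) {
      if (!all(quad %in% gt$tip.label)) next
      gt4 <- ape::unroot(ape::keep.tip(gt, quad))
      gt4$edge.length <- NULL
      if (gt4$Nnode < 2) next                     # unresolved quartet
      if (phangorn::RF.dist(sp4, gt4) == 0) total <- total + 1L
    }
  }
  total
}

# edge-side enumeration by deleting each edge of the leaf-labelled graph
edge_sides_oracle <- function(tree) {
  ed <- apply(tree$edge, 2, as.character)
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  ntip <- length(tree$tip.label)
  sides <- list()
  for (e in seq_len(nrow(ed))) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, ed[e, ]))
    comp <- igraph::components(g2)$membership
    for (side_id in 1:2) {
      nodes <- as.integer(names(comp)[comp == comp[ed[e, side_id]]])
      tips <- tree$tip.label[nodes[nodes <= ntip]]
      if (length(tips)) sides[[length(sides) + 1L]] <- sort(tips)
    }
  }
  unique(sides)
}

# the ranking of the paralog-pruning contract, applied to oracle sides
best_side_oracle <- function(tree) {
  sides <- edge_sides_oracle(tree)
  best <- NULL
  for (side in sides) {
    sp <- label_species(side)
    if (anyDuplicated(sp) || length(unique(sp)) < 2) next
    if (is.null(best)) { best <- side; next }
    bsp <- label_species(best)
    a <- c(length(unique(sp)), length(side))
    b <- c(length(unique(bsp)), length(best))
    if (a[1] > b[1] || (a[1] == b[1] && a[2] > b[2]) ||
        (all(a == b) && paste(side, collapse = "|") < paste(best, collapse = "|"))) {
      best <- side
    }
  }
  best
}

# standalone MCL limit-matrix iteration (the hand-iterable recursion)
mcl_limit_oracle <- function(W, inflation = 2, prune = 1e-5, tol = 1e-8) {
  diag(W) <- apply(W, 2, max)
  norm <- function(M) sweep(M, 2, pmax(colSums(M), .Machine$double.eps), "/")
  M <- norm(W)
  for (i in 1:200) {
    M2 <- norm({X <- (M %*% M)^inflation; X[X < prune] <- 0; X})
    if (max(abs(M2 - M)) < tol) return(M2)
    M <- M2
  }
  M
}

# random gene tree whose tips reuse species labels (paralog-rich)
random_paralog_tree <- function(n_leaves, n_species, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves)
  sp <- sample(paste0("sp", seq_len(n_species)), n_leaves, replace = TRUE)
  copy <- stats::ave(seq_along(sp), sp, FUN = seq_along)
  tr$tip.label <- paste(sp, copy, sep = ".")
  ape::unroot(tr)
}

balanced_species_tree <- function(internal_cu = 1.5, tip_cu = 1) {
  # fixed ultrametric 7-taxon tree, every internal branch = `internal_cu`
  i <- internal_cu; t1 <- tip_cu
  parse_newick(sprintf(
    "(((S1:%g,S2:%g):%g,(S3:%g,S4:%g):%g):%g,((S5:%g,S6:%g):%g,S7:%g):%g);",
    t1, t1, i, t1, t1, i, i, t1, t1, i, t1 + i, i))
}
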