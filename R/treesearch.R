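#' Optimize branch lengths of a fixed topology
#'
#' Coordinate ascent: each edge length in turn is optimised by Brent's
#' method ([stats::optimize()]) holding the others fixed, sweeping until the
#' log-likelihood gain of a full sweep falls below `tol`.
#'
#' @param tree `phylo` with (possibly crude) branch lengths.
#' @param enc Encoded alignment ([encode_alignment()]).
#' @param model `subst_model`.
#' @param max_sweeps,tol Convergence controls.
#' @param upper Upper bound per branch (substitutions/site).
#' @return list(tree, loglik).
#' @export
optimize_branch_lengths <- function(tree, enc, model, max_sweeps = 5L,
                                    tol = 1e-4, upper = 10) {
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length[tree$edge.length <= 0] <- 1e-8
  ll <- log_likelihood(tree, enc, model)
  for (sweep in seq_len(max_sweeps)) {
    ll0 <- ll
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(x) {
        tree$edge.length[e] <- x
        log_likelihood(tree, enc, model)
      }
      opt <- stats::optimize(f, lower = 1e-9, upper = upper, maximum = TRUE,
                             tol = 1e-6)
      if (opt$objective > ll) {
        tree$edge.length[e] <- opt$maximum
        ll <- opt$objective
      }
    }
    if (ll - ll0 < tol) break
  }
  list(tree = tree, loglik = ll)
}

#' Maximum-likelihood tree search
#'
#' Neighbor-joining start tree (Jukes-Cantor distances), Brent per-branch
#' length optimisation, and nearest-neighbour-interchange hill climbing to
#' a local optimum: the search stops when no NNI neighbour improves the
#' log-likelihood by more than `tol`. Deterministic for a given input.
#'
#' @param alignment Character matrix (rows = taxa).
#' @param model `subst_model`.
#' @param start Optional start topology (`phylo`); default NJ.
#' @param tol Improvement threshold for accepting an NNI move (log units).
#' @param max_rounds Cap on NNI acceptance rounds.
#' @return list(tree, loglik) of class `ml_result`; the tree is unrooted.
#' @export
ml_search <- function(alignment, model, start = NULL, tol = 1e-4,
                      max_rounds = 30L) {
  if (nrow(alignment) < 4) stop("need >= 4 taxa for tree search")
  enc <- encode_alignment(alignment, model)
  if (is.null(start)) {
    alpha_chr <- if (model$k == 4) "nt" else "aa"
    start <- neighbor_joining(jc_distance_matrix(alignment, alpha_chr))
  }
  if (!ape::is.binary(start)) start <- ape::multi2di(start, random = FALSE)
  start <- ape::unroot(start)
  cur <- optimize_branch_lengths(start, enc, model)
  if (!is.finite(cur$loglik)) stop("non-finite likelihood on start tree")
  for (round in seq_len(max_rounds)) {
    nbs <- nni_neighbors(cur$tree)
    best <- cur
    for (nb in nbs) {
      cand <- optimize_branch_lengths(nb, enc, model, max_sweeps = 3L)
      if (cand$loglik > best$loglik + tol) best <- cand
    }
    if (best$loglik <= cur$loglik + tol) break
    cur <- best
  }
  structure(list(tree = cur$tree, loglik = cur$loglik), class = "ml_result")
}

#' All nearest-neighbour-interchange neighbours of an unrooted binary tree
#'
#' Two alternative topologies per internal edge, in a deterministic order.
#' Branch lengths are carried over where the topology is unchanged; the
#' swapped edges keep their lengths.
#'
#' @param tree Unrooted binary `phylo`.
#' @return List of `phylo` objects.
#' @export
nni_neighbors <- function(tree) {
  nbs <- phangorn::nni(tree)
  lapply(nbs, function(nb) {
    if (is.null(nb$edge.length)) {
      nb$edge.length <- rep(0.1, nrow(nb$edge))
    }
    nb
  })
}

#' Nonparametric bootstrap support for an ML tree
#'
#' Resamples alignment columns with replacement, reruns [ml_search()] per
#' replicate, and annotates each internal branch of the point-estimate tree
#' with the percentage of replicates whose tree contains that bipartition.
#'
#' @param alignment Character matrix.
#' @param model `subst_model`.
#' @param n_reps Number of bootstrap replicates.
#' @param seed RNG seed (all resampling flows from it).
#' @param best Optional precomputed point-estimate `ml_result`.
#' @return list(tree = support-annotated `phylo`, loglik, replicates).
#' @export
bootstrap_support <- function(alignment, model, n_reps = 100L, seed = 1L,
                              best = NULL) {
  stopifnot(n_reps >= 1)
  if (is.null(best)) best <- ml_search(alignment, model)
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(alignment), replace = TRUE)
    reps[[b]] <- ml_search(alignment[, cols, drop = FALSE], model)$tree
  }
  tree <- annotate_support(best$tree, reps)
  list(tree = tree, loglik = best$loglik, replicates = reps)
}

#' Annotate a tree's internal branches with bipartition frequencies
#'
#' @param tree Point-estimate `phylo`.
#' @param trees Replicate trees (same leaf set).
#' @return `phylo` with integer percentage `node.label`s.
#' @export
annotate_support <- function(tree, trees) {
  rep_splits <- lapply(trees, tree_splits)
  counts <- table(unlist(rep_splits))
  ntip <- length(tree$tip.label)
  tips_all <- sort(tree$tip.label)
  labs <- character(tree$Nnode)
  tipsets <- node_tip_sets(tree)
  for (nd in seq_len(tree$Nnode)) {
    side <- sort(tipsets[[ntip + nd]])
    if (length(side) <= 1L || length(side) >= ntip - 1L) { labs[nd] <- ""; next }
    other <- setdiff(tips_all, side)
    canon <- if (length(side) < length(other)) side
             else if (length(side) > length(other)) other
             else min2(side, other)
    key <- paste(canon, collapse = "|")
    cnt <- if (key %in% names(counts)) counts[[key]] else 0L
    labs[nd] <- as.character(round(100 * cnt / length(trees)))
  }
  tree$node.label <- labs
  tree
}

# tip label sets below every node (index = node id)
node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  tree2 <- stats::reorder(tree, "postorder")
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree2$edge))) {
    par <- tree2$edge[e, 1]; ch <- tree2$edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  sets
}
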