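#' Convert an occupancy fraction to a minimum taxon count
#'
#' Round-half-up of `fraction * n_taxa`: the unique simple rounding rule
#' consistent with the 50%/75%/90% thresholds of a 69-taxon study
#' (35, 52 and 62 taxa respectively).
#'
#' @param fraction Required fraction in (0, 1].
#' @param n_taxa Total number of taxa.
#' @return Integer minimum taxon count.
#' @export
occupancy_threshold <- function(fraction, n_taxa) {
  stopifnot(fraction > 0, fraction <= 1, n_taxa >= 1)
  as.integer(floor(fraction * n_taxa + 0.5))
}

#' Concatenate ortholog groups into a supermatrix
#'
#' Genes with at least `min_taxa` species are concatenated in stable id
#' order; taxa absent from a gene are gap-filled. Gene occupancy is the
#' mean per-gene fraction of taxa present (x100); character occupancy is
#' the fraction of non-gap cells (x100).
#'
#' @param groups Named list of ortholog groups (`species`, `nt`, `aa`).
#' @param min_taxa Minimum species count per gene ([occupancy_threshold()]).
#' @param alphabet `"nt"` or `"aa"` (which alignment to concatenate).
#' @param taxa Optional fixed taxon set; default = union over kept genes.
#' @return Object of class `supermatrix`: alignment, partitions, presence
#'   mask, occupancy percentages.
#' @export
build_supermatrix <- function(groups, min_taxa, alphabet = c("nt", "aa"),
                              taxa = NULL) {
  alphabet <- match.arg(alphabet)
  keep <- vapply(groups, function(g) length(g$species) >= min_taxa, logical(1))
  groups <- groups[keep]
  if (!length(groups)) stop("zero genes meet the occupancy threshold")
  groups <- groups[order(names(groups))]
  if (is.null(taxa)) taxa <- sort(unique(unlist(lapply(groups, `[[`, "species"))))
  widths <- vapply(groups, function(g) ncol(g[[alphabet]]), integer(1))
  parts <- partition_table(names(groups), widths)
  aln <- matrix("-", length(taxa), sum(widths),
                dimnames = list(taxa, NULL))
  presence <- matrix(FALSE, length(taxa), length(groups),
                     dimnames = list(taxa, names(groups)))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    cols <- parts$start[i]:parts$end[i]
    rows <- intersect(taxa, g$species)
    aln[rows, cols] <- g[[alphabet]][rows, , drop = FALSE]
    presence[rows, i] <- TRUE
  }
  gene_occ <- 100 * mean(colMeans(presence))
  char_occ <- 100 * sum(presence * rep(widths, each = length(taxa))) /
    (length(taxa) * sum(widths))
  structure(list(taxa = taxa, alignment = aln, partitions = parts,
                 presence = presence, alphabet = alphabet,
                 gene_occupancy = gene_occ, character_occupancy = char_occ),
            class = "supermatrix")
}

# ---- quartet machinery -------------------------------------------------

# topological (unit-length) tip-tip distance matrix
topo_dist <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  ape::cophenetic.phylo(tree)
}

# induced quartet topologies of `tree` for the 4-row index matrix `quart`
# (indices into `taxa`): 1 = 12|34, 2 = 13|24, 3 = 14|23, 0 = unresolved
# or some taxon missing.
quartet_topologies <- function(tree, taxa, quart) {
  D <- topo_dist(tree)
  pos <- match(taxa, rownames(D))
  q <- matrix(pos[quart], nrow = 4)
  out <- integer(ncol(q))
  present <- colSums(is.na(q)) == 0
  if (!any(present)) return(out)
  qp <- q[, present, drop = FALSE]
  s1 <- D[cbind(qp[1, ], qp[2, ])] + D[cbind(qp[3, ], qp[4, ])]
  s2 <- D[cbind(qp[1, ], qp[3, ])] + D[cbind(qp[2, ], qp[4, ])]
  s3 <- D[cbind(qp[1, ], qp[4, ])] + D[cbind(qp[2, ], qp[3, ])]
  S <- rbind(s1, s2, s3)
  mn <- apply(S, 2, min)
  ties <- colSums(S == rep(mn, each = 3)) > 1
  topo <- max.col(t(-S), ties.method = "first")
  topo[ties] <- 0L
  out[present] <- topo
  out
}

# per-quartet gene-tree topology counts: nquartet x 3 matrix
quartet_counts <- function(gene_trees, taxa, quart) {
  counts <- matrix(0L, ncol(quart), 3)
  for (gt in gene_trees) {
    topo <- quartet_topologies(gt, taxa, quart)
    seen <- topo > 0
    if (any(seen)) {
      idx <- cbind(which(seen), topo[seen])
      counts[idx] <- counts[idx] + 1L
    }
  }
  counts
}

#' Quartet score of a species tree against gene trees
#'
#' The summary-coalescent optimality criterion: over all 4-taxon subsets of
#' the species tree's leaves and all gene trees, the number of cases where
#' the gene tree's induced resolved quartet topology matches the species
#' tree's. Gene trees missing a quartet's taxa, and unresolved induced
#' quartets, contribute nothing.
#'
#' @param species_tree `phylo`.
#' @param gene_trees List of `phylo` (leaf sets may be subsets).
#' @return Integer score.
#' @export
quartet_score <- function(species_tree, gene_trees) {
  taxa <- sort(species_tree$tip.label)
  quart <- utils::combn(length(taxa), 4)
  counts <- quartet_counts(gene_trees, taxa, quart)
  sp_topo <- quartet_topologies(species_tree, taxa, quart)
  score_from_counts(sp_topo, counts)
}

score_from_counts <- function(sp_topo, counts) {
  res <- sp_topo > 0
  sum(counts[cbind(which(res), sp_topo[res])])
}

#' Coalescent species tree by maximum quartet support
#'
#' Maximises the quartet score over unrooted topologies. `exact` mode
#' enumerates all (2n-5)!! topologies (n <= 9) and breaks ties towards the
#' lexicographically smallest Newick string; `heuristic` mode starts from a
#' neighbor-joining tree on the mean topological distance across gene
#' trees and hill-climbs with nearest-neighbour interchanges on the same
#' objective until no neighbour improves it.
#'
#' @param gene_trees List of `phylo`.
#' @param mode `"auto"`, `"exact"` or `"heuristic"`.
#' @return list(tree, quartet_score, mode) of class `species_tree_result`.
#' @export
coalescent_species_tree <- function(gene_trees,
                                    mode = c("auto", "exact", "heuristic")) {
  mode <- match.arg(mode)
  taxa <- sort(unique(unlist(lapply(gene_trees, `[[`, "tip.label"))))
  n <- length(taxa)
  if (n < 4) stop("need >= 4 taxa for a species tree")
  if (mode == "auto") mode <- if (n <= 9) "exact" else "heuristic"
  if (mode == "exact" && n > 9) stop("exact mode requires <= 9 taxa")
  quart <- utils::combn(n, 4)
  counts <- quartet_counts(gene_trees, taxa, quart)
  scorer <- function(tree) {
    score_from_counts(quartet_topologies(tree, taxa, quart), counts)
  }
  if (mode == "exact") {
    cand <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
    cand <- lapply(seq_along(cand), function(i) cand[[i]])  # expand TipLabel
    best <- NULL; best_score <- -1; best_nwk <- ""
    for (tr in cand) {
      s <- scorer(tr)
      nwk <- write_newick(tr)
      if (s > best_score || (s == best_score && nwk < best_nwk)) {
        best <- tr; best_score <- s; best_nwk <- nwk
      }
    }
  } else {
    D <- mean_topo_dist(gene_trees, taxa)
    best <- ape::unroot(neighbor_joining(D))
    best_score <- scorer(best)
    repeat {
      improved <- FALSE
      for (nb in nni_neighbors(best)) {
        s <- scorer(nb)
        if (s > best_score) { best <- nb; best_score <- s; improved <- TRUE }
      }
      if (!improved) break
    }
  }
  best$edge.length <- NULL
  structure(list(tree = best, quartet_score = as.integer(best_score),
                 mode = mode),
            class = "species_tree_result")
}

# mean topological distance across gene trees (pairs averaged over the
# gene trees containing both taxa)
mean_topo_dist <- function(gene_trees, taxa) {
  n <- length(taxa)
  acc <- matrix(0, n, n, dimnames = list(taxa, taxa))
  cnt <- matrix(0, n, n)
  for (gt in gene_trees) {
    D <- topo_dist(gt)
    pos <- match(taxa, rownames(D))
    ok <- which(!is.na(pos))
    sub <- D[pos[ok], pos[ok]]
    acc[ok, ok] <- acc[ok, ok] + sub
    cnt[ok, ok] <- cnt[ok, ok] + 1
  }
  if (any(cnt == 0 & row(cnt) != col(cnt))) {
    stop("some taxon pair never co-occurs in a gene tree")
  }
  diag(cnt) <- 1
  acc / cnt
}

#' Multilocus bootstrap support for the coalescent species tree
#'
#' Point estimate: per-gene trees are estimated by [ml_search()] and
#' summarised with [coalescent_species_tree()]. Each replicate resamples
#' genes with replacement and (in the default two-stage variant) also
#' resamples sites within each sampled gene before re-estimating its tree;
#' support on the point-estimate tree is the percentage of replicate
#' species trees containing each bipartition.
#'
#' @param gene_alignments Named list of alignment matrices (rows = species).
#' @param model `subst_model` for gene-tree estimation.
#' @param n_reps Bootstrap replicates.
#' @param seed RNG seed (drives all resampling).
#' @param stages 2 = genes then sites (default), 1 = genes only.
#' @param mode Passed to [coalescent_species_tree()].
#' @return list(tree = support-annotated `phylo`, point = the
#'   `species_tree_result`, gene_trees, replicates).
#' @export
multilocus_bootstrap <- function(gene_alignments, model, n_reps = 100L,
                                 seed = 1L, stages = 2L, mode = "auto") {
  stopifnot(n_reps >= 1, stages %in% c(1L, 2L))
  gene_trees <- lapply(gene_alignments, function(a) ml_search(a, model)$tree)
  point <- coalescent_species_tree(gene_trees, mode)
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    pick <- sample.int(length(gene_alignments), replace = TRUE)
    rep_trees <- lapply(pick, function(i) {
      if (stages == 2L) {
        a <- gene_alignments[[i]]
        ml_search(a[, sample.int(ncol(a), replace = TRUE), drop = FALSE],
                  model)$tree
      } else {
        gene_trees[[i]]
      }
    })
    reps[[b]] <- coalescent_species_tree(rep_trees, mode)$tree
  }
  list(tree = annotate_support(point$tree, reps), point = point,
       gene_trees = gene_trees, replicates = reps)
}
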