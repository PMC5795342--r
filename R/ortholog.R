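#' Homolog family container
#'
#' A cluster of sequence records, possibly with several copies per species,
#' optionally carrying the gene tree estimated over its members.
#'
#' @param id Family id.
#' @param members List of [seq_record()]s (>= 2).
#' @param tree Optional `phylo` whose tips match the member labels.
#' @export
homolog_family <- function(id, members, tree = NULL) {
  labels <- vapply(members, record_label, character(1))
  if (anyDuplicated(labels)) stop("duplicate member labels in family ", id)
  if (!is.null(tree) && !setequal(tree$tip.label, labels)) {
    stop("tree leaves differ from member labels in family ", id)
  }
  structure(list(id = id, members = members, tree = tree),
            class = "homolog_family")
}

family_species <- function(family) {
  vapply(family$members, function(m) m$species, character(1))
}

#' Remove all sequences of over-represented species from a family
#'
#' A species contributing more than `max_copies` sequences to one family is
#' most likely contaminated with assembly isoforms, so every sequence of
#' that species is dropped from the family; species at or under the cap are
#' untouched.
#'
#' @param family A [homolog_family()].
#' @param max_copies Per-species copy cap (strictly-greater triggers removal).
#' @return The filtered family (possibly with zero members; the caller
#'   flags empty families for exclusion).
#' @export
drop_overrepresented_species <- function(family, max_copies = 10L) {
  sp <- family_species(family)
  over <- names(which(table(sp) > max_copies))
  if (!length(over)) return(family)
  family$members <- family$members[!sp %in% over]
  if (!is.null(family$tree)) {
    keep <- vapply(family$members, record_label, character(1))
    family$tree <- if (length(keep) >= 2) ape::keep.tip(family$tree, keep) else NULL
  }
  family
}

#' Keep families present in enough species
#'
#' @param families List of [homolog_family()]s.
#' @param n_species_total Number of species in the study.
#' @param fraction Required fraction, converted to a count with
#'   [occupancy_threshold()].
#' @return Subset of `families`.
#' @export
occupancy_filter <- function(families, n_species_total, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  thr <- occupancy_threshold(fraction, n_species_total)
  keep <- vapply(families, function(f) {
    length(unique(family_species(f))) >= thr
  }, logical(1))
  families[keep]
}

#' Prune a homolog gene tree to its maximal one-copy-per-species subtree
#'
#' Every edge of the unrooted gene tree induces two rooted subtrees (one
#' per direction). Among the sides in which no species occurs twice, the
#' winner maximises (distinct species, then leaf count, then the
#' lexicographically smallest sorted leaf-label tuple); all other leaves
#' are pruned. A tree that is already one-copy-per-species is returned
#' unchanged. This is the monophyly-masking step that strips in-paralogs.
#'
#' @param gene_tree Unrooted `phylo`, tips labelled `species.copy`.
#' @return Pruned `phylo`, or `NULL` when no side with >= 2 distinct
#'   species is copy-clean (family discarded; a signal, not an error).
#' @export
prune_to_ortholog <- function(gene_tree) {
  labs <- gene_tree$tip.label
  if (!anyDuplicated(label_species(labs))) return(gene_tree)
  sides <- edge_sides(gene_tree)
  best <- NULL
  best_rank <- NULL
  for (side in sides) {
    sp <- label_species(side)
    if (anyDuplicated(sp) || length(unique(sp)) < 2) next
    rank <- list(nsp = length(unique(sp)), nleaf = length(side),
                 key = paste(sort(side), collapse = "|"))
    if (is.null(best_rank) || rank_better(rank, best_rank)) {
      best <- side
      best_rank <- rank
    }
  }
  if (is.null(best)) return(NULL)
  ape::keep.tip(gene_tree, best)
}

rank_better <- function(a, b) {
  if (a$nsp != b$nsp) return(a$nsp > b$nsp)
  if (a$nleaf != b$nleaf) return(a$nleaf > b$nleaf)
  a$key < b$key
}

# both tip-label sides of every edge of the tree
edge_sides <- function(tree) {
  sets <- node_tip_sets(tree)
  all_tips <- tree$tip.label
  sides <- list()
  for (e in seq_len(nrow(tree$edge))) {
    below <- sets[[tree$edge[e, 2]]]
    sides[[length(sides) + 1L]] <- below
    sides[[length(sides) + 1L]] <- setdiff(all_tips, below)
  }
  unique(Filter(length, sides))
}

#' Filter pruned gene trees down to strict 1-to-1 ortholog groups
#'
#' @param pruned_trees Named list of pruned `phylo` trees (NULLs allowed,
#'   they are skipped).
#' @param min_taxa Minimum number of distinct species (>= 4).
#' @return Character vector of the ids that pass: every present species has
#'   exactly one sequence and the species count reaches `min_taxa`.
#' @export
one_to_one_filter <- function(pruned_trees, min_taxa = 4L) {
  stopifnot(min_taxa >= 4)
  ok <- vapply(names(pruned_trees), function(id) {
    tr <- pruned_trees[[id]]
    if (is.null(tr)) return(FALSE)
    sp <- label_species(tr$tip.label)
    !anyDuplicated(sp) && length(sp) >= min_taxa
  }, logical(1))
  names(pruned_trees)[ok]
}

#' Trim an alignment: gappy columns and poorly conserved flanks
#'
#' A simplified alignment masker. Decisions are taken on the amino-acid
#' alignment: columns whose gap fraction exceeds `max_gap_fraction` are
#' dropped, then leading and trailing columns are trimmed until a run of 3
#' consecutive columns each reaches a majority-residue frequency of at
#' least `min_flank_conservation`. The decision is mapped to the nucleotide
#' twin codon-wise (x3), so the nt column count stays a multiple of 3.
#'
#' @param aa Amino-acid alignment matrix.
#' @param nt Optional codon-level twin (3x the aa columns).
#' @param max_gap_fraction Gap tolerance per column.
#' @param min_flank_conservation Majority-residue frequency for flank runs.
#' @return list(aa, nt, kept): trimmed matrices (possibly 0 columns) and
#'   the retained aa column indices.
#' @export
trim_alignment <- function(aa, nt = NULL, max_gap_fraction = 0.5,
                           min_flank_conservation = 0.85) {
  if (!is.null(nt) && ncol(nt) != 3L * ncol(aa)) {
    stop("nt alignment is not the codon twin of the aa alignment")
  }
  n <- nrow(aa)
  gapfrac <- colMeans(aa == "-" | aa == "X")
  keep1 <- which(gapfrac <= max_gap_fraction)
  cons <- vapply(keep1, function(j) {
    col <- aa[, j]
    col <- col[col != "-" & col != "X"]
    if (!length(col)) return(0)
    max(table(col)) / n
  }, numeric(1))
  good <- cons >= min_flank_conservation
  run3 <- which(good & c(good[-1], FALSE) & c(good[-(1:2)], FALSE, FALSE))
  if (!length(run3)) {
    kept <- integer(0)
  } else {
    first <- run3[1]
    rev_good <- rev(good)
    run3r <- which(rev_good & c(rev_good[-1], FALSE) &
                     c(rev_good[-(1:2)], FALSE, FALSE))
    last <- length(good) - run3r[1] + 1L
    kept <- keep1[first:last]
  }
  out_aa <- aa[, kept, drop = FALSE]
  out_nt <- NULL
  if (!is.null(nt)) {
    nt_cols <- as.vector(vapply(kept, function(j) (3L * (j - 1L) + 1L):(3L * j),
                                integer(3)))
    out_nt <- nt[, nt_cols, drop = FALSE]
  }
  list(aa = out_aa, nt = out_nt, kept = kept)
}

#' Minimum-length filter on a trimmed ortholog group
#'
#' Keeps groups whose trimmed alignments reach 150 nucleotide and 50
#' amino-acid columns (inclusive: 150 nt = 50 aa keeps the two clauses
#' consistent).
#'
#' @param group list with `nt` and `aa` alignment matrices.
#' @param min_nt,min_aa Column thresholds.
#' @return TRUE to keep.
#' @export
length_filter <- function(group, min_nt = 150L, min_aa = 50L) {
  ncol(group$nt) >= min_nt && ncol(group$aa) >= min_aa
}

#' From homolog families to 1-to-1 ortholog groups
#'
#' Runs the full extraction chain on families with per-member nt/aa
#' alignments: copy-number filter, occupancy filter, gene-tree estimation
#' (when absent), paralog pruning, 1-to-1 filter, trimming, length filter.
#' An audit table records every family's fate.
#'
#' @param families Named list; each element needs `id`, `nt`, `aa`
#'   (alignment matrices over `species.copy` rows) and optionally `tree`.
#' @param n_species_total Species count in the study.
#' @param opts Options block (see `default_config()$ortholog`).
#' @param gene_tree_fun Function(alignment matrix) -> `phylo`, used when a
#'   family has no tree yet; default NJ on JC distances.
#' @return list(groups = named list of ortholog groups (species, nt, aa),
#'   audit = data.frame(id, fate)).
#' @export
extract_ortholog_groups <- function(families, n_species_total,
                                    opts = default_config()$ortholog,
                                    gene_tree_fun = NULL) {
  if (is.null(gene_tree_fun)) {
    gene_tree_fun <- function(aln) {
      neighbor_joining(jc_distance_matrix(aln, "aa"))
    }
  }
  thr <- occupancy_threshold(opts$occupancy_fraction, n_species_total)
  fate <- character(0)
  groups <- list()
  for (id in names(families)) {
    fam <- families[[id]]
    labs <- rownames(fam$aa)
    sp <- label_species(labs)
    over <- names(which(table(sp) > opts$max_copies))
    if (length(over)) {
      keep <- !sp %in% over
      fam$aa <- fam$aa[keep, , drop = FALSE]
      fam$nt <- fam$nt[keep, , drop = FALSE]
      if (!is.null(fam$tree) && sum(keep) >= 2) {
        fam$tree <- ape::keep.tip(fam$tree, labs[keep])
      } else fam$tree <- NULL
      labs <- labs[keep]; sp <- sp[keep]
    }
    if (length(labs) < 2) { fate[id] <- "dropped-overrepresented"; next }
    if (length(unique(sp)) < thr) { fate[id] <- "low-occupancy"; next }
    if (is.null(fam$tree)) fam$tree <- gene_tree_fun(fam$aa)
    pruned <- prune_to_ortholog(fam$tree)
    if (is.null(pruned)) { fate[id] <- "no-valid-subtree"; next }
    tips <- pruned$tip.label
    spp <- label_species(tips)
    if (anyDuplicated(spp) || length(spp) < opts$min_taxa) {
      fate[id] <- "not-1-to-1"; next
    }
    tr <- trim_alignment(fam$aa[tips, , drop = FALSE],
                         fam$nt[tips, , drop = FALSE],
                         opts$max_gap_fraction, opts$min_flank_conservation)
    grp <- list(id = id, species = spp, nt = tr$nt, aa = tr$aa)
    rownames(grp$nt) <- spp
    rownames(grp$aa) <- spp
    if (!length_filter(grp, opts$min_nt_length, opts$min_aa_length)) {
      fate[id] <- "too-short"; next
    }
    fate[id] <- "retained"
    groups[[id]] <- grp
  }
  list(groups = groups,
       audit = data.frame(id = names(families),
                          fate = unname(fate[names(families)]),
                          stringsAsFactors = FALSE))
}
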