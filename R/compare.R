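#' Cross-method topology comparison report
#'
#' Compares the four species trees of the method-by-datatype grid
#' (coalescent/concatenation x nucleotide/amino acid). Bipartitions present
#' in some but not all trees are grouped into conflict neighbourhoods
#' (overlapping smaller sides are merged), and each neighbourhood is
#' rendered per tree as the induced rooted subtree over its taxa, with the
#' rest of the tree collapsed — the style of a "site / per-combination
#' topology" conflict table. Congruent inputs give a zero-row report.
#'
#' @param trees Named list of >= 2 `phylo` objects on one leaf set, e.g.
#'   `list(coalescent_nt = ..., coalescent_aa = ..., concat_nt = ...,
#'   concat_aa = ...)`.
#' @return data.frame of class `comparison_report`: columns `site` (A, B,
#'   ...), `taxa`, one topology-string column per input tree, `congruent`.
#' @export
compare_topologies <- function(trees) {
  stopifnot(length(trees) >= 2, !is.null(names(trees)))
  tipsets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(tipsets)) != 1) stop("leaf-set mismatch across trees")
  splits <- lapply(trees, tree_splits)
  all_splits <- unique(unlist(splits))
  in_all <- vapply(all_splits, function(s) {
    all(vapply(splits, function(sp) s %in% sp, logical(1)))
  }, logical(1))
  conflict <- all_splits[!in_all]
  empty <- data.frame(site = character(), taxa = character(),
                      stringsAsFactors = FALSE)
  for (nm in names(trees)) empty[[nm]] <- character()
  empty$congruent <- logical()
  if (!length(conflict)) {
    return(structure(empty, class = c("comparison_report", "data.frame")))
  }
  sides <- lapply(conflict, split_side)
  comp <- merge_overlapping(sides)
  rows <- lapply(seq_along(comp), function(i) {
    taxa <- sort(unique(unlist(sides[comp[[i]]])))
    strs <- vapply(trees, render_site, character(1), site_taxa = taxa)
    c(list(site = LETTERS[((i - 1) %% 26) + 1], taxa = paste(taxa, collapse = ",")),
      as.list(strs), list(congruent = length(unique(strs)) == 1))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  structure(out, class = c("comparison_report", "data.frame"))
}

# union-find style merge of taxon sets that share members
merge_overlapping <- function(sides) {
  n <- length(sides)
  grp <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (length(intersect(sides[[i]], sides[[j]]))) {
        grp[grp == grp[j]] <- grp[i]
      }
    }
  }
  unname(split(seq_len(n), grp))
}

# induced rooted topology string for the site taxa, rooted by (and then
# stripped of) a representative of the collapsed remainder
render_site <- function(tree, site_taxa) {
  others <- setdiff(tree$tip.label, site_taxa)
  if (!length(others)) {
    sub <- ape::keep.tip(tree, site_taxa)
    sub$edge.length <- NULL
    return(write_newick(sub))
  }
  rep_tip <- sort(others)[1]
  sub <- ape::keep.tip(tree, c(site_taxa, rep_tip))
  sub <- ape::root(sub, outgroup = rep_tip, resolve.root = TRUE)
  sub <- ape::drop.tip(sub, rep_tip)
  sub$edge.length <- NULL
  sub$node.label <- NULL
  write_newick(sub)
}

#' @export
print.comparison_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("All topologies congruent: no conflicts.\n")
  } else {
    cat("Inconsistent topologies across methods/datatypes:\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Write the comparison report as TSV
#' @param report A `comparison_report`.
#' @param path Output file.
#' @export
write_comparison_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
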