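#' Parse a Newick string into a tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Integer internal-node
#' labels are kept as bootstrap-style support values in `[0, 100]`; edge
#' lengths must be non-negative.
#'
#' @param text Newick string (single tree, trailing `;`).
#' @return An [ape::phylo] object.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 warning = function(w) NULL, error = function(e) NULL)
  if (is.null(tr)) stop("Newick parse error: ", substr(text, 1, 60))
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative edge length in Newick input")
  }
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    if (any(!is.na(sup) & (sup < 0 | sup > 100))) {
      stop("support values outside [0, 100]")
    }
  }
  tr
}

#' @rdname parse_newick
#' @param tree A `phylo` object.
#' @param digits Branch-length precision.
#' @export
write_newick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

#' Read / write one-tree-per-line Newick samples
#' @param path File path.
#' @export
read_tree_sample <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, parse_newick)
}

#' @rdname read_tree_sample
#' @param trees List of `phylo` objects.
#' @export
write_tree_sample <- function(trees, path) {
  writeLines(vapply(trees, write_newick, character(1)), path)
}

#' Canonical nontrivial bipartitions of an unrooted tree
#'
#' Each internal edge of the unrooted topology defines a split of the leaf
#' set; the canonical key is the smaller side (ties broken lexicographically)
#' sorted and joined with `|`. Used for bootstrap support annotation and for
#' the cross-method comparison report.
#'
#' @param tree `phylo` object.
#' @return Character vector of split keys (possibly empty).
#' @export
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- sort(tree$tip.label)
  n <- length(tips)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    side <- sort(labs[idx])
    if (length(side) <= 1L || length(side) >= n - 1L) return(NA_character_)
    other <- setdiff(tips, side)
    canon <- if (length(side) < length(other)) side
             else if (length(side) > length(other)) other
             else min2(side, other)
    paste(canon, collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

min2 <- function(a, b) {
  if (paste(a, collapse = "|") <= paste(b, collapse = "|")) a else b
}

split_side <- function(key) strsplit(key, "|", fixed = TRUE)[[1]]
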