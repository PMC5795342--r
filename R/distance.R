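#' Jukes-Cantor distance matrix
#'
#' Pairwise distances d = -(3/4) ln(1 - (4/3) p) for nucleotides, with the
#' 19/20-state analogue for amino acids; `p` is the mismatch proportion over
#' pairwise-complete (both unambiguous) columns. Saturated pairs, where the
#' logarithm's argument is non-positive, are set to `d_max`.
#'
#' @param alignment Character matrix (rows = taxa).
#' @param alphabet `"nt"` or `"aa"`; guessed when `NULL`.
#' @param d_max Cap for saturated pairs.
#' @return Symmetric distance matrix with taxa dimnames.
#' @export
jc_distance_matrix <- function(alignment, alphabet = NULL, d_max = 5.0) {
  if (is.null(alphabet)) {
    alphabet <- guess_alphabet(paste(alignment, collapse = ""))
  }
  states <- if (alphabet == "nt") NT_RESIDUES else AA_RESIDUES
  k <- length(states)
  n <- nrow(alignment)
  if (n < 2) stop("need at least 2 taxa")
  idx <- match(alignment, states)
  dim(idx) <- dim(alignment)
  D <- matrix(0, n, n, dimnames = list(rownames(alignment), rownames(alignment)))
  b <- (k - 1) / k
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
      m <- sum(ok)
      if (m == 0) stop("no comparable columns for pair ",
                       rownames(alignment)[i], " / ", rownames(alignment)[j])
      p <- sum(idx[i, ok] != idx[j, ok]) / m
      arg <- 1 - p / b
      D[i, j] <- D[j, i] <- if (arg <= 0) d_max else min(-b * log(arg), d_max)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via [ape::nj()]); negative estimated branch
#' lengths are clipped to a small positive value so the result is usable as
#' a maximum-likelihood start tree.
#'
#' @param dist Square symmetric non-negative matrix with dimnames.
#' @return Unrooted `phylo`.
#' @export
neighbor_joining <- function(dist) {
  if (anyNA(dist)) stop("NaN/NA in distance matrix")
  stopifnot(isSymmetric(unname(dist)), all(dist >= 0))
  if (nrow(dist) == 3L) {
    # unique unrooted 3-taxon tree; solve the three pendant lengths
    l <- rownames(dist)
    x <- (dist[1, 2] + dist[1, 3] - dist[2, 3]) / 2
    y <- (dist[1, 2] + dist[2, 3] - dist[1, 3]) / 2
    z <- (dist[1, 3] + dist[2, 3] - dist[1, 2]) / 2
    return(parse_newick(sprintf("(%s:%g,%s:%g,%s:%g);",
                                l[1], max(x, 0), l[2], max(y, 0), l[3], max(z, 0))))
  }
  tr <- ape::nj(stats::as.dist(dist))
  tr$edge.length[tr$edge.length < 0] <- 1e-8
  tr
}

#' Robinson-Foulds distance between two unrooted trees
#'
#' Count of nontrivial bipartitions present in exactly one of the trees.
#'
#' @param t1,t2 `phylo` objects over the same leaf set.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("leaf-set mismatch between trees")
  }
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)))
}
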