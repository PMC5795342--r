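#' Markov clustering of a weighted similarity graph
#'
#' Classic MCL: self-loops are added (weight = maximum incident weight per
#' node, the conventional regularisation), columns are normalised to a
#' stochastic matrix, then expansion (matrix self-product) and inflation
#' (entrywise power `inflation`, column renormalisation) alternate, pruning
#' entries below `prune_threshold`, until the largest column change falls
#' below `tol`. Clusters are read off the limit matrix attractor-wise: two
#' nodes share a family iff some attractor row has positive mass on both.
#'
#' @param edges data.frame(a, b, weight) undirected edge list (weights > 0,
#'   no self-loops), or a square weight matrix with dimnames.
#' @param inflation Inflation exponent (> 1); 2 is the usual default.
#' @param min_weight Edges below this weight are dropped before clustering
#'   (the `gq`-style pre-filter); use 0 to keep everything.
#' @param prune_threshold Entries below this are zeroed each iteration.
#' @param max_iter Iteration cap; non-convergence warns and clusters the
#'   current matrix.
#' @param tol Convergence tolerance on the max entrywise change.
#' @return Named list: family id (`fam0001`, ...) -> member ids. Every node
#'   appears in exactly one family; singletons get their own family.
#' @export
mcl_cluster <- function(edges, inflation = 2.0, min_weight = 0,
                        prune_threshold = 1e-5, max_iter = 100L, tol = 1e-8) {
  stopifnot(inflation > 1)
  if (is.matrix(edges)) {
    M <- edges
    nodes <- rownames(M)
  } else {
    if (!nrow(edges)) stop("empty graph")
    if (any(edges$weight <= 0) || any(!is.finite(edges$weight))) {
      stop("edge weights must be finite and positive")
    }
    keep <- edges$weight >= min_weight
    dropped_nodes <- unique(c(edges$a, edges$b))
    edges <- edges[keep, , drop = FALSE]
    nodes <- sort(dropped_nodes)  # filtered-out nodes stay as singletons
    n <- length(nodes)
    M <- matrix(0, n, n, dimnames = list(nodes, nodes))
    if (nrow(edges)) {
      ia <- match(edges$a, nodes); ib <- match(edges$b, nodes)
      if (any(ia == ib)) stop("self-loop in input edge list")
      if (any(edges$weight <= 0) || any(!is.finite(edges$weight))) {
        stop("edge weights must be finite and positive")
      }
      M[cbind(ia, ib)] <- edges$weight
      M[cbind(ib, ia)] <- edges$weight
    }
  }
  n <- nrow(M)
  loop <- apply(M, 2, max)
  loop[loop == 0] <- 1
  diag(M) <- loop
  M <- normalize_cols(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                       # expansion
    M2 <- M2^inflation                  # inflation
    M2[M2 < prune_threshold] <- 0
    M2 <- normalize_cols(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter,
            " iterations; clustering the current matrix")
  }
  interpret_mcl(M, rownames(M))
}

normalize_cols <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1
  sweep(M, 2, cs, "/")
}

# attractor-based interpretation: attractors are nodes with positive
# diagonal mass; nodes i, j share a cluster iff some attractor row has
# positive mass on both columns. Overlapping attractor systems are merged.
interpret_mcl <- function(M, nodes) {
  eps <- 1e-9
  attract <- which(diag(M) > eps)
  if (!length(attract)) attract <- seq_along(nodes)
  member <- lapply(attract, function(a) which(M[a, ] > eps))
  assign <- rep(NA_integer_, length(nodes))
  cl <- 0L
  for (i in seq_along(member)) {
    hit <- unique(stats::na.omit(assign[member[[i]]]))
    if (length(hit)) {
      tgt <- min(hit)
      assign[member[[i]]] <- tgt
      assign[assign %in% hit] <- tgt
    } else {
      cl <- cl + 1L
      assign[member[[i]]] <- cl
    }
  }
  for (i in which(is.na(assign))) {     # isolated nodes -> singleton families
    cl <- cl + 1L
    assign[i] <- cl
  }
  fams <- split(nodes, assign)
  fams <- fams[order(vapply(fams, `[`, character(1), 1))]
  names(fams) <- sprintf("fam%04d", seq_along(fams))
  fams
}

#' Write MCL families in the native one-family-per-line dialect
#' @param families Named list of member-id vectors.
#' @param path Output file.
#' @export
write_families <- function(families, path) {
  writeLines(vapply(families, paste, character(1), collapse = "\t"), path)
}
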