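#' Mk transition probability
#'
#' The symmetric k-state, single-rate Markov model for unordered discrete
#' characters. From the eigendecomposition of the equal-rates generator:
#' `P(same) = 1/k + ((k-1)/k) exp(-k q t)` and
#' `P(different, specific) = 1/k - (1/k) exp(-k q t)`.
#'
#' @param i,j State indices (only their equality matters).
#' @param q Rate parameter (>= 0).
#' @param t Elapsed branch length (>= 0).
#' @param k Number of states (>= 2).
#' @return Transition probability.
#' @export
mk_transition_prob <- function(i, j, q, t, k) {
  stopifnot(q >= 0, t >= 0, k >= 2)
  e <- exp(-k * q * t)
  ifelse(i == j, 1 / k + (k - 1) / k * e, 1 / k - e / k)
}

mk_matrix <- function(q, t, k) {
  e <- exp(-k * q * t)
  off <- (1 - e) / k
  M <- matrix(off, k, k)
  diag(M) <- 1 / k + (k - 1) / k * e
  M
}

# character input: named integer vector (1..k) or named character vector of
# state names resolved against `states`; NA = missing
encode_states <- function(characters, k, states = NULL) {
  if (is.character(characters)) {
    if (is.null(states)) stop("state names require a state vocabulary")
    idx <- match(characters, states)
    if (any(is.na(idx) & !is.na(characters))) {
      stop("unknown state name: ",
           paste(setdiff(characters, states), collapse = ", "))
    }
    stats::setNames(idx, names(characters))
  } else {
    if (any(characters > k | characters < 1, na.rm = TRUE)) {
      stop("state index outside 1..k")
    }
    characters
  }
}

# up-pass partial likelihoods; returns list of k x 1 vectors per node
mk_up_partials <- function(tree, states, q, k) {
  ntip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  partial <- rep(list(rep(1, k)), ntip + tree$Nnode)
  has <- logical(ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (ch <= ntip) {
      s <- states[tree$tip.label[ch]]
      L <- rep(1, k)
      if (!is.na(s)) { L <- rep(0, k); L[s] <- 1 }
    } else L <- partial[[ch]]
    up <- mk_matrix(q, tree$edge.length[e], k) %*% L
    partial[[par]] <- if (has[par]) partial[[par]] * up else up
    has[par] <- TRUE
  }
  partial
}

#' Mk log-likelihood of a character on a rooted tree
#'
#' Felsenstein pruning with a uniform 1/k root prior; missing tips
#' contribute all-ones partials.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param characters Named state vector covering the tips (indices `1..k`,
#'   or names resolved against `states`). A matrix (species x characters)
#'   sums the per-character log-likelihoods (joint single-rate fit).
#' @param q Rate parameter.
#' @param k Number of states.
#' @param states Optional state-name vocabulary.
#' @return Log-likelihood.
#' @export
mk_log_likelihood <- function(tree, characters, q, k = 7L, states = NULL) {
  if (is.matrix(characters)) {
    return(sum(apply(characters, 2, function(col)
      mk_log_likelihood(tree, stats::setNames(col, rownames(characters)),
                        q, k, states))))
  }
  st <- encode_states(characters, k, states)
  ntip <- length(tree$tip.label)
  up <- mk_up_partials(tree, st, q, k)
  root <- up[[ntip + 1L]]
  log(sum(root / k))
}

#' Maximum-likelihood estimate of the Mk rate
#'
#' Deterministic 1-D bounded maximisation (Brent via [stats::optimize()])
#' of [mk_log_likelihood()] over `q`. A character with no variation drives
#' the estimate to the lower bound.
#'
#' @param tree Rooted `phylo`.
#' @param characters As in [mk_log_likelihood()].
#' @param k Number of states.
#' @param q_max Upper bound of the search bracket.
#' @param states Optional state vocabulary.
#' @return Fitted rate `q`.
#' @export
fit_mk_rate <- function(tree, characters, k = 7L, q_max = 100,
                        states = NULL) {
  f <- function(q) mk_log_likelihood(tree, characters, q, k, states)
  # the surface flattens for large q (saturation), where golden-section
  # search alone can stall: bracket the maximum on a log-spaced grid first
  grid <- exp(seq(log(1e-8), log(q_max), length.out = 25))
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(f, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-8)
  if (vals[1] >= opt$objective) return(1e-8)
  opt$maximum
}

#' Marginal ancestral state probabilities under the Mk model
#'
#' Up-down algorithm: the up (pruning) pass collects tip information below
#' each node, the down pass propagates information from the rest of the
#' tree; the marginal posterior of a node's state is the normalised
#' product (uniform root prior). These are the "proportional likelihood"
#' values of likelihood-based character tracing.
#'
#' @inheritParams mk_log_likelihood
#' @return Matrix (internal nodes x k) of posterior probabilities; row
#'   names are node numbers, rows sum to 1.
#' @export
marginal_ancestral_states <- function(tree, characters, q, k = 7L,
                                      states = NULL) {
  st <- encode_states(characters, k, states)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  up <- mk_up_partials(tree, st, q, k)
  post <- stats::reorder(tree, "postorder")
  # per-edge upward message: P(t_e) %*% up[child]
  msg <- vector("list", nrow(post$edge))
  for (e in seq_len(nrow(post$edge))) {
    ch <- post$edge[e, 2]
    L <- if (ch <= ntip) {
      s <- st[post$tip.label[ch]]
      v <- rep(1, k); if (!is.na(s)) { v <- rep(0, k); v[s] <- 1 }
      v
    } else up[[ch]]
    msg[[e]] <- as.numeric(mk_matrix(q, post$edge.length[e], k) %*% L)
  }
  down <- vector("list", ntip + nnode)
  down[[ntip + 1L]] <- rep(1 / k, k)
  for (e in rev(seq_len(nrow(post$edge)))) {   # preorder
    par <- post$edge[e, 1]; ch <- post$edge[e, 2]
    if (ch <= ntip) next
    sibs <- which(post$edge[, 1] == par & post$edge[, 2] != ch)
    out <- down[[par]]
    for (s in sibs) out <- out * msg[[s]]
    down[[ch]] <- as.numeric(mk_matrix(q, post$edge.length[e], k) %*% out)
  }
  res <- matrix(NA_real_, nnode, k)
  rownames(res) <- as.character(ntip + seq_len(nnode))
  if (!is.null(states)) colnames(res) <- states[seq_len(k)]
  for (nd in seq_len(nnode)) {
    v <- up[[ntip + nd]] * down[[ntip + nd]]
    res[nd, ] <- v / sum(v)
  }
  res
}

#' Average ancestral reconstructions across a tree sample
#'
#' For each tree the Mk rate is fitted per character and marginal node
#' probabilities computed; internal nodes are indexed by their clade
#' (leaf-species set) so reconstructions can be averaged across trees.
#' Clades absent from a tree are skipped; the count column records how
#' many trees contain each clade.
#'
#' @param trees List of rooted `phylo` sharing a leaf set.
#' @param characters Named state vector (or matrix species x characters;
#'   the first column is traced and the rest contribute nothing here).
#' @param k Number of states.
#' @param states State-name vocabulary (default the 7 annulus states).
#' @return data.frame of class `ancestral_state_table`: `clade`, `count`,
#'   one probability column per state, `state` (argmax name).
#' @export
trace_over_trees <- function(trees, characters, k = 7L,
                             states = annulus_states[seq_len(k)]) {
  if (!length(trees)) stop("empty tree list")
  if (is.matrix(characters)) {
    characters <- stats::setNames(characters[, 1], rownames(characters))
  }
  acc <- list()
  cnt <- list()
  for (tr in trees) {
    q <- fit_mk_rate(tr, characters, k, states = states)
    marg <- marginal_ancestral_states(tr, characters, q, k, states)
    tipsets <- node_tip_sets(tr)
    ntip <- length(tr$tip.label)
    for (nd in seq_len(tr$Nnode)) {
      key <- paste(sort(tipsets[[ntip + nd]]), collapse = ",")
      if (is.null(acc[[key]])) { acc[[key]] <- rep(0, k); cnt[[key]] <- 0L }
      acc[[key]] <- acc[[key]] + marg[nd, ]
      cnt[[key]] <- cnt[[key]] + 1L
    }
  }
  keys <- names(acc)
  probs <- do.call(rbind, lapply(keys, function(kk) acc[[kk]] / cnt[[kk]]))
  colnames(probs) <- states
  out <- data.frame(clade = keys, count = unlist(cnt[keys]),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(probs))
  out$state <- states[max.col(probs, ties.method = "first")]
  rownames(out) <- NULL
  structure(out, class = c("ancestral_state_table", "data.frame"))
}

#' Write an ancestral-state table as TSV
#' @param table An `ancestral_state_table`.
#' @param path Output file.
#' @export
write_ancestral_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
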