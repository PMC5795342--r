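#' Encode an alignment as state indices with pattern compression
#'
#' Gaps and ambiguity characters become `NA` (missing: partial likelihood 1
#' for every state). Identical site patterns are collapsed and weighted,
#' which is what makes repeated likelihood evaluation during tree search
#' affordable.
#'
#' @param alignment Character matrix (rows = taxa).
#' @param model `subst_model` giving the state ordering.
#' @return list(patterns = integer matrix taxa x npattern, weights,
#'   constant_state = index of the shared state for constant patterns else NA).
#' @export
encode_alignment <- function(alignment, model) {
  idx <- match(alignment, model$states)
  dim(idx) <- dim(alignment)
  rownames(idx) <- rownames(alignment)
  key <- apply(idx, 2, paste, collapse = ",")
  first <- !duplicated(key)
  pat <- idx[, first, drop = FALSE]
  w <- as.numeric(table(factor(key, levels = key[first])))
  const <- apply(pat, 2, function(col) {
    s <- unique(col[!is.na(col)])
    if (length(s) == 1L) s else NA_integer_
  })
  list(patterns = pat, weights = w, constant_state = const)
}

# Per-pattern site likelihoods for one rate category.
# Returns list(lik = numeric npattern, log_scale = numeric npattern).
prune_patterns <- function(tree, pat, model, rate) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  npat <- ncol(pat)
  k <- model$k
  tree <- stats::reorder(tree, "postorder")
  ord <- match(tree$tip.label, rownames(pat))
  if (anyNA(ord)) stop("tree tips missing from alignment: ",
                       paste(tree$tip.label[is.na(ord)], collapse = ", "))
  partial <- vector("list", ntip + nnode)
  logscale <- matrix(0, 1, npat)
  has <- logical(ntip + nnode)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (ch <= ntip) {
      L <- matrix(1, k, npat)
      st <- pat[ord[ch], ]
      obs <- !is.na(st)
      if (any(obs)) {
        L[, obs] <- 0
        L[cbind(st[obs], which(obs))] <- 1
      }
    } else {
      L <- partial[[ch]]
    }
    P <- transition_matrix(model, tree$edge.length[e] * rate)
    up <- P %*% L
    if (!has[par]) { partial[[par]] <- up; has[par] <- TRUE }
    else partial[[par]] <- partial[[par]] * up
  }
  root <- ntip + 1L
  M <- partial[[root]]
  mx <- apply(M, 2, max)
  mx[mx <= 0] <- 1
  lik <- as.numeric(model$freqs %*% sweep(M, 2, mx, "/"))
  list(lik = lik, log_scale = log(mx))
}

#' Felsenstein-pruning log-likelihood of a tree
#'
#' Sums site log-likelihoods under the model's discrete-gamma mixture (and
#' invariant-site class when `p_inv > 0`), with gaps treated as missing
#' data. The root placement is irrelevant for these reversible models
#' (pulley principle), so rooted and unrooted trees give identical values.
#'
#' @param tree `phylo`; leaves must appear in the alignment, lengths >= 0.
#' @param alignment Character matrix, or a pre-encoded object from
#'   [encode_alignment()].
#' @param model A [substitution_model()].
#' @return Log-likelihood (single numeric).
#' @export
log_likelihood <- function(tree, alignment, model) {
  enc <- if (is.list(alignment) && !is.null(alignment$patterns)) alignment
         else encode_alignment(alignment, model)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  pat <- enc$patterns[tree$tip.label, , drop = FALSE]
  rates <- category_rates(model)
  ncat <- length(rates)
  lik <- 0
  # all categories share the scaling of the first so they can be averaged
  ls0 <- NULL
  for (r in rates) {
    pr <- prune_patterns(tree, pat, model, r)
    if (is.null(ls0)) {
      ls0 <- pr$log_scale
      lik <- pr$lik / ncat
    } else {
      lik <- lik + exp(pr$log_scale - ls0) * pr$lik / ncat
    }
  }
  site_log <- log(lik) + ls0
  if (model$p_inv > 0) {
    const <- enc$constant_state
    pinv_lik <- ifelse(is.na(const), 0, model$freqs[ifelse(is.na(const), 1, const)])
    site_log <- log((1 - model$p_inv) * exp(site_log) + model$p_inv * pinv_lik)
  }
  sum(enc$weights * site_log)
}
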