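#' Substitution models for the likelihood engine
#'
#' Time-reversible models over nucleotides (`JC69`, `GTR`) or amino acids
#' (`POISSON`, `EMPIRICAL`). The instantaneous rate matrix is built from
#' symmetric exchangeabilities and stationary frequencies, normalised to a
#' mean rate of 1 substitution per site per unit branch length. Among-site
#' rate variation uses the discrete-gamma approximation with `gamma_categories`
#' equiprobable categories (category means), optionally mixed with a
#' proportion `p_inv` of invariant sites.
#'
#' @param kind One of `"JC69"`, `"GTR"`, `"POISSON"`, `"EMPIRICAL"`.
#' @param exchangeabilities For GTR: 6 rates in the order AC, AG, AT, CG,
#'   CT, GT. For EMPIRICAL: ignored (the bundled table is used).
#' @param freqs Stationary frequencies (length 4 or 20); for EMPIRICAL,
#'   `NULL` means the bundled frequencies, or supply empirical ("+F")
#'   frequencies estimated from the data with [empirical_freqs()].
#' @param alpha Gamma shape; used when `gamma_categories > 1`.
#' @param gamma_categories Number of discrete gamma categories (1 = none).
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @return Object of class `subst_model` with the eigendecomposition cached.
#' @export
substitution_model <- function(kind = c("JC69", "GTR", "POISSON", "EMPIRICAL"),
                               exchangeabilities = NULL, freqs = NULL,
                               alpha = 1.0, gamma_categories = 1L,
                               p_inv = 0.0) {
  kind <- match.arg(kind)
  stopifnot(alpha > 0, gamma_categories >= 1, p_inv >= 0, p_inv < 1)
  if (kind %in% c("JC69", "GTR")) {
    states <- NT_RESIDUES
    miss <- c("-", "N")
    if (kind == "JC69") {
      ex <- rep(1, 6)
      freqs <- rep(0.25, 4)
    } else {
      ex <- exchangeabilities %||% rep(1, 6)
      freqs <- freqs %||% rep(0.25, 4)
      stopifnot(length(ex) == 6, length(freqs) == 4)
    }
  } else {
    states <- AA_RESIDUES
    miss <- c("-", "X")
    if (kind == "POISSON") {
      ex <- rep(1, 190)
      freqs <- freqs %||% rep(0.05, 20)
    } else {
      jtt <- load_jtt_table()
      ex <- jtt$exchangeabilities
      freqs <- freqs %||% jtt$freqs
    }
    stopifnot(length(ex) == 190, length(freqs) == 20)
  }
  if (abs(sum(freqs) - 1) > 1e-8) stop("frequencies must sum to 1")
  freqs <- freqs / sum(freqs)
  k <- length(states)
  R <- matrix(0, k, k)
  R[lower.tri(R)] <- ex
  R <- R + t(R)
  Q <- R %*% diag(freqs)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  # symmetrised eigendecomposition (reversibility): B = D^1/2 Q D^-1/2
  d <- sqrt(freqs)
  B <- diag(d) %*% Q %*% diag(1 / d)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(
    kind = kind, states = states, missing_chars = miss, k = k,
    freqs = freqs, Q = Q,
    eig_left = diag(1 / d) %*% eig$vectors,
    eig_right = t(eig$vectors) %*% diag(d),
    eig_values = eig$values,
    alpha = alpha, gamma_categories = as.integer(gamma_categories),
    p_inv = p_inv
  ), class = "subst_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_jtt_table <- function() {
  exf <- system.file("extdata", "jtt_model.tsv", package = "fernbone",
                     mustWork = TRUE)
  frf <- system.file("extdata", "jtt_freqs.tsv", package = "fernbone",
                     mustWork = TRUE)
  ex <- utils::read.table(exf, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  fr <- utils::read.table(frf, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(nrow(ex) == 190, nrow(fr) == 20,
            identical(fr$aa, AA_RESIDUES))
  # rows are the lower triangle in column-major order over the fixed
  # amino-acid ordering, matching how the rate matrix is filled
  list(exchangeabilities = ex$rate,
       freqs = stats::setNames(fr$freq, fr$aa))
}

#' Transition probability matrix P(t) for one rate category
#' @param model A `subst_model`.
#' @param t Branch length (expected substitutions/site), `t >= 0`.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(t >= 0)
  P <- model$eig_left %*% (exp(model$eig_values * t) * model$eig_right)
  P[P < 0] <- 0
  P
}

#' Discrete-gamma category rates (category means)
#'
#' Mean-of-category discretisation of the gamma(alpha, alpha) rate
#' distribution into `ncat` equiprobable categories.
#' @param alpha Shape parameter.
#' @param ncat Number of categories.
#' @export
discrete_gamma_rates <- function(alpha, ncat) {
  if (ncat == 1L) return(1)
  b <- stats::qgamma(seq_len(ncat - 1) / ncat, shape = alpha, rate = alpha)
  p <- stats::pgamma(c(0, b, Inf), shape = alpha + 1, rate = alpha)
  ncat * diff(p)
}

category_rates <- function(model) {
  r <- discrete_gamma_rates(model$alpha, model$gamma_categories)
  if (model$p_inv > 0) r <- r / (1 - model$p_inv)  # keep mean rate 1 overall
  r
}

#' Empirical residue frequencies of an alignment ("+F")
#' @param alignment Character matrix (rows = taxa).
#' @param alphabet `"nt"` or `"aa"`.
#' @export
empirical_freqs <- function(alignment, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  states <- if (alphabet == "nt") NT_RESIDUES else AA_RESIDUES
  counts <- table(factor(alignment, levels = states))
  n <- sum(counts)
  if (n == 0) stop("alignment has no unambiguous residues")
  # light pseudocount so no state has probability exactly zero
  as.numeric(counts + 0.5) / (n + 0.5 * length(states))
}
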