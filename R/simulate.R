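#' Simulate a Yule species tree
#'
#' Forward pure-birth process: each extant lineage splits at rate
#' `yule_rate`; the process is stopped once `n_species` lineages exist and
#' the present is placed one further (exponential) waiting time later, so
#' pendant edges have positive length. The tree is rooted, binary and
#' ultrametric, with leaves `S1..Sn`. Branch lengths are interpreted as
#' coalescent units by the multispecies-coalescent stage.
#'
#' @param n_species Number of tips (>= 4).
#' @param yule_rate Speciation rate per lineage per unit time.
#' @param seed RNG seed.
#' @return Ultrametric rooted `phylo`.
#' @export
sim_species_tree <- function(n_species, yule_rate = 1.0, seed = NULL) {
  stopifnot(n_species >= 4, yule_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  # node bookkeeping: children lists + birth times
  children <- list(integer(0))
  birth <- 0
  active <- 1L
  t <- 0
  nxt <- 2L
  while (length(active) < n_species) {
    t <- t + stats::rexp(1, yule_rate * length(active))
    who <- active[sample.int(length(active), 1L)]
    kids <- c(nxt, nxt + 1L)
    children[[who]] <- kids
    children[[nxt]] <- integer(0)
    children[[nxt + 1L]] <- integer(0)
    birth[kids] <- t
    active <- c(setdiff(active, who), kids)
    nxt <- nxt + 2L
  }
  t_end <- t + stats::rexp(1, yule_rate * n_species)
  tip_counter <- 0L
  nwk <- function(node) {
    kids <- children[[node]]
    end <- if (length(kids)) birth[kids[1]] else t_end
    len <- end - birth[node]
    if (!length(kids)) {
      tip_counter <<- tip_counter + 1L
      sprintf("S%d:%.10f", tip_counter, len)
    } else {
      sprintf("(%s,%s):%.10f", nwk(kids[1]), nwk(kids[2]), len)
    }
  }
  root_kids <- children[[1L]]
  txt <- sprintf("(%s,%s);", nwk(root_kids[1]), nwk(root_kids[2]))
  parse_newick(txt)
}

#' Lineage count of a Yule process run to a fixed time
#'
#' Shares the birth-process primitive with [sim_species_tree()]; used to
#' check the exponential-growth expectation E[N(t)] = e^(rate * t).
#' @param yule_rate Speciation rate.
#' @param t_max Stopping time.
#' @param seed RNG seed.
#' @export
yule_lineage_count <- function(yule_rate, t_max, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 1L
  t <- stats::rexp(1, yule_rate)
  while (t <= t_max) {
    n <- n + 1L
    t <- t + stats::rexp(1, yule_rate * n)
  }
  n
}

# heights (time above the present) of every node; requires ultrametric tree
node_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Simulate gene trees under the multispecies coalescent
#'
#' One haploid gene lineage is sampled per species tip; lineages coalesce
#' backwards in time within species-tree branches at rate `choose(j, 2)`
#' per coalescent unit, and are censored at speciation nodes (incomplete
#' lineage sorting), with free coalescence above the root. Gene-tree
#' topologies therefore may disagree with the species tree.
#'
#' @param species_tree Rooted ultrametric `phylo`, lengths in coalescent units.
#' @param n_genes Number of independent gene trees.
#' @param seed RNG seed.
#' @return List of rooted `phylo` gene trees, tips labelled like the species.
#' @export
sim_gene_trees_msc <- function(species_tree, n_genes, seed = NULL) {
  if (is.null(species_tree$edge.length)) {
    stop("species tree must carry coalescent-unit branch lengths")
  }
  if (!is.null(seed)) set.seed(seed)
  h <- node_heights(species_tree)
  ntip <- length(species_tree$tip.label)
  root <- ntip + 1L
  kids <- split(species_tree$edge[, 2], species_tree$edge[, 1])
  lapply(seq_len(n_genes), function(g) one_msc_gene(species_tree, h, kids, root, ntip))
}

one_msc_gene <- function(sptree, h, kids, root, ntip) {
  # each gene lineage is a growing newick fragment with its current height
  coalesce_interval <- function(lin, t0, t1) {
    while (length(lin$lab) > 1) {
      j <- length(lin$lab)
      t_next <- t0 + stats::rexp(1, choose(j, 2))
      if (t_next > t1) break
      pair <- sample.int(j, 2)
      a <- pair[1]; b <- pair[2]
      nw <- sprintf("(%s:%.10f,%s:%.10f)",
                    lin$lab[a], t_next - lin$h[a],
                    lin$lab[b], t_next - lin$h[b])
      lin$lab <- c(lin$lab[-c(a, b)], nw)
      lin$h <- c(lin$h[-c(a, b)], t_next)
      t0 <- t_next
    }
    lin
  }
  walk <- function(node) {
    if (node <= ntip) {
      lin <- list(lab = sptree$tip.label[node], h = 0)
    } else {
      parts <- lapply(kids[[as.character(node)]], walk)
      lin <- list(lab = unlist(lapply(parts, `[[`, "lab")),
                  h = unlist(lapply(parts, `[[`, "h")))
    }
    t1 <- if (node == root) Inf else h[node_parent(sptree, node)]
    coalesce_interval(lin, h[node], t1)
  }
  res <- walk(root)
  parse_newick(paste0(res$lab[1], ";"))
}

node_parent <- function(tree, node) tree$edge[tree$edge[, 2] == node, 1]

# ---- nested-list tree representation for the duplication/loss process ----

phylo_to_nested <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  build <- function(node, len) {
    ke <- kids[[as.character(node)]]
    if (is.null(ke)) {
      list(label = tree$tip.label[node], length = len, children = NULL)
    } else {
      list(label = NULL, length = len,
           children = lapply(ke, function(e)
             build(tree$edge[e, 2], tree$edge.length[e])))
    }
  }
  build(ntip + 1L, 0)
}

nested_to_phylo <- function(nested) {
  nwk <- function(nd) {
    if (is.null(nd$children)) {
      sprintf("%s:%.10f", nd$label, nd$length)
    } else if (length(nd$children) == 1L) {
      # splice degree-2 node: absorb its length into the child
      ch <- nd$children[[1]]
      ch$length <- ch$length + nd$length
      nwk(ch)
    } else {
      sprintf("(%s):%.10f",
              paste(vapply(nd$children, nwk, character(1)), collapse = ","),
              nd$length)
    }
  }
  top <- nested
  top$length <- 0
  while (!is.null(top$children) && length(top$children) == 1L) {
    top <- top$children[[1]]
    top$length <- 0
  }
  if (is.null(top$children)) stop("empty gene: all leaves lost")
  parse_newick(paste0(nwk(top), ";"))
}

#' Graft gene duplications and losses onto a gene tree
#'
#' A linear birth-death process runs down every lineage of the gene tree:
#' duplications copy the subtree below the event point in place (the two
#' copies then evolve, duplicate and get lost independently), losses prune
#' the lineage. Surviving leaves are relabelled `species.copy` with copies
#' numbered per species in traversal order; degree-2 nodes left by losses
#' are suppressed, so the result is binary again.
#'
#' @param gene_tree Rooted `phylo` with species-labelled tips.
#' @param dup_rate,loss_rate Events per lineage per unit branch length.
#' @param seed RNG seed.
#' @return Relabelled `phylo`; errors with "empty gene" if nothing survives.
#' @export
graft_duplications_losses <- function(gene_tree, dup_rate = 0, loss_rate = 0,
                                      seed = NULL) {
  stopifnot(dup_rate >= 0, loss_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  nested <- phylo_to_nested(gene_tree)
  total <- dup_rate + loss_rate
  evolve <- function(nd, len) {
    # nd: subtree to place below a branch of remaining length len
    if (total > 0) {
      t_ev <- stats::rexp(1, total)
      if (t_ev < len) {
        if (stats::runif(1) < loss_rate / total) return(NULL)
        a <- evolve(nd, len - t_ev)
        b <- evolve(nd, len - t_ev)
        if (is.null(a) && is.null(b)) return(NULL)
        if (is.null(a)) return(add_len(b, t_ev))
        if (is.null(b)) return(add_len(a, t_ev))
        return(list(label = NULL, length = t_ev, children = list(a, b)))
      }
    }
    # no event on this branch: recurse into children
    if (is.null(nd$children)) {
      return(list(label = nd$label, length = len, children = NULL))
    }
    out <- Filter(Negate(is.null),
                  lapply(nd$children, function(ch) evolve(ch, ch$length)))
    if (!length(out)) return(NULL)
    list(label = NULL, length = len, children = out)
  }
  res <- evolve(nested, 0)
  if (is.null(res)) stop("empty gene: all leaves lost")
  tr <- nested_to_phylo(res)
  if (length(tr$tip.label) < 2) stop("empty gene: fewer than 2 leaves survive")
  copies <- stats::ave(seq_along(tr$tip.label), tr$tip.label, FUN = seq_along)
  tr$tip.label <- paste(tr$tip.label, copies, sep = ".")
  tr
}

add_len <- function(nd, extra) { nd$length <- nd$length + extra; nd }

#' Evolve codon sequences along a tree
#'
#' Sites evolve independently under the nucleotide model, codon by codon:
#' any substitution draw that turns a codon into a stop (TAA/TAG/TGA) is
#' redrawn, and root codons are drawn stop-free from the stationary
#' frequencies, so every sequence translates cleanly. No indels are
#' simulated, so the output is already aligned.
#'
#' @param tree `phylo`, branch lengths in substitutions/site.
#' @param model Nucleotide [substitution_model()].
#' @param n_codons Number of codons (alignment = `3 * n_codons` nt columns).
#' @param seed RNG seed.
#' @return list(nt, aa): character alignment matrices (rows = tip labels).
#' @export
evolve_sequences <- function(tree, model, n_codons, seed = NULL) {
  stopifnot(model$k == 4, n_codons >= 1)
  if (!is.null(seed)) set.seed(seed)
  nsite <- 3L * n_codons
  ntip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  # preorder: reverse of postorder edge order
  eord <- rev(seq_len(nrow(tree$edge)))
  seqs <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  seqs[[root]] <- draw_root_codons(model, n_codons)
  for (e in eord) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    P <- transition_matrix(model, tree$edge.length[e])
    seqs[[ch]] <- mutate_codons(seqs[[par]], P, n_codons)
  }
  nt <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(nt) <- tree$tip.label
  nt_chr <- matrix(NT_RESIDUES[nt], nrow = ntip,
                   dimnames = list(tree$tip.label, NULL))
  aa_chr <- t(apply(nt_chr, 1, translate_codons))
  rownames(aa_chr) <- tree$tip.label
  list(nt = nt_chr, aa = aa_chr)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

draw_root_codons <- function(model, n_codons) {
  s <- sample.int(4, 3 * n_codons, replace = TRUE, prob = model$freqs)
  repeat {
    bad <- which_stop(s, n_codons)
    if (!length(bad)) return(s)
    pos <- as.vector(outer(1:3, (bad - 1) * 3, `+`))
    s[pos] <- sample.int(4, length(pos), replace = TRUE, prob = model$freqs)
  }
}

mutate_codons <- function(parent, P, n_codons) {
  child <- draw_states(parent, P)
  repeat {
    bad <- which_stop(child, n_codons)
    if (!length(bad)) return(child)
    pos <- as.vector(outer(1:3, (bad - 1) * 3, `+`))
    child[pos] <- draw_states(parent[pos], P)
  }
}

draw_states <- function(parent, P) {
  out <- integer(length(parent))
  for (s in 1:4) {
    idx <- which(parent == s)
    if (length(idx)) {
      out[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[s, ])
    }
  }
  out
}

which_stop <- function(states, n_codons) {
  codon <- matrix(NT_RESIDUES[states], nrow = 3)
  which(paste0(codon[1, ], codon[2, ], codon[3, ]) %in% STOP_CODONS)
}

translate_codons <- function(chars) {
  n <- length(chars) %/% 3L
  codons <- paste0(chars[seq(1, by = 3, length.out = n)],
                   chars[seq(2, by = 3, length.out = n)],
                   chars[seq(3, by = 3, length.out = n)])
  unname(GENETIC_CODE_TABLE[codons])
}

GENETIC_CODE_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(as.vector(t(outer(bases, bases, paste0))),
                              bases, paste0)))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aas, codons)
})

#' Similarity edge list with within-family signal and cross-family noise
#'
#' Emulates an all-vs-all protein similarity search: every within-family
#' pair receives a high weight around `within_mean`, and each cross-family
#' pair independently receives a weak edge with probability
#' `cross_noise_rate`. All weights are positive.
#'
#' @param families Named list: family id -> character vector of member ids.
#' @param within_mean Mean within-family edge weight.
#' @param cross_noise_rate Per-pair probability of a spurious cross edge.
#' @param seed RNG seed.
#' @return data.frame(a, b, weight).
#' @export
derive_similarity_graph <- function(families, within_mean = 100,
                                    cross_noise_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(cross_noise_rate >= 0, cross_noise_rate <= 1, within_mean > 0)
  memb <- unlist(families, use.names = FALSE)
  if (anyDuplicated(memb)) stop("families must be disjoint")
  edges <- list()
  for (fam in families) {
    if (length(fam) < 2) next
    pr <- t(utils::combn(fam, 2))
    w <- pmax(stats::rnorm(nrow(pr), within_mean, within_mean / 10),
              within_mean / 10)
    edges[[length(edges) + 1L]] <- data.frame(a = pr[, 1], b = pr[, 2],
                                              weight = w)
  }
  if (cross_noise_rate > 0 && length(families) > 1) {
    fam_of <- rep(names(families), lengths(families))
    pr <- t(utils::combn(memb, 2))
    cross <- fam_of[match(pr[, 1], memb)] != fam_of[match(pr[, 2], memb)]
    hit <- cross & stats::runif(nrow(pr)) < cross_noise_rate
    if (any(hit)) {
      w <- stats::runif(sum(hit), 0.5, 5)
      edges[[length(edges) + 1L]] <- data.frame(a = pr[hit, 1], b = pr[hit, 2],
                                                weight = w)
    }
  }
  if (!length(edges)) return(data.frame(a = character(), b = character(),
                                        weight = numeric()))
  do.call(rbind, edges)
}

#' Evolve one Mk discrete character along a tree
#'
#' The root state is uniform on the `k` states; along each branch the state
#' transitions according to the symmetric k-state Markov process with rate
#' `q` (see [mk_transition_prob()]).
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param q Mk rate parameter (>= 0).
#' @param k Number of states (default 7, the annulus vocabulary).
#' @param seed RNG seed.
#' @return Named integer vector of tip states in `1..k`.
#' @export
evolve_discrete_character <- function(tree, q, k = 7L, seed = NULL) {
  stopifnot(q >= 0, k >= 2)
  if (!is.null(seed)) set.seed(seed)
  ntip <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  eord <- rev(seq_len(nrow(tree$edge)))
  state <- integer(ntip + tree$Nnode)
  state[ntip + 1L] <- sample.int(k, 1)
  for (e in eord) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    p_same <- mk_transition_prob(1, 1, q, t, k)
    if (stats::runif(1) < p_same) {
      state[ch] <- state[par]
    } else {
      others <- setdiff(seq_len(k), state[par])
      state[ch] <- others[sample.int(k - 1L, 1)]
    }
  }
  stats::setNames(state[seq_len(ntip)], tree$tip.label)
}
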