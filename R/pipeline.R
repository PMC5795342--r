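#' Simulate a full synthetic dataset with ground truth
#'
#' Draws a Yule species tree, multispecies-coalescent gene trees (branch
#' lengths scaled to coalescent units by `coalescent_scale`), grafts
#' duplications/losses, evolves codon sequences (branch lengths scaled to
#' substitutions/site by `subst_scale`), builds the similarity graph, and
#' evolves discrete tip characters on the species tree. The returned
#' manifest carries every true object so downstream stages can be checked
#' against the truth.
#'
#' @param cfg `simulate` block of the configuration (see [default_config()]).
#' @param seed Seed for all randomness in the simulation.
#' @param species_tree Optional fixed species tree (rooted ultrametric
#'   `phylo`, branch lengths already in coalescent units); when supplied it
#'   is used as-is instead of a Yule draw, e.g. to pin the ILS regime.
#' @return list: species_tree (CU lengths), gene_trees, families (per gene:
#'   nt/aa alignments over `species.copy` rows), true_families (id ->
#'   member labels), edges, characters, config.
#' @export
simulate_dataset <- function(cfg = default_config()$simulate, seed = 1L,
                             species_tree = NULL) {
  set.seed(seed)
  if (is.null(species_tree)) {
    sp <- sim_species_tree(cfg$n_species, cfg$yule_rate)
    sp$edge.length <- sp$edge.length * cfg$coalescent_scale
  } else {
    sp <- species_tree
    cfg$n_species <- length(sp$tip.label)
  }
  gts <- sim_gene_trees_msc(sp, cfg$n_genes)
  model <- substitution_model("JC69")
  families <- list()
  gene_trees <- list()
  for (g in seq_len(cfg$n_genes)) {
    id <- sprintf("gene%04d", g)
    gt <- graft_duplications_losses(gts[[g]], cfg$dup_rate, cfg$loss_rate)
    seq_tree <- gt
    seq_tree$edge.length <- seq_tree$edge.length * cfg$subst_scale
    seqs <- evolve_sequences(seq_tree, model, cfg$seq_length)
    rownames(seqs$nt) <- paste0(id, "|", rownames(seqs$nt))
    rownames(seqs$aa) <- paste0(id, "|", rownames(seqs$aa))
    gene_trees[[id]] <- gt
    families[[id]] <- list(id = id, nt = seqs$nt, aa = seqs$aa)
  }
  true_families <- lapply(families, function(f) rownames(f$aa))
  edges <- derive_similarity_graph(true_families, cfg$within_mean,
                                   cfg$cross_noise_rate)
  chars <- sapply(seq_len(cfg$n_characters), function(i)
    evolve_discrete_character(sp, cfg$mk_rate, k = 7L))
  rownames(chars) <- sp$tip.label
  list(species_tree = sp, gene_trees = gene_trees, families = families,
       true_families = true_families, edges = edges, characters = chars,
       config = cfg)
}

#' Run the full phylogenomic pipeline on a synthetic dataset
#'
#' Clustering of the similarity graph, ortholog extraction, per-gene ML
#' trees, the four species trees of the method-by-datatype grid
#' (coalescent/concatenation x nt/aa), the cross-method comparison report,
#' and ancestral-state reconstruction of the simulated character over a
#' bootstrap tree sample of the nucleotide concatenation analysis.
#'
#' @param config Full configuration list ([default_config()]).
#' @param seed Master seed; the simulation and every stochastic stage
#'   derive their seeds from it.
#' @param asr Also run the ancestral-state stage (needs `asr$n_trees`
#'   bootstrap trees; slowest part).
#' @param species_tree Optional fixed coalescent-unit species tree passed
#'   to [simulate_dataset()].
#' @return list with the simulation, families, ortholog groups + audit,
#'   gene trees, species_trees (named list of 4 `phylo`), supermatrices,
#'   comparison report, and optionally the ancestral-state table.
#' @export
run_pipeline <- function(config = default_config(), seed = config$seed,
                         asr = FALSE, species_tree = NULL) {
  sim <- simulate_dataset(config$simulate, seed = seed,
                          species_tree = species_tree)
  n_species <- length(sim$species_tree$tip.label)
  fams <- mcl_cluster(sim$edges,
                      inflation = config$cluster$inflation,
                      min_weight = config$cluster$min_weight,
                      prune_threshold = config$cluster$prune_threshold,
                      max_iter = config$cluster$max_iter,
                      tol = config$cluster$tol)
  # attach the simulated alignments to the recovered families
  seq_nt <- do.call(rbind, lapply(sim$families, `[[`, "nt"))
  seq_aa <- do.call(rbind, lapply(sim$families, `[[`, "aa"))
  families <- lapply(names(fams), function(fid) {
    memb <- fams[[fid]]
    list(id = fid,
         nt = strip_gene_prefix(seq_nt[memb, , drop = FALSE]),
         aa = strip_gene_prefix(seq_aa[memb, , drop = FALSE]))
  })
  names(families) <- names(fams)
  ex <- extract_ortholog_groups(families, n_species, config$ortholog)
  if (!length(ex$groups)) stop("no ortholog groups retained")
  nt_model <- substitution_model(config$phylo$nt_model,
                                 gamma_categories = config$phylo$gamma_categories,
                                 alpha = config$phylo$alpha)
  aa_model <- substitution_model(config$phylo$aa_model,
                                 gamma_categories = config$phylo$gamma_categories,
                                 alpha = config$phylo$alpha)
  gene_trees_nt <- lapply(ex$groups, function(g) ml_search(g$nt, nt_model)$tree)
  gene_trees_aa <- lapply(ex$groups, function(g) ml_search(g$aa, aa_model)$tree)
  coal_nt <- coalescent_species_tree(gene_trees_nt, config$speciestree$mode)
  coal_aa <- coalescent_species_tree(gene_trees_aa, config$speciestree$mode)
  min_taxa <- occupancy_threshold(config$ortholog$occupancy_fraction, n_species)
  sm_nt <- build_supermatrix(ex$groups, min_taxa, "nt")
  sm_aa <- build_supermatrix(ex$groups, min_taxa, "aa")
  concat_nt <- ml_search(sm_nt$alignment, nt_model)
  concat_aa <- ml_search(sm_aa$alignment, aa_model)
  species_trees <- list(coalescent_nt = coal_nt$tree,
                        coalescent_aa = coal_aa$tree,
                        concat_nt = concat_nt$tree,
                        concat_aa = concat_aa$tree)
  report <- compare_topologies(species_trees)
  out <- list(sim = sim, families = families, groups = ex$groups,
              audit = ex$audit,
              gene_trees = list(nt = gene_trees_nt, aa = gene_trees_aa),
              species_trees = species_trees,
              coalescent = list(nt = coal_nt, aa = coal_aa),
              supermatrices = list(nt = sm_nt, aa = sm_aa),
              comparison = report)
  if (asr) {
    boot <- bootstrap_support(sm_nt$alignment, nt_model,
                              n_reps = config$asr$n_trees, seed = seed + 1L,
                              best = concat_nt)
    chars <- stats::setNames(sim$characters[, 1], rownames(sim$characters))
    out$asr <- trace_over_trees(boot$replicates, chars, k = config$asr$k)
    out$bootstrap <- boot
  }
  out
}

strip_gene_prefix <- function(m) {
  rownames(m) <- sub("^[^|]+\\|", "", rownames(m))
  m
}
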