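#' Default pipeline configuration
#'
#' A single nested key-value structure drives every stage, so that one file
#' plus a seed reproduces the full 2x2 (method x datatype) experiment grid.
#' Values can be overridden by a YAML file ([read_config()]) or per-call
#' arguments.
#'
#' @return Nested list of configuration blocks.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    simulate = list(
      n_species = 8L,
      yule_rate = 1.0,
      n_genes = 20L,
      coalescent_scale = 2.0,   # multiplies species-tree lengths into CU
      dup_rate = 0.0,
      loss_rate = 0.0,
      seq_length = 150L,        # codons
      subst_scale = 0.01,       # substitutions/site per coalescent unit
      mk_rate = 0.3,
      n_characters = 1L,
      within_mean = 100,
      cross_noise_rate = 0.0
    ),
    cluster = list(
      inflation = 2.0,
      min_weight = 20,
      prune_threshold = 1e-5,
      max_iter = 100L,
      tol = 1e-8
    ),
    ortholog = list(
      max_copies = 10L,
      occupancy_fraction = 0.5,
      min_taxa = 4L,
      max_gap_fraction = 0.5,
      min_flank_conservation = 0.85,
      min_nt_length = 150L,
      min_aa_length = 50L
    ),
    phylo = list(
      nt_model = "GTR",
      aa_model = "EMPIRICAL",
      gamma_categories = 1L,
      alpha = 1.0,
      p_inv = 0.0,
      n_bootstrap = 100L
    ),
    speciestree = list(
      mode = "auto",            # exact for <= 9 taxa, else heuristic
      bootstrap_stages = 2L,
      n_bootstrap = 100L
    ),
    asr = list(
      k = 7L,
      n_trees = 100L
    )
  )
}

#' Read a YAML configuration file over the defaults
#'
#' @param path YAML file; missing keys fall back to [default_config()].
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modify_list_deep(cfg, user)
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}
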