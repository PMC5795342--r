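---
title: "fernbone: methods and design of the backbone-phylogeny pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fernbone: methods and design of the backbone-phylogeny pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fernbone)
```

## The problem

Deep relationships among fern (monilophyte) lineages have long been
contested: plastid-gene phylogenies disagree with each other and with
morphology, partly because incomplete lineage sorting (ILS) makes
individual gene trees differ from the species tree. A transcriptome-scale
approach addresses this by estimating a species tree from thousands of
nuclear 1-to-1 ortholog genes with both coalescent-summary and
concatenation methods, on both nucleotide and amino-acid data, and then
reading morphological evolution — here the sporangial annulus, the row of
specialised cells that catapults fern spores — on the resulting backbone.

`fernbone` re-implements that analysis chain at desk scale, from an
all-vs-all similarity graph to an ancestral-state table, and couples it to
a synthetic-data generator that plays the role of the wet-lab stages
(RNA-seq, assembly, BLAST). Every downstream stage can therefore be tested
against known truth: the generating species tree, the true gene families,
and the true ancestral states.

## Pipeline stages and their models

### Homolog clustering (MCL)

The similarity edge list (`id_a, id_b, weight`) is clustered with Markov
clustering: add self-loops, column-normalise, then alternate *expansion*
(matrix self-product) and *inflation* (entrywise power, here 2.0, followed
by column renormalisation), pruning entries below `1e-5`, until the
largest entrywise change falls below `1e-8`. Clusters are read off the
limit matrix attractor-wise. Two conventions the literature leaves open
are fixed as follows: the self-loop weight is the node's maximum incident
weight (the usual regularisation), and edges below `min_weight = 20` are
dropped before clustering, mirroring a `gq(20)`-style score pre-filter on
whatever weight scale the input uses. Under the per-node self-loop rule a
weakly attached node is absorbed by a strong hub rather than split off;
this is a property of the algorithm as specified, and the test suite pins
it with an independent matrix-iteration oracle.

### Ortholog extraction

From each homolog family the pipeline (i) removes **all** sequences of any
species contributing more than 10 copies (isoform contamination guard —
strictly greater than 10, so exactly 10 copies survive); (ii) keeps
families with at least `round_half_up(0.5 * n_species)` species; (iii)
estimates a gene tree; (iv) prunes paralogs: every edge of the unrooted
gene tree induces two rooted subtrees, and among the sides in which no
species occurs twice the winner maximises (distinct species, then leaf
count, then the lexicographically smallest leaf-label tuple). The
unrooted edge-side reading avoids inventing a root, and a single pass
returns exactly one subtree per family, so each family contributes at
most one ortholog group. Ties are broken deterministically for
reproducibility. (v) Groups where any species retains two sequences, or
with fewer than `min_taxa` species, are discarded; (vi) alignments are
trimmed (below) and groups shorter than 150 nt / 50 aa are dropped — the
bounds are read inclusively, since 150 nt equals 50 aa exactly.

The trimmer is a deliberately simplified stand-in for Gblocks-style
masking: columns with more than 50% gaps are removed, then leading and
trailing columns are cut until a run of three consecutive columns each
reaches a majority-residue frequency of 0.85. Decisions are taken on the
amino-acid alignment and mapped codon-wise (x3) to the nucleotide twin,
so nucleotide widths stay multiples of three. Both thresholds are
config-exposed; downstream results do not depend on trimming details.

### Likelihood engine and tree search

Gene and concatenation trees are estimated by maximum likelihood with a
Felsenstein-pruning engine written for this package and cross-checked in
the tests against exhaustive state enumeration (small instances) and an
independent implementation. Models: JC69 or GTR for nucleotides, Poisson
or an empirical-matrix model for amino acids; the bundled empirical table
is the JTT exchangeability matrix (shipped as a data file, optionally with
"+F" frequencies estimated from the data). Rate variation uses the
discrete-gamma approximation with 4 equiprobable categories (category
means), optionally mixed with an invariant-site class whose proportion is
fitted by 1-D optimisation for the concatenation run ("GTR+Γ4+I"); gene
trees default to no invariant class. A CAT-style rate approximation is
deliberately not reproduced — it is an implementation-specific speed hack,
and Γ4 is the statistically standard form of the same assumption.

The search is neighbor-joining (on Jukes-Cantor distances; saturated
pairs capped at 5.0 substitutions/site) followed by per-branch Brent
optimisation and NNI hill climbing until no neighbour improves the
log-likelihood by more than `1e-4`. NNI-only search is a documented
simplification appropriate to the package's target sizes (tens of taxa);
it is exact on the easy, well-resolved instances the tests use and is
deterministic given the input.

### Species trees

The coalescent species tree maximises the *quartet score*: the number of
(gene tree, 4-taxon subset) pairs whose induced resolved quartet topology
matches the candidate tree — the standard quartet-summary optimality
criterion, which is statistically consistent under the multispecies
coalescent. The search over topologies is exact enumeration of all
(2n−5)!! unrooted trees for n ≤ 9 (ties to the lexicographically smallest
Newick), and NNI hill climbing from a neighbor-joining start on the mean
topological distance across gene trees otherwise. The objective, not the
search heuristic, defines the method; tests verify heuristic = exact on
all 6- and 7-taxon instances tried. Unresolved gene-tree quartets and
quartets with missing taxa contribute nothing.

Branch support comes from a multilocus bootstrap: each replicate resamples
genes with replacement and, in the default two-stage variant, also
resamples sites within each sampled gene before re-estimating its tree;
support is the percentage of replicate species trees containing each
bipartition of the point estimate. Whether the original procedure
resampled sites within genes is not decidable from its description, so
the stage count is a flag (`bootstrap_stages`, default 2 — the two-stage
variant subsumes the gene-only one).

Concatenation trees are estimated on supermatrices built from all groups
meeting an occupancy threshold, concatenated in stable id order with
absent taxa gap-filled. The fraction-to-count rule is round-half-up — the
unique simple rule consistent with the 50%/75%/90% thresholds of a
69-taxon design (35, 52 and 62). A single model spans all partitions; the
partition table is retained for bookkeeping only.

### Comparison report

The four trees of the {coalescent, concatenation} x {nt, aa} grid are
compared bipartition-wise. Splits present in some but not all trees are
merged into conflict neighbourhoods (overlapping smaller sides pooled);
each neighbourhood is rendered per tree as the induced rooted subtree over
its taxa with the remainder collapsed, giving a compact
"site / per-combination topology" conflict table. Congruent inputs yield
an empty report.

### Ancestral states (Mk)

The annulus character takes one of 7 unordered states (vertical, oblique,
rudimentary, ex-annulus, apical, transverse, vestigial). Evolution is
modelled with the k-state single-rate Markov model: all transitions
equally likely, uniform stationary distribution, transition probability
`1/k + ((k-1)/k) exp(-kqt)` on the diagonal. The rate `q` is fitted per
character and per tree by bounded 1-D maximisation; because the
log-likelihood flattens at saturating rates, the optimiser first brackets
the maximum on a log-spaced grid and then refines by Brent's method.
Marginal ("proportional likelihood") node probabilities come from the
standard up-down algorithm under a uniform root prior. To propagate
phylogenetic uncertainty, reconstructions are averaged across a tree
sample: internal nodes are matched across trees by their exact leaf-species
set (the only unambiguous reading of frequency-based averaging across
trees), and each clade's row records how many trees contain it. The tree
sample is wired to the bootstrap replicates of the nucleotide
concatenation run — the only size-100 tree sample the pipeline produces.

## The synthetic-data generator

`simulate_dataset()` emulates, in order: a Yule species tree (forward
birth process, stopped at `n_species` lineages, the present placed one
further waiting time on so pendant edges are positive; branch lengths are
read as coalescent units after scaling by `coalescent_scale`); gene trees
under the censored multispecies coalescent, one haploid lineage per
species (matching one transcriptome per species); gene duplications and
losses as a linear birth-death process along gene-tree lineages
(duplication copies the subtree below the event point, creating the
in-paralogs the masking step must remove); codon sequences evolved
site-independently under the nucleotide model with stop-codon draws
rejected, so translations are clean; a similarity graph with
Normal-weighted within-family edges and Bernoulli cross-family noise; and
Mk tip characters on the species tree.

Defaults and why:

* `yule_rate = 1`, `coalescent_scale = 2`: internal branches of order one
  coalescent unit, i.e. moderate ILS — gene-tree discordance is visible
  but the species tree is identifiable.
* `subst_scale = 0.01` substitutions/site per coalescent unit: pairwise
  nucleotide divergences of roughly 5–15% across the tree, in line with
  the conserved single-copy nuclear genes used for deep phylogenies
  (alignments dominated by conserved columns, as the trimming defaults
  presuppose). Much larger values would emulate saturated, fast-evolving
  sequence that such pipelines deliberately avoid.
* `seq_length = 150` codons: at the short end of real ortholog alignments,
  chosen so whole-pipeline runs stay interactive.
* `dup_rate = loss_rate = 0` and `cross_noise_rate = 0` by default: the
  clean regime in which the recovery guarantees (families = truth, all
  genes 1-to-1, species trees = truth) are provable properties; tests
  switch the rates on where paralogy or noise is the thing under test.
* `mk_rate = 0.3`: a few state changes per tree depth, the regime where
  ancestral states are informative but not trivial.

What the generator does **not** emulate: indels and alignment error
(sequences are emitted pre-aligned; the upstream aligner is out of scope
by construction), rate heterogeneity among lineages, codon-level
selection, hybridisation/reticulation, and assembly artefacts beyond
simple copy multiplication. Passing tests therefore certify algorithmic
correctness on model-true data, not robustness to real-data pathologies.

## Numerical choices

* Transition probabilities via symmetrised eigendecomposition of the
  reversible generator; negative round-off entries clamped at zero.
* Site patterns are compressed with weights before any likelihood work;
  partial likelihoods are rescaled at the root (column maxima) to avoid
  underflow at the package's target sizes.
* Brent per-branch optimisation on `[1e-9, 10]` substitutions/site,
  sweeps until a full pass gains less than `1e-4` log units.
* Degenerate inputs are contracts, not crashes: empty families are
  flagged for exclusion, a family whose gene tree has no copy-clean side
  with two species is discarded as a signal (`NULL`), an all-gap column
  pair in distance computation names the offending pair, and a gene tree
  losing every leaf raises an "empty gene" error.
* All randomness flows from explicit seeds; identical seed and
  configuration reproduce byte-identical outputs. Tree searches and
  tie-breaks are deterministic (lexicographic rules), and polytomies are
  resolved non-randomly.

## Test design and problem sizes

The suite favours oracle equivalence over spot values: pruning
likelihoods (nucleotide, amino acid, Mk) against exhaustive
state-enumeration on ≤ 5-taxon instances; paralog pruning against a
brute-force edge-side search (via graph component splitting) on random
12-leaf trees; the quartet heuristic against exact enumeration on 6–7
taxa; marginal reconstructions against enumeration and against an
independent engine. Monte-Carlo checks (Yule growth, 3-taxon MSC
concordance at `1 − (2/3)e^{−T}`, Jukes-Cantor divergence, birth-process
leaf counts) run at sizes of 10^3–10^4 draws and assert agreement within
3–4 Monte-Carlo standard errors. The end-to-end smoke run uses 7 species
(fixed species tree with 1.5-coalescent-unit internal branches, i.e. the
low-ILS regime in which exact recovery is the expected behaviour), 10
genes of 150 codons, and checks that every simulated gene returns as a
1-to-1 ortholog and that all four method-by-datatype species trees equal
the truth with an empty conflict report. These sizes are the package's
validation design; the same code runs unchanged at larger settings.

## Known limitations

* NNI-only topology search can be trapped by local optima on hard
  likelihood surfaces; the exemplar analyses here are easy by design.
* Exact quartet optimisation is capped at 9 taxa ((2n−5)!! growth); the
  heuristic carries no optimality certificate beyond the tested sizes.
* Per-gene protein model selection is not re-implemented; the empirical
  model is fixed to the bundled JTT table (+F optional).
* The concatenation run uses one model across partitions.
* The Mk engine is the strict 1-parameter symmetric model: no asymmetric
  rates, no ordered states, no stochastic character mapping.
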