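#' Per-sample transcriptome assembly statistics
#'
#' The bundled table of sequencing and assembly statistics for the 69
#' sampled fern transcriptomes: clean data volume (Gb), read counts, Q30,
#' contig counts, N50, mean contig length, and the number of ortholog genes
#' each sample contributes to the two supermatrices.
#'
#' @return data.frame with one row per sample.
#' @export
read_assembly_stats <- function() {
  path <- system.file("extdata", "table1_assembly_stats.tsv",
                      package = "fernbone", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}

#' Corpus-level totals of the assembly statistics
#'
#' Sums the per-sample table: total contigs, total clean reads (also in
#' millions) and total clean data in Gbp.
#'
#' @param stats data.frame from [read_assembly_stats()].
#' @return Named list of totals.
#' @export
assembly_totals <- function(stats = read_assembly_stats()) {
  list(
    n_samples = nrow(stats),
    total_contigs = sum(stats$n_contigs),
    total_reads = sum(stats$total_reads),
    total_reads_million = sum(stats$total_reads) / 1e6,
    total_clean_gb = sum(stats$clean_data_gb)
  )
}

#' Single-copy-ortholog completeness percentage
#'
#' Completeness of an assembly against a reference set of conserved
#' single-copy orthologs: complete hits over the reference total, as a
#' percentage rounded to one decimal.
#'
#' @param n_complete Number of complete reference orthologs recovered.
#' @param n_reference Size of the reference ortholog set.
#' @export
busco_completeness <- function(n_complete, n_reference) {
  stopifnot(n_complete >= 0, n_reference > 0, n_complete <= n_reference)
  round(100 * n_complete / n_reference, 1)
}
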