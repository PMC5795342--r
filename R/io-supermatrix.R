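#' Partition table for a concatenated alignment
#'
#' Ordered 1-based inclusive column intervals, one per gene, contiguous and
#' covering `1..total_columns`.
#'
#' @param gene_ids Character vector of gene ids (concatenation order).
#' @param widths Integer vector of per-gene column counts.
#' @return data.frame with columns `gene`, `start`, `end`.
#' @export
partition_table <- function(gene_ids, widths) {
  stopifnot(length(gene_ids) == length(widths), all(widths >= 1))
  end <- cumsum(widths)
  start <- c(1L, utils::head(end, -1L) + 1L)
  data.frame(gene = gene_ids, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

#' Serialize a supermatrix as relaxed PHYLIP plus a RAxML partition file
#'
#' The PHYLIP text has an `ntaxa ncols` header and one `taxon  sequence` row
#' per taxon, with `-` filling genes a taxon lacks. The partition file uses
#' the `DNA, gene1 = 1-300` dialect (`WAG,` for amino-acid matrices).
#'
#' @param sm A supermatrix from [build_supermatrix()].
#' @param phylip_path,partition_path Optional output files.
#' @return list(phylip = text, partitions = text), invisibly when written.
#' @export
write_supermatrix <- function(sm, phylip_path = NULL, partition_path = NULL) {
  stopifnot(inherits(sm, "supermatrix"))
  if (nrow(sm$partitions) == 0L) stop("empty gene list")
  seqs <- matrix_to_strings(sm$alignment)
  if (length(unique(nchar(seqs))) != 1L) stop("ragged supermatrix rows")
  hdr <- paste(length(seqs), nchar(seqs[[1]]))
  rows <- paste0(format(names(seqs), width = max(nchar(names(seqs))) + 2), seqs)
  phylip <- paste(c(hdr, rows), collapse = "\n")
  dtype <- if (sm$alphabet == "nt") "DNA" else "WAG"
  parts <- sprintf("%s, %s = %d-%d", dtype, sm$partitions$gene,
                   sm$partitions$start, sm$partitions$end)
  partitions <- paste(parts, collapse = "\n")
  if (!is.null(phylip_path)) writeLines(phylip, phylip_path)
  if (!is.null(partition_path)) writeLines(partitions, partition_path)
  out <- list(phylip = phylip, partitions = partitions)
  if (is.null(phylip_path) && is.null(partition_path)) out else invisible(out)
}

#' Read / write a TSV similarity edge list
#'
#' Three columns, no header: `id_a<TAB>id_b<TAB>weight`.
#' @param path File path.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("a", "b", "weight"),
                          colClasses = c("character", "character", "numeric"))
  df
}

#' @rdname read_edge_list
#' @param edges data.frame with columns `a`, `b`, `weight`.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges[, c("a", "b", "weight")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read / write a species-to-state character matrix TSV
#'
#' Two columns, no header: `species<TAB>state`. States are names from the
#' state vocabulary (see [annulus_states]).
#' @param path File path.
#' @export
read_character_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("species", "state"),
                          colClasses = "character")
  stats::setNames(df$state, df$species)
}

#' @rdname read_character_matrix
#' @param states Named character vector, species -> state name.
#' @export
write_character_matrix <- function(states, path) {
  utils::write.table(data.frame(names(states), unname(states)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' The seven sporangial-annulus states
#'
#' Unordered discrete states of the fern sporangial annulus used in the
#' ancestral-state reconstruction: vertical, oblique, rudimentary,
#' ex-annulus (absent), apical, transverse, and vestigial annulus.
#' @export
annulus_states <- c("vertical", "oblique", "rudimentary", "ex-annulus",
                    "apical", "transverse", "vestigial")
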