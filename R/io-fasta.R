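NT_RESIDUES <- c("A", "C", "G", "T")
AA_RESIDUES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a sequence record
#'
#' A sequence record is one sequence copy: a species identifier, a copy
#' identifier unique within that species, the residue string, and its
#' alphabet. Copies arise from gene duplication (in-paralogs) and from
#' transcriptome assembly artefacts; the pipeline keeps them apart via the
#' `species.copy` labelling convention (`.` is forbidden inside species ids).
#'
#' @param species Species identifier (no `.`).
#' @param copy Copy identifier, or `NA` for a bare single-copy label.
#' @param residues Residue string; `-` is a gap, `N`/`X` missing.
#' @param alphabet `"nt"` or `"aa"`; guessed from the residues when `NULL`.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(species, copy = NA_character_, residues, alphabet = NULL) {
  if (!nzchar(residues)) stop("empty sequence for '", species, "'")
  if (grepl(".", species, fixed = TRUE)) {
    stop("species id must not contain '.': ", species)
  }
  res <- toupper(residues)
  if (is.null(alphabet)) alphabet <- guess_alphabet(res)
  chars <- unique(strsplit(res, "")[[1]])
  ok <- if (alphabet == "nt") c(NT_RESIDUES, "-", "N") else c(AA_RESIDUES, "-", "X")
  bad <- setdiff(chars, ok)
  if (length(bad)) {
    stop("residues of ", record_label_chr(species, copy),
         " not valid for alphabet '", alphabet, "': ", paste(bad, collapse = ""))
  }
  structure(list(species = species, copy = copy, residues = res,
                 alphabet = alphabet),
            class = "seq_record")
}

guess_alphabet <- function(residues) {
  chars <- unique(strsplit(toupper(residues), "")[[1]])
  if (all(chars %in% c(NT_RESIDUES, "-", "N"))) "nt" else "aa"
}

record_label_chr <- function(species, copy) {
  ifelse(is.na(copy), species, paste(species, copy, sep = "."))
}

#' @export
record_label <- function(rec) record_label_chr(rec$species, rec$copy)

split_label <- function(label) {
  dot <- regexpr(".", label, fixed = TRUE)
  if (dot < 0) list(species = label, copy = NA_character_)
  else list(species = substr(label, 1, dot - 1),
            copy = substr(label, dot + 1, nchar(label)))
}

#' Species part of a `species.copy` label
#' @param labels Character vector of leaf or sequence labels.
#' @export
label_species <- function(labels) sub("\\..*$", "", labels)

#' Parse FASTA text into sequence records
#'
#' Headers follow the `species.copy` (or bare `species`) convention.
#' Round-trips with [write_fasta()] byte-identically up to line wrapping.
#'
#' @param text A single string (with newlines) or a character vector of lines.
#' @return List of [seq_record()] objects, input order preserved.
#' @export
parse_fasta <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else text
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) stop("not FASTA: first line is not a header")
  grp <- cumsum(hdr)
  labels <- sub("^>", "", trimws(lines[hdr]))
  seqs <- unname(vapply(split(lines[!hdr], grp[!hdr]),
                        paste, character(1), collapse = ""))
  if (length(seqs) != length(labels) || any(!nzchar(seqs))) {
    stop("empty sequence in FASTA (header without residues)")
  }
  dup <- labels[duplicated(labels)]
  if (length(dup)) stop("duplicate FASTA label: ", paste(unique(dup), collapse = ", "))
  lapply(seq_along(labels), function(i) {
    sp <- split_label(labels[i])
    seq_record(sp$species, sp$copy, seqs[i])
  })
}

#' @rdname parse_fasta
#' @param path File to read.
#' @export
read_fasta <- function(path) parse_fasta(readLines(path))

#' Write sequence records as FASTA
#'
#' @param records List of [seq_record()]s, or a named character vector of
#'   residue strings (names are labels).
#' @param path Optional output file; when `NULL` the text is returned.
#' @param width Line-wrap width.
#' @return FASTA text, invisibly when `path` is given.
#' @export
write_fasta <- function(records, path = NULL, width = 60L) {
  if (is.character(records)) {
    labels <- names(records)
    seqs <- unname(records)
  } else {
    labels <- vapply(records, record_label, character(1))
    seqs <- vapply(records, function(r) r$residues, character(1))
  }
  chunks <- lapply(seq_along(labels), function(i) {
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", labels[i]), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  out <- paste0(paste(unlist(chunks), collapse = "\n"), "\n")
  if (is.null(path)) return(out)
  writeLines(sub("\n$", "", out), path)
  invisible(out)
}

#' Stack equal-length records into an alignment matrix
#'
#' @param records List of [seq_record()]s or named character vector.
#' @return Character matrix, one row per sequence (rownames = labels),
#'   one column per alignment position.
#' @export
records_to_matrix <- function(records) {
  if (is.character(records)) {
    labels <- names(records); seqs <- unname(records)
  } else {
    labels <- vapply(records, record_label, character(1))
    seqs <- vapply(records, function(r) r$residues, character(1))
  }
  n <- nchar(seqs)
  if (length(unique(n)) != 1L) stop("ragged alignment: lengths ", paste(unique(n), collapse = ","))
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- labels
  m
}

#' @rdname records_to_matrix
#' @param m Character alignment matrix with rownames.
#' @export
matrix_to_strings <- function(m) {
  stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}
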