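#' Read contigs from a FASTA file
#'
#' Reads nucleotide contigs, uppercases the sequences, and validates that
#' headers are unique, sequences are non-empty, and the alphabet is
#' restricted to A/C/G/T/N. Header text after the first whitespace is
#' dropped (standard contig-id convention).
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig id, with `mcols`
#'   columns `sample_id` (NA) and `zone` (`"unknown"`) that callers may
#'   fill in from sample metadata.
#' @seealso [writeContigFasta()]
#' @export
readContigFasta <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    .stopf("duplicate FASTA header(s): %s", paste(dup, collapse = ", "))
  if (any(Biostrings::width(x) == 0L))
    .stopf("empty sequence for header(s): %s",
           paste(ids[Biostrings::width(x) == 0L], collapse = ", "))
  seqs <- toupper(as.character(x))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    .stopf("sequence(s) with characters outside A/C/G/T/N: %s",
           paste(ids[bad], collapse = ", "))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    sample_id = rep(NA_character_, length(ids)),
    zone = rep("unknown", length(ids)), row.names = ids)
  out
}

#' Write contigs to a FASTA file
#'
#' Sequences are wrapped at 60 columns; headers are the contig ids, so
#' `readContigFasta(writeContigFasta(x))` round-trips ids and sequences.
#'
#' @param contigs A [Biostrings::DNAStringSet] (or named character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeContigFasta <- function(contigs, path) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  if (is.null(names(contigs)) || any(names(contigs) == ""))
    .stopf("all contigs must be named")
  Biostrings::writeXStringSet(contigs, filepath = path, width = 60L)
  invisible(path)
}
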