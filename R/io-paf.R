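.paf_cols <- c("read_id", "read_length", "read_start", "read_end", "strand",
               "contig_id", "contig_length", "contig_start", "contig_end",
               "matches", "block_length", "mapq")

#' Read read-to-contig alignments from a PAF file
#'
#' Parses the standard 12+-column PAF layout (minimap2 dialect). All
#' coordinates are 0-based half-open, as in PAF itself. The derived column
#' `aligned_read_bases` is `read_end - read_start`; `matches` is PAF
#' column 10. Extra optional tag columns are ignored. Both strands are
#' kept (strand does not affect abundance).
#'
#' @param path Path to a PAF file (may be empty).
#' @param sample_id Sample identifier attached to every record (PAF does
#'   not carry one).
#' @return A `data.frame` with the 12 PAF fields plus `aligned_read_bases`
#'   and `sample_id`; zero rows for an empty file.
#' @seealso [writePAF()], [filterAlignments()]
#' @export
readPAF <- function(path, sample_id = NA_character_) {
  if (!file.exists(path)) .stopf("PAF file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- data.frame(read_id = character(), read_length = integer(),
                      read_start = integer(), read_end = integer(),
                      strand = character(), contig_id = character(),
                      contig_length = integer(), contig_start = integer(),
                      contig_end = integer(), matches = integer(),
                      block_length = integer(), mapq = integer(),
                      aligned_read_bases = integer(),
                      sample_id = character(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    .stopf("PAF line %d has %d column(s); at least 12 required",
           which(nf < 12L)[1], nf[which(nf < 12L)[1]])
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  num_cols <- c(2, 3, 4, 7, 8, 9, 10, 11, 12)
  vals <- suppressWarnings(
    lapply(num_cols, function(j) as.integer(m[, j])))
  bad <- Reduce(`|`, lapply(vals, is.na))
  if (any(bad))
    .stopf("PAF line %d: non-numeric value in a coordinate/count column",
           which(bad)[1])
  out <- data.frame(
    read_id = m[, 1], read_length = vals[[1]], read_start = vals[[2]],
    read_end = vals[[3]], strand = m[, 5], contig_id = m[, 6],
    contig_length = vals[[4]], contig_start = vals[[5]],
    contig_end = vals[[6]], matches = vals[[7]], block_length = vals[[8]],
    mapq = vals[[9]], stringsAsFactors = FALSE)
  out$aligned_read_bases <- out$read_end - out$read_start
  out$sample_id <- sample_id
  chk <- function(cond, msg) {
    if (any(cond)) .stopf("PAF line %d: %s", which(cond)[1], msg)
  }
  chk(!out$strand %in% c("+", "-"), "strand must be '+' or '-'")
  chk(out$read_start >= out$read_end, "inverted read coordinates")
  chk(out$contig_start >= out$contig_end, "inverted contig coordinates")
  chk(out$contig_end > out$contig_length, "contig_end exceeds contig length")
  chk(out$contig_start < 0L | out$read_start < 0L, "negative coordinate")
  chk(out$aligned_read_bases > out$read_length,
      "aligned read bases exceed read length")
  chk(out$matches < 0L | out$matches > out$aligned_read_bases,
      "matches outside [0, aligned_read_bases]")
  out
}

#' Write read alignments to a PAF file
#'
#' Inverse of [readPAF()]: writes the 12 standard columns so that
#' `readPAF(writePAF(x))` reproduces `x` field-for-field.
#'
#' @param alignments `data.frame` as returned by [readPAF()] or
#'   [simulateAlignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePAF <- function(alignments, path) {
  miss <- setdiff(.paf_cols, names(alignments))
  if (length(miss))
    .stopf("alignments table is missing column(s): %s",
           paste(miss, collapse = ", "))
  m <- alignments[, .paf_cols, drop = FALSE]
  write.table(m, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
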