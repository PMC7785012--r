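#' Apply read-retention filters to alignments
#'
#' Retains an alignment iff read identity
#' `100 * matches / aligned_read_bases >= minIdentity` and aligned read
#' fraction `aligned_read_bases / read_length >= minReadFraction` (the
#' "95% identity over 90% of the read" recruitment rule; both thresholds
#' inclusive). Idempotent.
#'
#' @param alignments `data.frame` as from [readPAF()] or
#'   [simulateAlignments()].
#' @param minIdentity Minimum read identity in percent (default 95).
#' @param minReadFraction Minimum aligned fraction of the read
#'   (default 0.90).
#' @return The retained rows of `alignments`.
#' @export
filterAlignments <- function(alignments, minIdentity = 95.0,
                             minReadFraction = 0.90) {
  need <- c("read_length", "aligned_read_bases", "matches")
  miss <- setdiff(need, names(alignments))
  if (length(miss))
    .stopf("alignments table is missing column(s): %s",
           paste(miss, collapse = ", "))
  if (!nrow(alignments)) return(alignments)
  if (any(alignments$read_length <= 0))
    .stopf("read_length must be > 0 (row %d)",
           which(alignments$read_length <= 0)[1])
  if (any(alignments$aligned_read_bases <= 0))
    .stopf("aligned_read_bases must be > 0 (row %d)",
           which(alignments$aligned_read_bases <= 0)[1])
  identity <- 100 * alignments$matches / alignments$aligned_read_bases
  fraction <- alignments$aligned_read_bases / alignments$read_length
  alignments[identity >= minIdentity & fraction >= minReadFraction, ,
             drop = FALSE]
}

.coverage_one <- function(starts, ends, contig_length) {
  if (!length(starts)) return(list(covered = 0L, aligned = 0))
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  list(covered = sum(IRanges::width(ir)), aligned = sum(ends - starts))
}

#' Coverage, breadth and normalized abundance of one contig in one sample
#'
#' Breadth is the fraction of contig positions covered by at least one
#' retained alignment (interval union of the `[contig_start, contig_end)`
#' spans); mean depth is total aligned bases divided by contig length.
#' The normalized abundance is mean depth per Gbp of metagenome, and is
#' set to 0 unless breadth exceeds 0.75 (strict), the contig-level
#' retention rule.
#'
#' @param alignments Retained alignments for this contig and sample (see
#'   [filterAlignments()]); rows for other contigs/samples are an error.
#' @param contigLength Contig length in bp.
#' @param metagenomeSizeBp Total sequenced bases in the sample's read
#'   library.
#' @param minBreadth Breadth retention threshold (strict; default 0.75).
#' @return A one-row `data.frame`: `breadth`, `total_aligned_bases`,
#'   `mean_depth`, `normalized_abundance`.
#' @export
contigCoverage <- function(alignments, contigLength, metagenomeSizeBp,
                           minBreadth = 0.75) {
  stopifnot(contigLength > 0, metagenomeSizeBp > 0)
  if (nrow(alignments)) {
    if (any(alignments$contig_end > contigLength |
              alignments$contig_start < 0))
      .stopf("alignment interval outside [0, %d)", contigLength)
    if (length(unique(alignments$contig_id)) > 1L)
      .stopf("alignments span multiple contigs")
  }
  cov <- .coverage_one(alignments$contig_start, alignments$contig_end,
                       contigLength)
  breadth <- cov$covered / contigLength
  mean_depth <- cov$aligned / contigLength
  data.frame(
    breadth = breadth,
    total_aligned_bases = cov$aligned,
    mean_depth = mean_depth,
    normalized_abundance =
      if (breadth > minBreadth) mean_depth / (metagenomeSizeBp / 1e9) else 0)
}

#' Coverage table for all contig-sample pairs
#'
#' Applies the read-retention filters and then [contigCoverage()] to every
#' (contig, sample) pair present in the alignment table.
#'
#' @param alignments Alignment table with a `sample_id` column.
#' @param contigLengths Named integer vector of contig lengths (or a
#'   [Biostrings::DNAStringSet]).
#' @param samples Sample metadata `data.frame` (`sample_id`,
#'   `metagenome_size_bp`).
#' @param minIdentity,minReadFraction,minBreadth Retention thresholds;
#'   see [filterAlignments()] and [contigCoverage()].
#' @return `data.frame` with one row per (contig, sample) pair observed
#'   after read filtering: `contig_id`, `sample_id`, `breadth`,
#'   `total_aligned_bases`, `mean_depth`, `normalized_abundance`.
#' @export
computeCoverage <- function(alignments, contigLengths, samples,
                            minIdentity = 95.0, minReadFraction = 0.90,
                            minBreadth = 0.75) {
  if (methods::is(contigLengths, "DNAStringSet"))
    contigLengths <- setNames(Biostrings::width(contigLengths),
                              names(contigLengths))
  kept <- filterAlignments(alignments, minIdentity, minReadFraction)
  if (!nrow(kept)) {
    return(data.frame(contig_id = character(), sample_id = character(),
                      breadth = numeric(), total_aligned_bases = numeric(),
                      mean_depth = numeric(), normalized_abundance = numeric(),
                      stringsAsFactors = FALSE))
  }
  unknown <- setdiff(unique(kept$contig_id), names(contigLengths))
  if (length(unknown))
    .stopf("alignments reference unknown contig(s): %s",
           paste(head(unknown, 3), collapse = ", "))
  sizes <- setNames(samples$metagenome_size_bp, samples$sample_id)
  unknown_s <- setdiff(unique(kept$sample_id), names(sizes))
  if (length(unknown_s))
    .stopf("alignments reference unknown sample(s): %s",
           paste(unknown_s, collapse = ", "))
  groups <- split(kept, list(kept$contig_id, kept$sample_id), drop = TRUE)
  rows <- lapply(groups, function(g) {
    cbind(data.frame(contig_id = g$contig_id[1], sample_id = g$sample_id[1],
                     stringsAsFactors = FALSE),
          contigCoverage(g, contigLengths[[g$contig_id[1]]],
                         sizes[[g$sample_id[1]]], minBreadth))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the populations-by-samples abundance matrix
#'
#' Maps each coverage row to a viral population through its contig
#' (representative or member) and assembles the normalized abundance
#' matrix over all populations and all samples. Populations never
#' detected anywhere keep their all-zero rows (absence is information);
#' coverage rows for contigs not assigned to any population are skipped
#' with a warning. When several member contigs of one population have
#' coverage in the same sample their normalized abundances are summed.
#'
#' @param coverages Coverage table from [computeCoverage()].
#' @param populations A [VirPopSet].
#' @param samples Sample metadata `data.frame` (defines column order).
#' @return A [ViralAbundance].
#' @export
buildAbundanceMatrix <- function(coverages, populations, samples) {
  stopifnot(methods::is(populations, "VirPopSet"))
  m <- memberTable(populations)
  pop_of <- setNames(m$population_id, m$member_id)
  pops <- populationIds(populations)
  mat <- matrix(0, nrow = length(pops), ncol = nrow(samples),
                dimnames = list(pops, samples$sample_id))
  if (nrow(coverages)) {
    unmapped <- !(coverages$contig_id %in% names(pop_of))
    if (any(unmapped)) {
      .warnf("skipping coverage for %d contig(s) not assigned to any population (e.g. %s)",
             sum(unmapped), coverages$contig_id[which(unmapped)[1]])
      coverages <- coverages[!unmapped, , drop = FALSE]
    }
    for (i in seq_len(nrow(coverages))) {
      p <- pop_of[[coverages$contig_id[i]]]
      s <- coverages$sample_id[i]
      mat[p, s] <- mat[p, s] + coverages$normalized_abundance[i]
    }
  }
  ViralAbundance(mat, samples)
}
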