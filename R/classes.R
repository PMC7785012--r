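#' VirPopSet: species-level viral populations
#'
#' Container for the result of greedy ANI clustering of contigs into
#' species-level viral populations. Each population is represented by its
#' longest member (ties broken lexicographically by contig id), and every
#' member satisfies the ANI and aligned-fraction thresholds against its
#' representative.
#'
#' @slot members A `data.frame` with one row per member contig and columns
#'   `population_id`, `representative_id`, `member_id`, `member_length`,
#'   `ani_to_rep`, `af_to_rep`. The representative row of each population
#'   comes first and has `ani_to_rep = 100`, `af_to_rep = 1`.
#' @slot parameters Named list with the clustering parameters used
#'   (`min_length_bp`, `ani_threshold`, `af_threshold`, `seed_length`).
#'
#' @seealso [clusterPopulations()]
#' @export
setClass("VirPopSet",
         representation(members = "data.frame", parameters = "list"),
         prototype(members = data.frame(), parameters = list()))

.virpopset_cols <- c("population_id", "representative_id", "member_id",
                     "member_length", "ani_to_rep", "af_to_rep")

setValidity("VirPopSet", function(object) {
  m <- object@members
  if (nrow(m) == 0L) return(TRUE)
  miss <- setdiff(.virpopset_cols, names(m))
  if (length(miss))
    return(paste("missing members columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(m$member_id))
    return("member_id values must be unique (populations are disjoint)")
  for (pid in unique(m$population_id)) {
    rows <- m[m$population_id == pid, , drop = FALSE]
    rep_id <- rows$representative_id[1]
    if (rows$member_id[1] != rep_id)
      return(sprintf("population %s: representative must be listed first", pid))
    rep_len <- rows$member_length[1]
    if (any(rows$member_length > rep_len))
      return(sprintf("population %s: representative is not the longest member",
                     pid))
    ties <- rows$member_id[rows$member_length == rep_len]
    if (min(ties) != rep_id)
      return(sprintf(
        "population %s: representative tie must break lexicographically", pid))
  }
  TRUE
})

#' @describeIn VirPopSet Constructor from a member table.
#' @param members See the `members` slot.
#' @param parameters See the `parameters` slot.
#' @export
VirPopSet <- function(members, parameters = list()) {
  new("VirPopSet", members = as.data.frame(members), parameters = parameters)
}

#' @describeIn VirPopSet Number of populations.
#' @param x,object A `VirPopSet`.
#' @export
setMethod("nPopulations", "VirPopSet", function(x)
  length(unique(x@members$population_id)))

#' @describeIn VirPopSet Population identifiers, in representative-length
#'   order (longest first).
#' @export
setMethod("populationIds", "VirPopSet", function(x)
  unique(x@members$population_id))

#' @describeIn VirPopSet Representative contig id per population.
#' @export
setMethod("representativeIds", "VirPopSet", function(x) {
  m <- x@members[!duplicated(x@members$population_id), ]
  setNames(m$representative_id, m$population_id)
})

#' @describeIn VirPopSet The full member table.
#' @export
setMethod("memberTable", "VirPopSet", function(x) x@members)

setMethod("show", "VirPopSet", function(object) {
  m <- object@members
  cat(sprintf("VirPopSet: %d population(s), %d member contig(s)\n",
              nPopulations(object), nrow(m)))
  if (nrow(m)) {
    sizes <- table(m$population_id)
    cat(sprintf("  members per population: %s\n",
                paste(range(sizes), collapse = "-")))
    cat(sprintf("  representative lengths: %d-%d bp\n",
                min(m$member_length[!duplicated(m$population_id)]),
                max(m$member_length[!duplicated(m$population_id)])))
  }
  p <- object@parameters
  if (length(p))
    cat(sprintf("  thresholds: ANI >= %s%%, AF >= %s, length > %s bp\n",
                p$ani_threshold, p$af_threshold, p$min_length_bp))
  invisible(NULL)
})

#' ViralAbundance: populations-by-samples abundance container
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' normalized recruitment-based abundance matrix (assay `"abundance"`,
#' rows = viral populations, columns = samples) with sample metadata
#' (depth, redox zone, metagenome size) as `colData`. Values are mean
#' read depth per Gbp of metagenome, set to 0 where the 75% breadth
#' retention rule failed.
#'
#' @seealso [buildAbundanceMatrix()], [relativeAbundance()]
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("ViralAbundance", contains = "SummarizedExperiment")

setValidity("ViralAbundance", function(object) {
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'abundance' is required")
  a <- SummarizedExperiment::assay(object, "abundance")
  if (any(a < 0, na.rm = TRUE)) return("abundance values must be >= 0")
  TRUE
})

#' @describeIn ViralAbundance Constructor.
#' @param abundance Numeric matrix, populations x samples, with dimnames.
#' @param samples `data.frame` of sample metadata with a `sample_id`
#'   column matching `colnames(abundance)` (order is taken from the matrix).
#' @export
ViralAbundance <- function(abundance, samples = NULL) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
    .stopf("abundance matrix must have population rownames and sample colnames")
  if (is.null(samples)) {
    cd <- S4Vectors::DataFrame(sample_id = colnames(abundance),
                               row.names = colnames(abundance))
  } else {
    samples <- as.data.frame(samples)
    idx <- match(colnames(abundance), samples$sample_id)
    if (anyNA(idx))
      .stopf("samples table is missing sample(s): %s",
             paste(colnames(abundance)[is.na(idx)], collapse = ", "))
    cd <- S4Vectors::DataFrame(samples[idx, , drop = FALSE],
                               row.names = colnames(abundance))
  }
  new("ViralAbundance",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = abundance), colData = cd))
}

#' @describeIn ViralAbundance Per-sample relative abundances: each column
#'   divided by its sum; all-zero columns stay all-zero.
#' @param x A `ViralAbundance` (or plain matrix for the matrix method).
#' @export
setMethod("relativeAbundance", "ViralAbundance", function(x) {
  relativeAbundance(SummarizedExperiment::assay(x, "abundance"))
})

#' @describeIn ViralAbundance Matrix method for [relativeAbundance()].
#' @export
setMethod("relativeAbundance", "matrix", function(x) {
  if (any(x < 0, na.rm = TRUE)) .stopf("abundances must be >= 0")
  cs <- colSums(x)
  cs[cs == 0] <- 1  # all-zero column stays all-zero, no 0/0
  sweep(x, 2, cs, "/")
})

setMethod("show", "ViralAbundance", function(object) {
  a <- SummarizedExperiment::assay(object, "abundance")
  cat(sprintf("ViralAbundance: %d population(s) x %d sample(s)\n",
              nrow(a), ncol(a)))
  det <- colSums(a > 0)
  cat(sprintf("  detected populations per sample: %s\n",
              paste(det, collapse = ", ")))
  if ("zone" %in% names(SummarizedExperiment::colData(object)))
    cat(sprintf("  zones: %s\n",
                paste(SummarizedExperiment::colData(object)$zone,
                      collapse = ", ")))
  invisible(NULL)
})

#' ViromeSimulation: a ground-truthed synthetic virome
#'
#' Result container of [simulateVirome()]: simulated contigs, per-sample
#' read alignments, tool-evidence table, sample metadata, and the planted
#' ground truth used as the oracle by downstream tests.
#'
#' @slot contigs A [Biostrings::DNAStringSet] of simulated contigs.
#' @slot alignments `data.frame` of read alignments in PAF field layout.
#' @slot evidence `data.frame` of per-contig tool evidence.
#' @slot samples `data.frame` of sample metadata.
#' @slot truth Named list: `membership` (contig to population),
#'   `abundance` (planted fold-coverage matrix, populations x samples),
#'   `tier` (planted confidence tier per contig), `exclusivity`
#'   (planted habitat-exclusivity class and reference-detection flag
#'   per population).
#' @slot plan The [simulationPlan()] that produced the object.
#'
#' @seealso [simulateVirome()]
#' @export
#' @importClassesFrom Biostrings DNAStringSet
setClass("ViromeSimulation",
         representation(contigs = "DNAStringSet", alignments = "data.frame",
                        evidence = "data.frame", samples = "data.frame",
                        truth = "list", plan = "list"))

setValidity("ViromeSimulation", function(object) {
  tr <- object@truth
  if (!all(c("membership", "abundance", "tier", "exclusivity") %in% names(tr)))
    return("truth must contain membership, abundance, tier, exclusivity")
  if (anyDuplicated(tr$membership$contig_id))
    return("every contig must belong to exactly one truth population")
  if (!setequal(tr$membership$contig_id, names(object@contigs)))
    return("truth membership must cover exactly the simulated contigs")
  TRUE
})

#' @describeIn ViromeSimulation Simulated contigs.
#' @param x,object A `ViromeSimulation`.
#' @export
setMethod("contigs", "ViromeSimulation", function(x) x@contigs)

#' @describeIn ViromeSimulation Simulated read alignments.
#' @export
setMethod("alignments", "ViromeSimulation", function(x) x@alignments)

#' @describeIn ViromeSimulation Simulated tool-evidence table.
#' @export
setMethod("evidence", "ViromeSimulation", function(x) x@evidence)

#' @describeIn ViromeSimulation Sample metadata table.
#' @export
setMethod("sampleTable", "ViromeSimulation", function(x) x@samples)

#' @describeIn ViromeSimulation Planted ground truth (list).
#' @export
setMethod("groundTruth", "ViromeSimulation", function(x) x@truth)

setMethod("show", "ViromeSimulation", function(object) {
  cat(sprintf("ViromeSimulation: %d contig(s) in %d population(s), %d sample(s)\n",
              length(object@contigs),
              length(unique(object@truth$membership$population_id)),
              nrow(object@samples)))
  cat(sprintf("  alignments: %d; seed: %s\n",
              nrow(object@alignments), object@plan$seed))
  invisible(NULL)
})
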