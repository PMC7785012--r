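#' Greedy ANI clustering of contigs into viral populations
#'
#' Implements species-level viral population clustering: contigs larger
#' than `minLength` bp are sorted by length (descending, ties broken by
#' contig id ascending) and scanned greedily; each contig joins the first
#' existing population whose representative it matches at
#' `ANI >= aniThreshold` and aligned fraction of the shorter sequence
#' `>= afThreshold`, otherwise it founds a new population. Because of the
#' scan order, every representative is the longest member of its
#' population (ties lexicographic) and the output partition is invariant
#' to the input ordering.
#'
#' @param contigs A named [Biostrings::DNAStringSet] (or named character
#'   vector) of contigs with unique ids.
#' @param minLength Strict length filter: only contigs with
#'   `length > minLength` are clustered (default 5000, the conventional
#'   population-level cutoff).
#' @param aniThreshold Minimum ANI in percent (inclusive; default 95).
#' @param afThreshold Minimum aligned fraction of the shorter sequence
#'   (inclusive; default 0.80).
#' @param seedLength Seed length passed to [pairwiseANI()].
#' @param method ANI route passed to [pairwiseANI()].
#' @return A [VirPopSet] with populations ordered by representative
#'   length descending.
#' @export
clusterPopulations <- function(contigs, minLength = 5000L,
                               aniThreshold = 95.0, afThreshold = 0.80,
                               seedLength = 15L,
                               method = c("auto", "seed", "dp")) {
  method <- match.arg(method)
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  params <- list(min_length_bp = minLength, ani_threshold = aniThreshold,
                 af_threshold = afThreshold, seed_length = seedLength)
  if (length(contigs) == 0L) return(VirPopSet(data.frame(), params))
  ids <- names(contigs)
  if (is.null(ids) || any(ids == "")) .stopf("all contigs must be named")
  if (anyDuplicated(ids))
    .stopf("duplicate contig id(s): %s",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- Biostrings::width(contigs)
  keep <- lens > minLength
  if (!any(keep)) return(VirPopSet(data.frame(), params))

  ids <- ids[keep]
  lens <- lens[keep]
  seqs <- as.character(contigs[keep])
  ord <- order(-lens, ids)
  ids <- ids[ord]; lens <- lens[ord]; seqs <- seqs[ord]

  rep_idx <- integer(0)              # index into ids of each representative
  assign_pop <- integer(length(ids)) # population index per contig
  ani_rep <- numeric(length(ids))
  af_rep <- numeric(length(ids))
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (p in seq_along(rep_idx)) {
      hit <- pairwiseANI(seqs[i], seqs[rep_idx[p]], seedLength = seedLength,
                         method = method)
      if (hit$ani_percent >= aniThreshold &&
          hit$aligned_fraction_shorter >= afThreshold) {
        assign_pop[i] <- p
        ani_rep[i] <- hit$ani_percent
        af_rep[i] <- hit$aligned_fraction_shorter
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_idx <- c(rep_idx, i)
      assign_pop[i] <- length(rep_idx)
      ani_rep[i] <- 100
      af_rep[i] <- 1
    }
  }
  ## founders appear in length-descending order, so population order
  ## already is representative_length descending
  pop_id <- sprintf("vpop_%03d", seq_along(rep_idx))
  members <- data.frame(
    population_id = pop_id[assign_pop],
    representative_id = ids[rep_idx][assign_pop],
    member_id = ids,
    member_length = lens,
    ani_to_rep = ani_rep,
    af_to_rep = af_rep,
    stringsAsFactors = FALSE)
  ## within each population: representative first, then joiners in scan order
  members <- members[order(match(members$population_id, pop_id),
                           members$member_id != members$representative_id,
                           seq_len(nrow(members))), ]
  rownames(members) <- NULL
  VirPopSet(members, params)
}
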