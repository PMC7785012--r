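## shared fixture builders; everything is generated in code

## partition of contig ids implied by a clustering, as a canonical list
partition_of <- function(popset) {
  m <- memberTable(popset)
  parts <- split(m$member_id, m$population_id)
  unname(lapply(parts, sort))[order(vapply(lapply(parts, sort), `[`, "", 1))]
}

partition_of_truth <- function(truth, ids = NULL) {
  mem <- truth$membership
  if (!is.null(ids)) mem <- mem[mem$contig_id %in% ids, ]
  parts <- split(mem$contig_id, mem$population_id)
  unname(lapply(parts, sort))[order(vapply(lapply(parts, sort), `[`, "", 1))]
}

## VirPopSet straight from simulation ground truth (representative first)
truth_popset <- function(sim) {
  mem <- groundTruth(sim)$membership
  lens <- setNames(Biostrings::width(contigs(sim)), names(contigs(sim)))
  mem <- mem[order(mem$population_id, !mem$is_representative, mem$contig_id), ]
  rep_of <- setNames(
    mem$contig_id[mem$is_representative][
      match(mem$population_id, mem$population_id[mem$is_representative])],
    NULL)
  VirPopSet(data.frame(
    population_id = mem$population_id,
    representative_id = rep_of,
    member_id = mem$contig_id,
    member_length = as.integer(lens[mem$contig_id]),
    ani_to_rep = 100, af_to_rep = 1,
    stringsAsFactors = FALSE))
}

## alignment row in the readPAF() layout
aln_row <- function(contig_id, contig_start, contig_end, read_length = 150L,
                    aligned = read_length, matches = aligned,
                    sample_id = "s1", contig_length = 10000L) {
  data.frame(read_id = sprintf("r_%s_%d", contig_id, contig_start),
             read_length = as.integer(read_length), read_start = 0L,
             read_end = as.integer(aligned), strand = "+",
             contig_id = contig_id, contig_length = as.integer(contig_length),
             contig_start = as.integer(contig_start),
             contig_end = as.integer(contig_end),
             matches = as.integer(matches),
             block_length = as.integer(aligned), mapq = 60L,
             aligned_read_bases = as.integer(aligned), sample_id = sample_id,
             stringsAsFactors = FALSE)
}

## the full evidence grid used by the rule-engine tests
evidence_grid <- function() {
  expand.grid(virsorter_category = c(NA, 1:6),
              virfinder_score = c(NA, 0.5, 0.7, 0.8, 0.9, 0.95),
              cat_viral = c(NA, FALSE, TRUE),
              phaster_prophage = c(NA, FALSE, TRUE),
              KEEP.OUT.ATTRS = FALSE)
}

## independently written tier oracle (plain nested conditions, no shared
## code with the package implementation)
tier_oracle <- function(vs, vf, cat, ph) {
  has_vs <- !is.na(vs); has_vf <- !is.na(vf)
  if (has_vs && (vs == 1 || vs == 2)) return("high")
  if (has_vf && vf > 0.9) return("high")
  if (has_vs && vs >= 4 && vs <= 6 && isTRUE(ph)) return("medium")
  if (has_vs && vs == 3 && has_vf && vf >= 0.7 && vf <= 0.9 && isTRUE(cat))
    return("medium")
  id_vs <- has_vs && vs <= 3
  id_vf <- has_vf && vf >= 0.7
  if ((id_vs && !id_vf) || (id_vf && !id_vs)) return("medium")
  "none"
}

## exhaustive combinatorial oracle for the hypergeometric upper tail
hyper_tail_oracle <- function(shared, na, nb, ntot) {
  k <- shared:min(na, nb)
  sum(choose(na, k) * choose(ntot - na, nb - k)) / choose(ntot, nb)
}


## hand-constructed alignment table spanning the retention boundaries
boundary_alignments <- function() {
  rows <- list(
    aln_row("cA", 0, 1000, read_length = 1000, aligned = 1000, matches = 950),   # 95.0 / 1.00 -> keep
    aln_row("cA", 0, 1000, read_length = 1000, aligned = 1000, matches = 949),   # 94.9        -> drop
    aln_row("cA", 0, 900, read_length = 1000, aligned = 900, matches = 900),     # 100  / 0.90 -> keep
    aln_row("cA", 0, 890, read_length = 1000, aligned = 890, matches = 890),     # 0.89        -> drop
    aln_row("cA", 0, 900, read_length = 1000, aligned = 900, matches = 855),     # 95.0 / 0.90 -> keep
    aln_row("cA", 0, 900, read_length = 1000, aligned = 900, matches = 854),     # 94.89       -> drop
    aln_row("cB", 0, 1000, read_length = 1000, aligned = 1000, matches = 1000),  # keep
    aln_row("cB", 0, 500, read_length = 1000, aligned = 500, matches = 500),     # 0.50        -> drop
    aln_row("cB", 0, 1000, read_length = 1000, aligned = 1000, matches = 990),   # keep
    aln_row("cB", 0, 950, read_length = 1000, aligned = 950, matches = 902),     # 94.95       -> drop
    aln_row("cB", 0, 950, read_length = 1000, aligned = 950, matches = 903),     # 95.05/0.95  -> keep
    aln_row("cB", 0, 1000, read_length = 1000, aligned = 1000, matches = 0))     # drop
  do.call(rbind, rows)
}

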