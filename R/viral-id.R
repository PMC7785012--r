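## Evidence-tier rule engine.
##
## Four virus-detection evidence sources per contig (VirSorter category
## 1-6, VirFinder score in [0,1], CAT viral call, PHASTER prophage call)
## are integrated into high/medium/none confidence tiers:
##
##   high:   VirSorter category 1 or 2, OR VirFinder score > 0.9
##   medium: VirSorter category 4-6 AND PHASTER prophage, OR
##           VirSorter category 3 AND VirFinder in [0.7, 0.9] AND CAT viral, OR
##           exactly one of the two detectors identifies the contig
##           (VirSorter in 1-3, or VirFinder >= 0.7) and no high rule fired
##   none:   otherwise
##
## Rules are evaluated high -> medium in a fixed order; `rule_fired`
## records the first match. Missing evidence (NA) never satisfies a rule.

.classify_vec <- function(vs, vf, cat, phaster) {
  bad_vs <- !is.na(vs) & !(vs %in% 1:6)
  if (any(bad_vs))
    .stopf("virsorter_category outside 1-6 at row %d", which(bad_vs)[1])
  bad_vf <- !is.na(vf) & (vf < 0 | vf > 1)
  if (any(bad_vf))
    .stopf("virfinder_score outside [0,1] at row %d", which(bad_vf)[1])

  vs_high <- !is.na(vs) & vs %in% c(1L, 2L)
  vf_high <- !is.na(vf) & vf > 0.9
  prophage <- !is.na(vs) & vs %in% 4:6 & !is.na(phaster) & phaster
  cat3 <- !is.na(vs) & vs == 3L & !is.na(vf) & vf >= 0.7 & vf <= 0.9 &
    !is.na(cat) & cat
  ident_vs <- !is.na(vs) & vs %in% 1:3
  ident_vf <- !is.na(vf) & vf >= 0.7
  high <- vs_high | vf_high
  single <- xor(ident_vs, ident_vf) & !high

  tier <- rep("none", length(vs))
  rule <- ifelse(is.na(vs) & is.na(vf), "no_evidence", "none")
  hit <- function(cond, t, r) {
    sel <- cond & tier == "none" & rule %in% c("none", "no_evidence")
    tier[sel] <<- t
    rule[sel] <<- r
  }
  hit(vs_high, "high", "virsorter_cat_1_2")
  hit(vf_high, "high", "virfinder_gt_0.9")
  hit(prophage, "medium", "prophage_phaster")
  hit(cat3, "medium", "virsorter3_virfinder_cat")
  hit(single, "medium", "single_detector")
  data.frame(tier = tier, rule_fired = rule, stringsAsFactors = FALSE)
}

#' Classify one contig's tool evidence into a confidence tier
#'
#' Applies the integrated high/medium/none decision rules to a single
#' evidence record. Missing evidence is `NA` and never satisfies a rule;
#' a contig with neither a VirSorter category nor a VirFinder score is
#' `none` with `rule_fired = "no_evidence"`.
#'
#' @param virsorter_category Integer 1-6 or `NA`.
#' @param virfinder_score Number in \[0, 1\] or `NA`.
#' @param cat_viral Logical or `NA` (CAT validates the contig as viral).
#' @param phaster_prophage Logical or `NA` (PHASTER validates a prophage).
#' @return A one-row `data.frame` with `tier` (`"high"`, `"medium"`,
#'   `"none"`) and `rule_fired`.
#' @seealso [classifyContigs()]
#' @export
classifyContig <- function(virsorter_category = NA_integer_,
                           virfinder_score = NA_real_,
                           cat_viral = NA,
                           phaster_prophage = NA) {
  .classify_vec(as.integer(virsorter_category), as.numeric(virfinder_score),
                as.logical(cat_viral), as.logical(phaster_prophage))
}

#' Classify an evidence table into confidence tiers
#'
#' Applies [classifyContig()] to every contig at least `minLength` bp
#' long (shorter contigs are excluded before classification) and returns
#' the per-contig calls plus tier counts.
#'
#' @param evidence `data.frame` with columns `contig_id`,
#'   `virsorter_category`, `virfinder_score`, `cat_viral`,
#'   `phaster_prophage` and (if `minLength > 0`) `contig_length`;
#'   see [readPipelineTable()].
#' @param minLength Minimum contig length in bp retained for
#'   classification (default 1500).
#' @return A list with `calls` (`data.frame`: `contig_id`, `tier`,
#'   `rule_fired`) and `counts` (named integer vector over
#'   high/medium/none).
#' @export
classifyContigs <- function(evidence, minLength = 1500L) {
  if (anyDuplicated(evidence$contig_id))
    .stopf("duplicate contig_id(s) in evidence: %s",
           paste(unique(evidence$contig_id[duplicated(evidence$contig_id)]),
                 collapse = ", "))
  if (minLength > 0) {
    if (!"contig_length" %in% names(evidence))
      .stopf("evidence needs a contig_length column to apply minLength")
    evidence <- evidence[!is.na(evidence$contig_length) &
                           evidence$contig_length >= minLength, , drop = FALSE]
  }
  if (!nrow(evidence)) {
    return(list(calls = data.frame(contig_id = character(),
                                   tier = character(),
                                   rule_fired = character(),
                                   stringsAsFactors = FALSE),
                counts = c(high = 0L, medium = 0L, none = 0L)))
  }
  res <- .classify_vec(evidence$virsorter_category, evidence$virfinder_score,
                       evidence$cat_viral, evidence$phaster_prophage)
  calls <- data.frame(contig_id = evidence$contig_id, res,
                      stringsAsFactors = FALSE)
  counts <- vapply(c("high", "medium", "none"),
                   function(t) sum(calls$tier == t), integer(1))
  list(calls = calls, counts = counts)
}
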