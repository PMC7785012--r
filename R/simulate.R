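#' Default depth-stratified sample table
#'
#' Six virome samples spanning a permanently stratified water column:
#' two oxic (148 m, 200 m), three redoxcline (237, 247, 267 m) and one
#' euxinic (900 m), each with a 100 Mbp read library.
#'
#' @return Sample metadata `data.frame` (`sample_id`, `depth_m`, `zone`,
#'   `metagenome_size_bp`).
#' @export
defaultSampleTable <- function() {
  data.frame(
    sample_id = c("V148", "V200", "V237", "V247", "V267", "V900"),
    depth_m = c(148, 200, 237, 247, 267, 900),
    zone = c("oxic", "oxic", "redoxcline", "redoxcline", "redoxcline",
             "euxinic"),
    metagenome_size_bp = 1e8,
    stringsAsFactors = FALSE)
}

#' Default habitat-exclusivity mix for n populations
#'
#' Assigns exclusivity classes in proportions that mirror a stratified
#' basin community in miniature: mostly cosmopolitan and
#' basin-endemic-but-oxygenated populations, a tail of anoxic-exclusive
#' classes, and one near-undetectable population per ~20.
#'
#' @param n Number of populations.
#' @return Character vector of length `n` over the exclusivity classes.
#' @export
defaultExclusivityPlan <- function(n) {
  props <- c(cosmopolitan = 6, cariaco_only = 7, euxinic_only = 4,
             redoxcline_only = 1, redoxcline_and_euxinic = 1,
             undetectable = 1) / 20
  counts <- floor(props * n)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(props * n - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  rep(names(counts), counts)
}

#' Construct a validated simulation plan
#'
#' Bundles every knob of the synthetic virome generator. The defaults
#' define a miniature depth-stratified study: 20 populations of 3 member
#' contigs each (20 kb genomes, 2% within-population divergence), six
#' zone-stratified samples, log-normal abundances with a planted
#' habitat-exclusivity mix, 150 bp reads at 1% error and 20x mean target
#' depth, and noise-free evidence tables.
#'
#' @param n_populations Number of planted populations.
#' @param genome_length_bp Genome (contig) length in bp.
#' @param intra_divergence Per-site substitution rate of members relative
#'   to their population representative.
#' @param inter_divergence Minimum planted between-population divergence;
#'   representatives are independent random sequences, so realized
#'   inter-population divergence is far above any practical threshold.
#' @param members_per_population Contigs per population (the first member
#'   is the unmutated representative genome).
#' @param samples Sample metadata `data.frame`
#'   (default [defaultSampleTable()]).
#' @param abundance_lognormal_mu,abundance_lognormal_sigma Log-normal
#'   parameters of the planted abundance weights.
#' @param exclusivity_plan Character vector (length `n_populations`) over
#'   `cosmopolitan`, `cariaco_only`, `euxinic_only`, `redoxcline_only`,
#'   `redoxcline_and_euxinic`, `undetectable`
#'   (default [defaultExclusivityPlan()]).
#' @param tier_probs Probabilities of the planted high/medium/none
#'   confidence tiers per contig.
#' @param read_length Read length in bp.
#' @param read_error Per-base error rate (mismatch probability).
#' @param target_depth Mean fold-coverage of detectable populations per
#'   sample.
#' @param evidence_confusion Named probabilities (high/medium/none) that
#'   a contig's evidence is drawn for a wrong tier.
#' @param seed Integer seed; all generator output is a pure function of
#'   the plan including this seed.
#' @return A validated plan (classed list).
#' @export
simulationPlan <- function(n_populations = 20L,
                           genome_length_bp = 20000L,
                           intra_divergence = 0.02,
                           inter_divergence = 0.15,
                           members_per_population = 3L,
                           samples = defaultSampleTable(),
                           abundance_lognormal_mu = 0,
                           abundance_lognormal_sigma = 1,
                           exclusivity_plan = NULL,
                           tier_probs = c(high = 0.6, medium = 0.3,
                                          none = 0.1),
                           read_length = 150L,
                           read_error = 0.01,
                           target_depth = 20,
                           evidence_confusion = c(high = 0, medium = 0,
                                                  none = 0),
                           seed = 1L) {
  if (!(intra_divergence >= 0 && intra_divergence < inter_divergence &&
          inter_divergence <= 1))
    .stopf("need 0 <= intra_divergence < inter_divergence <= 1")
  if (inter_divergence <= 2 * intra_divergence)
    .warnf("inter_divergence <= 2 * intra_divergence: cluster separability not guaranteed")
  stopifnot(n_populations >= 1, members_per_population >= 1,
            genome_length_bp >= read_length,
            read_error >= 0, read_error <= 1,
            abs(sum(tier_probs) - 1) < 1e-8,
            all(tier_probs >= 0),
            all(evidence_confusion >= 0 & evidence_confusion <= 1),
            all(c("high", "medium", "none") %in% names(evidence_confusion)))
  .check_zone(samples$zone)
  if (is.null(exclusivity_plan))
    exclusivity_plan <- defaultExclusivityPlan(n_populations)
  if (length(exclusivity_plan) != n_populations)
    .stopf("exclusivity_plan must have one class per population")
  bad <- setdiff(unique(exclusivity_plan), .exclusivity_classes)
  if (length(bad))
    .stopf("unknown exclusivity class(es): %s", paste(bad, collapse = ", "))
  structure(list(
    n_populations = as.integer(n_populations),
    genome_length_bp = as.integer(genome_length_bp),
    intra_divergence = intra_divergence,
    inter_divergence = inter_divergence,
    members_per_population = as.integer(members_per_population),
    samples = samples,
    abundance_lognormal_mu = abundance_lognormal_mu,
    abundance_lognormal_sigma = abundance_lognormal_sigma,
    exclusivity_plan = exclusivity_plan,
    tier_probs = tier_probs,
    read_length = as.integer(read_length),
    read_error = read_error,
    target_depth = target_depth,
    evidence_confusion = evidence_confusion,
    seed = as.integer(seed)), class = "SimulationPlan")
}

.zones_of_class <- function(class) {
  switch(class,
         cosmopolitan = c("oxic", "redoxcline", "euxinic"),
         cariaco_only = c("oxic", "redoxcline", "euxinic"),
         euxinic_only = "euxinic",
         redoxcline_only = "redoxcline",
         redoxcline_and_euxinic = c("redoxcline", "euxinic"),
         undetectable = c("oxic", "redoxcline", "euxinic"))
}

#' Distribution class a planted exclusivity class should recover as
#'
#' Maps the generator's exclusivity classes onto the labels produced by
#' [classifyDistribution()]; `undetectable` maps to `indeterminate`
#' because such populations never pass the breadth retention rule.
#'
#' @param class Character vector of planted exclusivity classes.
#' @return Character vector of expected [classifyDistribution()] labels.
#' @export
expectedDistributionClass <- function(class) {
  map <- c(cosmopolitan = "cosmopolitan", cariaco_only = "oxygenated_only",
           euxinic_only = "euxinic_only", redoxcline_only = "redoxcline_only",
           redoxcline_and_euxinic = "redoxcline_and_euxinic",
           undetectable = "indeterminate")
  unname(map[class])
}

#' Simulate population genomes with planted ground truth
#'
#' Population representatives are independent uniform random genomes;
#' the first member of each population is the representative itself and
#' the remaining members carry i.i.d. substitutions at
#' `intra_divergence`. Planted per-sample fold-coverages are drawn
#' log-normally for the zones allowed by each population's exclusivity
#' class, scaled so detectable populations average `target_depth`;
#' `undetectable` populations get a fixed `0.05 * target_depth` so their
#' breadth stays below the 75% retention rule. A planted confidence tier
#' is drawn per contig. Deterministic for a fixed plan.
#'
#' @param plan A [simulationPlan()].
#' @return List with `contigs` ([Biostrings::DNAStringSet]) and `truth`
#'   (list: `membership`, `abundance`, `tier`, `exclusivity`).
#' @export
simulateGenomes <- function(plan) {
  stopifnot(inherits(plan, "SimulationPlan"))
  .with_seed(plan$seed + 1L, {
    np <- plan$n_populations
    nm <- plan$members_per_population
    pop_ids <- sprintf("pop_%02d", seq_len(np))
    reps <- vapply(seq_len(np), function(i) randomDNA(plan$genome_length_bp),
                   character(1))
    seqs <- character(np * nm)
    cids <- character(np * nm)
    k <- 0L
    for (p in seq_len(np)) {
      for (m in seq_len(nm)) {
        k <- k + 1L
        cids[k] <- sprintf("%s_m%d", pop_ids[p], m)
        seqs[k] <- if (m == 1L) reps[p] else
          mutateSequence(reps[p], plan$intra_divergence)
      }
    }
    contigs <- Biostrings::DNAStringSet(setNames(seqs, cids))
    membership <- data.frame(
      contig_id = cids,
      population_id = rep(pop_ids, each = nm),
      is_representative = rep(c(TRUE, rep(FALSE, nm - 1L)), np),
      stringsAsFactors = FALSE)

    zones <- plan$samples$zone
    ns <- nrow(plan$samples)
    undet <- plan$exclusivity_plan == "undetectable"
    ab <- matrix(0, nrow = np, ncol = ns,
                 dimnames = list(pop_ids, plan$samples$sample_id))
    for (p in seq_len(np)) {
      allowed <- zones %in% .zones_of_class(plan$exclusivity_plan[p])
      if (undet[p]) {
        ab[p, allowed] <- 0.05 * plan$target_depth
      } else {
        ab[p, allowed] <- rlnorm(sum(allowed), plan$abundance_lognormal_mu,
                                 plan$abundance_lognormal_sigma)
      }
    }
    ## rescale detectable weights so their mean fold-coverage per sample
    ## is target_depth; undetectable rows keep their fixed low coverage
    for (s in seq_len(ns)) {
      w <- ab[!undet, s]
      if (any(w > 0))
        ab[!undet, s] <- plan$target_depth * w / mean(w[w > 0])
    }
    tier <- sample(names(plan$tier_probs), np * nm, replace = TRUE,
                   prob = plan$tier_probs)
    truth <- list(
      membership = membership,
      abundance = ab,
      tier = data.frame(contig_id = cids, tier = tier,
                        stringsAsFactors = FALSE),
      exclusivity = data.frame(
        population_id = pop_ids,
        class = plan$exclusivity_plan,
        reference_detected = plan$exclusivity_plan == "cosmopolitan",
        stringsAsFactors = FALSE))
    list(contigs = contigs, truth = truth)
  })
}

#' Simulate read alignments from planted abundances
#'
#' Emits alignment summaries directly (PAF field layout), bypassing a
#' mapper: reads are placed uniformly along the representative contig of
#' each population, with Poisson read counts matching the planted
#' fold-coverage and binomial per-read match counts at `1 - read_error`.
#' All reads align full length.
#'
#' @param contigs Simulated contigs from [simulateGenomes()].
#' @param truth Ground-truth list from [simulateGenomes()].
#' @param plan The [simulationPlan()].
#' @return Alignment `data.frame` in the layout of [readPAF()].
#' @export
simulateAlignments <- function(contigs, truth, plan) {
  stopifnot(inherits(plan, "SimulationPlan"))
  if (plan$target_depth < 0) .stopf("target_depth must be >= 0")
  rep_of <- truth$membership$contig_id[truth$membership$is_representative]
  names(rep_of) <- truth$membership$population_id[
    truth$membership$is_representative]
  .with_seed(plan$seed + 2L, {
    out <- list()
    rl <- plan$read_length
    for (s in colnames(truth$abundance)) {
      for (p in rownames(truth$abundance)) {
        cov <- truth$abundance[p, s]
        if (cov <= 0) next
        cid <- rep_of[[p]]
        L <- Biostrings::width(contigs)[match(cid, names(contigs))]
        n <- rpois(1L, cov * L / rl)
        if (n == 0L) next
        starts <- sample.int(L - rl + 1L, n, replace = TRUE) - 1L
        matches <- rbinom(n, rl, 1 - plan$read_error)
        out[[length(out) + 1L]] <- data.frame(
          read_id = sprintf("%s_%s_r%06d", s, p, seq_len(n)),
          read_length = rl, read_start = 0L, read_end = rl,
          strand = "+", contig_id = cid, contig_length = L,
          contig_start = starts, contig_end = starts + rl,
          matches = matches, block_length = rl, mapq = 60L,
          aligned_read_bases = rl, sample_id = s,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(out)) {
      return(data.frame(read_id = character(), read_length = integer(),
                        read_start = integer(), read_end = integer(),
                        strand = character(), contig_id = character(),
                        contig_length = integer(), contig_start = integer(),
                        contig_end = integer(), matches = integer(),
                        block_length = integer(), mapq = integer(),
                        aligned_read_bases = integer(),
                        sample_id = character(), stringsAsFactors = FALSE))
    }
    do.call(rbind, out)
  })
}

.evidence_for_tier <- function(tier) {
  ev <- list(virsorter_category = NA_integer_, virfinder_score = NA_real_,
             cat_viral = NA, phaster_prophage = NA)
  if (tier == "high") {
    v <- sample(3L, 1L)
    if (v %in% c(1L, 3L)) ev$virsorter_category <- sample(1:2, 1L)
    if (v %in% c(2L, 3L)) ev$virfinder_score <- runif(1, 0.905, 0.999)
  } else if (tier == "medium") {
    v <- sample(4L, 1L)
    if (v == 1L) {
      ev$virsorter_category <- sample(4:6, 1L)
      ev$phaster_prophage <- TRUE
    } else if (v == 2L) {
      ev$virsorter_category <- 3L
      ev$virfinder_score <- runif(1, 0.70, 0.90)
      ev$cat_viral <- TRUE
    } else if (v == 3L) {
      ev$virsorter_category <- 3L
    } else {
      ev$virfinder_score <- runif(1, 0.70, 0.90)
    }
  } else {
    v <- sample(3L, 1L)
    if (v == 2L) ev$virfinder_score <- runif(1, 0, 0.695)
    if (v == 3L) {
      ev$cat_viral <- FALSE
      ev$phaster_prophage <- FALSE
    }
  }
  ev
}

#' Simulate a tool-evidence table from planted tiers
#'
#' With probability `1 - evidence_confusion[tier]` a contig's evidence is
#' drawn from configurations consistent with its planted tier under the
#' [classifyContig()] rules; otherwise a wrong tier is drawn uniformly
#' from the other two and evidence consistent with it is emitted.
#'
#' @inheritParams simulateAlignments
#' @return Evidence `data.frame` matching the `evidence` schema of
#'   [readPipelineTable()] (with `contig_length`).
#' @export
simulateEvidence <- function(contigs, truth, plan) {
  stopifnot(inherits(plan, "SimulationPlan"))
  .with_seed(plan$seed + 3L, {
    tiers <- c("high", "medium", "none")
    rows <- lapply(seq_along(truth$tier$contig_id), function(i) {
      t_true <- truth$tier$tier[i]
      t_eff <- t_true
      if (runif(1) < plan$evidence_confusion[[t_true]])
        t_eff <- sample(setdiff(tiers, t_true), 1L)
      ev <- .evidence_for_tier(t_eff)
      data.frame(contig_id = truth$tier$contig_id[i],
                 virsorter_category = ev$virsorter_category,
                 virfinder_score = ev$virfinder_score,
                 cat_viral = ev$cat_viral,
                 phaster_prophage = ev$phaster_prophage,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$contig_length <- Biostrings::width(contigs)[
      match(out$contig_id, names(contigs))]
    out
  })
}

#' Simulate a complete ground-truthed virome
#'
#' Runs [simulateGenomes()], [simulateAlignments()] and
#' [simulateEvidence()] under one plan and bundles the results.
#'
#' @param plan A [simulationPlan()].
#' @return A [ViromeSimulation].
#' @export
simulateVirome <- function(plan) {
  g <- simulateGenomes(plan)
  aln <- simulateAlignments(g$contigs, g$truth, plan)
  ev <- simulateEvidence(g$contigs, g$truth, plan)
  new("ViromeSimulation", contigs = g$contigs, alignments = aln,
      evidence = ev, samples = plan$samples, truth = g$truth,
      plan = unclass(plan))
}
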