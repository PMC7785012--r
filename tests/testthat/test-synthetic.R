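test_that("the generator is a pure function of the plan", {
  plan <- simulationPlan(n_populations = 3, genome_length_bp = 2000,
                         members_per_population = 2, target_depth = 4,
                         seed = 701)
  s1 <- simulateVirome(plan)
  s2 <- simulateVirome(plan)
  expect_identical(as.character(contigs(s1)), as.character(contigs(s2)))
  expect_identical(alignments(s1), alignments(s2))
  expect_identical(evidence(s1), evidence(s2))
  expect_identical(groundTruth(s1), groundTruth(s2))
})

test_that("plan validation catches inconsistent divergences and probabilities", {
  expect_error(simulationPlan(intra_divergence = 0.2, inter_divergence = 0.1),
               "intra_divergence")
  expect_warning(simulationPlan(intra_divergence = 0.08,
                                inter_divergence = 0.15, n_populations = 2,
                                members_per_population = 1),
                 "separability")
  expect_error(simulationPlan(read_error = 1.5))
  expect_error(simulationPlan(exclusivity_plan = rep("martian", 20)),
               "exclusivity")
})

test_that("zero intra-divergence makes members identical to their representative", {
  plan <- simulationPlan(n_populations = 3, genome_length_bp = 1000,
                         members_per_population = 3, intra_divergence = 0,
                         read_length = 100, seed = 702)
  g <- simulateGenomes(plan)
  seqs <- as.character(g$contigs)
  for (p in unique(g$truth$membership$population_id)) {
    ids <- g$truth$membership$contig_id[g$truth$membership$population_id == p]
    expect_equal(length(unique(seqs[ids])), 1L)
  }
})

test_that("member divergence tracks the planted substitution rate", {
  plan <- simulationPlan(n_populations = 2, genome_length_bp = 10000,
                         members_per_population = 2, intra_divergence = 0.02,
                         seed = 703)
  g <- simulateGenomes(plan)
  mem <- g$truth$membership
  for (p in unique(mem$population_id)) {
    rep_id <- mem$contig_id[mem$population_id == p & mem$is_representative]
    other <- setdiff(mem$contig_id[mem$population_id == p], rep_id)
    div <- mean(strsplit(as.character(g$contigs[[rep_id]]), "")[[1]] !=
                  strsplit(as.character(g$contigs[[other]]), "")[[1]])
    expect_equal(div, 0.02, tolerance = 0.25)
  }
})

test_that("planted populations are ANI-separable at the clustering threshold", {
  plan <- simulationPlan(n_populations = 4, genome_length_bp = 6000,
                         members_per_population = 2, seed = 704)
  g <- simulateGenomes(plan)
  mem <- g$truth$membership
  reps <- mem$contig_id[mem$is_representative]
  seqs <- as.character(g$contigs)
  intra <- c()
  for (p in unique(mem$population_id)) {
    ids <- mem$contig_id[mem$population_id == p]
    h <- pairwiseANI(seqs[[ids[1]]], seqs[[ids[2]]], method = "seed")
    intra <- c(intra, h$ani_percent)
  }
  inter <- c()
  for (i in 1:(length(reps) - 1)) {
    for (j in (i + 1):length(reps)) {
      h <- pairwiseANI(seqs[[reps[i]]], seqs[[reps[j]]], method = "seed")
      inter <- c(inter, h$ani_percent * h$aligned_fraction_shorter)
    }
  }
  expect_true(min(intra) > 95)
  expect_true(max(inter) < 95)
})

test_that("read totals follow the planted fold-coverage", {
  plan <- simulationPlan(n_populations = 1, genome_length_bp = 10000,
                         members_per_population = 1, target_depth = 50,
                         exclusivity_plan = "cosmopolitan", seed = 705)
  g <- simulateGenomes(plan)
  aln <- simulateAlignments(g$contigs, g$truth, plan)
  per_sample <- tapply(aln$aligned_read_bases, aln$sample_id, sum)
  ## Poisson read count: 3 SD band around 500,000 aligned bases
  sd3 <- 3 * sqrt(50 * 10000 / 150) * 150
  expect_true(all(abs(per_sample - 5e5) < sd3))
  ## no reads are lost between placement and the emitted table
  expect_equal(sum(aln$aligned_read_bases), nrow(aln) * plan$read_length)
  expect_true(all(aln$contig_end <= 10000 & aln$contig_start >= 0))
})

test_that("zero depth and zero error behave degenerately", {
  plan0 <- simulationPlan(n_populations = 2, genome_length_bp = 1000,
                          members_per_population = 1, target_depth = 0,
                          read_length = 100, seed = 706)
  g0 <- simulateGenomes(plan0)
  expect_equal(nrow(simulateAlignments(g0$contigs, g0$truth, plan0)), 0L)
  plan1 <- simulationPlan(n_populations = 2, genome_length_bp = 2000,
                          members_per_population = 1, target_depth = 5,
                          read_error = 0, read_length = 100, seed = 707)
  g1 <- simulateGenomes(plan1)
  a1 <- simulateAlignments(g1$contigs, g1$truth, plan1)
  expect_true(all(a1$matches == a1$aligned_read_bases))
})

test_that("exclusivity classes restrict abundance to their zones", {
  plan <- simulationPlan(
    n_populations = 6, genome_length_bp = 1000, members_per_population = 1,
    read_length = 100,
    exclusivity_plan = c("cosmopolitan", "cariaco_only", "euxinic_only",
                         "redoxcline_only", "redoxcline_and_euxinic",
                         "undetectable"),
    target_depth = 20, seed = 708)
  g <- simulateGenomes(plan)
  ab <- g$truth$abundance
  zones <- plan$samples$zone
  excl <- setNames(g$truth$exclusivity$class, g$truth$exclusivity$population_id)
  for (p in rownames(ab)) {
    detected <- zones[ab[p, ] > 0]
    allowed <- viropop:::.zones_of_class(excl[[p]])
    expect_true(all(detected %in% allowed), info = p)
  }
  ## undetectable populations sit at 5% of the target depth
  undet <- names(excl)[excl == "undetectable"]
  expect_equal(unname(ab[undet, ]), rep(1, 6))
  ## reference detection marks exactly the cosmopolitan class
  expect_equal(g$truth$exclusivity$reference_detected,
               g$truth$exclusivity$class == "cosmopolitan")
})

test_that("undetectable populations fail the breadth rule end-to-end", {
  plan <- simulationPlan(
    n_populations = 4, genome_length_bp = 20000, members_per_population = 1,
    exclusivity_plan = c("cosmopolitan", "cosmopolitan", "cosmopolitan",
                         "undetectable"),
    target_depth = 20, seed = 709)
  sim <- simulateVirome(plan)
  cov <- computeCoverage(alignments(sim), contigs(sim), sampleTable(sim))
  am <- buildAbundanceMatrix(cov, truth_popset(sim), sampleTable(sim))
  a <- SummarizedExperiment::assay(am, "abundance")
  undet <- groundTruth(sim)$exclusivity$population_id[
    groundTruth(sim)$exclusivity$class == "undetectable"]
  expect_true(all(a[undet, ] == 0))
  expect_true(all(a[setdiff(rownames(a), undet), ] > 0))
})
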