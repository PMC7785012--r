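## gene table builder: categories positioned along one contig
gene_table <- function(categories, contig_id = "ctg1",
                       amg_name = "PAPS_reductase") {
  n <- length(categories)
  data.frame(contig_id = contig_id, gene_index = seq_len(n) - 1L,
             start = (seq_len(n) - 1L) * 1000L,
             end = seq_len(n) * 1000L - 100L,
             strand = "+", category = categories,
             amg_name = ifelse(categories == "amg", amg_name, NA_character_),
             stringsAsFactors = FALSE)
}

test_that("an interior AMG with viral flanks but no boundary is high confidence", {
  cats <- rep("unknown", 40)
  cats[21] <- "amg"                 # gene index 20 of 40
  cats[c(18, 19, 23, 25)] <- "viral_like"
  cats[15] <- "viral_hallmark"
  res <- assessAMG(gene_table(cats), amgIndex = 20L)
  expect_equal(res$placement, "interior")
  expect_equal(res$boundary_status, "unbounded")
  expect_equal(res$viral_flank_left, 2L)   # within a 5-gene window
  expect_equal(res$viral_flank_right, 2L)
  expect_equal(res$confidence, "high")
})

test_that("an edge AMG without boundary evidence is low confidence", {
  cats <- rep("viral_like", 40)
  cats[2] <- "amg"                  # gene index 1 of 40
  res <- assessAMG(gene_table(cats, amg_name = "DGC"), amgIndex = 1L)
  expect_equal(res$placement, "edge")
  expect_equal(res$confidence, "low")
  ## a single-gene contig is degenerate: edge, low
  solo <- assessAMG(gene_table("amg", amg_name = "Ack"), amgIndex = 0L)
  expect_equal(solo$placement, "edge")
  expect_equal(solo$confidence, "low")
})

test_that("an att-bounded interior AMG is high confidence", {
  cats <- rep("viral_like", 30)
  cats[15] <- "amg"
  res <- assessAMG(gene_table(cats, amg_name = "Ack"), amgIndex = 14L,
                   boundary = list(attL_coord = 100L, attR_coord = 29000L))
  expect_equal(res$placement, "interior")
  expect_equal(res$boundary_status, "genome_bounded")
  expect_equal(res$confidence, "high")
  ## an edge AMG on a genome-bounded contig is recoverable to medium
  cats2 <- rep("viral_like", 30)
  cats2[1] <- "amg"
  res2 <- assessAMG(gene_table(cats2, amg_name = "Pta"), amgIndex = 0L,
                    boundary = list(attL_coord = 100L, attR_coord = 29000L))
  expect_equal(res2$placement, "edge")
  expect_equal(res2$confidence, "medium")
})

test_that("boundary evidence combines att sites, termini and PHASTER spans", {
  cats <- rep("unknown", 20)
  cats[10] <- "amg"
  g <- gene_table(cats)
  one_att <- assessAMG(g, 9L, boundary = list(attL_coord = 5L))
  expect_equal(one_att$boundary_status, "partial")
  term <- assessAMG(g, 9L, boundary = list(termini_predicted = TRUE))
  expect_equal(term$boundary_status, "genome_bounded")
  ## a PHASTER span excluding the AMG forces edge placement
  outside <- assessAMG(g, 9L,
                       boundary = list(phaster_start = 0L,
                                       phaster_end = 5000L))
  expect_equal(outside$placement, "edge")
  inside <- assessAMG(g, 9L,
                      boundary = list(phaster_start = 0L,
                                      phaster_end = 19900L))
  expect_equal(inside$placement, "interior")
  expect_error(assessAMG(g, 9L, boundary = list(attL_coord = 10L,
                                                attR_coord = 5L)), "attL")
  expect_error(assessAMG(g, 3L), "not annotated")
  expect_error(assessAMG(g, 99L), "not found")
})

test_that("adding a viral gene inside the window never lowers confidence", {
  rank <- c(low = 0, medium = 1, high = 2)
  cats <- rep("unknown", 20)
  cats[10] <- "amg"
  base <- assessAMG(gene_table(cats), 9L)
  for (pos in c(6, 7, 8, 11, 12)) {
    up <- cats
    up[pos] <- "viral_like"
    res <- assessAMG(gene_table(up), 9L)
    expect_gte(rank[[res$confidence]], rank[[base$confidence]])
  }
})

test_that("mirroring the gene order mirrors the flank counts", {
  cats <- rep("unknown", 15)
  cats[6] <- "amg"
  cats[c(3, 4)] <- "viral_like"
  cats[9] <- "viral_hallmark"
  fwd <- assessAMG(gene_table(cats), 5L)
  mir2 <- assessAMG(gene_table(rev(cats)), which(rev(cats) == "amg") - 1L)
  expect_equal(mir2$viral_flank_left, fwd$viral_flank_right)
  expect_equal(mir2$viral_flank_right, fwd$viral_flank_left)
  expect_equal(mir2$placement, fwd$placement)
})

test_that("assessments are deterministic and batch over contigs", {
  cats1 <- rep("viral_like", 12)
  cats1[6] <- "amg"
  cats2 <- rep("unknown", 8)
  cats2[1] <- "amg"
  genes <- rbind(gene_table(cats1, "ctgA", "NifU"),
                 gene_table(cats2, "ctgB", "DGC"))
  bounds <- data.frame(contig_id = "ctgB", attL_coord = 1L,
                       attR_coord = 7900L, termini_predicted = NA,
                       phaster_start = NA_integer_, phaster_end = NA_integer_,
                       stringsAsFactors = FALSE)
  res <- assessAllAMGs(genes, bounds)
  expect_equal(nrow(res), 2L)
  expect_identical(res, assessAllAMGs(genes, bounds))
  expect_equal(res$confidence[res$contig_id == "ctgA"], "high")
  expect_equal(res$confidence[res$contig_id == "ctgB"], "medium")
})

test_that("AMG abundance summaries add distinct populations per AMG name", {
  pops <- VirPopSet(data.frame(
    population_id = c("p1", "p2", "p3"),
    representative_id = c("cA", "cB", "cC"),
    member_id = c("cA", "cB", "cC"),
    member_length = 9000L, ani_to_rep = 100, af_to_rep = 1,
    stringsAsFactors = FALSE))
  m <- matrix(c(10, 30, 60, 0, 0, 0), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  am <- ViralAbundance(m)
  asmt <- data.frame(
    contig_id = c("cA", "cB", "cC", "cC"),
    gene_index = c(5L, 3L, 2L, 7L),
    amg_name = c("PAPS_reductase", "PAPS_reductase", "DGC", "DGC"),
    placement = "interior", viral_flank_left = 1L, viral_flank_right = 1L,
    boundary_status = "unbounded", confidence = "high",
    stringsAsFactors = FALSE)
  tab <- summarizeAMGAbundance(asmt, am, pops)
  expect_equal(tab["PAPS_reductase", "s1"], 0.1 + 0.3)
  ## two AMGs on one population count that population once
  expect_equal(tab["DGC", "s1"], 0.6)
  ## absent sample keeps an explicit zero
  expect_equal(unname(tab[, "s2"]), c(0, 0))
  asmt2 <- rbind(asmt, transform(asmt[1, ], contig_id = "ghost"))
  expect_warning(summarizeAMGAbundance(asmt2, am, pops), "population")
})

test_that("per-gene depth reports reflect local coverage", {
  genes <- gene_table(c("viral_like", "amg", "unknown"))
  aln <- rbind(aln_row("ctg1", 0, 900, read_length = 900,
                       contig_length = 3000),
               aln_row("ctg1", 0, 900, read_length = 900,
                       contig_length = 3000),
               aln_row("ctg1", 1000, 1900, read_length = 900,
                       contig_length = 3000))
  d <- geneRegionMeanDepth(aln, genes)
  expect_equal(d$mean_depth, c(2, 1, 0))
})
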