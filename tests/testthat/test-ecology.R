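test_that("Pielou's evenness matches hand arithmetic", {
  expect_equal(pielouEvenness(c(0.25, 0.25, 0.25, 0.25)), 1.0)
  expect_equal(pielouEvenness(c(0.5, 0.25, 0.25)), 1.039721 / log(3),
               tolerance = 1e-5)
  expect_true(is.na(pielouEvenness(c(1.0))))
  expect_true(is.na(pielouEvenness(c(5, 0, 0))))
  ## renormalization: counts give the same answer as proportions
  expect_equal(pielouEvenness(c(2, 1, 1)), pielouEvenness(c(0.5, 0.25, 0.25)))
  expect_error(pielouEvenness(c(-1, 2)), ">= 0")
  expect_error(pielouEvenness(c(0, 0)), "positive")
})

test_that("jackknife-2 matches the closed form and vegan's estimator", {
  ## S = 10, Q1 = 4, Q2 = 2, n = 6 -> 10 + 4*9/6 - 2*16/30 = 14.9333
  inc <- matrix(0L, 10, 6)
  inc[1:4, 1] <- 1L                       # four singletons
  inc[5:6, 1:2] <- 1L                     # two doubletons
  inc[7:10, 1:3] <- 1L                    # the rest in three samples
  expect_equal(jackknife2Richness(inc), 14.9333, tolerance = 1e-4)
  ## n = 2 with Q2: the (n-2)^2 term vanishes
  inc2 <- matrix(0L, 5, 2)
  inc2[1:2, 1] <- 1L
  inc2[3, 1:2] <- 1L
  inc2[4:5, 1:2] <- 1L
  ## S = 5, Q1 = 2, Q2 = 3 -> 5 + 2*(1/2) - 0 = 6
  expect_equal(jackknife2Richness(inc2), 6.0)
  ## no rare populations: estimate equals observed richness
  expect_equal(jackknife2Richness(matrix(1L, 7, 4)), 7)
  expect_error(jackknife2Richness(matrix(1L, 3, 1)), "2 samples")
  ## independent route: vegan::specpool on random incidence
  withr::local_seed(501)
  for (i in 1:3) {
    r <- matrix(rbinom(60, 1, 0.4), 12, 5)
    r[rowSums(r) == 0, 1] <- 1L
    expect_equal(jackknife2Richness(r),
                 vegan::specpool(t(r))$jack2, tolerance = 1e-8)
  }
})

test_that("accumulation curves are monotone, exact at k = n, and give the detection rate", {
  ## disjoint samples of 10 populations each: exact by symmetry
  inc <- matrix(0L, 30, 3)
  inc[1:10, 1] <- 1L
  inc[11:20, 2] <- 1L
  inc[21:30, 3] <- 1L
  acc <- accumulationCurve(inc, permutations = 50, seed = 5)
  expect_equal(acc$curve$mean_richness, c(10, 20, 30))
  expect_equal(acc$final_step_detection_rate, 1 / 3)
  ## identical samples: flat after k = 1
  same <- matrix(1L, 8, 4)
  acc2 <- accumulationCurve(same, permutations = 20, seed = 5)
  expect_equal(acc2$curve$mean_richness, rep(8, 4))
  expect_equal(acc2$final_step_detection_rate, 0)
  ## random incidence: monotone means, S_obs at the last step
  withr::local_seed(502)
  r <- matrix(rbinom(100, 1, 0.3), 20, 5)
  acc3 <- accumulationCurve(r, permutations = 40, seed = 6)
  expect_true(all(diff(acc3$curve$mean_richness) >= 0))
  expect_equal(acc3$curve$mean_richness[5], sum(rowSums(r) > 0))
  ## deterministic for a fixed seed
  acc4 <- accumulationCurve(r, permutations = 40, seed = 6)
  expect_equal(acc3$curve, acc4$curve)
})

test_that("Bray-Curtis matches hand cases and is a bounded symmetric dissimilarity", {
  m <- cbind(s1 = c(1, 0), s2 = c(1, 2), s3 = c(1, 0), s4 = c(0, 3))
  rownames(m) <- c("p1", "p2")
  d <- brayCurtis(m)
  expect_equal(d["s1", "s3"], 0)          # identical columns
  expect_equal(d["s1", "s4"], 1)          # disjoint support
  expect_equal(d["s1", "s2"], 0.5)        # (0 + 2) / (2 + 2)
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  z <- cbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  expect_warning(dz <- brayCurtis(z), "all-zero")
  expect_true(is.na(dz["a", "b"]))
})

test_that("sample dendrograms merge closest pairs first and keep all leaves", {
  ## Manhattan distances: d(A,B) = 2, d(A,C) = d(B,C) = 10
  m <- cbind(A = c(0, 1), B = c(1, 0), C = c(5, 6))
  hc <- hierarchicalClusterSamples(m)
  expect_equal(sort(hc$hclust$labels[-hc$hclust$merge[1, ]]), c("A", "B"))
  expect_equal(hc$hclust$height[1], 2)
  tr <- ape::read.tree(text = hc$newick)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  ## identical samples merge at height 0
  m2 <- cbind(X = c(1, 2), Y = c(1, 2), Z = c(9, 9))
  expect_equal(hierarchicalClusterSamples(m2)$hclust$height[1], 0)
  expect_error(hierarchicalClusterSamples(m, metric = "chebyshev"))
  expect_error(hierarchicalClusterSamples(m[, 1, drop = FALSE]), "2 samples")
})

test_that("distribution classification follows the zone-set rules and partitions", {
  zones <- c("oxic", "oxic", "redoxcline", "redoxcline", "euxinic")
  m <- rbind(
    eux_only = c(0, 0, 0, 0, 5),
    redox_only = c(0, 0, 2, 1, 0),
    redox_eux = c(0, 0, 3, 0, 1),
    everywhere = c(1, 1, 1, 1, 1),
    oxy_endemic = c(2, 0, 1, 0, 1),
    silent = c(0, 0, 0, 0, 0))
  colnames(m) <- paste0("s", 1:5)
  ref <- c(eux_only = FALSE, redox_only = FALSE, redox_eux = FALSE,
           everywhere = TRUE, oxy_endemic = FALSE, silent = FALSE)
  cls <- classifyDistribution(m, zones, ref)
  got <- setNames(as.character(cls$exclusivity), cls$population_id)
  expect_equal(got[["eux_only"]], "euxinic_only")
  expect_equal(got[["redox_only"]], "redoxcline_only")
  expect_equal(got[["redox_eux"]], "redoxcline_and_euxinic")
  expect_equal(got[["everywhere"]], "cosmopolitan")
  expect_equal(got[["oxy_endemic"]], "oxygenated_only")
  expect_equal(got[["silent"]], "indeterminate")
  expect_equal(setNames(cls$endemic, cls$population_id)[["everywhere"]], FALSE)
  expect_true(all(cls$endemic[cls$population_id != "everywhere"]))
  ## each population gets exactly one label
  expect_equal(nrow(cls), nrow(m))
  expect_false(anyNA(cls$exclusivity))
  ## epsilon turns trace detections into non-detections
  eps <- classifyDistribution(m, zones, ref, epsilon = 1.5)
  got_eps <- setNames(as.character(eps$exclusivity), eps$population_id)
  expect_equal(got_eps[["redox_eux"]], "redoxcline_only")
  expect_equal(got_eps[["everywhere"]], "indeterminate")
  expect_error(classifyDistribution(m, c(zones[-5], "abyssal"), ref),
               "unknown zone")
})

test_that("the diversity report combines richness, Shannon and evenness", {
  m <- cbind(s1 = c(4, 4, 4, 4), s2 = c(10, 0, 0, 0), s3 = c(8, 2, 0, 0))
  rownames(m) <- paste0("p", 1:4)
  rep <- diversityReport(m)
  expect_equal(rep$observed_richness, c(4L, 1L, 2L))
  expect_equal(rep$pielou_j[1], 1)
  expect_true(is.na(rep$pielou_j[2]))
  expect_equal(rep$shannon[3], -(0.8 * log(0.8) + 0.2 * log(0.2)))
  expect_equal(rep$jackknife2[1], jackknife2Richness(m > 0))
})
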