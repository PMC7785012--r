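#' Pielou's evenness of a relative-abundance vector
#'
#' `J = H' / ln(S)` with Shannon entropy `H'` in natural log over the
#' positive entries and `S` the number of positive entries. The input is
#' renormalized internally, so counts or unnormalized abundances are
#' accepted. With fewer than two positive entries evenness is undefined
#' and `NA` is returned (not 0).
#'
#' @param abundances Nonnegative numeric vector with positive sum.
#' @return Evenness in \[0, 1\], or `NA_real_` when `S < 2`.
#' @export
pielouEvenness <- function(abundances) {
  if (any(abundances < 0, na.rm = TRUE)) .stopf("abundances must be >= 0")
  tot <- sum(abundances, na.rm = TRUE)
  if (tot <= 0) .stopf("abundance vector must have a positive sum")
  p <- abundances[!is.na(abundances) & abundances > 0] / tot
  s <- length(p)
  if (s < 2L) return(NA_real_)
  h <- -sum(p * log(p))
  h / log(s)
}

#' Second-order jackknife richness estimate
#'
#' Burnham-Overton second-order jackknife from an incidence matrix:
#' `S_j2 = S_obs + Q1 (2n - 3)/n - Q2 (n - 2)^2 / (n (n - 1))`, where
#' `Q1`/`Q2` count populations occurring in exactly 1/2 samples.
#'
#' @param incidence Logical/0-1 matrix, populations x samples.
#' @return The richness estimate (number).
#' @export
jackknife2Richness <- function(incidence) {
  incidence <- as.matrix(incidence) > 0
  n <- ncol(incidence)
  if (n < 2L) .stopf("jackknife-2 needs at least 2 samples")
  occ <- rowSums(incidence)
  s_obs <- sum(occ > 0)
  q1 <- sum(occ == 1)
  q2 <- sum(occ == 2)
  s_obs + q1 * (2 * n - 3) / n - q2 * (n - 2)^2 / (n * (n - 1))
}

#' Sample accumulation curve with permutations
#'
#' Random-permutation accumulation of populations over samples (the
#' `specaccum(method = "random")` procedure): for each of `permutations`
#' random sample orders, the cumulative richness after each added sample.
#' Also reports the new-population detection rate at the final step: the
#' mean over permutations of the fraction of populations first observed
#' when the last sample is added.
#'
#' @param incidence Logical/0-1 matrix, populations x samples.
#' @param permutations Number of random orderings (default 100).
#' @param seed RNG seed for the permutations.
#' @return A list: `curve` (`data.frame` with `k`, `mean_richness`,
#'   `sd_richness`), `final_step_detection_rate`, and the underlying
#'   `vegan::specaccum` object as `specaccum`.
#' @export
accumulationCurve <- function(incidence, permutations = 100L, seed = 1L) {
  incidence <- as.matrix(incidence) > 0
  n <- ncol(incidence)
  s_obs <- sum(rowSums(incidence) > 0)
  if (n == 1L) {
    return(list(curve = data.frame(k = 1L, mean_richness = s_obs,
                                   sd_richness = 0),
                final_step_detection_rate = 1,
                specaccum = NULL))
  }
  acc <- .with_seed(seed, vegan::specaccum(
    t(incidence) * 1, method = "random", permutations = permutations))
  perm <- acc$perm  # n x permutations richness after each step
  rate <- mean((s_obs - perm[n - 1L, ]) / s_obs)
  list(curve = data.frame(k = seq_len(n), mean_richness = as.numeric(acc$richness),
                          sd_richness = ifelse(is.na(acc$sd), 0, acc$sd)),
       final_step_detection_rate = rate,
       specaccum = acc)
}

#' Bray-Curtis dissimilarities between samples
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over the abundance
#' columns: 0 for identical columns, 1 for disjoint support. Pairs of
#' all-zero columns are undefined and returned as `NA` with a warning.
#'
#' @param abundance Nonnegative matrix, populations x samples, or a
#'   [ViralAbundance].
#' @return Symmetric sample-by-sample dissimilarity matrix.
#' @export
brayCurtis <- function(abundance) {
  if (methods::is(abundance, "ViralAbundance"))
    abundance <- SummarizedExperiment::assay(abundance, "abundance")
  if (any(abundance < 0)) .stopf("abundances must be >= 0")
  d <- as.matrix(suppressWarnings(
    vegan::vegdist(t(abundance), method = "bray")))
  zero <- which(colSums(abundance) == 0)
  if (length(zero) >= 2L) {
    .warnf("Bray-Curtis undefined for %d pair(s) of all-zero samples; set to NA",
           choose(length(zero), 2))
    for (a in zero) for (b in zero) if (a != b) d[a, b] <- NA_real_
  }
  diag(d) <- 0
  d
}

#' Hierarchical clustering of samples with a Newick dendrogram
#'
#' Agglomerative clustering of the abundance columns (default Manhattan
#' distance, average linkage) with the dendrogram exported as a Newick
#' string whose branch lengths reflect merge heights.
#'
#' @param abundance Matrix (populations x samples) or [ViralAbundance];
#'   at least 2 samples.
#' @param metric One of `"manhattan"`, `"euclidean"`.
#' @param linkage One of `"average"`, `"complete"`, `"single"`.
#' @return A list: `hclust` (the [stats::hclust] tree), `newick`
#'   (character), `metric`, `linkage`.
#' @export
hierarchicalClusterSamples <- function(abundance, metric = "manhattan",
                                       linkage = "average") {
  if (methods::is(abundance, "ViralAbundance"))
    abundance <- SummarizedExperiment::assay(abundance, "abundance")
  metric <- match.arg(metric, c("manhattan", "euclidean"))
  linkage <- match.arg(linkage, c("average", "complete", "single"))
  if (ncol(abundance) < 2L) .stopf("need at least 2 samples to cluster")
  hc <- hclust(dist(t(abundance), method = metric), method = linkage)
  list(hclust = hc,
       newick = ape::write.tree(ape::as.phylo(hc)),
       metric = metric, linkage = linkage)
}

#' Per-sample diversity report
#'
#' Observed richness, Shannon entropy (natural log), Pielou's evenness
#' and, for context, the matrix-wide jackknife-2 richness estimate.
#'
#' @param abundance Matrix (populations x samples) or [ViralAbundance].
#' @return `data.frame` with one row per sample: `sample_id`,
#'   `observed_richness`, `shannon`, `pielou_j`, plus the common
#'   `jackknife2` estimate.
#' @export
diversityReport <- function(abundance) {
  if (methods::is(abundance, "ViralAbundance"))
    abundance <- SummarizedExperiment::assay(abundance, "abundance")
  s <- colSums(abundance > 0)
  h <- apply(abundance, 2, function(x) {
    p <- x[x > 0]
    if (!length(p)) return(0)
    p <- p / sum(p)
    -sum(p * log(p))
  })
  j <- ifelse(s >= 2, h / log(pmax(s, 2)), NA_real_)
  jk <- if (ncol(abundance) >= 2) jackknife2Richness(abundance > 0) else NA_real_
  data.frame(sample_id = colnames(abundance), observed_richness = as.integer(s),
             shannon = as.numeric(h), pielou_j = as.numeric(j),
             jackknife2 = jk, stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify population distributions: endemism and habitat exclusivity
#'
#' A population is endemic when it is not detected in the reference
#' (global) virome set. Its habitat-exclusivity class follows from the
#' set of redox zones in which its abundance exceeds `epsilon`:
#' zones containing oxic water give `cosmopolitan` (if also in the
#' reference set) or `oxygenated_only`; `{euxinic}` gives `euxinic_only`;
#' `{redoxcline}` gives `redoxcline_only`; `{redoxcline, euxinic}` gives
#' `redoxcline_and_euxinic`; an empty set (never above `epsilon`
#' anywhere, i.e. near-undetectable) gives `indeterminate`.
#'
#' @param abundance Matrix (populations x samples) or [ViralAbundance]
#'   (zones then default to its `colData`).
#' @param zones Character vector of zones per sample (oxic/redoxcline/
#'   euxinic), recycled from `colData(abundance)$zone` when `NULL`.
#' @param referenceDetected Logical per population (named or in row
#'   order): detected in the reference set? Default `FALSE` for all.
#' @param epsilon Detection threshold on normalized abundance
#'   (default 0: detection = passed the breadth rule).
#' @return `data.frame`: `population_id`, `endemic`, `exclusivity`.
#' @export
classifyDistribution <- function(abundance, zones = NULL,
                                 referenceDetected = NULL, epsilon = 0) {
  if (methods::is(abundance, "ViralAbundance")) {
    if (is.null(zones))
      zones <- SummarizedExperiment::colData(abundance)$zone
    abundance <- SummarizedExperiment::assay(abundance, "abundance")
  }
  if (is.null(zones)) .stopf("zones must be supplied")
  if (length(zones) != ncol(abundance))
    .stopf("need one zone per sample (%d != %d)", length(zones),
           ncol(abundance))
  .check_zone(zones)
  if (any(zones == "unknown")) .stopf("zone 'unknown' cannot be classified")
  stopifnot(epsilon >= 0)
  pops <- rownames(abundance)
  if (is.null(referenceDetected)) {
    referenceDetected <- setNames(rep(FALSE, length(pops)), pops)
  } else if (!is.null(names(referenceDetected))) {
    referenceDetected <- referenceDetected[pops]
    referenceDetected[is.na(referenceDetected)] <- FALSE
  } else if (length(referenceDetected) != length(pops)) {
    .stopf("referenceDetected must have one value per population")
  }
  excl <- character(length(pops))
  for (i in seq_along(pops)) {
    zset <- unique(zones[abundance[i, ] > epsilon])
    excl[i] <- if (!length(zset)) {
      "indeterminate"
    } else if ("oxic" %in% zset) {
      if (isTRUE(referenceDetected[[i]])) "cosmopolitan" else "oxygenated_only"
    } else if (setequal(zset, "euxinic")) {
      "euxinic_only"
    } else if (setequal(zset, "redoxcline")) {
      "redoxcline_only"
    } else {
      "redoxcline_and_euxinic"
    }
  }
  data.frame(population_id = pops,
             endemic = !as.logical(referenceDetected),
             exclusivity = factor(excl, levels = .distribution_classes),
             stringsAsFactors = FALSE, row.names = NULL)
}
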