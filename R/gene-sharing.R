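#' Hypergeometric significance of a shared protein-cluster count
#'
#' Probability, under random draws, that two genomes with `nA` and `nB`
#' protein clusters (PCs) out of `nTotal` share at least `shared` of
#' them: the hypergeometric upper tail
#' `P = sum_{k >= shared} C(nA, k) C(nTotal - nA, nB - k) / C(nTotal, nB)`.
#' The score is `-log10 P`, computed in log space so large PC universes
#' do not overflow.
#'
#' @param shared Number of shared PCs (0 <= shared <= min(nA, nB)).
#' @param nA,nB PC repertoire sizes of the two genomes.
#' @param nTotal Total number of distinct PCs in the dataset.
#' @return The score (nonnegative number; 0 when `shared = 0`).
#' @seealso [buildGeneSharingNetwork()]
#' @export
edgeSignificance <- function(shared, nA, nB, nTotal) {
  stopifnot(length(shared) == 1, length(nA) == 1, length(nB) == 1,
            length(nTotal) == 1)
  if (nA > nTotal || nB > nTotal)
    .stopf("profile sizes cannot exceed nTotal")
  if (shared < 0 || shared > min(nA, nB))
    .stopf("shared must be in [0, min(nA, nB)]")
  if (shared == 0) return(0)
  logp <- phyper(shared - 1, nA, nTotal - nA, nB,
                 lower.tail = FALSE, log.p = TRUE)
  -logp / log(10)
}

#' Build the gene-sharing network over populations
#'
#' Vertices are populations; an undirected weighted edge joins two
#' populations when the [edgeSignificance()] of their shared
#' protein-cluster count reaches `threshold`. The PC universe size is the
#' number of distinct PC ids in `profiles`.
#'
#' @param profiles `data.frame` with columns `population_id`, `pc_id`
#'   (one row per membership; see the `pcs` schema of
#'   [readPipelineTable()]).
#' @param threshold Minimum retained score (default 1.0, i.e.
#'   `P <= 0.1`).
#' @return An [igraph::graph] with all populations as vertices (isolated
#'   ones included) and edge attribute `weight` holding the scores.
#' @export
buildGeneSharingNetwork <- function(profiles, threshold = 1.0) {
  stopifnot(all(c("population_id", "pc_id") %in% names(profiles)))
  pops <- sort(unique(profiles$population_id))
  if (!length(pops))
    return(igraph::make_empty_graph(0, directed = FALSE))
  pcs <- unique(profiles$pc_id)
  inc <- matrix(0L, nrow = length(pops), ncol = length(pcs),
                dimnames = list(pops, pcs))
  inc[cbind(match(profiles$population_id, pops),
            match(profiles$pc_id, pcs))] <- 1L
  shared <- tcrossprod(inc)
  sizes <- rowSums(inc)
  n_total <- length(pcs)
  edges <- NULL
  idx <- which(upper.tri(shared) & shared > 0, arr.ind = TRUE)
  if (nrow(idx)) {
    scores <- vapply(seq_len(nrow(idx)), function(r) {
      i <- idx[r, 1]; j <- idx[r, 2]
      edgeSignificance(shared[i, j], sizes[i], sizes[j], n_total)
    }, numeric(1))
    keep <- scores >= threshold
    if (any(keep))
      edges <- data.frame(from = pops[idx[keep, 1]], to = pops[idx[keep, 2]],
                          weight = scores[keep], stringsAsFactors = FALSE)
  }
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = pops, n_pcs = sizes,
                          stringsAsFactors = FALSE))
}

#' Assign genus-level clusters and statuses from the network
#'
#' Connected components of size >= 2 whose internal edge density reaches
#' `densityMin` become genera. Within an accepted component, nodes with
#' at least `membershipMinEdges` internal edges are `clustered` members;
#' nodes failing the membership rule, or belonging to a component
#' rejected by the density check, are `outliers`; isolated nodes are
#' `singletons`. If membership filtering leaves fewer than two clustered
#' members, the genus is dissolved and its nodes become outliers.
#'
#' @param graph Network from [buildGeneSharingNetwork()].
#' @param membershipMinEdges Minimum internal edges for clustered
#'   membership (default 1).
#' @param densityMin Minimum internal edge density of a genus component
#'   (default 0.5).
#' @return `data.frame`: `population_id`, `genus_id` (`NA` when not
#'   clustered), `status` (`clustered`/`outlier`/`singleton`).
#' @export
assignGenera <- function(graph, membershipMinEdges = 1L, densityMin = 0.5) {
  n <- igraph::vcount(graph)
  if (n == 0L)
    return(data.frame(population_id = character(), genus_id = character(),
                      status = character(), stringsAsFactors = FALSE))
  comp <- igraph::components(graph)
  ids <- igraph::V(graph)$name
  status <- rep("singleton", n)
  genus <- rep(NA_character_, n)
  genus_counter <- 0L
  for (ci in seq_len(comp$no)) {
    nodes <- which(comp$membership == ci)
    if (length(nodes) < 2L) next  # isolated -> singleton
    sub <- igraph::induced_subgraph(graph, nodes)
    dens <- igraph::ecount(sub) / choose(length(nodes), 2)
    deg <- igraph::degree(sub)
    member <- deg >= membershipMinEdges
    if (dens >= densityMin && sum(member) >= 2L) {
      genus_counter <- genus_counter + 1L
      gid <- sprintf("genus_%03d", genus_counter)
      status[nodes[member]] <- "clustered"
      genus[nodes[member]] <- gid
      status[nodes[!member]] <- "outlier"
    } else {
      status[nodes] <- "outlier"
    }
  }
  data.frame(population_id = ids, genus_id = genus,
             status = factor(status,
                             levels = c("clustered", "outlier", "singleton")),
             stringsAsFactors = FALSE, row.names = NULL)
}
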