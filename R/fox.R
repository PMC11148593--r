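#' Detect overlapping modules by approximated weighted community clustering
#'
#' A triangle-based overlapping detector in the spirit of WCC-maximizing
#' algorithms. Because counting exact triangles against every candidate
#' community is expensive, the per-node triangle count with respect to a
#' community is *approximated from the node's in-community (weighted)
#' degree*: with global clustering coefficient \eqn{\gamma}, a node with
#' in-community degree \eqn{k_C} and total degree \eqn{k} is assumed to
#' close \eqn{\gamma k_C (k_C - 1)/2} of its in-community wedges. The
#' resulting per-node score is
#' \deqn{\widehat{wcc}(v, C) = \frac{k_C (k_C - 1)}{k (k - 1)} \cdot
#'   \frac{k}{|C| - 1 + (k - k_C)}}
#' (0 when \eqn{k < 2} or \eqn{|C| = 1}), and a community's score is the
#' mean over its members.
#'
#' Communities are seeded from each node together with its neighborhood,
#' taking nodes in decreasing (weighted) degree order with lexicographic
#' tie-break and skipping nodes already covered. Each seed community then
#' greedily admits the boundary node with the largest gain in community
#' score, as long as that gain exceeds `wcc_threshold`; a node may join
#' several communities, which is what makes the modules overlapping.
#' Duplicate communities are collapsed and communities below `min_size`
#' discarded. The procedure is fully deterministic.
#'
#' This variant is normative for this package: it preserves the
#' degree-based triangle approximation and threshold-gated joining of the
#' published WCC-approximation algorithms but is not a reimplementation of
#' any reference binary.
#'
#' @param network `coexpr_network`.
#' @param params list from [detection_params()]; `wcc_threshold` (default
#'   0.05) gates joining, `min_size` (default 3) filters output.
#' @return `coexpr_modules` tibble; cohesiveness is reported with the
#'   same `penalty` as the cohesiveness detector for comparability.
#' @export
fox_detect <- function(network, params = detection_params()) {
  nodes <- network_nodes(network)
  if (length(nodes) == 0 || nrow(network) == 0) {
    return(modules_tbl(list(), network, params$penalty))
  }
  adj <- adjacency_list(network)
  wd <- weighted_degree(network)
  seed_order <- nodes[order(-wd[nodes], nodes, method = "radix")]

  covered <- character(0)
  comms <- list()
  for (seed in seed_order) {
    if (seed %in% covered) next
    comm <- sort(c(seed, names(adj[[seed]])), method = "radix")
    if (length(comm) < 2) next
    comm <- grow_wcc(comm, adj, wd, params$wcc_threshold)
    comms <- c(comms, list(comm))
    covered <- union(covered, comm)
  }

  comms <- comms[vapply(comms, length, integer(1)) >= params$min_size]
  comms <- unique(comms)
  modules_tbl(comms, network, params$penalty)
}

# mean approximated per-node WCC of community `comm`
wcc_score <- function(comm, adj, wd) {
  if (length(comm) < 2) {
    return(0)
  }
  vals <- vapply(comm, function(v) {
    nb <- adj[[v]]
    k <- wd[[v]]
    k_in <- sum(nb[names(nb) %in% comm])
    if (k < 2 || k_in < 1) {
      return(0)
    }
    closure <- max(0, k_in * (k_in - 1)) / (k * (k - 1))
    reach <- k / (length(comm) - 1 + (k - k_in))
    closure * reach
  }, numeric(1))
  mean(vals)
}

grow_wcc <- function(comm, adj, wd, wcc_threshold) {
  score <- wcc_score(comm, adj, wd)
  repeat {
    boundary <- setdiff(
      unique(unlist(lapply(comm, function(v) names(adj[[v]])),
                    use.names = FALSE)), comm)
    if (length(boundary) == 0) break
    gains <- vapply(boundary, function(v) {
      wcc_score(c(comm, v), adj, wd) - score
    }, numeric(1))
    best <- max(gains)
    if (best <= wcc_threshold) break
    tied <- boundary[gains >= best - 1e-12]
    v <- sort(tied, method = "radix")[1]
    comm <- sort(c(comm, v), method = "radix")
    score <- score + gains[match(v, boundary)]
  }
  comm
}
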