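#' Detect overlapping modules by greedy cohesiveness growth
#'
#' Cohesiveness-based overlapping community detection. Seeds are taken in
#' decreasing weighted-degree order (ties broken lexicographically by node
#' id), skipping vertices already covered by a previously grown group.
#' From each seed a group is grown greedily: at every step the single
#' boundary-vertex addition or internal-vertex removal that most increases
#' the cohesiveness \eqn{f(V) = w_{in}/(w_{in} + w_{bound} + p|V|)} is
#' applied, until no move improves it (a local optimum). Groups smaller
#' than `min_size` or with density below `min_density` are discarded.
#' Highly redundant groups — overlap score \eqn{\omega \ge}
#' `merge_overlap` — are then merged by connected-component union, and the
#' surviving modules are emitted in discovery order with recomputed
#' cohesiveness and density.
#'
#' @param network `coexpr_network` from [read_edge_list()].
#' @param params list from [detection_params()]; `min_density` defaults
#'   to 0.3, `penalty` to 2, `min_size` to 3 and `merge_overlap` to 0.8.
#' @return `coexpr_modules` tibble (`module_id`, `size`, `cohesiveness`,
#'   `density`, list-column `genes`). May be empty.
#' @examples
#' net <- coexpr_network(tibble::tibble(
#'   from = c("a", "a", "b", "c", "c", "d"),
#'   to   = c("b", "c", "c", "d", "e", "e")))
#' cluster_one_detect(net)
#' @export
cluster_one_detect <- function(network, params = detection_params()) {
  nodes <- network_nodes(network)
  if (length(nodes) == 0 || nrow(network) == 0) {
    return(modules_tbl(list(), network, params$penalty))
  }
  adj <- adjacency_list(network)
  wd <- weighted_degree(network)
  seed_order <- nodes[order(-wd[nodes], nodes, method = "radix")]

  covered <- character(0)
  groups <- list()
  for (seed in seed_order) {
    if (seed %in% covered) next
    grp <- grow_cohesive(seed, adj, params$penalty)
    groups <- c(groups, list(grp))
    covered <- union(covered, grp)
  }

  keep <- vapply(groups, function(g) {
    length(g) >= params$min_size &&
      module_density(network, g) >= params$min_density
  }, logical(1))
  groups <- groups[keep]
  if (length(groups) == 0) {
    return(modules_tbl(list(), network, params$penalty))
  }
  merged <- merge_overlapping(groups, params$merge_overlap)
  modules_tbl(merged, network, params$penalty)
}

# Greedy local search maximizing cohesiveness from a singleton seed.
# State tracks w_in and w_bound incrementally; each iteration evaluates
# every boundary addition and every internal removal and applies the
# strict best (ties: additions before removals, then lexicographic id).
grow_cohesive <- function(seed, adj, penalty) {
  mem <- seed
  w_in <- 0
  w_bound <- sum(adj[[seed]])
  f_cur <- cohesive_f(w_in, w_bound, 1, penalty)

  repeat {
    boundary <- setdiff(
      unique(unlist(lapply(mem, function(v) names(adj[[v]])), use.names = FALSE)),
      mem)
    cand_node <- c(boundary, if (length(mem) > 1L) mem)
    cand_kind <- c(rep("add", length(boundary)),
                   rep("remove", if (length(mem) > 1L) length(mem) else 0))
    if (length(cand_node) == 0) break

    cand_f <- vapply(seq_along(cand_node), function(k) {
      v <- cand_node[k]
      nb <- adj[[v]]
      to_in <- sum(nb[names(nb) %in% mem])
      to_out <- sum(nb) - to_in
      if (cand_kind[k] == "add") {
        cohesive_f(w_in + to_in, w_bound - to_in + to_out,
                   length(mem) + 1L, penalty)
      } else {
        cohesive_f(w_in - to_in, w_bound + to_in - to_out,
                   length(mem) - 1L, penalty)
      }
    }, numeric(1))

    best_f <- max(cand_f)
    if (best_f <= f_cur + 1e-12) break
    # deterministic tie-break: additions first, then lexicographic node id
    tied <- which(cand_f >= best_f - 1e-12)
    tied <- tied[order(cand_kind[tied] != "add", cand_node[tied],
                       method = "radix")]
    k <- tied[1]
    v <- cand_node[k]
    nb <- adj[[v]]
    to_in <- sum(nb[names(nb) %in% mem])
    to_out <- sum(nb) - to_in
    if (cand_kind[k] == "add") {
      mem <- c(mem, v)
      w_in <- w_in + to_in
      w_bound <- w_bound - to_in + to_out
    } else {
      mem <- setdiff(mem, v)
      w_in <- w_in - to_in
      w_bound <- w_bound + to_in - to_out
    }
    f_cur <- cand_f[k]
  }
  sort(mem, method = "radix")
}

cohesive_f <- function(w_in, w_bound, n, penalty) {
  denom <- w_in + w_bound + penalty * n
  if (denom <= 0) 0 else w_in / denom
}

# single-pass union of groups whose overlap score reaches the threshold:
# build the overlap graph, take connected components, union each
merge_overlapping <- function(groups, merge_overlap) {
  n <- length(groups)
  if (n <= 1) {
    return(groups)
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (overlap_score(groups[[i]], groups[[j]]) >= merge_overlap) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (r in unique(roots)) {
    out <- c(out, list(sort(unique(unlist(groups[roots == r])),
                            method = "radix")))
  }
  out
}
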