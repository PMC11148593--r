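#' Read a weighted coexpression network from an edge list
#'
#' Builds an undirected simple graph from a TSV edge list
#' `geneA<TAB>geneB<TAB>weight` (weight optional, defaulting to 1).
#' Duplicate pairs are collapsed keeping the maximum weight; self-loops
#' are dropped and rows with nonpositive weight rejected, each with a
#' warning.
#'
#' @param path edge-list TSV without header.
#' @return a `coexpr_network`: tibble of edges (`from`, `to`, `weight`)
#'   with `from < to` lexicographically.
#' @export
read_edge_list <- function(path) {
  # rows may be ragged (the weight column is optional per row)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(coexpr_network(tibble::tibble(from = character(0),
                                         to = character(0),
                                         weight = numeric(0))))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    stop(sprintf("edge list '%s' has row(s) with fewer than 2 columns",
                 path), call. = FALSE)
  }
  w <- vapply(parts, function(x)
    if (length(x) >= 3) suppressWarnings(as.numeric(x[3])) else 1,
    numeric(1))
  w[is.na(w)] <- 1
  edges <- tibble::tibble(from = vapply(parts, `[[`, character(1), 1),
                          to = vapply(parts, `[[`, character(1), 2),
                          weight = w)
  coexpr_network(edges)
}

#' Construct a coexpression network from an edge tibble
#'
#' @param edges tibble with columns `from`, `to` and optionally `weight`.
#' @return `coexpr_network` tibble.
#' @export
coexpr_network <- function(edges) {
  edges <- tibble::as_tibble(edges)
  if (!"weight" %in% names(edges)) edges$weight <- 1
  bad_w <- !is.finite(edges$weight) | edges$weight <= 0
  if (any(bad_w)) {
    warning(sprintf("rejecting %d edge(s) with nonpositive or non-finite weight",
                    sum(bad_w)), call. = FALSE)
    edges <- edges[!bad_w, , drop = FALSE]
  }
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop(s)", sum(loops)), call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges <- tibble::tibble(from = a, to = b, weight = edges$weight)
  if (nrow(edges) > 0) {
    edges <- edges |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(weight = max(.data$weight), .groups = "drop") |>
      dplyr::arrange(.data$from, .data$to)
  }
  structure(edges, class = c("coexpr_network", class(edges)))
}

#' Node ids of a network
#' @param network `coexpr_network`.
#' @return sorted character vector of node ids.
#' @export
network_nodes <- function(network) {
  sort(unique(c(network$from, network$to)), method = "radix")
}

# adjacency as a named list of named numeric weight vectors
adjacency_list <- function(network) {
  nodes <- network_nodes(network)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  if (nrow(network) == 0) {
    return(lapply(adj, function(x) numeric(0)))
  }
  both <- tibble::tibble(
    node = c(network$from, network$to),
    nbr = c(network$to, network$from),
    w = c(network$weight, network$weight)
  )
  sp <- split(both[, c("nbr", "w")], both$node)
  for (nm in names(sp)) {
    adj[[nm]] <- stats::setNames(sp[[nm]]$w, sp[[nm]]$nbr)
  }
  for (nm in nodes) {
    if (is.null(adj[[nm]])) adj[[nm]] <- stats::setNames(numeric(0), character(0))
  }
  adj
}

# weighted degree per node, named numeric
weighted_degree <- function(network) {
  nodes <- network_nodes(network)
  wd <- stats::setNames(rep(0, length(nodes)), nodes)
  if (nrow(network) > 0) {
    s <- rowsum(c(network$weight, network$weight),
                c(network$from, network$to))
    wd[rownames(s)] <- s[, 1]
  }
  wd
}

#' Cohesiveness of a node set
#'
#' The cohesiveness score underlying the greedy detector:
#' \deqn{f(V) = w_{in}(V) / (w_{in}(V) + w_{bound}(V) + p\,|V|)}
#' where \eqn{w_{in}} is the total weight of edges with both ends in `V`,
#' \eqn{w_{bound}} the total weight of edges with exactly one end in `V`,
#' and `p` a per-node penalty modelling unobserved external connections.
#'
#' @param network `coexpr_network`.
#' @param genes nonempty character vector of node ids, all in the network.
#' @param penalty nonnegative per-node penalty `p` (default 2).
#' @return cohesiveness in `[0, 1]`; 0 when the set has no internal edges.
#' @examples
#' net <- coexpr_network(tibble::tibble(from = c("a", "a", "b"),
#'                                      to = c("b", "c", "c")))
#' cohesiveness(net, c("a", "b", "c"), penalty = 0)
#' @export
cohesiveness <- function(network, genes, penalty = 2) {
  if (length(genes) == 0) {
    stop("cohesiveness of an empty gene set is undefined", call. = FALSE)
  }
  stray <- setdiff(genes, network_nodes(network))
  if (length(stray) > 0) {
    stop(sprintf("gene(s) not in the network: %s",
                 paste(utils::head(stray, 3), collapse = ", ")),
         call. = FALSE)
  }
  inA <- network$from %in% genes
  inB <- network$to %in% genes
  w_in <- sum(network$weight[inA & inB])
  w_bound <- sum(network$weight[xor(inA, inB)])
  denom <- w_in + w_bound + penalty * length(genes)
  if (denom == 0) {
    return(0)
  }
  w_in / denom
}

#' Edge density of a module
#'
#' Total internal edge weight over the number of node pairs,
#' `w_in / (|V| (|V|-1) / 2)`. With unit weights this is the usual graph
#' density.
#'
#' @inheritParams cohesiveness
#' @return density in `[0, 1]` for unit-weight simple graphs.
#' @export
module_density <- function(network, genes) {
  if (length(genes) < 2) {
    stop("module density requires at least 2 genes", call. = FALSE)
  }
  inA <- network$from %in% genes
  inB <- network$to %in% genes
  w_in <- sum(network$weight[inA & inB])
  w_in / (length(genes) * (length(genes) - 1) / 2)
}

#' Overlap score between two node sets
#'
#' The match coefficient \eqn{\omega(A,B) = |A \cap B|^2 / (|A||B|)} used
#' to decide whether two grown groups describe the same module.
#'
#' @param a,b nonempty character vectors.
#' @return overlap score in `[0, 1]`.
#' @export
overlap_score <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("overlap score of an empty set is undefined", call. = FALSE)
  }
  a <- unique(a)
  b <- unique(b)
  length(intersect(a, b))^2 / (length(a) * length(b))
}

#' Default module-detection parameters
#'
#' @param min_density minimum module density for emission (default 0.3).
#' @param penalty cohesiveness node penalty `p` (default 2).
#' @param min_size minimum module size (default 3).
#' @param merge_overlap overlap score at or above which grown groups are
#'   merged (default 0.8).
#' @param wcc_threshold join gate for the triangle-approximation detector
#'   (default 0.05).
#' @return named list of parameters.
#' @export
detection_params <- function(min_density = 0.3, penalty = 2, min_size = 3,
                             merge_overlap = 0.8, wcc_threshold = 0.05) {
  stopifnot(penalty >= 0, min_density >= 0, min_density <= 1,
            min_size >= 2, merge_overlap > 0, merge_overlap <= 1)
  list(min_density = min_density, penalty = penalty, min_size = min_size,
       merge_overlap = merge_overlap, wcc_threshold = wcc_threshold)
}

# package a list of gene sets into the module result tibble
modules_tbl <- function(gene_sets, network, penalty) {
  if (length(gene_sets) == 0) {
    out <- tibble::tibble(module_id = integer(0), size = integer(0),
                          cohesiveness = numeric(0), density = numeric(0),
                          genes = list())
  } else {
    out <- tibble::tibble(
      module_id = seq_along(gene_sets),
      size = vapply(gene_sets, length, integer(1)),
      cohesiveness = vapply(gene_sets, function(g)
        cohesiveness(network, g, penalty), numeric(1)),
      density = vapply(gene_sets, function(g)
        module_density(network, g), numeric(1)),
      genes = lapply(gene_sets, function(g) sort(g, method = "radix"))
    )
  }
  structure(out, class = c("coexpr_modules", class(out)))
}

#' Long-format module membership
#'
#' @param x `coexpr_modules` tibble from [cluster_one_detect()] or
#'   [fox_detect()].
#' @param ... unused.
#' @return tibble with one row per (module_id, gene_id) membership.
#' @method tidy coexpr_modules
#' @export
tidy.coexpr_modules <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble::tibble(module_id = integer(0), gene_id = character(0)))
  }
  tidyr::unnest(
    tibble::tibble(module_id = x$module_id, gene_id = x$genes),
    "gene_id")
}

#' @method glance coexpr_modules
#' @export
glance.coexpr_modules <- function(x, ...) {
  tibble::tibble(
    n_modules = nrow(x),
    n_genes_covered = length(unique(unlist(x$genes))),
    mean_size = if (nrow(x)) mean(x$size) else NA_real_,
    mean_density = if (nrow(x)) mean(x$density) else NA_real_
  )
}

#' Size/density overview of detected modules
#'
#' @param object `coexpr_modules`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot coexpr_modules
#' @export
autoplot.coexpr_modules <- function(object, ...) {
  d <- tibble::as_tibble(object)[, c("size", "density", "cohesiveness")]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$size, y = .data$density,
                                  colour = .data$cohesiveness)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "module size (genes)", y = "module density",
                  title = "Detected coexpression modules") +
    ggplot2::theme_minimal()
}
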