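#' One-tailed Fisher exact test (enrichment direction)
#'
#' Upper-tail probability of the 2x2 table
#' \tabular{lcc}{
#'             \tab implicated \tab not implicated \cr
#' in unit     \tab `a`        \tab `b` \cr
#' not in unit \tab `c`        \tab `d`
#' }
#' i.e. \eqn{P(X \ge a)} for
#' \eqn{X \sim \mathrm{Hypergeom}(N = a+b+c+d,\ K = a+c,\ n = a+b)}.
#' The tail is summed exactly in log space (via `lchoose` and
#' log-sum-exp), which keeps the result stable for large counts.
#' Vectorized over tables.
#'
#' @param a,b,c,d nonnegative integer counts.
#' @return p-values in `(0, 1]`.
#' @examples
#' fisher_exact_greater(3, 7, 2, 38)
#' @export
fisher_exact_greater <- function(a, b, c, d) {
  counts <- cbind(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency counts must be nonnegative integers", call. = FALSE)
  }
  vapply(seq_len(nrow(counts)), function(i) {
    a <- counts[i, 1]; b <- counts[i, 2]; c <- counts[i, 3]; d <- counts[i, 4]
    N <- a + b + c + d
    K <- a + c          # implicated genes in the background
    n <- a + b          # genes in the unit being tested
    if (N == 0 || a == 0) {
      return(1)
    }
    ks <- a:min(K, n)
    if (length(ks) == 0) {
      return(1)
    }
    logp <- lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)
    m <- max(logp)
    min(1, exp(m + log(sum(exp(logp - m)))))
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR control: sort p-values ascending, multiply the i-th by
#' `m/i`, enforce monotonicity from the largest down, cap at 1 and return
#' in the original input order. Delegates to [stats::p.adjust()] with
#' `method = "BH"` after validating the input.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) {
    return(numeric(0))
  }
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Module enrichment in GWAS/QTL-implicated genes
#'
#' Tests every detected module for overrepresentation of the implicated
#' genes. The background gene set is the union of genes across all
#' detected modules; implicated genes outside that background are dropped
#' (their count is reported via a message) rather than added, since
#' adding them would break the 2x2 marginal structure. Each module gets a
#' one-tailed Fisher exact test and Benjamini-Hochberg adjustment across
#' all modules; a module is enriched when its adjusted p-value is below
#' `alpha`.
#'
#' @param modules `coexpr_modules` tibble.
#' @param implicated character vector of implicated gene ids.
#' @param alpha enrichment significance level on the adjusted p (default
#'   0.05).
#' @return an `enrichment_result` tibble with columns `unit_id`, `a`,
#'   `b`, `c`, `d`, `p_raw`, `p_adj`, `enriched`.
#' @export
enrich_modules <- function(modules, implicated, alpha = 0.05) {
  if (nrow(modules) == 0) {
    stop("no modules to test", call. = FALSE)
  }
  background <- sort(unique(unlist(modules$genes)), method = "radix")
  implicated <- unique(implicated)
  outside <- setdiff(implicated, background)
  if (length(outside) > 0) {
    message(sprintf("%d implicated gene(s) outside the module background dropped",
                    length(outside)))
  }
  implicated <- intersect(implicated, background)
  N <- length(background)
  K <- length(implicated)
  tab <- purrr::map_dfr(seq_len(nrow(modules)), function(i) {
    g <- modules$genes[[i]]
    a <- length(intersect(g, implicated))
    b <- length(g) - a
    tibble::tibble(unit_id = as.character(modules$module_id[i]),
                   a = a, b = b, c = K - a, d = N - K - b)
  })
  finish_enrichment(tab, alpha)
}

finish_enrichment <- function(tab, alpha) {
  tab$p_raw <- fisher_exact_greater(tab$a, tab$b, tab$c, tab$d)
  tab$p_adj <- bh_adjust(tab$p_raw)
  tab$enriched <- tab$p_adj < alpha
  structure(tab, class = c("enrichment_result", class(tab)))
}

#' Read GMT-style annotation gene sets
#'
#' One term per line: `term_id<TAB>description<TAB>gene1,gene2,...`.
#'
#' @param path annotation TSV.
#' @param namespace label for the annotation family (e.g. `"GO"`, `"TO"`,
#'   `"PO"`, `"pathway"`); recorded on every term.
#' @return tibble with columns `term_id`, `description`, `namespace` and
#'   list-column `genes`.
#' @export
read_gmt <- function(path, namespace = "GO") {
  raw <- readr::read_tsv(path, col_names = c("term_id", "description",
                                             "genes"),
                         col_types = "ccc", progress = FALSE)
  genes <- stringr::str_split(raw$genes, ",")
  genes <- lapply(genes, function(g) sort(unique(g[nzchar(g)]),
                                          method = "radix"))
  if (any(lengths(genes) == 0)) {
    stop(sprintf("term(s) with empty gene set in '%s'", path), call. = FALSE)
  }
  tibble::tibble(term_id = raw$term_id, description = raw$description,
                 namespace = namespace, genes = genes)
}

#' Overrepresentation analysis against annotation terms
#'
#' Hypergeometric (one-tailed Fisher) overrepresentation of a query gene
#' set in each annotation term, against an explicit background
#' ("gene universe"). Term gene sets are restricted to the background;
#' terms sharing no gene with the query are excluded from testing.
#' Benjamini-Hochberg adjustment is applied within each namespace
#' separately.
#'
#' @param query character vector of gene ids, must be a subset of
#'   `background`.
#' @param annotations term tibble from [read_gmt()].
#' @param background character vector: the gene universe.
#' @param alpha adjusted-p enrichment threshold (default 0.05).
#' @return `enrichment_result` tibble with columns `unit_id`,
#'   `description`, `namespace`, `a`, `b`, `c`, `d`, `p_raw`, `p_adj`,
#'   `enriched`, sorted by `(namespace, p_adj, unit_id)`.
#' @export
ora <- function(query, annotations, background, alpha = 0.05) {
  query <- unique(query)
  background <- unique(background)
  stray <- setdiff(query, background)
  if (length(stray) > 0) {
    stop(sprintf("query gene(s) outside the background: %s",
                 paste(utils::head(stray, 5), collapse = ", ")),
         call. = FALSE)
  }
  N <- length(background)
  K <- length(query)
  tab <- purrr::map_dfr(seq_len(nrow(annotations)), function(i) {
    term_genes <- intersect(annotations$genes[[i]], background)
    a <- length(intersect(term_genes, query))
    if (a == 0) {
      return(NULL)
    }
    tibble::tibble(unit_id = annotations$term_id[i],
                   description = annotations$description[i],
                   namespace = annotations$namespace[i],
                   a = a, b = length(term_genes) - a, c = K - a,
                   d = N - K - (length(term_genes) - a))
  })
  if (is.null(tab) || nrow(tab) == 0) {
    out <- tibble::tibble(unit_id = character(0), description = character(0),
                          namespace = character(0), a = integer(0),
                          b = integer(0), c = integer(0), d = integer(0),
                          p_raw = numeric(0), p_adj = numeric(0),
                          enriched = logical(0))
    return(structure(out, class = c("enrichment_result", class(out))))
  }
  tab$p_raw <- fisher_exact_greater(tab$a, tab$b, tab$c, tab$d)
  tab <- tab |>
    dplyr::group_by(.data$namespace) |>
    dplyr::mutate(p_adj = bh_adjust(.data$p_raw)) |>
    dplyr::ungroup() |>
    dplyr::mutate(enriched = .data$p_adj < alpha) |>
    dplyr::arrange(.data$namespace, .data$p_adj, .data$unit_id)
  structure(tab, class = c("enrichment_result", class(tab)))
}

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(n_tested = nrow(x), n_enriched = sum(x$enriched),
                 min_p_adj = if (nrow(x)) min(x$p_adj) else NA_real_)
}

#' Bar chart of the most enriched units
#'
#' @param object `enrichment_result`.
#' @param n_top number of units to display (default 15).
#' @param ... unused.
#' @return a ggplot of `-log10(p_adj)` per unit.
#' @method autoplot enrichment_result
#' @export
autoplot.enrichment_result <- function(object, n_top = 15, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::arrange(.data$p_adj) |>
    utils::head(n_top)
  d$unit_id <- factor(d$unit_id, levels = rev(unique(d$unit_id)))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p_adj),
                                  y = .data$unit_id,
                                  fill = .data$enriched)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10](adjusted~italic(p))), y = NULL,
                  title = "Enrichment results") +
    ggplot2::theme_minimal()
}
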