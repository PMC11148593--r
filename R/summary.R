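#' Per-gene prioritization summary
#'
#' Aggregates all analyses into one row per candidate gene:
#'
#' * `n_pathways` — pathways whose gene set contains the gene;
#' * `n_module_terms` — ontology terms and pathways enriched in *any*
#'   module containing the gene, deduplicated by term id so a term shared
#'   by two of the gene's modules is counted once;
#' * `n_articles` — abstracts mentioning the gene;
#' * `module_ids` — comma-separated ids of the modules containing it;
#' * `in_lifted_target` — whether an ortholog of the gene lies inside the
#'   lifted target intervals (`common` category of the comparison), when
#'   a comparison is supplied.
#'
#' @param genes gene-model tibble of candidate genes (from
#'   [genes_overlapping()]).
#' @param modules `coexpr_modules` tibble.
#' @param module_ora named list (by module id, as character) of
#'   [ora()] results per module, or `NULL`.
#' @param pathways pathway term tibble from [read_gmt()], or `NULL`.
#' @param literature tibble from [literature_for_genes()], or `NULL`.
#' @param comparison `pangenome_comparison` from [liftover_gene_sets()],
#'   or `NULL`.
#' @return a `gene_summary` tibble, one row per gene in `genes`, sorted
#'   by `(chrom, start)`.
#' @export
build_summary <- function(genes, modules, module_ora = NULL,
                          pathways = NULL, literature = NULL,
                          comparison = NULL) {
  membership <- tidy(modules)
  if (!is.null(literature)) {
    missing_genes <- setdiff(genes$gene_id, literature$gene_id)
    if (length(missing_genes) > 0) {
      stop(sprintf("literature table lacks %d candidate gene(s); inputs must come from the same run",
                   length(missing_genes)), call. = FALSE)
    }
  }
  rows <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes$gene_id[i]
    mods <- membership$module_id[membership$gene_id == g]
    n_pathways <- if (is.null(pathways)) 0L else
      sum(vapply(pathways$genes, function(s) g %in% s, logical(1)))
    terms <- character(0)
    if (!is.null(module_ora) && length(mods) > 0) {
      for (m in as.character(mods)) {
        res <- module_ora[[m]]
        if (!is.null(res) && nrow(res) > 0) {
          terms <- c(terms, res$unit_id[res$enriched])
        }
      }
    }
    n_articles <- if (is.null(literature)) 0L else
      literature$n_articles[match(g, literature$gene_id)]
    in_target <- if (is.null(comparison)) NA else
      g %in% comparison$common$src_gene
    tibble::tibble(
      gene_id = g,
      chrom = genes$chrom[i],
      start = genes$start[i],
      end = genes$end[i],
      n_modules = length(mods),
      module_ids = paste(sort(unique(mods)), collapse = ","),
      n_pathways = as.integer(n_pathways),
      n_module_terms = length(unique(terms)),
      n_articles = as.integer(n_articles),
      in_lifted_target = in_target
    )
  })
  ord <- order(norm_chrom(rows$chrom), rows$start, rows$gene_id,
               method = "radix")
  out <- rows[ord, , drop = FALSE]
  structure(out, class = c("gene_summary", class(out)))
}

#' Multi-column stable sort of a summary table
#'
#' @param rows summary tibble.
#' @param keys list of `c(column, direction)` pairs, applied
#'   lexicographically; direction is `"asc"` or `"desc"`. An empty list
#'   preserves the input order.
#' @return the same rows, reordered; the sort is stable (equal keys keep
#'   input order).
#' @examples
#' \dontrun{
#' sort_summary(rows, list(c("n_module_terms", "desc"), c("gene_id", "asc")))
#' }
#' @export
sort_summary <- function(rows, keys = list()) {
  if (length(keys) == 0 || nrow(rows) <= 1) {
    return(rows)
  }
  cols <- vapply(keys, `[[`, character(1), 1)
  dirs <- vapply(keys, function(k) {
    if (length(k) >= 2) k[[2]] else "asc"
  }, character(1))
  unknown <- setdiff(cols, names(rows))
  if (length(unknown) > 0) {
    stop(sprintf("unknown sort column(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (!all(dirs %in% c("asc", "desc"))) {
    stop("sort direction must be 'asc' or 'desc'", call. = FALSE)
  }
  args <- purrr::map2(cols, dirs, function(col, dir) {
    v <- rows[[col]]
    if (dir == "desc") {
      if (is.numeric(v) || is.logical(v)) -xtfrm(v) else
        -xtfrm(factor(v, levels = sort(unique(v), method = "radix")))
    } else {
      xtfrm(if (is.character(v)) factor(v, levels = sort(unique(v),
                                                         method = "radix"))
            else v)
    }
  })
  ord <- do.call(order, c(args, list(method = "radix")))
  rows[ord, , drop = FALSE]
}

#' @method glance gene_summary
#' @export
glance.gene_summary <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_in_modules = sum(x$n_modules > 0),
    n_with_literature = sum(x$n_articles > 0),
    total_articles = sum(x$n_articles)
  )
}

#' Candidate-gene overview plot
#'
#' @param object `gene_summary`.
#' @param ... unused.
#' @return a ggplot ranking genes by enriched module terms and articles.
#' @method autoplot gene_summary
#' @export
autoplot.gene_summary <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$gene_id <- factor(d$gene_id,
                      levels = d$gene_id[order(d$n_module_terms,
                                               d$n_articles)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_module_terms,
                                  y = .data$gene_id,
                                  size = .data$n_articles,
                                  colour = .data$n_modules > 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "enriched terms over containing modules",
                  y = NULL, size = "articles", colour = "in a module",
                  title = "Candidate gene prioritization") +
    ggplot2::theme_minimal()
}
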