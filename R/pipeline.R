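#' Read a pipeline configuration file
#'
#' YAML key-value file naming all inputs and parameters of
#' [run_pipeline()]. Relative file paths are resolved against the
#' config file's directory.
#'
#' @param path YAML file.
#' @return named list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  file_keys <- c("src_gff", "tgt_gff", "alignment", "orthologs", "network",
                 "go_terms", "pathways", "tfbs_dir", "text_annotations",
                 "chrom_sizes", "regions_file", "out_dir")
  for (k in intersect(file_keys, names(cfg))) {
    if (!grepl("^/", cfg[[k]])) cfg[[k]] <- file.path(base, cfg[[k]])
  }
  cfg
}

#' Run the full prioritization pipeline
#'
#' Orchestrates genes -> lift-over -> module detection -> module
#' enrichment -> per-module overrepresentation -> binding-site
#' enrichment -> literature lookup -> per-gene summary. Any analysis
#' whose inputs are not configured is skipped and the summary degrades
#' gracefully.
#'
#' When a lift-over is configured, target-interval genes whose source
#' ortholog lies *outside* the input loci contribute those source
#' orthologs to the implicated gene set before module enrichment —
#' candidates that a single-reference analysis would have missed.
#'
#' @param config named list (see [read_pipeline_config()]) with keys:
#'   `regions` (character vector of region strings) or `regions_file`;
#'   `src_gff`, `source_genome`; optionally `tgt_gff`, `target_genome`,
#'   `alignment`, `orthologs`; `network`, `algo`
#'   (`"clusterone"`/`"fox"`), detection parameters (`min_density`,
#'   `penalty`, `min_size`, `merge_overlap`, `wcc_threshold`);
#'   `go_terms`, `pathways`; `tfbs_dir`, `chrom_sizes`, `n_perm`;
#'   `text_annotations`; `seed`; `alpha`; optionally `out_dir` to write
#'   TSV reports.
#' @param verbose log progress to stderr.
#' @return list with elements `candidates`, `comparison`, `modules`,
#'   `module_enrichment`, `module_ora`, `tfbs`, `literature`, `summary`,
#'   `implicated`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- as.integer(config$seed %||% 1)
  alpha <- config$alpha %||% 0.05
  src_genome <- config$source_genome %||% "source"

  regions <- if (!is.null(config$regions_file)) {
    readLines(config$regions_file)
  } else {
    config$regions
  }
  loci <- parse_region(regions, genome = src_genome)
  say("parsed %d region(s)", nrow(loci))

  src_genes <- read_gff3(config$src_gff, src_genome)
  candidates <- genes_overlapping(loci, src_genes)
  say("%d candidate gene(s) overlap the loci", nrow(candidates))
  implicated <- candidates$gene_id

  comparison <- NULL
  if (!is.null(config$tgt_gff) && !is.null(config$alignment)) {
    tgt_genome <- config$target_genome %||% "target"
    tgt_genes <- read_gff3(config$tgt_gff, tgt_genome)
    aln <- read_alignments(config$alignment, src_genome, tgt_genome)
    orthology <- read_orthologs(config$orthologs)
    comparison <- liftover_gene_sets(loci, src_genes, tgt_genes, aln,
                                     orthology)
    # source orthologs of target genes whose ortholog lies outside the
    # loci join the implicated set for the downstream network analyses
    extra <- unlist(lapply(comparison$ortholog_elsewhere$tgt_gene,
                           function(tg) orthologs_of(orthology, tg,
                                                     src_genome)))
    extra <- sort(unique(extra), method = "radix")
    say("lift-over adds %d source ortholog(s) outside the loci",
        length(extra))
    implicated <- sort(union(implicated, extra), method = "radix")
  }

  modules <- NULL
  module_enrichment <- NULL
  module_ora <- NULL
  annotations <- NULL
  pathways_tbl <- NULL
  if (!is.null(config$network)) {
    network <- read_edge_list(config$network)
    params <- detection_params(
      min_density = config$min_density %||% 0.3,
      penalty = config$penalty %||% 2,
      min_size = config$min_size %||% 3,
      merge_overlap = config$merge_overlap %||% 0.8,
      wcc_threshold = config$wcc_threshold %||% 0.05)
    algo <- config$algo %||% "clusterone"
    modules <- switch(algo,
                      clusterone = cluster_one_detect(network, params),
                      fox = fox_detect(network, params),
                      stop(sprintf("unknown detection algorithm '%s'", algo),
                           call. = FALSE))
    say("%s detected %d module(s)", algo, nrow(modules))
    if (nrow(modules) > 0) {
      module_enrichment <- suppressMessages(
        enrich_modules(modules, implicated, alpha = alpha))
      say("%d module(s) enriched", sum(module_enrichment$enriched))
    }

    ann_parts <- list()
    if (!is.null(config$go_terms)) {
      ann_parts <- c(ann_parts, list(read_gmt(config$go_terms, "GO")))
    }
    if (!is.null(config$pathways)) {
      pathways_tbl <- read_gmt(config$pathways, "pathway")
      ann_parts <- c(ann_parts, list(pathways_tbl))
    }
    if (length(ann_parts) > 0 && !is.null(modules) && nrow(modules) > 0) {
      annotations <- dplyr::bind_rows(ann_parts)
      annotated <- unique(unlist(annotations$genes))
      background <- intersect(network_nodes(network), annotated)
      module_ora <- list()
      for (i in seq_len(nrow(modules))) {
        q <- intersect(modules$genes[[i]], background)
        if (length(q) == 0) next
        module_ora[[as.character(modules$module_id[i])]] <-
          ora(q, annotations, background, alpha = alpha)
      }
    }
  }

  tfbs_res <- NULL
  if (!is.null(config$tfbs_dir)) {
    tfbs <- read_tfbs(config$tfbs_dir, src_genome)
    sizes <- read_chrom_sizes(config$chrom_sizes)
    tfbs_res <- tfbs_enrichment(loci, tfbs, sizes,
                                n_perm = config$n_perm %||% 1000,
                                seed = seed, alpha = alpha)
    say("tested %d TF(s) for binding-site overlap", nrow(tfbs_res))
  }

  literature <- NULL
  if (!is.null(config$text_annotations)) {
    index <- read_annotations(config$text_annotations)
    literature <- literature_for_genes(index, candidates$gene_id)
  }

  summary_tbl <- build_summary(
    candidates,
    modules %||% modules_empty(),
    module_ora = module_ora,
    pathways = pathways_tbl,
    literature = literature,
    comparison = comparison)
  summary_tbl <- sort_summary(summary_tbl,
                              list(c("n_module_terms", "desc"),
                                   c("n_articles", "desc"),
                                   c("gene_id", "asc")))

  out <- list(candidates = candidates, comparison = comparison,
              modules = modules, module_enrichment = module_enrichment,
              module_ora = module_ora, tfbs = tfbs_res,
              literature = literature, summary = summary_tbl,
              implicated = implicated)
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(out, config$out_dir)
    say("reports written under %s", config$out_dir)
  }
  out
}

modules_empty <- function() {
  structure(tibble::tibble(module_id = integer(0), size = integer(0),
                           cohesiveness = numeric(0), density = numeric(0),
                           genes = list()),
            class = c("coexpr_modules", "tbl_df", "tbl", "data.frame"))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tibble::as_tibble(res$summary),
                   file.path(out_dir, "summary.tsv"))
  jsonlite::write_json(tibble::as_tibble(res$summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(res$modules) && nrow(res$modules) > 0) {
    readr::write_tsv(tidy(res$modules),
                     file.path(out_dir, "module_members.tsv"))
    stats_cols <- tibble::as_tibble(res$modules)[
      , c("module_id", "size", "cohesiveness", "density")]
    readr::write_tsv(stats_cols, file.path(out_dir, "module_stats.tsv"))
  }
  if (!is.null(res$module_enrichment)) {
    readr::write_tsv(tibble::as_tibble(res$module_enrichment),
                     file.path(out_dir, "module_enrichment.tsv"))
  }
  if (!is.null(res$module_ora) && length(res$module_ora) > 0) {
    ora_all <- dplyr::bind_rows(
      lapply(names(res$module_ora), function(m) {
        d <- tibble::as_tibble(res$module_ora[[m]])
        d$module_id <- m
        d
      }))
    readr::write_tsv(ora_all, file.path(out_dir, "module_ora.tsv"))
  }
  if (!is.null(res$tfbs)) {
    readr::write_tsv(tibble::as_tibble(res$tfbs),
                     file.path(out_dir, "tfbs_enrichment.tsv"))
  }
  if (!is.null(res$comparison)) {
    readr::write_tsv(tidy(res$comparison),
                     file.path(out_dir, "liftover.tsv"))
  }
  invisible(out_dir)
}
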