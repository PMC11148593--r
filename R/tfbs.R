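#' Read a transcription-factor binding-site collection
#'
#' Accepts either a directory of per-TF BED files (TF name taken from the
#' file name without extension) or a single BED file whose fourth column
#' carries the TF name. The prediction variant (motif scan, motif +
#' conservation, or function-informed prediction; whole genome or
#' promoter) is a data-selection property of the files, recorded as a tag.
#'
#' @param path directory of `.bed` files, or one BED file with TF names
#'   in column 4.
#' @param genome_id genome identifier.
#' @param variant free-text tag describing how the sites were predicted.
#' @return tibble of binding sites: `tf`, `genome`, `chrom`, `start`,
#'   `end`, sorted by `(tf, chrom, start)`, with attribute `variant`.
#' @export
read_tfbs <- function(path, genome_id, variant = "motif-scan") {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.bed$", full.names = TRUE),
                  method = "radix")
    if (length(files) == 0) {
      stop(sprintf("no .bed files under '%s'", path), call. = FALSE)
    }
    sites <- purrr::map_dfr(files, function(f) {
      b <- read_bed(f, genome_id)
      b$tf <- sub("\\.bed$", "", basename(f))
      b
    })
  } else {
    sites <- read_bed(path, genome_id)
    if (!"name" %in% names(sites)) {
      stop("single-file TFBS input needs TF names in BED column 4",
           call. = FALSE)
    }
    sites$tf <- sites$name
    sites$name <- NULL
  }
  sites <- sites[, c("tf", "genome", "chrom", "start", "end")]
  ord <- order(sites$tf, norm_chrom(sites$chrom), sites$start,
               method = "radix")
  out <- sites[ord, , drop = FALSE]
  attr(out, "variant") <- variant
  out
}

#' Count binding sites overlapping a query region set
#'
#' Site-centric overlap statistic: the number of site intervals that
#' intersect (by at least 1 bp, half-open) at least one query interval.
#'
#' @param query interval tibble (the GWAS/QTL loci).
#' @param sites interval tibble (one TF's binding sites).
#' @return integer count.
#' @export
count_overlaps_sites <- function(query, sites) {
  if (nrow(sites) == 0 || nrow(query) == 0) {
    return(0L)
  }
  count_overlaps_fast(query$chrom, query$start, query$end,
                      sites$chrom, sites$start, sites$end)
}

# Merge intervals per chromosome (base R, sorted sweep). Returns a named
# list of lists with sorted disjoint `start`/`end` vectors.
merge_by_chrom <- function(chrom, start, end) {
  ch <- norm_chrom(chrom)
  ord <- order(ch, start, method = "radix")
  ch <- ch[ord]
  s <- start[ord]
  e <- end[ord]
  out <- list()
  for (c0 in unique(ch)) {
    sel <- ch == c0
    ss <- s[sel]
    ee <- cummax(e[sel])
    new_grp <- c(TRUE, ss[-1] > ee[-length(ee)])
    first <- which(new_grp)
    last <- c(first[-1] - 1, length(ee))
    out[[c0]] <- list(start = ss[first], end = ee[last])
  }
  out
}

# Count sites overlapping any merged query interval. For each site start
# s, findInterval locates the last merged query starting at or before s;
# a site [s, e) is covered iff that query is still open past s, or the
# next query starts before e. O(s log q), no per-site loops.
count_against_merged <- function(merged, s_chrom, s_start, s_end) {
  sc <- norm_chrom(s_chrom)
  total <- 0L
  for (ch in unique(sc)) {
    m <- merged[[ch]]
    if (is.null(m)) next
    sel <- sc == ch
    s <- s_start[sel]
    e <- s_end[sel]
    nq <- length(m$start)
    j <- findInterval(s, m$start)
    covered <- (j >= 1 & m$end[pmax(j, 1)] > s) |
      (j < nq & m$start[pmin(j + 1, nq)] < e)
    total <- total + sum(covered)
  }
  as.integer(total)
}

count_overlaps_fast <- function(q_chrom, q_start, q_end,
                                s_chrom, s_start, s_end) {
  count_against_merged(merge_by_chrom(q_chrom, q_start, q_end),
                       s_chrom, s_start, s_end)
}

#' Shuffle intervals within their chromosomes
#'
#' The permutation null for overlap testing: each interval is
#' independently repositioned uniformly at random within its own
#' chromosome, preserving its length and chromosome assignment. An
#' interval as long as its chromosome stays in place (the only legal
#' placement).
#'
#' @param intervals interval tibble.
#' @param chrom_sizes tibble from [read_chrom_sizes()] or a named numeric
#'   vector.
#' @param seed integer seed making the draw reproducible; `NULL` uses the
#'   current RNG state.
#' @return interval tibble of the same shape with new `start`/`end`.
#' @export
shuffle_intervals <- function(intervals, chrom_sizes, seed = NULL) {
  validate_intervals(intervals)
  sizes <- chrom_sizes_vec(chrom_sizes)
  len <- intervals$end - intervals$start
  room <- sizes[norm_chrom(intervals$chrom)] - len
  if (any(is.na(room))) {
    stop("interval chromosome missing from chrom_sizes", call. = FALSE)
  }
  if (any(room < 0)) {
    stop("interval longer than its chromosome", call. = FALSE)
  }
  draw <- function() floor(stats::runif(nrow(intervals)) * (room + 1))
  new_start <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- intervals
  out$start <- as.numeric(new_start)
  out$end <- as.numeric(new_start) + len
  out
}

#' Binding-site overlap enrichment by Monte-Carlo shuffling
#'
#' For each transcription factor, counts the binding sites overlapping
#' the query loci, then compares the observed count against a null
#' distribution obtained by repositioning the query intervals uniformly
#' within their chromosomes (`n_perm` independent shuffles, lengths and
#' chromosome assignments preserved). The add-one Monte-Carlo estimate
#' \deqn{p = (1 + \#\{\mathrm{shuffles\ with\ count} \ge
#'   \mathrm{observed}\}) / (1 + n_{perm})}
#' is never smaller than `1/(n_perm + 1)`. TFs with no observed overlap
#' are excluded from testing; Benjamini-Hochberg adjustment is applied
#' across the tested TFs.
#'
#' @param query interval tibble (the loci).
#' @param tfbs site tibble from [read_tfbs()].
#' @param chrom_sizes chromosome sizes for the query genome.
#' @param n_perm number of shuffles (default 1000).
#' @param seed integer seed; the full procedure is deterministic given
#'   `(inputs, n_perm, seed)`.
#' @param alpha adjusted-p threshold for the `enriched` flag.
#' @return a `tfbs_enrichment` tibble: `tf`, `observed`, `null_ge`,
#'   `n_perm`, `p_raw`, `p_adj`, `enriched`, sorted by `(p_adj, tf)`.
#' @export
tfbs_enrichment <- function(query, tfbs, chrom_sizes, n_perm = 1000,
                            seed = 1, alpha = 0.05) {
  stopifnot(n_perm >= 1)
  validate_intervals(query)
  tfs <- sort(unique(tfbs$tf), method = "radix")
  site_split <- split(tfbs[, c("chrom", "start", "end")], tfbs$tf)
  observed <- vapply(tfs, function(tf) {
    s <- site_split[[tf]]
    count_overlaps_fast(query$chrom, query$start, query$end,
                        s$chrom, s$start, s$end)
  }, integer(1))

  tested <- tfs[observed > 0]
  if (length(tested) == 0) {
    out <- tibble::tibble(tf = character(0), observed = integer(0),
                          null_ge = integer(0), n_perm = integer(0),
                          p_raw = numeric(0), p_adj = numeric(0),
                          enriched = logical(0))
    return(structure(out, class = c("tfbs_enrichment", class(out))))
  }
  null_ge <- stats::setNames(rep(0L, length(tested)), tested)
  run_null <- function() {
    for (b in seq_len(n_perm)) {
      shuf <- shuffle_intervals(query, chrom_sizes, seed = NULL)
      merged <- merge_by_chrom(shuf$chrom, shuf$start, shuf$end)
      for (tf in tested) {
        s <- site_split[[tf]]
        cnt <- count_against_merged(merged, s$chrom, s$start, s$end)
        if (cnt >= observed[[tf]]) null_ge[[tf]] <<- null_ge[[tf]] + 1L
      }
    }
  }
  if (is.null(seed)) run_null() else withr::with_seed(seed, run_null())

  ge <- as.integer(null_ge[tested])
  out <- tibble::tibble(
    tf = tested,
    observed = as.integer(observed[tested]),
    null_ge = ge,
    n_perm = as.integer(n_perm),
    p_raw = (1 + as.numeric(ge)) / (1 + n_perm)
  )
  out$p_adj <- bh_adjust(out$p_raw)
  out$enriched <- out$p_adj < alpha
  out <- dplyr::arrange(out, .data$p_adj, .data$tf)
  structure(out, class = c("tfbs_enrichment", class(out)))
}

#' @method glance tfbs_enrichment
#' @export
glance.tfbs_enrichment <- function(x, ...) {
  tibble::tibble(n_tested = nrow(x), n_enriched = sum(x$enriched),
                 min_p_raw = if (nrow(x)) min(x$p_raw) else NA_real_)
}

#' Observed vs null overlap significance per TF
#'
#' @param object `tfbs_enrichment`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot tfbs_enrichment
#' @export
autoplot.tfbs_enrichment <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$tf <- factor(d$tf, levels = rev(d$tf))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p_adj), y = .data$tf,
                                  fill = .data$enriched)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10](adjusted~italic(p))), y = NULL,
                  title = "Binding-site overlap enrichment") +
    ggplot2::theme_minimal()
}
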