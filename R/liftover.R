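#' Read a one-to-one ungapped alignment segment table
#'
#' Pairwise whole-genome alignments are consumed as ungapped one-to-one
#' segments: each row maps a source span onto a target span of identical
#' length, on either strand. One-to-one means a base pair of either genome
#' aligns to at most one base pair of the other, so no two segments may
#' overlap on the source side nor on the target side; gapped alignment
#' blocks must be decomposed into ungapped pieces upstream. Non-colinear
#' (rearranged) segments are allowed, so a single query interval can
#' project onto several target chromosomes.
#'
#' @param path TSV with columns
#'   `src_chrom src_start src_end tgt_chrom tgt_start tgt_end strand`
#'   (no header), all coordinates 0-based half-open.
#' @param source_genome,target_genome genome identifiers recorded on the
#'   returned table.
#' @return an `alignment_set`: a tibble of validated segments with
#'   attributes `source_genome` and `target_genome`.
#' @export
read_alignments <- function(path, source_genome = "source",
                            target_genome = "target") {
  seg <- readr::read_tsv(
    path,
    col_names = c("src_chrom", "src_start", "src_end",
                  "tgt_chrom", "tgt_start", "tgt_end", "strand"),
    col_types = "cddcddc", progress = FALSE
  )
  alignment_set(seg, source_genome, target_genome)
}

#' Construct and validate an alignment set
#'
#' @param segments tibble with the seven segment columns (see
#'   [read_alignments()]).
#' @param source_genome,target_genome genome identifiers.
#' @return validated `alignment_set` tibble.
#' @export
alignment_set <- function(segments, source_genome = "source",
                          target_genome = "target") {
  seg <- tibble::as_tibble(segments)
  if (nrow(seg) > 0) {
    if (!all(seg$strand %in% c("+", "-"))) {
      stop("alignment strand must be '+' or '-'", call. = FALSE)
    }
    src_len <- seg$src_end - seg$src_start
    tgt_len <- seg$tgt_end - seg$tgt_start
    if (any(src_len <= 0) || any(tgt_len <= 0)) {
      stop(sprintf("alignment row(s) %s have empty spans",
                   paste(which(src_len <= 0 | tgt_len <= 0), collapse = ",")),
           call. = FALSE)
    }
    if (any(src_len != tgt_len)) {
      bad <- which(src_len != tgt_len)
      stop(sprintf(
        "alignment row(s) %s are not length-preserving (ungapped segments must map equal spans)",
        paste(bad, collapse = ",")), call. = FALSE)
    }
    check_disjoint(seg$src_chrom, seg$src_start, seg$src_end, "source")
    check_disjoint(seg$tgt_chrom, seg$tgt_start, seg$tgt_end, "target")
  }
  structure(seg, source_genome = source_genome,
            target_genome = target_genome,
            class = c("alignment_set", class(seg)))
}

check_disjoint <- function(chrom, start, end, side) {
  ord <- order(norm_chrom(chrom), start, method = "radix")
  ch <- norm_chrom(chrom)[ord]
  s <- start[ord]
  e <- end[ord]
  n <- length(s)
  if (n < 2) {
    return(invisible(TRUE))
  }
  clash <- which(ch[-n] == ch[-1] & e[-n] > s[-1])
  if (length(clash) > 0) {
    rows <- sort(c(ord[clash], ord[clash + 1]))
    stop(sprintf(
      "alignment is not one-to-one: segments overlap on the %s side (rows %s)",
      side, paste(unique(rows), collapse = ",")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Project intervals through an alignment
#'
#' For every alignment segment intersecting a query interval, emits the
#' image of the intersection under the segment's affine map. On a forward
#' strand segment position `x` maps to `tgt_start + (x - src_start)`; on a
#' reverse strand segment the orientation flips, so the half-open image of
#' `[a, b)` is `[tgt_end - (b - src_start), tgt_end - (a - src_start))`.
#' Images may land on several target chromosomes (the alignments need not
#' be colinear). Abutting or overlapping images on the same chromosome are
#' merged; gaps are never bridged, since that would fabricate unaligned
#' sequence as lifted.
#'
#' @param intervals interval tibble on the query genome.
#' @param aln `alignment_set` from [read_alignments()].
#' @param direction `"source_to_target"` (default) or `"target_to_source"`.
#' @return interval tibble on the other genome, sorted by `(chrom, start)`.
#' @export
project_interval <- function(intervals, aln,
                             direction = c("source_to_target",
                                           "target_to_source")) {
  direction <- match.arg(direction)
  validate_intervals(intervals)
  if (direction == "source_to_target") {
    q_chrom <- aln$src_chrom
    q_start <- aln$src_start
    q_end <- aln$src_end
    t_chrom <- aln$tgt_chrom
    t_start <- aln$tgt_start
    t_end <- aln$tgt_end
    out_genome <- attr(aln, "target_genome")
  } else {
    q_chrom <- aln$tgt_chrom
    q_start <- aln$tgt_start
    q_end <- aln$tgt_end
    t_chrom <- aln$src_chrom
    t_start <- aln$src_start
    t_end <- aln$src_end
    out_genome <- attr(aln, "source_genome")
  }
  if (nrow(intervals) == 0 || nrow(aln) == 0) {
    return(intervals_tbl(character(0), character(0), numeric(0), numeric(0)))
  }
  qn <- norm_chrom(q_chrom)
  known <- norm_chrom(intervals$chrom) %in% qn
  if (any(!known)) {
    warning(sprintf("%d query interval(s) on chromosomes absent from the alignment",
                    sum(!known)), call. = FALSE)
  }
  p_chrom <- character(0)
  p_start <- numeric(0)
  p_end <- numeric(0)
  strand_fwd <- aln$strand == "+"
  iv_chrom <- norm_chrom(intervals$chrom)
  for (i in seq_len(nrow(intervals))) {
    hit <- which(qn == iv_chrom[i] & q_start < intervals$end[i] &
                   intervals$start[i] < q_end)
    if (length(hit) == 0) next
    a <- pmax(intervals$start[i], q_start[hit])
    b <- pmin(intervals$end[i], q_end[hit])
    fwd <- strand_fwd[hit]
    ts <- ifelse(fwd, t_start[hit] + (a - q_start[hit]),
                 t_end[hit] - (b - q_start[hit]))
    te <- ifelse(fwd, t_start[hit] + (b - q_start[hit]),
                 t_end[hit] - (a - q_start[hit]))
    p_chrom <- c(p_chrom, t_chrom[hit])
    p_start <- c(p_start, ts)
    p_end <- c(p_end, te)
  }
  if (length(p_chrom) == 0) {
    return(intervals_tbl(character(0), character(0), numeric(0), numeric(0)))
  }
  # merge abutting/overlapping images per chromosome (sorted sweep);
  # chromosome names keep the case of the first occurrence
  name_of <- stats::setNames(p_chrom, norm_chrom(p_chrom))
  merged <- merge_touching(p_chrom, p_start, p_end)
  out <- intervals_tbl(out_genome, unname(name_of[merged$chrom]),
                       merged$start, merged$end)
  ord <- order(norm_chrom(out$chrom), out$start, method = "radix")
  out[ord, , drop = FALSE]
}

merge_touching <- function(chrom, start, end) {
  by <- merge_by_chrom(chrom, start, end)
  tibble::tibble(
    chrom = rep(names(by), vapply(by, function(m) length(m$start),
                                  integer(1))),
    start = unlist(lapply(by, `[[`, "start"), use.names = FALSE),
    end = unlist(lapply(by, `[[`, "end"), use.names = FALSE))
}

#' Compare source and target gene sets through lift-over and orthology
#'
#' Lifts the input loci onto the target genome, collects the gene models
#' overlapping the loci on each side, and partitions them by ortholog
#' group membership:
#'
#' * `common` — (source gene, target gene) ortholog pairs with both genes
#'   inside their respective intervals;
#' * `ortholog_elsewhere` — target genes whose source ortholog exists but
#'   lies outside the input intervals (candidates invisible to the
#'   original single-reference analysis);
#' * `no_ortholog` — target genes with no ortholog group member in the
#'   source genome;
#' * `unique_to_source` — source genes with no ortholog inside the lifted
#'   target intervals.
#'
#' Every target-interval gene falls in exactly one of the first three
#' categories.
#'
#' @param src_intervals loci on the source genome.
#' @param src_genes,tgt_genes gene-model tibbles for the two genomes.
#' @param aln `alignment_set` between them.
#' @param orthology ortholog tibble from [read_orthologs()].
#' @return a `pangenome_comparison` object (list of tibbles `common`,
#'   `ortholog_elsewhere`, `no_ortholog`, `unique_to_source`, plus
#'   `src_genes_in_loci`, `tgt_genes_in_loci` and `tgt_intervals`).
#' @export
liftover_gene_sets <- function(src_intervals, src_genes, tgt_genes, aln,
                               orthology) {
  src_in <- genes_overlapping(src_intervals, src_genes)
  tgt_intervals <- suppressWarnings(
    project_interval(src_intervals, aln, "source_to_target"))
  tgt_in <- if (nrow(tgt_intervals) > 0) {
    genes_overlapping(tgt_intervals, tgt_genes)
  } else {
    tgt_genes[0, , drop = FALSE]
  }
  src_genome <- unique(src_genes$genome)
  tgt_genome <- unique(tgt_genes$genome)

  common <- list()
  elsewhere <- character(0)
  no_ortho <- character(0)
  matched_src <- character(0)
  for (tg in tgt_in$gene_id) {
    src_orth <- orthologs_of(orthology, tg, src_genome)
    if (tg %in% src_in$gene_id && identical(src_genome, tgt_genome)) {
      # identity comparison: a gene is its own ortholog
      src_orth <- union(src_orth, tg)
    }
    if (length(src_orth) == 0) {
      no_ortho <- c(no_ortho, tg)
    } else {
      inside <- intersect(src_orth, src_in$gene_id)
      if (length(inside) > 0) {
        common <- c(common, list(tibble::tibble(src_gene = inside,
                                                tgt_gene = tg)))
        matched_src <- union(matched_src, inside)
      } else {
        elsewhere <- c(elsewhere, tg)
      }
    }
  }
  common <- if (length(common) > 0) dplyr::bind_rows(common) else
    tibble::tibble(src_gene = character(0), tgt_gene = character(0))
  unique_src <- setdiff(src_in$gene_id, matched_src)

  structure(list(
    common = dplyr::arrange(common, .data$src_gene, .data$tgt_gene),
    ortholog_elsewhere = tibble::tibble(
      tgt_gene = sort(elsewhere, method = "radix")),
    no_ortholog = tibble::tibble(
      tgt_gene = sort(no_ortho, method = "radix")),
    unique_to_source = tibble::tibble(
      src_gene = sort(unique_src, method = "radix")),
    src_genes_in_loci = src_in,
    tgt_genes_in_loci = tgt_in,
    tgt_intervals = tgt_intervals
  ), class = "pangenome_comparison")
}

#' @export
print.pangenome_comparison <- function(x, ...) {
  cat("Pangenome interval comparison\n")
  cat(sprintf("  source genes in loci : %d\n", nrow(x$src_genes_in_loci)))
  cat(sprintf("  target genes in loci : %d\n", nrow(x$tgt_genes_in_loci)))
  cat(sprintf("  common ortholog pairs: %d\n", nrow(x$common)))
  cat(sprintf("  ortholog elsewhere   : %d\n", nrow(x$ortholog_elsewhere)))
  cat(sprintf("  no ortholog          : %d\n", nrow(x$no_ortholog)))
  cat(sprintf("  unique to source     : %d\n", nrow(x$unique_to_source)))
  invisible(x)
}

#' Tidy a pangenome comparison into one row per gene
#'
#' @param x `pangenome_comparison` from [liftover_gene_sets()].
#' @param ... unused.
#' @return tibble with columns `gene_id`, `genome_side`
#'   (`"source"`/`"target"`), `category`, and `partner` (the ortholog on
#'   the other side for `common` pairs, `NA` otherwise).
#' @method tidy pangenome_comparison
#' @export
tidy.pangenome_comparison <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(gene_id = x$common$tgt_gene, genome_side = "target",
                   category = "common", partner = x$common$src_gene),
    tibble::tibble(gene_id = x$ortholog_elsewhere$tgt_gene,
                   genome_side = "target", category = "ortholog_elsewhere",
                   partner = NA_character_),
    tibble::tibble(gene_id = x$no_ortholog$tgt_gene, genome_side = "target",
                   category = "no_ortholog", partner = NA_character_),
    tibble::tibble(gene_id = x$common$src_gene, genome_side = "source",
                   category = "common", partner = x$common$tgt_gene),
    tibble::tibble(gene_id = x$unique_to_source$src_gene,
                   genome_side = "source", category = "unique_to_source",
                   partner = NA_character_)
  )
}

#' @method glance pangenome_comparison
#' @export
glance.pangenome_comparison <- function(x, ...) {
  tibble::tibble(
    n_src_genes = nrow(x$src_genes_in_loci),
    n_tgt_genes = nrow(x$tgt_genes_in_loci),
    n_common_pairs = nrow(x$common),
    n_ortholog_elsewhere = nrow(x$ortholog_elsewhere),
    n_no_ortholog = nrow(x$no_ortholog),
    n_unique_to_source = nrow(x$unique_to_source)
  )
}

#' Bar chart of pangenome comparison categories
#'
#' @param object `pangenome_comparison`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pangenome_comparison
#' @export
autoplot.pangenome_comparison <- function(object, ...) {
  d <- glance(object)
  long <- tidyr::pivot_longer(
    d[, c("n_common_pairs", "n_ortholog_elsewhere", "n_no_ortholog",
          "n_unique_to_source")],
    cols = dplyr::everything(), names_to = "category", values_to = "n")
  long$category <- sub("^n_", "", long$category)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Lift-over ortholog partition") +
    ggplot2::theme_minimal()
}
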