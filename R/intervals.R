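#' Genomic interval tables
#'
#' `gwaspan` represents genomic intervals as plain tibbles with columns
#' `genome`, `chrom`, `start`, `end`. Coordinates are **0-based half-open**
#' throughout the package: `start` is the first base covered, `end` is one
#' past the last, and `end - start` is the length in bp. All printed
#' region strings and all GFF3/BED input are converted to this convention
#' at the boundary, exactly once.
#'
#' @param genome genome identifier (recycled).
#' @param chrom chromosome names.
#' @param start,end integer coordinates, 0-based half-open.
#' @return A tibble with columns `genome`, `chrom`, `start`, `end`.
#' @examples
#' intervals_tbl("NB", "Chr01", 0, 1000)
#' @export
intervals_tbl <- function(genome, chrom, start, end) {
  out <- tibble::tibble(
    genome = as.character(genome),
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end)
  )
  validate_intervals(out)
  out
}

validate_intervals <- function(x, arg = "intervals") {
  req <- c("genome", "chrom", "start", "end")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s is missing column(s): %s", arg,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (any(is.na(x$start)) || any(is.na(x$end))) {
    stop(sprintf("%s has NA coordinates", arg), call. = FALSE)
  }
  if (any(x$start < 0)) {
    stop(sprintf("%s has negative start coordinates", arg), call. = FALSE)
  }
  if (any(x$start >= x$end)) {
    bad <- which(x$start >= x$end)[1]
    stop(sprintf("%s row %d is empty or inverted: start %s >= end %s", arg,
                 bad, format(x$start[bad], scientific = FALSE),
                 format(x$end[bad], scientific = FALSE)), call. = FALSE)
  }
  if (any(!nzchar(x$chrom)) || any(is.na(x$chrom))) {
    stop(sprintf("%s has empty chromosome names", arg), call. = FALSE)
  }
  invisible(x)
}

#' Normalize a chromosome name for comparison
#'
#' Lowercases and strips a leading "chr" prefix, so `Chr01`, `chr01` and
#' `01` compare equal. Names from different genomes are never assumed
#' comparable; this is only used to match names within one genome.
#'
#' @param x character vector of chromosome names.
#' @return normalized character vector.
#' @export
norm_chrom <- function(x) {
  sub("^chr", "", tolower(as.character(x)))
}

#' Parse printed region strings
#'
#' Parses loci written in the usual 1-based inclusive form
#' `"<chrom>:<start>-<end>"` (e.g. `"Chr01:1,523,625-1,770,814"`) into the
#' package's 0-based half-open interval tibble. Thousands separators
#' (commas) and surrounding whitespace are stripped; a case-insensitive
#' `chr` prefix is canonicalized to `Chr`.
#'
#' @param text character vector of region strings.
#' @param genome genome identifier attached to the result.
#' @return interval tibble (one row per region string).
#' @examples
#' parse_region("Chr04:4662701-4670717")
#' @export
parse_region <- function(text, genome = "source") {
  text <- stringr::str_trim(as.character(text))
  stripped <- gsub(",", "", text, fixed = TRUE)
  m <- stringr::str_match(stripped, "^([A-Za-z0-9_.]+):([0-9]+)-([0-9]+)$")
  bad <- which(is.na(m[, 1]))
  if (length(bad) > 0) {
    stop(sprintf("cannot parse region string: '%s'", text[bad[1]]),
         call. = FALSE)
  }
  chrom <- sub("^[Cc][Hh][Rr]", "Chr", m[, 2])
  start1 <- as.numeric(m[, 3])
  end1 <- as.numeric(m[, 4])
  if (any(start1 < 1)) {
    stop(sprintf("region start must be >= 1 in '%s'",
                 text[which(start1 < 1)[1]]), call. = FALSE)
  }
  if (any(start1 > end1)) {
    i <- which(start1 > end1)[1]
    stop(sprintf("region start exceeds end in '%s'", text[i]), call. = FALSE)
  }
  if (any(start1 == end1)) {
    i <- which(start1 == end1)[1]
    stop(sprintf("empty span in region '%s'", text[i]), call. = FALSE)
  }
  # 1-based inclusive [start1, end1] -> 0-based half-open [start1 - 1, end1)
  out <- intervals_tbl(genome, chrom, start1 - 1, end1)
  tryCatch(validate_intervals(out, "region"),
           error = function(e) stop(sprintf("degenerate region '%s': %s",
                                            text[1], conditionMessage(e)),
                                    call. = FALSE))
  out
}

#' Format intervals as printed region strings
#'
#' Inverse of [parse_region()] on canonical strings: prints the 1-based
#' inclusive form without thousands separators.
#'
#' @param intervals interval tibble.
#' @return character vector of `"<chrom>:<start>-<end>"` strings.
#' @export
format_region <- function(intervals) {
  validate_intervals(intervals)
  sprintf("%s:%s-%s", intervals$chrom,
          format(intervals$start + 1, scientific = FALSE, trim = TRUE),
          format(intervals$end, scientific = FALSE, trim = TRUE))
}

# Build a GRanges from a 0-based half-open interval table. The IRanges
# inside are 1-based inclusive ([start+1, end]), which preserves overlap
# semantics; seqnames use the normalized chromosome name so that "chr1"
# and "Chr1" from the same genome match.
as_granges0 <- function(x) {
  GenomicRanges::GRanges(
    seqnames = norm_chrom(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

#' Read gene models from a GFF3 file
#'
#' Keeps only records with feature type `gene` (mRNA/CDS children are
#' ignored; the analyses operate at gene-model granularity). GFF3 1-based
#' inclusive coordinates are converted to the internal 0-based half-open
#' convention. Records without an `ID` attribute are skipped with a
#' warning.
#'
#' @param path GFF3 file.
#' @param genome_id genome identifier for the annotation.
#' @return A gene-model tibble with columns `genome`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `description`, sorted by `(chrom, start)`.
#' @export
read_gff3 <- function(path, genome_id) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read GFF3 file '%s'", path), call. = FALSE)
  }
  gr <- tryCatch(
    suppressWarnings(rtracklayer::import(path, format = "gff3")),
    error = function(e) stop(sprintf("failed to parse GFF3 '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  if (length(gr) == 0) {
    return(empty_genes(genome_id))
  }
  gr <- gr[as.character(gr$type) == "gene"]
  if (length(gr) == 0) {
    return(empty_genes(genome_id))
  }
  ids <- as.character(gr$ID)
  drop <- is.na(ids) | !nzchar(ids)
  if (any(drop)) {
    warning(sprintf("skipping %d gene record(s) without an ID attribute",
                    sum(drop)), call. = FALSE)
    gr <- gr[!drop]
    ids <- ids[!drop]
  }
  desc <- if (!is.null(gr$description)) as.character(gr$description) else
    rep(NA_character_, length(gr))
  out <- tibble::tibble(
    genome = genome_id,
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = as.numeric(GenomicRanges::start(gr)) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    description = dplyr::coalesce(desc, "")
  )
  out$strand[!out$strand %in% c("+", "-")] <- "unknown"
  if (anyDuplicated(out$gene_id)) {
    stop(sprintf("duplicate gene IDs in '%s' (e.g. %s)", path,
                 out$gene_id[duplicated(out$gene_id)][1]), call. = FALSE)
  }
  sort_genes(out)
}

empty_genes <- function(genome_id) {
  tibble::tibble(
    genome = character(0), gene_id = character(0),
    chrom = character(0), start = numeric(0), end = numeric(0),
    strand = character(0), description = character(0)
  )
}

sort_genes <- function(genes) {
  ord <- order(norm_chrom(genes$chrom), genes$start, genes$gene_id,
               method = "radix")
  genes[ord, , drop = FALSE]
}

#' Genes overlapping a set of intervals
#'
#' Returns the gene models whose span intersects any of the query
#' intervals by at least one base pair (half-open intersection: a gene
#' starting exactly where an interval ends does not overlap). The result
#' is deduplicated and sorted by `(chrom, start)`.
#'
#' @param intervals interval tibble (query loci).
#' @param genes gene-model tibble from [read_gff3()].
#' @return subset of `genes`, sorted by `(chrom, start)`.
#' @examples
#' genes <- tibble::tibble(genome = "NB", gene_id = "g1", chrom = "Chr1",
#'                         start = 150, end = 160, strand = "+",
#'                         description = "")
#' genes_overlapping(intervals_tbl("NB", "Chr1", 100, 200), genes)
#' @export
genes_overlapping <- function(intervals, genes) {
  if (nrow(intervals) == 0 || nrow(genes) == 0) {
    return(genes[0, , drop = FALSE])
  }
  validate_intervals(intervals)
  gnm_q <- unique(intervals$genome)
  gnm_g <- unique(genes$genome)
  if (length(gnm_q) != 1 || length(gnm_g) != 1 || gnm_q != gnm_g) {
    stop(sprintf("genome mismatch: intervals are on '%s', genes on '%s'",
                 paste(gnm_q, collapse = ","),
                 paste(gnm_g, collapse = ",")), call. = FALSE)
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(genes),
                                      as_granges0(intervals))
  idx <- sort(unique(S4Vectors::queryHits(hits)))
  sort_genes(genes[idx, , drop = FALSE])
}

#' Read intervals from a BED3+ file
#'
#' BED is 0-based half-open already, so coordinates pass straight through.
#' Rows with `start >= end` are rejected with a warning. If a fourth
#' column is present it is kept as `name`.
#'
#' @param path BED file (tab-separated, no header).
#' @param genome_id genome identifier.
#' @return interval tibble sorted by `(chrom, start)`, with a `name`
#'   column when the file has one.
#' @export
read_bed <- function(path, genome_id) {
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(intervals_tbl(character(0), character(0), numeric(0), numeric(0)))
  }
  if (ncol(raw) < 3) {
    stop(sprintf("'%s' is not BED3+: fewer than 3 columns", path),
         call. = FALSE)
  }
  start <- as.numeric(raw[[2]])
  end <- as.numeric(raw[[3]])
  bad <- is.na(start) | is.na(end) | start < 0 | start >= end
  if (any(bad)) {
    warning(sprintf("rejecting %d BED row(s) with invalid coordinates",
                    sum(bad)), call. = FALSE)
  }
  out <- tibble::tibble(
    genome = genome_id,
    chrom = as.character(raw[[1]])[!bad],
    start = start[!bad],
    end = end[!bad]
  )
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])[!bad]
  ord <- order(norm_chrom(out$chrom), out$start, out$end, method = "radix")
  out[ord, , drop = FALSE]
}

#' Read chromosome sizes
#'
#' @param path two-column TSV `chrom<TAB>size` without header.
#' @return tibble with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("chrom", "size"),
                         col_types = "cd", progress = FALSE)
  if (any(is.na(raw$size)) || any(raw$size <= 0)) {
    stop(sprintf("invalid chromosome sizes in '%s'", path), call. = FALSE)
  }
  raw
}

# chrom sizes as a named vector keyed by normalized chromosome name
chrom_sizes_vec <- function(chrom_sizes) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    stats::setNames(as.numeric(chrom_sizes), norm_chrom(names(chrom_sizes)))
  } else {
    stats::setNames(as.numeric(chrom_sizes$size), norm_chrom(chrom_sizes$chrom))
  }
}
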