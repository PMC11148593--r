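#' Read literature-mined entity annotations
#'
#' Consumes the tabular output of an upstream named-entity-recognition
#' pipeline over curated abstracts: one row per recognized entity mention
#' with its PubMed id, surface text, entity type (one of `gene`,
#' `species`, `chemical`, `phenotype`) and, for gene mentions, the
#' normalized gene accession. Rows with an unknown entity type are
#' rejected with a warning.
#'
#' @param path TSV `pmid<TAB>surface<TAB>etype<TAB>gene_id` without
#'   header; `gene_id` may be empty for non-gene entities.
#' @return an `annotation_index` tibble with columns `pmid`, `surface`,
#'   `etype`, `gene_id`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read annotation file '%s'", path), call. = FALSE)
  }
  raw <- readr::read_tsv(path, col_names = c("pmid", "surface", "etype",
                                             "gene_id"),
                         col_types = "cccc", progress = FALSE)
  annotation_index(raw)
}

entity_types <- c("gene", "species", "chemical", "phenotype")

#' Construct an annotation index from a tibble
#'
#' @param x tibble with columns `pmid`, `surface`, `etype`, `gene_id`.
#' @return validated `annotation_index` tibble.
#' @export
annotation_index <- function(x) {
  x <- tibble::as_tibble(x)[, c("pmid", "surface", "etype", "gene_id")]
  x$gene_id[is.na(x$gene_id)] <- ""
  bad <- !x$etype %in% entity_types
  if (any(bad)) {
    warning(sprintf("rejecting %d annotation row(s) with unknown entity type (e.g. '%s')",
                    sum(bad), x$etype[bad][1]), call. = FALSE)
    x <- x[!bad, , drop = FALSE]
  }
  if (any(is.na(x$pmid) | !nzchar(x$pmid))) {
    stop("annotation rows must carry a PubMed id", call. = FALSE)
  }
  structure(x, class = c("annotation_index", class(x)))
}

#' Write an annotation table back to TSV
#'
#' @param index `annotation_index`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(index, path) {
  readr::write_tsv(tibble::as_tibble(index), path, col_names = FALSE)
  invisible(path)
}

#' Genes associated with a free-text query
#'
#' Case-insensitive substring match of `query` against the surface text
#' of annotations of the requested entity types, followed by
#' same-abstract co-occurrence: the result is the set of normalized gene
#' ids of gene-type annotations sharing a PubMed id with any matched
#' mention. Association is defined as per-abstract co-occurrence (no
#' stemming, no fuzzy matching).
#'
#' @param index `annotation_index`.
#' @param query free text, e.g. `"drought"` or `"gibberellic acid"`.
#' @param etypes entity types whose surfaces are searched (default: all
#'   four).
#' @return sorted character vector of gene ids (possibly empty).
#' @export
genes_for_query <- function(index, query, etypes = entity_types) {
  etypes <- match.arg(etypes, entity_types, several.ok = TRUE)
  hit <- index$etype %in% etypes &
    stringr::str_detect(index$surface,
                        stringr::fixed(query, ignore_case = TRUE))
  pmids <- unique(index$pmid[hit])
  genes <- index$gene_id[index$etype == "gene" & index$pmid %in% pmids &
                           nzchar(index$gene_id)]
  sort(unique(genes), method = "radix")
}

#' Literature attached to each gene
#'
#' @param index `annotation_index`.
#' @param genes character vector of gene ids.
#' @return tibble with one row per gene: `gene_id`, list-column `pmids`,
#'   and `n_articles`; genes absent from the index get an empty set.
#' @export
literature_for_genes <- function(index, genes) {
  genes <- unique(as.character(genes))
  gene_rows <- index[index$etype == "gene" & nzchar(index$gene_id), ,
                     drop = FALSE]
  pmids <- lapply(genes, function(g) {
    sort(unique(gene_rows$pmid[gene_rows$gene_id == g]), method = "radix")
  })
  tibble::tibble(gene_id = genes, pmids = pmids,
                 n_articles = lengths(pmids))
}
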