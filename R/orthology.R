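#' Read ortholog groups
#'
#' Ortholog groups (such as the cross-variety OGI groups of a pangenome
#' gene index) arrive as a three-column TSV `group_id<TAB>genome<TAB>gene_id`.
#' A gene id may belong to at most one group within its genome annotation.
#'
#' @param path TSV file without header.
#' @return tibble with columns `group_id`, `genome`, `gene_id`.
#' @export
read_orthologs <- function(path) {
  out <- readr::read_tsv(path, col_names = c("group_id", "genome", "gene_id"),
                         col_types = "ccc", progress = FALSE)
  dup <- duplicated(out[, c("genome", "gene_id")])
  if (any(dup)) {
    stop(sprintf("gene '%s' (genome '%s') appears in more than one group",
                 out$gene_id[dup][1], out$genome[dup][1]), call. = FALSE)
  }
  out
}

#' Orthologs of a gene in a target genome
#'
#' Looks up the gene's ortholog group and returns the members belonging to
#' `target_genome`. A gene absent from the map has no known orthologs and
#' yields an empty set, as does a singleton group queried for any other
#' genome.
#'
#' @param orthology ortholog tibble from [read_orthologs()].
#' @param gene_id gene accession to look up.
#' @param target_genome genome whose group members are wanted.
#' @return character vector of target-genome gene ids (possibly empty).
#' @export
orthologs_of <- function(orthology, gene_id, target_genome) {
  grp <- orthology$group_id[orthology$gene_id == gene_id]
  if (length(grp) == 0) {
    return(character(0))
  }
  # all group members in the target genome; the gene itself is a member
  # when queried against its own genome (identity lift-over case)
  hits <- orthology$gene_id[orthology$group_id %in% grp &
                              orthology$genome == target_genome]
  sort(unique(hits), method = "radix")
}
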