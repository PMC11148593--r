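#' Fixture specification for the synthetic data generator
#'
#' Defines the study conditions the generator emulates: a two-genome
#' toy pangenome with a rearranged and a deleted alignment block, a
#' coexpression network with one planted dense module intersecting the
#' query loci, annotation gene sets in which the planted module is
#' enriched for a designated term, binding-site tracks with one TF
#' concentrated in the loci, and a literature-annotation table with a
#' planted gene-phenotype co-occurrence.
#'
#' @param n_chroms chromosomes per genome (default 2).
#' @param chrom_len chromosome length in bp (default 1e6).
#' @param n_genes genes per genome, split evenly across chromosomes
#'   (default 100; these are also the network nodes).
#' @param n_rearrangements alignment blocks moved to another target
#'   chromosome, each containing one locus gene (default 1).
#' @param n_deletions alignment blocks deleted from the target, each
#'   removing one locus gene's alignment (default 1).
#' @param planted_module_size planted community size (default 12).
#' @param planted_within_p edge probability inside the planted module
#'   (default 0.9, weight 1.0).
#' @param background_edge_p edge probability elsewhere (default 0.05).
#' @param n_background_modules ordinary (unimplicated) communities
#'   planted alongside the implicated module (default 6); coexpression
#'   networks are modular, and these provide the union-of-modules
#'   background that module enrichment is tested against.
#' @param background_module_size size of each background community
#'   (default 8; same within-community edge probability and unit
#'   weights as the implicated module).
#' @param n_implicated genes covered by the query loci (default 10, of
#'   which `n_implicated_planted` belong to the planted module).
#' @param n_implicated_planted planted genes among the implicated
#'   (default 6).
#' @param n_tfs TF tracks (default 5); `planted_tf` concentrates one
#'   track's sites in the loci.
#' @param planted_tf logical (default TRUE).
#' @param n_terms,n_pathways annotation term counts (defaults 8 and 5).
#' @param n_abstracts abstracts in the text-annotation table (default 30).
#' @param seed RNG seed; every byte of output is a deterministic
#'   function of the spec including this seed.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_chroms = 2, chrom_len = 1e6, n_genes = 100,
                         n_rearrangements = 1, n_deletions = 1,
                         planted_module_size = 12, planted_within_p = 0.9,
                         background_edge_p = 0.05,
                         n_background_modules = 6,
                         background_module_size = 8, n_implicated = 10,
                         n_implicated_planted = 6, n_tfs = 5,
                         planted_tf = TRUE, n_terms = 8, n_pathways = 5,
                         n_abstracts = 30, seed = 1) {
  spec <- list(n_chroms = n_chroms, chrom_len = chrom_len,
               n_genes = n_genes, n_rearrangements = n_rearrangements,
               n_deletions = n_deletions,
               planted_module_size = planted_module_size,
               planted_within_p = planted_within_p,
               background_edge_p = background_edge_p,
               n_background_modules = n_background_modules,
               background_module_size = background_module_size,
               n_implicated = n_implicated,
               n_implicated_planted = n_implicated_planted,
               n_tfs = n_tfs, planted_tf = planted_tf, n_terms = n_terms,
               n_pathways = n_pathways, n_abstracts = n_abstracts,
               seed = seed)
  stopifnot(n_chroms >= 2, n_genes >= 20, chrom_len >= 2e5,
            planted_within_p >= 0, planted_within_p <= 1,
            background_edge_p >= 0, background_edge_p <= 1,
            n_implicated_planted <= n_implicated,
            n_implicated_planted < planted_module_size,
            n_rearrangements + n_deletions + n_implicated_planted <=
              n_genes / n_chroms)
  structure(spec, class = "fixture_spec")
}

#' Generate a complete synthetic input bundle
#'
#' Writes internally consistent toy datasets in every format the package
#' consumes, plus a JSON manifest recording the planted ground truth
#' (module members, enriched term, concentrated TF, expected lift-over
#' partition counts). Each category of the lift-over partition is
#' represented: most locus genes have their ortholog inside the lifted
#' target intervals (`common`); one extra target gene in the lifted
#' region has its source ortholog outside the loci
#' (`ortholog_elsewhere`); one target copy carries no ortholog group
#' (`no_ortholog`); deleted or group-less source genes are
#' `unique_to_source`.
#'
#' @param spec [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
simulate_bundle <- function(spec = fixture_spec(), out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create '%s'", out_dir), call. = FALSE)
  }
  withr::with_seed(spec$seed, simulate_bundle_impl(spec, out_dir))
}

simulate_bundle_impl <- function(spec, out_dir) {
  path <- function(...) file.path(out_dir, ...)
  chroms <- paste0("Chr", seq_len(spec$n_chroms))
  per_chrom <- spec$n_genes %/% spec$n_chroms

  ## ---- source gene layout -------------------------------------------
  src <- list()
  for (ci in seq_len(spec$n_chroms)) {
    cursor <- 10000
    n_here <- if (ci == spec$n_chroms) {
      spec$n_genes - per_chrom * (spec$n_chroms - 1)
    } else {
      per_chrom
    }
    for (k in seq_len(n_here)) {
      gap <- round(stats::runif(1, 4000, 8000))
      len <- round(stats::runif(1, 2000, 4000))
      cursor <- cursor + gap
      src <- c(src, list(tibble::tibble(
        chrom = chroms[ci], start = cursor, end = cursor + len)))
      cursor <- cursor + len
    }
  }
  src_genes <- dplyr::bind_rows(src)
  src_genes$gene_id <- sprintf("g%03d", seq_len(nrow(src_genes)))
  src_genes$strand <- sample(c("+", "-"), nrow(src_genes), replace = TRUE)
  src_genes$genome <- "SRC"
  stopifnot(max(src_genes$end) < spec$chrom_len)

  ## ---- query loci ----------------------------------------------------
  # locus 1 covers the first n_implicated_planted genes of Chr1; locus 2
  # covers the remaining implicated genes at the start of Chr2
  n_loc1 <- spec$n_implicated_planted
  n_loc2 <- spec$n_implicated - n_loc1
  chr1_genes <- src_genes[src_genes$chrom == chroms[1], ]
  chr2_genes <- src_genes[src_genes$chrom == chroms[2], ]
  locus1 <- intervals_tbl("SRC", chroms[1],
                          chr1_genes$start[1] - 500,
                          chr1_genes$end[n_loc1] + 500)
  regions <- locus1
  implicated <- chr1_genes$gene_id[seq_len(n_loc1)]
  if (n_loc2 > 0) {
    locus2 <- intervals_tbl("SRC", chroms[2],
                            chr2_genes$start[1] - 500,
                            chr2_genes$end[n_loc2] + 500)
    regions <- dplyr::bind_rows(regions, locus2)
    implicated <- c(implicated, chr2_genes$gene_id[seq_len(n_loc2)])
  }

  ## ---- alignment with rearrangements and deletions -------------------
  # rearranged blocks: genes 3, (then 3rd gene of each further chrom);
  # deleted blocks: gene 5, (then 5th of each further chrom); all inside
  # locus 1 when it is wide enough, so one query interval projects onto
  # two target chromosomes
  rearr_ids <- character(0)
  del_ids <- character(0)
  for (r in seq_len(spec$n_rearrangements)) {
    ch <- chroms[((r - 1) %% spec$n_chroms) + 1]
    idx <- 3 + ((r - 1) %/% spec$n_chroms)
    rearr_ids <- c(rearr_ids, src_genes$gene_id[src_genes$chrom == ch][idx])
  }
  for (d in seq_len(spec$n_deletions)) {
    ch <- chroms[((d - 1) %% spec$n_chroms) + 1]
    idx <- 5 + ((d - 1) %/% spec$n_chroms)
    del_ids <- c(del_ids, src_genes$gene_id[src_genes$chrom == ch][idx])
  }
  reserve <- 50000
  tail_cursor <- stats::setNames(rep(spec$chrom_len, spec$n_chroms), chroms)
  seg <- list()
  breaks <- list()
  rearr_map <- list()
  for (g in rearr_ids) {
    row <- src_genes[src_genes$gene_id == g, ]
    other <- chroms[which(chroms != row$chrom)[1]]
    blk_s <- row$start - 100
    blk_e <- row$end + 100
    seg <- c(seg, list(tibble::tibble(
      src_chrom = row$chrom, src_start = blk_s, src_end = blk_e,
      tgt_chrom = other, tgt_start = tail_cursor[[other]],
      tgt_end = tail_cursor[[other]] + (blk_e - blk_s), strand = "-")))
    rearr_map[[g]] <- list(chrom = other, tail = tail_cursor[[other]],
                           blk_s = blk_s, blk_e = blk_e)
    tail_cursor[[other]] <- tail_cursor[[other]] + (blk_e - blk_s)
    breaks[[row$chrom]] <- rbind(breaks[[row$chrom]], c(blk_s, blk_e))
  }
  for (g in del_ids) {
    row <- src_genes[src_genes$gene_id == g, ]
    breaks[[row$chrom]] <- rbind(breaks[[row$chrom]],
                                 c(row$start - 100, row$end + 100))
  }
  for (ch in chroms) {
    b <- breaks[[ch]]
    cuts <- if (is.null(b)) numeric(0) else b[order(b[, 1]), , drop = FALSE]
    s <- 0
    pieces <- list()
    if (length(cuts) > 0) {
      for (i in seq_len(nrow(cuts))) {
        if (cuts[i, 1] > s) pieces <- c(pieces, list(c(s, cuts[i, 1])))
        s <- cuts[i, 2]
      }
    }
    pieces <- c(pieces, list(c(s, spec$chrom_len)))
    for (p in pieces) {
      seg <- c(seg, list(tibble::tibble(
        src_chrom = ch, src_start = p[1], src_end = p[2],
        tgt_chrom = ch, tgt_start = p[1], tgt_end = p[2], strand = "+")))
    }
  }
  alignment <- dplyr::bind_rows(seg)
  aln <- alignment_set(alignment, "SRC", "TGT")

  ## ---- target genes and orthology ------------------------------------
  # copies of every non-deleted source gene at its projected position
  no_group_tgt <- src_genes$gene_id[src_genes$chrom == chroms[1]][4]
  tgt <- list()
  groups <- list()
  ogi <- 0
  for (i in seq_len(nrow(src_genes))) {
    gid <- src_genes$gene_id[i]
    if (gid %in% del_ids) next # deleted from the target genome
    if (gid %in% rearr_ids) {
      # image under the reverse-strand block map, computed directly
      rm <- rearr_map[[gid]]
      img <- tibble::tibble(
        chrom = rm$chrom,
        start = rm$tail + (rm$blk_e - src_genes$end[i]),
        end = rm$tail + (rm$blk_e - src_genes$start[i]))
    } else {
      img <- tibble::tibble(chrom = src_genes$chrom[i],
                            start = src_genes$start[i],
                            end = src_genes$end[i])
    }
    tid <- sub("^g", "t", gid)
    tgt <- c(tgt, list(tibble::tibble(
      genome = "TGT", gene_id = tid, chrom = img$chrom, start = img$start,
      end = img$end, strand = src_genes$strand[i], description = "")))
    if (gid %in% no_group_tgt) next # planted no-ortholog target copy
    ogi <- ogi + 1
    groups <- c(groups, list(tibble::tibble(
      group_id = sprintf("OG%05d", ogi),
      genome = c("SRC", "TGT"), gene_id = c(gid, tid))))
  }
  # one extra target gene inside the lifted locus-1 region whose source
  # ortholog lies outside the input loci
  gap_lo <- chr1_genes$end[1] + 500
  gap_hi <- chr1_genes$start[2] - 500
  extra <- tibble::tibble(
    genome = "TGT", gene_id = "t_extra1", chrom = chroms[1],
    start = gap_lo, end = max(gap_lo + 1000, gap_hi), strand = "+",
    description = "")
  tgt <- c(tgt, list(extra))
  elsewhere_src <- src_genes$gene_id[src_genes$chrom == chroms[1]][per_chrom %/% 2]
  tgt_genes <- sort_genes(dplyr::bind_rows(tgt))
  orthologs <- dplyr::bind_rows(groups)
  # t_extra1 joins its source partner's existing group
  grp <- orthologs$group_id[orthologs$gene_id == elsewhere_src][1]
  orthologs <- dplyr::bind_rows(
    orthologs,
    tibble::tibble(group_id = grp, genome = "TGT", gene_id = "t_extra1"))

  ## ---- coexpression network ------------------------------------------
  # one implicated planted module plus several unimplicated background
  # communities over ER noise: coexpression networks are modular, and the
  # union-of-modules enrichment background only exists if the detector
  # has ordinary (unimplicated) communities to find
  nodes <- src_genes$gene_id
  planted <- c(implicated[seq_len(spec$n_implicated_planted)],
               setdiff(nodes, implicated)[
                 seq_len(spec$planted_module_size -
                           spec$n_implicated_planted) + 10])
  pool <- setdiff(nodes, c(implicated, planted))
  bg_comms <- list()
  for (b in seq_len(spec$n_background_modules)) {
    take <- seq_len(spec$background_module_size) +
      (b - 1) * spec$background_module_size
    if (max(take) > length(pool)) break
    bg_comms <- c(bg_comms, list(pool[take]))
  }
  comm_of <- stats::setNames(rep(0L, length(nodes)), nodes)
  comm_of[planted] <- 1L
  for (b in seq_along(bg_comms)) comm_of[bg_comms[[b]]] <- b + 1L
  pairs <- utils::combn(sort(nodes, method = "radix"), 2)
  same_comm <- comm_of[pairs[1, ]] > 0 &
    comm_of[pairs[1, ]] == comm_of[pairs[2, ]]
  p_edge <- ifelse(same_comm, spec$planted_within_p,
                   spec$background_edge_p)
  keep <- stats::runif(ncol(pairs)) < p_edge
  # module edges carry full weight (strong coexpression); chance
  # background edges carry mid-range weight, as befits spurious
  # correlations
  network <- tibble::tibble(from = pairs[1, keep], to = pairs[2, keep],
                            weight = ifelse(same_comm[keep], 1.0, 0.5))

  ## ---- annotation gene sets ------------------------------------------
  go <- list(tibble::tibble(
    term_id = "TERM001",
    description = "seed dormancy regulation (planted)",
    genes = paste(sort(planted, method = "radix"), collapse = ",")))
  for (tno in seq(2, spec$n_terms)) {
    sz <- sample(8:15, 1)
    go <- c(go, list(tibble::tibble(
      term_id = sprintf("TERM%03d", tno),
      description = sprintf("random process %d", tno),
      genes = paste(sort(sample(nodes, sz), method = "radix"),
                    collapse = ","))))
  }
  go_tbl <- dplyr::bind_rows(go)
  pw <- list(tibble::tibble(
    term_id = "PW001", description = "starch and sucrose metabolism (planted)",
    genes = paste(sort(c(planted[1:6],
                         sample(setdiff(nodes, planted), 4)),
                       method = "radix"), collapse = ",")))
  for (pno in seq(2, spec$n_pathways)) {
    pw <- c(pw, list(tibble::tibble(
      term_id = sprintf("PW%03d", pno),
      description = sprintf("random pathway %d", pno),
      genes = paste(sort(sample(nodes, sample(6:12, 1)), method = "radix"),
                    collapse = ","))))
  }
  pw_tbl <- dplyr::bind_rows(pw)

  ## ---- TF binding sites ----------------------------------------------
  tf_dir <- path("tfbs")
  dir.create(tf_dir, showWarnings = FALSE)
  site_len <- 20
  tf_names <- sprintf("TF%02d", seq_len(spec$n_tfs))
  planted_tf_name <- if (spec$planted_tf) tf_names[1] else NA_character_
  for (tf in tf_names) {
    if (identical(tf, planted_tf_name)) {
      # concentrate sites inside the loci: >= 5x genome-wide density
      inside <- purrr::map_dfr(seq_len(nrow(regions)), function(ri) {
        n_in <- if (ri == 1) 10 else 5
        s <- sort(round(stats::runif(
          n_in, regions$start[ri], regions$end[ri] - site_len)))
        tibble::tibble(chrom = regions$chrom[ri], start = s,
                       end = s + site_len)
      })
      out_s <- sort(round(stats::runif(5, 6e5, spec$chrom_len - site_len)))
      sites <- dplyr::bind_rows(
        inside, tibble::tibble(chrom = chroms[1], start = out_s,
                               end = out_s + site_len))
    } else {
      sites <- purrr::map_dfr(chroms, function(ch) {
        s <- sort(round(stats::runif(15, 0, spec$chrom_len - site_len)))
        tibble::tibble(chrom = ch, start = s, end = s + site_len)
      })
    }
    sites <- sites[order(norm_chrom(sites$chrom), sites$start,
                         method = "radix"), ]
    readr::write_tsv(sites, file.path(tf_dir, paste0(tf, ".bed")),
                     col_names = FALSE)
  }

  ## ---- text annotations ----------------------------------------------
  pmids <- sprintf("%07d", seq_len(spec$n_abstracts) + 1000000)
  planted_query <- "preharvest sprouting"
  text_genes <- implicated[seq_len(min(3, length(implicated)))]
  rows <- list()
  for (i in seq_along(text_genes)) {
    for (pm in pmids[(2 * i - 1):(2 * i)]) {
      rows <- c(rows, list(
        tibble::tibble(pmid = pm, surface = "Preharvest sprouting",
                       etype = "phenotype", gene_id = ""),
        tibble::tibble(pmid = pm, surface = paste0("Os", text_genes[i]),
                       etype = "gene", gene_id = text_genes[i])))
    }
  }
  for (pm in pmids[-seq_len(2 * length(text_genes))]) {
    g <- sample(nodes, 1)
    rows <- c(rows, list(
      tibble::tibble(pmid = pm, surface = "Oryza sativa",
                     etype = "species", gene_id = ""),
      tibble::tibble(pmid = pm, surface = paste0("Os", g),
                     etype = "gene", gene_id = g)))
    if (stats::runif(1) < 0.3) {
      rows <- c(rows, list(tibble::tibble(
        pmid = pm, surface = "gibberellic acid", etype = "chemical",
        gene_id = "")))
    }
  }
  text_tbl <- dplyr::bind_rows(rows)

  ## ---- write files ----------------------------------------------------
  write_gff3(src_genes, path("src_genes.gff3"))
  write_gff3(tgt_genes, path("tgt_genes.gff3"))
  readr::write_tsv(alignment, path("alignment.tsv"), col_names = FALSE)
  readr::write_tsv(orthologs, path("orthologs.tsv"), col_names = FALSE)
  readr::write_tsv(network, path("network.tsv"), col_names = FALSE)
  readr::write_tsv(go_tbl, path("go_terms.tsv"), col_names = FALSE)
  readr::write_tsv(pw_tbl, path("pathways.tsv"), col_names = FALSE)
  readr::write_tsv(text_tbl, path("text_annotations.tsv"),
                   col_names = FALSE)
  readr::write_tsv(tibble::tibble(chrom = chroms, size = spec$chrom_len),
                   path("chrom_sizes_source.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(chrom = chroms,
                                  size = spec$chrom_len + reserve),
                   path("chrom_sizes_target.tsv"), col_names = FALSE)
  writeLines(format_region(regions), path("regions.txt"))
  yaml::write_yaml(list(
    regions_file = "regions.txt",
    source_genome = "SRC", target_genome = "TGT",
    src_gff = "src_genes.gff3", tgt_gff = "tgt_genes.gff3",
    alignment = "alignment.tsv", orthologs = "orthologs.tsv",
    network = "network.tsv", algo = "clusterone",
    go_terms = "go_terms.tsv", pathways = "pathways.tsv",
    tfbs_dir = "tfbs", chrom_sizes = "chrom_sizes_source.tsv",
    n_perm = 200, text_annotations = "text_annotations.tsv",
    seed = spec$seed, out_dir = "results"), path("config.yaml"))

  ## ---- expected lift-over partition (by construction) -----------------
  # every implicated gene's copy sits inside the lifted region and is an
  # ortholog pair, except deleted genes (no copy) and the group-less copy;
  # t_extra1 is the one ortholog-elsewhere gene; deleted and group-less
  # source genes have no ortholog in the lifted region
  n_del_loci <- length(intersect(del_ids, implicated))
  n_nogrp_loci <- length(intersect(no_group_tgt, implicated))
  expected <- list(
    common_pairs = spec$n_implicated - n_del_loci - n_nogrp_loci,
    ortholog_elsewhere = 1L,
    no_ortholog = n_nogrp_loci,
    unique_to_source = n_del_loci + n_nogrp_loci)
  manifest <- list(
    seed = spec$seed,
    genomes = list(source = "SRC", target = "TGT"),
    files = list(
      src_gff = "src_genes.gff3", tgt_gff = "tgt_genes.gff3",
      alignment = "alignment.tsv", orthologs = "orthologs.tsv",
      network = "network.tsv", go_terms = "go_terms.tsv",
      pathways = "pathways.tsv", tfbs_dir = "tfbs",
      text_annotations = "text_annotations.tsv",
      chrom_sizes_source = "chrom_sizes_source.tsv",
      chrom_sizes_target = "chrom_sizes_target.tsv",
      regions = "regions.txt"),
    regions = format_region(regions),
    implicated_genes = implicated,
    planted_module = list(
      genes = sort(planted, method = "radix"),
      null = spec$planted_within_p <= spec$background_edge_p),
    planted_term = "TERM001",
    planted_pathway = "PW001",
    planted_tf = planted_tf_name,
    text_query = planted_query,
    text_query_genes = sort(text_genes, method = "radix"),
    rearranged_genes = rearr_ids,
    deleted_genes = del_ids,
    liftover_expected = expected
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

src_genes_tbl <- function(src_genes) {
  out <- src_genes[, c("genome", "gene_id", "chrom", "start", "end",
                       "strand")]
  out$description <- ""
  sort_genes(out)
}

write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, as.integer(genes$start + 1),
                     as.integer(genes$end),
                     ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
                     genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}
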