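make_aln <- function(rows, src = "NB", tgt = "T") {
  alignment_set(rows, src, tgt)
}

seg_row <- function(sc, ss, se, tc, ts, te, strand = "+") {
  tibble::tibble(src_chrom = sc, src_start = ss, src_end = se,
                 tgt_chrom = tc, tgt_start = ts, tgt_end = te,
                 strand = strand)
}

test_that("alignment TSV loads and validates the one-to-one invariants", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Chr1\t0\t100\tchrA\t50\t150\t+",
               "Chr1\t200\t300\tchrA\t400\t500\t-"), f)
  aln <- read_alignments(f, "NB", "T")
  expect_equal(nrow(aln), 2)
  expect_equal(attr(aln, "source_genome"), "NB")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Chr1\t0\t100\tchrA\t0\t99\t+", f2)
  expect_error(read_alignments(f2), "length-preserving")

  # overlap on the target side
  expect_error(make_aln(dplyr::bind_rows(
    seg_row("Chr1", 0, 100, "chrA", 0, 100),
    seg_row("Chr2", 0, 100, "chrA", 50, 150))),
    "one-to-one.*target")
  # overlap on the source side
  expect_error(make_aln(dplyr::bind_rows(
    seg_row("Chr1", 0, 100, "chrA", 0, 100),
    seg_row("Chr1", 50, 150, "chrB", 0, 100))),
    "one-to-one.*source")
})

test_that("projection applies the affine segment maps", {
  aln <- make_aln(seg_row("Chr12", 1000, 2000, "chrA", 5000, 6000))
  got <- project_interval(intervals_tbl("NB", "Chr12", 1500, 1600), aln)
  expect_equal(c(got$chrom, got$start, got$end),
               c("chrA", 5500, 1600 + 4000))

  rev <- make_aln(seg_row("Chr12", 1000, 2000, "chrA", 5000, 6000, "-"))
  got2 <- project_interval(intervals_tbl("NB", "Chr12", 1000, 1010), rev)
  expect_equal(c(got2$start, got2$end), c(5990, 6000))

  expect_equal(nrow(suppressWarnings(
    project_interval(intervals_tbl("NB", "Chr9", 0, 100), aln))), 0)
})

test_that("a query spanning two rearranged segments lands on two chromosomes", {
  aln <- make_aln(dplyr::bind_rows(
    seg_row("Chr1", 0, 1000, "chrA", 0, 1000),
    seg_row("Chr1", 1000, 2000, "chrB", 7000, 8000)))
  got <- project_interval(intervals_tbl("NB", "Chr1", 500, 1500), aln)
  expect_setequal(got$chrom, c("chrA", "chrB"))
  expect_equal(sum(got$end - got$start), 1000)
})

test_that("abutting images merge and unaligned gaps are not bridged", {
  # two segments abutting on the target
  aln <- make_aln(dplyr::bind_rows(
    seg_row("Chr1", 0, 100, "chrA", 0, 100),
    seg_row("Chr1", 100, 200, "chrA", 100, 200)))
  got <- project_interval(intervals_tbl("NB", "Chr1", 50, 150), aln)
  expect_equal(nrow(got), 1)
  expect_equal(c(got$start, got$end), c(50, 150))

  # gap in the target: two separate images
  aln2 <- make_aln(dplyr::bind_rows(
    seg_row("Chr1", 0, 100, "chrA", 0, 100),
    seg_row("Chr1", 100, 200, "chrA", 500, 600)))
  got2 <- project_interval(intervals_tbl("NB", "Chr1", 50, 150), aln2)
  expect_equal(nrow(got2), 2)
})

test_that("projection round-trips through the alignment", {
  set.seed(5)
  aln <- make_aln(dplyr::bind_rows(
    seg_row("Chr1", 0, 5000, "chrA", 10000, 15000),
    seg_row("Chr1", 6000, 9000, "chrB", 0, 3000, "-"),
    seg_row("Chr2", 100, 4100, "chrA", 20000, 24000, "-")))
  for (i in 1:100) {
    seg_i <- sample.int(3, 1)
    src_s <- c(0, 6000, 100)[seg_i]
    src_e <- c(5000, 9000, 4100)[seg_i]
    chrom <- c("Chr1", "Chr1", "Chr2")[seg_i]
    a <- src_s + sample.int(src_e - src_s - 1, 1) - 1
    b <- a + sample.int(src_e - a, 1)
    q <- intervals_tbl("NB", chrom, a, b)
    fwd <- project_interval(q, aln, "source_to_target")
    back <- project_interval(fwd, aln, "target_to_source")
    expect_equal(nrow(back), 1)
    expect_equal(c(back$start, back$end), c(a, b))
    expect_equal(norm_chrom(back$chrom), norm_chrom(chrom))
  }
})

test_that("projected length never exceeds query length, equal iff covered", {
  aln <- make_aln(dplyr::bind_rows(
    seg_row("Chr1", 1000, 2000, "chrA", 0, 1000),
    seg_row("Chr1", 3000, 4000, "chrA", 5000, 6000, "-")))
  inside <- project_interval(intervals_tbl("NB", "Chr1", 1200, 1300), aln)
  expect_equal(sum(inside$end - inside$start), 100)
  spanning <- project_interval(intervals_tbl("NB", "Chr1", 1500, 3500), aln)
  expect_lt(sum(spanning$end - spanning$start), 2000)
  expect_equal(sum(spanning$end - spanning$start), 1000)
})

test_that("projection is monotone forward and order-reversing on reverse strand", {
  fwd <- make_aln(seg_row("Chr1", 0, 10000, "chrA", 0, 10000))
  rev <- make_aln(seg_row("Chr1", 0, 10000, "chrA", 0, 10000, "-"))
  xs <- c(100, 2500, 7000)
  f_starts <- vapply(xs, function(x)
    project_interval(intervals_tbl("NB", "Chr1", x, x + 10), fwd)$start,
    numeric(1))
  r_starts <- vapply(xs, function(x)
    project_interval(intervals_tbl("NB", "Chr1", x, x + 10), rev)$start,
    numeric(1))
  expect_true(all(diff(f_starts) > 0))
  expect_true(all(diff(r_starts) < 0))
})

test_that("gene sets partition into the four ortholog categories", {
  src_genes <- genes_tbl("NB", "Chr1", c(100, 300, 500, 5000),
                         c(200, 400, 600, 5100),
                         gene_id = c("g1", "g2", "g3", "g9"))
  tgt_genes <- genes_tbl("T", "chrA", c(100, 300, 500),
                         c(200, 400, 600),
                         gene_id = c("t1", "t2", "t3"))
  aln <- make_aln(seg_row("Chr1", 0, 1000, "chrA", 0, 1000))
  ort <- tibble::tibble(
    group_id = c("OG1", "OG1", "OG2", "OG2"),
    genome = c("NB", "T", "NB", "T"),
    gene_id = c("g1", "t1", "g9", "t2"))
  cmp <- liftover_gene_sets(intervals_tbl("NB", "Chr1", 0, 1000),
                            src_genes, tgt_genes, aln, ort)
  expect_equal(cmp$common$src_gene, "g1")
  expect_equal(cmp$common$tgt_gene, "t1")
  expect_equal(cmp$ortholog_elsewhere$tgt_gene, "t2") # ortholog g9 outside
  expect_equal(cmp$no_ortholog$tgt_gene, "t3")
  expect_setequal(cmp$unique_to_source$src_gene, c("g2", "g3"))

  td <- tidy(cmp)
  expect_true(all(c("common", "ortholog_elsewhere", "no_ortholog",
                    "unique_to_source") %in% td$category))
})

test_that("no alignment coverage leaves all source genes unique", {
  src_genes <- genes_tbl("NB", "Chr1", c(100, 300), c(200, 400),
                         gene_id = c("g1", "g2"))
  tgt_genes <- genes_tbl("T", "chrA", 100, 200, gene_id = "t1")
  aln <- make_aln(seg_row("Chr9", 0, 1000, "chrZ", 0, 1000))
  cmp <- suppressWarnings(liftover_gene_sets(
    intervals_tbl("NB", "Chr1", 0, 1000), src_genes, tgt_genes, aln,
    tibble::tibble(group_id = character(0), genome = character(0),
                   gene_id = character(0))))
  expect_equal(nrow(cmp$tgt_genes_in_loci), 0)
  expect_setequal(cmp$unique_to_source$src_gene, c("g1", "g2"))
})

test_that("a genome compared against itself through identity alignment is all common", {
  genes <- genes_tbl("NB", "Chr1", c(100, 300), c(200, 400),
                     gene_id = c("g1", "g2"))
  aln <- make_aln(seg_row("Chr1", 0, 1000, "Chr1", 0, 1000),
                  src = "NB", tgt = "NB")
  cmp <- liftover_gene_sets(intervals_tbl("NB", "Chr1", 0, 1000),
                            genes, genes, aln,
                            tibble::tibble(group_id = character(0),
                                           genome = character(0),
                                           gene_id = character(0)))
  expect_equal(cmp$common$src_gene, cmp$common$tgt_gene)
  expect_setequal(cmp$common$src_gene, c("g1", "g2"))
  expect_equal(nrow(cmp$unique_to_source), 0)
  expect_equal(nrow(cmp$no_ortholog), 0)
})

test_that("target-side categories are exhaustive and disjoint on random fixtures", {
  set.seed(23)
  for (rep in 1:200) {
    n_src <- sample(3:8, 1)
    n_tgt <- sample(3:8, 1)
    src_genes <- genes_tbl("NB", "Chr1", s <- sort(sample.int(5e3, n_src)) * 10,
                           s * 10 + 50, gene_id = sprintf("g%d", 1:n_src))
    tgt_genes <- genes_tbl("T", "chrA", t <- sort(sample.int(5e3, n_tgt)) * 10,
                           t * 10 + 50, gene_id = sprintf("t%d", 1:n_tgt))
    aln <- make_aln(seg_row("Chr1", 0, 6e5, "chrA", 0, 6e5))
    # random orthology: each target gene joins a random source gene's
    # group with prob 0.6
    rows <- list()
    for (i in seq_len(n_tgt)) {
      if (runif(1) < 0.6) {
        j <- sample.int(n_src, 1)
        rows <- c(rows, list(tibble::tibble(
          group_id = sprintf("OG%d", i),
          genome = c("NB", "T"),
          gene_id = c(sprintf("g%d", j), sprintf("t%d", i)))))
      }
    }
    ort <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble::tibble(group_id = character(0), genome = character(0),
                     gene_id = character(0))
    ort <- ort[!duplicated(ort[, c("genome", "gene_id")]), ]
    q <- intervals_tbl("NB", "Chr1", 0, sample(c(1e5, 3e5, 6e5), 1))
    cmp <- liftover_gene_sets(q, src_genes, tgt_genes, aln, ort)
    in_loci <- cmp$tgt_genes_in_loci$gene_id
    cats <- list(unique(cmp$common$tgt_gene),
                 cmp$ortholog_elsewhere$tgt_gene,
                 cmp$no_ortholog$tgt_gene)
    expect_setequal(unlist(cats), in_loci)
    expect_equal(sum(lengths(cats)), length(in_loci))
  }
})
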