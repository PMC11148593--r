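test_that("region strings parse with 1-based inclusive printed convention", {
  r <- parse_region("Chr01:1523,625-1770814")
  expect_equal(r$chrom, "Chr01")
  expect_equal(r$start, 1523624)
  expect_equal(r$end, 1770814)

  r2 <- parse_region("Chr04:4662701-4670717")
  expect_equal(c(r2$start, r2$end), c(4662700, 4670717))

  # chr prefix canonicalized, whitespace tolerated
  expect_equal(parse_region("  chr7:10-20 ")$chrom, "Chr7")
})

test_that("malformed or degenerate regions are rejected with the offender named", {
  expect_error(parse_region("Chr1:5-5"), "degenerate|empty")
  expect_error(parse_region("Chr1:50-10"), "exceeds")
  expect_error(parse_region("Chr1:abc-10"), "cannot parse.*abc")
  expect_error(parse_region("banana"), "banana")
  expect_error(parse_region("Chr1:0-10"), ">= 1")
})

test_that("parse_region and format_region round trip on canonical strings", {
  set.seed(42)
  for (i in 1:50) {
    s <- sample.int(1e7, 1)
    e <- s + sample.int(1e5, 1)
    txt <- sprintf("Chr%d:%d-%d", sample.int(12, 1), s, e)
    expect_identical(format_region(parse_region(txt)), txt)
  }
})

test_that("GFF3 gene records convert to half-open 0-based coordinates", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t101\t200\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\tsrc\tgene\t500\t900\t.\t-\t.\tID=g2",
    "chr2\tsrc\tgene\t50\t80\t.\t+\t.\tID=g3"
  ), gff)
  ann <- read_gff3(gff, "NB")
  expect_equal(nrow(ann), 3) # mRNA child ignored
  g1 <- ann[ann$gene_id == "g1", ]
  expect_equal(c(g1$start, g1$end), c(100, 200))
  expect_equal(ann$genome, rep("NB", 3))
  expect_equal(ann[ann$gene_id == "g2", ]$strand, "-")
})

test_that("GFF3 records without an ID are skipped with a warning", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tgene\t300\t400\t.\t+\t.\tName=anonymous"
  ), gff)
  expect_warning(ann <- read_gff3(gff, "NB"), "without an ID")
  expect_equal(ann$gene_id, "g1")
})

test_that("an empty GFF3 yields an empty annotation", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", gff)
  expect_equal(nrow(read_gff3(gff, "NB")), 0)
  expect_error(read_gff3(file.path(tempdir(), "nope.gff3"), "NB"),
               "cannot read")
})

test_that("interval-gene overlap is half-open and deduplicated", {
  genes <- genes_tbl("NB", c("Chr1", "Chr1", "Chr1"),
                     c(150, 300, 200), c(160, 400, 210),
                     gene_id = c("a", "b", "c"))
  hit <- genes_overlapping(intervals_tbl("NB", "Chr1", 100, 200), genes)
  expect_equal(hit$gene_id, "a") # touching gene "c" at 200 excluded

  # gene overlapping two query intervals reported once
  two <- dplyr::bind_rows(intervals_tbl("NB", "Chr1", 140, 155),
                          intervals_tbl("NB", "Chr1", 155, 170))
  expect_equal(genes_overlapping(two, genes)$gene_id, "a")

  empty <- intervals_tbl(character(0), character(0), numeric(0), numeric(0))
  expect_equal(nrow(genes_overlapping(empty, genes)), 0)
})

test_that("overlap queries refuse mismatched genomes", {
  genes <- genes_tbl("NB", "Chr1", 10, 20)
  expect_error(genes_overlapping(intervals_tbl("IR64", "Chr1", 0, 100),
                                 genes),
               "genome mismatch")
})

test_that("overlap query agrees with a brute-force all-pairs scan", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 400
    genes <- genes_tbl("NB", sample(c("Chr1", "Chr2"), n, TRUE),
                       s <- sample.int(1e6, n), s + sample.int(5e3, n),
                       gene_id = sprintf("g%04d", 1:n))
    q <- intervals_tbl("NB", sample(c("Chr1", "Chr2"), 5, TRUE),
                       qs <- sample.int(9e5, 5), qs + sample.int(1e5, 5))
    got <- genes_overlapping(q, genes)$gene_id
    want <- genes$gene_id[vapply(seq_len(n), function(i) {
      any(norm_chrom(genes$chrom[i]) == norm_chrom(q$chrom) &
            genes$start[i] < q$end & q$start < genes$end[i])
    }, logical(1))]
    expect_setequal(got, want)
  }
})

test_that("gene-vs-interval overlap is symmetric", {
  set.seed(11)
  for (rep in 1:20) {
    g_start <- sample.int(1e5, 1)
    g_end <- g_start + sample.int(5e3, 1)
    i_start <- sample.int(1e5, 1)
    i_end <- i_start + sample.int(5e3, 1)
    gene <- genes_tbl("NB", "Chr1", g_start, g_end, gene_id = "g")
    fwd <- nrow(genes_overlapping(intervals_tbl("NB", "Chr1", i_start,
                                                i_end), gene)) == 1
    # reversed roles: treat the gene span as the query
    iv_gene <- genes_tbl("NB", "Chr1", i_start, i_end, gene_id = "i")
    rev <- nrow(genes_overlapping(intervals_tbl("NB", "Chr1", g_start,
                                                g_end), iv_gene)) == 1
    expect_identical(fwd, rev)
  }
})

test_that("ortholog lookup returns the target-genome group members", {
  ort <- tibble::tibble(
    group_id = c("OG1", "OG1", "OG2"),
    genome = c("NB", "IR64", "NB"),
    gene_id = c("g1", "t1", "g2"))
  expect_equal(orthologs_of(ort, "g1", "IR64"), "t1")
  expect_equal(orthologs_of(ort, "missing", "IR64"), character(0))
  expect_equal(orthologs_of(ort, "g2", "IR64"), character(0)) # singleton
})

test_that("ortholog TSV rejects a gene in two groups of the same genome", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("OG1\tNB\tg1", "OG2\tNB\tg1"), f)
  expect_error(read_orthologs(f), "more than one group")
})

test_that("BED3+ input is validated and sorted", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t500\t600\tsiteB", "chr1\t10\t10\tbad",
               "chr1\t100\t200\tsiteA"), f)
  expect_warning(b <- read_bed(f, "NB"), "rejecting 1")
  expect_equal(b$name, c("siteA", "siteB"))
  expect_equal(b$start, c(100, 500))
})
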