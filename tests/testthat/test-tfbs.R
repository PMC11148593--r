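sizes2 <- tibble::tibble(chrom = c("Chr1", "Chr2"), size = c(1e6, 1e6))

test_that("site-centric overlap counting is half-open", {
  q <- intervals_tbl("NB", "Chr1", 100, 200)
  sites <- intervals_tbl("NB", c("Chr1", "Chr1"), c(150, 300), c(160, 310))
  expect_equal(count_overlaps_sites(q, sites), 1L)
  expect_equal(count_overlaps_sites(q, intervals_tbl("NB", "Chr1", 200, 210)),
               0L)
  expect_equal(count_overlaps_sites(q, sites[0, ]), 0L)
})

test_that("overlap counting agrees with the quadratic scan and GenomicRanges", {
  set.seed(19)
  for (rep in 1:20) {
    nq <- sample(1:10, 1)
    ns <- sample(1:200, 1)
    q <- intervals_tbl("NB", sample(c("Chr1", "Chr2"), nq, TRUE),
                       qs <- sample.int(1e5, nq), qs + sample.int(2e4, nq))
    sites <- intervals_tbl("NB", sample(c("Chr1", "Chr2"), ns, TRUE),
                           ss <- sample.int(12e4, ns),
                           ss + sample.int(500, ns))
    got <- count_overlaps_sites(q, sites)
    expect_equal(got, oracle_overlap_count(q, sites))
    gr_q <- GenomicRanges::GRanges(norm_chrom(q$chrom),
                                   IRanges::IRanges(q$start + 1, q$end))
    gr_s <- GenomicRanges::GRanges(norm_chrom(sites$chrom),
                                   IRanges::IRanges(sites$start + 1,
                                                    sites$end))
    expect_equal(got,
                 sum(GenomicRanges::countOverlaps(gr_s, gr_q) > 0))
  }
})

test_that("shuffling preserves lengths and stays inside the chromosome", {
  q <- intervals_tbl("NB", "Chr1", 100, 200)
  sizes <- tibble::tibble(chrom = "Chr1", size = 1000)
  for (s in 1:25) {
    shuf <- shuffle_intervals(q, sizes, seed = s)
    expect_gte(shuf$start, 0)
    expect_lte(shuf$start, 900)
    expect_equal(shuf$end - shuf$start, 100)
    expect_equal(shuf$chrom, "Chr1")
  }
  expect_identical(shuffle_intervals(q, sizes, seed = 4),
                   shuffle_intervals(q, sizes, seed = 4))

  # interval as long as its chromosome stays put
  full <- intervals_tbl("NB", "Chr1", 0, 1000)
  expect_equal(shuffle_intervals(full, sizes, seed = 1)$start, 0)
  too_long <- intervals_tbl("NB", "Chr1", 0, 1001)
  expect_error(shuffle_intervals(too_long, sizes), "longer than")
})

test_that("shuffle positions cover the support roughly uniformly", {
  q <- intervals_tbl("NB", "Chr1", 0, 100)
  sizes <- tibble::tibble(chrom = "Chr1", size = 1000)
  starts <- vapply(1:400, function(s)
    shuffle_intervals(q, sizes, seed = s)$start, numeric(1))
  expect_gt(min(starts), -1)
  expect_lte(max(starts), 900)
  # both halves of the support are visited
  expect_gt(mean(starts < 450), 0.3)
  expect_gt(mean(starts >= 450), 0.3)
})

test_that("TFs without observed overlap are excluded from testing", {
  q <- intervals_tbl("NB", "Chr1", 1000, 2000)
  tfbs <- tibble::tibble(
    tf = c("hit", "miss"), genome = "NB", chrom = "Chr1",
    start = c(1500, 5e5), end = c(1520, 5e5 + 20))
  res <- tfbs_enrichment(q, tfbs, sizes2, n_perm = 20, seed = 1)
  expect_equal(res$tf, "hit")
  expect_equal(res$p_raw, (1 + res$null_ge) / 21)
  expect_gte(res$p_raw, 1 / 21)
})

test_that("sites tiling the query attain the permutation floor", {
  # query is a tiny fraction of the genome and every site sits inside it
  q <- intervals_tbl("NB", "Chr1", 10000, 12000)
  starts <- seq(10000, 11900, by = 100)
  tfbs <- tibble::tibble(tf = "dense", genome = "NB", chrom = "Chr1",
                         start = starts, end = starts + 50)
  res <- tfbs_enrichment(q, tfbs, sizes2, n_perm = 999, seed = 2)
  expect_equal(res$p_raw, 1 / 1000)
  expect_equal(res$observed, length(starts))
})

test_that("the full procedure is deterministic given the seed", {
  set.seed(101)
  q <- intervals_tbl("NB", c("Chr1", "Chr2"), c(1e4, 2e4), c(3e4, 5e4))
  tfbs <- tibble::tibble(
    tf = rep(c("A", "B"), each = 40), genome = "NB",
    chrom = sample(c("Chr1", "Chr2"), 80, TRUE),
    start = st <- sample.int(9e5, 80))
  tfbs$end <- tfbs$start + 25
  r1 <- tfbs_enrichment(q, tfbs, sizes2, n_perm = 99, seed = 12)
  r2 <- tfbs_enrichment(q, tfbs, sizes2, n_perm = 99, seed = 12)
  expect_identical(r1, r2)
  r3 <- tfbs_enrichment(q, tfbs, sizes2, n_perm = 99, seed = 13)
  expect_false(identical(r1$null_ge, r3$null_ge))
})

test_that("TFBS collections load from a directory of per-TF BEDs", {
  d <- withr::local_tempdir()
  writeLines("Chr1\t10\t30", file.path(d, "TFA.bed"))
  writeLines(c("Chr2\t5\t25", "Chr1\t40\t60"), file.path(d, "TFB.bed"))
  sites <- read_tfbs(d, "NB", variant = "FunTFBS")
  expect_equal(sites$tf, c("TFA", "TFB", "TFB"))
  expect_equal(attr(sites, "variant"), "FunTFBS")

  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("Chr1\t10\t30\tTFA", "Chr1\t50\t80\tTFB"), f)
  single <- read_tfbs(f, "NB")
  expect_setequal(single$tf, c("TFA", "TFB"))
})
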