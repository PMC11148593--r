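test_that("one-tailed exact test matches the tail-summation oracle", {
  expect_equal(fisher_exact_greater(3, 7, 2, 38),
               oracle_hyper_tail(3, 7, 2, 38), tolerance = 1e-12)
  expect_equal(round(fisher_exact_greater(3, 7, 2, 38), 5), 0.04826)
  expect_equal(fisher_exact_greater(0, 10, 5, 35), 1)
  expect_equal(fisher_exact_greater(5, 0, 45, 0), 1) # all background implicated
  expect_error(fisher_exact_greater(-1, 2, 3, 4), "nonnegative")
})

test_that("exact test agrees with oracle and stats cross-checks on random tables", {
  set.seed(13)
  for (i in 1:200) {
    N <- sample(4:200, 1)
    a <- sample(0:min(20, N), 1)
    b <- sample(0:(N - a), 1)
    c <- sample(0:(N - a - b), 1)
    d <- N - a - b - c
    p <- fisher_exact_greater(a, b, c, d)
    expect_equal(p, oracle_hyper_tail(a, b, c, d), tolerance = 1e-12)
    # independent route: hypergeometric tail from stats
    expect_equal(p, stats::phyper(a - 1, a + c, b + d, a + b,
                                  lower.tail = FALSE), tolerance = 1e-10)
  }
  # and the full Fisher machinery on a handful
  for (i in 1:10) {
    tab <- matrix(sample(0:15, 4, TRUE), 2)
    expect_equal(
      fisher_exact_greater(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
      stats::fisher.test(tab, alternative = "greater")$p.value,
      tolerance = 1e-8)
  }
})

test_that("step-up adjustment equals the direct formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.9, 0.0001)), c(0.9, 0.0002))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, -0.1)), "0, 1")
  expect_equal(bh_adjust(numeric(0)), numeric(0))

  set.seed(3)
  # every permutation of a length-5 list gives the permuted same answer
  base <- c(0.001, 0.02, 0.3, 0.7, 0.04)
  ref <- bh_adjust(base)
  for (i in 1:20) {
    prm <- sample(5)
    expect_equal(bh_adjust(base[prm]), ref[prm])
  }
  for (i in 1:100) {
    p <- runif(sample(1:8, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-15 & adj <= 1))
  }
})

test_that("module enrichment uses the union-of-modules background", {
  mods <- structure(tibble::tibble(
    module_id = 1:2, size = c(10L, 10L),
    cohesiveness = c(0.5, 0.5), density = c(0.5, 0.5),
    genes = list(sprintf("g%d", 1:10), sprintf("g%d", 11:20))),
    class = c("coexpr_modules", "tbl_df", "tbl", "data.frame"))
  res <- enrich_modules(mods, c("g1", "g2", "g3"))
  # N=20, K=3, n=10, a=3 -> C(17,7)/C(20,10)
  expect_equal(res$p_raw, c(choose(17, 7) / choose(20, 10), 1))
  expect_equal(round(res$p_raw[1], 5), 0.10526)
  expect_equal(res$p_adj, c(2 * res$p_raw[1], 1))
  expect_false(any(res$enriched))

  # implicated genes outside the background are dropped with a message
  expect_message(res2 <- enrich_modules(mods, c("g1", "zz")), "1 implicated")
  expect_equal(res2$a, c(1L, 0L))

  # perfectly concentrated implicated set -> enriched after BH
  res3 <- enrich_modules(mods, sprintf("g%d", 1:10))
  expect_lt(res3$p_adj[1], 0.05)
  expect_true(res3$enriched[1])
  expect_false(res3$enriched[2])

  # empty implicated set -> all p = 1
  res4 <- enrich_modules(mods, character(0))
  expect_equal(res4$p_raw, c(1, 1))
})

test_that("null implicated draws reject at most at the nominal rate", {
  set.seed(77)
  mods <- structure(tibble::tibble(
    module_id = 1:4, size = rep(10L, 4),
    cohesiveness = rep(0.5, 4), density = rep(0.5, 4),
    genes = list(sprintf("g%d", 1:10), sprintf("g%d", 11:20),
                 sprintf("g%d", 21:30), sprintf("g%d", 31:40))),
    class = c("coexpr_modules", "tbl_df", "tbl", "data.frame"))
  background <- sprintf("g%d", 1:40)
  alpha <- 0.1
  trials <- 300
  hits <- 0L
  for (t in seq_len(trials)) {
    imp <- sample(background, 6)
    res <- enrich_modules(mods, imp)
    hits <- hits + sum(res$p_raw <= alpha)
  }
  frac <- hits / (4 * trials)
  expect_lte(frac, alpha + 3 * sqrt(alpha * (1 - alpha) / (4 * trials)))
})

test_that("overrepresentation analysis tests terms against the gene universe", {
  background <- sprintf("g%d", 1:50)
  ann <- tibble::tibble(
    term_id = c("T1", "T2"),
    description = c("five-gene term", "disjoint term"),
    namespace = "GO",
    genes = list(sprintf("g%d", 1:5), sprintf("g%d", 40:45)))
  query <- sprintf("g%d", c(1:3, 20:26))
  res <- ora(query, ann, background)
  expect_equal(res$unit_id, "T1") # disjoint term excluded
  expect_equal(res$p_raw, oracle_hyper_tail(3, 2, 7, 38), tolerance = 1e-12)
  expect_equal(round(res$p_raw, 5), 0.04826)

  expect_error(ora(c("g1", "nope"), ann, background), "outside the background")

  # query equal to the background cannot be enriched
  res2 <- ora(background, ann, background)
  expect_true(all(res2$p_raw == 1))
})

test_that("ora adjusts within namespaces separately", {
  background <- sprintf("g%d", 1:30)
  ann <- tibble::tibble(
    term_id = c("GO1", "GO2", "PW1"),
    description = "x",
    namespace = c("GO", "GO", "pathway"),
    genes = list(sprintf("g%d", 1:5), sprintf("g%d", c(1, 6:9)),
                 sprintf("g%d", 1:5)))
  res <- ora(sprintf("g%d", 1:5), ann, background)
  go <- res[res$namespace == "GO", ]
  pw <- res[res$namespace == "pathway", ]
  # the pathway family has a single test: adjusted equals raw
  expect_equal(pw$p_adj, pw$p_raw)
  expect_equal(go$p_adj, oracle_bh(go$p_raw))
})
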