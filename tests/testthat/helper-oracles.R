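# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (direct formulas, quadratic scans, exhaustive
# enumeration) and share no code with the implementation they check.

# hypergeometric upper tail P(X >= a) by direct summation of choose()
oracle_hyper_tail <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  n <- a + b
  if (a == 0) {
    return(1)
  }
  ks <- a:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Benjamini-Hochberg step-up by the textbook formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# quadratic all-pairs half-open overlap scan (site-centric count)
oracle_overlap_count <- function(query, sites) {
  hit <- 0L
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(query))) {
      if (gwaspan::norm_chrom(sites$chrom[i]) ==
            gwaspan::norm_chrom(query$chrom[j]) &&
          sites$start[i] < query$end[j] && query$start[j] < sites$end[i]) {
        hit <- hit + 1L
        break
      }
    }
  }
  hit
}

# cohesiveness recomputed straight from the edge table
oracle_cohesiveness <- function(edges, genes, penalty) {
  w_in <- 0
  w_bound <- 0
  for (i in seq_len(nrow(edges))) {
    a_in <- edges$from[i] %in% genes
    b_in <- edges$to[i] %in% genes
    if (a_in && b_in) w_in <- w_in + edges$weight[i]
    if (xor(a_in, b_in)) w_bound <- w_bound + edges$weight[i]
  }
  denom <- w_in + w_bound + penalty * length(genes)
  if (denom == 0) 0 else w_in / denom
}

# TRUE iff no single-vertex addition or removal improves cohesiveness
oracle_is_local_optimum <- function(edges, genes, penalty, tol = 1e-9) {
  nodes <- unique(c(edges$from, edges$to))
  f0 <- oracle_cohesiveness(edges, genes, penalty)
  for (v in setdiff(nodes, genes)) {
    if (oracle_cohesiveness(edges, c(genes, v), penalty) > f0 + tol) {
      return(FALSE)
    }
  }
  if (length(genes) > 1) {
    for (v in genes) {
      if (oracle_cohesiveness(edges, setdiff(genes, v), penalty) >
            f0 + tol) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# random Erdos-Renyi edge tibble over n named nodes
random_edges <- function(n, p_edge, weighted = FALSE) {
  nodes <- sprintf("n%02d", seq_len(n))
  prs <- utils::combn(nodes, 2)
  keep <- stats::runif(ncol(prs)) < p_edge
  tibble::tibble(
    from = prs[1, keep], to = prs[2, keep],
    weight = if (weighted) round(stats::runif(sum(keep), 0.1, 1), 3) else 1
  )
}

# small gene-model tibble without touching the GFF3 reader
genes_tbl <- function(genome, chrom, start, end,
                      gene_id = sprintf("g%d", seq_along(start))) {
  tibble::tibble(genome = genome, gene_id = gene_id, chrom = chrom,
                 start = start, end = end, strand = "+", description = "")
}

# shared fixture bundle for the expensive end-to-end tests: generated
# once per test run, reused by several files
bundle_dir <- local({
  dir <- NULL
  function(seed = 3) {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), sprintf("gwaspan-bundle-%d", seed))
      if (!dir.exists(dir)) {
        gwaspan::simulate_bundle(gwaspan::fixture_spec(seed = seed), dir)
      }
    }
    dir
  }
})

# permutations of 1..n, tiny and dependency-free
combinat_perms <- function(n) {
  if (n == 1) {
    return(list(1L))
  }
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (k in 0:(n - 1)) {
      out <- c(out, list(append(p, n, after = k)))
    }
  }
  out
}

# Warm the lazily-loaded S4 I/O stack once so timed blocks measure the
# package's algorithms rather than first-use namespace loading.
local({
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\twarm\tgene\t1\t10\t.\t+\t.\tID=w1"), f)
  invisible(gwaspan::read_gff3(f, "warmup"))
  unlink(f)
})
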