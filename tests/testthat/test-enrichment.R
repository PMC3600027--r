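test_that("expected overlap fractions come from the merged footprint", {
  gm <- genome_model(c(chr1 = 3e9), effective_length = 3e9)
  rs <- region_set("half", data.frame(chrom = "chr1", start = 1,
                                      end = 1.5e9))
  expect_equal(expected_overlap_fraction(rs, gm), 0.5)
  empty <- region_set("none", data.frame(chrom = character(0),
                                         start = numeric(0),
                                         end = numeric(0)))
  expect_equal(expected_overlap_fraction(empty, gm), 0)
  # overlap within the set does not inflate the footprint
  dup <- region_set("dup", data.frame(chrom = "chr1",
                                      start = c(1, 1), end = c(1e6, 1e6)))
  expect_equal(expected_overlap_fraction(dup, gm), 1e6 / 3e9)
})

test_that("log-space binomial tail is exact against direct summation", {
  expect_equal(log_binomial_sf(1, 1, 0.5), log10(0.5))
  expect_equal(log_binomial_sf(5, 0, 0.3), 0)
  # closed form at k = n
  expect_equal(log_binomial_sf(29, 29, 0.02), 29 * log10(0.02))
  expect_equal(log_binomial_sf(10, 8, 0.15), oracle_log10_sf(10, 8, 0.15),
               tolerance = 1e-12)
  # grid of small problems, 1e-9 relative agreement on the log scale
  set.seed(23)
  for (i in 1:60) {
    n <- sample.int(100, 1)
    k <- sample.int(n, 1)
    p0 <- runif(1, 0.01, 0.99)
    mine <- log_binomial_sf(n, k, p0)
    ref <- oracle_log10_sf(n, k, p0)
    # relative on the log scale, absolute near log10 p = 0
    expect_lt(abs(mine - ref), 1e-9 * max(1, abs(ref)))
  }
  # deep-tail stability without underflow
  lp <- log_binomial_sf(3000, 2900, 0.1)
  expect_true(is.finite(lp) && lp < -250)
  expect_error(log_binomial_sf(10, 4, 0), "p0")
  expect_error(log_binomial_sf(10, 11, 0.5), "k")
})

test_that("the tail is monotone in k and in p0", {
  lp_k <- vapply(0:20, function(k) log_binomial_sf(20, k, 0.3), numeric(1))
  expect_true(all(diff(lp_k) < 0))
  lp_p <- vapply(seq(0.2, 0.8, by = 0.1),
                 function(p) log_binomial_sf(30, 15, p), numeric(1))
  expect_true(all(diff(lp_p) > 0))
})

test_that("breakpoint overlap test counts hits and picks the tail direction", {
  gm <- genome_model(c(chr1 = 1e6, chr2 = 1e6), effective_length = 2e6)
  rs <- region_set("half", data.frame(chrom = c("chr1", "chr2"),
                                      start = 1, end = 5e5))
  bp <- data.frame(chrom = "chr1", pos = seq(1000, 400000, length.out = 10))
  res <- breakpoint_overlap_test(bp, rs, gm)
  expect_equal(res$k, 10L)
  expect_equal(res$direction, "above")
  expect_equal(res$log10_p, 10 * log10(0.5))

  # breakpoints on a chromosome absent from the set contribute no hits
  bp2 <- data.frame(chrom = "chr3", pos = rep(1000, 5))
  expect_equal(count_in_regions(bp2, rs), 0L)

  # uniform null breakpoints: observed near p0 and non-significant
  set.seed(3)
  bp3 <- data.frame(chrom = sample(c("chr1", "chr2"), 2000, replace = TRUE),
                    pos = floor(runif(2000, 1, 1e6)))
  res3 <- breakpoint_overlap_test(bp3, rs, gm)
  expect_lt(abs(res3$observed_fraction - 0.5), 0.05)
  expect_gt(res3$log10_p, -3)
})

test_that("regions_hit counts merged intervals with any breakpoint", {
  rs <- region_set("five", data.frame(chrom = "chr1",
                                      start = (0:4) * 1e4 + 1,
                                      end = (0:4) * 1e4 + 5000))
  bp <- data.frame(chrom = "chr1", pos = c(100, 2000, 4000))
  expect_equal(regions_hit(bp, rs), 1L)
  expect_equal(regions_hit(bp[0, ], rs), 0L)
  one_each <- data.frame(chrom = "chr1", pos = (0:4) * 1e4 + 2500)
  expect_equal(regions_hit(one_each, rs), 5L)
})

test_that("gene-set enrichment uses the census-style null", {
  none <- gene_set_enrichment(letters[1:10], LETTERS[1:5], 1000)
  expect_equal(none$k, 0L)
  expect_equal(none$log10_p, 0)
  hit <- gene_set_enrichment(c(sprintf("g%d", 1:25), "A", "B", "C", "D"),
                             c("A", "B", "C", "D"), total_genes = 21000,
                             set_size = 420)  # p0 = 0.02
  expect_equal(hit$n, 29L)
  expect_equal(hit$k, 4L)
  expect_equal(hit$log10_p, oracle_log10_sf(29, 4, 0.02), tolerance = 1e-9)
  all_in <- gene_set_enrichment(LETTERS[1:4], LETTERS[1:4],
                                total_genes = 200, set_size = 4)
  expect_equal(all_in$log10_p, 4 * log10(4 / 200))
  expect_error(gene_set_enrichment("A", letters, total_genes = 10),
               "total_genes")
})

test_that("validation aggregation reproduces the cohort totals", {
  tab <- read_validation_summary()
  s <- summarize_validation(tab)
  expect_equal(s$attempted, 165)
  expect_equal(s$validated, 100)
  expect_equal(s$constitutional, 60)
  expect_equal(s$somatic, 40)
  expect_equal(unname(s$somatic_by_type),
               c(8, 6, 26)[match(names(s$somatic_by_type),
                                 c("deletion", "inversion",
                                   "translocation"))])
  expect_equal(s$translocation_constitutional_fraction, 14 / 40)
  expect_equal(s$interchromosomal_somatic_fraction, 26 / 40)
  expect_equal(s$inter_intra_ratio, 26 / 14)
  expect_equal(s$deletion_constitutional_fraction, 43 / 51)

  # empty table: zero totals, undefined ratios
  e <- summarize_validation(tab[0, ])
  expect_equal(e$attempted, 0)
  expect_true(is.na(e$inter_intra_ratio))

  # a row violating the sum invariant is named
  bad <- tab
  bad$deletion_somatic[3] <- bad$deletion_somatic[3] + 1
  expect_error(summarize_validation(bad), "row 3")
})
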