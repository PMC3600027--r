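test_that("mate-pair reader drops flagged records and collapses redundancy", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "s1\tp1\tchr1\t100\t+\tchr1\t2600\t+",
    "s1\tp2\tchr1\t200\t+\tchr1\t2700\t+\tambiguous",
    "s1\tp3\tchr2\t300\t+\tchr2\t2800\t+"), f)
  rec <- read_mate_pairs(f)
  expect_equal(nrow(rec), 2L)
  expect_false("p2" %in% rec$pair_id)

  writeLines(rep("s1\tp1\tchr1\t100\t+\tchr1\t2600\t+", 2), f)
  expect_equal(nrow(read_mate_pairs(f)), 1L)

  file.create(f2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_equal(nrow(read_mate_pairs(f2)), 0L)
})

test_that("malformed input and unknown chromosomes are reported precisely", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tp1\tchr1\t100\t+\tchr1\t2600\t+",
               "s1\tp2\tchr1\t100\t+"), f)
  expect_error(read_mate_pairs(f), "line 2")

  writeLines("s1\tp1\tchrX\t100\t+\tchrX\t2600\t+", f)
  expect_error(read_mate_pairs(f, genome = tiny_genome()),
               "unknown chromosome")
  writeLines("s1\tp1\tchr1\t100\t*\tchr1\t2600\t+", f)
  expect_error(read_mate_pairs(f), "strand")
})

test_that("anchors are canonicalised and write/read round-trips", {
  rec <- pairs_df(c("chr2", "chr1"), c(500, 9000), "+",
                  c("chr1", "chr1"), c(800, 5000), "-",
                  genome = tiny_genome())
  # first record swapped to put chr1 anchor first
  expect_equal(rec$chrom1, c("chr1", "chr1"))
  expect_true(all(rec$pos1 <= rec$pos2 | rec$chrom1 != rec$chrom2))

  f <- withr::local_tempfile(fileext = ".tsv")
  write_mate_pairs(rec, f)
  back <- read_mate_pairs(f, genome = tiny_genome())
  expect_equal(as.data.frame(back)[names(back) != "read_length"],
               as.data.frame(rec)[names(rec) != "read_length"])
})

test_that("insert model estimation matches its contract", {
  # constant separations: median exact, sigma at the 5% floor
  rec <- concordant_pairs(200, sep = 2500)
  m <- estimate_insert_model(rec)
  expect_equal(m$median, 2500)
  expect_equal(m$sigma, 125)
  expect_equal(c(m$lo, m$hi), c(2125, 2875))

  # seeded gaussian separations recover location and scale
  set.seed(1)
  sep <- round(rnorm(10000, 2500, 150))
  rec <- pairs_df("chr1", seq_len(10000) * 10, "+",
                  "chr1", seq_len(10000) * 10 + sep, "+")
  m <- estimate_insert_model(rec)
  expect_lt(abs(m$median - 2500), 10)
  expect_lt(abs(m$sigma - 150), 15)

  # too little data: actionable error; fixed fallback model
  expect_error(estimate_insert_model(concordant_pairs(3)), "insert_size_model")
  d <- insert_size_model()
  expect_equal(unlist(d[c("median", "sigma", "lo", "hi")],
                      use.names = FALSE), c(2500, 125, 2125, 2875))
})

test_that("region sets merge intervals and validate bounds", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100", f)
  rs <- read_bed(f)
  expect_equal(rs$total_length, 100)
  expect_equal(GenomicRanges::start(rs$merged), 1)

  rs <- region_set("m", data.frame(chrom = "chr1", start = c(1, 51),
                                   end = c(100, 150)))
  expect_equal(rs$total_length, 150)
  # idempotent: merging the merged set changes nothing
  rs2 <- region_set("m", rs$merged)
  expect_equal(rs2$total_length, rs$total_length)
  expect_identical(as.data.frame(rs2$merged), as.data.frame(rs$merged))

  expect_error(region_set("bad", data.frame(chrom = "chr1", start = 100,
                                            end = 50)), "end")
  expect_error(region_set("oob", data.frame(chrom = "chr1", start = 1,
                                            end = 2e6),
                          genome = tiny_genome()), "bounds")

  # footprint bounded by genome size
  set.seed(7)
  gm <- tiny_genome()
  for (i in 1:5) {
    s <- sort(sample.int(9e5, 50))
    rs <- region_set("r", data.frame(chrom = "chr1", start = s,
                                     end = pmin(s + sample.int(5e4, 50),
                                                1e6)), genome = gm)
    expect_lte(rs$total_length, sum(gm$chromosomes))
  }
})

test_that("BED12 gene models number exons in transcript orientation", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t1000\t3000\tPLUS\t0\t+\t1000\t3000\t0\t3\t100,100,100,\t0,900,1900,",
    "chr1\t5000\t7000\tMINUS\t0\t-\t5000\t7000\t0\t3\t100,100,100,\t0,900,1900,"),
    f)
  g <- read_genes(f)
  expect_equal(nrow(g$genes), 2L)
  p <- g$exons[g$exons$symbol == "PLUS", ]
  m <- g$exons[g$exons$symbol == "MINUS", ]
  expect_equal(p$exon_number, 1:3)
  expect_equal(m$exon_number, 3:1)  # genomically first exon is exon 3
  expect_equal(p$start[1], 1001)    # BED 0-based converted
})

test_that("BEDPE export round-trips calls exactly", {
  calls <- rbind(
    call_row("deletion", "chr1", 1000, 2000, "chr1", 6000, 7000,
             support = 5, call_id = "a", members = "p1,p2,p3,p4,p5"),
    call_row("translocation", "chr1", 1000, 2000, "chr2", 500, 900,
             support = 7, call_id = "b", orientation = "inverted",
             pattern = "+-", members = "q1,q2"),
    call_row("inversion", "chr2", 100, 400, "chr2", 9000, 9400,
             support = 4, call_id = "c", orientation = "inverted",
             pattern = "-+", members = "r1"))
  class(calls) <- c("sv_calls", "data.frame")
  f <- withr::local_tempfile(fileext = ".bedpe")
  write_bedpe(calls, f)
  back <- read_bedpe(f)
  expect_equal(as.data.frame(back), as.data.frame(calls))
})
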