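make_plus_gene <- function(sym = "GPLUS", chrom = "chr1", first = 100000,
                           n = 12, width = 200, intron = 800) {
  starts <- first + (seq_len(n) - 1) * (width + intron)
  data.frame(symbol = sym, chrom = chrom, strand = "+", start = starts,
             end = starts + width - 1)
}

test_that("breakpoints are labelled by exon or intron in transcript numbering", {
  m <- default_model()
  genes <- gene_models(make_plus_gene())
  # intron 10-11 lies between exon 10 end and exon 11 start
  e10_end <- 100000 + 9 * 1000 + 199
  bp <- e10_end + 400
  call <- call_row("translocation", "chr1", bp, bp, "chr2", 5e5, 5e5,
                   support = 6)
  ann <- annotate_genes(call, genes, m)
  expect_equal(ann$disrupted, "GPLUS (intron 10-11)")

  call2 <- call_row("translocation", "chr1", 100000 + 4 * 1000 + 50,
                    100000 + 4 * 1000 + 60, "chr2", 5e5, 5e5, support = 6)
  expect_equal(annotate_genes(call2, genes, m)$disrupted, "GPLUS (exon 5)")
})

test_that("minus-strand genes number exons from the genomically last one", {
  m <- default_model()
  g <- make_plus_gene("GMINUS", n = 3)
  g$strand <- "-"
  genes <- gene_models(g)
  # hit the genomically first exon: transcript exon 3
  call <- call_row("deletion", "chr1", 100050, 100060, "chr1", 100055,
                   100065, support = 6)
  expect_equal(annotate_genes(call, genes, m)$disrupted, "GMINUS (exon 3)")
  # genomically first intron is intron 2-3 in transcript numbering
  call2 <- call_row("deletion", "chr1", 100400, 100410, "chr1", 100405,
                    100415, support = 6)
  expect_equal(annotate_genes(call2, genes, m)$disrupted,
               "GMINUS (intron 2-3)")
})

test_that("distance controls disruption and the near-gene criterion", {
  m <- default_model()
  genes <- gene_models(make_plus_gene(first = 100000, n = 3))
  gene_end <- 100000 + 2 * 1000 + 199
  # 10 kb away with median 2500: neither disrupted nor near
  far <- call_row("deletion", "chr1", gene_end + 10000, gene_end + 10010,
                  "chr1", gene_end + 10005, gene_end + 10015, support = 6)
  af <- annotate_genes(far, genes, m)
  expect_equal(af$disrupted, "")
  expect_false(af$near_gene)
  # 4 kb away: within two insert lengths
  nearby <- call_row("deletion", "chr1", gene_end + 4000, gene_end + 4010,
                     "chr1", gene_end + 4005, gene_end + 4015, support = 6)
  an <- annotate_genes(nearby, genes, m)
  expect_equal(an$disrupted, "")
  expect_true(an$near_gene)
})

test_that("validation selection enforces the three criteria and deep-sample rules", {
  m <- default_model()
  genes <- gene_models(make_plus_gene())
  mk <- function(sample_id, support, startA = 104000, verdict = NA) {
    k <- call_row("translocation", "chr1", startA, startA + 100, "chr2",
                  5e5, 5e5 + 100, support = support, sample_id = sample_id,
                  call_id = paste0(sample_id, "_", support))
    k$verdict <- verdict
    k
  }
  cohort <- rbind(mk("s1", 4), mk("s2", 6), mk("s3", 3),
                  mk("s4", 5, startA = 110500))
  class(cohort) <- c("sv_calls", "data.frame")
  ann <- annotate_genes(cohort, genes, m)
  sel <- select_candidates(ann, m)
  # s1/s2 recur and sit in the gene; s3 fails support; s4 is non-recurrent
  expect_equal(sel$selected, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sel$recurrent, c(TRUE, TRUE, TRUE, FALSE))
  # recurrence is symmetric by construction
  expect_equal(sel$recurrent[1], sel$recurrent[2])
  # relaxed mode drops criterion 3
  rel <- select_candidates(ann, m, require_recurrent = FALSE)
  expect_equal(rel$selected, c(TRUE, TRUE, FALSE, TRUE))
  # raising min_support never adds candidates
  for (ms in c(5, 6, 40)) {
    stricter <- select_candidates(ann, m, min_support = ms)
    expect_true(all(!stricter$selected | sel$selected))
  }
  # deep samples: support >= 40 and a passing correlation verdict
  deep <- rbind(mk("d1", 45, verdict = "pass"),
                mk("d2", 45, verdict = "fail"),
                mk("d3", 12, verdict = "pass"))
  class(deep) <- c("sv_calls", "data.frame")
  dsel <- select_candidates(annotate_genes(deep, genes, m), m,
                            deep_samples = c("d1", "d2", "d3"))
  expect_equal(dsel$selected, c(TRUE, FALSE, FALSE))
})

test_that("primer flanks sit immediately outside the brackets, truncated at ends", {
  gm <- tiny_genome()
  call <- call_row("deletion", "chr1", 10001, 10500, "chr1", 20001, 20500,
                   support = 6)
  fl <- primer_flanks(call, genome = gm)
  expect_equal(fl$start, c(9801, 20501))
  expect_equal(fl$end, c(10000, 20700))
  # 50 bp from the chromosome start: left flank truncated
  call2 <- call_row("deletion", "chr1", 51, 500, "chr1", 20001, 20500,
                    support = 6)
  fl2 <- primer_flanks(call2, genome = gm)
  expect_equal(fl2$start[1], 1)
  expect_equal(fl2$end[1], 50)
  # translocations get flanks on both chromosomes
  call3 <- call_row("translocation", "chr1", 10001, 10500, "chr2", 30001,
                    30500, support = 6)
  fl3 <- primer_flanks(call3, genome = gm)
  expect_equal(fl3$chrom, c("chr1", "chr2"))
})

test_that("the packaged breakpoint table reproduces its printed gene labels", {
  genes <- read_genes(matesv_extdata("sv_gene_models_synthetic.bed"))
  tab <- read_sv_table()
  calls <- data.frame(call_id = sprintf("fx%02d", seq_len(nrow(tab))),
                      sample_id = tab$sample_id, type = tab$type,
                      chromA = tab$chrom1, startA = tab$breakpoint1,
                      endA = tab$breakpoint1, chromB = tab$chrom2,
                      startB = tab$breakpoint2, endB = tab$breakpoint2,
                      orientation = "same", pattern = "++", support = 10L,
                      members = "", stringsAsFactors = FALSE)
  class(calls) <- c("sv_calls", "data.frame")
  ann <- annotate_genes(calls, genes, default_model())
  norm <- function(x) vapply(strsplit(x, ";\\s*"), function(p)
    paste(sort(trimws(p[p != ""])), collapse = "; "), character(1))
  expect_equal(norm(ann$disrupted), norm(tab$disrupted_genes))
  syms <- unique(sub(" .*", "", unlist(strsplit(
    tab$disrupted_genes[tab$disrupted_genes != ""], ";\\s*"))))
  expect_equal(length(syms), 29L)
})
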