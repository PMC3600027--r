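small_cfg <- function(seed = 5, ...) {
  simulation_config(n_chromosomes = 2, chromosome_length = 2e6,
                    n_genes = 10, n_deletions = 2, n_insertions = 1,
                    n_inversions = 1, n_translocations = 1, n_decoys = 1,
                    chimera_rate = 0.002, n_controls = 1, seed = seed, ...)
}

test_that("the generator is deterministic under its seed", {
  a <- simulate_study(small_cfg())
  b <- simulate_study(small_cfg())
  expect_identical(a$truth, b$truth)
  expect_identical(as.data.frame(a$samples$tumor$records),
                   as.data.frame(b$samples$tumor$records))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_mate_pairs(a$samples$tumor$records, f1)
  write_mate_pairs(b$samples$tumor$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  c_ <- simulate_study(small_cfg(seed = 6))
  expect_false(identical(as.data.frame(a$samples$tumor$records),
                         as.data.frame(c_$samples$tumor$records)))
})

test_that("a rearrangement-free, noise-free genome yields only concordant pairs", {
  cfg <- simulation_config(n_chromosomes = 1, chromosome_length = 1e6,
                           n_genes = 0, n_deletions = 0, n_insertions = 0,
                           n_inversions = 0, n_translocations = 0,
                           n_decoys = 0, chimera_rate = 0, n_controls = 0,
                           seed = 2)
  study <- simulate_study(cfg)
  cl <- classify_pairs(study$samples$tumor$records,
                       insert_size_model(2500, 150))
  expect_equal(mean(cl$category == "concordant"), 1)
})

test_that("implant constraints and error paths hold", {
  cfg <- small_cfg(germline_fraction = 1)
  study <- simulate_study(cfg)
  expect_true(all(study$truth$status == "germline"))
  del <- study$truth[study$truth$type == "deletion", ]
  expect_true(all(del$pos2 - del$pos1 + 1 >= 3000 &
                  del$pos2 - del$pos1 + 1 <= 10000))
  # breakpoints inside chromosome bounds and clear of excluded regions
  expect_true(all(study$truth$pos1 > 0 & study$truth$pos2 <= 2e6))

  one_chrom <- simulation_config(n_chromosomes = 1,
                                 chromosome_length = 1e6, n_genes = 0,
                                 n_translocations = 1, seed = 3)
  sim <- simulate_genome(one_chrom)
  expect_error(implant_svs(sim, one_chrom), "chromosomes")

  dense <- simulation_config(n_chromosomes = 1, chromosome_length = 1e6,
                             n_genes = 5000, seed = 4)
  expect_error(simulate_genome(dense), "density")

  none <- simulation_config(n_chromosomes = 1, chromosome_length = 1e6,
                            n_genes = 0, n_translocations = 0, seed = 4)
  expect_equal(nrow(simulate_genome(none)$genes$genes), 0L)
})

test_that("a somatic deletion at 8-fold clone coverage is well supported", {
  # expected junction-spanning fragments ~ coverage * (median - 2r)/median
  hits <- vapply(1:20, function(seed) {
    cfg <- simulation_config(n_chromosomes = 1, chromosome_length = 8e5,
                             n_genes = 0, n_deletions = 1,
                             deletion_size = c(5000, 5000),
                             n_insertions = 0, n_inversions = 0,
                             n_translocations = 0, germline_fraction = 0,
                             n_decoys = 0, chimera_rate = 0,
                             n_controls = 0, seed = seed)
    study <- simulate_study(cfg)
    nrow(study$samples$tumor$pair_truth)
  }, numeric(1))
  expect_gte(mean(hits >= 4), 0.9)
  expect_gt(mean(hits), 6)
})

test_that("germline implants are vetoed by the matched normal", {
  flagged <- 0L; eligible <- 0L
  for (seed in c(31, 32, 33)) {
    cfg <- simulation_config(seed = seed, germline_fraction = 0.6)
    study <- simulate_study(cfg)
    model <- insert_size_model(2500, 150)
    tum_calls <- cluster_events(
      classify_pairs(study$samples$tumor$records, model), model)
    nrm_calls <- cluster_events(
      classify_pairs(study$samples$normal$records, model), model)
    res <- apply_filters(tum_calls, study$genome, model,
      filter_config(matched_normal = nrm_calls))
    germ <- study$truth[study$truth$status == "germline", ]
    ev <- evaluate_recovery(res$calls, germ)
    idx <- which(ev$call_matched & res$calls$support >= 4)
    eligible <- eligible + length(idx)
    flagged <- flagged + sum(res$calls$in_matched_normal[idx])
  }
  expect_gt(eligible, 10)
  expect_gte(flagged / eligible, 0.95)
})
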