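test_that("calls near excluded regions are flagged at two insert lengths", {
  gm <- tiny_genome()  # chr1 centromere at [500001, 510000]
  m <- default_model()
  # breakpoint region ending 4000 bp before the centromere: 4000 < 5000
  near <- call_row("deletion", "chr1", 490001, 496000, "chr1", 520001,
                   526000, support = 6, call_id = "near")
  far <- call_row("deletion", "chr1", 100000, 106000, "chr1", 120000,
                  126000, support = 6, call_id = "far")
  calls <- rbind(near, far)
  class(calls) <- c("sv_calls", "data.frame")
  res <- apply_filters(calls, gm, m, filter_config())
  expect_equal(res$calls$near_excluded, c(TRUE, FALSE))
  expect_equal(res$calls$pass, c(FALSE, TRUE))
})

test_that("control, known-variant, support and matched-normal flags apply", {
  gm <- tiny_genome()
  m <- default_model()
  a <- call_row("deletion", "chr1", 100000, 105000, "chr1", 120000, 125000,
                support = 6, call_id = "a")
  b <- call_row("deletion", "chr1", 200000, 205000, "chr1", 220000, 225000,
                support = 3, call_id = "b")
  c_ <- call_row("inversion", "chr1", 300000, 305000, "chr1", 320000,
                 325000, support = 8, call_id = "c", pattern = "+-",
                 orientation = "inverted")
  calls <- rbind(a, b, c_)
  class(calls) <- c("sv_calls", "data.frame")

  ctl <- call_row("deletion", "chr1", 100500, 105500, "chr1", 120500,
                  125500, support = 5, sample_id = "ctl")
  nrm <- call_row("inversion", "chr1", 300100, 305100, "chr1", 320100,
                  325100, support = 5, sample_id = "nrm", pattern = "+-",
                  orientation = "inverted")
  kv <- region_set("dgv", data.frame(chrom = "chr1", start = 202000,
                                     end = 222000, type = "deletion"))
  res <- apply_filters(calls, gm, m,
    filter_config(control_calls = list(ctl), known_variants = kv,
                  matched_normal = nrm))
  df <- res$calls
  expect_equal(df$in_control, c(TRUE, FALSE, FALSE))
  expect_equal(df$known_variant, c(FALSE, TRUE, FALSE))
  expect_equal(df$low_support, c(FALSE, TRUE, FALSE))
  expect_equal(df$in_matched_normal, c(FALSE, FALSE, TRUE))
  expect_equal(df$pass, c(FALSE, FALSE, FALSE))
  expect_equal(res$report$stage,
               c("in_control", "near_excluded", "known_variant",
                 "low_support", "in_matched_normal"))

  # an untyped known variant matches regardless of call type; a
  # single-pair "event" in a companion sample is not treated as observed
  kv2 <- region_set("dgv", data.frame(chrom = "chr1", start = 302000,
                                      end = 322000))
  ctl1 <- ctl
  ctl1$support <- 1L
  res2 <- apply_filters(calls, gm, m,
    filter_config(control_calls = list(ctl1), known_variants = kv2))
  expect_equal(res2$calls$known_variant, c(FALSE, FALSE, TRUE))
  expect_false(any(res2$calls$in_control))
})

test_that("flags are independent and support thresholds nest", {
  gm <- tiny_genome()
  m <- default_model()
  set.seed(5)
  rows <- lapply(1:20, function(i) {
    s <- sample.int(8e5, 1) + 5e4
    call_row("deletion", "chr1", s, s + 5000, "chr1", s + 15000, s + 20000,
             support = sample.int(8, 1), call_id = sprintf("r%02d", i))
  })
  calls <- do.call(rbind, rows)
  class(calls) <- c("sv_calls", "data.frame")
  r4 <- apply_filters(calls, gm, m, filter_config(min_support = 4))
  r3 <- apply_filters(calls, gm, m, filter_config(min_support = 3))
  # pass under the stricter threshold is a subset of the relaxed one
  expect_true(all(!r4$calls$pass | r3$calls$pass))
  # pass is exactly "no flag raised", independent of stage order
  flags <- as.matrix(r4$calls[, c("in_control", "near_excluded",
                                  "known_variant", "low_support",
                                  "in_matched_normal")])
  expect_equal(r4$calls$pass, !apply(flags, 1, any))
})

test_that("clean somatic simulations lose calls only to the support stage", {
  cfg <- simulation_config(n_chromosomes = 2, chromosome_length = 2e6,
                           n_genes = 0, n_deletions = 3, n_insertions = 0,
                           n_inversions = 2, n_translocations = 1,
                           germline_fraction = 0, n_decoys = 0,
                           chimera_rate = 0, n_controls = 1, seed = 42)
  study <- simulate_study(cfg)
  tum <- study$samples$tumor
  model <- insert_size_model(2500, 150)
  calls <- cluster_events(classify_pairs(tum$records, model), model)
  res <- run_pipeline(tum$records, study$genome, model = model,
                      control_records = list(study$samples$control1$records),
                      matched_normal_records = study$samples$normal$records)
  rep <- res$report
  other <- rep[rep$stage != "low_support", ]
  expect_equal(sum(other$calls_flagged), 0L)
  expect_equal(attr(rep, "removed_fraction_presupport"), 0)
})
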