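# shared in-code fixtures for the test suite

tiny_genome <- function() {
  genome_model(
    c(chr1 = 1e6, chr2 = 1e6),
    excluded = data.frame(
      chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
      start = c(1, 990001, 500001, 1, 990001),
      end = c(10000, 1e6, 510000, 10000, 1e6),
      label = c("telomere", "telomere", "centromere", "telomere",
                "telomere")))
}

default_model <- function() insert_size_model(2500, 125)

# build a mate_pairs table from anchor vectors
pairs_df <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                     sample_id = "s1", pair_id = NULL, genome = NULL) {
  n <- max(length(pos1), length(pos2))
  df <- data.frame(sample_id = sample_id,
                   pair_id = pair_id %||% sprintf("p%03d", seq_len(n)),
                   chrom1 = chrom1, pos1 = pos1, strand1 = strand1,
                   chrom2 = chrom2, pos2 = pos2, strand2 = strand2,
                   stringsAsFactors = FALSE)
  mate_pairs(df, genome = genome)
}

# concordant-ish pair block at a position
concordant_pairs <- function(n, chrom = "chr1", start = 50000, sep = 2500,
                             sample_id = "s1", prefix = "c") {
  pos1 <- start + seq_len(n) * 100
  pairs_df(chrom, pos1, "+", chrom, pos1 + sep, "+", sample_id = sample_id,
           pair_id = sprintf("%s%03d", prefix, seq_len(n)))
}

# one synthetic call row
call_row <- function(type = "deletion", chromA = "chr1", startA, endA,
                     chromB = chromA, startB, endB, support = 5,
                     sample_id = "s1", orientation = "same",
                     pattern = "++", call_id = "c1", members = "") {
  df <- data.frame(call_id = call_id, sample_id = sample_id, type = type,
                   chromA = chromA, startA = startA, endA = endA,
                   chromB = chromB, startB = startB, endB = endB,
                   orientation = orientation, pattern = pattern,
                   support = support, members = members,
                   stringsAsFactors = FALSE)
  class(df) <- c("sv_calls", "data.frame")
  df
}

# brute-force binomial upper tail on the log10 scale (independent oracle)
oracle_log10_sf <- function(n, k, p0) {
  if (k <= 0) return(0)
  log10(sum(stats::dbinom(k:n, n, p0)))
}
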