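#' Expected fraction of uniform breakpoints falling in a region set
#'
#' Under a uniform null, a random breakpoint lands in the set with
#' probability `total merged footprint / effective genome length`.
#'
#' @param regions A [region_set()].
#' @param genome A [genome_model()] (supplies `effective_length`).
#' @return The null probability (0 for an empty set).
#' @examples
#' gm <- genome_model(c(chr1 = 3e9), effective_length = 3e9)
#' rs <- region_set("x", data.frame(chrom = "chr1", start = 1, end = 4.5e8))
#' expected_overlap_fraction(rs, gm)  # 0.15
#' @export
expected_overlap_fraction <- function(regions, genome) {
  stopifnot(inherits(regions, "region_set"), inherits(genome, "genome_model"))
  if (genome$effective_length <= 0) stop_msg("effective_length must be > 0")
  regions$total_length / genome$effective_length
}

#' Exact log10 upper binomial tail
#'
#' `log10 P(X >= k)` for `X ~ Binomial(n, p0)`, computed by exact log-space
#' summation of the binomial terms (no normal approximation), stable for
#' tails far below double underflow (e.g. 1e-250).
#'
#' @param n Number of trials.
#' @param k Success count (0..n).
#' @param p0 Null success probability in (0, 1).
#' @return `log10 P(X >= k)` (<= 0; 0 when `k <= 0`).
#' @examples
#' log_binomial_sf(1, 1, 0.5)  # -0.30103
#' @export
log_binomial_sf <- function(n, k, p0) {
  if (!is_count(n) || !is_count(k) || k > n)
    stop_msg("need integer 0 <= k <= n")
  if (!is.numeric(p0) || p0 <= 0 || p0 >= 1)
    stop_msg("'p0' must be in (0, 1)")
  if (k <= 0) return(0)
  i <- k:n
  terms <- lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)
  min(logsumexp(terms), 0) / log(10)
}

new_enrichment_result <- function(n, k, p0, log10_p, direction) {
  structure(list(n = n, k = k, p0 = p0,
                 observed_fraction = if (n > 0) k / n else NA_real_,
                 log10_p = log10_p, direction = direction),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: k=%d/%d (%.3f observed vs %.4f expected), %s, log10 p = %.4g\n",
    x$k, x$n, x$observed_fraction, x$p0, x$direction, x$log10_p))
  invisible(x)
}

#' Binomial test of breakpoint overlap with a region set
#'
#' Counts breakpoints falling inside the merged region set and compares the
#' observed fraction with the uniform-null expectation
#' ([expected_overlap_fraction()]) by an exact one-sided binomial tail in
#' the direction of the deviation. Both breakpoints of every event should
#' be supplied (n = 2 x number of translocations).
#'
#' @param breakpoints data.frame with columns `chrom`, `pos` (1-based).
#' @param regions A [region_set()].
#' @param genome A [genome_model()].
#' @return An `enrichment_result`: `n`, `k`, `p0`, `observed_fraction`,
#'   `log10_p` (one-sided, in the deviation `direction`), `direction`
#'   (`above`/`below`).
#' @export
breakpoint_overlap_test <- function(breakpoints, regions, genome) {
  stopifnot(is.data.frame(breakpoints),
            all(c("chrom", "pos") %in% names(breakpoints)))
  p0 <- expected_overlap_fraction(regions, genome)
  if (p0 <= 0 || p0 >= 1)
    stop_msg("degenerate null probability %g", p0)
  n <- nrow(breakpoints)
  k <- count_in_regions(breakpoints, regions)
  if (n == 0) return(new_enrichment_result(0L, 0L, p0, 0, "above"))
  if (k / n >= p0) {
    new_enrichment_result(n, k, p0, log_binomial_sf(n, k, p0), "above")
  } else {
    # P(X <= k) = P(n - X >= n - k) with success prob 1 - p0
    new_enrichment_result(n, k, p0, log_binomial_sf(n, n - k, 1 - p0),
                          "below")
  }
}

count_in_regions <- function(breakpoints, regions) {
  if (nrow(breakpoints) == 0L) return(0L)
  gr <- GenomicRanges::GRanges(breakpoints$chrom,
          IRanges::IRanges(breakpoints$pos, breakpoints$pos))
  # chromosomes absent from the set legitimately contribute no hits
  sum(suppressWarnings(IRanges::overlapsAny(gr, regions$merged)))
}

#' Count regions hit by at least one breakpoint
#'
#' The count is over the merged (non-redundant) intervals of the set.
#'
#' @inheritParams breakpoint_overlap_test
#' @return Number of merged intervals containing >= 1 breakpoint.
#' @export
regions_hit <- function(breakpoints, regions) {
  if (nrow(breakpoints) == 0L) return(0L)
  gr <- GenomicRanges::GRanges(breakpoints$chrom,
          IRanges::IRanges(breakpoints$pos, breakpoints$pos))
  sum(suppressWarnings(IRanges::overlapsAny(regions$merged, gr)))
}

#' Gene-set enrichment among rearrangement-affected genes
#'
#' Binomial test of the overlap between the genes disrupted by validated
#' rearrangements and a curated gene set (e.g. a cancer-gene census), under
#' the null that each affected gene is in the set with probability
#' `|gene_set| / total_genes`.
#'
#' @param affected Character vector of affected gene symbols.
#' @param gene_set Character vector of gene-set symbols.
#' @param total_genes Size of the gene universe (default 21000
#'   protein-coding genes).
#' @param set_size Size of the curated set used for the null probability;
#'   defaults to `length(gene_set)`. Supply it when `gene_set` lists only
#'   the members relevant to the comparison (e.g. the overlapping genes of
#'   a large census whose full membership is not shipped).
#' @return An `enrichment_result` with `n = |affected|`,
#'   `k = |affected in set|`.
#' @export
gene_set_enrichment <- function(affected, gene_set, total_genes = 21000,
                                set_size = NULL) {
  affected <- unique(affected)
  gene_set <- unique(gene_set)
  set_size <- set_size %||% length(gene_set)
  if (set_size < length(gene_set))
    stop_msg("set_size (%d) < genes listed (%d)", set_size,
             length(gene_set))
  if (total_genes < set_size)
    stop_msg("total_genes (%d) < gene-set size (%d)", total_genes, set_size)
  p0 <- set_size / total_genes
  n <- length(affected)
  k <- length(intersect(affected, gene_set))
  if (n == 0) return(new_enrichment_result(0L, 0L, p0, 0, "above"))
  # enrichment question: always the upper tail P(X >= k)
  dir <- if (k / n >= p0) "above" else "below"
  new_enrichment_result(n, k, p0, log_binomial_sf(n, k, p0), dir)
}

#' Write enrichment results as TSV
#'
#' @param results Named list of `enrichment_result` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  rows <- do.call(rbind, lapply(names(results), function(nm) {
    x <- results[[nm]]
    data.frame(test = nm, n = x$n, k = x$k, p0 = x$p0,
               observed = x$observed_fraction, log10_p = x$log10_p,
               direction = x$direction)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
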