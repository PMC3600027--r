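#' Insert-size model for a mate-pair library
#'
#' Long-insert mate-pair libraries have a tight fragment-length
#' distribution (~2.5 kb here); a pair whose anchor separation falls
#' outside the concordance window `[lo, hi]` is evidence of an indel.
#' `sigma` is a robust scale; the window is `median +/- 3 * sigma`.
#'
#' @param median Median insert length in bp (default 2500, the nominal
#'   library size).
#' @param sigma Robust scale in bp; defaults to the 5%-of-median floor that
#'   keeps the window non-degenerate (125 bp at the default median).
#' @return An object of class `insert_size_model` with elements `median`,
#'   `sigma`, `lo`, `hi`.
#' @examples
#' insert_size_model()          # 2500 / 125, window [2125, 2875]
#' @export
insert_size_model <- function(median = 2500, sigma = 0.05 * median) {
  if (!is.numeric(median) || median <= 0) stop_msg("'median' must be positive")
  if (!is.numeric(sigma) || sigma <= 0) stop_msg("'sigma' must be positive")
  lo <- median - 3 * sigma
  hi <- median + 3 * sigma
  if (!(lo < median && median < hi))
    stop_msg("degenerate concordance window: lo=%g median=%g hi=%g",
             lo, median, hi)
  structure(list(median = as.numeric(median), sigma = as.numeric(sigma),
                 lo = lo, hi = hi), class = "insert_size_model")
}

#' @export
print.insert_size_model <- function(x, ...) {
  cat(sprintf("insert_size_model: median %g bp, sigma %g bp, window [%g, %g]\n",
              x$median, x$sigma, x$lo, x$hi))
  invisible(x)
}

#' Estimate the insert-size model from mate-pair records
#'
#' Candidate concordant pairs are those with both anchors on the same
#' chromosome and strand and a separation inside the plausible range.
#' The model is the median separation with a robust scale
#' `1.4826 * MAD`, floored at 5% of the median so that constant-separation
#' inputs do not produce a zero-width window.
#'
#' @param records A `mate_pairs` data.frame.
#' @param min_concordant Minimum number of candidate pairs required
#'   (default 100).
#' @param plausible Two-element range of separations (bp) considered
#'   plausible library fragments. Default `c(200, 20000)`.
#' @return An [insert_size_model()].
#' @export
estimate_insert_model <- function(records, min_concordant = 100,
                                  plausible = c(200, 20000)) {
  sep <- records$pos2 - records$pos1
  cand <- sep[records$chrom1 == records$chrom2 &
              records$strand1 == records$strand2 &
              sep >= plausible[1] & sep <= plausible[2]]
  if (length(cand) < min_concordant)
    stop_msg(paste0("only %d candidate concordant pairs (need >= %d); ",
                    "supply a fixed model, e.g. insert_size_model(2500)"),
             length(cand), min_concordant)
  med <- stats::median(cand)
  sigma <- max(stats::mad(cand), 0.05 * med)
  insert_size_model(median = med, sigma = sigma)
}
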