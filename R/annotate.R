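#' Annotate SV breakpoints with disrupted genes
#'
#' Each breakpoint region overlapping a gene is labelled in exon/intron
#' style: a region intersecting exon k gives `"exon k"`; a region lying
#' wholly between consecutive exons gives `"intron k-(k+1)"`. Exon numbers
#' follow transcript orientation (on the minus strand the genomically last
#' exon is exon 1). Both breakpoints are annotated; `near_gene` records
#' whether any gene lies within two insert lengths of either breakpoint,
#' the proximity used for validation selection.
#'
#' @param calls `sv_calls` (breakpoint-bracketing intervals or point
#'   breakpoints).
#' @param genes A [gene_models()] object.
#' @param model The [insert_size_model()] (supplies the two-insert-length
#'   proximity).
#' @return `calls` with columns `disrupted` (semicolon-separated
#'   `"SYMBOL (label)"` entries, `""` when no gene is hit) and `near_gene`.
#' @export
annotate_genes <- function(calls, genes, model) {
  stopifnot(inherits(genes, "gene_models"),
            inherits(model, "insert_size_model"))
  df <- as.data.frame(calls)
  prox <- 2 * model$median
  g <- genes$genes
  ex <- genes$exons

  label_region <- function(chrom, start, end) {
    hits <- which(g$chrom == chrom & g$start <= end & g$end >= start)
    labs <- character(0)
    for (j in hits) {
      e <- ex[ex$symbol == g$symbol[j], , drop = FALSE]
      inter <- which(e$start <= end & e$end >= start)
      if (length(inter)) {
        k <- min(e$exon_number[inter])
        labs <- c(labs, sprintf("%s (exon %d)", g$symbol[j], k))
      } else {
        left <- which(e$end < start)   # genomically before the region
        right <- which(e$start > end)
        if (length(left) && length(right)) {
          i1 <- e$exon_number[max(left)]
          i2 <- e$exon_number[min(right)]
          labs <- c(labs, sprintf("%s (intron %d-%d)", g$symbol[j],
                                  min(i1, i2), max(i1, i2)))
        }
        # region overlapping the gene span but outside first/last exon
        # (possible for bracketing intervals) carries no label
      }
    }
    labs
  }
  near_region <- function(chrom, start, end) {
    any(g$chrom == chrom & g$start <= end + prox & g$end >= start - prox)
  }

  disrupted <- character(nrow(df))
  near <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    labs <- unique(c(label_region(df$chromA[i], df$startA[i], df$endA[i]),
                     label_region(df$chromB[i], df$startB[i], df$endB[i])))
    disrupted[i] <- paste(labs, collapse = "; ")
    near[i] <- near_region(df$chromA[i], df$startA[i], df$endA[i]) ||
               near_region(df$chromB[i], df$startB[i], df$endB[i])
  }
  df$disrupted <- disrupted
  df$near_gene <- near
  attr(df, "chrom_levels") <- attr(calls, "chrom_levels")
  class(df) <- c("sv_calls", "data.frame")
  df
}

#' Select candidate rearrangements for validation
#'
#' Strict selection requires all three criteria: the call (1) occurs in or
#' within two insert lengths of a gene (`near_gene`), (2) is supported by at
#' least `min_support` pairs, and (3) recurs -- a call of the same type in
#' another sample has both breakpoint regions within two insert lengths.
#' For deeply sequenced samples the translocation support cutoff is raised
#' to `deep_min_support` and a passing anchor-correlation verdict is
#' additionally required. `require_recurrent = FALSE` gives the relaxed
#' (criteria 1 and 2 only) mode.
#'
#' @param annotated Cohort `sv_calls` covering all samples, annotated by
#'   [annotate_genes()] (and, for deep samples, [screen_translocations()]).
#' @param model The [insert_size_model()].
#' @param min_support Support cutoff (default 4).
#' @param deep_samples Character vector of deeply sequenced sample ids.
#' @param deep_min_support Translocation support cutoff in deep samples
#'   (default 40).
#' @param require_recurrent Require criterion 3 (default TRUE).
#' @return `annotated` with logical columns `recurrent` and `selected`.
#' @export
select_candidates <- function(annotated, model, min_support = 4,
                              deep_samples = character(),
                              deep_min_support = 40,
                              require_recurrent = TRUE) {
  df <- as.data.frame(annotated)
  if (!"near_gene" %in% names(df))
    stop_msg("run annotate_genes() before select_candidates()")
  prox <- 2 * model$median

  recurrent <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    cand <- df$type == df$type[i] & df$sample_id != df$sample_id[i] &
            df$chromA == df$chromA[i] & df$chromB == df$chromB[i]
    if (!any(cand)) next
    o <- df[cand, , drop = FALSE]
    gapA <- interval_gap(df$startA[i], df$endA[i], o$startA, o$endA)
    gapB <- interval_gap(df$startB[i], df$endB[i], o$startB, o$endB)
    recurrent[i] <- any(gapA <= prox & gapB <= prox)
  }
  df$recurrent <- recurrent

  sel <- df$near_gene & df$support >= min_support
  if (require_recurrent) sel <- sel & df$recurrent
  deep <- df$sample_id %in% deep_samples & df$type == "translocation"
  if (any(deep)) {
    verdict <- if ("verdict" %in% names(df)) df$verdict
               else rep(NA_character_, nrow(df))
    ok <- df$support >= deep_min_support & !is.na(verdict) &
          verdict == "pass"
    sel[deep] <- sel[deep] & ok[deep]
  }
  df$selected <- sel
  attr(df, "chrom_levels") <- attr(annotated, "chrom_levels")
  class(df) <- c("sv_calls", "data.frame")
  df
}

#' Primer-design flanks for a breakpoint pair
#'
#' Returns the 200-bp windows immediately outside the two
#' breakpoint-bracketing intervals, oriented toward the junction (the
#' regions a forward/reverse PCR primer pair would be designed in).
#' Windows are truncated at chromosome ends.
#'
#' @param call One row of an `sv_calls` data.frame.
#' @param flank Flank width in bp (default 200).
#' @param genome Optional [genome_model()] for right-end truncation.
#' @return data.frame with two rows (`side` = `A`/`B`): `chrom`, `start`,
#'   `end` (1-based closed; zero-width flanks at a chromosome edge are
#'   returned with `end < start` width 0 semantics avoided by clamping to
#'   an empty 0-row entry).
#' @export
primer_flanks <- function(call, flank = 200, genome = NULL) {
  stopifnot(nrow(call) == 1L)
  lenA <- lenB <- Inf
  if (!is.null(genome)) {
    lenA <- genome$chromosomes[[call$chromA]]
    lenB <- genome$chromosomes[[call$chromB]]
  }
  a_start <- max(1, call$startA - flank)
  a_end <- call$startA - 1
  b_start <- min(call$endB + 1, lenB + 1)
  b_end <- min(call$endB + flank, lenB)
  out <- data.frame(side = c("A", "B"),
                    chrom = c(call$chromA, call$chromB),
                    start = c(a_start, b_start),
                    end = c(a_end, b_end), stringsAsFactors = FALSE)
  out[out$end >= out$start, , drop = FALSE]
}

#' Write annotated calls as a breakpoint/gene table
#'
#' One row per call with 1-based breakpoint-bracketing coordinates and
#' the disrupted-gene labels, mirroring the layout of published somatic-SV
#' tables.
#'
#' @param annotated `sv_calls` annotated by [annotate_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_table <- function(annotated, path) {
  df <- as.data.frame(annotated)
  cols <- c("sample_id", "type", "chromA", "startA", "endA",
            "chromB", "startB", "endB", "support", "disrupted")
  cols <- intersect(cols, names(df))
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
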