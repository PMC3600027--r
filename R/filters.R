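#' Configuration for the somatic filter cascade
#'
#' @param proximity_multiple Matching/exclusion distance in insert lengths
#'   (default 2: "within two insert lengths").
#' @param min_support Minimum supporting pairs (default 4; 3 is the common
#'   relaxed alternative).
#' @param control_min_support Minimum support for a control / matched-normal
#'   call to count as an observed event when matching (default 2): a single
#'   stray pair in a low-coverage companion sample is not treated as
#'   evidence that the variant is present there.
#' @param control_calls List of `sv_calls` tables from healthy-control
#'   samples, produced by the same pipeline.
#' @param known_variants Optional [region_set()] of known germline variants
#'   (Database-of-Genomic-Variants style BED). Interval `type` metadata, when
#'   present and one of `deletion`/`insertion`/`inversion`, makes matching
#'   type-aware; untyped intervals match any intrachromosomal call.
#' @param matched_normal Optional `sv_calls` table from the patient-matched
#'   normal sample (in-silico surrogate for wet-lab somatic determination).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(proximity_multiple = 2, min_support = 4,
                          control_calls = list(), known_variants = NULL,
                          matched_normal = NULL, control_min_support = 2) {
  if (!is.numeric(proximity_multiple) || proximity_multiple <= 0)
    stop_msg("'proximity_multiple' must be positive")
  if (!is_count(min_support) || min_support < 1)
    stop_msg("'min_support' must be a count >= 1")
  if (!is_count(control_min_support) || control_min_support < 1)
    stop_msg("'control_min_support' must be a count >= 1")
  if (!is.null(known_variants) && !inherits(known_variants, "region_set"))
    stop_msg("'known_variants' must be a region_set")
  structure(list(proximity_multiple = proximity_multiple,
                 min_support = as.integer(min_support),
                 control_calls = control_calls,
                 known_variants = known_variants,
                 matched_normal = matched_normal,
                 control_min_support = as.integer(control_min_support)),
            class = "filter_config")
}

# TRUE for each row of `calls` matching any row of `other`:
# same type and chromosome pair, both breakpoint regions within `prox` bp.
match_call_set <- function(calls, other, prox) {
  hit <- logical(nrow(calls))
  if (is.null(other) || nrow(other) == 0L || nrow(calls) == 0L) return(hit)
  for (i in seq_len(nrow(calls))) {
    cand <- other$type == calls$type[i] &
            other$chromA == calls$chromA[i] &
            other$chromB == calls$chromB[i]
    if (!any(cand)) next
    o <- other[cand, , drop = FALSE]
    gapA <- interval_gap(calls$startA[i], calls$endA[i], o$startA, o$endA)
    gapB <- interval_gap(calls$startB[i], calls$endB[i], o$startB, o$endB)
    hit[i] <- any(gapA <= prox & gapB <= prox)
  }
  hit
}

# distance from each breakpoint region to the nearest excluded interval
near_excluded_flag <- function(calls, genome, prox) {
  if (length(genome$excluded) == 0L)
    stop_msg("genome has no excluded intervals; supply them or use filter stages selectively")
  ex <- genome$excluded
  near_side <- function(chrom, start, end) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    hits <- GenomicRanges::distanceToNearest(gr, ex)
    out <- rep(FALSE, length(gr))
    out[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance <= prox
    out
  }
  near_side(calls$chromA, calls$startA, calls$endA) |
    near_side(calls$chromB, calls$startB, calls$endB)
}

known_variant_flag <- function(calls, known, prox) {
  hit <- logical(nrow(calls))
  if (is.null(known) || length(known$raw) == 0L || nrow(calls) == 0L)
    return(hit)
  kv <- known$raw
  kchrom <- as.character(GenomeInfoDb::seqnames(kv))
  ks <- GenomicRanges::start(kv)
  ke <- GenomicRanges::end(kv)
  ktype <- S4Vectors::mcols(kv)$type
  if (is.null(ktype)) ktype <- rep(NA_character_, length(kv))
  typed <- ktype %in% c("deletion", "insertion", "inversion")
  for (i in seq_len(nrow(calls))) {
    if (calls$type[i] == "translocation") next
    cand <- kchrom == calls$chromA[i] &
            (!typed | (typed & ktype == calls$type[i]))
    cand[is.na(cand)] <- FALSE
    if (!any(cand)) next
    gapA <- interval_gap(calls$startA[i], calls$endA[i], ks[cand], ks[cand])
    gapB <- interval_gap(calls$startB[i], calls$endB[i], ke[cand], ke[cand])
    hit[i] <- any(gapA <= prox & gapB <= prox)
  }
  hit
}

#' Apply the somatic filter cascade to SV calls
#'
#' Candidate calls are flagged, in order, when (1) a matching call exists in
#' any healthy-control call set, (2) either breakpoint region lies within
#' `proximity_multiple` insert lengths of a telomere, centromere or assembly
#' gap, (3) a matching known germline variant exists, (4) read support is
#' below `min_support`, and (5, optional) a matching call exists in the
#' patient-matched normal. Flags are independent: every stage is evaluated
#' on every call, so reordering stages changes per-stage attribution but
#' never the final pass set. Two calls "match" when they have the same type
#' and both breakpoint regions lie within the proximity distance.
#'
#' @param calls `sv_calls` from one sample ([cluster_events()]).
#' @param genome A [genome_model()] with excluded intervals.
#' @param model The [insert_size_model()].
#' @param config A [filter_config()].
#' @return A list of class `filter_result`: `calls` (input plus logical flag
#'   columns and `pass`, plus a `filter_flags` summary string) and `report`
#'   (per-stage data.frame `stage`, `calls_in`, `calls_flagged`, `fraction`,
#'   with attributes `removed_fraction` (all stages) and
#'   `removed_fraction_presupport` (stages before the read-support
#'   threshold)).
#' @export
apply_filters <- function(calls, genome, model, config = filter_config()) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(model, "insert_size_model"),
            inherits(config, "filter_config"))
  prox <- config$proximity_multiple * model$median
  df <- as.data.frame(calls)

  observed <- function(set) {
    s <- as.data.frame(set)
    s[s$support >= config$control_min_support, , drop = FALSE]
  }
  in_control <- logical(nrow(df))
  for (ctl in config$control_calls)
    in_control <- in_control | match_call_set(df, observed(ctl), prox)
  near_ex <- if (nrow(df)) near_excluded_flag(df, genome, prox)
             else logical(0)
  known <- known_variant_flag(df, config$known_variants, prox)
  low_support <- df$support < config$min_support
  in_normal <- if (is.null(config$matched_normal)) logical(nrow(df))
               else match_call_set(df, observed(config$matched_normal),
                                   prox)

  flags <- cbind(in_control = in_control, near_excluded = near_ex,
                 known_variant = known, low_support = low_support,
                 in_matched_normal = in_normal)
  df$in_control <- in_control
  df$near_excluded <- near_ex
  df$known_variant <- known
  df$low_support <- low_support
  df$in_matched_normal <- in_normal
  df$pass <- !apply(flags, 1, any)
  df$filter_flags <- apply(flags, 1, function(f)
    paste(colnames(flags)[f], collapse = ","))

  stages <- colnames(flags)
  remaining <- rep(TRUE, nrow(df))
  report <- do.call(rbind, lapply(stages, function(s) {
    calls_in <- sum(remaining)
    flagged <- sum(remaining & flags[, s])
    remaining <<- remaining & !flags[, s]
    data.frame(stage = s, calls_in = calls_in, calls_flagged = flagged,
               fraction = if (calls_in > 0) flagged / calls_in else NA_real_)
  }))
  n <- nrow(df)
  attr(report, "removed_fraction") <-
    if (n > 0) 1 - sum(df$pass) / n else NA_real_
  pre <- c("in_control", "near_excluded", "known_variant")
  attr(report, "removed_fraction_presupport") <-
    if (n > 0) mean(apply(flags[, pre, drop = FALSE], 1, any)) else NA_real_

  class(df) <- c("sv_calls", "data.frame")
  structure(list(calls = df, report = report), class = "filter_result")
}

#' Write a per-stage filter report as TSV
#'
#' @param result A `filter_result` from [apply_filters()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(result, path) {
  stopifnot(inherits(result, "filter_result"))
  utils::write.table(result$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
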