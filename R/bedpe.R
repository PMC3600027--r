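#' Write SV calls as BEDPE
#'
#' Standard 10-column BEDPE (0-based half-open on disk) with the call
#' annotations in columns 11+: sample, orientation, support, member pair
#' ids, filter flags, and -- when present -- the anchor-correlation columns
#' `r`, `p_value`, `n_cor`, `verdict`.
#'
#' @param calls An `sv_calls` data.frame (see [cluster_events()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_bedpe()] for the inverse.
#' @export
write_bedpe <- function(calls, path) {
  df <- as.data.frame(calls)
  flags <- if ("filter_flags" %in% names(df)) df$filter_flags else
           rep(".", nrow(df))
  flags[flags == "" | is.na(flags)] <- "."
  fmt <- function(x) ifelse(is.na(x), ".", format(x, digits = 12,
                                                  scientific = FALSE,
                                                  trim = TRUE))
  out <- data.frame(
    chrom1 = df$chromA, start1 = df$startA - 1, end1 = df$endA,
    chrom2 = df$chromB, start2 = df$startB - 1, end2 = df$endB,
    name = df$call_id, score = df$support,
    strand1 = substr(df$pattern, 1, 1), strand2 = substr(df$pattern, 2, 2),
    type = df$type, sample_id = df$sample_id, orientation = df$orientation,
    members = df$members, flags = flags,
    r = fmt(if ("r" %in% names(df)) df$r else rep(NA_real_, nrow(df))),
    p_value = fmt(if ("p_value" %in% names(df)) df$p_value else
                  rep(NA_real_, nrow(df))),
    n_cor = fmt(if ("n_cor" %in% names(df)) df$n_cor else
                rep(NA_real_, nrow(df))),
    verdict = if ("verdict" %in% names(df)) {
      v <- df$verdict; v[is.na(v)] <- "."; v
    } else rep(".", nrow(df)),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read SV calls from a BEDPE file written by [write_bedpe()]
#'
#' @param path Path to a BEDPE file.
#' @return An `sv_calls` data.frame.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop_msg("BEDPE file not found: %s", path)
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "name",
            "score", "strand1", "strand2", "type", "sample_id",
            "orientation", "members", "flags", "r", "p_value", "n_cor",
            "verdict")
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                        cols))
  } else {
    df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                            stringsAsFactors = FALSE, col.names = cols,
                            colClasses = "character")
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
  out <- data.frame(call_id = df$name, sample_id = df$sample_id,
                    type = df$type, chromA = df$chrom1,
                    startA = as.numeric(df$start1) + 1,
                    endA = as.numeric(df$end1), chromB = df$chrom2,
                    startB = as.numeric(df$start2) + 1,
                    endB = as.numeric(df$end2),
                    orientation = df$orientation,
                    pattern = paste0(df$strand1, df$strand2),
                    support = as.integer(df$score), members = df$members,
                    stringsAsFactors = FALSE)
  if (any(df$flags != ".")) {
    out$filter_flags <- ifelse(df$flags == ".", "", df$flags)
  }
  if (any(df$verdict != ".")) {
    out$r <- num(df$r)
    out$p_value <- num(df$p_value)
    out$n_cor <- num(df$n_cor)
    out$verdict <- ifelse(df$verdict == ".", NA_character_, df$verdict)
  }
  class(out) <- c("sv_calls", "data.frame")
  out
}

#' Export somatic translocations as a Circos-style link file
#'
#' One line per interchromosomal call:
#' `chrA startA endA chrB startB endB` (1-based inclusive), the plain-text
#' link format consumed by Circos-like plotting tools.
#'
#' @param calls An `sv_calls` data.frame; only rows with
#'   `type == "translocation"` are written.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_circos_links <- function(calls, path) {
  df <- as.data.frame(calls)
  df <- df[df$type == "translocation", , drop = FALSE]
  utils::write.table(df[, c("chromA", "startA", "endA",
                            "chromB", "startB", "endB")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
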