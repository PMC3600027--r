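#' Construct a canonical mate-pair record table
#'
#' A mate pair is one sequenced long-insert fragment with two mapped anchors
#' (chromosome, 1-based leftmost position, strand). Anchors are stored in
#' canonical order: anchor 1 is the anchor on the earlier chromosome (genome
#' order when a [genome_model()] is given, otherwise lexicographic), or at
#' the smaller position on the same chromosome. Records flagged `ambiguous`
#' or `duplicate` are dropped, and records with identical (sample, anchors)
#' are collapsed to one.
#'
#' @param df data.frame with columns `sample_id`, `pair_id`, `chrom1`,
#'   `pos1`, `strand1`, `chrom2`, `pos2`, `strand2`, optionally `flags`
#'   (comma-separated subset of `ambiguous`, `duplicate`) and `read_length`.
#' @param genome Optional [genome_model()]; enables chromosome validation
#'   and genome-order canonicalisation.
#' @param read_length Read length in bp used when `df` has no `read_length`
#'   column. Default 50.
#' @return A data.frame of class `mate_pairs` with canonicalised anchors and
#'   a `chrom_levels` attribute recording the chromosome order used.
#' @export
mate_pairs <- function(df, genome = NULL, read_length = 50) {
  need <- c("sample_id", "pair_id", "chrom1", "pos1", "strand1",
            "chrom2", "pos2", "strand2")
  if (!all(need %in% names(df)))
    stop_msg("mate-pair table needs columns %s", paste(need, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$pair_id <- as.character(df$pair_id)
  for (cc in c("chrom1", "chrom2", "strand1", "strand2"))
    df[[cc]] <- as.character(df[[cc]])
  bad <- which(!(df$strand1 %in% c("+", "-")) | !(df$strand2 %in% c("+", "-")))
  if (length(bad)) stop_msg("invalid strand in record %d", bad[1])
  bad <- which(!is.finite(df$pos1) | !is.finite(df$pos2) |
               df$pos1 < 1 | df$pos2 < 1)
  if (length(bad)) stop_msg("invalid position in record %d", bad[1])

  if (!"read_length" %in% names(df))
    df$read_length <- rep(as.numeric(read_length), nrow(df))

  if ("flags" %in% names(df)) {
    fl <- as.character(df$flags)
    fl[is.na(fl)] <- ""
    drop <- grepl("ambiguous", fl, fixed = TRUE) |
            grepl("duplicate", fl, fixed = TRUE)
    df <- df[!drop, , drop = FALSE]
    df$flags <- NULL
  }

  if (!is.null(genome)) {
    levels <- names(genome$chromosomes)
    unknown <- setdiff(unique(c(df$chrom1, df$chrom2)), levels)
    if (length(unknown))
      stop_msg("unknown chromosome(s) in mate pairs: %s",
               paste(unknown, collapse = ", "))
    bad <- which(df$pos1 > genome$chromosomes[df$chrom1] |
                 df$pos2 > genome$chromosomes[df$chrom2])
    if (length(bad)) stop_msg("position beyond chromosome end in record %d",
                              bad[1])
  } else {
    levels <- sort(unique(c(df$chrom1, df$chrom2)))
  }

  o1 <- match(df$chrom1, levels)
  o2 <- match(df$chrom2, levels)
  swap <- o1 > o2 | (o1 == o2 & df$pos1 > df$pos2)
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "pos1", "strand1")]
    df[swap, c("chrom1", "pos1", "strand1")] <-
      df[swap, c("chrom2", "pos2", "strand2")]
    df[swap, c("chrom2", "pos2", "strand2")] <- tmp
  }

  key <- paste(df$sample_id, df$chrom1, df$pos1, df$strand1,
               df$chrom2, df$pos2, df$strand2, sep = "\r")
  df <- df[order(key, df$pair_id), , drop = FALSE]
  df <- df[!duplicated(paste(df$sample_id, df$chrom1, df$pos1, df$strand1,
                             df$chrom2, df$pos2, df$strand2, sep = "\r")), ,
           drop = FALSE]
  df <- df[order(match(df$chrom1, levels), df$pos1,
                 match(df$chrom2, levels), df$pos2, df$pair_id), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "chrom_levels") <- levels
  class(df) <- c("mate_pairs", "data.frame")
  df
}

#' Read mate-pair alignment records from a tab-delimited file
#'
#' The dialect is one record per line, tab-separated:
#' `sample_id  pair_id  chrom1  pos1  strand1  chrom2  pos2  strand2 [flags]`
#' where `pos` is the 1-based leftmost aligned base of the read and the
#' optional 9th column is a comma-separated flag list (`ambiguous`,
#' `duplicate`). Flagged records are dropped and redundant records (same
#' sample and anchors) are collapsed, mirroring standard mate-pair
#' pre-processing.
#'
#' @inheritParams mate_pairs
#' @param path Path to the TSV file.
#' @return A `mate_pairs` data.frame (possibly with zero rows).
#' @export
read_mate_pairs <- function(path, genome = NULL, read_length = 50) {
  if (!file.exists(path)) stop_msg("mate-pair file not found: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L || is.null(nf)) {
    return(mate_pairs(data.frame(sample_id = character(0),
      pair_id = character(0), chrom1 = character(0), pos1 = numeric(0),
      strand1 = character(0), chrom2 = character(0), pos2 = numeric(0),
      strand2 = character(0)), genome = genome, read_length = read_length))
  }
  bad <- which(!nf %in% c(8L, 9L))
  if (length(bad))
    stop_msg("malformed mate-pair line %d in '%s': expected 8 or 9 fields, got %d",
             bad[1], path, nf[bad[1]])
  df <- utils::read.table(path, sep = "\t", quote = "", comment.char = "",
                          stringsAsFactors = FALSE, fill = TRUE,
                          col.names = c("sample_id", "pair_id", "chrom1",
                                        "pos1", "strand1", "chrom2", "pos2",
                                        "strand2", "flags")[seq_len(max(nf))],
                          colClasses = c("character", "character", "character",
                                         "numeric", "character", "character",
                                         "numeric", "character",
                                         "character")[seq_len(max(nf))])
  badpos <- which(!is.finite(df$pos1) | !is.finite(df$pos2))
  if (length(badpos))
    stop_msg("malformed position on line %d of '%s'", badpos[1], path)
  mate_pairs(df, genome = genome, read_length = read_length)
}

#' Write mate-pair records in the package TSV dialect
#'
#' Inverse of [read_mate_pairs()]: writing then reading canonicalised
#' records is the identity.
#'
#' @param records A `mate_pairs` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mate_pairs <- function(records, path) {
  cols <- c("sample_id", "pair_id", "chrom1", "pos1", "strand1",
            "chrom2", "pos2", "strand2")
  utils::write.table(as.data.frame(records)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
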