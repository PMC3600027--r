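#' Classify mate pairs as concordant or one of four discordance types
#'
#' Classification follows mate-pair geometry: anchors on different
#' chromosomes indicate a translocation; same chromosome with disparate
#' strand orientations an inversion; same chromosome and strand with a
#' separation above the concordance window a deletion, below it an
#' insertion; anything else is concordant. For indels the implied event
#' size is `|separation - median insert|`.
#'
#' @param records A `mate_pairs` data.frame (canonical anchor order).
#' @param model An [insert_size_model()].
#' @return `records` with columns `category` (one of `concordant`,
#'   `deletion`, `insertion`, `inversion`, `translocation`), `separation`
#'   (bp; `NA` for translocations) and `implied_size` (bp; indels only).
#' @export
classify_pairs <- function(records, model) {
  stopifnot(inherits(model, "insert_size_model"))
  n <- nrow(records)
  sep <- ifelse(records$chrom1 == records$chrom2,
                records$pos2 - records$pos1, NA_real_)
  cat_ <- rep("concordant", n)
  cat_[records$chrom1 != records$chrom2] <- "translocation"
  same <- records$chrom1 == records$chrom2
  cat_[same & records$strand1 != records$strand2] <- "inversion"
  indel <- same & records$strand1 == records$strand2
  cat_[indel & sep > model$hi] <- "deletion"
  cat_[indel & sep < model$lo] <- "insertion"
  implied <- rep(NA_real_, n)
  implied[cat_ == "deletion"] <- sep[cat_ == "deletion"] - model$median
  implied[cat_ == "insertion"] <- model$median - sep[cat_ == "insertion"]
  records$category <- cat_
  records$separation <- sep
  records$implied_size <- implied
  records
}
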