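#' Greedily cluster discordant mate pairs into SV calls
#'
#' Pairs reporting the same rearrangement type at the same chromosomal
#' position are clustered into one candidate structural variant. "Same
#' position" is single linkage: two pairs are linked when both anchor
#' starts are within `cluster_window` of each other; clusters are the
#' connected components, computed per (sample, type, chromosome pair,
#' strand pattern). The strand pattern stratification keeps the two
#' junction-side clusters of an inversion, and same-orientation versus
#' inverted translocations, as distinct calls.
#'
#' Each breakpoint is reported as a bracketing interval: the tightest
#' interval consistent with every member under the constraint that the
#' junction lies within one maximal insert length (`model$hi`) of each
#' anchor, i.e. `[max(anchor end) - hi, min(anchor start) + hi]`.
#'
#' @param classified Output of [classify_pairs()] for one or more samples.
#' @param model An [insert_size_model()].
#' @param cluster_window Linkage window in bp; default one insert length
#'   (`model$median`), the clone-length resolution of the library.
#' @return A data.frame of class `sv_calls`, ordered by (sample, chromA,
#'   startA): `call_id`, `sample_id`, `type`, `chromA`, `startA`, `endA`,
#'   `chromB`, `startB`, `endB`, `orientation` (`same`/`inverted`),
#'   `pattern` (anchor strands), `support`, `members` (comma-separated
#'   pair ids).
#' @export
cluster_events <- function(classified, model, cluster_window = NULL) {
  stopifnot(inherits(model, "insert_size_model"))
  w <- cluster_window %||% model$median
  if (!is.numeric(w) || w <= 0) stop_msg("'cluster_window' must be positive")
  levels <- attr(classified, "chrom_levels") %||%
    sort(unique(c(classified$chrom1, classified$chrom2)))

  d <- as.data.frame(classified)[classified$category != "concordant", ,
                                 drop = FALSE]
  empty <- data.frame(call_id = character(0), sample_id = character(0),
                      type = character(0), chromA = character(0),
                      startA = numeric(0), endA = numeric(0),
                      chromB = character(0), startB = numeric(0),
                      endB = numeric(0), orientation = character(0),
                      pattern = character(0), support = integer(0),
                      members = character(0), stringsAsFactors = FALSE)
  if (nrow(d) == 0L) {
    class(empty) <- c("sv_calls", "data.frame")
    return(empty)
  }

  key <- paste(d$sample_id, d$category, d$chrom1, d$chrom2,
               paste0(d$strand1, d$strand2), sep = "\r")
  groups <- split(d, key)
  calls <- lapply(groups, function(g) {
    g <- g[order(g$pos1, g$pos2, g$pair_id), , drop = FALSE]
    comp <- link_components(g$pos1, g$pos2, w)
    do.call(rbind, lapply(split(seq_len(nrow(g)), comp), function(idx) {
      m <- g[idx, , drop = FALSE]
      rl <- m$read_length
      endA1 <- m$pos1 + rl - 1
      endB1 <- m$pos2 + rl - 1
      startA <- max(1, max(endA1) - model$hi)
      endA <- min(m$pos1) + model$hi
      if (endA < startA) { startA <- min(m$pos1); endA <- max(endA1) }
      startB <- max(1, max(endB1) - model$hi)
      endB <- min(m$pos2) + model$hi
      if (endB < startB) { startB <- min(m$pos2); endB <- max(endB1) }
      data.frame(sample_id = m$sample_id[1], type = m$category[1],
                 chromA = m$chrom1[1], startA = startA, endA = endA,
                 chromB = m$chrom2[1], startB = startB, endB = endB,
                 orientation = if (m$strand1[1] == m$strand2[1]) "same"
                               else "inverted",
                 pattern = paste0(m$strand1[1], m$strand2[1]),
                 support = nrow(m),
                 members = paste(sort(m$pair_id), collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, calls)
  out <- out[order(out$sample_id, match(out$chromA, levels), out$startA,
                   match(out$chromB, levels), out$startB, out$members), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$call_id <- sprintf("%s_%s_%04d", out$sample_id,
                         substr(out$type, 1, 3), seq_len(nrow(out)))
  out <- out[, names(empty)]
  attr(out, "chrom_levels") <- levels
  class(out) <- c("sv_calls", "data.frame")
  out
}

# connected components under |dx|<=w AND |dy|<=w single linkage;
# x assumed sorted ascending
link_components <- function(x, y, w) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && x[j] - x[i] <= w) {
      if (abs(y[j] - y[i]) <= w) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
      j <- j + 1L
    }
  }
  vapply(seq_len(n), find, integer(1))
}
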