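#' Genome model: chromosome lengths, excluded regions, effective length
#'
#' Container describing the reference genome the mate pairs were mapped to:
#' ordered chromosome lengths, excluded intervals (assembly gaps, telomeres,
#' centromeres -- regions where rearrangement calls are unreliable), and the
#' effective genome length used as the denominator when converting a region
#' set's footprint into a uniform-null overlap probability.
#'
#' Chromosome order is the order of `chromosomes` and defines the canonical
#' ordering of mate-pair anchors. All coordinates are 1-based and closed.
#'
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param excluded Excluded intervals: a data.frame with columns `chrom`,
#'   `start`, `end` and optionally `label` (`"gap"`, `"telomere"` or
#'   `"centromere"`), or a [GenomicRanges::GRanges]. May be `NULL` (no
#'   excluded regions).
#' @param effective_length Effective genome length in bp used by
#'   [expected_overlap_fraction()]. Default `3e9`.
#' @return An object of class `genome_model`.
#' @examples
#' gm <- genome_model(c(chr1 = 1e6, chr2 = 5e5),
#'   excluded = data.frame(chrom = "chr1", start = 1, end = 1e4,
#'                         label = "telomere"))
#' gm
#' @export
genome_model <- function(chromosomes, excluded = NULL, effective_length = 3e9) {
  if (is.null(names(chromosomes)) || anyNA(names(chromosomes)) ||
      any(names(chromosomes) == "") || anyDuplicated(names(chromosomes)))
    stop_msg("'chromosomes' must be a uniquely named vector of lengths")
  if (!all(is.finite(chromosomes)) || any(chromosomes <= 0))
    stop_msg("chromosome lengths must be positive")
  if (!is.numeric(effective_length) || effective_length <= 0)
    stop_msg("'effective_length' must be positive")

  chromosomes <- stats::setNames(as.numeric(chromosomes), names(chromosomes))
  gr <- excluded_to_granges(excluded, chromosomes)

  structure(list(chromosomes = chromosomes, excluded = gr,
                 effective_length = as.numeric(effective_length)),
            class = "genome_model")
}

excluded_to_granges <- function(excluded, chromosomes) {
  if (is.null(excluded)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$label <- character(0)
    return(gr)
  }
  if (is.data.frame(excluded)) {
    if (!all(c("chrom", "start", "end") %in% names(excluded)))
      stop_msg("'excluded' needs columns chrom, start, end")
    lab <- if ("label" %in% names(excluded)) as.character(excluded$label)
           else rep("gap", nrow(excluded))
    gr <- GenomicRanges::GRanges(excluded$chrom,
            IRanges::IRanges(excluded$start, excluded$end), label = lab)
  } else if (methods::is(excluded, "GRanges")) {
    gr <- excluded
    if (is.null(S4Vectors::mcols(gr)$label))
      S4Vectors::mcols(gr)$label <- rep("gap", length(gr))
  } else stop_msg("'excluded' must be a data.frame or GRanges")

  chr <- as.character(GenomeInfoDb::seqnames(gr))
  unknown <- setdiff(unique(chr), names(chromosomes))
  if (length(unknown))
    stop_msg("excluded intervals on unknown chromosome(s): %s",
             paste(unknown, collapse = ", "))
  if (any(GenomicRanges::start(gr) < 1) ||
      any(GenomicRanges::end(gr) > chromosomes[chr]))
    stop_msg("excluded intervals must lie within chromosome bounds")
  sort(GenomeInfoDb::sortSeqlevels(gr))
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosomes, %.3g bp total, %d excluded intervals\n",
              length(x$chromosomes), sum(x$chromosomes), length(x$excluded)))
  cat(sprintf("  effective length: %.3g bp\n", x$effective_length))
  invisible(x)
}

#' Region set: named interval collection with merged footprint
#'
#' A named set of genomic intervals (array-painting breakpoint regions,
#' fragile sites, known germline variants, ...). Overlapping intervals are
#' merged once at construction; `total_length` is the merged (non-redundant)
#' footprint in bp, the quantity that enters null overlap probabilities.
#'
#' @param name Label for the set.
#' @param intervals data.frame with columns `chrom`, `start`, `end` (1-based,
#'   closed) and optionally `type`, or a `GRanges`.
#' @param genome Optional [genome_model()]; when supplied, intervals are
#'   validated against chromosome bounds.
#' @return An object of class `region_set` with elements `name`, `raw`
#'   (GRanges as supplied, `type` metadata kept), `merged` (reduced GRanges)
#'   and `total_length`.
#' @examples
#' rs <- region_set("demo", data.frame(chrom = "chr1",
#'   start = c(1, 51), end = c(100, 150)))
#' rs$total_length  # 150 after merging
#' @export
region_set <- function(name, intervals, genome = NULL) {
  if (is.data.frame(intervals)) {
    if (!all(c("chrom", "start", "end") %in% names(intervals)))
      stop_msg("'intervals' needs columns chrom, start, end")
    if (nrow(intervals) && any(intervals$end < intervals$start))
      stop_msg("region_set '%s': interval end < start", name)
    gr <- GenomicRanges::GRanges(intervals$chrom,
            IRanges::IRanges(intervals$start, intervals$end))
    if ("type" %in% names(intervals))
      S4Vectors::mcols(gr)$type <- as.character(intervals$type)
  } else if (methods::is(intervals, "GRanges")) {
    gr <- intervals
  } else stop_msg("'intervals' must be a data.frame or GRanges")

  if (!is.null(genome)) {
    chr <- as.character(GenomeInfoDb::seqnames(gr))
    unknown <- setdiff(unique(chr), names(genome$chromosomes))
    if (length(unknown))
      stop_msg("region_set '%s': unknown chromosome(s) %s", name,
               paste(unknown, collapse = ", "))
    if (length(gr) && (any(GenomicRanges::start(gr) < 1) ||
        any(GenomicRanges::end(gr) > genome$chromosomes[chr])))
      stop_msg("region_set '%s': intervals outside chromosome bounds", name)
  }
  merged <- GenomicRanges::reduce(sort(GenomeInfoDb::sortSeqlevels(gr)))
  structure(list(name = name, raw = gr, merged = merged,
                 total_length = sum(as.numeric(IRanges::width(merged)))),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set '%s': %d intervals (%d merged), %.4g bp non-redundant\n",
              x$name, length(x$raw), length(x$merged), x$total_length))
  invisible(x)
}

#' Read a BED file into a region set
#'
#' Standard UCSC BED (0-based half-open on disk; converted to 1-based closed
#' in memory by rtracklayer). A 4th (name) column, when present, is kept as
#' the interval `type` -- used e.g. for typed known-variant catalogues.
#'
#' @param path Path to a BED file.
#' @param name Name for the region set (default: file base name).
#' @param genome Optional [genome_model()] for bounds validation.
#' @return A [region_set()].
#' @export
read_bed <- function(path, name = NULL, genome = NULL) {
  if (!file.exists(path)) stop_msg("BED file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop_msg("failed to parse BED '%s': %s",
                                              path, conditionMessage(e)))
  nm <- S4Vectors::mcols(gr)$name
  mc <- S4Vectors::DataFrame(row.names = seq_along(gr))
  if (!is.null(nm)) mc$type <- as.character(nm)
  S4Vectors::mcols(gr) <- mc
  region_set(name %||% sub("\\.bed$", "", basename(path)), gr, genome = genome)
}

#' Gene models from an exon table
#'
#' Builds a `gene_models` object from a per-exon table. Exon numbering
#' follows transcript orientation: on the minus strand the genomically last
#' exon is exon 1.
#'
#' @param exons data.frame with columns `symbol`, `chrom`, `strand` (`+`/`-`)
#'   and 1-based closed `start`, `end`, one row per exon.
#' @return An object of class `gene_models`: list with `genes` (one row per
#'   gene: symbol, chrom, strand, span, exon count) and `exons` (exon rows
#'   with `genomic_index` and transcript `exon_number`).
#' @export
gene_models <- function(exons) {
  need <- c("symbol", "chrom", "strand", "start", "end")
  if (!all(need %in% names(exons)))
    stop_msg("'exons' needs columns %s", paste(need, collapse = ", "))
  if (nrow(exons) == 0L) {
    genes <- data.frame(symbol = character(0), chrom = character(0),
                        strand = character(0), start = numeric(0),
                        end = numeric(0), n_exons = integer(0))
    ex <- cbind(exons[, need], genomic_index = integer(0),
                exon_number = integer(0))
    return(structure(list(genes = genes, exons = ex), class = "gene_models"))
  }
  if (!all(exons$strand %in% c("+", "-")))
    stop_msg("gene strand must be '+' or '-'")
  if (any(exons$end < exons$start)) stop_msg("exon end < start")

  exons <- exons[order(exons$symbol, exons$start), need, drop = FALSE]
  out <- do.call(rbind, lapply(split(exons, exons$symbol), function(e) {
    if (length(unique(e$chrom)) != 1L || length(unique(e$strand)) != 1L)
      stop_msg("gene '%s': exons on mixed chromosome/strand", e$symbol[1])
    if (nrow(e) > 1L && any(e$start[-1] <= e$end[-nrow(e)]))
      stop_msg("gene '%s': overlapping exons", e$symbol[1])
    n <- nrow(e)
    e$genomic_index <- seq_len(n)
    e$exon_number <- if (e$strand[1] == "+") seq_len(n) else rev(seq_len(n))
    e
  }))
  rownames(out) <- NULL
  genes <- do.call(rbind, lapply(split(out, out$symbol), function(e)
    data.frame(symbol = e$symbol[1], chrom = e$chrom[1], strand = e$strand[1],
               start = min(e$start), end = max(e$end), n_exons = nrow(e))))
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = out), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons\n",
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Read gene models from a BED12 file
#'
#' Exon structures are taken from the block fields; the BED name column is
#' the gene symbol. Exons are numbered in transcript orientation.
#'
#' @param path Path to a BED12 file.
#' @return A [gene_models()] object.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop_msg("gene BED12 file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop_msg("failed to parse BED12 '%s': %s",
                                              path, conditionMessage(e)))
  blocks <- S4Vectors::mcols(gr)$blocks
  if (is.null(blocks))
    stop_msg("'%s' has no block (exon) fields; BED12 required", path)
  rows <- lapply(seq_along(gr), function(i) {
    b <- blocks[[i]]  # 1-based, relative to feature start
    data.frame(symbol = S4Vectors::mcols(gr)$name[i],
               chrom = as.character(GenomeInfoDb::seqnames(gr))[i],
               strand = as.character(GenomicRanges::strand(gr))[i],
               start = GenomicRanges::start(gr)[i] + IRanges::start(b) - 1L,
               end = GenomicRanges::start(gr)[i] + IRanges::end(b) - 1L)
  })
  gene_models(do.call(rbind, rows))
}
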