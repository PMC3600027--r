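# Build the synthetic gene-model fixture: exon structures constructed so
# that every breakpoint in inst/extdata/somatic_svs.tsv reproduces its
# printed exon/intron label. Run from the repo root after installing the
# package:  Rscript tools/make_gene_fixture.R

suppressMessages(library(matesv))

stride <- 1000L   # exon-to-exon start distance for generic genes
ew <- 200L        # generic exon width

# + strand gene whose exon k contains all of `pts`
exon_gene <- function(sym, chrom, k, pts, n_exons = k + 1L) {
  ks <- min(pts) - 100L
  ke <- max(pts) + 100L
  starts <- ends <- numeric(n_exons)
  for (j in seq_len(n_exons)) {
    if (j < k) { starts[j] <- ks - (k - j) * stride; ends[j] <- starts[j] + ew - 1L }
    else if (j == k) { starts[j] <- ks; ends[j] <- ke }
    else { starts[j] <- ke + 1L + (j - k - 1L) * stride + (stride - ew)
           ends[j] <- starts[j] + ew - 1L }
  }
  data.frame(symbol = sym, chrom = chrom, strand = "+",
             start = starts, end = ends)
}

# + strand gene whose intron k-(k+1) contains all of `pts`
intron_gene <- function(sym, chrom, k, pts, n_exons = k + 1L) {
  ke <- min(pts) - 300L          # exon k end
  ks1 <- max(pts) + 300L         # exon k+1 start
  starts <- ends <- numeric(n_exons)
  for (j in seq_len(n_exons)) {
    if (j <= k) { ends[j] <- ke - (k - j) * stride; starts[j] <- ends[j] - ew + 1L }
    else { starts[j] <- ks1 + (j - k - 1L) * stride; ends[j] <- starts[j] + ew - 1L }
  }
  data.frame(symbol = sym, chrom = chrom, strand = "+",
             start = starts, end = ends)
}

rows <- rbind(
  exon_gene("GUCY1A2", "11", 7L, c(106618805, 106622567), 8L),
  intron_gene("EYA1", "8", 7L, c(72214170, 72217978), 8L),
  intron_gene("H2AFY", "5", 2L, c(134715922, 134720809), 3L),
  intron_gene("PIP4K2A", "10", 3L, c(22889925, 22892366), 4L),
  intron_gene("PCDP1", "2", 6L, c(120331908, 120335057), 7L),
  intron_gene("KIAA1217", "10", 2L, c(24436405, 24438757), 3L),
  intron_gene("METAP1D", "2", 1L, 172893909, 2L),
  intron_gene("CHN1", "2", 1L, 175831452, 2L),
  intron_gene("MECOM", "3", 2L, 168893755, 3L),
  intron_gene("TNIK", "3", 12L, 170864487, 13L),
  intron_gene("KDM3B", "5", 11L, c(137738030, 137744577), 12L),
  intron_gene("EPHA5", "4", 3L, c(66411362, 66411644), 4L),
  intron_gene("ZNF536", "19", 2L, c(30945107, 30951050), 3L),
  intron_gene("PFKM", "12", 3L, 48517177, 4L),
  intron_gene("LCA10", "X", 5L, 153152399, 6L),
  intron_gene("JMJD1C", "10", 1L, 65204015, 2L),
  intron_gene("KSR1", "17", 3L, 25904801, 4L),
  intron_gene("PCBP3", "21", 1L, 47148999, 2L),
  intron_gene("RCAN1", "21", 1L, 35917066, 2L),
  intron_gene("DSCAM", "21", 3L, 41870300, 4L),
  intron_gene("THSD4", "15", 6L, 71750638, 7L),
  exon_gene("TMEM99", "17", 3L, 38990874, 4L),
  intron_gene("DDX10", "11", 10L, c(108583473, 108583658), 11L),
  intron_gene("SPRED2", "2", 2L, 65563071, 3L),
  intron_gene("CLTC", "17", 13L, 57745082, 14L),
  intron_gene("LRBA", "4", 48L, 151298580, 49L),
  intron_gene("SMARCC1", "3", 2L, 47806974, 3L),
  # minus-strand genes: printed labels force descending genomic numbering
  # SKA3: exon 5 contains 21735983, exon 4 contains 21742368
  data.frame(symbol = "SKA3", chrom = "13", strand = "-",
             start = c(21735883, 21742268, 21743268, 21744268, 21745268),
             end   = c(21736083, 21742468, 21743467, 21744467, 21745467)),
  # RORA: intron 1-2 contains 61356378 and 61375512; intron 2-3 contains
  # 60833617
  data.frame(symbol = "RORA", chrom = "15", strand = "-",
             start = c(60700000, 61000000, 61400000),
             end   = c(60700199, 61000199, 61400199))
)

genes <- gene_models(rows)
stopifnot(nrow(genes$genes) == 29L)

# verify: every fixture row reproduces its printed labels exactly
tab <- read_sv_table(file.path("inst", "extdata", "somatic_svs.tsv"))
calls <- data.frame(call_id = sprintf("fx%02d", seq_len(nrow(tab))),
                    sample_id = tab$sample_id, type = tab$type,
                    chromA = tab$chrom1, startA = tab$breakpoint1,
                    endA = tab$breakpoint1, chromB = tab$chrom2,
                    startB = tab$breakpoint2, endB = tab$breakpoint2,
                    orientation = "same", pattern = "++",
                    support = 10L, members = "", stringsAsFactors = FALSE)
class(calls) <- c("sv_calls", "data.frame")
ann <- annotate_genes(calls, genes, insert_size_model(2500))

norm <- function(x) vapply(strsplit(x, ";\\s*"), function(p)
  paste(sort(trimws(p[p != ""])), collapse = "; "), character(1))
got <- norm(ann$disrupted)
want <- norm(tab$disrupted_genes)
bad <- which(got != want)
if (length(bad)) {
  for (i in bad)
    cat(sprintf("row %d (%s %s): want [%s] got [%s]\n", i, tab$sample_id[i],
                tab$type[i], want[i], got[i]))
  stop("fixture does not reproduce printed labels")
}
cat("all", nrow(tab), "rows reproduce their printed labels;",
    nrow(genes$genes), "genes\n")

# write BED12
g <- genes$genes
bed <- vapply(seq_len(nrow(g)), function(i) {
  e <- genes$exons[genes$exons$symbol == g$symbol[i], ]
  e <- e[order(e$start), ]
  paste(g$chrom[i], g$start[i] - 1L, g$end[i], g$symbol[i], 0, g$strand[i],
        g$start[i] - 1L, g$end[i], 0, nrow(e),
        paste0(paste(e$end - e$start + 1L, collapse = ","), ","),
        paste0(paste(e$start - g$start[i], collapse = ","), ","),
        sep = "\t")
}, character(1))
writeLines(bed, file.path("inst", "extdata", "sv_gene_models_synthetic.bed"))
cat("wrote inst/extdata/sv_gene_models_synthetic.bed\n")
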