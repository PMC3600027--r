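#' Configuration for the synthetic mate-pair study generator
#'
#' The generator emulates the mapped output of a long-insert mate-pair
#' experiment: a multi-chromosome reference with telomere / centromere /
#' gap exclusions and synthetic multi-exon genes, implanted rearrangements
#' (germline and somatic), fragments of length `Normal(insert_median,
#' insert_sigma)` -- truncated at 2.5 sigma, emulating gel size selection
#' -- tiled to the requested clone coverage on the rearranged donor
#' genome, repeat-decoy clusters with uncorrelated downstream anchors, and
#' a uniform chimeric-pair background. Defaults follow the
#' study design the pipeline targets: ~2.5 kb inserts (sigma 150), 50 bp
#' reads, 8-fold clone coverage, two healthy controls.
#'
#' @param n_chromosomes,chromosome_length Reference shape (default 6 x 8 Mb).
#' @param n_genes Synthetic genes to place (default 80).
#' @param gene_exons Range of exon counts per gene (default 2..10).
#' @param insert_median,insert_sigma Fragment-length distribution in bp
#'   (default 2500 / 150).
#' @param read_length Read length in bp (default 50).
#' @param clone_coverage Mean number of fragments spanning a position
#'   (default 8).
#' @param n_deletions,deletion_size Deletion count and size range
#'   (default 12, 3-10 kb).
#' @param n_insertions,insertion_size Insertion count and size range
#'   (default 8, 600-1500 bp).
#' @param n_inversions,inversion_size Inversion count and size range
#'   (default 8, 3-10 kb).
#' @param n_translocations Reciprocal translocations (default 3; each uses
#'   two otherwise-untranslocated chromosomes).
#' @param germline_fraction Probability an implant is germline, i.e. also
#'   present in the matched normal (default 0.35).
#' @param known_variant_fraction Fraction of germline deletions/inversions
#'   also recorded in the synthetic known-variant catalogue (default 0.5).
#' @param n_decoys,decoy_width,decoy_pairs Repeat-decoy clusters: loci
#'   emitting `decoy_pairs` pairs whose downstream anchors are uniform over
#'   a `decoy_width` bp repeat (default 4 loci, 10 kb, 10 pairs).
#' @param chimera_rate Fraction of pairs given a uniformly random second
#'   anchor (default 0.005).
#' @param n_controls Healthy-control samples (default 2).
#' @param telomere_length,centromere_length,gap_length Excluded-region
#'   sizes per chromosome.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_chromosomes = 6, chromosome_length = 8e6,
                              n_genes = 80, gene_exons = c(2, 10),
                              insert_median = 2500, insert_sigma = 150,
                              read_length = 50, clone_coverage = 8,
                              n_deletions = 12, deletion_size = c(3000, 10000),
                              n_insertions = 8, insertion_size = c(600, 1500),
                              n_inversions = 8, inversion_size = c(3000, 10000),
                              n_translocations = 3,
                              germline_fraction = 0.35,
                              known_variant_fraction = 0.5,
                              n_decoys = 4, decoy_width = 10000,
                              decoy_pairs = 10, chimera_rate = 0.005,
                              n_controls = 2, telomere_length = 50000,
                              centromere_length = 100000, gap_length = 50000,
                              seed = 1) {
  cfg <- as.list(environment())
  counts <- c("n_chromosomes", "n_genes", "n_deletions", "n_insertions",
              "n_inversions", "n_translocations", "n_decoys", "decoy_pairs",
              "n_controls")
  for (nm in counts)
    if (!is_count(cfg[[nm]])) stop_msg("'%s' must be a non-negative count", nm)
  if (cfg$n_chromosomes < 1) stop_msg("need at least one chromosome")
  for (nm in c("chromosome_length", "insert_median", "insert_sigma",
               "read_length", "clone_coverage"))
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop_msg("'%s' must be positive", nm)
  if (cfg$chimera_rate < 0 || cfg$chimera_rate > 1 ||
      cfg$germline_fraction < 0 || cfg$germline_fraction > 1)
    stop_msg("rates must be in [0, 1]")
  structure(cfg, class = "simulation_config")
}

sim_margin <- 15000   # keep implants clear of excluded regions and ends
sim_min_gap <- 25000  # min spacing between implanted events

#' Simulate a reference genome with excluded regions and genes
#'
#' Chromosomes carry telomeres at both ends, a central centromere and one
#' assembly gap; multi-exon genes are placed uniformly outside the
#' excluded regions (non-overlapping, bounded retries). Deterministic
#' under `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return list with `genome` ([genome_model()]) and `genes`
#'   ([gene_models()]).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  len <- config$chromosome_length
  chroms <- stats::setNames(rep(len, config$n_chromosomes),
                            sprintf("chr%02d", seq_len(config$n_chromosomes)))
  tel <- config$telomere_length
  cen <- config$centromere_length
  gap <- config$gap_length
  if (len < 2 * tel + cen + gap + 10 * sim_min_gap)
    stop_msg("chromosome_length too small for the excluded-region layout")
  excluded <- do.call(rbind, lapply(names(chroms), function(cc) {
    mid <- floor(len / 2)
    q1 <- floor(len / 4)
    data.frame(chrom = cc,
               start = c(1, len - tel + 1, mid - floor(cen / 2), q1),
               end = c(tel, len, mid + ceiling(cen / 2) - 1, q1 + gap - 1),
               label = c("telomere", "telomere", "centromere", "gap"))
  }))
  genome <- genome_model(chroms, excluded = excluded)

  blocked <- excluded_blocks(genome)
  exon_rows <- list()
  for (gi in seq_len(config$n_genes)) {
    placed <- FALSE
    for (try in seq_len(200)) {
      n_ex <- sample(seq(config$gene_exons[1], config$gene_exons[2]), 1)
      widths <- round(stats::runif(n_ex, 150, 400))
      introns <- if (n_ex > 1) round(stats::runif(n_ex - 1, 500, 3000))
                 else numeric(0)
      glen <- sum(widths) + sum(introns)
      cc <- sample(names(genome$chromosomes), 1)
      start <- floor(stats::runif(1, sim_margin,
                                  genome$chromosomes[[cc]] - glen - sim_margin))
      if (!region_is_free(blocked, cc, start - 1000, start + glen + 1000))
        next
      blocked <- block_region(blocked, cc, start - 1000, start + glen + 1000)
      starts <- start + cumsum(c(0, widths[-n_ex] + introns))
      exon_rows[[length(exon_rows) + 1L]] <-
        data.frame(symbol = sprintf("SYNG%03d", gi), chrom = cc,
                   strand = sample(c("+", "-"), 1),
                   start = starts, end = starts + widths - 1)
      placed <- TRUE
      break
    }
    if (!placed)
      stop_msg("could not place gene %d: density too high for the genome",
               gi)
  }
  genes <- if (length(exon_rows)) gene_models(do.call(rbind, exon_rows))
           else gene_models(data.frame(symbol = character(0),
                  chrom = character(0), strand = character(0),
                  start = numeric(0), end = numeric(0)))
  list(genome = genome, genes = genes)
}

# blocked-interval bookkeeping: per-chromosome matrix of [start, end]
excluded_blocks <- function(genome) {
  out <- lapply(names(genome$chromosomes), function(cc) {
    ex <- genome$excluded[GenomeInfoDb::seqnames(genome$excluded) == cc]
    cbind(GenomicRanges::start(ex) - sim_margin,
          GenomicRanges::end(ex) + sim_margin)
  })
  stats::setNames(out, names(genome$chromosomes))
}

region_is_free <- function(blocked, chrom, start, end) {
  b <- blocked[[chrom]]
  if (is.null(b) || nrow(b) == 0L) return(TRUE)
  !any(b[, 1] <= end & b[, 2] >= start)
}

block_region <- function(blocked, chrom, start, end) {
  blocked[[chrom]] <- rbind(blocked[[chrom]], c(start, end))
  blocked
}

#' Implant rearrangements into a simulated genome
#'
#' Places mutually non-overlapping deletions, insertions, inversions and
#' reciprocal translocations outside excluded regions, labels each
#' germline or somatic, draws a synthetic known-variant catalogue from the
#' germline intrachromosomal events, and fixes the repeat-decoy loci.
#' Translocation breakpoints use two dedicated chromosomes per event.
#'
#' @param sim Output of [simulate_genome()].
#' @param config The [simulation_config()].
#' @return list with `truth` (data.frame: `sv_id`, `type`, `chrom1`,
#'   `pos1`, `chrom2`, `pos2`, `size`, `orientation`, `status`),
#'   `known_variants` ([region_set()] or `NULL`) and `decoys` (data.frame
#'   of decoy loci).
#' @export
implant_svs <- function(sim, config) {
  stopifnot(inherits(config, "simulation_config"))
  genome <- sim$genome
  set.seed(config$seed + 1L)
  blocked <- excluded_blocks(genome)
  chrom_names <- names(genome$chromosomes)
  clen <- genome$chromosomes

  place_point <- function(chrom) {
    for (try in seq_len(500)) {
      p <- floor(stats::runif(1, sim_margin, clen[[chrom]] - sim_margin))
      if (region_is_free(blocked, chrom, p - sim_min_gap, p + sim_min_gap)) {
        blocked <<- block_region(blocked, chrom, p - sim_min_gap,
                                 p + sim_min_gap)
        return(p)
      }
    }
    stop_msg("could not place a breakpoint on %s", chrom)
  }
  place_interval <- function(size) {
    for (try in seq_len(500)) {
      chrom <- sample(chrom_names, 1)
      s <- floor(stats::runif(1, sim_margin, clen[[chrom]] - size - sim_margin))
      if (region_is_free(blocked, chrom, s - sim_min_gap,
                         s + size + sim_min_gap)) {
        blocked <<- block_region(blocked, chrom, s - sim_min_gap,
                                 s + size + sim_min_gap)
        return(list(chrom = chrom, start = s))
      }
    }
    stop_msg("could not place an interval of %d bp", size)
  }

  rows <- list()
  add_row <- function(type, chrom1, pos1, chrom2, pos2, size, orientation) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2,
      pos2 = pos2, size = size, orientation = orientation,
      stringsAsFactors = FALSE)
  }

  # translocations first: two dedicated chromosomes per event
  if (config$n_translocations > 0) {
    if (length(chrom_names) < 2 * config$n_translocations)
      stop_msg("%d translocations need %d chromosomes; genome has %d",
               config$n_translocations, 2 * config$n_translocations,
               length(chrom_names))
    picked <- sample(chrom_names, 2 * config$n_translocations)
    for (i in seq_len(config$n_translocations)) {
      ca <- picked[2 * i - 1]; cb <- picked[2 * i]
      # canonical order: chrom1 earlier in genome order
      if (match(ca, chrom_names) > match(cb, chrom_names)) {
        tmp <- ca; ca <- cb; cb <- tmp
      }
      pa <- place_point(ca)
      pb <- place_point(cb)
      orient <- sample(c("same", "inverted"), 1)
      add_row("translocation", ca, pa, cb, pb, NA_real_, orient)
      # the unbalanced derivative displaces one arm of each chromosome;
      # later implants must not land on absent sequence
      blocked <- block_region(blocked, ca, pa, clen[[ca]])
      blocked <- if (orient == "same")
        block_region(blocked, cb, 1, pb)
      else block_region(blocked, cb, pb, clen[[cb]])
    }
  }
  for (i in seq_len(config$n_deletions)) {
    size <- round(stats::runif(1, config$deletion_size[1],
                               config$deletion_size[2]))
    at <- place_interval(size)
    add_row("deletion", at$chrom, at$start, at$chrom, at$start + size - 1,
            size, "same")
  }
  for (i in seq_len(config$n_insertions)) {
    size <- round(stats::runif(1, config$insertion_size[1],
                               config$insertion_size[2]))
    at <- place_interval(1)
    add_row("insertion", at$chrom, at$start, at$chrom, at$start, size,
            "same")
  }
  for (i in seq_len(config$n_inversions)) {
    size <- round(stats::runif(1, config$inversion_size[1],
                               config$inversion_size[2]))
    at <- place_interval(size)
    add_row("inversion", at$chrom, at$start, at$chrom, at$start + size - 1,
            size, "inverted")
  }

  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(0), chrom1 = character(0), pos1 = numeric(0),
               chrom2 = character(0), pos2 = numeric(0), size = numeric(0),
               orientation = character(0), stringsAsFactors = FALSE)
  truth$status <- if (nrow(truth))
    ifelse(stats::runif(nrow(truth)) < config$germline_fraction,
           "germline", "somatic") else character(0)
  truth$sv_id <- sprintf("sv%03d", seq_len(nrow(truth)))
  truth <- truth[, c("sv_id", "type", "chrom1", "pos1", "chrom2", "pos2",
                     "size", "orientation", "status")]

  kv <- NULL
  g <- truth[truth$status == "germline" &
             truth$type %in% c("deletion", "inversion"), , drop = FALSE]
  if (nrow(g)) {
    keep <- stats::runif(nrow(g)) < config$known_variant_fraction
    if (any(keep))
      kv <- region_set("known_variants",
                       data.frame(chrom = g$chrom1[keep],
                                  start = g$pos1[keep], end = g$pos2[keep],
                                  type = g$type[keep]), genome = genome)
  }

  decoys <- NULL
  if (config$n_decoys > 0) {
    if (length(chrom_names) < 2)
      stop_msg("decoy repeats need at least two chromosomes")
    decoys <- do.call(rbind, lapply(seq_len(config$n_decoys), function(i) {
      w <- config$decoy_width
      for (try in seq_len(500)) {
        ca <- sample(chrom_names, 1)
        cb <- sample(setdiff(chrom_names, ca), 1)
        pa <- floor(stats::runif(1, sim_margin, clen[[ca]] - sim_margin))
        if (!region_is_free(blocked, ca, pa - sim_min_gap,
                            pa + sim_min_gap)) next
        s <- floor(stats::runif(1, sim_margin, clen[[cb]] - w - sim_margin))
        if (!region_is_free(blocked, cb, s - sim_min_gap,
                            s + w + sim_min_gap)) next
        blocked <<- block_region(blocked, ca, pa - sim_min_gap,
                                 pa + sim_min_gap)
        blocked <<- block_region(blocked, cb, s - sim_min_gap,
                                 s + w + sim_min_gap)
        return(data.frame(decoy_id = sprintf("decoy%02d", i), chromA = ca,
                          posA = pa, chromB = cb, repeat_start = s,
                          width = w, stringsAsFactors = FALSE))
      }
      stop_msg("could not place decoy repeat %d", i)
    }))
  }
  list(truth = truth, known_variants = kv, decoys = decoys)
}

# ---- donor genome as a reference segment map --------------------------------

new_seg <- function(ref_chrom, r_start, r_end, strand = "+", novel_len = 0,
                    junc_left = NA_character_) {
  data.frame(ref_chrom = ref_chrom, r_start = r_start, r_end = r_end,
             strand = strand, novel_len = novel_len, junc_left = junc_left,
             stringsAsFactors = FALSE)
}

seg_lengths <- function(segs) {
  ifelse(segs$novel_len > 0, segs$novel_len, segs$r_end - segs$r_start + 1)
}

# reverse a segment list (derivative-chromosome arm flip)
rev_segs <- function(segs) {
  n <- nrow(segs)
  if (n == 0L) return(segs)
  out <- segs[n:1, , drop = FALSE]
  out$strand <- ifelse(out$strand == "+", "-", "+")
  jl <- segs$junc_left
  # boundary between old segments i and i+1 (tag jl[i+1]) now lies left of
  # old segment i
  out$junc_left <- c(NA_character_, rev(jl[-1]))
  rownames(out) <- NULL
  out
}

split_segs_at <- function(segs, ref_pos) {
  lens <- seg_lengths(segs)
  idx <- which(segs$novel_len == 0 & segs$strand == "+" &
               segs$r_start <= ref_pos & segs$r_end >= ref_pos)
  if (length(idx) != 1L)
    stop_msg("breakpoint %g does not fall in a unique forward segment",
             ref_pos)
  s <- segs[idx, ]
  left <- segs[seq_len(idx - 1), , drop = FALSE]
  right <- segs[-seq_len(idx), , drop = FALSE]
  left <- rbind(left, new_seg(s$ref_chrom, s$r_start, ref_pos, "+", 0,
                              s$junc_left))
  if (ref_pos < s$r_end)
    right <- rbind(new_seg(s$ref_chrom, ref_pos + 1, s$r_end), right)
  list(left = left, right = right)
}

# donor map for one genotype: a named list of segment data.frames
build_donor_map <- function(genome, svs) {
  donors <- lapply(names(genome$chromosomes), function(cc) {
    len <- genome$chromosomes[[cc]]
    intra <- svs[svs$chrom1 == cc & svs$type != "translocation", ,
                 drop = FALSE]
    intra <- intra[order(intra$pos1), , drop = FALSE]
    segs <- NULL
    cursor <- 1
    pending <- NA_character_
    push <- function(seg) {
      seg$junc_left[1] <- pending
      pending <<- NA_character_
      segs <<- rbind(segs, seg)
    }
    for (i in seq_len(nrow(intra))) {
      sv <- intra[i, ]
      if (sv$type == "deletion") {
        push(new_seg(cc, cursor, sv$pos1 - 1))
        pending <- sv$sv_id
        cursor <- sv$pos2 + 1
      } else if (sv$type == "insertion") {
        push(new_seg(cc, cursor, sv$pos1))
        pending <- sv$sv_id
        push(new_seg(cc, NA, NA, "+", sv$size))
        pending <- sv$sv_id
        cursor <- sv$pos1 + 1
      } else if (sv$type == "inversion") {
        push(new_seg(cc, cursor, sv$pos1 - 1))
        pending <- sv$sv_id
        push(new_seg(cc, sv$pos1, sv$pos2, "-"))
        pending <- sv$sv_id
        cursor <- sv$pos2 + 1
      }
    }
    push(new_seg(cc, cursor, len))
    segs
  })
  names(donors) <- names(genome$chromosomes)

  # unbalanced translocations: one derivative joins the left arm of chrom1
  # to chrom2; the displaced arms are lost, as is typical of tumor genomes,
  # and each junction yields exactly one discordant cluster
  tra <- svs[svs$type == "translocation", , drop = FALSE]
  for (i in seq_len(nrow(tra))) {
    sv <- tra[i, ]
    a <- split_segs_at(donors[[sv$chrom1]], sv$pos1)
    b <- split_segs_at(donors[[sv$chrom2]], sv$pos2)
    donors[[sv$chrom1]] <- NULL
    donors[[sv$chrom2]] <- NULL
    arm <- if (sv$orientation == "same") b$right else rev_segs(b$left)
    arm$junc_left[1] <- sv$sv_id
    donors[[sprintf("der_%s_%s", sv$chrom1, sv$chrom2)]] <-
      rbind(a$left, arm)
  }

  # flatten with global donor coordinates
  map <- do.call(rbind, lapply(names(donors), function(dn) {
    segs <- donors[[dn]]
    lens <- seg_lengths(segs)
    segs$donor_chrom <- dn
    segs$d_start <- cumsum(c(1, lens[-length(lens)]))
    segs$d_end <- cumsum(lens)
    segs
  }))
  rownames(map) <- NULL
  off <- cumsum(c(0, tapply(map$d_end, factor(map$donor_chrom,
                 levels = unique(map$donor_chrom)), max)))
  names(off) <- c(unique(map$donor_chrom), "end")
  map$gd_start <- map$d_start + off[map$donor_chrom]
  map$gd_end <- map$d_end + off[map$donor_chrom]
  map
}

# ---- read-pair emission -----------------------------------------------------

emit_sample <- function(map, genome, decoys, config, sample_id, seed) {
  set.seed(seed)
  r <- config$read_length
  donor_names <- unique(map$donor_chrom)
  donor_len <- vapply(donor_names,
                      function(dn) max(map$d_end[map$donor_chrom == dn]),
                      numeric(1))
  total <- sum(donor_len)
  n_frag <- round(config$clone_coverage * total / config$insert_median)

  dc <- sample(seq_along(donor_names), n_frag, replace = TRUE,
               prob = donor_len)
  # gel size selection: fragment lengths truncated at +/- 2.5 sigma
  L <- round(stats::rnorm(n_frag, config$insert_median,
                          config$insert_sigma))
  while (any(bad <- abs(L - config$insert_median) >
               2.5 * config$insert_sigma))
    L[bad] <- round(stats::rnorm(sum(bad), config$insert_median,
                                 config$insert_sigma))
  L <- pmax(2 * r + 10, L)
  maxstart <- donor_len[dc] - L + 1
  ok <- maxstart >= 1
  dc <- dc[ok]; L <- L[ok]
  f <- 1 + floor(stats::runif(length(L)) * (donor_len[dc] - L + 1))

  off <- stats::setNames(c(0, cumsum(donor_len))[seq_along(donor_names)],
                         donor_names)
  gA1 <- off[donor_names[dc]] + f
  gA2 <- gA1 + r - 1
  gB2 <- off[donor_names[dc]] + f + L - 1
  gB1 <- gB2 - r + 1

  starts <- map$gd_start
  segA <- findInterval(gA1, starts)
  segB <- findInterval(gB1, starts)
  within <- gA2 <= map$gd_end[segA] & gB2 <= map$gd_end[segB] &
            map$novel_len[segA] == 0 & map$novel_len[segB] == 0
  segA <- segA[within]; segB <- segB[within]
  gA1 <- gA1[within]; gA2 <- gA2[within]
  gB1 <- gB1[within]; gB2 <- gB2[within]

  map_read <- function(seg, g1, g2) {
    plus <- map$strand[seg] == "+"
    pos <- ifelse(plus,
                  map$r_start[seg] + (g1 - map$gd_start[seg]),
                  map$r_start[seg] + (map$gd_end[seg] - g2))
    list(chrom = map$ref_chrom[seg], pos = pos,
         strand = ifelse(plus, "+", "-"))
  }
  A <- map_read(segA, gA1, gA2)
  B <- map_read(segB, gB1, gB2)

  # sv tag: first junction label strictly between the two segments
  sv_id <- rep(NA_character_, length(segA))
  span <- which(segA != segB)
  for (i in span) {
    tags <- map$junc_left[(segA[i] + 1L):segB[i]]
    tags <- tags[!is.na(tags)]
    if (length(tags)) sv_id[i] <- tags[1]
  }

  n <- length(segA)
  df <- data.frame(sample_id = sample_id,
                   pair_id = sprintf("%s_p%06d", sample_id, seq_len(n)),
                   chrom1 = A$chrom, pos1 = A$pos, strand1 = A$strand,
                   chrom2 = B$chrom, pos2 = B$pos, strand2 = B$strand,
                   stringsAsFactors = FALSE)
  pair_truth <- data.frame(pair_id = df$pair_id, sv_id = sv_id,
                           stringsAsFactors = FALSE)
  pair_truth <- pair_truth[!is.na(pair_truth$sv_id), , drop = FALSE]

  # uniform chimeric background
  chim <- which(stats::runif(n) < config$chimera_rate)
  if (length(chim)) {
    cn <- names(genome$chromosomes)
    cc <- sample(cn, length(chim), replace = TRUE)
    df$chrom2[chim] <- cc
    df$pos2[chim] <- 1 + floor(stats::runif(length(chim)) *
                               (genome$chromosomes[cc] - r))
    df$strand2[chim] <- sample(c("+", "-"), length(chim), replace = TRUE)
    pair_truth <- pair_truth[!pair_truth$pair_id %in% df$pair_id[chim], ,
                             drop = FALSE]
  }

  # repeat-decoy clusters: tight upstream anchor, uncorrelated downstream
  decoy_pairs <- data.frame(pair_id = character(0), decoy_id = character(0),
                            stringsAsFactors = FALSE)
  if (!is.null(decoys) && nrow(decoys)) {
    drows <- do.call(rbind, lapply(seq_len(nrow(decoys)), function(i) {
      d <- decoys[i, ]
      k <- config$decoy_pairs
      data.frame(sample_id = sample_id,
                 pair_id = sprintf("%s_%s_%02d", sample_id, d$decoy_id,
                                   seq_len(k)),
                 chrom1 = d$chromA,
                 pos1 = d$posA + floor(stats::runif(k) *
                          (config$insert_median - 2 * r)),
                 strand1 = "+", chrom2 = d$chromB,
                 pos2 = d$repeat_start + floor(stats::runif(k) * d$width),
                 strand2 = "+", stringsAsFactors = FALSE)
    }))
    decoy_pairs <- data.frame(
      pair_id = drows$pair_id,
      decoy_id = sub(sprintf("^%s_(decoy\\d+)_\\d+$", sample_id), "\\1",
                     drows$pair_id),
      stringsAsFactors = FALSE)
    df <- rbind(df, drows)
  }

  list(records = mate_pairs(df, genome = genome,
                            read_length = config$read_length),
       pair_truth = pair_truth, decoy_pairs = decoy_pairs)
}

#' Simulate mate-pair records for tumor, matched normal and controls
#'
#' Fragments are tiled on the rearranged donor genome (all implants for the
#' tumor, germline implants only for the matched normal, none for the
#' healthy controls) and anchor coordinates are emitted in reference space
#' by inverting the donor-to-reference segment map; fragments spanning an
#' implanted junction therefore yield discordant pairs whose geometry
#' matches the implanted event. Reads falling in novel (inserted) sequence
#' or across a segment boundary are unmappable and dropped. All samples
#' additionally receive the decoy clusters and the uniform chimeric
#' background.
#'
#' @param sim Output of [simulate_genome()].
#' @param implants Output of [implant_svs()].
#' @param config The [simulation_config()].
#' @return list of per-sample results (`tumor`, `normal`, `control1`, ...),
#'   each a list with `records` (a `mate_pairs` table), `pair_truth`
#'   (pair id -> implanted `sv_id` for junction-spanning pairs) and
#'   `decoy_pairs` (pair id -> decoy locus).
#' @export
simulate_mate_pairs <- function(sim, implants, config) {
  stopifnot(inherits(config, "simulation_config"))
  genome <- sim$genome
  truth <- implants$truth
  tumor_map <- build_donor_map(genome, truth)
  normal_map <- build_donor_map(genome,
                  truth[truth$status == "germline", , drop = FALSE])
  plain_map <- build_donor_map(genome, truth[0, , drop = FALSE])

  out <- list(
    tumor = emit_sample(tumor_map, genome, implants$decoys, config,
                        "tumor", config$seed + 2L),
    normal = emit_sample(normal_map, genome, implants$decoys, config,
                         "normal", config$seed + 3L))
  for (i in seq_len(config$n_controls)) {
    nm <- sprintf("control%d", i)
    out[[nm]] <- emit_sample(plain_map, genome, implants$decoys, config,
                             nm, config$seed + 3L + i)
  }
  out
}

#' Run the full synthetic study: genome, implants, mate pairs
#'
#' Convenience wrapper chaining [simulate_genome()], [implant_svs()] and
#' [simulate_mate_pairs()].
#'
#' @param config A [simulation_config()].
#' @return list with `genome`, `genes`, `truth`, `known_variants`,
#'   `decoys` and `samples` (see [simulate_mate_pairs()]).
#' @export
simulate_study <- function(config = simulation_config()) {
  sim <- simulate_genome(config)
  implants <- implant_svs(sim, config)
  samples <- simulate_mate_pairs(sim, implants, config)
  list(genome = sim$genome, genes = sim$genes, truth = implants$truth,
       known_variants = implants$known_variants, decoys = implants$decoys,
       samples = samples)
}

#' Compare calls with implanted truth
#'
#' A call recovers an implanted event when the types match, the chromosome
#' pair matches, and each breakpoint-bracketing interval contains the
#' corresponding true breakpoint.
#'
#' @param calls `sv_calls` (typically the filtered pass set).
#' @param truth Truth rows to evaluate against (e.g. the somatic subset).
#' @return list with `call_matched`, `truth_matched` (logicals),
#'   `precision` (fraction of calls matching some truth row) and `recall`
#'   (fraction of truth rows matched by some call).
#' @export
evaluate_recovery <- function(calls, truth) {
  df <- as.data.frame(calls)
  cm <- logical(nrow(df))
  tm <- logical(nrow(truth))
  for (i in seq_len(nrow(df))) {
    hit <- truth$type == df$type[i] &
           truth$chrom1 == df$chromA[i] & truth$chrom2 == df$chromB[i] &
           truth$pos1 >= df$startA[i] & truth$pos1 <= df$endA[i] &
           truth$pos2 >= df$startB[i] & truth$pos2 <= df$endB[i]
    if (any(hit)) {
      cm[i] <- TRUE
      tm[hit] <- TRUE
    }
  }
  list(call_matched = cm, truth_matched = tm,
       precision = if (length(cm)) mean(cm) else NA_real_,
       recall = if (length(tm)) mean(tm) else NA_real_)
}
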