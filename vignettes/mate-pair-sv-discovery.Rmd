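---
title: "Detecting somatic structural variants from long-insert mate pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic structural variants from long-insert mate pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Long-insert mate-pair libraries circularise ~2.5 kb genomic fragments and
sequence a short read from each end. After mapping, the two anchors of a
concordant pair sit on the same chromosome, on the same strand (once the
platform's tag chemistry is abstracted away), and roughly one insert
length apart. A genomic rearrangement between the two reads breaks one of
those three properties, so at ~8-fold *clone* coverage — many fragments
spanning each position even when nucleotide coverage is below 1x — the
discordant pairs betray deletions, insertions, inversions and
interchromosomal translocations far more cheaply than deep short-insert
sequencing. `matesv` implements that inference as a reusable, tested
pipeline: classification, clustering, a somatic filter cascade, an
anchor-correlation artifact screen, gene annotation and
validation-candidate selection, and the cohort-level enrichment
statistics, together with a coordinate-level simulator that exercises
every stage without external data.

# Classification and clustering

Each canonicalised pair (anchors ordered by genome position) is compared
with an insert-size model `(median, sigma, lo = median - 3*sigma,
hi = median + 3*sigma)`:

* different chromosomes → **translocation**;
* same chromosome, disparate strands → **inversion**;
* same chromosome and strand, separation above `hi` → **deletion**
  (implied size `separation - median`), below `lo` → **insertion**
  (implied size `median - separation`);
* otherwise concordant.

Separation is measured between anchor start positions; the model is
estimated from the same quantity (`estimate_insert_model()`: median, and
`1.4826 * MAD` floored at 5% of the median so constant-separation input
cannot produce a zero-width window), so the read length cancels and no
offset correction is needed. With too few candidate pairs the estimator
refuses and suggests a fixed `insert_size_model()` (default 2500/125,
window 2125–2875).

Pairs of one sample reporting the same rearrangement type at the same
chromosomal position are greedily clustered (`cluster_events()`). "Same
position" is single linkage: two pairs are linked when *both* anchor
starts lie within `cluster_window` (default one insert length, the
clone-length resolution of the library) and clusters are the connected
components, computed per (type, chromosome pair, strand pattern). The
union-find formulation makes two contract properties structural rather
than incidental: the output is invariant to input order, and enlarging
the window can only merge clusters, never create new ones. Stratifying by
strand pattern keeps the two junction-side clusters of an inversion and
same-orientation versus inverted translocations as separate calls, which
the correlation screen later relies on.

Each breakpoint is reported as a *bracketing interval*, the tightest
interval consistent with all members given only that a junction lies
within one maximal insert length (`hi`) of every anchor:
`[max(anchor end) - hi, min(anchor start) + hi]`. This is deliberately
direction-agnostic — mate-pair data cannot place junctions at base
resolution, and a symmetric bracket provably contains the junction for
every rearrangement geometry the simulator generates. Whether the original
analysis refined intervals by intersection or union of member evidence is
not recoverable; the bracketing contract is our documented choice.

# The somatic filter cascade

`apply_filters()` evaluates five independent flags on every call and
reports sequential per-stage attribution:

1. `in_control` — a matching call (same type, both brackets within
   `proximity_multiple` insert lengths; default 2) in any healthy-control
   call set produced by the same pipeline;
2. `near_excluded` — either bracket within two insert lengths of a
   telomere, centromere or assembly gap;
3. `known_variant` — a matching catalogued germline variant
   (type-aware when the catalogue records a type, type-agnostic
   otherwise, since BED-style catalogues vary);
4. `low_support` — fewer than `min_support` pairs (default 4, with 3 as
   the conventional relaxed alternative);
5. `in_matched_normal` — a matching call in the patient-matched normal,
   the in-silico surrogate for wet-lab somatic/constitutional
   determination.

Because the flags are independent, reordering stages changes the
attribution table but never the pass set. The report carries both the
overall removed fraction and the fraction removed before the support
threshold, since "removed" can reasonably be accounted either way.

One deliberate refinement: a control or matched-normal call must itself
have `control_min_support` (default 2) member pairs to count as an
observed event. A single stray pair in a companion sample — e.g. one
fragment from the extreme of the size distribution — is not evidence that
the variant exists there, and without this guard such strays occasionally
veto genuine somatic calls a few kilobases away.

# The anchor-correlation screen

Clusters caused by repetitive sequence look like translocations but lack
internal geometry: their downstream anchors scatter over the repeat. For
a genuine junction, as the upstream anchor position increases the
downstream position must increase in lock-step (same-orientation
junction) or decrease (inverted junction). `anchor_correlation()`
computes the Pearson correlation of member anchor positions with a
two-sided p-value from the t transform on `n - 2` df (a permutation
p-value is available), and a verdict:

* **pass** — sign matches the orientation expectation and `p < alpha`;
* **fail** — otherwise;
* **indeterminate** — fewer than `min_pairs` members (default 4) or zero
  variance in either coordinate.

`alpha = 0.05`, `min_pairs = 4` and the parametric p-value are defaults,
configurable because the source method states only "significant
correlation". The screen annotates translocations and insertions; the
pipeline *removes* only failing translocations — correlation-based
exclusion targets interchromosomal repeat artifacts, and for insertion
calls the spanned window is often so narrow relative to the
fragment-length noise that a true event cannot reach significance at
`n = 4`. The expected correlation strengthens with the ratio of anchor
window to fragment-length sigma; the test suite checks this monotonicity
on a three-point grid.

"Upstream" is the first canonical anchor — the one on the earlier
chromosome in genome order, which coincides with lexicographic order for
lexicographically named genomes.

# Annotation, selection, primers

`annotate_genes()` labels each bracket that overlaps a gene in
transcript-oriented exon numbering: intersecting exon *k* gives
`"exon k"`, lying wholly between exons *k* and *k + 1* gives
`"intron k-(k+1)"`; on the minus strand the genomically last exon is
exon 1. Validation selection (`select_candidates()`) applies three
criteria: in or within two insert lengths of a gene, at least four
supporting pairs, and recurrence (a same-type call in another sample with
both brackets within two insert lengths). Strict mode requires all three;
a relaxed mode drops recurrence, since validated non-recurrent events do
occur and the criteria are best exposed as a switch. For deeply
sequenced samples the translocation support cutoff rises to 40 and a
passing correlation verdict is additionally required. `primer_flanks()`
returns the 200 bp windows immediately outside each bracket, oriented
toward the junction and truncated at chromosome ends.

# Enrichment statistics

`log_binomial_sf()` computes `log10 P(X >= k)` by exact log-space
summation of binomial terms. No normal approximation is involved, so
tails far below double underflow (1e-250 and beyond) are exact; the suite
verifies 1e-9 agreement (relative on the log scale, absolute near 0)
against direct `dbinom` summation wherever that is representable, and the
closed form at `k = n`. `breakpoint_overlap_test()` compares the fraction
of breakpoints inside a merged region set with the uniform-null
expectation `footprint / effective genome length`, one-sided in the
deviation direction, matching the enrichment question the statistic
exists to answer; `gene_set_enrichment()` asks the analogous upper-tail
question for curated gene sets (universe default 21,000 protein-coding
genes, configurable; `set_size` lets the null reflect a large census of
which only the overlapping members are supplied). The effective genome
length defaults to 3.0e9 — the single value that reproduces both
published expected-overlap percentages (15% for 456,615,397 bp of
array-painting breakpoint regions, 13.4% for 402,989,448 bp of fragile
sites) — and is configurable on the `genome_model`.

`summarize_validation()` aggregates a per-sample validation count table
(attempted / non-validated / constitutional / somatic per type),
enforcing the row sums, and derives the cohort quantities: validated
total, somatic split, germline fractions, the interchromosomal fraction
of somatic events and the interchromosomal:intrachromosomal somatic
ratio. Where a published prose figure conflicts with the table (the
germline-deletion fraction: 83% in prose, 43/51 = 84.3% from the table),
the summarizer reports the table-derived value.

# The synthetic study generator

`simulate_study()` produces the full evaluation world at mapped-
coordinate level; no nucleotide sequence or aligner is involved, because
the pipeline consumes alignments and the computation under test begins
there. A genome of 6 x 8 Mb chromosomes carries telomeres, a centromere
and an assembly gap per chromosome plus uniformly placed multi-exon
genes. Implants (defaults: 12 deletions of 3–10 kb, 8 insertions of
600–1500 bp, 8 inversions of 3–10 kb, 3 translocations; 35% germline)
are mutually non-overlapping, clear of excluded regions, and spaced so
filter proximity matching cannot confuse neighbours. Fragments of length
`Normal(2500, 150)` — truncated at 2.5 sigma, emulating gel size
selection, which also makes "concordant" exact for noise-free tests —
are tiled to 8-fold clone coverage on the *donor* genome (all implants
for the tumor, germline only for the matched normal, none for two
healthy controls) and anchors are emitted in reference space by
inverting the donor-to-reference segment map, so junction-spanning
fragments produce discordant pairs with the correct geometry
automatically. Reads falling in inserted (novel) sequence or across a
segment boundary are unmappable and dropped, as they would be in
practice.

Translocations are implanted *unbalanced*: one derivative joins the left
arm of one chromosome to an arm of the other and the displaced arms are
lost. This is the common configuration in tumor genomes and gives each
junction exactly one discordant cluster — the geometry the per-cluster
correlation statistic assumes. (A reciprocal pair of derivatives
produces two adjacent clusters that single-linkage merging would fuse
into one call whose two parallel anchor trends cancel the correlation.)

Two artifact channels mimic what the filters and the screen exist to
remove: *decoy repeats* (default 4 loci, 10 kb wide, 10 pairs each) emit
clustered pairs whose upstream anchors are tight but whose downstream
anchors are uniform over the repeat — translocation-like clusters with no
anchor coupling — and a uniform *chimera* background (0.5% of pairs)
models random library chimerism. The chimera rate is chosen only to
provide a non-trivial filterable background: the published 8% discordant
fraction mixes true variation and artifacts in unknown proportion and is
not a calibration target. Features of real data the generator does not
model: mappability structure, GC and coverage bias, sequencing error,
microhomology at junctions, subclonal variant fractions. Passing
round-trip tests therefore demonstrate the correctness of the
computation, not the field performance of the laboratory assay.

# Numerical and interface choices

* Coordinates are 1-based and closed throughout the R API
  (GenomicRanges convention); BED/BED12 input converts at the boundary
  via `rtracklayer`, the BEDPE writer emits standard 0-based half-open
  columns, and all human-readable reports are 1-based inclusive.
* The mate-pair TSV dialect defines `pos` as the 1-based leftmost
  aligned base of the read.
* `|r| >= 1 - 1e-12` short-circuits to `p = 0` to keep the t transform
  away from a vanishing denominator; degenerate member sets yield an
  `indeterminate` verdict rather than an error.
* Bracket intervals are clipped at chromosome starts; a pathological
  chain whose extent exceeds `2*hi` falls back to the anchor extent.
* Sub-seeds for the generator are small fixed offsets of the study seed,
  so every sample and stage is independently reproducible.

# Problem sizes used in the checks

The packaged checks run ten default synthetic cohorts (~48 Mb genome,
~150,000 pairs per sample, tumor + normal + two controls) for round-trip
recovery, ten 22-chromosome cohorts with ten true and ten decoy
translocations each for the screening rates, and 1000 replicates of 2000
uniform breakpoints against a 15% footprint for the null calibration of
the overlap test — sizes chosen to give stable rates (about a hundred
events per tally) while keeping a full run in the minutes range on one
CPU.

# Known limitations

* Breakpoints are bracketed at insert-length resolution; exact junctions
  require orthogonal evidence (the package only extracts primer flanks).
* The matched-normal subtraction is a computational surrogate for
  wet-lab somatic determination; with a low-coverage normal, germline
  events with too few spanning pairs there can escape the veto.
* Insertions longer than the insert size leave no spanning pairs and are
  invisible by construction; insertions near the detectability edge
  (implied size within ~3 sigma of zero) lose support to the concordance
  window.
* The gene annotation assumes one transcript per gene symbol; isoform
  arbitration is out of scope.
* Recurrence matching is positional; it does not attempt to distinguish
  shared artifacts from genuinely recurrent biology.
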