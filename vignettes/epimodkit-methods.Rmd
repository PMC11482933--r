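---
title: "Methods: multiplexed RNA modification mapping with epimodkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiplexed RNA modification mapping with epimodkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The assay and the analysis problem

Proximity-barcoded RNA modification profiling captures fragmented RNA on
magnetic beads that each display a single modification-specific binder
together with a barcoded sequencing adapter. When a bead captures a
fragment, reverse transcription transfers the bead's modification barcode
(MBC) and a unique molecular identifier (UMI) onto the cDNA, so the
sequencing read records which binder captured the fragment. Splitting the
reaction into an *enrichment* aliquot (exposed to the beads) and a
*solution control* (barcoded at random, modified or not) turns modification
mapping into a coverage-enrichment problem: loci where the enrichment
library piles up relative to the solution control are candidate
modification sites. Two modifications are multiplexed here:
N6-methyladenosine (m6A), which sits in DRACH motifs (D = A/G/U, R = A/G,
H = A/C/U) and concentrates in 3'UTRs, and inosine, the product of
ADAR-mediated A-to-I editing, which base-pairs like G and is therefore read
as an A-to-G mismatch by the sequencer — giving an orthogonal, single-base
line of evidence under every inosine peak.

`epimodkit` implements the complete downstream analysis — barcode
processing, spike-in quantification, peak calling, reproducibility-based
confidence filtering, A-to-G variant detection, annotation and differential
comparison — together with a fully seeded simulator that generates
libraries with known ground truth for every stage. Read alignment itself is
out of scope: the pipeline consumes aligned fragments (or the simulator's
truth alignments in test mode).

# The simulator: what it emulates

`sim_config()` fixes the study conditions. The defaults describe the
desk-scale toy used throughout the test-suite: a single ~50 kb chromosome
carrying 8 genes (5'UTR, intron-bearing CDS, 3'UTR; both strands), 20 m6A
sites planted only on DRACH adenosines with a 0.8 probability of drawing
from the 3'UTR DRACH pool, and 10 inosine sites on adenosines biased to
introns and UTRs (weights 0.5/0.25/0.15/0.1 for intron/5'UTR/3'UTR/CDS,
following the reported inosine distribution across gene regions).
Site stoichiometries are uniform on [0.5, 1]. Sites of the same
modification are kept >= 300 nt apart — the assay is peak-resolution, and
two sites closer than the fragment-plus-smoothing scale (~190 nt) would be
a single unresolvable peak, making per-site recall ill-defined.

Fragments are drawn per gene (lognormal expression weights, sdlog 0.5) with
lengths Normal(140, 20) truncated at 1 nt, matching the ~140 bp
fragmentation of the assay. A fragment overlapping a modification site is
*modified* with probability equal to the site's stoichiometry (combined
independently across overlapping sites).

**Capture model.** Each of the two bead types captures a candidate
fragment with affinity proportional to `capture_enrichment` (default 8)
when the fragment carries that bead's modification and 1 otherwise; the
fragment enters the library with probability `sum(affinity) / (2 *
capture_enrichment)` and takes the capturing bead's MBC. Consequences we
consider essential to the assay's logic:

* at `capture_enrichment = 1` every fragment is captured and barcoded at
  random — the enrichment reaction is exactly exchangeable with the
  solution control (the null configuration);
* unmodified fragments are captured non-specifically at rate `1/(2k)`
  regardless of what sites they overlap, so one modification's sites do
  not bleed into the other's channel;
* a fragment carrying both modifications is strongly captured by both bead
  types (co-modified loci appear in both channels, as reported for genes
  carrying adjacent m6A and inosine sites).

`n_reads_enrich` counts fragments *offered* to the beads; the realized
enrichment library is the captured subset (~1/8 of unmodified candidates at
the default boost). Randomness is consumed in a fixed per-candidate layout
(placement, firing, acceptance, barcode choice), so removing one
modification's sites perturbs nothing else — the property behind the
decoupling contract tested in the suite.

Reads: read 1 is the insert in cDNA sense orientation; read 2 starts with
the 8 nt MBC, then the 10 nt UMI, then insert from the opposite end. The
published read layout states only that paired-end sequencing reads "the
UMI, MBC along with the RNA sequence" (cycles 151/8/8/71); the 8+8 index
cycles may equally be sample indices, so the layout here is configurable
and this choice is recorded in the run manifest. Inosine read-out: a read
over an edited adenosine reports G with probability stoichiometry x
`inosine_editing_rate` (default 1: every edited molecule reads as G).
Sequencing error is a uniform 0.1% substitution rate; PCR duplicates
(default 10%) share the molecule's UMI and edits but acquire independent
errors. The simulator does not model per-cycle error profiles, polyA
selection, or structure-driven ADAR targeting; passing tests therefore
demonstrate the pipeline's correctness against its own generative
assumptions, not performance on real libraries.

# Barcode processing

`extract_and_trim()` removes MBC and UMI from read 2 and stores them as
tags. MBCs are error-corrected to the whitelist within Hamming distance 1
(the two default barcodes are distance 8 apart, so correction is
unambiguous); anything farther, or equally close to two entries, routes to
`undetermined`. Quality trimming is a 3' sliding window (window 4, mean
Q < 20), a common default the source pipeline leaves unspecified; trimmed
inserts shorter than 30 nt are discarded and counted. Deduplication
collapses on (reference, start, strand, MBC, UMI) — deliberately
position-aware, since positionless UMI collapse across a transcriptome
would merge distinct molecules; `position_aware = FALSE` restores the
plain (reference, MBC, UMI) key. The retained representative is the
highest mean base quality, ties broken by read id, making deduplication
deterministic and idempotent. `downsample_equal_mbc()` equalizes per-MBC
coverage across samples before quantitative comparison (minimum count per
MBC, sampled without replacement, seeded).

# Spike-in scaling

The spike-in reference ("LMS") carries one densely modified segment per
modification plus an internal-standard segment with a single site per
modification. Fragments are assigned to the segment containing their
midpoint (left of the two central bases for even lengths, so boundary
midpoints go left). Counts are normalized per million deduplicated mapped
fragments per sample and MBC — per-MBC rather than global, because the
two channels are sequenced at very different depths; a flag in
`count_spikein()`'s `library_sizes` lets callers supply any other basis.
The enrichment factor is `curve(cpm on mod segments / cpm on internal
standard)` on the enrichment sample. The published pipeline uses an
internally measured standard curve whose coefficients are proprietary;
`standard_curve()` therefore provides identity (default), linear, and
piecewise-linear-from-TSV curves — preserving the scaling contract without
inventing coefficients. Per-million normalization makes the factor
invariant to sequencing depth, and the dense-segment/single-site design
makes it increase with the capture boost, which the suite verifies.

# Peak calling

Per MBC, enrichment and solution-control fragment coverage are normalized
to counts per million library fragments and combined into
`log2((signal + a) / (background + a))` with pseudocount `a = 0.5`,
smoothed by a centered 51 nt moving average (the window must be odd; 51 is
the odd neighbor of the intended 50). Candidate summits are local maxima
with topographic prominence >= 0.5 log2 units and ratio >= `r_min = 2`;
boundaries extend until the ratio falls below half the summit ratio or
below `r_min`, whichever comes first, and overlapping candidates merge
keeping the higher summit. All parameters are echoed into the peaks'
metadata and the run manifest.

One refinement proved necessary: near transcript ends, fragment placement
is constrained (fragments cannot extend past the end), which flattens the
enrichment ratio between a site and the end — the ratio argmax then
wanders tens of nt. The *reported summit* is therefore the maximum of the
smoothed normalized signal coverage within the peak interval, which peaks
at the site itself; candidate detection and merging still operate on the
ratio. Raw enrichment is the smoothed ratio at that summit;
`scale_peaks()` multiplies it by the modification's spike-in factor to give
the final fold-enrichment, preserving within-modification ranking.

# Confidence filtering

False positives are modeled by reproducibility: for a grid of 40
log-spaced fold-enrichment cutoffs (1 to the 99.5th percentile), the FPR at
cutoff c is the fraction of peaks >= c in one replicate lacking any >= 1 nt
overlap in the other, averaged over both directions (`fpr_curve()`, either
single direction available). The curve is fit with
f(c) = A exp(-k c) + m c + b, A >= 0, k > 0. The fit is deterministic: a
separable profile over a fixed k-grid (the model is linear in A, m, b for
fixed k; ordinary least squares with A clamped at 0) followed by a
Levenberg-Marquardt polish from both the fixed initialization
(A = max, k = 1, m = 0, b = min) and the profiled optimum, keeping the
lower-RMSE solution — plain Levenberg-Marquardt from the fixed start hits
singular gradients on step-shaped curves. The selected cutoff is the
smallest grid value with modeled FPR <= 5%; if none qualifies or the
linearity diagnostic fails, the cutoff falls back to the largest cutoff at
which a top-anchored linear fit still held, and with no valid fallback the
grid maximum is used (flagged conservative). The linearity tolerance is
`max(0.01, 0.75/n)` where n is the smaller replicate's peak count in the
window: an FPR estimated from n peaks is quantized in 1/n steps, so a fixed
0.01 tolerance is unattainable at desk scale while the floor still binds at
realistic (tens of thousands) peak counts. High-confidence peaks satisfy
fold-enrichment >= cutoff AND enrichment summit depth >= 5 deduplicated
reads; peaks are flagged, never deleted.

**Pseudo-replicates.** A single-sample run has no true replicates, so the
pipeline splits the deduplicated enrichment fragments into halves by a
content-stable hash of each fragment's UMI and position (UMIs are random,
so the split is unbiased, and a fragment's half assignment does not depend
on which other fragments exist). A full-depth peak counts as reproduced in
a half when the half's smoothed enrichment ratio *at the peak summit*
reaches a relaxed threshold (half of r_min's log-fold): requiring a full
re-call in each half would read half-depth shape noise as
irreproducibility, while summit-level ratio keeps weak true peaks and
still fails fluctuations that split across the halves. With fewer than 10
peaks the curve is not estimated and the cutoff is set above every
observed fold-enrichment (nothing high-confidence) — reproducibility
cannot be assessed, so the conservative answer is chosen. Pseudo-replicates
share any library-level fluctuation by construction, so occasional
reproducible noise peaks survive (the toy yields 10/12 true inosine peaks
at high confidence); true replicates do not have this limitation.

# Inosine A-to-G variants

A native pileup walks aligned fragments (CIGAR-aware; M/=/X, I/S, D/N;
malformed records skipped and counted) restricted to inosine peak
intervals, with a 20,000-read depth cap and a Q13 base-quality floor. BAQ
recalibration, an alignment-quality heuristic of the external caller the
published pipeline used, is intentionally not reproduced — the quality
floor stands in; the thresholding logic is what defines the result. A site
is reported when the transcript-strand reference base is A (genomic T with
C alternate on minus-strand genes), the variant rate alt/depth — computed
after depth capping — is >= 10%, and depth strictly exceeds 5 (the two
depth rules are kept exactly as printed: the peak rule is >= 5, the
variant rule is > 5). Output is VCF 4.2 (1-based) with depth, alt count,
rate and owning peak id; `peak_variant_support()` reports each peak's best
site and the global fraction of inosine peaks with at least one site.

# Annotation, metagene and motif shift

Peaks are annotated by summit position against the gene models (interval
mode behind a flag); when a summit hits several features the precedence is
3'UTR > 5'UTR > CDS-exon > ncRNA-exon > intron — an implementation
decision recorded in the output, since the source does not state one. The
metagene profile maps each summit to a fractional position in concatenated
5'UTR | CDS | 3'UTR segments (30/60/30 bins); intronic summits count
within the CDS segment, consistent with peak calling in genome space and
with the way transcript plots fold introns into the CDS. Densities sum
to 1. `drach_scan()` finds DRACH 5-mers via IUPAC matching (U = T);
`motif_shift()` collects the signed transcript-strand distance from each
summit to the nearest DRACH adenosine and compares it to the same statistic
at positions drawn uniformly from gene bodies. In a uniform-random toy
genome DRACH occurs about every 57 nt, so the null's nearest-motif distance
is itself concentrated within +/-50 nt; the discriminating check at desk
scale is the +/-5 nt central window (where planted summits put all their
mass), not the +/-500 nt panorama a real transcriptome affords.

# Differential comparison

`match_peaks()` merges overlapping peak intervals (>= 1 nt; abutting peaks
stay distinct) across conditions into loci by single linkage; per locus
and condition the fold-enrichment is the maximum over contributing peaks,
absence is 0 with a presence flag, and mixing modifications in one call is
an error. Correlation (`peak_correlation()`) is Pearson over co-present
loci only, mirroring how fold-enrichment scatter plots treat
condition-unique peaks; R^2 = r^2. `rank_test()` is the two-sided Wilcoxon
rank-sum test (exact when both n <= 8 without ties, else normal
approximation with tie and continuity correction).
`cluster_gene_scores()` aggregates loci to gene means per condition,
z-scores each gene across conditions (the reading of "aggregated z-scores"
adopted here; a flag transposes), and clusters genes by Ward linkage on
Euclidean distances — `hclust(method = "ward.D2")`, which the suite
cross-checks against an independent Lance-Williams implementation. Rows
are ordered by gene id so the dendrogram is deterministic.

# Pipeline orchestration

`run_pipeline()` executes simulate, demux, align (truth-join or external
fragments), dedup, spike-in, callpeaks, filter, variants, annotate in
order. Every stage saves its state and a completion marker; re-running
skips completed stages until the first missing marker and regenerates
everything downstream (`force = TRUE` reruns all). The manifest echoes
every parameter; the log reconciles read counts at each stage (input =
kept + rejected per reason). A thin command-line wrapper
(`inst/cli/epimodkit`) exposes `simulate` and `run-all`; all other spec'd
subcommands (demux, dedup, spikein, callpeaks, filter, variants, annotate,
diff) are the exported functions themselves, which is the interface an R
package's users script against.

# Problem sizes and numerical choices

The bundled study condition is deliberately desk-scale: ~50 kb of genome,
40,000 candidate fragments per reaction (about 10,000 captured in the
enrichment library at the default boost), 20 + 10 planted sites. The full
test-suite, including several end-to-end pipeline runs, completes in a few
minutes on one CPU. Tolerances worth knowing: the noise-model fit recovers
clean parameters to ~1e-11 RMSE and tolerates 1% multiplicative noise
within ~1-2% relative error; cutoff selection treats the max-FPR boundary
as inclusive (with a 1e-9 guard for floating point); peak-match tolerance
for ground-truth evaluation is a summit within +/-50 nt of a planted site,
half the smoothing window above the assay's fragment-scale resolution.

Known limitations: pseudo-replicates cannot flag library-level coverage
fluctuations (see above); the simulator's capture model treats bead
affinities as independent and memoryless; enrichment-derived A-to-G rates
over-represent edited molecules, so variant rates under inosine peaks are
capture-weighted, not biological editing rates — the same caveat the assay
itself carries.
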