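---
title: "meripr: models and methods for MeRIP-seq downstream analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{meripr: models and methods for MeRIP-seq downstream analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meripr)
```

# The analysis problem

MeRIP-seq localizes N6-methyladenosine (m6A) on mRNA by sequencing an
antibody-enriched (IP) library alongside a matched input library; peak
callers such as MACS2 then report intervals of IP enrichment per
replicate. Everything downstream of peak calling — deciding which peaks
are reproducible, how methylated each peak is, where m6A sits along
transcripts, whether the RRACH consensus is present, and how methylation
relates to gene expression across conditions — is the subject of this
package. The motivating design is a developmental time course (three
stages, three biological replicates each), but every function takes the
stage/replicate structure from its inputs.

# Consensus peaks

A replicate peak pair "agrees" when the overlap covers at least half of
the **shorter** interval. The length whose half is meant is genuinely
ambiguous in common usage; the shorter-interval convention is the only
symmetric choice that never penalizes a narrow peak nested in a broad one,
and it keeps the agreement relation symmetric. Consensus peaks are the
connected components of the agreement graph restricted to cross-replicate
edges; components touching at least two distinct replicates survive.
Components — rather than mutual-overlap cliques — make the result
independent of replicate ordering and of chained overlaps (A–B and B–C
merge even when A and C barely touch). The consensus interval is the
component's span; its summit is the summit of the highest-scoring member
(ties: leftmost summit), which keeps the representative summit an actually
observed maximum rather than an average of disagreeing replicates. The
identical rule applied across stages yields the cross-stage Venn
decomposition, whose regions therefore count *distinct peak entities*, and
region counts sum to the number of entities by construction.

Peaks are attached to genes by their summit (a point, not the interval):
a summit within the transcript span (exons plus introns, any isoform) of
exactly one gene is assigned there; in overlap regions the gene with the
longest transcript wins, ties resolved by gene identifier. A single
deterministic assignment per peak is required for modified-gene counts
and peaks-per-gene histograms to be well-defined.

# Quantification

A fragment counts toward a peak when the overlap covers at least 50% of
the fragment **or** at least 50% of the peak — the second clause matters
for long fragments straddling narrow peaks. A fragment may legitimately
count toward two overlapping peaks; no uniqueness is imposed. Counts are
normalized per library to fragments per million (FPM), and per-replicate
enrichment is

$$\mathrm{enrich} = \frac{\mathrm{FPM}_{IP} + \varepsilon}
{\mathrm{FPM}_{input} + \varepsilon},\qquad \varepsilon = 0.25\ \mathrm{FPM}.$$

The symmetric pseudo-count keeps ratios finite over zero-input peaks while
perturbing well-covered peaks by under 3%; it cancels exactly when IP and
input FPM agree, so a log2 enrichment of zero means literally equal
coverage. The stage-level statistic is the arithmetic mean of replicate
log2 enrichments, the scale on which the downstream t tests operate.
Expression is FPKM per input library (fragments / exon-union kb / million
mapped), averaged over a stage's replicates; genes above 0.1 FPKM count
as expressed. Fragments overlapping the exons of more than one gene are
discarded as ambiguous rather than double-counted.

# Five-segment topology and the metagene axis

Topology uses one isoform per gene — the longest coding transcript, the
conventional metagene choice when isoform usage is unknown. Each such
transcript is split into five disjoint segments covering it exactly:

* **TSS** — the first min(200, 5'UTR length) nt;
* **UTR5** — the remaining 5'UTR;
* **CDS** — the annotated CDS minus the stop window;
* **STOP** — a 400-nt window centered on the first base of the stop codon
  (the first base after the annotated CDS, which excludes the stop codon
  in the Ensembl convention), clipped to the transcript;
* **UTR3** — the remaining 3'UTR.

The stop window takes precedence in overlaps; because it is anchored at
the CDS end, each remaining segment stays a single (possibly empty)
interval, and the five lengths always sum to the transcript length — a
property the tests verify base-by-base against an independent labeling
oracle. Segment frequencies are tallied per summit (one segment per
peak), and relative enrichment divides each segment's share of summits by
the fraction of the transcriptome the segment occupies, so a uniform
summit distribution calibrates to 1.0 in every segment.

The metagene axis has 300 bins: 100 bins of 20 nt covering the 2 kb 5' of
the CDS start, 100 bins scaling the CDS, and 100 bins of 20 nt covering
the 2 kb 3' of the CDS end. Because the axis is anchored at the CDS,
flanks run through the UTRs and — where a UTR is shorter than 2 kb — into
genomic flank, in "extended transcript coordinates". Summits in introns
are not projectable and are excluded. The smoothed profile is a trailing
4-bin moving average plotted at the window's last bin, with the first
three bins carrying raw values; trailing windows keep the smoothing
causal and shift the apparent mode by at most ~1.5 bins, which the
recovery tolerance accommodates.

# RRACH motif content

Instead of de-novo discovery, the scanner matches the RRACH consensus
(R ∈ {A,G}, central methylatable A, C, H ∈ {A,C,T}) exactly, reporting
every overlapping occurrence; N never matches. Windows of 101 nt centered
on summits are scanned on the host gene's annotated strand (reverse
complement for minus-strand genes), since m6A is a transcript mark;
intergenic peaks are scanned on both strands and a hit on either counts
once. Positional density profiles use 301-nt windows averaged in 40-bp
bins (the last bin is 21 nt), with windows clipped at chromosome ends
contributing only their covered positions. On i.i.d. uniform sequence the
per-position hit probability is (2/4)(2/4)(1/4)(1/4)(3/4) = 12/1024, the
closed form the calibration tests check against.

# Differential calls

"Student's t test" is implemented as the classical pooled-variance
two-sample test on log2 quantities (not Welch), two-sided, at α = 0.05
with no multiple-testing correction — raw P values are the stated
convention for these calls. Degenerate constant-data cases are resolved
deterministically (equal constant groups: t = 0, p = 1; separated
constant groups: |t| = ∞, p = 0) so that synthetic edge cases cannot
crash a run. A peak is "higher in stage S" when it beats **both** other
stages (log2FC > 0 and p < α against each) or when it appears only in
S's consensus set; the union of a conjunction test and a stage-unique
clause mirrors how presence/absence and quantitative differences jointly
express stage specificity. Expression sets are built the same way on
log2(FPKM + 0.01) without a stage-unique clause; the 0.01 pseudo-FPKM
keeps zero-expression genes finite on the log scale. Gene-level
differential methylation means "carries at least one differential peak".
The per-stage higher-methylation sets are pairwise disjoint by
construction, and enlarging α can only grow them — both properties are
asserted in the tests.

# Methylation–expression association

Correlations are Pearson product-moment on log2 enrichment versus
log2(stage-mean FPKM + 0.01). Both axes span orders of magnitude, and raw
scales would be dominated by a few highly expressed genes; log–log is the
scale on which the relationship is approximately linear. Each peak
contributes one point; per-segment correlations reuse the summit-based
segment assignment so all figures share one definition of "a peak in the
stop segment". The methylated-fraction-versus-expression curve ranks
expressed genes by log10 stage-mean FPKM into 20 equal-count bins — the
bin count is a display choice; equal-count bins make the per-bin
fractions directly comparable.

# The synthetic study

The generator is first-class, tested code: it emits a genome FASTA, GTF,
per-replicate narrowPeak files, count matrices and ground-truth tables
whose aggregate structure matches the motivating study, so every analysis
stage is testable without any download. Defaults and what they emulate:

* 2,000 coding genes (100 per chromosome), exon counts 1 + Poisson(2),
  CDS 900–2,400 nt, UTRs 100–600 nt — compact but realistic gene models
  that keep a full run under a minute;
* exactly 33% of genes methylated, with 1 + Poisson(0.37) peaks per
  modified gene (mean ≈ 1.37) and ≥ 600 nt between summits of one gene so
  distinct peaks cannot merge under the 50% rule;
* summit placement 45% in the stop window (normal, SD 70 nt, truncated to
  ±200), 20% in TSS/5'UTR, 35% uniform in the CDS — reproducing a
  stop-codon-centred topology whose mode falls at the CDS/3'-flank
  boundary of the metagene axis;
* RRACH planted at exactly 79% of summits, with variant frequencies
  weighted toward GGACC/GGACT; the background sequence is
  **RRACH-suppressed on both strands** (chance occurrences are mutated
  away before planting). An unsuppressed random background would contain
  RRACH in ~68% of 101-nt windows, making a planted fraction
  unidentifiable — suppression is what turns the motif fraction into a
  recoverable ground truth;
* per-peak latent log2 enrichment (mean 1.5, SD 1.5) constructed to have
  **exactly** the configured sample correlation (−0.45) with the host
  gene's latent log expression, via Gram–Schmidt orthogonalization. The
  exact-count methylation/motif subsets and the exact-correlation
  construction are variance-control devices: recovery error then reflects
  the pipeline's measurement process, not the generator's sampling noise;
* negative-binomial counts with dispersion 0.1 (the standard order of
  magnitude for biological replicates of sequencing counts), constant
  input coverage per peak (mean 200 fragments per library) so the noise
  on log2 enrichment is homoscedastic rather than confounded with
  expression, and declared library sizes of 2×10^7;
* per-replicate detection probability 0.92 and ~4% stage-unique peaks per
  stage, exercising the ≥2-replicate consensus rule and the stage-unique
  clause; 5% false single-replicate peaks per file that consensus must
  discard; boundary jitter uniform within ±10% of peak length;
* five planted higher-methylation/lower-expression genes in the newborn
  stage at 16-fold effects, with their peaks called only in that stage.

The 16-fold default deserves its power analysis. With dispersion 0.1 the
per-replicate SD of log2 FPKM is ≈ √(0.1)/ln 2 ≈ 0.46, so a pooled t test
at n = 3 vs 3 (4 df, critical value 2.78) has noncentrality ≈ 2.7 per
log2 unit of effect. A 4-fold effect (noncentrality ≈ 5.4) sits near the
detection boundary — per-comparison power around 0.95, so the conjunction
over two comparisons and five genes succeeds only ~60% of the time, and
"exact recovery of all planted genes" would test t-test power at the
boundary rather than the identification logic. At 16-fold the planted
genes are unambiguous (noncentrality ≈ 9–11, per-gene recovery ≈ 0.995)
while false positives remain negligible (the conjunction of two
directional tests at α = 0.05 has a null rate ≈ 6×10⁻⁴ per gene per
side).

What the generator deliberately does **not** model: mappability and GC
structure of a real genome, isoform diversity, fragment-level coverage
autocorrelation, peak-width/expression coupling, and expression-dependent
enrichment noise. Passing the recovery suite therefore demonstrates that
the pipeline's rules and estimators are implemented correctly and are
well-calibrated under a clean generative model — not that they are robust
to every artifact of real MeRIP-seq data.

# Numerical and interface choices

* All internal coordinates are 0-based half-open; GTF (1-based closed) is
  converted at the parser boundary, which is also where malformed lines
  are reported with their line numbers.
* narrowPeak summit offsets of −1 fall back to the interval midpoint,
  with a logged message.
* Precomputed count matrices are keyed by the peak names carried in
  narrowPeak column 4; consensus peaks inherit the name of their
  best-scoring member, which is how counts re-attach to consensus peaks
  without re-counting fragments. When fragments are supplied instead, the
  counting rule is applied directly.
* Ties anywhere (summit choice, gene assignment, expression-bin order)
  are broken deterministically, and the pipeline itself draws no random
  numbers, so a fixed generator seed makes entire runs byte-identical —
  asserted by hashing every report table across repeated runs.
* Problem sizes in the tests (2,000 genes for recovery, 10,000 summits
  and null peaks for calibration, 10⁶ nt for the motif density check)
  were chosen so each statistical tolerance sits at ≥ 3 binomial sigma.

# Known limitations

* Differential methylation uses the stated t-test rule throughout; a
  count-model alternative (negative-binomial GLM à la DESeq2) is named in
  the source literature for expression but is out of scope here, and raw
  P < 0.05 calls carry the usual multiplicity caveat.
* Whether the motif fraction should be pooled over stages or averaged per
  stage is unspecified in the motivating description; the package reports
  both (`motif$pooled$fraction`, `motif$per_stage_fraction`).
* Per-segment correlations assume stage-level mean enrichment;
  replicate-level correlations are computable from the returned records
  but are not the headline statistic.
* The five-segment scheme requires a CDS; non-coding transcripts are
  excluded from topology (with a log message) but still receive peaks at
  the gene level.
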