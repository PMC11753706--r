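---
title: "Methods: single-nucleotide 5'P degradome profiling with fivePdecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-nucleotide 5'P degradome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fivePdecay)
```

## The measurement and its model

5'P degradome sequencing captures the 5'-monophosphate ends of mRNA
degradation intermediates: every read marks a molecule that has been
decapped (or endonucleolytically cleaved) and is awaiting or undergoing
5'->3' exonucleolytic decay. Because the major cytoplasmic 5'->3'
exonuclease degrades mRNA while the last ribosome is still translating,
the exonuclease is repeatedly stalled a fixed distance behind the
ribosome. Two signatures follow at single-nucleotide resolution:

* a **3-nt periodicity** of 5'P ends over coding regions, phased with the
  codon frame, because ribosomes advance three nucleotides at a time; and
* a **strong peak 17 nt upstream of the stop codon**, where the
  exonuclease abuts the ribosome paused during termination.

`fivePdecay` quantifies both, classifies genes by how their degradation
intermediates redistribute between strains, and relates strain-level
expression features by PCA. Every analysis operates on two containers: a
`GenomeAnnotation` (per-gene TSS, start-codon, stop-codon and termination
anchors, strand, expression weight) and a `FivePrimeEndTable`
(single-nucleotide 5'P end counts per sequence/position/strand). A 5'P
end is always a single base: the 5'-most aligned position of a read, which
on the minus strand is the highest genomic coordinate.

### Coordinate conventions

Internally all anchors are 1-based genomic nucleotide positions, the
native convention of the R/Bioconductor ranges stack used for I/O
(`rtracklayer`, `GenomicRanges`); BED input/output is converted at the
boundary by those libraries, so no hand-written off-by-one arithmetic
exists anywhere in the package. Offsets are always computed on the
transcript axis (`pos - anchor` on plus, `anchor - pos` on minus), so
offset 0 is the first nucleotide of the start (or stop) codon for either
strand, and the stop-pause position is offset -17 from the first stop
nucleotide. GFF3 CDS features are written and read as *including* the
stop codon (SGD style); the internal `cds_end` anchor, the first stop
nucleotide, is recovered on reading. Genes with a multi-segment CDS are
excluded on reading with a logged reason: the gene model is deliberately
flat (single contiguous CDS), which fits the compact yeast-like
transcriptomes the method targets; spliced genes would need a
concatenated exonic axis that this package does not implement.

## Metagene profiles

`anchored_profile()` accumulates sense-strand 5'P signal per nt offset
around the start or stop codon across genes, after `rpm_normalize()`
(counts scaled by $10^6/\text{total}$). Values are reported either as
summed rpm or as a per-gene mean (`value = "sum"` or `"mean"`); the two
differ only in y-axis scale. Neighbouring genes are not masked: windows
are purely positional, and signal from an upstream gene's 3' end can
enter a long upstream flank — a property of the method worth remembering
when interpreting TSS-proximal flanks.

`genebody_profile()` renders whole coding regions comparable across
lengths: each gene's CDS coverage (stop codon included) is resampled to
`n_bins` bins by linear interpolation of its *cumulative* count vector.
This monotone, mass-preserving transform replaces spline fitting for
length normalization: it cannot produce negative coverage and conserves
each gene's total signal exactly. Flanks remain in natural nt units. Per
position, genes are averaged after discarding the `trim_extreme` fraction
(default 0.05, i.e. 5%) of the most extreme values, half highest and half
lowest — a robustness filter that keeps a handful of very highly covered
genes from dominating the average. `trim_extreme = 0` gives the plain
mean.

## The frame protection index

`frame_counts()` assigns every sense 5'P end inside the CDS (stop codon
excluded; UTR ends do not contribute) to a codon frame, the offset from
the first start-codon nucleotide modulo 3. The frame protection index of
a gene is then

$$\mathrm{FPI} = \log_2\!\frac{2\,F_\mathrm{preferred}}{F_\mathrm{total}-F_\mathrm{preferred}}$$

which is 0 for uniform frames and grows as one frame is increasingly
protected. The preferred frame is chosen per gene as the argmax of its
frame counts (ties resolved to the lowest frame index), because frame
phasing is a per-gene property. Two numerical guards are exposed as
parameters: a pseudocount (default 1) added to each frame keeps the
statistic finite when all ends fall in one frame or a gene is empty, and
genes with fewer than `min_reads` (default 10) in-CDS ends are flagged
missing rather than contributing noisy values to group statistics. Strain
level summaries report both the median and the mean of per-gene FPIs; the
median is the default, being robust to the long tail of low-coverage
genes.

`fpi_recovery(fpi_wt, fpi_mut, fpi_null)` places a mutant on the scale
spanned by the exonuclease null (0) and the wild type (1):
$(\mathrm{FPI}_{mut}-\mathrm{FPI}_{null})/(\mathrm{FPI}_{wt}-\mathrm{FPI}_{null})$.
With strain-level FPIs of 1.00 (WT), 0.87 (import-deficient mutant) and
0.79 (null) this evaluates to 0.381 — the mutant recovers only ~38% of
wild-type cotranslational decay capacity:

```{r recovery}
fpi_recovery(fpi_wt = 1.00, fpi_mut = 0.87, fpi_null = 0.79)
```

## The KDIS classification

When the exonuclease cannot enter the nucleus, a subset of genes
accumulates decapped-but-untrimmed 5'P ends just upstream of the start
codon. `kdis_classify()` operationalizes this: both libraries are
rpm-normalized; per gene, `window_signal()` sums sense 5'P signal in the
200-nt window around the first start-codon nucleotide, read as the
half-open interval $[-100, +100)$ (a symmetric reading; the bounds are
parameters); the per-gene mutant/WT ratio uses a pseudocount of 0.5 rpm
on both sides so zero-signal genes are defined (and equal to 1);
`decile_partition()` sorts genes by ratio from highest to lowest (stable
tie-break on gene id) and cuts them into `k = 10` contiguous equal-sized
clusters, any remainder going to the first clusters. Genes in clusters
1–2 are called KDIS (Kem1 5'-decay import sensitive). On 5100 genes this
yields ten clusters of 510 and a KDIS class of 1020. Sorting into
equal-sized rank clusters is the normative partition — it is what makes
the printed cluster sizes arithmetic — but a 1-D k-means alternative
(`method = "kmeans"`) is available for comparison.

Supporting group statistics are deliberately generic: `group_compare()`
runs pairwise two-sided Wilcoxon rank-sum tests with the conventional
tier labels (`ns`, `*`, `**`, `***`, `****` at 0.05, 0.01, 0.001,
0.0001), `overlap_test()` computes the upper-tail hypergeometric
probability of a gene-set overlap, and
`expression_normalized_profile()` divides each gene's coverage vector by
its mRNA abundance before averaging, removing expression-level
confounds from group profile comparisons.

## Strain-feature PCA

`build_strain_matrix()` assembles strains-by-genes matrices of
log2(mutant/WT) relative values, one per metric (mRNA half-life HL,
amount RA, synthesis rate SR), complete-cased over genes present and
positive everywhere. Metrics are analyzed separately by default — each
has its own dynamics — with concatenation left to the caller.
`strain_pca()` is a column-centered SVD (`prcomp`); variables are not
scaled to unit variance by default, since the inputs are already
log-ratios on a common scale, but `scale. = TRUE` is available. Component
signs are fixed (largest-magnitude loading positive) so results are
deterministic and invariant to gene order.

The claim that a plane of two components "separates" a binary strain
feature is made explicit by `feature_separation()`: the score is the
distance between the two class centroids divided by the mean distance of
classified strains to their own centroid, in the chosen component plane.
A plane is labelled separated when the score exceeds a threshold
(default 2, i.e. centroids at least twice as far apart as the typical
within-class spread). Strains with an undetermined label (`"nd"`) are
excluded from the score but assigned to the nearest centroid, mirroring
how an uncharacterized mutant is classified by its position among known
strains. The score is invariant under rotation of the plane, and a
label-permuted control destroys it.

## The synthetic degradome generator

The generator exists so that every downstream stage is testable, with
known ground truth, at any depth. `generate_annotation()` lays out
non-overlapping single-exon genes on synthetic chromosomes, strands
alternating, with yeast-like length distributions chosen once:

| parameter | distribution | rationale |
|---|---|---|
| 5'UTR | lognormal(log 45, 0.55), clamped 10–120 nt | compact yeast leaders, median ~45 nt |
| CDS | 3 × lognormal(log 400, 0.45) codons, clamped 40–2000 | median ~1.2 kb coding length |
| 3'UTR | lognormal(log 120, 0.5), clamped 20–400 nt | typical yeast trailer lengths |
| expression weight | lognormal, sd(log) = 1 | broad expression dynamic range |

`simulate_library()` draws each of `depth` molecules from a per-gene
mixture: (1) with probability `tss_accum` (KDIS-flagged genes only, or
all genes in the `null` regime) the end is decapped-but-untrimmed,
placed a geometric(0.08) offset downstream of the TSS, clamped to the
5'UTR; (2) else uniform background over the transcript with probability
`noise_rate`; (3) else ribosome-coupled with probability
`trim_coupling` — at the stop-pause position (default offset -17 from
the first stop nucleotide) with probability
`stop_pause_weight/(1+stop_pause_weight)`, otherwise in a codon frame
drawn from `frame_bias` at a uniform codon; (4) else endonucleolytic
background, periodic like (3) but frame-displaced by `bg_frame_shift`
(mod 3) with no stop pause. The three regime presets encode the strain
classes: `wt` (trim 0.90, frames 0.60/0.22/0.18, stop pause 0.25, noise
0.10), `dnls12` (trim 0.80, frames 0.52/0.26/0.22, stop pause 0.18,
`tss_accum` 0.75, noise 0.12) and `null` (no trimming, `tss_accum` 0.60
on all genes, background displaced by -1 nt, noise 0.35). The
frame-displacement of the null background is phenomenological — real
endonucleolytic periodicity arises from sequence composition, which the
generator does not model.

What the generator does *not* emulate is worth stating: no nucleotide
sequence (so no sequence-dependent cleavage or mappability structure),
no UMI/PCR artifacts, no overlapping or spliced genes, no antisense
transcription, and per-gene depths that are exactly multinomial in the
expression weights rather than biologically overdispersed. Passing tests
on synthetic data therefore demonstrate coordinate correctness,
statistical behaviour of the estimators and classifier recovery under
the stated model — not robustness to every artifact of real libraries.

### Measured behaviour at scale

Two behaviours of the full-scale synthetic conditions (5100 genes, depth
$10^6$ per strain, `kdis_fraction` 0.2) that the test suite computes are
worth knowing. The stop-anchored metagene argmax recovers the configured
-17 offset exactly. Planted KDIS recovery by the decile classifier sits
just above 90%: the misses are systematic, dominated by planted genes
whose 5'UTR exceeds 100 nt — their TSS-proximal accumulation falls
upstream of the fixed $[-100,+100)$ window — plus a tail of
low-expression genes whose window counts are too noisy to rank. A fixed
start-codon window is blind to accumulation at distant TSSs; widening
the window or anchoring it at the TSS would trade this against dilution
of the signal, and the package keeps the 200-nt start-codon window as
the normative definition.

## Pipeline, problem sizes and determinism

`run_pipeline()` chains simulate → write → load → metagene/FPI → KDIS →
PCA, writing tables, a timestamped log with library totals and exclusion
counts, a `summary.json` and a checksummed manifest; reruns with the
same configuration are bit-identical (figures are off by default for
that reason). All stochastic steps take explicit integer seeds and are
reproducible bit-for-bit. The default configuration uses 1000 genes at
depth $2\times 10^5$, which exercises every stage in seconds; the test
suite uses 5100 genes and depth $10^6$ where a claim is about full-scale
behaviour, and small hand-built fixtures (three genes, counts verifiable
on paper) where a claim is about coordinates. Degenerate inputs are
handled explicitly: empty libraries and empty gene sets are errors,
zero-count genes keep all-zero frame counts, all-tied rank-sum input
returns p = 1 with a warning, genes shorter than the bin count are
resampled rather than dropped, and rank-deficient PCA returns the
available components with a warning.

```{r worked, message = FALSE}
ann <- generate_annotation(300, seed = 1)
wt <- simulate_library(ann, decay_regime("wt"), kdis_fraction = 0.2,
                       depth = 2e5, seed = 2)
mut <- simulate_library(ann, decay_regime("dnls12"), kdis_fraction = 0.2,
                        kdis_genes = wt$truth$gene_id[wt$truth$kdis_flag],
                        depth = 2e5, seed = 3)
pr <- anchored_profile(rpm_normalize(wt$ends), ann, "stop", 200, 50)
pr$positions[which.max(pr$values)]          # stop-pause peak position

f <- fpi(frame_counts(wt$ends, ann))
median(f$fpi, na.rm = TRUE)                 # strain-level FPI (median)

asg <- kdis_classify(wt$ends, mut$ends, ann)
sum(asg$kdis)                               # = 2 * 300/10 genes called KDIS
```
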