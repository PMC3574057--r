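---
title: "Methods: cell-type specificity of ChIP-seq peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type specificity of ChIP-seq peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The problem

ChIP-seq peak sets for the same transcription factor differ between cell
lines. Given peaks called per TF in a reference and a comparison cell type,
the package asks three questions. How does the probability that a peak is
*common* (overlaps a same-TF peak in the other cell type by at least one
base) depend on peak height and genomic context? Which measurable features
distinguish common from cell-type specific peaks? And can a classifier
trained on one cell-type pair predict commonness against a third cell type?

## Conventions and primitives

All coordinates are 0-based half-open (BED convention); "at least one base
pair" of overlap means a non-empty intersection under that convention, so
abutting intervals do not overlap. Relative overlap is the number of
reference peaks with an overlapping comparison peak divided by the smaller
of the two set sizes; the ratio is reported literally and may exceed 1 when
several reference peaks pile onto one comparison peak — we do not clip it.

Peak clusters pool the peaks of *all* TFs in one cell type, extend each
peak symmetrically to a total footprint of 2000 bp (peaks already longer
are left alone; an odd remainder goes to the right side; extension clamps
at coordinate 0), and take connected components of pairwise extended
overlap. A peak in no multi-peak cluster is its own singleton cluster
(cluster TF count 1, cluster average height equal to its own height);
using zeros instead would conflate missingness with weak clustering.

## Annotation features

Promoters are the strand-aware window from 2000 bp upstream to 200 bp
downstream of the TSS plus the gene's first intron in transcription order;
Pol III promoters use the same window around tRNA starts. TSS distance is
measured from the peak midpoint (the anchor is a package choice; midpoints
make the feature symmetric in peak length) and capped at 20 000 bp to limit
the feature's range — we read the published "max 20 000" as a cap, since
the stated intent is range limiting, although the same source elsewhere
words it as a maximum of the two numbers, which would be a floor.

CpG classification follows the observed/expected convention: the expected
CpG count of a window is `count(C)·count(G)/length`, and "CpG frequency" is
observed/expected. A sequence is *rich* if any 500 bp window has GC > 0.55
and ratio > 0.75, *poor* if the whole-region ratio is below 0.48 (the
window-versus-region scope of the poor test is ambiguous in the source
convention; we use the whole region and expose the thresholds as
arguments), otherwise *intermediate*, so the two classifier indicator
features can both be zero. The scanning step is 10 bp by default; the test
suite checks that 10 bp and 1 bp scans agree on its sequences.

## Signal and motif scores

Tag signal over a region is `count / length / (total tags / 10^6)` —
reads-per-million per base pair. Conservation over a region is the average
of overlapping track values weighted by overlap length; regions without
coverage score 0 and carry an explicit flag rather than being dropped, so
downstream consumers decide. Per-cell-type pairs of signals are summarised
as the average `(a+b)/2` and the difference `a−b` (reference minus
comparison). Expression differences and peak-count differences are mapped
to `[−1, 1]` with the bounded relative difference `(a−b)/(a+b)`, the
standard parameter-free normalisation.

PWM counts receive a pseudo-count of 1 per cell before conversion to
log-odds against the genome-wide base distribution; we use log base 2
throughout (every downstream analysis depends only on score order, which is
base-invariant). Background frequencies are floored at `1e-6` and
renormalised so degenerate synthetic genomes cannot produce infinite
log-odds. The score of a peak is the maximum over all windows on both
strands; ties break to the smaller forward offset, then "+" strand. Windows
containing `N` are skipped. When several PWMs share a TF, the one with the
highest mean per-column information content is used; TFs without a PWM
carry an `NA` PWM score and the `hpp` model silently drops that feature for
them.

## Genotype analysis

SNP records code genotypes 0 (reference-homozygous) and 1
(alternate-homozygous); heterozygous or missing calls are `NA`. The
homozygous-different selection keeps records where both cell types have
confident homozygous calls that differ; calls with quality below 20 (a
config-exposed threshold standing in for upstream genotype filtering, whose
exact cutoffs the source pipeline does not state) are excluded. For each
cell-type specific peak carrying such a SNP, the peak sequence is rewritten
under each genotype (all of that genotype's alleles substituted), rescanned,
and kept when a SNP lies inside the best-scoring motif window of the
own-genotype sequence. The paired one-sided t-test then asks whether scores
are higher under the genotype of the cell type that has the peak. When all
differences are zero the test is undefined and reported as p = 1.

## Trend analyses

Peaks are sorted by height (ties broken by peak id for determinism) and
split into 10 contiguous bins whose sizes differ by at most one; remainder
peaks go to the highest bins. The trend statistic is an OLS fit of the 10
bin means on the bin index — the regression is on bin means, not raw peaks,
matching the per-bin presentation of the analysis it reproduces (a
raw-peak variant would be a one-line change but is not the default), with
a two-sided slope t-test at α = 0.05 and no multiple-testing correction.
The GC-balanced subset trims the top and bottom 5 % of GC values, bins the
rest into 10 equal-interval GC bins, and samples an equal number of peaks
from every non-empty GC bin within each height bin, using a caller-supplied
seed. The "30 % highest/lowest" chromatin comparisons select by height rank
in the full per-TF peak set before overlap labelling and compare the
own-cell and other-cell signal distributions at specific peaks by
two-sample KS test (exact p-values below 30 observations per group,
asymptotic above).

## Classifiers

The 16 features are: height percentile (average rank / n × 100 within the
TF and cell type, so a single peak is the 100th percentile and ties share a
value), peak length, promoter indicator, capped TSS distance, cluster TF
count, cluster average height, DNase average and difference, H3K4me3
average and difference, H3K27me3 average and difference, CpG
observed/expected ratio, high- and low-CpG indicators, and conservation.
The published setup does not state the SVM kernel or cost; we use a
soft-margin linear kernel with C = 1 and per-training-fold z-score
standardisation (16 features, thousands of examples, and the emphasis on
feature attribution favour a linear model); both are arguments. Classes
are weighted inversely to their training frequencies: common and specific
peaks are rarely balanced, and an unweighted soft-margin SVM on heavily
overlapping classes can collapse onto the majority class — the weight
vector shrinks to numerical zero with arbitrary sign, destroying the
decision-value ranking the ROC score depends on. ROC scores
are computed from continuous decision values by the rank statistic.
Cross-validation is stratified: each class is shuffled under the seed and
dealt round-robin, so fold class counts differ by at most one.

Feature-group elimination removes one group at a time (Height, Length,
Promoter, TSS dist, Cluster, Chromatin, H3K4me3, H3K27me3, CpG, PhyloP) and
reports the change in mean cross-validated ROC under identical folds. The
reduced "supergroup" analysis removes height and clustering first and
groups the remaining 13 features into cell-type specific context
(chromatin and both histone marks), promoter/sequence-associated (promoter,
TSS distance, CpG features — and length, which we place here so the three
groups partition the remainder), and conservation.

The cross-cell-type protocol stratifies folds over the reference peaks,
trains each fold's model on features and labels derived against comparison
cell type B, and evaluates on the held-out fold relabelled and
recontextualised against cell type C; train and test peak sets are disjoint
by construction and the cell-type specific features come from different
cell types in train and test.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume, not
read-level realism. Geometry: peaks live on a 500 bp slot grid, so peak
regions never collide; multi-TF loci occupy consecutive slots (at most one
peak per TF per locus), and extended-overlap chaining between nearby loci
is allowed — cluster sizes are whatever `cluster_peaks()` finds, and the
commonness model is applied *after* clustering, so ground truth is always
consistent with the emitted files. Each common reference peak gets a
partner peak in the other cell type, jittered by up to ±50 bp within the
slot so overlap is at least one base but never accidental with a
neighbouring peak.

Key default conditions, chosen once:

* `beta_height = 0.04` per height percentile and `beta_cluster = 0.5` per
  cluster TF; the intercept `beta0 = -4.4` puts mean commonness near the
  one-third overlap reported for real cell-line pairs.
* Two chromosomes of 10 Mb and 2000 peaks per TF for 5 TFs. (At half that
  genome size the 20 000 peak regions of two cell types would chain into a
  single genome-wide cluster under 2 kb extension; 10 Mb preserves a
  realistic cluster-size distribution at the published per-TF peak counts.)
* Peak lengths uniform on 100–400 bp, matching trimmed peak-region sizes;
  heights log-normal (meanlog 3, sdlog 1).
* Chromatin: tags are 36 bp; a cell's mean tag count over a region it has
  a peak in is `tag_mu × chromatin_effect`, scaled with height percentile
  (so higher peaks show larger between-cell differences); only a fraction
  `chromatin_asym_prob = 0.6` of specific peaks are chromatin-driven
  (closed in the other cell type) — the rest are accessible in both, which
  keeps the chromatin features informative but not perfectly separating,
  as in real data where the distributions overlap. H3K27me3 is generated
  at the background rate everywhere and carries no label signal.
* Conservation is elevated by 0.25 (sd 0.3) at common peaks; motifs
  (width 10, one high-information column) are planted in 60 % of reference
  peaks; a configurable fraction of specific peaks (default 10 %) instead
  carry a homozygous-different SNP converting the consensus base of the
  high-information column to the worst-scoring base in the partner
  genotype. Incidental SNPs occur in 12 % of peaks with a realistic mix of
  concordant, heterozygous, discordant and low-quality calls.
* A CpG-island sequence generator rewrites 40 % of gene promoters so the
  CpG features vary; 35 % of peak loci are placed at promoters.

What passing tests on this generator do and do not show: they demonstrate
that the pipeline recovers planted structure — monotone height trends,
chromatin asymmetry, motif-disrupting genotypes, and the dominance of
height and clustering in the classifiers — and that the statistics are
calibrated under the matching nulls. They do not validate biological
conclusions about real ENCODE data: the generator has no mappability or GC
sequencing bias, no replicate structure, independent noise across marks,
and a literal logistic commonness model.

## Problem sizes and numerical choices

The test suite and acceptance checks run at reduced but non-trivial sizes
chosen as representative: 2000 reference peaks per cell type for classifier
checks (10 seeds for elimination properties, 20 for trend and genotype
properties), 500 null simulations for calibration, and the full
10 Mb × 2-chromosome scale for decile-monotonicity checks, where binomial
noise at 1000 peaks per decile is small relative to the modelled increments.
Degenerate inputs are defined rather than left to chance: empty peak sets
error in relative overlap; zero-variance bin means report slope 0, p = 1
with a flag; all-N windows produce a no-hit motif result; zero-coverage
conservation scores 0 with a flag; constant features pass through
standardisation with unit scale.

## Known limitations

Relative overlap above 1 is reported as computed. The SNP exchange format
extends the published field list with position and alleles, which the
analysis needs but the original table does not carry. Expression analysis
operates on supplied tables; read counting is out of scope. The pipeline
evaluates one reference cell type against one comparison at a time;
three-way analyses are compositions of pairwise runs.
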