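---
title: "Methods: the variant-landscape analysis in varscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the variant-landscape analysis in varscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

`varscape` characterises the polymorphism landscape of resequenced genomes
called against a common reference, in the style of crop resequencing panels
that compare *indica*- and *japonica*-type rice landraces: per-sample
qualification of SNP and InDel calls, windowed density tracks, SNP-desert
detection, the base-change spectrum with the transition/transversion ratio,
native consequence annotation against gene models, boxplot-fence outlier
genes, and Pearson-correlation clustering of samples. The package starts
from variant calls (VCF); read alignment and variant calling themselves are
out of scope.

All internal coordinates are 0-based half-open. VCF (1-based positions) and
GFF3 (1-based inclusive intervals) are converted at the I/O boundary only,
which keeps every overlap and codon computation in a single convention.

# Variant qualification

A call is kept when every available quality passes inclusively:

* mean mapping quality ≥ 20,
* depth of coverage ≥ 10,
* average base quality ≥ 30,
* variant allele frequency ≥ 0.1 for SNPs and ≥ 0.3 for InDels.

These are the VarScan-style minima commonly used to qualify resequencing
calls. Two reading choices were genuinely open and are fixed here:

* **Inclusive comparisons.** "Mapping quality of 20" is read as the minimum
  acceptable value (`>=`), matching the semantics of VarScan's `--min-*`
  options; a call exactly at every boundary is kept.
* **Absent fields skip their criterion** rather than fail it. VCFs from
  callers other than VarScan may lack one of the four annotations; silently
  rejecting such records would make the filter caller-dependent. The filter
  report counts every skipped criterion so the decision is visible.

A record failing several criteria is tallied once, under the first failing
criterion in the order mapq, depth, base quality, VAF. Multi-allelic rows
are decomposed into biallelic records before filtering; symbolic alleles
(`<DEL>`, breakends) are typed `OTHER` and always rejected. VarScan's
percent-formatted frequencies ("12.5%") are parsed to fractions.

# Windowed density and SNP deserts

Counts are binned per variant class into fixed non-overlapping windows
(default 100 kb). A variant at 1-based position $p$ lands in window
$\lfloor (p-1)/w \rfloor$; InDels are anchored at the first REF base. The
final window of a chromosome keeps its true (possibly partial) width and is
weighted by it in per-kb summaries — dropping it would silently delete
telomeric variants.

A *SNP desert* is a maximal run of consecutive windows whose density is
**strictly** below 1 SNP/kb (a window of width $w$ bp qualifies iff
$\text{count} < w/1000$). Runs never cross chromosomes, single windows
count, and no merging over interrupting high windows is performed. Deserts
shared by all samples are the bp-level set intersection of the per-sample
intervals; on a common window grid these stay window-aligned, but fragments
shorter than one window are retained and flagged `sub_window` for future
variable grids. Gene content of a desert counts gene spans *fully
contained* in the interval, since the interesting observation on real data
is a shared desert containing no genes at all.

# Base-change spectrum

Base changes are unordered pairs (G→A counts under A/G), giving six
classes: the transitions A/G and C/T and the transversions A/C, A/T, C/G,
G/T. The ratio is

$$\mathrm{Ts/Tv} = \frac{n_{A/G} + n_{C/T}}
{n_{A/C} + n_{A/T} + n_{C/G} + n_{G/T}},$$

reported unrounded in the result object and rounded half-up to 3 decimals
in exports, the convention of published tables. With no transversions the
ratio is undefined and exported as missing, never infinity. InDel lengths
are signed (`nchar(alt) - nchar(ref)`) on prefix-normalized alleles.

# Consequence annotation

Annotation is native (no external annotator): gene models are read from
GFF3, UTRs are taken from explicit features when present and otherwise
derived as exonic-minus-CDS split by transcription order, and introns are
the transcript span minus its exons. Each gene carries regulatory flanks of
5,000 bp on both sides (upstream/downstream by strand). 5 kb is the common
annotation-tool default; since published studies rarely state their flank,
it is a configuration knob (`flank_bp`).

Per variant, one effect record is emitted per overlapping gene, at the most
severe consequence across that gene's transcripts under the standard
precedence `cds > utr > intron > regulatory`; within CDS, nonsynonymous
outranks synonymous. This per-(variant, gene) granularity deliberately
reproduces the over-counting that overlapping gene models cause in
published annotation tables while avoiding per-transcript inflation. A
variant overlapping nothing yields a single intergenic record.

CDS SNPs are classified by rebuilding the transcript's coding sequence in
transcription order (reverse-complemented on minus-strand transcripts),
substituting the alternate base (complemented on minus strand), and
translating the affected codon with the standard genetic code. Stop gain
and loss count as nonsynonymous — the published partition is binary.
Transcripts whose CDS length is not a multiple of 3, or whose first CDS
segment has non-zero phase, are retained but flagged incomplete, and their
CDS SNPs are reported `cds_unclassified` rather than silently dropped,
which would bias the partition percentages. Codons containing N are
likewise unclassified. Splice sites are not a separate category (the
published tables have none); such positions fall to intron or CDS by
coordinate.

The test suite checks the single-codon path against an independent oracle
that rebuilds and translates the *entire* mutant protein for random
multi-exon transcripts on both strands.

# Outlier genes

Per gene, the statistic is nonsynonymous SNPs per kb of the gene's CDS
union (bases shared between overlapping transcripts counted once; the full
gene span is available as an alternative denominator). The cutoff is the
classic box-and-whisker fence: with Tukey hinges — the median of the
lower/upper half of the sorted data, halves including the overall median
when n is odd — the fence is $Q_3 + 1.5\,\mathrm{IQR}$, and outliers lie
**strictly above** it (the fence itself is the whisker end, not an
outlier). The cutoff is one-sided; depleted genes are never flagged. Tukey
hinges were chosen over interpolated quantiles because the method is
defined by the boxplot; the hinge rule matches `stats::fivenum()`, which
the tests use as a cross-check.

# Sample correlation and clustering

The windowed SNP counts of all samples on the shared grid form a windows ×
samples matrix; sample relatedness is Pearson's r between columns, computed
genome-wide over the concatenated windows (per-chromosome matrices are also
emitted, since published figures are sometimes drawn per chromosome). Raw
counts are correlated by default; `log1p` is available as an option.
Windows that are empty in every sample are retained — a shared desert is
signal. Samples are clustered on the distance $d = 1 - r$ with average
linkage (UPGMA) by default (no linkage is standard in this literature;
single and complete are options), after lexicographic ordering of sample
names so exact ties resolve deterministically. The tree exports to Newick
via `ape`.

# The synthetic-data generator

The simulator emulates the statistical structure such a study assumes, and
records ground truth for every planted feature:

* **Two groups with a ~2.5× density contrast**: defaults 7.7 vs 3.0
  SNPs/kb, the approximate *indica*/*japonica* contrast.
* **Within-group sharing**: 80% of each sample's variant rate comes from a
  group-shared pool, regenerated deterministically from the master seed so
  all group members inherit identical shared variants.
* **Group-level rate landscape**: each group gets its own mean-one
  log-normal rate multiplier per 100-kb block (sd 0.6 on the log scale).
  This is what makes the correlation structure realistic: samples of one
  group share a landscape (r near 1) while the two groups' landscapes are
  independent (r near 0). Without it, the only shared spatial structure
  would be the planted desert and between-group correlations would be
  spuriously high.
* **Transition bias**: alternate alleles are transitions with probability
  0.70, giving an expected Ts/Tv of 7/3 ≈ 2.33, inside the 2.2–2.4 range
  of real rice panels.
* **InDels**: rate 1/kb, geometric lengths (p = 0.55, so ~55%
  mononucleotide), deletions slightly favoured (p = 0.55).
* **Planted deserts and hot genes**: desert intervals override the local
  rate with `base_rate × multiplier` (default 0.05 → ~0.4 SNPs/kb in the
  high group, well under the 1/kb threshold); hot-gene CDS intervals
  likewise override at `hot_multiplier` (default 5). Overrides — desert
  winning over hot winning over profile — rather than stacked multipliers
  ensure the ground-truth labels correspond to realized effects: with
  stacking, a "hot" gene inside a low-rate block (or a desert) could
  realize a below-background rate and the truth label would be false. For
  the same reason hot genes are never drawn from inside planted deserts.
* **Gene models**: non-overlapping genes on alternating strands with fixed
  architecture (60 bp UTR5, 900 bp CDS split over three exons by 150 bp
  introns, 90 bp UTR3); every CDS starts ATG, ends with a stop, contains
  no internal stop. Genomic placement is uniform with random gaps.
* **Quality fields**: drawn to pass the default thresholds, with a 5%
  slice deliberately broken on one random criterion so the filter report
  is exercised end to end. Frequencies are written in VarScan's percent
  dialect to exercise the parser.

Determinism: every stage derives its own RNG substream from
`(master seed, label)` — reference, hot-gene choice, per-group shared
pools, per-sample private pools, per-sample quality fields — so the same
seed reproduces byte-identical FASTA/GFF3/VCF output, and per-sample
streams are independent of sample order.

Ground-truth category labels are computed from the simulator's own
transcription-order bookkeeping (segment tables and the stored mRNA coding
sequence), a different code path from the annotator's genome-sequence
extraction, and the tests require per-(variant, gene) agreement ≥ 99%.

What the simulator does *not* model: linkage disequilibrium and haplotype
structure, sequencing-error profiles, reference bias, non-uniform base
composition, transposable elements, organellar genomes, and overlapping
gene models. Passing recovery tests therefore demonstrate that the
pipeline's statistics recover planted structure under the stated sampling
assumptions — not that they are robust to every artefact of real
resequencing data.

# Problem sizes and numerical choices

The default simulation is 2 chromosomes × 2 Mb with 250 genes each, five
samples in a 3 + 2 group design — large enough that windowed statistics
(20 windows per chromosome), the Tukey fence (500 genes) and the
correlation matrix are all well-populated, while a full dataset simulates
in under a minute. The test suite uses a 1 Mb single-chromosome version for
speed; group-bipartition replication uses 50 variant-draw seeds on one
fixed gene-free reference, since only the variant draws, not the sequence,
matter for windowed correlations. Where a sampling distribution is checked
(Poisson totals, transition fraction, mononucleotide fraction), tolerances
are three standard errors of the estimator at the realized n.

Known limitations: the reader trusts GFF3 `Parent` attributes (no
inference of missing links); InDel normalization is prefix-based only (no
left-alignment); the annotator selects no canonical transcript (all
transcripts of a gene compete by severity); and percentages in exports are
rounded half-up, which can differ from banker's rounding in the last digit.
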