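---
title: "Detecting RNA degradation bias in poly(A)-selected RNA-seq"
author: "dryqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting RNA degradation bias in poly(A)-selected RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Poly(A)-selected RNA-seq libraries are built by capturing transcripts
through their poly(A) tail. When RNA degrades by strand cleavage, the 5'
fragment loses its connection to the tail and is washed away during
capture, so sequencing reads drain from the 5' end of the gene body: a
classic 3' bias. A second decay route removes whole molecules (for
example ARE-mediated deadenylation followed by exonucleolytic decay),
which lowers a gene's abundance without distorting its coverage profile.
Distinguishing these two signatures — *positional* 5' loss versus
*uniform* downsampling — is the core question this package answers, for
experiments that compare a treatment or storage condition against
matched controls with a handful of replicates per group.

`dryqc` implements the complete analysis around that question: library
QC metrics, per-cycle mismatch profiling, gene-body coverage, library
complexity (cumulative gene diversity), FPKM quantification with the
standard expression and biotype filters, the 40-bin degradation-bias
classifier, transcript-feature and ARE enrichment of affected gene
sets, and efficiency-corrected RT-qPCR integrity ratios. A molecule-level
simulator generates degraded libraries with ground truth so that every
stage is validated end to end at desk scale.

## The classifier

For each gene we build a **meta-transcript**: the union of all annotated
transcripts' exons, merged and laid 5'→3' (for minus-strand genes,
meta-coordinate 0 is the genomic right end). Each assigned read
contributes the meta-position $m$ of its 5' end, binned into 40 bins of
2.5% of the gene length each ($b = \lfloor 40\,m/L \rfloor + 1$). Per
bin, counts are averaged within each group, and the per-bin ratio

$$ r_i = \frac{\bar{c}^{\,\mathrm{treated}}_i}{\bar{c}^{\,\mathrm{control}}_i},
   \qquad i = 1, \dots, 40 $$

is regressed on the bin index by ordinary least squares. The two-sided
t-test of the slope $\beta$ against zero classifies the gene at level
$\alpha = 0.01$:

* $P \ge \alpha$ — **uniform** downsampling (the ratio is flat);
* $P < \alpha,\ \beta > 0$ — **5' underrepresented** in the treated
  group (the ratio rises toward the 3' end, the poly(A)-capture
  signature of cleavage);
* $P < \alpha,\ \beta < 0$ — **3' underrepresented**.

Bins whose control mean is zero are masked rather than pseudocounted:
a pseudocount would pull ratios of low-abundance genes toward zero at
the sparse end and bias the slope. At least 10 usable bins are required;
below that the gene is reported `unclassifiable` instead of being
forced through a meaningless regression. No multiple-testing correction
enters the classification itself (the per-gene $P < 0.01$ convention);
a BH q-value across genes is reported alongside for users who screen
genome-wide.

```{r}
library(dryqc)
fit <- degradation_bias(read_list, groups, metas, models = models)
summary(fit)
plot(fit, gene = "G0001")
```

## Surrounding stages and their conventions

**Coordinates.** Everything internal is 0-based half-open; GTF input and
output are 1-based closed and converted at the boundary.

**Read assignment.** A read belongs to a gene iff any alignment block
overlaps the gene's merged exons; reads touching exons of more than one
gene are discarded as ambiguous and counted. Binning uses only the
read's 5'-end meta-position — a read is never spread across bins —
because the 5' end is the quantity that the capture chemistry acts on,
and point-binning is deterministic and monotone under 5' loss.

**Uniqueness and duplicates.** A record is uniquely mapped if `NH == 1`,
or `MAPQ >= 10` when NH is absent. Duplicate-flagged records (SAM
0x400) are *excluded* from mismatch-rate denominators (a PCR copy is
not an independent observation of the base) but *included* in
duplication-rate numerators and in expression counts (flag-and-count,
not remove); both choices are arguments where a different policy is
needed.

**Library metrics and outliers.** Per-sample deviation from the
cross-sample median, $(x - \tilde{x})/\tilde{x}$, is computed for each
metric; a sample is an outlier iff $|{\rm deviation}| \ge 30\%$ for any
metric. The boundary counts as an outlier ("less than 30%" being the
non-outlier side).

**Mismatch profiling.** Rates are per opportunity: the denominator of
`rate(X>Y, p)` is the number of aligned bases at read cycle `p` whose
*reference* base is X (recovered from MD tags; reverse-strand
alignments are flipped and complemented into cycle space). Group
comparison uses a pooled-variance two-sample t-test per (type, cycle)
cell with BH correction across the whole 12 × read-length family at 5%
FDR. The pooled form is deliberate: groups are libraries of matched
depth, so the binomial sampling variance of a rate is equal across
groups by design, and with three replicates per group the
Welch-Satterthwaite approximation collapses to ~2 degrees of freedom,
bounding attainable P values near $10^{-4}$ — too coarse for a
900-cell BH family regardless of effect size. The pooled test keeps
$n_1 + n_2 - 2$ degrees of freedom; its null calibration is checked by
simulation (below).

**Expression.** Gene-level counts over union exons (no isoform
deconvolution — differential-expression testing is out of scope and
folds are descriptive), FPKM $= c \cdot 10^9 / (L \cdot M)$ with $M$
the sample's reads assigned to any gene. Genes with FPKM below 1 in
every sample are unexpressed (FPKM = 1 is kept); poly(A)-free small-RNA
classes (snRNA, snoRNA, scaRNA, vtRNA, snaR, miRNA) are excluded
regardless of abundance because their capture under poly(A) selection
is ambiguous. Folds are oriented control/treated so genes downsampled
by the treatment exceed 1. Abundance classes: high (>100), moderate
(10–100), low (1–10), extremely low (<1).

**Coverage and diversity.** Gene-body coverage profiles are computed
over genes in the upper middle quartile of read counts — linearly
interpolated percentiles on expressed genes, interval closed at P50 and
open at P75, with the degenerate all-tied case selecting the tied
value. Cumulative gene diversity sorts genes by count (ties broken by
gene id for determinism) and reports the read fraction captured by the
top 10/100/1000/10000 genes.

**Feature enrichment.** Mann-Whitney U compares a gene set against the
full annotated background of the same biotype stratum (background
includes the set, mirroring the all-versus-selected design; a flag
excludes it). The exact distribution is used when $n_1 n_2 \le 400$
without ties, otherwise midranks with tie-corrected variance and
continuity correction. lncRNA strata compare whole-transcript length
and GC; protein-coding strata compare cDNA, CDS, 5'UTR and 3'UTR
lengths and GC. Features are computed on the longest transcript variant
(by exonic length; ties broken by transcript id — the length-vs-CDS
ambiguity for coding genes is resolved in favour of exonic length and
applied uniformly). Absent regions (a transcript without a 3'UTR) are
excluded from that feature's vectors, never scored as 0% GC.

**qPCR.** An assay of efficiency $E$ multiplies template per cycle by
$E$, so quantity $\propto E^{-C_p} = 2^{-C_p \log_2 E}$; the corrected
$C_p' = C_p \log_2 E$ is the unique rescaling that makes the usual
$2^{-\Delta C_p}$ arithmetic exact across assays of different
efficiency. The integrity ratio is $2^{-(C_p'^{3'} - C_p'^{5'})}$ —
equal corrected values give 1 and 5' loss pushes it above 1. Replicates
are averaged on the Cp scale (geometric mean of quantities). The paired
group test degenerates with zero-variance differences; the convention
is P = 1 for a zero mean difference and P = 0 otherwise, flagged.

## The simulator and what it does (and does not) emulate

`sim_config()` / `simulate_experiment()` generate a toy genome (two or
more chromosomes, both strands, multi-exon genes, configurable biotype
mix including the poly(A)-free classes) and molecule-level libraries:

1. per-gene expression $\theta_g$ (log-normal, or equal), molecule
   counts multinomial given $\theta$ at a fixed per-sample depth —
   mirroring the compositional nature of sequencing;
2. uniform decay: each molecule lost with probability $p_g$;
3. cleavage: cut positions as a Poisson process at $\lambda_g$ events
   per kb; only the 3'-terminal fragment (the one carrying the poly(A)
   tail) survives capture — a deliberate simplification of the
   chemistry;
4. a full-length read placed with its 5' end uniform over retained
   positions that admit it; molecules whose retained segment is shorter
   than the read are dropped and counted;
5. a configurable fraction of emitted records resampled as duplicates
   (flag 0x400), because the pipeline consumes duplicate flags rather
   than re-deriving them;
6. substitution errors drawn per (reference base, cycle) from a
   12 × read-length rate table, with optional group-specific excesses.

Reads map back through the meta-transcript to genomic coordinates
(split over junctions), and the SAM carries NH/NM/MD tags whose
byte-level agreement with `samtools calmd` is asserted in the tests.
Poly(A)-free biotypes are transcribed but not captured, matching their
exclusion from quantification; a switch captures them for filter tests.

Not emulated: base-quality variation (all bases maximal quality),
indels, paired-end reads, multi-mappers, isoform switching, GC-coverage
bias, and overlapping genes. Passing simulations therefore validate the
*arithmetic and inference* of the pipeline — coordinate maps, counting
rules, the ratio regression, FDR control — under a known generative
model, not the behaviour of any particular aligner or chemistry on real
tissue.

An important compositional consequence shows up in the fold checks:
with a fixed per-sample depth, decaying a set of genes with probability
$p$ yields an expected control/treated FPKM fold of $2 - D/T$ (where
$D/T$ is the decayed share of library mass), *not* $1/(1-p)$ — if every
gene decays equally, folds return to 1. The fold-recovery study design
(50 decayed + 50 stable genes of equal expression, $p = 0.5$, expected
fold 1.5) was chosen with this arithmetic in mind.

## Validation suite and problem sizes

`validate_pipeline()` (and `scripts/acceptance.R`) run the full honest
path — simulate, write SAM, parse, analyse — at these sizes, chosen to
keep the whole suite in the minutes range on a single core while the
stochastic bounds stay tight:

* **Type-I error**: 400 genes, 3 + 3 samples, no degradation, ~100
  reads/gene/sample; the non-uniform fraction at $\alpha = 0.01$ must
  sit in the 95% binomial band [0.002, 0.025].
* **Power**: 100 genes with one expected cut per treated molecule
  ($\lambda L = 1$), ~200 reads/gene/sample; ≥80% must be called
  5'-underrepresented, with 3' calls at most at the false-positive
  rate.
* **Fold recovery**: the decay design above; median fold in
  [1.35, 1.65] and ≤10% of decayed genes flagged non-uniform.
* **Coverage flatness**: one library of 450k reads over 120 genes of
  ~30 kb; every bin fraction in [0.020, 0.030]. The 30 kb length is
  derived from the closed form for the last bin,
  $(L/40 - \ell)/(L - \ell)$ at read length $\ell = 75$: 5'-end binning
  cannot place reads in the final read-length of the transcript, so the
  bound demands $L \gtrsim 15$ kb; 30 kb leaves >5 SE of margin.
* **Mismatch recovery**: +0.02 C>T at cycles 1–10 in one group of
  three 100k-read libraries; ≥8/10 cells significant at 5% BH FDR.
  Null calibration runs 100 repetitions of the comparison on
  binomial-sampled rate profiles at matched depth (the SAM layer adds
  nothing to the null of the *test*, and simulating 600 full libraries
  would be wasteful); at most ~10 repetitions may show any significant
  cell.
* **Exact oracles**: cumulative diversity against an independent
  sort-and-sum implementation on 1000 random tables; exact Mann-Whitney
  against full enumeration for all group sizes with $n_1 + n_2 \le 10$;
  qPCR closed forms to $10^{-9}$.
* **Determinism**: the full pipeline run twice on a fixed-seed fixture
  must produce byte-identical outputs; all randomness flows from one
  master seed through fixed per-sample derivations.

## Known limitations

* The ratio regression assumes homoscedastic errors across bins; ratio
  variance grows where control counts are low. Masking zero bins
  removes the worst cases but low-abundance genes remain noisy — the
  `unclassifiable` path and the reported q-values are the guard rails.
* The classifier models a *linear* ratio trend; segmented or localized
  degradation would dilute into the slope.
* FPKM folds are compositional (see above); they are descriptive, not
  a substitute for a differential-expression model.
* Five-prime loss is inferred through the poly(A)-capture mechanism;
  for ribo-depleted libraries the directional interpretation does not
  transfer.
* `read_sam()` handles substitution-only alignments (CIGAR M/=/X/N/S);
  indel-containing records are rejected rather than mis-profiled.
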