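# dryqc — degradation-aware QC for poly(A)-selected RNA-seq

`dryqc` is an R package for bioinformaticians who need to answer a
specific question about a poly(A)-selected, single-end RNA-seq
experiment: *did a treatment or storage condition degrade the RNA, and
if so, by which mechanism?* Under poly(A) capture, strand cleavage
washes the 5' fragment off the beads, draining reads from the gene's 5'
end, while whole-molecule decay lowers abundance without touching the
coverage profile. The package separates these signatures and wraps them
in the full QC battery such comparisons need.

## What it computes

* **Library metrics** — uniquely-mapped fraction, duplication rate
  (SAM 0x400), per-read GC histogram, chromosome and RNA-biotype read
  distributions, detected genes, and the 30%-deviation-from-median
  outlier rule.
* **Mismatch profiles** — per substitution type and read cycle, counts
  over base-specific opportunities (from MD tags), compared between
  groups with a pooled t-test and Benjamini–Hochberg control at 5% FDR
  over the 12 × read-length family.
* **Gene-body coverage** — read 5'-end positions on strand-aware
  meta-transcripts (union of exons), 40 bins of 2.5% of gene length,
  restricted to upper-middle-quartile genes.
* **Cumulative gene diversity** — read fraction captured by the top
  10/100/1000/10000 genes.
* **Expression** — union-exon counts, FPKM = c·10⁹/(L·M), the
  "FPKM ≥ 1 in at least one sample" filter, exclusion of poly(A)-free
  small RNAs, control/treated folds and log₂ group-mean R².
* **Degradation-bias classifier** — the core method. Per gene, the
  bin-to-bin ratio of treated to control mean counts is regressed on
  bin index; the slope's t-test at α = 0.01 classifies the gene as
  `uniform`, `five_prime_underrepresented` (slope > 0: ratio rises
  toward 3') or `three_prime_underrepresented` (slope < 0).
* **Enrichment** — Mann–Whitney comparison of transcript features
  (lengths, GC of transcript/cDNA/CDS/UTRs) between a gene set and the
  annotation background, and the ARE/bias overlap partition.
* **qPCR** — efficiency-corrected Cp (Cp′ = Cp·log₂E), the 3'/5'
  integrity ratio 2^−(Cp′₃−Cp′₅), ΔCp expression normalized to a
  reference gene, paired t-tests.
* **Simulator** — molecule-level degraded libraries (uniform decay
  p, Poisson cleavage λ per kb with 3'-fragment capture, PCR
  duplicates, positional substitution errors) emitted as SAM + GTF +
  FASTA + ground-truth tables, deterministic per seed.

## Worked example

Simulate a paired experiment (3 control vs 3 treated replicates; every
treated molecule carries one expected cleavage event and 10% uniform
decay), then run the whole pipeline:

```r
library(dryqc)

cfg <- sim_config(
  seed = 1, n_genes = 60, depth = 30000,
  groups = list(
    control = list(n = 3, p = 0,   lambda = 0),
    treated = list(n = 3, p = 0.1, expected_cuts = 1)
  )
)
exp <- simulate_experiment(cfg, "example_run/sim")

report <- run_pipeline(run_config(
  sam    = setNames(exp$manifest$sam, exp$manifest$sample_id),
  groups = setNames(exp$manifest$group, exp$manifest$sample_id),
  gtf    = exp$annotation$gtf,
  fasta  = exp$annotation$fasta,
  outdir = "example_run/out"
))
report
#> dryqc_report: 6 samples, 60 genes (55 expressed)
#>   R^2(log2 group means) = 0.9936
#> bias_scan: 55 genes, treated vs control, alpha = 0.01
#>   uniform 0 | 5' under 55 | 3' under 0 | unclassifiable 0
```

Expression is essentially unperturbed (R² = 0.99 — uniform decay of
*all* genes renormalizes away at fixed depth), yet the classifier flags
every expressed gene as 5'-underrepresented, exactly the cleavage
signature that abundance comparisons miss. Per-gene detail:

```r
head(report$bias$results[report$bias$results$class != "uniform", 1:5])
#>   gene_id n_usable      slope    intercept      p_value
#> 1   G0001       39 0.05698621 -0.111682446 3.114705e-09
#> 2   G0003       40 0.11150311 -0.781638597 7.318898e-04
#> 3   G0005       40 0.07961931 -0.473269587 2.825971e-08
```

A positive slope of ~0.06 per bin means the treated/control read ratio
roughly doubles from the 5' to the 3' end of these genes.
`plot(report$bias, gene = "G0001")` draws the per-bin group means and
the fitted ratio regression for one gene. All stage tables (metrics,
mismatch comparison, coverage, diversity, counts/FPKM, bias,
features) are written under `example_run/out/`.

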