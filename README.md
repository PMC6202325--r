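# fusionframe

Reading-frame annotation of gene fusions and cohort statistics for diffuse
gastric cancer (DGC).

## What this package is for

Recurrent chimeric transcripts — above all fusions whose 3′ partner
contributes a RhoGAP domain (e.g. *CLDN18–ARHGAP26*, *ANXA2–MYO9A*) or a
PAP2 domain (*TACC2–PPAPDC1A*) — define an aggressive molecular subset of
DGC. Deciding whether a caller-reported breakpoint pair actually produces
a translatable fusion protein, and what that protein retains, is the core
analytical step between raw fusion calls and any clinical statement.

`fusionframe` implements that step and the cohort layer around it:

* **Breakpoint resolution** — genomic (DNA-level) breakpoints are mapped
  through the transcript model: intronic breakpoints are spliced to the
  flanking exon boundary, exonic breakpoints are kept as cryptic
  junctions. All arithmetic is done in transcript coordinates (1-based;
  position 1 is the first transcribed base, also on the minus strand).
* **Frame classification** — with `n5` retained 5′-partner coding bases
  and the first retained base at offset `d3` of the 3′ CDS, the chimera is
  in frame iff

      n5 ≡ d3 − 1  (mod 3)

  with explicit classes for promoter swaps (intact 3′ ORF behind the 5′
  promoter), junction-codon stops, frameshifts and non-coding outcomes.
  Every call is cross-checked by brute-force translation of the fused
  cDNA (the protein must terminate exactly at the native 3′ stop and
  reproduce the native 3′ protein suffix).
* **Domain retention** — retained amino-acid spans
  (`[1, floor(n5/3)]` and `[ceil((d3+2)/3), protein length]`) are
  intersected with a protein-domain table; a domain counts as retained
  only when fully contained, and RhoGAP-/PAP2-retaining fusions get class
  labels.
* **Expression imbalance** — exon-level FPKM is log2-transformed and
  gene-centred; the breakpoint score contrasts mean centred expression of
  exons at/after the first retained exon against upstream exons, and is
  standardised against the same statistic in all other samples.
* **Cohort statistics** — prevalence (half-up percent rounding),
  recurrence (≥ 2 distinct samples), mutual-exclusivity 2×2 tests
  (uncorrected Pearson chi-square and Fisher's exact), Wilcoxon rank-sum.
* **Survival** — Kaplan–Meier with log–log confidence bands, the
  Mantel–Haenszel log-rank test, Cox proportional-hazards regression by
  Newton–Raphson with Efron (default) or Breslow tie handling, and the
  Schoenfeld required-events formula
  `d = (z₁₋α/₂ + z₁₋β)² / (p(1−p)·ln²HR)`.
* **Synthetic data** — a seeded generator for genomes, gene models,
  domain tables, fusion candidates with known truth labels, exon
  expression matrices and survival cohorts, so every stage is testable
  without patient-level data.

## Worked example

```r
library(fusionframe)

cfg <- sim_config(seed = 7)            # 384 samples, 13/2/2 fusion carriers
out <- simulate_dataset(cfg, "demo")   # writes FASTA/GTF/TSV inputs
rep <- run_pipeline(list(
  genome = out$paths$genome, gtf = out$paths$gtf,
  domains = out$paths$domains, candidates = out$paths$candidates,
  exon_matrix = out$paths$exon_matrix, cohort = out$paths$cohort,
  outdir = "demo/report", log_level = "quiet"))

head(rep$annotations[, c("gene5", "gene3", "frame_status",
                         "aa5_span", "aa3_span", "class_labels")], 3)
#>   gene5 gene3 frame_status aa5_span aa3_span         class_labels
#> 1   G01   G02     IN_FRAME    1-197    9-335 RhoGAP-domain fusion
#> 2   G01   G02     IN_FRAME    1-197    9-335 RhoGAP-domain fusion
#> 3   G01   G02     IN_FRAME    1-197    9-335 RhoGAP-domain fusion

rep$prevalence
#> $count: 17   $n: 384   $percent: 4.4

rep$recurrent
#> [1] "G01-G02" "G03-G02" "G05-G06"

rep$cox_univariate
#> <cox_fit> n = 384, events = 232, ties = efron, iter = 6
#>          coef     HR lower95 upper95      p
#> fusion 0.8222 2.2755  1.3432  3.8551 0.0022

required_events(0.05, 0.8, p = 0.15, hr = 2)
#> [1] 128
```

The 17 carriers among 384 samples give the 4.4% prevalence; the three
planted fusions are recovered as recurrent; the univariate Cox fit
estimates the carrier hazard ratio (planted at 2.8 in this one noisy
replicate) with its Wald 95% CI; and the design arithmetic returns the
number of deaths a log-rank comparison needs at a 15% exposure prevalence
and a target hazard ratio of 2.

A report bundle (annotation TSV, fusion events, expression-imbalance
table, KM curve points, JSON summary) is written to `demo/report/`.

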