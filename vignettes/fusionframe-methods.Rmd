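---
title: "Fusion reading-frame annotation and cohort statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusion reading-frame annotation and cohort statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionframe)
```

This vignette is the package's account of its models and the design
choices behind them: what is computed, under which conventions, why the
defaults are what they are, and what the synthetic-data tests do and do
not demonstrate about real tumor data.

## Coordinate conventions

All genomic coordinates are 1-based and inclusive (the `g.chr3:137,749,947`
style used in clinical fusion reports). Transcript coordinate 1 is the
first transcribed base; on minus-strand transcripts that is the
genomically 3′-most base, and all breakpoint arithmetic is done after
mapping into transcript coordinates, so strand never appears in the frame
logic itself. Introns are numbered in transcript orientation: intron *i*
follows exon *i*.

Two conventions deserve emphasis because published fusion tables are
silent on both:

* **Breakpoint semantics.** The 5′-gene coordinate is the *last retained
  transcribed base*; the 3′-gene coordinate is the *first retained base*.
  This matches the one-coordinate-per-gene layout of fusion validation
  tables.
* **CDS span.** `cds_start`–`cds_end` *includes the stop codon*. With
  this choice a junction at/after `cds_end5` provably retains an intact
  5′ terminator (translation can never read across), and a 3′ breakpoint
  inside the last three coding bases provably destroys the native
  terminator; both become clean `NON_CODING` classifications instead of
  edge cases. Published "coding sequence 1–750"-style counts do not
  disambiguate this; the choice is internal and consistent.

When per-gene isoform choice is unspecified (as in most fusion reports),
the canonical transcript is the one with the longest CDS, ties broken by
smallest transcript id; an explicit transcript id always overrides.

## From DNA breakpoint to frame call

A DNA-level rearrangement breakpoint in an intron is spliced out of the
mature chimeric transcript; the observed mRNA breakpoint is the flanking
exon boundary (last base of the preceding exon for the 5′ partner, first
base of the following exon for the 3′ partner). Exonic DNA breakpoints
are kept as-is: they model cryptic splice junctions such as the
well-known donor inside *CLDN18* exon 5. `infer_mrna_breakpoint()` is
idempotent on exonic input, so mRNA-level candidate tables pass through
unchanged.

With `t5`, `t3` the breakpoint transcript coordinates, `n5 = t5 −
cds_start5 + 1` retained 5′ coding bases and `d3 = t3 − cds_start3 + 1`
the entry offset into the 3′ CDS, the classification is:

| condition | call |
|---|---|
| `t5 < cds_start5`, 3′ CDS fully retained | `PROMOTER_SWAP` |
| `t5 < cds_start5`, 3′ CDS truncated | `NON_CODING` |
| `t5 ≥ cds_end5` or `t3 > cds_end3 − 2` | `NON_CODING` |
| phases differ (`n5 ≢ d3 − 1 mod 3`) | `FRAMESHIFT` |
| phases agree, stop codon at the junction | `JUNCTION_STOP` |
| phases agree, no junction stop | `IN_FRAME` |

Two refinements make this rule *exactly* equivalent to translating the
fused cDNA, not just approximately:

1. **Hybrid junction codon.** When `n5 mod 3 = r > 0`, one codon takes
   `r` bases from the 5′ partner and `3 − r` from the 3′ partner. It is
   translated and reported separately (it belongs to neither native
   protein); if it happens to be a stop, the call is `JUNCTION_STOP` — a
   phase-congruent but untranslatable chimera, deliberately kept distinct
   from `FRAMESHIFT` because the phase information is real.
2. **Read-through spacer.** If the 3′ breakpoint lies upstream of the 3′
   CDS while the 5′ junction is coding, the retained stretch of 3′
   5′-UTR is read through before the native start codon. The phase rule
   extends across the spacer (`n5 + u ≡ 0 mod 3` with `u` spacer bases)
   and the spacer codons are scanned for stops.

Every `annotate_candidate()` call cross-checks the arithmetic against a
string-level oracle: translate the fused cDNA from the retained start and
require termination exactly at the native 3′ stop plus exact recovery of
the native 3′ protein suffix. Disagreement raises an internal error
rather than emitting a label. The test suite replicates this oracle
independently (via `Biostrings::translate`) and confirms 100% agreement
over 1,000 unconstrained random breakpoint pairs, which cover all five
classes including UTR junctions and stop-codon-spanning breakpoints.

Retained spans are `[1, floor(n5/3)]` and `[ceil((d3+2)/3), L3]`
(first *complete* native 3′ codon; the hybrid residue is counted in
neither). A protein domain is *retained* only when its full interval lies
inside the retained span — partial overlap is reported as truncated,
never as retained, because a clipped RhoGAP or PAP2 domain cannot be
assumed functional. Class labels (`RhoGAP-domain fusion`,
`PAP2-domain fusion`) follow retained domains on either side.

## Candidate intake

Fusion callers report breakpoints with a few bases of jitter, so fusions
are identified at the (sample, ordered gene pair) level; distinct
breakpoints for one pair are isoforms of one fusion event, which is also
the unit for recurrence counting. The support filter keeps candidates
with **strictly more than 3** junction-spanning reads (configurable).
Multi-caller consensus matches on the same key, with union (support
count annotated) and intersection (≥ 2 callers) modes, because published
pipelines rarely state their exact combination rule. Read-through
candidates (same contig, 5′ upstream of 3′, within 100 kb by default)
are flagged but never dropped automatically: no published distance rule
exists, so silent removal would be worse than annotation.

## Expression imbalance

A fusion that places 3′-partner exons behind an active promoter
overexpresses exactly the exons at and downstream of the breakpoint.
FPKM is transformed as `log2(x + 1)` before per-exon gene centering —
published exon heatmaps are plainly log-scaled and FPKM spans orders of
magnitude; a flag allows linear centering for comparison. The imbalance
score for sample *s* at breakpoint exon *k* is

```
score(s) = mean(centred, exons ≥ k, s) − mean(centred, exons < k, s)
```

standardised by the mean and SD of the same statistic in all other
samples; `z` is reported as `NA` when the null SD is zero. Under a pure
null this leave-one-out z is close to standard normal: the test suite
verifies a ≈ 5% exceedance rate at |z| > 1.96 over 1,000 null samples
and that power is monotone in the planted effect (0–3 log2-units).
Outlier ranking (1 = highest, dense ranks, ties share the better rank)
uses exon-length-weighted mean FPKM when no gene-level matrix is given.

Note that with *m* carriers of the same fusion, gene centering absorbs
part of the planted signal and carriers enter each other's null; both
effects are negligible at the 3–4% carrier prevalence this package
targets, but they mean "rank 1 for the carrier" is only a meaningful
expectation in the single-carrier (discovery-outlier) geometry, which is
what the acceptance tests use.

## Cohort statistics

Prevalence percentages are rounded **half-up** to one decimal (4.35 →
4.4, matching clinical-report style). The 2×2 association test is the
**uncorrected** Pearson chi-square — verified by hand computation to
reproduce the published exclusivity P values, which the Yates-corrected
variant does not — with the corrected variant behind a flag and Fisher's
exact test (hypergeometric, two-sided by the minimum-likelihood rule)
alongside. The Wilcoxon rank-sum test uses the exact distribution for
untied samples below 50 per group and a tie-corrected normal
approximation otherwise. Molecular flags are missing outside the
sequenced subset of a cohort and are excluded test-wise, so each 2×2 is
built over the samples actually assayed for that flag.

## Survival

Kaplan–Meier estimation uses Greenwood variance with log–log (complementary
log-log) 95% bands; the median is the earliest time with S(t) ≤ 0.5 and
its confidence limits are the earliest times at which each band crosses
0.5, reported as "not reached" (`NA`) when a bound never crosses — the
standard Brookmeyer–Crowley-style construction. The log-rank test is the
Mantel–Haenszel form (U²/V over event times with hypergeometric
variances).

Cox regression maximises the partial likelihood by Newton–Raphson with
step-halving, declaring convergence when the largest score component
falls below 1e-8 (at most 50 iterations). **Efron tie handling is the
default**: survival recorded in months ties heavily, and Efron's
approximation is less biased than Breslow's there; Breslow is available
by flag. Wald CIs and p-values are reported per covariate
(`exp(β ± 1.96·SE)`), plus the likelihood-ratio statistic for the model.
Monotone likelihood (perfect separation) is detected by coefficient
divergence and flagged with a warning instead of failing. The test suite
checks coefficients, standard errors and log-likelihoods against the
`survival` package to 1e-6 under both tie methods, the log-rank/Cox
score-test identity on tie-free data, and shrinking bias with ~95% CI
coverage as n grows (150 vs 1,200).

The design calculation is Schoenfeld's: required events
`d = (z₁₋α/₂ + z₁₋β)² / (p(1−p)·ln²HR)`, rounded to the nearest integer
(α = 0.05 two-sided, power 0.8, p = 0.15, HR = 2 gives 128), and cohort
size `ceil(d / event rate)` (a one-third event rate gives 384).

## The synthetic-data generator

The generator's defaults *are* the study conditions the package targets:
384 samples; three in-frame fusions carried by 13, 2 and 2 disjoint
samples; CDH1/RHOA mutation flags at 31%/15% among fusion-negative
samples, mutually exclusive with carriers when the exclusivity switch is
on, observed in a sequenced subset of 229; a +3 log2-unit expression
effect on 3′-of-breakpoint exons of carriers (exon noise SD 0.5);
exponential survival with a 94.6-month baseline median and a carrier
hazard ratio of 2.8; administrative censoring at 120 months plus a 20%
uniform-dropout fraction (≈ 50–60% of patients reach an event — no
censoring distribution is ever published, so this is a stated modeling
choice); carrier ages biased younger (mean 45 vs 58) to emulate
early-onset enrichment.

Genes (`G01`, `G02`, …) are non-overlapping, multi-exon, on both strands,
with ATG/stop-delimited CDSs free of internal stops; one gene carries a
C-terminal `RhoGAP` domain and one a `PAP2` domain so 3′-retaining
fusions keep them. Fusion breakpoints are *chosen to realise the
requested truth label* (in-frame / frameshift / promoter-swap, intronic
or exonic) and verified through `classify_frame()` at generation time;
decoy candidates get ≤ 3 spanning reads so the intake filter removes
them. A single master seed drives everything, with fixed per-stage
offsets (reference +0, fusions +1, expression +2, cohort +3) so stages
re-run independently yet reproducibly, byte-identical at equal seed.

What passing tests on these data show — and what they do not: the
generator exercises coordinate arithmetic, frame logic, domain
containment, planted-signal recovery and estimator calibration under a
correctly-specified model. It does not emulate read-level noise,
alignment artefacts, caller-specific breakpoint jitter, isoform
switching, non-exponential hazards or informative censoring; agreement
on synthetic data is therefore evidence of implementation correctness,
not of robustness to every failure mode of real RNA-seq.

## Numerical and degenerate-input choices

* Chi-square on a table with a zero marginal is an error (the statistic
  is undefined), while Fisher's test returns p = 1 there.
* An all-equal expression matrix yields score 0 with null SD 0 and a
  `NA` z, never a division by zero; a breakpoint at exon 1 (no upstream
  side) is rejected.
* `km_estimate` on fully censored data returns S ≡ 1 with "not reached"
  medians.
* Cox rejects constant covariates (non-identifiable) and missing values
  (listwise deletion is the caller's responsibility and is applied by
  the pipeline for the multivariable model, mirroring analyses restricted
  to the subset with complete molecular annotation).
* Ties in outlier ranking share the better rank (dense ranking), so an
  all-tied cohort ranks everyone first.

## Problem sizes used by the checks

The routine test suite and the acceptance analyses run at the geometry
described above: 1,000 random breakpoint pairs for the frame oracle;
200 replicate cohorts (n = 384, 17 exposed) for Cox parameter recovery;
500 null cohorts (n = 200) for log-rank calibration; 200 replicate
expression matrices (n = 80, single carrier) plus a 500-sample null
matrix for imbalance detection and calibration; eight seeded end-to-end
pipeline runs at n = 96. These sizes were chosen to keep Monte-Carlo
error well inside the asserted tolerances.

## Known limitations

* One canonical transcript per gene anchors all numbering; real isoform
  diversity (e.g. aa spans that only match a specific long isoform) is
  out of scope.
* No reciprocal-fusion handling, splice-motif scoring of cryptic sites,
  or read-level evidence re-evaluation; caller output is trusted after
  the spanning-read filter.
* The Cox layer has no time-varying covariates, stratification,
  competing risks or proportionality diagnostics.
* Percent values are reported as computed; where a published frequency
  is internally inconsistent with its own counts (e.g. a 2-in-384 fusion
  described as 0.1%), the computed value (0.5%) is reported and the
  discrepancy is left to the reader.
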