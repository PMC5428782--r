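---
title: "Somatic variant triage, genomic subtyping and sensitivity modelling for a targeted melanoma panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic variant triage, genomic subtyping and sensitivity modelling for a targeted melanoma panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melpanel)
```

## Scope

`melpanel` reconstructs, as reusable and tested code, the analysis layer of a
clinical targeted-amplicon sequencing workflow for primary melanoma: a
35-gene AmpliSeq-style panel sequenced to deep coverage on FFPE tumour
samples, followed by somatic-variant triage, TCGA-style genomic subtyping,
clinicopathological association statistics, coverage quality control, and a
dilution-series sensitivity model. Everything upstream of the annotated
variant table — base calling, alignment, the variant caller itself, and the
in-silico predictors whose verdicts are consumed as inputs — is out of
scope. Because per-sample raw data of the kind this pipeline consumes are
generally not publishable, the package ships a synthetic-cohort generator
that emulates the statistical structure of such a study, so that every stage
is exercised end-to-end by code alone.

## The triage cascade

An annotated variant record carries its locus, protein change, region class
(exonic / intronic / UTR / promoter), consequence, read support
(`total_depth`, `variant_reads`, `allele_frequency`), the caller's
per-variant p-value, five in-silico pathogenicity verdicts (Provean, SIFT,
PolyPhen-2, SNPS&GO, Condel — each benign / damaging / unknown), and two
database flags (COSMIC-recurrent, dbSNP-germline). Triage proceeds in four
stages, each with an audited count:

1. **Region/consequence** — non-exonic and synonymous calls are dropped.
   TERT promoter variants (named by offset from the ATG, e.g. `-146C>T`)
   bypass this filter: they are real drivers that no protein-level filter
   can judge, and are carried as a separate annotation on the result.
2. **Read support** — retain calls with total depth ≥ 500 reads, variant
   reads ≥ 20 and caller p-value < 0.01 (boundary semantics exactly ≥, ≥,
   strict <). The caller p-value is stored, never recomputed: its
   definition belongs to the upstream caller.
3. **Pathogenicity consensus** — a call is excluded when at least 3 of the
   5 predictors explicitly vote *benign*. `unknown` never counts as benign,
   because the rule is about explicit benign predictions. COSMIC-recurrent
   hotspots bypass the vote (recurrence screening precedes
   variant-of-unknown-significance assessment), as do records the database
   screen will classify as germline polymorphisms — the vote applies to
   variants of unknown significance only.
4. **Germline partition** — calls whose (gene, protein change) is in the
   polymorphism catalog (MC1R red-hair-colour alleles, CDK4 R24/L22, MITF
   E318K; user-extensible) or that are dbSNP-flagged without being
   COSMIC-recurrent are reported separately as polymorphisms, never as
   somatic mutations — even when predictors call them damaging.

The three buckets (pathogenic somatic, polymorphisms, rejected-with-stage)
always partition the input, the cascade is idempotent on its own pathogenic
output, and a single-pass boolean predicate over each variant reproduces the
staged result — all three are enforced as property tests.

```{r triage-example}
v <- rbind(
  annotated_variant(gene = "BRAF", protein_change = "p.V600E",
                    cosmic_recurrent = TRUE),
  annotated_variant(gene = "MC1R", protein_change = "p.V60L",
                    dbsnp_germline = TRUE),
  annotated_variant(gene = "PTEN", consequence = "synonymous",
                    protein_change = "p.T100T"),
  annotated_variant(gene = "NF1", protein_change = "p.R1362*",
                    consequence = "nonsense", total_depth = 400L,
                    variant_reads = 40L, allele_frequency = 0.1))
triage_sample("S1", v)
```

## Genomic subtyping

Samples are assigned to the four TCGA cutaneous-melanoma classes from their
pathogenic somatic variants. Defaults, and why:

* **BRAF** — the named hotspot changes (V600E/K/R/D, K601E, L597R/S) plus
  any non-synonymous change at codons 600/601/597. Non-hotspot BRAF changes
  (e.g. G464R) count only under an explicit any-nonsynonymous flag, because
  the mutual-exclusivity structure of melanoma cohorts is a statement about
  hotspots.
* **RAS** (NRAS/KRAS/HRAS) — any non-synonymous change by default. This
  covers the canonical codon 12/13/61 hotspots and the rarer activating
  alleles (A146, E62) that co-occur with them in real samples.
* **NF1** — loss-of-function consequence (nonsense/frameshift) by default,
  since nonsense alleles dominate NF1-driven melanoma; missense acceptance
  is a flag.
* **Precedence** BRAF > RAS > NF1: samples carrying NF1 alongside a BRAF or
  RAS driver are classed by the oncogene, which is how concurrent-mutation
  samples are handled in practice; every additional qualifying class is
  recorded as a concurrent flag rather than discarded. A `strict` mode
  returns `ambiguous` instead of resolving by precedence.
* No qualifying driver — `triple_wt` (KIT, PTEN and TERT promoter mutations
  do not define a class).

Per-gene prevalence distinguishes *pathogenic* prevalence (post-consensus)
from *any-variation* prevalence (all calls surviving the region and support
stages); genes with many passenger-like variants of unknown significance
(PREX2, GRIN2A) differ substantially between the two definitions.
Co-occurrence between two gene sets is summarized as 2×2 sample counts with
a mutual-exclusivity fraction `1 − both/total`.

## Association statistics

For a binary exposure the package uses the cross-product odds ratio with the
Woolf log-scale standard error,

$$\widehat{OR} = \frac{ad}{bc},\qquad
  SE = \sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d},\qquad
  CI_{95} = \exp(\log\widehat{OR} \pm 1.96\,SE),$$

with a two-sided Wald p-value. When exactly one cell is zero the
Haldane–Anscombe 0.5 correction is applied to all cells and the result is
flagged; a table with both cross products zero has no defined OR and is
reported as such. For an ordered exposure with k levels coded 1..k, the
per-level odds ratio is the exponentiated slope of a univariate logistic
MLE (IRLS via `stats::glm`, log-likelihood tolerance 1e-8, max 100
iterations); zero-event levels are fine as long as other levels anchor the
fit, and complete separation is flagged rather than silently returned. A
brute-force likelihood grid search serves as an independent oracle in the
tests.

```{r assoc-example}
odds_ratio_2x2(4, 22, 1, 73)     # mutation status by ulceration
ordinal_trend_or(c(2, 0, 4, 3), c(47, 21, 19, 13))  # by thickness category
```

The screening battery runs one test per gene × feature pair with the coding
declared per feature (binary or ordinal), reports raw p-values with a 0.05
significance flag — deliberately uncorrected, as in single-study screening —
and appends Benjamini–Hochberg q-values as a clearly separate column. Wald
intervals are approximate: over repeated 2×2 sampling at n = 100 their
coverage sits in the 90–98% band, which the acceptance battery checks by
simulation.

One reproduction caveat is worth stating: published tables that print an OR
next to its own 2×2 counts occasionally disagree with the cross product of
those counts (unstated adjustment or coding upstream). Such rows are not
reproduction targets here; the package reports what the counts imply.

## Sensitivity and limit of detection

A dilution series mixes heterozygous mutant DNA (variant fraction 0.5) into
wild-type DNA at ratios 1:k, giving expected allele fractions
$0.5/(1+k)$ — the default series 1:1, 1:3, 1:24, 1:49, 1:99, 1:999 plus the
undiluted sample spans 50% down to 0.05%. Observed variant reads at a locus
of depth $D$ are modelled as $\mathrm{Binomial}(D,\; f + e)$ where $f$ is
the true fraction and $e$ the background false-read rate folded into a
single additive per-read probability toward the variant allele (strand and
sequence-context effects are out of scope; FFPE deamination artifacts are
assumed removed upstream by UNG treatment).

Detection is a one-sided binomial test against the error null: a point is
detected when its variant reads strictly exceed the $(1-\alpha)$ quantile
of $\mathrm{Binomial}(D, e)$, and the limit of detection is the smallest
expected fraction whose simulated detection frequency reaches the power
target. Defaults $\alpha = 0.01$, power 0.95, 1000 replicates, depth 3000
(the order of real per-point coverages in such assays, ~1900–5000). With a
0.1% error rate this rule puts the LOD at the 0.5% series point: the null
mean is 3 false reads against a threshold of `qbinom(0.99, 3000, 0.001)` =
8, which a 0.5% allele (expected 18 reads) clears with >99% power while a
0.05% allele (expected 4.5 reads) does not. The published account of such
assays states the inputs (0.05% detectable reads, 0.1% false reads) and the
output (0.5% LOD) without the decision rule; the tail-test-with-power rule
used here is this package's formalization, and any detection margin between
roughly 1 and 5 times the error rate would select the same series point.
LOD is monotone — non-increasing in depth, non-decreasing in error rate and
power target — and this is property-tested over a grid.

```{r lod-example}
lod <- estimate_lod(dilution_series(depths = 3000L, error_rate = 0.001),
                    seed = 20170329L)
attr(lod, "detection")
```

## Coverage QC

`coverage_summary()` reports mean amplicon coverage, the percentage of
targeted bases at or above each depth threshold (defaults 100× and 500×),
the on-target read fraction, and uniformity defined as the percentage of
targeted bases with depth ≥ 0.2 × mean — the platform's conventional
definition, stated here explicitly because published uniformity figures
rarely come with a formula. Uniformity is invariant to scaling all depths,
and percent-covered is non-increasing in the threshold; both are tested.
Base-level metrics use a per-base depth vector when one is supplied and
otherwise weight per-amplicon means by amplicon length; with neither, each
amplicon contributes equally, so run-level and cohort-averaged summaries
can both be produced from the same profile.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions the pipeline assumes:

* **Cohort scale** — 100 samples by default; gene prevalences BRAF 0.50,
  NRAS 0.15, PREX2 0.14, GRIN2A 0.13, ERBB4 0.12, PTEN 0.09, NF1 0.08,
  RAC1 0.08, PPP6C 0.06, KIT 0.05, KRAS 0.03, TERT promoter 0.33, MC1R
  polymorphism carriage 0.66.
* **Allele spectra** — conditional on a gene being mutated, e.g. BRAF
  V600E 0.80, V600K 0.10, K601E 0.04 and 0.02 each for L597R/L584F/G464R;
  NRAS dominated by codon 61; NF1 dominated by nonsense alleles; TERT
  promoter split across −146C>T, −124C>T, the CC>TT tandems and −57A>C.
  Genes without a published spectrum carry labelled synthetic missense
  alleles.
* **Clinical features** — drawn independently from the cohort marginals
  (age, sex, site, sun exposure, histology, Breslow category, ulceration,
  regression, mitosis, growth rate, stage). The joint distribution of real
  cohorts is unpublished, so independence is the stated stand-in; where an
  association is wanted, an injected log-OR couples mutation status to a
  coded feature through a logistic conditional whose intercept is
  calibrated (by root-finding) to preserve the marginal prevalence.
  Within-category ages and Breslow thicknesses are drawn uniformly over
  the category range.
* **Noise model** — raw tables average 56.6 calls of which 8.9 are exonic.
  Every noise call is engineered to fail exactly one named stage
  (non-exonic, synonymous, sub-threshold support, benign-majority vote)
  while passing all earlier ones, and its intended rejection stage is
  recorded in the truth labels. Planted drivers pass every stage by
  construction, so triage recovery is exact, not approximate — a planted
  truth-label round trip, not a statistical comparison.
* **Depth model** — per-amplicon coverage is lognormal with mean 2575.5
  over 515 amplicons; the log-scale spread is solved in closed form so the
  expected uniformity matches the 0.919 target.

What passing these tests does *not* show about real data: the generator
draws features independently, plants at most one driver per gene per
sample unless asked otherwise, knows nothing about sequence context,
mutational signatures, FFPE artifact spectra or caller-specific error
modes, and makes noise calls fail exactly one stage when real rejected
calls often fail several. Exact planted-truth recovery validates the
bookkeeping and boundary semantics of the cascade, not the biological
error profile.

## Numerical and design choices

* Seeds: every stochastic operation takes an explicit integer seed
  (default 20170329); fixed seed implies byte-identical pipeline reports,
  which is tested via JSON serialization.
* Problem sizes in the test suite: property tests run on 1,000 random
  variants, truth recovery on cohorts of 100 (with one 1,000-sample cohort
  for prevalence recovery within 3 binomial SEs), CI coverage on 1,000
  simulated tables, LOD stability over 20 seeded repeats of 1,000
  replicates — sizes chosen to make binomial noise small relative to the
  asserted tolerances.
* Degenerate inputs: empty variant tables triage to empty results with the
  raw count preserved; an all-zero-cross-product table raises an
  undefined-OR error rather than returning a number; the screen converts
  per-pair failures into flagged rows and continues; a zero-background LOD
  run detects the smallest series point, matching the direct binomial
  computation.
* Coordinates: variant positions are 1-based (VCF convention), panel
  amplicon intervals 0-based half-open (BED convention). Protein changes
  are normalized to one-letter HGVS-p short form on input; TERT promoter
  variants keep their offset-from-ATG labels.
* The ordinal-trend reproduction deserves a note: fitting the logistic MLE
  to the published per-category NF1-by-thickness counts (2/47, 0/21, 4/19,
  3/13, codes 1–4) gives a per-level OR of 2.21, not the published 2.16.
  No standard recoding of the four categories reproduces 2.16 exactly from
  those counts; the original model most plausibly used per-sample
  continuous thickness, which is not published. The package reports the
  value the counts imply.

## Known limitations

Subtype assignment uses point mutations only (a targeted amplicon panel
sees neither copy number nor structural variants, which genuinely
contribute to NF1-class and triple-wt biology); exact conditional logistic
regression is not implemented (Wald intervals misbehave at very small
counts beyond what the continuity correction repairs); survival/outcome
modelling is out of scope; and the VCF dialect expects annotations in INFO
keys rather than parsing caller-specific FORMAT fields.
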