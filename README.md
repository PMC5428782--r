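# melpanel

Analysis pipeline for custom targeted amplicon sequencing panels in primary
melanoma, written for molecular-diagnostics and translational-research
groups who run 30–40-gene melanoma panels on FFPE tumour DNA and need the
downstream analysis — not the sequencing — as reproducible, tested code.

The package covers, end to end:

* **Somatic variant triage** — a four-stage cascade over annotated calls:
  region/consequence filtering (drop non-exonic and synonymous calls, with
  a TERT-promoter bypass), read-support thresholds (total depth ≥ 500,
  variant reads ≥ 20, caller p-value < 0.01), an in-silico pathogenicity
  consensus (exclude when ≥ 3 of the 5 predictors Provean / SIFT /
  PolyPhen-2 / SNPS&GO / Condel vote *benign*; COSMIC-recurrent hotspots
  bypass the vote), and a germline-polymorphism partition (MC1R / CDK4 /
  MITF catalog plus dbSNP flags). Every record lands in exactly one of
  three buckets — pathogenic somatic, polymorphism, rejected-with-stage —
  with a per-stage audit trail.
* **Genomic subtyping** — TCGA four-class assignment (BRAF / RAS / NF1 /
  triple-wild-type) with configurable hotspot rules, precedence handling
  of concurrent drivers, per-gene prevalence (pathogenic vs any-variation)
  and co-occurrence / mutual-exclusivity counts.
* **Association statistics** — cross-product odds ratios with Woolf
  log-SE Wald intervals, `OR = ad/bc`, `SE = √(1/a+1/b+1/c+1/d)`;
  logistic MLE with separation flagging; per-level ordinal-trend odds
  ratios; and a gene × feature screening battery with BH q-values as a
  separate column.
* **Sensitivity modelling** — serial-dilution design (expected allele
  fraction `het/(1+k)` for a 1:k mix), binomial read-count simulation with
  an additive background false-read rate, and a simulation-based limit of
  detection: smallest series fraction whose variant reads exceed the
  99th-percentile binomial error null with ≥ 95% power.
* **Coverage QC** — mean amplicon coverage, % targeted bases ≥ 100× / 500×,
  on-target fraction, and uniformity (% bases ≥ 0.2 × mean depth).
* **Synthetic cohorts** — a fully seeded generator planting driver
  mutations at study-scale prevalences (BRAF 50%, NRAS 15%, … TERT
  promoter 33%, MC1R polymorphisms 66%) inside realistic noise (~56.6 raw
  / 8.9 exonic calls per sample), each noise call engineered to fail one
  named triage stage, with complete truth labels.

## Worked example

```r
library(melpanel)

report <- run_pipeline(run_config(seed = 20170329L))
print(report)
#> Cohort analysis report
#>   samples: 100 (56.0 raw / 6.1 exonic-functional / 1.8 pathogenic calls per sample)
#>   subtypes: BRAF=48, RAS=10, NF1=1, triple_wt=41, ambiguous=0
#>   BRAF/RAS exclusivity: 0.88
#>   limit of detection: 0.5% AF
```

With no input paths the run simulates a 100-sample cohort, triages every
sample, subtypes it, and summarizes prevalence, co-occurrence,
associations, coverage QC and the limit of detection. The subtype line
says 48 samples carry a qualifying BRAF hotspot, 10 a RAS driver, and 41
carry none of the three class-defining drivers; exclusivity 0.88 is
`1 − both/total` for BRAF vs NRAS/KRAS/HRAS — lower than in real cohorts
because the generator plants drivers independently unless told otherwise.
The LOD line is the smallest dilution-series allele fraction detectable
over a 0.1% false-read background at depth 3000.

```r
head(report$prevalence)
#>    gene count   n fraction any_count any_fraction
#> 1  BRAF    50 100     0.50        53         0.53
#> 2  NRAS    19 100     0.19        26         0.26
#> 3  KRAS     4 100     0.04         8         0.08
#> 4   NF1    12 100     0.12        16         0.16
#> 5   KIT     5 100     0.05        12         0.12
#> 6 PREX2    11 100     0.11        14         0.14
```

`fraction` counts samples with a post-consensus pathogenic variant;
`any_fraction` counts every call that survived the region and
read-support stages, including benign-voted variants of unknown
significance — the distinction that matters for passenger-heavy genes
like PREX2 and GRIN2A.

Single components work standalone:

```r
odds_ratio_2x2(4, 22, 1, 73)      # mutation status x ulceration, n = 100
#> OR 13.27 (95% CI 1.41-125.00), p = 0.0238 [cross_product, n = 100]

as.numeric(estimate_lod(dilution_series(depths = 3000L, error_rate = 0.001)))
#> [1] 0.005
```

A thin command-line wrapper with subcommands `simulate`, `triage`,
`subtype`, `sensitivity`, `qc` and `run-all` ships in `inst/cli/melpanel.R`.

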