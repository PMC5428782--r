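# Fixture builders and independent oracles shared across the suite.

# a random but invariant-respecting variant table for property tests
random_variant_table <- function(n, seed) {
  set.seed(seed)
  depth <- sample(0:4000, n, replace = TRUE)
  vr <- vapply(depth, function(d) sample(0:d, 1L), integer(1))
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K")
  from <- sample(aa, n, replace = TRUE)
  to <- sample(aa, n, replace = TRUE)
  df <- data.frame(
    sample_id = "SX",
    gene = sample(panel_genes(), n, replace = TRUE),
    chrom = "chr1",
    pos = sample.int(1e6, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    protein_change = paste0("p.", from, sample(30:900, n, replace = TRUE), to),
    region_class = sample(c("exonic", "intronic", "UTR", "promoter"), n,
                          replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1)),
    consequence = sample(c("missense", "nonsense", "frameshift",
                           "inframe_indel", "synonymous", "other"),
                         n, replace = TRUE),
    total_depth = depth,
    variant_reads = vr,
    allele_frequency = ifelse(depth > 0, vr / depth, 0),
    caller_pvalue = 10^runif(n, -6, 0),
    provean = sample(c("benign", "damaging", "unknown"), n, replace = TRUE),
    sift = sample(c("benign", "damaging", "unknown"), n, replace = TRUE),
    polyphen2 = sample(c("benign", "damaging", "unknown"), n, replace = TRUE),
    snps_go = sample(c("benign", "damaging", "unknown"), n, replace = TRUE),
    condel = sample(c("benign", "damaging", "unknown"), n, replace = TRUE),
    cosmic_recurrent = sample(c(TRUE, FALSE), n, replace = TRUE,
                              prob = c(0.2, 0.8)),
    dbsnp_germline = sample(c(TRUE, FALSE), n, replace = TRUE,
                            prob = c(0.2, 0.8)),
    stringsAsFactors = FALSE)
  df
}

# single-pass brute-force triage predicate: one boolean expression per
# variant, written independently of the staged cascade
brute_force_bucket <- function(v, thr = triage_thresholds(),
                               catalog = polymorphism_catalog()) {
  in_cat <- paste(v$gene, v$protein_change) %in%
    paste(catalog$gene, catalog$protein_change)
  is_poly <- in_cat | (v$dbsnp_germline & !v$cosmic_recurrent)
  pass_region <- (v$region_class == "exonic" &
                    v$consequence != "synonymous") |
    v$region_class == "promoter"
  pass_support <- v$total_depth >= thr$min_total_depth &
    v$variant_reads >= thr$min_variant_reads &
    v$caller_pvalue < thr$max_caller_pvalue
  n_benign <- (v$provean == "benign") + (v$sift == "benign") +
    (v$polyphen2 == "benign") + (v$snps_go == "benign") +
    (v$condel == "benign")
  pass_vote <- v$region_class == "promoter" | v$cosmic_recurrent |
    is_poly | n_benign < thr$benign_votes_to_exclude
  ifelse(pass_region & pass_support & pass_vote & is_poly, "polymorphism",
         ifelse(pass_region & pass_support & pass_vote, "pathogenic",
                "rejected"))
}

# brute-force grid maximization of the grouped binomial-logistic likelihood
# for an ordinal exposure coded 1..k; independent of glm
grid_search_trend_or <- function(mutated, totals, tol = 1e-4) {
  x <- seq_along(mutated)
  ll <- function(b0, b1) {
    p <- plogis(b0 + b1 * x)
    sum(mutated * log(p) + (totals - mutated) * log(1 - p))
  }
  b1_grid <- seq(-3, 3, by = 0.05)
  best <- -Inf; best_b1 <- 0
  refine <- function(grid) {
    for (b1 in grid) {
      opt <- stats::optimize(function(b0) ll(b0, b1), c(-20, 5),
                             maximum = TRUE, tol = 1e-9)
      if (opt$objective > best) { best <<- opt$objective; best_b1 <<- b1 }
    }
  }
  refine(b1_grid)
  step <- 0.05
  while (step > tol / 10) {
    step <- step / 10
    refine(seq(best_b1 - step * 10, best_b1 + step * 10, by = step))
  }
  exp(best_b1)
}

# variant set that makes a sample pathogenic-mutant in `gene`
make_mutant <- function(sample_id, gene, protein_change = "p.G100E",
                        consequence = "missense", cosmic = FALSE) {
  annotated_variant(sample_id = sample_id, gene = gene,
                    protein_change = protein_change,
                    consequence = consequence, cosmic_recurrent = cosmic)
}

# triaged cohort built directly from per-sample variant tables
triage_cohort <- function(tables) {
  out <- lapply(names(tables), function(s) triage_sample(s, tables[[s]]))
  names(out) <- names(tables)
  out
}
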