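## Synthetic cohort generator: per-sample raw variant tables,
## clinicopathological features and coverage profiles carrying the
## statistical structure the analysis pipeline assumes, with full truth
## labels (planted pathogenic sets, intended rejection stage of every noise
## call, implied genomic subtype), so every downstream stage is testable
## without patient-level sequencing data.

#' Gene content of the 35-gene melanoma panel
#'
#' @return Character vector of HGNC symbols.
#' @export
panel_genes <- function() {
  c("NRAS", "ERBB4", "HOXD8", "ALK", "MITF", "BAP1", "PIK3CA", "KIT", "TERT",
    "EPHA7", "STK19", "BRAF", "MET", "GRM3", "RAC1", "STK31", "TRRAP",
    "PREX2", "CDKN2A", "GNAQ", "TAF1L", "PPP6C", "PTEN", "HRAS", "KRAS",
    "CDK4", "MAP2K1", "MC1R", "GRIN2A", "ADAMTS18", "NF1", "GNA11",
    "MAP2K2", "STK11", "IRS4")
}

# synthetic genomic anchor per gene (chromosome + base position); positions
# are arbitrary but stable so generated tables are reproducible
gene_anchor <- function(gene) {
  genes <- panel_genes()
  i <- match(gene, genes)
  i[is.na(i)] <- length(genes) + 1L
  list(chrom = paste0("chr", (i %% 22L) + 1L),
       pos = 1000000L + i * 100000L)
}

spectrum <- function(change, prob, consequence = NULL, cosmic = FALSE) {
  if (is.null(consequence))
    consequence <- ifelse(grepl("\\*$", change), "nonsense", "missense")
  data.frame(change = change, prob = prob, consequence = consequence,
             cosmic = rep_len(cosmic, length(change)),
             stringsAsFactors = FALSE)
}

default_allele_spectra <- function() {
  list(
    BRAF = spectrum(c("p.V600E", "p.V600K", "p.K601E", "p.L597R", "p.L584F",
                      "p.G464R"),
                    c(0.80, 0.10, 0.04, 0.02, 0.02, 0.02),
                    cosmic = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)),
    NRAS = spectrum(c("p.Q61R", "p.Q61L", "p.Q61K", "p.G12S", "p.E62Q"),
                    c(0.45, 0.25, 0.176, 0.063, 0.061),
                    cosmic = c(TRUE, TRUE, TRUE, TRUE, FALSE)),
    KRAS = spectrum(c("p.Q61R", "p.G12V", "p.A146V"), c(0.65, 0.20, 0.15),
                    cosmic = c(TRUE, TRUE, FALSE)),
    KIT = spectrum(c("p.L576P", "p.Y553S", "p.Y578C", "p.K642E"),
                   c(0.40, 0.20, 0.20, 0.20),
                   cosmic = c(TRUE, FALSE, FALSE, TRUE)),
    NF1 = spectrum(c("p.R1362*", "p.Q1070*", "p.W1512*", "p.R2450*",
                     "p.R711C", "p.K1844T"),
                   c(0.25, 0.125, 0.125, 0.125, 0.1875, 0.1875)),
    PTEN = spectrum(c("p.F278L", "p.R130*", "p.G129E"), c(0.4, 0.3, 0.3),
                    cosmic = c(FALSE, TRUE, TRUE)),
    PREX2 = spectrum(c("p.E824K", "p.G844D", "p.S619F"), c(0.4, 0.3, 0.3)),
    GRIN2A = spectrum(c("p.R714C", "p.E1070K", "p.S281F"), c(0.4, 0.3, 0.3)),
    ERBB4 = spectrum(c("p.E317K", "p.E452K", "p.E542K"), c(0.4, 0.3, 0.3),
                     cosmic = c(TRUE, FALSE, FALSE)),
    RAC1 = spectrum(c("p.P29S", "p.P69L"), c(0.875, 0.125),
                    cosmic = c(TRUE, FALSE)),
    PPP6C = spectrum(c("p.R264C", "p.D193Y", "p.P209L"), c(0.67, 0.165, 0.165),
                     cosmic = c(TRUE, TRUE, TRUE)),
    TERT_promoter = spectrum(c("-146C>T", "-124C>T", "-138/-139CC>TT",
                               "-124/-125CC>TT", "-57A>C"),
                             c(0.45, 0.30, 0.15, 0.06, 0.03),
                             consequence = "other", cosmic = TRUE),
    MC1R_polymorphism = spectrum(c("p.V60L", "p.V92M", "p.D294H", "p.R160W"),
                                 c(0.545, 0.258, 0.136, 0.061)))
}

default_feature_marginals <- function() {
  list(age_class = c("<40" = 0.06, "40-65" = 0.44, ">65" = 0.50),
       sex = c(male = 0.53, female = 0.47),
       anatomic_site = c("head/neck" = 0.16, "upper extremities" = 0.16,
                         "trunk" = 0.42, "lower extremities" = 0.18,
                         "acral" = 0.08),
       sun_exposure = c("non-exposed" = 0.21, "occasionally" = 0.63,
                        "usually" = 0.16),
       histology = c(LMM = 0.10, SSM = 0.68, NM = 0.14, ALM = 0.08),
       breslow_class = c("<=1" = 0.47, "1-2" = 0.21, "2-4" = 0.19,
                         ">4" = 0.13),
       ulceration = c("FALSE" = 0.74, "TRUE" = 0.26),
       regression = c("none" = 0.52, "<50%" = 0.41, ">50%" = 0.07),
       mitosis_high = c("FALSE" = 0.48, "TRUE" = 0.52),
       growth_rate = c(SGM = 0.76, FGM = 0.24),
       stage_class = c("I-II" = 0.75, "III-IV" = 0.25))
}

#' Synthetic cohort specification
#'
#' Defaults encode the study conditions the generator emulates: 100 samples;
#' gene-level prevalences BRAF 0.50, NRAS 0.15, PREX2 0.14, GRIN2A 0.13,
#' ERBB4 0.12, PTEN 0.09, NF1 0.08, RAC1 0.08, PPP6C 0.06, KIT 0.05,
#' KRAS 0.03, TERT promoter 0.33, MC1R polymorphism carriage 0.66;
#' within-gene allele spectra (e.g. BRAF p.V600E 80% of BRAF mutants);
#' clinicopathological marginals of the cohort; a raw-call noise model with
#' 56.6 total and 8.9 exonic variants per sample on average; an amplicon
#' depth model with mean 2575.5 and uniformity target 0.919.
#'
#' @param n_samples cohort size.
#' @param gene_prevalences named fraction per gene (special entries
#'   `TERT_promoter`, `MC1R_polymorphism`).
#' @param allele_spectra per-gene data.frames (change, prob, consequence,
#'   cosmic); probabilities are renormalized at draw time.
#' @param feature_marginals named probability vectors per feature.
#' @param injected_log_ors optional data.frame (gene, feature, coding,
#'   log_or): mutation status is drawn from a logistic conditional on the
#'   coded feature with the intercept calibrated to preserve the marginal
#'   prevalence.
#' @param noise list: `mean_total`, `mean_exonic` raw calls per sample, and
#'   the split of exonic noise into `synonymous_frac`, `support_fail_frac`,
#'   `benign_frac`.
#' @param depth_model list: `mean_depth`, `uniformity`, `n_amplicons`.
#' @param co_mutation optional list(`genes` = pair, `n` = count) forcing
#'   `n` samples to carry drivers of both genes (subtype stress tests).
#' @param seed integer seed.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 100L,
                        gene_prevalences = c(BRAF = 0.50, NRAS = 0.15,
                                             PREX2 = 0.14, GRIN2A = 0.13,
                                             ERBB4 = 0.12, PTEN = 0.09,
                                             NF1 = 0.08, RAC1 = 0.08,
                                             PPP6C = 0.06, KIT = 0.05,
                                             KRAS = 0.03,
                                             TERT_promoter = 0.33,
                                             MC1R_polymorphism = 0.66),
                        allele_spectra = default_allele_spectra(),
                        feature_marginals = default_feature_marginals(),
                        injected_log_ors = NULL,
                        noise = list(mean_total = 56.6, mean_exonic = 8.9,
                                     synonymous_frac = 0.45,
                                     support_fail_frac = 0.30,
                                     benign_frac = 0.25),
                        depth_model = list(mean_depth = 2575.5,
                                           uniformity = 0.919,
                                           n_amplicons = 515L),
                        co_mutation = NULL,
                        seed = 20170329L) {
  stopifnot(n_samples >= 1L,
            all(gene_prevalences >= 0 & gene_prevalences <= 1))
  missing_spec <- setdiff(names(gene_prevalences), names(allele_spectra))
  if (length(missing_spec) > 0L)
    stop("cohort spec error: no allele spectrum for ",
         paste(missing_spec, collapse = ", "), call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 gene_prevalences = gene_prevalences,
                 allele_spectra = allele_spectra,
                 feature_marginals = feature_marginals,
                 injected_log_ors = injected_log_ors,
                 noise = noise, depth_model = depth_model,
                 co_mutation = co_mutation, seed = as.integer(seed)),
            class = "cohort_spec")
}

sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

generate_features <- function(spec) {
  n <- spec$n_samples
  fm <- spec$feature_marginals
  age_class <- sample_cat(n, fm$age_class)
  age <- round(ifelse(age_class == "<40", runif(n, 21, 40),
                      ifelse(age_class == "40-65", runif(n, 40, 65),
                             runif(n, 65, 90))))
  breslow_class <- sample_cat(n, fm$breslow_class)
  breslow_mm <- round(ifelse(breslow_class == "<=1", runif(n, 0.2, 1),
                             ifelse(breslow_class == "1-2", runif(n, 1, 2),
                                    ifelse(breslow_class == "2-4",
                                           runif(n, 2, 4),
                                           runif(n, 4, 9)))), 1)
  # rounding must not move a thickness across its category boundary
  breslow_mm <- pmin(pmax(breslow_mm,
                          c("<=1" = 0.2, "1-2" = 1.1, "2-4" = 2.1,
                            ">4" = 4.1)[breslow_class]),
                     c("<=1" = 1, "1-2" = 2, "2-4" = 4,
                       ">4" = 9)[breslow_class])
  data.frame(sample_id = sprintf("S%03d", seq_len(n)), age = age,
             sex = sample_cat(n, fm$sex),
             anatomic_site = sample_cat(n, fm$anatomic_site),
             sun_exposure = sample_cat(n, fm$sun_exposure),
             histology = sample_cat(n, fm$histology),
             breslow_mm = unname(breslow_mm),
             breslow_class = breslow_class,
             ulceration = sample_cat(n, fm$ulceration) == "TRUE",
             regression = sample_cat(n, fm$regression),
             mitosis_high = sample_cat(n, fm$mitosis_high) == "TRUE",
             growth_rate = sample_cat(n, fm$growth_rate),
             stage_class = sample_cat(n, fm$stage_class),
             stringsAsFactors = FALSE)
}

# intercept of the logistic conditional preserving the marginal prevalence
calibrate_intercept <- function(prev, eta) {
  if (prev <= 0) return(-Inf)
  uniroot(function(b0) mean(plogis(b0 + eta)) - prev,
          interval = c(-30, 30))$root
}

draw_mutation_indicators <- function(spec, features) {
  n <- spec$n_samples
  out <- list()
  for (g in names(spec$gene_prevalences)) {
    prev <- spec$gene_prevalences[[g]]
    inj <- spec$injected_log_ors
    inj <- if (!is.null(inj)) inj[inj$gene == g, , drop = FALSE]
    if (!is.null(inj) && nrow(inj) > 0L) {
      eta <- rep(0, n)
      for (i in seq_len(nrow(inj))) {
        x <- code_feature(features, inj$feature[i], inj$coding[i])
        eta <- eta + inj$log_or[i] * as.numeric(x)
      }
      b0 <- calibrate_intercept(prev, eta)
      out[[g]] <- runif(n) < plogis(b0 + eta)
    } else {
      out[[g]] <- runif(n) < prev
    }
  }
  if (!is.null(spec$co_mutation)) {
    idx <- sample.int(n, spec$co_mutation$n)
    for (g in spec$co_mutation$genes) out[[g]][idx] <- TRUE
  }
  out
}

verdict_matrix <- function(n, pool, prob = NULL) {
  matrix(sample(pool, 5L * n, replace = TRUE, prob = prob), nrow = n)
}

nucleotides <- c("A", "C", "G", "T")

# all planted variants for spectrum entry `g` across samples `sids` at once
plant_variants_bulk <- function(sids, g, spec) {
  n <- length(sids)
  if (n == 0L) return(NULL)
  sp <- spec$allele_spectra[[g]]
  i <- sample.int(nrow(sp), n, replace = TRUE, prob = sp$prob)
  promoter <- identical(g, "TERT_promoter")
  polymorphism <- identical(g, "MC1R_polymorphism")
  gene <- if (promoter) "TERT" else if (polymorphism) "MC1R" else g
  depth <- pmin(pmax(round(rlnorm(n, log(2000), 0.3)), 600L), 8000L)
  af <- runif(n, 0.05, 0.6)
  vr <- pmax(20L, as.integer(round(af * depth)))
  anchor <- gene_anchor(gene)
  verdicts <- if (polymorphism)
    verdict_matrix(n, c("benign", "unknown"), c(0.7, 0.3))
  else verdict_matrix(n, c("damaging", "unknown"), c(0.8, 0.2))
  data.frame(
    sample_id = sids, gene = gene, chrom = anchor$chrom,
    pos = anchor$pos + sample.int(5000L, n, replace = TRUE),
    ref = sample(nucleotides, n, replace = TRUE),
    alt = sample(nucleotides, n, replace = TRUE),
    protein_change = sp$change[i],
    region_class = if (promoter) "promoter" else "exonic",
    consequence = sp$consequence[i],
    total_depth = as.integer(depth), variant_reads = vr,
    allele_frequency = vr / depth,
    caller_pvalue = 10^runif(n, -8, -3),
    provean = verdicts[, 1L], sift = verdicts[, 2L],
    polyphen2 = verdicts[, 3L], snps_go = verdicts[, 4L],
    condel = verdicts[, 5L],
    cosmic_recurrent = sp$cosmic[i], dbsnp_germline = polymorphism,
    stringsAsFactors = FALSE)
}

# noise calls engineered to fail exactly `stage`, one row per entry of `sids`
plant_noise_bulk <- function(sids, stage, spec, catalog) {
  n <- length(sids)
  if (n == 0L) return(NULL)
  gene <- sample(setdiff(panel_genes(), c("MC1R", "CDK4", "MITF")), n,
                 replace = TRUE)
  anchor <- gene_anchor(gene)
  codon <- sample(100:999, n, replace = TRUE)
  aa_pool <- unname(aa3to1[names(aa3to1) != "Ter"])
  aa_from <- sample(aa_pool, n, replace = TRUE)
  aa_to <- sample(aa_pool, n, replace = TRUE)
  pc <- paste0("p.", aa_from, codon, aa_to)
  depth <- as.integer(round(runif(n, 800, 4000)))
  af <- runif(n, 0.05, 0.5)
  vr <- as.integer(round(af * depth))
  pval <- 10^runif(n, -6, -3)
  verdicts <- verdict_matrix(n, c("damaging", "unknown"))
  region <- rep("exonic", n); consequence <- rep("missense", n)
  if (stage == "non_exonic") {
    region <- sample(c("intronic", "UTR"), n, replace = TRUE)
    consequence <- rep("other", n)
  } else if (stage == "synonymous") {
    consequence <- rep("synonymous", n)
    pc <- paste0("p.", aa_from, codon, aa_from)
  } else if (stage == "support") {
    mode <- sample(c("depth", "reads", "pvalue"), n, replace = TRUE)
    shallow <- mode == "depth"
    depth[shallow] <- sample(100:499, sum(shallow), replace = TRUE)
    vr[shallow] <- as.integer(round(af[shallow] * depth[shallow]))
    few <- mode == "reads"
    vr[few] <- sample(0:19, sum(few), replace = TRUE)
    pval[mode == "pvalue"] <- runif(sum(mode == "pvalue"), 0.01, 0.5)
  } else if (stage == "benign_consensus") {
    n_benign <- sample(3:5, n, replace = TRUE)
    verdicts <- t(vapply(n_benign, function(k)
      sample(c(rep("benign", k),
               sample(c("damaging", "unknown"), 5L - k, replace = TRUE))),
      character(5L)))
    vr <- pmax(vr, 25L)
  }
  out <- data.frame(
    sample_id = sids, gene = gene, chrom = anchor$chrom,
    pos = anchor$pos + sample.int(20000L, n, replace = TRUE),
    ref = sample(nucleotides, n, replace = TRUE),
    alt = sample(nucleotides, n, replace = TRUE),
    protein_change = pc, region_class = region, consequence = consequence,
    total_depth = depth, variant_reads = vr, allele_frequency = vr / depth,
    caller_pvalue = pval,
    provean = verdicts[, 1L], sift = verdicts[, 2L],
    polyphen2 = verdicts[, 3L], snps_go = verdicts[, 4L],
    condel = verdicts[, 5L],
    cosmic_recurrent = FALSE, dbsnp_germline = FALSE,
    stringsAsFactors = FALSE)
  hit <- in_catalog(out, catalog)    # avoid accidental catalog collisions
  out$protein_change[hit] <- paste0("p.", aa_from[hit], codon[hit] + 1L,
                                    aa_to[hit])
  out
}

#' Generate a synthetic melanoma cohort with truth labels
#'
#' Samples clinicopathological features from the specified marginals
#' (coupled to mutation status only through injected log odds ratios),
#' plants per-gene driver and polymorphism variants passing every triage
#' stage, and surrounds them with noise calls engineered to fail one named
#' stage each. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return List: `features` (data.frame), `variants` (single data.frame for
#'   all samples with a `variant_id` column), `truth` (per-variant planted
#'   labels, per-sample pathogenic variant ids and implied genomic subtype).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  catalog <- polymorphism_catalog()
  features <- generate_features(spec)
  ind <- draw_mutation_indicators(spec, features)

  mean_planted_exonic <- sum(spec$gene_prevalences[
    setdiff(names(spec$gene_prevalences), "TERT_promoter")])
  mean_exonic_noise <- max(0, spec$noise$mean_exonic - mean_planted_exonic)
  mean_nonexonic <- max(0, spec$noise$mean_total - spec$noise$mean_exonic)
  stage_fracs <- c(synonymous = spec$noise$synonymous_frac,
                   support = spec$noise$support_fail_frac,
                   benign_consensus = spec$noise$benign_frac)
  stage_means <- c(non_exonic = mean_nonexonic,
                   mean_exonic_noise * stage_fracs / sum(stage_fracs))

  parts <- list(); stages <- list()
  for (g in names(ind)) {
    sids <- features$sample_id[ind[[g]]]
    df <- plant_variants_bulk(sids, g, spec)
    if (is.null(df)) next
    parts[[length(parts) + 1L]] <- df
    stages[[length(stages) + 1L]] <-
      rep(if (identical(g, "MC1R_polymorphism")) "polymorphism"
          else "pathogenic", nrow(df))
  }
  for (stage in names(stage_means)) {
    counts <- rpois(spec$n_samples, stage_means[[stage]])
    sids <- rep(features$sample_id, counts)
    df <- plant_noise_bulk(sids, stage, spec, catalog)
    if (is.null(df)) next
    parts[[length(parts) + 1L]] <- df
    stages[[length(stages) + 1L]] <- rep(stage, nrow(df))
  }
  variants <- do.call(rbind, parts)
  variants$variant_id <- sprintf("v%06d", seq_len(nrow(variants)))
  truth <- data.frame(sample_id = variants$sample_id, gene = variants$gene,
                      planted_stage = unlist(stages),
                      variant_id = variants$variant_id,
                      stringsAsFactors = FALSE)
  # group rows per sample (stable order: planted first, then noise stages)
  ord <- order(match(variants$sample_id, features$sample_id))
  variants <- variants[ord, , drop = FALSE]
  truth <- truth[ord, , drop = FALSE]
  rownames(variants) <- rownames(truth) <- NULL

  # implied genomic subtype from the planted pathogenic set, default rules
  planted <- variants[truth$planted_stage == "pathogenic", , drop = FALSE]
  by_sample <- split(planted, factor(planted$sample_id,
                                     levels = features$sample_id))
  subtypes <- vapply(by_sample, function(d)
    classify_genomic_subtype(d)$subtype, character(1))
  names(subtypes) <- features$sample_id

  list(features = features, variants = variants,
       truth = list(variants = truth,
                    pathogenic_ids = split(
                      truth$variant_id[truth$planted_stage == "pathogenic"],
                      truth$sample_id[truth$planted_stage == "pathogenic"]),
                    subtype = subtypes))
}

#' Split a generated variant table by sample
#'
#' @param variants the `variants` data.frame from [generate_cohort()].
#' @param sample_ids sample order for the output list.
#' @return Named list of per-sample variant data.frames.
#' @export
split_by_sample <- function(variants,
                            sample_ids = unique(variants$sample_id)) {
  out <- lapply(sample_ids, function(sid)
    variants[variants$sample_id == sid, , drop = FALSE])
  names(out) <- sample_ids
  out
}

#' Simulate a dilution-series sequencing experiment
#'
#' Fills the `observed` slot of a [dilution_series()] with replicate variant
#' read counts drawn from the binomial read-count model (two independent
#' replicates per point by default).
#'
#' @param series a [dilution_series()].
#' @param n_replicates replicates per dilution point.
#' @param seed integer seed.
#' @return The series with `observed`: data.frame (expected_af, depth,
#'   replicate, variant_reads, observed_af).
#' @export
generate_dilution_experiment <- function(series = dilution_series(),
                                         n_replicates = 2L,
                                         seed = 20170329L) {
  set.seed(seed)
  pts <- series$points
  obs <- lapply(seq_len(nrow(pts)), function(i) {
    counts <- simulate_read_counts(pts$expected_af[i], pts$depth[i],
                                   series$error_rate, n_replicates)
    data.frame(expected_af = pts$expected_af[i], depth = pts$depth[i],
               replicate = seq_len(n_replicates), variant_reads = counts,
               observed_af = counts / pts$depth[i])
  })
  series$observed <- do.call(rbind, obs)
  series
}

#' Simulate a per-amplicon coverage profile
#'
#' Amplicon mean depths are drawn lognormal with the log-scale spread solved
#' so that the expected uniformity (fraction of coverage >= 0.2 x mean)
#' matches the target.
#'
#' @param n_amplicons number of panel amplicons.
#' @param mean_depth target mean amplicon coverage.
#' @param uniformity target uniformity fraction (0-1 scale).
#' @param seed integer seed.
#' @return A [coverage_profile()] with amplicon lengths drawn in 125-175 bp
#'   and an on-target read fraction of about 0.94.
#' @export
generate_coverage_profile <- function(n_amplicons = 515L,
                                      mean_depth = 2575.5,
                                      uniformity = 0.919,
                                      seed = 20170329L) {
  set.seed(seed)
  q <- qnorm(1 - uniformity)
  sdlog <- q + sqrt(q^2 - 2 * log(0.2))   # root of P(X < 0.2 mean) = 1 - u
  depths <- rlnorm(n_amplicons, log(mean_depth) - sdlog^2 / 2, sdlog)
  lengths <- sample(125:175, n_amplicons, replace = TRUE)
  on_target <- sum(depths * lengths) / 150
  coverage_profile(per_amplicon_mean_depth = depths,
                   amplicon_lengths = lengths,
                   total_reads = round(on_target / 0.94),
                   on_target_reads = round(on_target))
}
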