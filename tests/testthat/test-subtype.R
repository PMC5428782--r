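tv <- function(gene, pc, consequence = "missense", cosmic = FALSE,
               sample_id = "S1") {
  annotated_variant(sample_id = sample_id, gene = gene,
                    protein_change = normalize_protein_change(pc),
                    consequence = consequence, cosmic_recurrent = cosmic)
}

test_that("precedence mode resolves concurrent drivers and flags them", {
  # RAS + NF1 loss-of-function concurrence resolves to RAS
  s62 <- rbind(tv("KRAS", "p.Gly12Val", cosmic = TRUE),
               tv("NF1", "p.Trp1512*", consequence = "nonsense"))
  call <- classify_genomic_subtype(s62)
  expect_equal(call$subtype, "RAS")
  expect_equal(call$concurrent_flags, list(c("RAS", "NF1")))

  # BRAF hotspot + RAS hotspot resolves to BRAF
  s80 <- rbind(tv("BRAF", "p.Val600Glu", cosmic = TRUE),
               tv("NRAS", "p.Gln61Arg", cosmic = TRUE))
  call <- classify_genomic_subtype(s80)
  expect_equal(call$subtype, "BRAF")
  expect_equal(call$concurrent_flags, list(c("BRAF", "RAS")))

  # KIT mutations do not define a class
  expect_equal(classify_genomic_subtype(tv("KIT", "p.L576P",
                                           cosmic = TRUE))$subtype,
               "triple_wt")
  expect_equal(classify_genomic_subtype(empty_variant_table())$subtype,
               "triple_wt")
})

test_that("NF1 class requires loss of function by default", {
  expect_equal(classify_genomic_subtype(
    tv("NF1", "p.Arg711Cys"))$subtype, "triple_wt")
  expect_equal(classify_genomic_subtype(
    tv("NF1", "p.Gln1070*", consequence = "nonsense"))$subtype, "NF1")
  relaxed <- subtype_rules(nf1_allow_missense = TRUE)
  expect_equal(classify_genomic_subtype(tv("NF1", "p.Arg711Cys"),
                                        relaxed)$subtype, "NF1")
})

test_that("BRAF qualification covers hotspot codons, not arbitrary changes", {
  expect_equal(classify_genomic_subtype(tv("BRAF", "p.V600D"))$subtype,
               "BRAF")   # any change at codon 600
  expect_equal(classify_genomic_subtype(tv("BRAF", "p.G464R"))$subtype,
               "triple_wt")
  wide <- subtype_rules(braf_any_nonsyn = TRUE)
  expect_equal(classify_genomic_subtype(tv("BRAF", "p.G464R"), wide)$subtype,
               "BRAF")
})

test_that("strict mode reports concurrences as ambiguous", {
  s <- rbind(tv("BRAF", "p.V600E", cosmic = TRUE),
             tv("NRAS", "p.Q61R", cosmic = TRUE))
  expect_equal(classify_genomic_subtype(
    s, subtype_rules(mode = "strict"))$subtype, "ambiguous")
  # never ambiguous in precedence mode; counts sum to cohort size
  sim <- generate_cohort(cohort_spec(n_samples = 25L, seed = 3L))
  cohort <- triage_cohort(split_by_sample(sim$variants,
                                          sim$features$sample_id))
  st <- classify_cohort(cohort)
  expect_equal(nrow(st), 25L)
  expect_false(any(st$subtype == "ambiguous"))
})

test_that("classification is invariant to variant order within a sample", {
  s <- rbind(tv("NF1", "p.Q1070*", consequence = "nonsense"),
             tv("NRAS", "p.Q61R", cosmic = TRUE),
             tv("BRAF", "p.V600E", cosmic = TRUE))
  set.seed(8)
  for (i in 1:5) {
    perm <- s[sample.int(nrow(s)), , drop = FALSE]
    expect_equal(classify_genomic_subtype(perm)$subtype, "BRAF")
  }
})

test_that("gene prevalence counts mutated samples under both definitions", {
  tabs <- c(lapply(1:5, function(i)
    make_mutant(sprintf("M%d", i), "BRAF", "p.V600E", cosmic = TRUE)),
    lapply(6:10, function(i)
      make_mutant(sprintf("M%d", i), "PTEN", "p.G100E")))
  names(tabs) <- sprintf("M%d", 1:10)
  cohort <- triage_cohort(tabs)
  p <- gene_prevalence(cohort, "BRAF")
  expect_equal(p$fraction, 0.5)
  expect_equal(p$count, 5L)
  expect_equal(gene_prevalence(cohort, "KIT")$fraction, 0)
  expect_error(gene_prevalence(list(), "BRAF"), "empty cohort")
})

test_that("pathogenic_only reproduces the any-variation vs pathogenic split", {
  # 14 samples with damaging PREX2, 14 more whose PREX2 call loses the vote
  benign_prex2 <- function(sid)
    annotated_variant(sample_id = sid, gene = "PREX2",
                      protein_change = "p.S619F", provean = "benign",
                      sift = "benign", polyphen2 = "benign")
  tabs <- c(lapply(1:14, function(i) make_mutant(sprintf("P%02d", i), "PREX2")),
            lapply(15:28, function(i) benign_prex2(sprintf("P%02d", i))),
            lapply(29:100, function(i) make_mutant(sprintf("P%02d", i), "BRAF",
                                                   "p.V600E", cosmic = TRUE)))
  names(tabs) <- sprintf("P%02d", 1:100)
  cohort <- triage_cohort(tabs)
  expect_equal(gene_prevalence(cohort, "PREX2", pathogenic_only = TRUE)$fraction,
               0.14)
  expect_equal(gene_prevalence(cohort, "PREX2", pathogenic_only = FALSE)$fraction,
               0.28)
})

test_that("co-occurrence counts and exclusivity match hand enumeration", {
  # 100 samples, 3 planted BRAF+RAS double mutants
  tabs <- c(lapply(1:3, function(i)
    rbind(make_mutant(sprintf("C%03d", i), "BRAF", "p.V600E", cosmic = TRUE),
          make_mutant(sprintf("C%03d", i), "NRAS", "p.Q61R", cosmic = TRUE))),
    lapply(4:50, function(i)
      make_mutant(sprintf("C%03d", i), "BRAF", "p.V600E", cosmic = TRUE)),
    lapply(51:60, function(i)
      make_mutant(sprintf("C%03d", i), "NRAS", "p.Q61R", cosmic = TRUE)),
    lapply(61:100, function(i)
      make_mutant(sprintf("C%03d", i), "PTEN", "p.G100E")))
  names(tabs) <- sprintf("C%03d", 1:100)
  cohort <- triage_cohort(tabs)
  cc <- cooccurrence_counts(cohort, "BRAF", c("NRAS", "KRAS"))
  expect_equal(cc$both, 3L)
  expect_equal(cc$a_only, 47L)
  expect_equal(cc$b_only, 10L)
  expect_equal(cc$neither, 40L)
  expect_equal(cc$exclusivity, 0.97)

  expect_error(cooccurrence_counts(cohort, "BRAF", c("BRAF", "NRAS")),
               "overlap")

  # exhaustive 8-sample fixture vs direct enumeration
  genes8 <- list("BRAF", "NRAS", c("BRAF", "NRAS"), "PTEN", "BRAF",
                 character(0), "NRAS", c("BRAF", "NRAS"))
  tabs8 <- lapply(seq_along(genes8), function(i) {
    g <- genes8[[i]]
    if (length(g) == 0L) return(empty_variant_table())
    do.call(rbind, lapply(g, function(gg)
      make_mutant(sprintf("E%d", i), gg, "p.V600E", cosmic = TRUE)))
  })
  names(tabs8) <- sprintf("E%d", 1:8)
  cc8 <- cooccurrence_counts(triage_cohort(tabs8), "BRAF", "NRAS")
  in_a <- vapply(genes8, function(g) "BRAF" %in% g, logical(1))
  in_b <- vapply(genes8, function(g) "NRAS" %in% g, logical(1))
  expect_equal(cc8$both, sum(in_a & in_b))
  expect_equal(cc8$a_only, sum(in_a & !in_b))
  expect_equal(cc8$b_only, sum(!in_a & in_b))
  expect_equal(cc8$neither, sum(!in_a & !in_b))
  expect_equal(cc8$exclusivity, 1 - sum(in_a & in_b) / 8)
})
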