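test_that("region/consequence filter keeps exonic non-synonymous calls", {
  v <- rbind(annotated_variant(gene = "BRAF", consequence = "missense"),
             annotated_variant(gene = "PTEN", consequence = "synonymous"),
             annotated_variant(gene = "NF1", region_class = "intronic",
                               consequence = "other"))
  expect_equal(filter_exonic_functional(v)$gene, "BRAF")
  expect_equal(nrow(filter_exonic_functional(empty_variant_table())), 0L)

  # enumerated expectation over a random fixture
  r <- random_variant_table(10L, 33L)
  want <- which((r$region_class == "exonic" & r$consequence != "synonymous") |
                  r$region_class == "promoter")
  expect_equal(rownames(filter_exonic_functional(r)), as.character(want))
})

test_that("TERT promoter calls bypass the exonic filter", {
  v <- annotated_variant(gene = "TERT", protein_change = "-146C>T",
                         region_class = "promoter", consequence = "other")
  expect_equal(nrow(filter_exonic_functional(v)), 1L)
  ts <- triage_sample("S1", v)
  expect_equal(nrow(ts$pathogenic_somatic), 1L)
  expect_equal(nrow(ts$tert_promoter), 1L)
})

test_that("support filter applies >=500 / >=20 / <0.01 boundary semantics", {
  keep <- annotated_variant(total_depth = 500L, variant_reads = 20L,
                            caller_pvalue = 0.009)
  expect_equal(nrow(filter_by_support(keep)), 1L)

  shallow <- annotated_variant(total_depth = 499L, variant_reads = 30L,
                               caller_pvalue = 0.001)
  expect_equal(nrow(filter_by_support(shallow)), 0L)

  edge_p <- annotated_variant(caller_pvalue = 0.01)
  expect_equal(nrow(filter_by_support(edge_p)), 0L)

  # deep locus, ultra-low fraction: ~2 supporting reads fails the read floor
  trace <- annotated_variant(total_depth = 4993L,
                             variant_reads = round(0.0004 * 4993),
                             allele_frequency = 0.0004)
  expect_equal(nrow(filter_by_support(trace)), 0L)

  neg <- annotated_variant()
  neg$variant_reads <- -1L
  expect_error(filter_by_support(neg), "negative")
})

test_that("consensus vote excludes on >=3 explicit benign calls only", {
  verd <- function(...) {
    v <- c(...)
    annotated_variant(provean = v[1], sift = v[2], polyphen2 = v[3],
                      snps_go = v[4], condel = v[5])
  }
  expect_equal(consensus_pathogenicity(
    verd("benign", "benign", "benign", "damaging", "damaging")),
    "exclude_benign")
  expect_equal(consensus_pathogenicity(
    verd("benign", "benign", "damaging", "damaging", "damaging")), "keep")
  # unknown never counts as benign
  expect_equal(consensus_pathogenicity(
    verd("benign", "benign", "unknown", "unknown", "unknown")), "keep")
  # recurrent hotspots bypass the vote entirely
  hot <- verd("benign", "benign", "benign", "benign", "benign")
  hot$cosmic_recurrent <- TRUE
  expect_equal(consensus_pathogenicity(hot), "keep")
})

test_that("known polymorphisms are partitioned away from somatic calls", {
  v <- rbind(annotated_variant(gene = "MC1R", protein_change = "p.V60L",
                               dbsnp_germline = TRUE),
             annotated_variant(gene = "MITF", protein_change = "p.E318K"),
             annotated_variant(gene = "BRAF", protein_change = "p.V600E",
                               cosmic_recurrent = TRUE),
             annotated_variant(gene = "CDK4", protein_change = "p.R24H"))
  part <- partition_germline_polymorphisms(v)
  expect_setequal(part$polymorphisms$gene, c("MC1R", "MITF", "CDK4"))
  expect_equal(part$somatic$gene, "BRAF")
  expect_equal(nrow(part$somatic) + nrow(part$polymorphisms), nrow(v))
  # dbSNP-flagged but COSMIC-recurrent stays somatic
  known_hotspot <- annotated_variant(gene = "NRAS", protein_change = "p.Q61R",
                                     dbsnp_germline = TRUE,
                                     cosmic_recurrent = TRUE)
  expect_equal(nrow(partition_germline_polymorphisms(known_hotspot)$somatic),
               1L)
})

test_that("the cascade fills an audit trail and yields the planted counts", {
  sim <- generate_cohort(cohort_spec(n_samples = 1L, seed = 42L))
  tab <- sim$variants
  ts <- triage_sample(tab$sample_id[1L], tab)
  sc <- ts$stage_counts
  expect_equal(unname(sc[["raw"]]), nrow(tab))
  expect_true(all(diff(unname(sc)) <= 0))   # monotone along the cascade
  truth <- sim$truth$variants
  expect_setequal(ts$pathogenic_somatic$variant_id,
                  truth$variant_id[truth$planted_stage == "pathogenic"])

  all_syn <- rbind(annotated_variant(consequence = "synonymous"),
                   annotated_variant(gene = "PTEN",
                                     consequence = "synonymous"))
  ts2 <- triage_sample("S1", all_syn)
  expect_equal(nrow(ts2$pathogenic_somatic), 0L)
  expect_equal(unname(ts2$stage_counts[["raw"]]), 2L)
  expect_equal(ts2$rejected$rejection_stage, c("synonymous", "synonymous"))
})

test_that("concurrent high-support mutations in one gene are both retained", {
  v <- rbind(annotated_variant(sample_id = "71", gene = "KIT",
                               protein_change = "p.Tyr553Ser",
                               total_depth = 2000L, variant_reads = 636L,
                               allele_frequency = 0.318),
             annotated_variant(sample_id = "71", gene = "KIT",
                               protein_change = "p.Tyr578Cys",
                               total_depth = 2000L, variant_reads = 878L,
                               allele_frequency = 0.439))
  v$protein_change <- normalize_protein_change(v$protein_change)
  ts <- triage_sample("71", v)
  expect_setequal(ts$pathogenic_somatic$protein_change,
                  c("p.Y553S", "p.Y578C"))
})

test_that("the three buckets always partition the input", {
  for (seed in c(1L, 2L, 3L)) {
    v <- random_variant_table(200L, seed)
    ts <- triage_sample("SX", v)
    expect_equal(nrow(ts$pathogenic_somatic) + nrow(ts$polymorphisms) +
                   nrow(ts$rejected), nrow(v))
    expect_equal(sort(c(ts$pathogenic_somatic$pos, ts$polymorphisms$pos,
                        ts$rejected$pos)), sort(v$pos))
  }
})

test_that("lowering thresholds never drops a previously retained variant", {
  v <- random_variant_table(300L, 17L)
  strict <- triage_sample("SX", v)
  lax <- triage_sample("SX", v,
                       triage_thresholds(min_total_depth = 100L,
                                         min_variant_reads = 5L,
                                         max_caller_pvalue = 0.05,
                                         benign_votes_to_exclude = 4L))
  expect_true(all(strict$pathogenic_somatic$pos %in%
                    lax$pathogenic_somatic$pos))
})

test_that("staged cascade equals the single-pass brute-force predicate", {
  v <- random_variant_table(1000L, 99L)
  want <- brute_force_bucket(v)
  ts <- triage_sample("SX", v)
  expect_equal(sort(ts$pathogenic_somatic$pos), sort(v$pos[want == "pathogenic"]))
  expect_equal(sort(ts$polymorphisms$pos), sort(v$pos[want == "polymorphism"]))
  expect_equal(sort(ts$rejected$pos), sort(v$pos[want == "rejected"]))
})

test_that("triage is idempotent on its own pathogenic output", {
  v <- random_variant_table(400L, 55L)
  once <- triage_sample("SX", v)
  twice <- triage_sample("SX", once$pathogenic_somatic)
  expect_equal(twice$pathogenic_somatic, once$pathogenic_somatic,
               ignore_attr = TRUE)
  expect_equal(nrow(twice$rejected), 0L)
})
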