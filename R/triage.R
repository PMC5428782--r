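## The variant triage cascade: raw annotated calls -> pathogenic somatic
## variants, germline polymorphisms, and rejected calls with the stage at
## which each was dropped.
##
## Stage order: region/consequence filter -> read-support filter ->
## in-silico pathogenicity consensus -> germline-polymorphism partition.
## TERT promoter calls bypass the region filter and the predictor consensus
## (they are genotyped independently of the protein-impact machinery) but are
## still held to the read-support thresholds.

#' Triage thresholds
#'
#' Cut-offs of the read-support filter and the pathogenicity consensus vote.
#' Defaults: total depth >= 500 reads, variant reads >= 20, caller p-value
#' < 0.01, and exclusion when at least 3 of the 5 predictors call the variant
#' benign.
#'
#' @param min_total_depth minimum total coverage (reads) at the locus.
#' @param min_variant_reads minimum reads supporting the variant allele.
#' @param max_caller_pvalue strict upper bound on the caller's p-value.
#' @param benign_votes_to_exclude explicit benign verdicts needed to exclude.
#' @param n_predictors number of predictor slots (fixed panel of five tools).
#' @return Object of class `triage_thresholds`.
#' @export
triage_thresholds <- function(min_total_depth = 500L, min_variant_reads = 20L,
                              max_caller_pvalue = 0.01,
                              benign_votes_to_exclude = 3L, n_predictors = 5L) {
  stopifnot(min_total_depth > 0, min_variant_reads > 0, max_caller_pvalue > 0,
            benign_votes_to_exclude > 0,
            benign_votes_to_exclude <= n_predictors)
  structure(list(min_total_depth = min_total_depth,
                 min_variant_reads = min_variant_reads,
                 max_caller_pvalue = max_caller_pvalue,
                 benign_votes_to_exclude = benign_votes_to_exclude,
                 n_predictors = n_predictors),
            class = "triage_thresholds")
}

#' Germline polymorphism catalog
#'
#' Known melanoma-related germline polymorphisms keyed by (gene, protein
#' change). The default catalog holds the recurrent MC1R red-hair-colour
#' alleles, the CDK4 R24/L22 germline changes and MITF p.E318K. Any
#' dbSNP-flagged, non-COSMIC-recurrent call is additionally treated as a
#' polymorphism at partition time. User entries extend the default.
#'
#' @param entries optional data.frame with columns `gene`, `protein_change`
#'   to append (protein changes are HGVS-p normalized on entry).
#' @return data.frame of class `polymorphism_catalog`.
#' @export
polymorphism_catalog <- function(entries = NULL) {
  base <- data.frame(
    gene = c(rep("MC1R", 5L), rep("CDK4", 3L), "MITF"),
    protein_change = c("p.V60L", "p.V92M", "p.R160W", "p.D294H", "p.R151C",
                       "p.R24H", "p.R24C", "p.L22R",
                       "p.E318K"),
    stringsAsFactors = FALSE)
  if (!is.null(entries)) {
    stopifnot(all(c("gene", "protein_change") %in% names(entries)))
    entries$protein_change <- normalize_protein_change(entries$protein_change)
    base <- unique(rbind(base, entries[, c("gene", "protein_change")]))
  }
  structure(base, class = c("polymorphism_catalog", "data.frame"))
}

in_catalog <- function(variants, catalog) {
  paste(variants$gene, variants$protein_change) %in%
    paste(catalog$gene, catalog$protein_change)
}

#' Region/consequence filter
#'
#' Retains exonic, non-synonymous records. Promoter-class records (TERT
#' promoter hotspots) bypass this filter and are carried forward for separate
#' handling. Record order is preserved.
#'
#' @param variants variant data.frame.
#' @return Subset of `variants`.
#' @export
filter_exonic_functional <- function(variants) {
  keep <- (variants$region_class == "exonic" &
             variants$consequence != "synonymous") |
    variants$region_class == "promoter"
  variants[keep, , drop = FALSE]
}

#' Read-support filter
#'
#' Keeps records with `total_depth >= min_total_depth`, `variant_reads >=
#' min_variant_reads` and `caller_pvalue < max_caller_pvalue` (boundary
#' semantics: >=, >=, strict <).
#'
#' @param variants variant data.frame.
#' @param thresholds a [triage_thresholds()] object.
#' @return Subset of `variants`.
#' @export
filter_by_support <- function(variants, thresholds = triage_thresholds()) {
  if (any(variants$total_depth < 0 | variants$variant_reads < 0))
    stop("support filter validation error: negative read count", call. = FALSE)
  keep <- variants$total_depth >= thresholds$min_total_depth &
    variants$variant_reads >= thresholds$min_variant_reads &
    variants$caller_pvalue < thresholds$max_caller_pvalue
  variants[keep, , drop = FALSE]
}

#' In-silico pathogenicity consensus vote
#'
#' A variant is excluded when at least `benign_votes_to_exclude` of the five
#' predictor verdicts are explicitly benign; `unknown` never counts as benign.
#' COSMIC-recurrent hotspots always pass (recurrence screening precedes the
#' variant-of-unknown-significance vote), as do promoter-class records.
#'
#' @param variants variant data.frame (one or more rows).
#' @param thresholds a [triage_thresholds()] object.
#' @return Character vector, `"keep"` or `"exclude_benign"` per record.
#' @export
consensus_pathogenicity <- function(variants, thresholds = triage_thresholds()) {
  verdicts <- as.matrix(variants[, predictor_columns(), drop = FALSE])
  n_benign <- rowSums(verdicts == "benign")
  excl <- n_benign >= thresholds$benign_votes_to_exclude &
    !variants$cosmic_recurrent &
    variants$region_class != "promoter"
  ifelse(excl, "exclude_benign", "keep")
}

#' Partition filtered calls into somatic variants and germline polymorphisms
#'
#' A record is a polymorphism when its (gene, protein change) is in the
#' catalog — regardless of predictor verdicts — or when it is dbSNP-flagged
#' germline and not COSMIC-recurrent. Outputs are disjoint and their union is
#' the input.
#'
#' @param variants variant data.frame.
#' @param catalog a [polymorphism_catalog()].
#' @return List with elements `somatic` and `polymorphisms`.
#' @export
partition_germline_polymorphisms <- function(variants,
                                             catalog = polymorphism_catalog()) {
  is_poly <- in_catalog(variants, catalog) |
    (variants$dbsnp_germline & !variants$cosmic_recurrent)
  list(somatic = variants[!is_poly, , drop = FALSE],
       polymorphisms = variants[is_poly, , drop = FALSE])
}

#' Run the full triage cascade on one sample
#'
#' Applies, in order: region/consequence filter, read-support filter,
#' pathogenicity consensus, germline-polymorphism partition. The three output
#' buckets (pathogenic somatic, polymorphisms, rejected) partition the input;
#' `stage_counts` records the audit trail. Re-triaging the pathogenic output
#' returns it unchanged.
#'
#' @param sample_id sample identifier; all records must carry it.
#' @param raw_variants validated variant data.frame for this sample.
#' @param thresholds a [triage_thresholds()].
#' @param catalog a [polymorphism_catalog()].
#' @return Object of class `triaged_sample` with fields `sample_id`,
#'   `pathogenic_somatic`, `polymorphisms`, `rejected` (with a
#'   `rejection_stage` column over `non_exonic`, `synonymous`, `support`,
#'   `benign_consensus`), `tert_promoter` (view of promoter-class pathogenic
#'   records) and `stage_counts`.
#' @export
triage_sample <- function(sample_id, raw_variants,
                          thresholds = triage_thresholds(),
                          catalog = polymorphism_catalog()) {
  validate_variants(raw_variants)
  if (nrow(raw_variants) > 0L &&
      !all(raw_variants$sample_id == sample_id))
    stop("triage error: records not belonging to sample ", sample_id,
         call. = FALSE)
  rownames(raw_variants) <- NULL   # row names index the cascade bookkeeping

  rejected_parts <- list()         # accumulated so extra columns survive
  note_rejects <- function(vs, stage) {
    if (nrow(vs) == 0L) return()
    vs$rejection_stage <- stage
    rejected_parts[[length(rejected_parts) + 1L]] <<- vs
  }

  # stage 1: region / consequence
  s1 <- filter_exonic_functional(raw_variants)
  dropped <- raw_variants[!rownames(raw_variants) %in% rownames(s1), ,
                          drop = FALSE]
  note_rejects(dropped[dropped$region_class != "exonic", , drop = FALSE],
               "non_exonic")
  note_rejects(dropped[dropped$region_class == "exonic", , drop = FALSE],
               "synonymous")

  # stage 2: read support
  s2 <- filter_by_support(s1, thresholds)
  note_rejects(s1[!rownames(s1) %in% rownames(s2), , drop = FALSE], "support")

  # stage 3: predictor consensus — applies to variants of unknown
  # significance only; records the database screen will partition as
  # germline polymorphisms are exempt from the vote
  is_poly2 <- in_catalog(s2, catalog) |
    (s2$dbsnp_germline & !s2$cosmic_recurrent)
  call3 <- if (nrow(s2) > 0L) consensus_pathogenicity(s2, thresholds)
           else character(0)
  keep3 <- is_poly2 | call3 == "keep"
  s3 <- s2[keep3, , drop = FALSE]
  note_rejects(s2[!keep3, , drop = FALSE], "benign_consensus")

  # stage 4: germline polymorphism partition
  part <- partition_germline_polymorphisms(s3, catalog)

  rejected <- if (length(rejected_parts) > 0L) do.call(rbind, rejected_parts)
  else {
    r0 <- raw_variants[0L, , drop = FALSE]
    r0$rejection_stage <- character(0)
    r0
  }
  somatic <- part$somatic
  rownames(somatic) <- rownames(part$polymorphisms) <- rownames(rejected) <- NULL
  structure(list(
    sample_id = sample_id,
    pathogenic_somatic = somatic,
    polymorphisms = part$polymorphisms,
    rejected = rejected,
    tert_promoter = somatic[somatic$region_class == "promoter", ,
                            drop = FALSE],
    stage_counts = c(raw = nrow(raw_variants),
                     exonic_functional = nrow(s1),
                     support_pass = nrow(s2),
                     prediction_pass = nrow(s3),
                     somatic_final = nrow(somatic))),
    class = "triaged_sample")
}

#' @export
print.triaged_sample <- function(x, ...) {
  sc <- x$stage_counts
  cat(sprintf(paste0("Triaged sample %s: %d raw -> %d exonic/functional -> ",
                     "%d support -> %d non-benign -> %d pathogenic somatic ",
                     "(+%d polymorphisms)\n"),
              x$sample_id, sc[["raw"]], sc[["exonic_functional"]],
              sc[["support_pass"]], sc[["prediction_pass"]],
              sc[["somatic_final"]], nrow(x$polymorphisms)))
  invisible(x)
}
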