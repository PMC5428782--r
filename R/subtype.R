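## TCGA-style four-class genomic subtyping (BRAF / RAS / NF1 / triple-wt),
## per-gene mutation prevalence, and co-occurrence / mutual-exclusivity
## summaries over a triaged cohort.

#' Genomic subtype classification rules
#'
#' Driver-gene membership and qualifying-variant rules for the four TCGA
#' cutaneous melanoma classes. Defaults: BRAF qualifies on the named hotspot
#' changes plus any change at codons 600/601/597; RAS (NRAS/KRAS/HRAS)
#' accepts any non-synonymous change (covering the codon 12/13/61 hotspots
#' and the rarer A146/E62 alleles); NF1 requires a loss-of-function
#' consequence (nonsense or frameshift). In `precedence` mode the first class
#' in `precedence` order with a qualifying variant wins and additional
#' qualifying classes are recorded as concurrent flags; `strict` mode returns
#' `ambiguous` when more than one class qualifies.
#'
#' @param braf_hotspots protein changes that always qualify for BRAF.
#' @param braf_codons codons whose non-synonymous changes qualify for BRAF.
#' @param braf_any_nonsyn accept any non-synonymous BRAF change.
#' @param ras_genes RAS family gene symbols.
#' @param ras_hotspot_codons canonical activating codons.
#' @param ras_any_nonsyn accept any non-synonymous RAS change (default TRUE).
#' @param nf1_lof_consequences consequences counting as NF1 loss of function.
#' @param nf1_allow_missense also accept NF1 missense changes.
#' @param precedence class order used to break concurrences.
#' @param mode `"precedence"` or `"strict"`.
#' @return Object of class `subtype_rules`.
#' @export
subtype_rules <- function(braf_hotspots = c("p.V600E", "p.V600K", "p.V600R",
                                            "p.V600D", "p.K601E", "p.L597R",
                                            "p.L597S"),
                          braf_codons = c(600L, 601L, 597L),
                          braf_any_nonsyn = FALSE,
                          ras_genes = c("NRAS", "KRAS", "HRAS"),
                          ras_hotspot_codons = c(12L, 13L, 61L),
                          ras_any_nonsyn = TRUE,
                          nf1_lof_consequences = c("nonsense", "frameshift"),
                          nf1_allow_missense = FALSE,
                          precedence = c("BRAF", "RAS", "NF1"),
                          mode = c("precedence", "strict")) {
  mode <- match.arg(mode)
  if (!setequal(precedence, c("BRAF", "RAS", "NF1")))
    stop("subtype rules error: precedence must permute BRAF, RAS, NF1",
         call. = FALSE)
  structure(list(braf_hotspots = braf_hotspots, braf_codons = braf_codons,
                 braf_any_nonsyn = braf_any_nonsyn, ras_genes = ras_genes,
                 ras_hotspot_codons = ras_hotspot_codons,
                 ras_any_nonsyn = ras_any_nonsyn,
                 nf1_lof_consequences = nf1_lof_consequences,
                 nf1_allow_missense = nf1_allow_missense,
                 precedence = precedence, mode = mode),
            class = "subtype_rules")
}

# logical vector: which variants qualify a sample for `cls`
qualifies_class <- function(variants, cls, rules) {
  if (nrow(variants) == 0L) return(logical(0))
  nonsyn <- variants$consequence != "synonymous" &
    variants$region_class == "exonic"
  codon <- protein_codon(variants$protein_change)
  switch(cls,
    BRAF = variants$gene == "BRAF" & nonsyn &
      (rules$braf_any_nonsyn |
         variants$protein_change %in% rules$braf_hotspots |
         (!is.na(codon) & codon %in% rules$braf_codons)),
    RAS = variants$gene %in% rules$ras_genes & nonsyn &
      (rules$ras_any_nonsyn |
         (!is.na(codon) & codon %in% rules$ras_hotspot_codons)),
    NF1 = variants$gene == "NF1" &
      (variants$consequence %in% rules$nf1_lof_consequences |
         (rules$nf1_allow_missense & variants$consequence == "missense")),
    stop("unknown driver class ", cls, call. = FALSE))
}

#' Assign the genomic subtype of a triaged sample
#'
#' @param sample a `triaged_sample` (its pathogenic somatic variants are
#'   used), or a variant data.frame.
#' @param rules a [subtype_rules()] object.
#' @return Object of class `subtype_call`: `sample_id`, `subtype` (one of
#'   BRAF, RAS, NF1, triple_wt, ambiguous), `supporting_variants`,
#'   `concurrent_flags` (list of class pairs present).
#' @export
classify_genomic_subtype <- function(sample, rules = subtype_rules()) {
  variants <- if (inherits(sample, "triaged_sample"))
    sample$pathogenic_somatic else sample
  sample_id <- if (inherits(sample, "triaged_sample")) sample$sample_id
               else if (nrow(variants) > 0L) variants$sample_id[1L] else NA

  qual <- lapply(rules$precedence, qualifies_class,
                 variants = variants, rules = rules)
  names(qual) <- rules$precedence
  has_class <- vapply(qual, any, logical(1))
  classes <- names(has_class)[has_class]

  if (length(classes) == 0L) {
    subtype <- "triple_wt"; support <- variants[0L, , drop = FALSE]
    flags <- list()
  } else if (rules$mode == "strict" && length(classes) > 1L) {
    subtype <- "ambiguous"
    support <- variants[Reduce(`|`, qual), , drop = FALSE]
    flags <- utils::combn(classes, 2L, simplify = FALSE)
  } else {
    subtype <- classes[1L]
    support <- variants[qual[[subtype]], , drop = FALSE]
    flags <- lapply(setdiff(classes, subtype), function(other)
      c(subtype, other))
  }
  structure(list(sample_id = sample_id, subtype = subtype,
                 supporting_variants = support, concurrent_flags = flags),
            class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  cat(sprintf("Sample %s: %s subtype (%d supporting variant(s)%s)\n",
              x$sample_id, x$subtype, nrow(x$supporting_variants),
              if (length(x$concurrent_flags))
                paste0("; concurrent: ",
                       paste(vapply(x$concurrent_flags, paste,
                                    character(1), collapse = "+"),
                             collapse = ", "))
              else ""))
  invisible(x)
}

#' Subtype an entire cohort
#'
#' @param cohort list of `triaged_sample` objects.
#' @param rules a [subtype_rules()].
#' @return data.frame with one row per sample: `sample_id`, `subtype`,
#'   `n_supporting`, `concurrent`.
#' @export
classify_cohort <- function(cohort, rules = subtype_rules()) {
  calls <- lapply(cohort, classify_genomic_subtype, rules = rules)
  data.frame(
    sample_id = vapply(calls, function(x) as.character(x$sample_id),
                       character(1)),
    subtype = vapply(calls, `[[`, character(1), "subtype"),
    n_supporting = vapply(calls, function(x) nrow(x$supporting_variants),
                          integer(1)),
    concurrent = vapply(calls, function(x)
      paste(vapply(x$concurrent_flags, paste, character(1), collapse = "+"),
            collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}

# variants a sample retained through region+support stages (any filtered-in
# call: pathogenic, benign-consensus-excluded, or catalog polymorphism)
filtered_in_variants <- function(ts) {
  rbind(ts$pathogenic_somatic[, variant_columns(), drop = FALSE],
        ts$polymorphisms[, variant_columns(), drop = FALSE],
        ts$rejected[ts$rejected$rejection_stage == "benign_consensus",
                    variant_columns(), drop = FALSE])
}

#' Per-gene mutation prevalence over a cohort
#'
#' Fraction of samples carrying at least one qualifying variant in `gene`.
#' With `pathogenic_only = TRUE` (default) only post-consensus pathogenic
#' somatic variants count; with `FALSE` every call surviving the region and
#' read-support stages counts (the "any variation" vs "pathogenic variant"
#' distinction in gene-level reporting).
#'
#' @param cohort non-empty list of `triaged_sample` objects.
#' @param gene HGNC symbol.
#' @param pathogenic_only see above.
#' @return List: `fraction`, `count`, `n`.
#' @export
gene_prevalence <- function(cohort, gene, pathogenic_only = TRUE) {
  if (length(cohort) == 0L)
    stop("gene_prevalence error: empty cohort", call. = FALSE)
  hit <- vapply(cohort, function(ts) {
    vs <- if (pathogenic_only) ts$pathogenic_somatic
          else filtered_in_variants(ts)
    gene %in% vs$gene
  }, logical(1))
  list(fraction = mean(hit), count = sum(hit), n = length(cohort))
}

#' Mutation prevalence table for a gene list
#'
#' @param cohort list of `triaged_sample` objects.
#' @param genes character vector of gene symbols.
#' @return data.frame: gene, count, n, fraction (pathogenic-only), plus
#'   `any_count`/`any_fraction` for the pre-consensus definition.
#' @export
prevalence_table <- function(cohort, genes) {
  rows <- lapply(genes, function(g) {
    p <- gene_prevalence(cohort, g, pathogenic_only = TRUE)
    a <- gene_prevalence(cohort, g, pathogenic_only = FALSE)
    data.frame(gene = g, count = p$count, n = p$n, fraction = p$fraction,
               any_count = a$count, any_fraction = a$fraction,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Co-occurrence counts between two gene sets
#'
#' Classifies each sample by pathogenic somatic mutation status in two
#' disjoint gene sets and reports the 2x2 sample counts plus the mutual
#' exclusivity fraction `1 - both/total`.
#'
#' @param cohort list of `triaged_sample` objects.
#' @param genes_a,genes_b disjoint character vectors of gene symbols.
#' @return List: `a_only`, `b_only`, `both`, `neither`, `exclusivity`.
#' @export
cooccurrence_counts <- function(cohort, genes_a, genes_b) {
  if (length(intersect(genes_a, genes_b)) > 0L)
    stop("cooccurrence error: gene sets overlap", call. = FALSE)
  in_set <- function(ts, genes) any(ts$pathogenic_somatic$gene %in% genes)
  a <- vapply(cohort, in_set, logical(1), genes = genes_a)
  b <- vapply(cohort, in_set, logical(1), genes = genes_b)
  list(a_only = sum(a & !b), b_only = sum(!a & b), both = sum(a & b),
       neither = sum(!a & !b),
       exclusivity = 1 - sum(a & b) / length(cohort))
}
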