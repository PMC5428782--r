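## Domain model for annotated variant calls coming off a targeted amplicon
## panel (Ion Torrent-style caller output after annotation).  A variant table
## is an ordinary data.frame with a fixed column contract; per-record
## validation enforces the invariants the downstream triage cascade assumes.

#' Column contract for annotated variant tables
#'
#' Names and order of the columns every variant table carries. Predictor
#' verdicts occupy five dedicated columns (one per in-silico tool).
#'
#' @return Character vector of column names.
#' @export
variant_columns <- function() {
  c("sample_id", "gene", "chrom", "pos", "ref", "alt", "protein_change",
    "region_class", "consequence", "total_depth", "variant_reads",
    "allele_frequency", "caller_pvalue",
    "provean", "sift", "polyphen2", "snps_go", "condel",
    "cosmic_recurrent", "dbsnp_germline")
}

#' @rdname variant_columns
#' @export
predictor_columns <- function() c("provean", "sift", "polyphen2", "snps_go", "condel")

region_levels      <- c("exonic", "intronic", "UTR", "promoter")
consequence_levels <- c("missense", "nonsense", "frameshift", "inframe_indel",
                        "synonymous", "other")
verdict_levels     <- c("benign", "damaging", "unknown")

#' Construct a single annotated variant record
#'
#' Convenience constructor used heavily by tests and the synthetic-cohort
#' generator; returns a one-row data.frame obeying [variant_columns()].
#' `allele_frequency` defaults to `variant_reads / total_depth`.
#'
#' @param sample_id,gene,chrom,pos,ref,alt,protein_change identifying fields;
#'   `protein_change` is one-letter HGVS-p (e.g. `"p.V600E"`) or a promoter
#'   offset label (e.g. `"-146C>T"`).
#' @param region_class one of exonic, intronic, UTR, promoter.
#' @param consequence one of missense, nonsense, frameshift, inframe_indel,
#'   synonymous, other.
#' @param total_depth,variant_reads read support at the locus.
#' @param allele_frequency fraction in \[0, 1\].
#' @param caller_pvalue per-variant quality p-value emitted by the upstream
#'   caller (stored, never computed here).
#' @param provean,sift,polyphen2,snps_go,condel predictor verdicts, each one
#'   of benign, damaging, unknown.
#' @param cosmic_recurrent,dbsnp_germline database flags.
#' @return One-row data.frame.
#' @export
annotated_variant <- function(sample_id = "S1", gene = "BRAF", chrom = "chr7",
                              pos = 140453136L, ref = "A", alt = "T",
                              protein_change = "p.V600E",
                              region_class = "exonic", consequence = "missense",
                              total_depth = 2000L, variant_reads = 500L,
                              allele_frequency = variant_reads / total_depth,
                              caller_pvalue = 1e-6,
                              provean = "damaging", sift = "damaging",
                              polyphen2 = "damaging", snps_go = "damaging",
                              condel = "damaging",
                              cosmic_recurrent = FALSE, dbsnp_germline = FALSE) {
  data.frame(sample_id = sample_id, gene = gene, chrom = chrom,
             pos = as.integer(pos), ref = ref, alt = alt,
             protein_change = protein_change, region_class = region_class,
             consequence = consequence, total_depth = as.integer(total_depth),
             variant_reads = as.integer(variant_reads),
             allele_frequency = allele_frequency,
             caller_pvalue = caller_pvalue, provean = provean, sift = sift,
             polyphen2 = polyphen2, snps_go = snps_go, condel = condel,
             cosmic_recurrent = cosmic_recurrent,
             dbsnp_germline = dbsnp_germline, stringsAsFactors = FALSE)
}

#' Validate a variant table against the domain invariants
#'
#' Checks the column contract, enumerated vocabularies, and per-record
#' invariants: `variant_reads <= total_depth`, `pos >= 1`, and
#' `|allele_frequency - variant_reads/total_depth| <= 0.01` when both support
#' fields are present. Errors name the offending field and record.
#'
#' @param variants data.frame of variant records.
#' @return The validated data.frame, invisibly usable in a pipe.
#' @export
validate_variants <- function(variants) {
  stopifnot(is.data.frame(variants))
  missing_cols <- setdiff(variant_columns(), names(variants))
  if (length(missing_cols) > 0L)
    stop("variant table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(variants) == 0L) return(invisible(variants))

  locate <- function(bad, what) {
    i <- which(bad)[1L]
    stop(sprintf("variant validation error: %s (record %d, sample %s, %s %s)",
                 what, i, variants$sample_id[i], variants$gene[i],
                 variants$protein_change[i]), call. = FALSE)
  }
  check_enum <- function(col, levels) {
    bad <- !(variants[[col]] %in% levels)
    if (any(bad)) locate(bad, sprintf("invalid %s value '%s'",
                                      col, variants[[col]][which(bad)[1L]]))
  }
  check_enum("region_class", region_levels)
  check_enum("consequence", consequence_levels)
  for (p in predictor_columns()) check_enum(p, verdict_levels)

  if (any(bad <- variants$pos < 1L)) locate(bad, "pos < 1")
  if (any(bad <- variants$total_depth < 0L | variants$variant_reads < 0L))
    locate(bad, "negative read count")
  if (any(bad <- variants$variant_reads > variants$total_depth))
    locate(bad, "variant_reads > total_depth")

  have_af <- !is.na(variants$allele_frequency) & variants$total_depth > 0L
  if (any(bad <- have_af &
            (variants$allele_frequency < 0 | variants$allele_frequency > 1)))
    locate(bad, "allele_frequency outside [0, 1]")
  af_imp <- variants$variant_reads / pmax(variants$total_depth, 1L)
  if (any(bad <- have_af &
            abs(variants$allele_frequency - af_imp) > 0.01))
    locate(bad, "allele_frequency inconsistent with variant_reads/total_depth")
  invisible(variants)
}

# three-letter -> one-letter amino-acid map (HGVS-p short form)
aa3to1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
            Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
            Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
            Tyr = "Y", Val = "V", Ter = "*")

#' Normalize a protein change to one-letter HGVS-p short form
#'
#' Converts three-letter forms such as `"p.Val600Glu"` to `"p.V600E"` and
#' `"p.Trp1512Ter"`/`"p.Trp1512*"` to `"p.W1512*"`. Promoter offset labels
#' (anything not starting with `"p."`) and already-short forms pass through
#' unchanged.
#'
#' @param x character vector of protein-change labels.
#' @return Character vector, same length.
#' @export
normalize_protein_change <- function(x) {
  out <- x
  is_p <- !is.na(x) & startsWith(x, "p.")
  conv <- function(s) {
    body <- sub("^p\\.", "", s)
    for (a3 in names(aa3to1))
      body <- gsub(a3, aa3to1[[a3]], body, fixed = TRUE)
    paste0("p.", body)
  }
  out[is_p] <- vapply(x[is_p], conv, character(1), USE.NAMES = FALSE)
  out
}

#' Extract the affected codon from a one-letter HGVS-p label
#'
#' @param x character vector like `"p.V600E"`, `"p.W1512*"`.
#' @return Integer vector of codon numbers; `NA` where no codon is parseable
#'   (promoter labels, frameshift suffixes are tolerated).
#' @export
protein_codon <- function(x) {
  m <- regmatches(x, regexpr("^p\\.[A-Z*][0-9]+", x))
  out <- rep(NA_integer_, length(x))
  hit <- grepl("^p\\.[A-Z*][0-9]+", x)
  out[hit] <- as.integer(sub("^p\\.[A-Z*]", "", m))
  out
}

#' Targeted panel design
#'
#' Container for the gene content and amplicon layout of the custom panel.
#' Amplicon intervals are 0-based half-open (BED convention).
#'
#' @param genes character vector of HGNC symbols on the panel.
#' @param amplicons data.frame with columns chrom, start, end.
#' @return Object of class `panel_design` with `genes`, `amplicons`,
#'   `n_amplicons` and `total_bases` (sum of interval widths).
#' @export
panel_design <- function(genes, amplicons) {
  stopifnot(length(genes) > 0L,
            all(c("chrom", "start", "end") %in% names(amplicons)))
  width <- amplicons$end - amplicons$start
  if (any(width < 125 | width > 175))
    stop("panel design error: amplicon length outside [125, 175] bp",
         call. = FALSE)
  structure(list(genes = genes,
                 amplicons = amplicons[, c("chrom", "start", "end")],
                 n_amplicons = nrow(amplicons),
                 total_bases = sum(width)),
            class = "panel_design")
}

#' @export
print.panel_design <- function(x, ...) {
  cat(sprintf("Targeted panel: %d genes, %d amplicons, %d targeted bases\n",
              length(x$genes), x$n_amplicons, x$total_bases))
  invisible(x)
}

## vocabulary for the clinicopathological feature table
feature_levels <- list(
  sex           = c("male", "female"),
  anatomic_site = c("head/neck", "upper extremities", "trunk",
                    "lower extremities", "acral"),
  sun_exposure  = c("non-exposed", "occasionally", "usually"),   # ordered
  histology     = c("LMM", "SSM", "NM", "ALM"),
  breslow_class = c("<=1", "1-2", "2-4", ">4"),                  # ordered
  regression    = c("none", "<50%", ">50%"),
  growth_rate   = c("SGM", "FGM"),
  stage_class   = c("I-II", "III-IV")
)

#' Validate a cohort feature table
#'
#' Checks the categorical vocabulary of each clinicopathological feature and
#' the consistency of the Breslow class with the millimetre measurement.
#'
#' @param features data.frame with one row per sample.
#' @return The validated data.frame, invisibly.
#' @export
validate_features <- function(features) {
  needed <- c("sample_id", "age", names(feature_levels), "breslow_mm",
              "ulceration", "mitosis_high")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols) > 0L)
    stop("feature table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in names(feature_levels)) {
    bad <- !(features[[col]] %in% feature_levels[[col]])
    if (any(bad))
      stop(sprintf("feature validation error: invalid %s value '%s' (sample %s)",
                   col, features[[col]][which(bad)[1L]],
                   features$sample_id[which(bad)[1L]]), call. = FALSE)
  }
  implied <- breslow_class_of(features$breslow_mm)
  bad <- implied != features$breslow_class
  if (any(bad))
    stop(sprintf("feature validation error: breslow_class inconsistent with breslow_mm (sample %s)",
                 features$sample_id[which(bad)[1L]]), call. = FALSE)
  invisible(features)
}

#' Breslow thickness category from millimetres
#'
#' @param mm numeric vector of Breslow thickness in millimetres.
#' @return Character vector over `"<=1"`, `"1-2"`, `"2-4"`, `">4"`.
#' @export
breslow_class_of <- function(mm) {
  cut(mm, breaks = c(-Inf, 1, 2, 4, Inf),
      labels = c("<=1", "1-2", "2-4", ">4"), right = TRUE) |> as.character()
}
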