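## Readers and writers for the formats around the pipeline: the annotated
## variant table (TSV dialect or VCF 4.2 with annotation carried in INFO),
## the panel BED, the clinicopathological feature TSV, and JSON/TSV reports.

# default VCF INFO key for each annotation column
default_info_keys <- function() {
  c(sample_id = "SM", gene = "GENE", protein_change = "AAC",
    region_class = "FUNC", consequence = "CONSEQ", total_depth = "FDP",
    variant_reads = "FAO", allele_frequency = "AF", caller_pvalue = "PVAL",
    provean = "PROVEAN", sift = "SIFT", polyphen2 = "PPH2",
    snps_go = "SNPSGO", condel = "CONDEL", cosmic_recurrent = "COSMIC",
    dbsnp_germline = "DBSNP")
}

#' Read an annotated variant table
#'
#' Two dialects are supported: the package's documented tab-separated layout
#' (one column per [variant_columns()] entry) and VCF 4.2 with the annotation
#' fields carried in INFO keys. Unparseable optional predictor verdicts become
#' `"unknown"`; mandatory fields must be present. Every record is validated
#' against the domain invariants; record order is preserved.
#'
#' @param path file to read.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param info_keys named character vector mapping annotation columns to VCF
#'   INFO keys (VCF dialect only); defaults cover Ion-style keys FDP/FAO etc.
#' @return data.frame of validated variant records (possibly zero rows).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf"),
                               info_keys = default_info_keys()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("variant table I/O error: file not found: ", path, call. = FALSE)
  df <- if (dialect == "tsv") read_variant_tsv(path) else
    read_variant_vcf(path, info_keys)
  validate_variants(df)
  df
}

read_variant_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(variant_columns(), names(df))
  if (length(missing_cols) > 0L)
    stop("variant table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[, variant_columns()]
  coerce_variant_types(df)
}

coerce_variant_types <- function(df) {
  if (nrow(df) == 0L) return(empty_variant_table())
  int_cols <- c("pos", "total_depth", "variant_reads")
  num_cols <- c("allele_frequency", "caller_pvalue")
  lgl_cols <- c("cosmic_recurrent", "dbsnp_germline")
  for (col in int_cols) df[[col]] <- as.integer(df[[col]])
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])
  for (col in lgl_cols)
    df[[col]] <- if (is.logical(df[[col]])) df[[col]] else
      tolower(as.character(df[[col]])) %in% c("1", "true")
  for (p in predictor_columns()) {
    v <- df[[p]]
    v[is.na(v) | !(v %in% verdict_levels)] <- "unknown"
    df[[p]] <- v
  }
  df$protein_change <- normalize_protein_change(df$protein_change)
  rownames(df) <- NULL
  df
}

#' @rdname read_variant_table
#' @export
empty_variant_table <- function() {
  av <- annotated_variant()
  av[0L, , drop = FALSE]
}

read_variant_vcf <- function(path, info_keys) {
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(empty_variant_table())
  pull <- function(col, mandatory = TRUE) {
    key <- info_keys[[col]]
    v <- vcfR::extract.info(vcf, element = key)
    if (mandatory && (is.null(v) || all(is.na(v))))
      stop("variant table format error: missing INFO key ", key,
           " (field ", col, ")", call. = FALSE)
    if (is.null(v)) rep(NA_character_, nrow(fix)) else v
  }
  df <- data.frame(
    sample_id = pull("sample_id"), gene = pull("gene"),
    chrom = fix$CHROM, pos = fix$POS, ref = fix$REF, alt = fix$ALT,
    protein_change = pull("protein_change"),
    region_class = pull("region_class"), consequence = pull("consequence"),
    total_depth = pull("total_depth"), variant_reads = pull("variant_reads"),
    allele_frequency = pull("allele_frequency"),
    caller_pvalue = pull("caller_pvalue"),
    stringsAsFactors = FALSE)
  for (p in predictor_columns()) df[[p]] <- pull(p, mandatory = FALSE)
  df$cosmic_recurrent <- pull("cosmic_recurrent", mandatory = FALSE)
  df$dbsnp_germline <- pull("dbsnp_germline", mandatory = FALSE)
  df$cosmic_recurrent[is.na(df$cosmic_recurrent)] <- "0"
  df$dbsnp_germline[is.na(df$dbsnp_germline)] <- "0"
  coerce_variant_types(df)
}

#' Write an annotated variant table
#'
#' Inverse of [read_variant_table()] for both dialects. The VCF writer emits a
#' minimal VCF 4.2 with the annotation schema declared in the header and each
#' record's fields serialized into INFO.
#'
#' @param variants validated variant data.frame.
#' @param path output file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param info_keys as in [read_variant_table()].
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path, dialect = c("tsv", "vcf"),
                                info_keys = default_info_keys()) {
  dialect <- match.arg(dialect)
  validate_variants(variants)
  if (dialect == "tsv") {
    write.table(variants[, variant_columns()], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  hdr <- c("##fileformat=VCFv4.2",
           vapply(seq_along(info_keys), function(i) {
             sprintf('##INFO=<ID=%s,Number=1,Type=String,Description="%s">',
                     info_keys[[i]], names(info_keys)[i])
           }, character(1)),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants) == 0L) character(0) else
    vapply(seq_len(nrow(variants)), function(i) {
      v <- variants[i, ]
      fmt <- function(col) {
        val <- v[[col]]
        if (is.logical(val)) val <- as.integer(val)
        paste0(info_keys[[col]], "=", as.character(val))
      }
      info <- paste(vapply(names(info_keys), fmt, character(1)),
                    collapse = ";")
      paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
            sep = "\t")
    }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a panel definition from BED
#'
#' Amplicon intervals are read with `rtracklayer` (BED 0-based half-open
#' convention); the gene list is taken from the BED name column when present,
#' otherwise supplied explicitly.
#'
#' @param path BED file of amplicon intervals.
#' @param genes optional character vector of panel gene symbols; defaults to
#'   the unique BED name entries.
#' @return A [panel_design()] object.
#' @export
read_panel_bed <- function(path, genes = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  amp <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,   # back to 0-based
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (is.null(genes)) {
    nm <- gr$name
    if (is.null(nm)) stop("panel BED has no name column; supply `genes`",
                          call. = FALSE)
    genes <- unique(sub("_.*$", "", nm))
  }
  panel_design(genes, amp)
}

#' Read a cohort clinicopathological feature table
#'
#' Tab-separated, one row per sample, columns matching the documented
#' vocabulary (see [validate_features()]).
#'
#' @param path TSV file.
#' @return Validated data.frame.
#' @export
read_sample_features <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$ulceration <- as.logical(df$ulceration)
  df$mitosis_high <- as.logical(df$mitosis_high)
  validate_features(df)
  df
}

## ---- generic report serialization ------------------------------------------

serialize_report <- function(x) {
  if (inherits(x, "triaged_sample")) {
    list(type = "triaged_sample", sample_id = x$sample_id,
         columns = names(x$pathogenic_somatic),   # survive empty buckets
         pathogenic_somatic = x$pathogenic_somatic,
         polymorphisms = x$polymorphisms, rejected = x$rejected,
         tert_promoter = x$tert_promoter,
         stage_counts = as.list(x$stage_counts))
  } else if (inherits(x, "cohort_report")) {
    c(list(type = "cohort_report"), unclass(x))
  } else if (is.data.frame(x)) {
    list(type = "table", data = x)
  } else {
    stop("report schema error: cannot serialize object of class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
}

#' Write a pipeline product to disk
#'
#' JSON serialization (deterministic field order, typed envelope) for any
#' pipeline product; TSV for tabular products with a fixed column order.
#' JSON round trips through [read_report()] reproduce the object.
#'
#' @param x a triaged sample, association/subtype table, or cohort report.
#' @param path output file.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(x))
      stop("report schema error: TSV output requires a tabular product",
           call. = FALSE)
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  jsonlite::write_json(serialize_report(x), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON report written by [write_report()]
#'
#' @param path JSON file.
#' @return The deserialized product: a `triaged_sample`, a data.frame, or a
#'   `cohort_report` list.
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  restore_vt <- function(d, columns = variant_columns()) {
    if (is.null(d) || (is.list(d) && length(d) == 0L)) {
      out <- empty_variant_table()
      for (col in setdiff(columns, names(out))) out[[col]] <- character(0)
      return(out)
    }
    extra <- setdiff(names(d), variant_columns())
    out <- coerce_variant_types(as.data.frame(d, stringsAsFactors = FALSE))
    for (col in extra) out[[col]] <- d[[col]]
    out
  }
  type <- obj$type
  if (identical(type, "triaged_sample")) {
    cols <- if (is.null(obj$columns)) variant_columns() else obj$columns
    rej <- restore_vt(obj$rejected, c(cols, "rejection_stage"))
    if (!"rejection_stage" %in% names(rej))
      rej$rejection_stage <- character(nrow(rej))
    somatic <- restore_vt(obj$pathogenic_somatic, cols)
    structure(list(sample_id = obj$sample_id,
                   pathogenic_somatic = somatic,
                   polymorphisms = restore_vt(obj$polymorphisms, cols),
                   rejected = rej,
                   # derived view, rebuilt rather than deserialized
                   tert_promoter = somatic[somatic$region_class == "promoter",
                                           , drop = FALSE],
                   stage_counts = unlist(obj$stage_counts)),
              class = "triaged_sample")
  } else if (identical(type, "table")) {
    as.data.frame(obj$data, stringsAsFactors = FALSE)
  } else if (identical(type, "cohort_report")) {
    obj$type <- NULL
    structure(obj, class = "cohort_report")
  } else {
    stop("report schema error: unknown report type ", type, call. = FALSE)
  }
}
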