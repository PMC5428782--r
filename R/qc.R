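## Run- and panel-level coverage QC: mean amplicon coverage, percentage of
## targeted bases over depth thresholds, coverage uniformity, on-target rate.

#' Coverage profile of one sequencing run
#'
#' @param per_amplicon_mean_depth numeric vector of mean depths, one per
#'   panel amplicon.
#' @param amplicon_lengths optional amplicon lengths (bases) matched to the
#'   depths; used to weight base-level summaries when no per-base vector is
#'   given.
#' @param per_base_depth optional depth vector over all targeted bases.
#' @param total_reads,on_target_reads read counts for the on-target rate.
#' @return Object of class `coverage_profile`.
#' @export
coverage_profile <- function(per_amplicon_mean_depth, amplicon_lengths = NULL,
                             per_base_depth = NULL, total_reads = NA_real_,
                             on_target_reads = NA_real_) {
  if (length(per_amplicon_mean_depth) == 0L)
    stop("coverage profile error: empty profile", call. = FALSE)
  if (any(per_amplicon_mean_depth < 0) ||
      (!is.null(per_base_depth) && any(per_base_depth < 0)))
    stop("coverage profile error: negative depth", call. = FALSE)
  if (!is.na(total_reads) && !is.na(on_target_reads) &&
      on_target_reads > total_reads)
    stop("coverage profile error: on-target reads exceed total reads",
         call. = FALSE)
  structure(list(per_amplicon_mean_depth = per_amplicon_mean_depth,
                 amplicon_lengths = amplicon_lengths,
                 per_base_depth = per_base_depth,
                 total_reads = total_reads,
                 on_target_reads = on_target_reads),
            class = "coverage_profile")
}

#' Coverage QC summary
#'
#' Reports mean amplicon coverage, the percentage of targeted bases covered
#' at or above each threshold, coverage uniformity (percentage of targeted
#' bases with depth >= 0.2 x mean depth, the platform's conventional
#' definition) and the on-target read fraction. Percentages are on the 0-100
#' scale. Base-level metrics use the per-base depth vector when available,
#' otherwise per-amplicon depths weighted by amplicon length.
#'
#' @param profile a [coverage_profile()].
#' @param thresholds depth thresholds for the percent-covered metrics.
#' @return List: `mean_amplicon_coverage`, `pct_bases_ge` (named by
#'   threshold), `uniformity`, `on_target_fraction`.
#' @export
coverage_summary <- function(profile, thresholds = c(100, 500)) {
  base_depth <- if (!is.null(profile$per_base_depth)) profile$per_base_depth
  else if (!is.null(profile$amplicon_lengths))
    rep(profile$per_amplicon_mean_depth, times = profile$amplicon_lengths)
  else profile$per_amplicon_mean_depth
  mean_base <- mean(base_depth)
  pct <- vapply(thresholds, function(t) 100 * mean(base_depth >= t),
                numeric(1))
  names(pct) <- paste0("ge_", thresholds, "x")
  list(mean_amplicon_coverage = mean(profile$per_amplicon_mean_depth),
       pct_bases_ge = pct,
       uniformity = 100 * mean(base_depth >= 0.2 * mean_base),
       on_target_fraction = profile$on_target_reads / profile$total_reads)
}

#' Read a per-base depth table
#'
#' Three-column TSV (chrom, pos, depth) as produced by depth-profiling tools.
#'
#' @param path TSV file with a header.
#' @return data.frame with columns chrom, pos, depth.
#' @export
read_depth_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos", "depth") %in% names(df)))
    stop("depth table format error: need columns chrom, pos, depth",
         call. = FALSE)
  df
}
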