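## Dilution-series sensitivity model: expected allele fractions for serial
## mixes of a heterozygous mutant DNA into wild-type DNA, binomial read-count
## simulation with an additive background false-read rate, and a
## simulation-based limit-of-detection estimate.

#' Expected allele fraction of a 1:k dilution
#'
#' Mixing heterozygous mutant DNA (variant fraction `het_fraction`) into
#' wild-type DNA at ratio 1:k yields expected fraction
#' `het_fraction / (1 + k)`; k = 0 is the undiluted sample.
#'
#' @param het_fraction variant allele fraction of the undiluted DNA
#'   (0.5 for a heterozygous diploid line).
#' @param k wild-type parts per one part mutant DNA (>= 0).
#' @return Expected allele fraction.
#' @export
expected_dilution_af <- function(het_fraction = 0.5, k) {
  if (any(k < 0)) stop("dilution error: negative mixing ratio", call. = FALSE)
  het_fraction / (1 + k)
}

#' Serial dilution series design
#'
#' The default series mixes heterozygous (50%) mutant DNA at ratios
#' 1:1, 1:3, 1:24, 1:49, 1:99, 1:999 plus the undiluted sample, giving
#' nominal variant fractions 25%, 12.5%, 2%, 1%, 0.5%, 0.05% (and 50%).
#'
#' @param het_allele_fraction variant fraction of the undiluted mutant DNA.
#' @param ratios wild-type:mutant mixing ratios `k` (0 = undiluted).
#' @param depths per-point sequencing depth, recycled to the series length.
#' @param error_rate background false-read fraction toward the variant
#'   allele (in \[0, 0.05\]).
#' @return Object of class `dilution_series` with a `points` data.frame
#'   (ratio_k, expected_af, depth) ordered by decreasing expected fraction,
#'   and an `observed` slot filled by [generate_dilution_experiment()].
#' @export
dilution_series <- function(het_allele_fraction = 0.5,
                            ratios = c(0, 1, 3, 24, 49, 99, 999),
                            depths = 3000L, error_rate = 0.001) {
  if (error_rate < 0 || error_rate > 0.05)
    stop("dilution error: error_rate outside [0, 0.05]", call. = FALSE)
  af <- expected_dilution_af(het_allele_fraction, ratios)
  ord <- order(af, decreasing = TRUE)
  if (anyDuplicated(af)) stop("dilution error: duplicate dilution points",
                              call. = FALSE)
  pts <- data.frame(ratio_k = ratios[ord], expected_af = af[ord],
                    depth = as.integer(rep_len(depths, length(ratios))[ord]))
  structure(list(het_allele_fraction = het_allele_fraction, points = pts,
                 error_rate = error_rate, observed = NULL),
            class = "dilution_series")
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("Dilution series: %d points, %.2g%%-%.2g%% expected AF, error rate %.2g%%\n",
              nrow(x$points), 100 * max(x$points$expected_af),
              100 * min(x$points$expected_af), 100 * x$error_rate))
  invisible(x)
}

#' Simulate variant read counts at one dilution point
#'
#' Each replicate draws `Binomial(depth, true_af + error_rate)`: the
#' background false-read rate is folded into a single additive per-read
#' probability toward the variant allele.
#'
#' @param true_af true variant allele fraction.
#' @param depth reads at the locus (>= 1).
#' @param error_rate background false-read fraction.
#' @param n_replicates number of replicates to draw.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return Integer vector of variant read counts, length `n_replicates`.
#' @export
simulate_read_counts <- function(true_af, depth, error_rate = 0.001,
                                 n_replicates = 1L, seed = NULL) {
  p <- true_af + error_rate
  if (depth < 1 || true_af < 0 || error_rate < 0 || p > 1)
    stop("read-count simulation error: invalid probability or depth",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rbinom(n_replicates, size = depth, prob = p)
}

#' Simulation-based limit of detection for a dilution series
#'
#' For each series point, a variant is called detected when its variant read
#' count strictly exceeds the `(1 - alpha)` quantile of the binomial error
#' null `Binomial(depth, error_rate)`. The limit of detection is the smallest
#' expected allele fraction whose simulated detection frequency reaches
#' `power_target`; `Inf` when no point qualifies.
#'
#' @param series a [dilution_series()].
#' @param alpha tail probability of the error-null detection threshold.
#' @param power_target required detection frequency.
#' @param n_replicates simulated replicates per point.
#' @param seed integer seed (one stream across all points).
#' @return The LOD as an allele fraction, with the per-point power table
#'   attached as attribute `"detection"`.
#' @export
estimate_lod <- function(series = dilution_series(), alpha = 0.01,
                         power_target = 0.95, n_replicates = 1000L,
                         seed = 20170329L) {
  pts <- series$points
  set.seed(seed)
  det <- lapply(seq_len(nrow(pts)), function(i) {
    threshold <- qbinom(1 - alpha, pts$depth[i], series$error_rate)
    counts <- simulate_read_counts(pts$expected_af[i], pts$depth[i],
                                   series$error_rate, n_replicates)
    data.frame(expected_af = pts$expected_af[i], depth = pts$depth[i],
               threshold = threshold, power = mean(counts > threshold))
  })
  det <- do.call(rbind, det)
  ok <- det$power >= power_target
  lod <- if (any(ok)) min(det$expected_af[ok]) else Inf
  structure(lod, detection = det)
}
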