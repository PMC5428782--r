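## Clinicopathological association statistics: cross-product Wald odds
## ratios with Woolf log-SE confidence intervals for 2x2 tables, logistic
## maximum likelihood for general designs, per-level ordinal-trend odds
## ratios, and the gene-by-feature screening battery.

#' 2x2 contingency table of mutation status by exposure
#'
#' @param a mutated & exposed count.
#' @param b wildtype & exposed count.
#' @param c mutated & unexposed count.
#' @param d wildtype & unexposed count.
#' @return Object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("contingency table error: negative count",
                            call. = FALSE)
  if (sum(counts) == 0) stop("contingency table error: empty table",
                             call. = FALSE)
  structure(as.list(counts), class = "contingency_2x2")
}

association_result <- function(or, ci_low, ci_high, p_value, method, n,
                               corrected = FALSE, separation = FALSE) {
  structure(list(or = or, ci_low = ci_low, ci_high = ci_high,
                 p_value = p_value, method = method, n = n,
                 corrected = corrected, separation = separation),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), p = %.3g [%s, n = %d]%s%s\n",
              x$or, x$ci_low, x$ci_high, x$p_value, x$method, x$n,
              if (x$corrected) ", continuity-corrected" else "",
              if (x$separation) ", SEPARATED" else ""))
  invisible(x)
}

#' Cross-product odds ratio with Wald confidence interval
#'
#' `OR = (a*d)/(b*c)`; 95% CI `exp(log OR +/- 1.96 * SE)` with the Woolf
#' log-scale standard error `SE = sqrt(1/a + 1/b + 1/c + 1/d)`; two-sided
#' Wald p-value from `z = log OR / SE`. When exactly one cell is zero the
#' Haldane-Anscombe 0.5 continuity correction is applied to all cells and the
#' result flagged `corrected`; a table with both cross products zero has no
#' defined OR and raises an error.
#'
#' @param t a [contingency_2x2()], or the `a` count with `b`, `c`, `d`
#'   supplied positionally.
#' @param b,c,d counts when `t` is given as a scalar.
#' @return An `association_result` (method `"cross_product"`).
#' @export
odds_ratio_2x2 <- function(t, b = NULL, c = NULL, d = NULL) {
  if (!inherits(t, "contingency_2x2")) t <- contingency_2x2(t, b, c, d)
  counts <- unlist(t[c("a", "b", "c", "d")])
  n <- sum(counts)
  if (counts[["a"]] * counts[["d"]] == 0 && counts[["b"]] * counts[["c"]] == 0)
    stop("odds ratio undefined: both cross products are zero", call. = FALSE)
  corrected <- sum(counts == 0) == 1L
  if (corrected) counts <- counts + 0.5
  or <- (counts[["a"]] * counts[["d"]]) / (counts[["b"]] * counts[["c"]])
  se <- sqrt(sum(1 / counts))
  z <- log(or) / se
  association_result(or = or,
                     ci_low = exp(log(or) - 1.96 * se),
                     ci_high = exp(log(or) + 1.96 * se),
                     p_value = 2 * pnorm(-abs(z)),
                     method = "cross_product", n = n, corrected = corrected)
}

#' Logistic regression fit with Wald standard errors
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, log-likelihood convergence 1e-8, at most 100 iterations). An
#' intercept is always included. Complete or quasi-complete separation is
#' flagged rather than silently returning a diverged estimate.
#'
#' @param outcome binary (0/1 or logical) response vector.
#' @param design numeric covariate vector or matrix (without intercept); a
#'   zero-column matrix fits the intercept-only model.
#' @return List: `coefficients`, `se`, `or` (exponentiated slopes),
#'   `converged`, `separation`, `n`.
#' @export
logistic_fit <- function(outcome, design) {
  y <- as.numeric(outcome)
  x <- as.matrix(design)
  if (ncol(x) > 0L && nrow(x) != length(y))
    stop("logistic fit error: design/outcome length mismatch", call. = FALSE)
  if (ncol(x) > 0L && qr(cbind(1, x))$rank < ncol(x) + 1L)
    stop("logistic fit error: design not full rank", call. = FALSE)
  if (ncol(x) > 0L && is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  dat <- data.frame(.y = y)
  for (j in seq_len(ncol(x))) dat[[colnames(x)[j]]] <- x[, j]
  fml <- stats::as.formula(
    if (ncol(x) == 0L) ".y ~ 1"
    else paste(".y ~", paste(colnames(x), collapse = " + ")))
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = dat,
        control = glm.control(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned_sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  separation <- (warned_sep && max(abs(cf)) > 10) || any(se > 100)
  list(coefficients = cf, se = se, or = exp(cf[-1L]),
       converged = fit$converged && !separation,
       separation = separation, n = length(y))
}

#' Per-level odds ratio for an ordered exposure (ordinal trend)
#'
#' Expands per-level (mutated, total) counts into individual records with the
#' level coded 1..k as a single numeric covariate, fits the logistic MLE, and
#' reports the exponentiated slope: the odds ratio per one-level increment.
#' Zero-event levels are permitted as long as other levels anchor the fit.
#'
#' @param mutated integer vector of mutated counts per ordered level.
#' @param totals integer vector of per-level totals.
#' @return An `association_result` (method `"ordinal_trend"`).
#' @export
ordinal_trend_or <- function(mutated, totals) {
  k <- length(mutated)
  if (k < 3L) stop("ordinal trend error: need >= 3 ordered levels",
                   call. = FALSE)
  if (length(totals) != k || any(mutated > totals) || any(mutated < 0))
    stop("ordinal trend error: invalid counts", call. = FALSE)
  level <- rep(seq_len(k), times = totals)
  y <- unlist(lapply(seq_len(k), function(i)
    rep(c(1, 0), c(mutated[i], totals[i] - mutated[i]))))
  fit <- logistic_fit(y, matrix(level, ncol = 1L, dimnames = list(NULL, "level")))
  slope <- fit$coefficients[["level"]]
  se <- fit$se[["level"]]
  association_result(or = exp(slope),
                     ci_low = exp(slope - 1.96 * se),
                     ci_high = exp(slope + 1.96 * se),
                     p_value = 2 * pnorm(-abs(slope / se)),
                     method = "ordinal_trend", n = sum(totals),
                     separation = fit$separation)
}

#' Build the gene-by-feature cohort table
#'
#' Joins sample features to per-gene pathogenic mutation indicators from a
#' triaged cohort.
#'
#' @param features validated feature data.frame.
#' @param cohort list of `triaged_sample` objects (matched by `sample_id`).
#' @param genes gene symbols to add as logical `mut_<gene>` columns.
#' @return data.frame, one row per sample.
#' @export
build_cohort_table <- function(features, cohort, genes) {
  ids <- vapply(cohort, function(ts) as.character(ts$sample_id), character(1))
  if (!all(features$sample_id %in% ids))
    stop("cohort table error: features contain samples without triage results",
         call. = FALSE)
  m <- match(features$sample_id, ids)
  out <- features
  for (g in genes)
    out[[paste0("mut_", g)]] <- vapply(cohort[m], function(ts)
      g %in% ts$pathogenic_somatic$gene, logical(1))
  out
}

# feature value -> exposure coding used by the screen
code_feature <- function(tbl, name, coding) {
  v <- tbl[[name]]
  if (coding == "binary") {
    if (is.logical(v)) return(v)
    lv <- feature_levels[[name]]
    if (!is.null(lv) && length(lv) == 2L) return(v == lv[2L])
    stop("association screen error: feature ", name,
         " is not binary; declare an ordinal coding", call. = FALSE)
  } else if (coding == "ordinal") {
    lv <- feature_levels[[name]]
    if (is.null(lv)) stop("association screen error: no ordered vocabulary for ",
                          name, call. = FALSE)
    return(match(v, lv))
  }
  stop("association screen error: unknown coding '", coding, "'",
       call. = FALSE)
}

#' Gene-by-feature association screen
#'
#' One association per gene x feature pair: binary features are tested with
#' the cross-product Wald odds ratio; ordinal features with the per-level
#' trend odds ratio. Raw p-values carry a significance flag at 0.05 (no
#' multiplicity correction, consistent with single-study screening practice);
#' Benjamini-Hochberg q-values are appended as a clearly separate column.
#'
#' @param cohort_table output of [build_cohort_table()].
#' @param genes gene symbols (need `mut_<gene>` columns).
#' @param features list of `(name, coding)` pairs, e.g.
#'   `list(c("ulceration", "binary"), c("breslow_class", "ordinal"))`.
#' @return data.frame: gene, feature, coding, n, or, ci_low, ci_high,
#'   p_value, method, defined, corrected, separation, significant, q_value.
#' @export
association_screen <- function(cohort_table, genes, features) {
  rows <- list()
  for (g in genes) {
    mut <- cohort_table[[paste0("mut_", g)]]
    if (is.null(mut))
      stop("association screen error: no mutation column for gene ", g,
           call. = FALSE)
    for (f in features) {
      name <- f[[1L]]; coding <- f[[2L]]
      res <- tryCatch({
        if (coding == "binary") {
          e <- code_feature(cohort_table, name, "binary")
          odds_ratio_2x2(sum(mut & e), sum(!mut & e),
                         sum(mut & !e), sum(!mut & !e))
        } else {
          lev <- code_feature(cohort_table, name, "ordinal")
          k <- length(feature_levels[[name]])
          ordinal_trend_or(
            mutated = vapply(seq_len(k), function(i) sum(mut[lev == i]),
                             numeric(1)),
            totals = vapply(seq_len(k), function(i) sum(lev == i), numeric(1)))
        }
      }, error = function(e) NULL)
      rows[[length(rows) + 1L]] <- if (is.null(res))
        data.frame(gene = g, feature = name, coding = coding,
                   n = nrow(cohort_table), or = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, p_value = NA_real_,
                   method = NA_character_, defined = FALSE, corrected = FALSE,
                   separation = FALSE, stringsAsFactors = FALSE)
      else
        data.frame(gene = g, feature = name, coding = coding, n = res$n,
                   or = res$or, ci_low = res$ci_low, ci_high = res$ci_high,
                   p_value = res$p_value, method = res$method, defined = TRUE,
                   corrected = res$corrected, separation = res$separation,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < 0.05
  out$q_value <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
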