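test_that("cross-product odds ratios reproduce the printed screening rows", {
  # (a, b, c, d) = (mutated&exposed, wt&exposed, mutated&unexposed, wt&unexposed)
  rows <- list(
    list(t = c(4, 22, 1, 73), or = 13.3, ci = c(1.4, 124.9), p = 0.024),
    list(t = c(3, 16, 2, 79), or = 7.4, ci = c(1.1, 47.9), p = 0.036),
    list(t = c(11, 41, 3, 45), or = 4.0, ci = c(1.0, 15.4), p = 0.042),
    list(t = c(11, 41, 2, 46), or = 6.2, ci = c(1.3, 29.5), p = 0.023))
  for (r in rows) {
    got <- odds_ratio_2x2(r$t[1], r$t[2], r$t[3], r$t[4])
    expect_equal(round(got$or, 1), r$or)
    # CI bounds within one unit of the last printed digit; the published
    # bounds carry a rounding wobble from three-decimal intermediate
    # coefficients
    expect_lt(abs(got$ci_low - r$ci[1]), 0.1)
    expect_lt(abs(got$ci_high - r$ci[2]), 0.1)
    expect_equal(round(got$p_value, 3), r$p)
    expect_false(got$corrected)
  }
})

test_that("a symmetric table gives OR 1 with p = 1", {
  got <- odds_ratio_2x2(10, 10, 10, 10)
  expect_equal(got$or, 1)
  expect_equal(got$p_value, 1)
  expect_true(got$ci_low < 1 && got$ci_high > 1)
})

test_that("zero-cell handling: single zero corrected, double zero undefined", {
  z <- odds_ratio_2x2(0, 20, 5, 75)
  expect_true(z$corrected)
  expect_true(is.finite(z$or))
  expect_error(odds_ratio_2x2(0, 20, 0, 75), "undefined")
})

test_that("swapping exposure labels inverts the OR and swaps the CI", {
  set.seed(31)
  for (i in 1:20) {
    t <- sample(1:50, 4)
    a <- odds_ratio_2x2(t[1], t[2], t[3], t[4])
    b <- odds_ratio_2x2(t[3], t[4], t[1], t[2])
    expect_equal(b$or, 1 / a$or, tolerance = 1e-12)
    expect_equal(b$ci_low, 1 / a$ci_high, tolerance = 1e-12)
    expect_equal(b$ci_high, 1 / a$ci_low, tolerance = 1e-12)
    expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
  }
})

test_that("single-covariate logistic MLE matches the cross product to 1e-6", {
  set.seed(12)
  for (i in 1:5) {
    t <- sample(5:60, 4)   # all-positive table
    cross <- odds_ratio_2x2(t[1], t[2], t[3], t[4])
    x <- rep(c(1, 1, 0, 0), t)
    y <- rep(c(1, 0, 1, 0), t)
    fit <- logistic_fit(y, matrix(x, ncol = 1))
    expect_equal(unname(fit$or), cross$or, tolerance = 1e-6)
  }
})

test_that("intercept-only fit recovers the closed-form log odds", {
  y <- rep(c(1, 0), c(30, 70))
  fit <- logistic_fit(y, matrix(numeric(0), nrow = 100, ncol = 0))
  expect_equal(unname(fit$coefficients[1]), log(30 / 70), tolerance = 1e-8)
})

test_that("complete separation is flagged, not silently estimated", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- x
  fit <- logistic_fit(y, matrix(x, ncol = 1))
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("ordinal trend OR matches the brute-force likelihood grid", {
  # melanoma NF1-by-thickness category counts (one zero-event level)
  got <- ordinal_trend_or(c(2, 0, 4, 3), c(47, 21, 19, 13))
  oracle <- grid_search_trend_or(c(2, 0, 4, 3), c(47, 21, 19, 13))
  expect_equal(got$or, oracle, tolerance = 1e-3)
  expect_equal(round(got$or, 2), 2.21)
  expect_false(got$separation)

  # an arbitrary 3-level fixture against the same oracle
  got3 <- ordinal_trend_or(c(3, 8, 15), c(40, 35, 30))
  expect_equal(got3$or, grid_search_trend_or(c(3, 8, 15), c(40, 35, 30)),
               tolerance = 1e-3)
})

test_that("equal event fractions across levels give trend OR 1", {
  got <- ordinal_trend_or(c(5, 10, 15), c(20, 40, 60))
  expect_equal(got$or, 1, tolerance = 1e-6)
})

test_that("the screen runs the declared coding per feature and survives
           undefined cells", {
  ctab <- data.frame(
    sample_id = sprintf("T%03d", 1:100),
    mut_KIT = rep(c(TRUE, FALSE, TRUE, FALSE), c(3, 16, 2, 79)),
    mut_ZERO = FALSE,
    stage_class = rep(c("III-IV", "III-IV", "I-II", "I-II"), c(3, 16, 2, 79)),
    breslow_class = sample(c("<=1", "1-2", "2-4", ">4"), 100, replace = TRUE),
    stringsAsFactors = FALSE)
  out <- association_screen(ctab, c("KIT", "ZERO"),
                            list(c("stage_class", "binary"),
                                 c("breslow_class", "ordinal")))
  expect_equal(nrow(out), 4L)
  kit_stage <- out[out$gene == "KIT" & out$feature == "stage_class", ]
  expect_equal(round(kit_stage$or, 1), 7.4)
  expect_equal(kit_stage$method, "cross_product")
  expect_true(kit_stage$significant)
  # zero-mutant gene: binary OR undefined, ordinal trend flagged separated;
  # the screen continues either way
  zero <- out[out$gene == "ZERO", ]
  expect_false(zero$defined[zero$coding == "binary"])
  expect_true(zero$separation[zero$coding == "ordinal"])
  expect_true(all(c("significant", "q_value") %in% names(out)))
})

test_that("injected effect is recovered within its own Wald CI", {
  # logistic coupling: mutation ~ plogis(b0 + log(4) * mitosis), marginal 0.14
  set.seed(2024)
  calib <- function(prev, eta)
    uniroot(function(b0) mean(plogis(b0 + eta)) - prev, c(-20, 20))$root
  hits <- 0L
  for (r in 1:200) {
    x <- runif(100) < 0.52
    b0 <- calib(0.14, log(4) * x)
    y <- runif(100) < plogis(b0 + log(4) * x)
    res <- tryCatch(odds_ratio_2x2(sum(y & x), sum(!y & x),
                                   sum(y & !x), sum(!y & !x)),
                    error = function(e) NULL)
    if (!is.null(res) && res$ci_low <= 4 && 4 <= res$ci_high)
      hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.9)
})
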