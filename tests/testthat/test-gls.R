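# a reusable heteroscedastic fixture: known beta, known per-site ratios
make_het_data <- function(n_per_site, deltas, beta = c(1, 0.5, -0.3),
                          seed = 1) {
  S <- length(deltas)
  withr::with_seed(seed, {
    site <- rep(sprintf("s%02d", seq_len(S)), each = n_per_site)
    n <- S * n_per_site
    d <- data.frame(x1 = stats::rnorm(n), x2 = stats::rnorm(n), site = site)
    d$y <- beta[1] + beta[2] * d$x1 + beta[3] * d$x2 +
      stats::rnorm(n) * rep(deltas, each = n_per_site)
    d
  })
}

test_that("unit variance ratios reproduce OLS exactly", {
  d <- make_het_data(40, c(1, 1, 1), seed = 2)
  f <- gls_fit(d, "y", c("x1", "x2"), varstruct = FALSE, method = "REML")
  o <- stats::lm(y ~ x1 + x2, d)
  expect_equal(f$coefficients$estimate, unname(stats::coef(o)),
               tolerance = 1e-10)
  expect_equal(f$coefficients$std_error,
               unname(summary(o)$coefficients[, 2]), tolerance = 1e-10)
  expect_equal(f$coefficients$p_value,
               unname(summary(o)$coefficients[, 4]), tolerance = 1e-10)
})

test_that("REML log-likelihood matches the dense restricted oracle on small fixtures", {
  # 2 sites, n = 8, evaluated at the fitted variance structure
  d <- make_het_data(4, c(1, 3), seed = 3)
  f <- gls_fit(d, "y", c("x1", "x2"), varstruct = TRUE, method = "REML")
  X <- cbind(1, d$x1, d$x2)
  delta_obs <- f$deltas$delta[match(d$site, f$deltas$site)]
  expect_equal(f$logLik, dense_reml_loglik(d$y, X, delta_obs, f$sigma2),
               tolerance = 1e-8)

  # n = 12, 3 sites
  d2 <- make_het_data(4, c(0.5, 1, 2), seed = 4)
  f2 <- gls_fit(d2, "y", c("x1", "x2"), varstruct = TRUE, method = "REML")
  X2 <- cbind(1, d2$x1, d2$x2)
  delta2 <- f2$deltas$delta[match(d2$site, f2$deltas$site)]
  expect_equal(f2$logLik, dense_reml_loglik(d2$y, X2, delta2, f2$sigma2),
               tolerance = 1e-8)
})

test_that("the engine agrees with the reference GLS implementation", {
  d <- make_het_data(20, c(1, 1.7, 0.6, 2.5), seed = 5)
  for (m in c("REML", "ML")) {
    f <- gls_fit(d, "y", c("x1", "x2"), varstruct = TRUE, method = m)
    g <- nlme::gls(y ~ x1 + x2, d,
                   weights = nlme::varIdent(form = ~ 1 | site), method = m)
    expect_equal(f$logLik, as.numeric(stats::logLik(g)), tolerance = 1e-5)
    expect_equal(f$AIC, stats::AIC(g), tolerance = 1e-4)
    expect_equal(f$coefficients$estimate, unname(stats::coef(g)),
                 tolerance = 1e-5)
    dl <- stats::coef(g$modelStruct$varStruct, unconstrained = FALSE,
                      allCoef = TRUE)
    expect_equal(sort(f$deltas$delta), sort(as.numeric(dl)),
                 tolerance = 1e-3)
  }
})

test_that("variance ratios are recovered from heteroscedastic data", {
  d <- make_het_data(100, c(1, 2, 4), seed = 6)
  f <- gls_fit(d, "y", c("x1", "x2"), varstruct = TRUE, method = "REML")
  expect_equal(f$deltas$delta, c(1, 2, 4), tolerance = 0.3)
})

test_that("AIC bookkeeping counts coefficients, ratios and sigma", {
  d <- make_het_data(30, c(1, 2), seed = 7)
  f_ols <- gls_fit(d, "y", c("x1", "x2"), varstruct = FALSE)
  expect_equal(f_ols$df, 3L + 1L)  # 3 coefficients + sigma
  f_vs <- gls_fit(d, "y", c("x1", "x2"), varstruct = TRUE)
  expect_equal(f_vs$df, 3L + 1L + 1L)  # + one free ratio
  expect_equal(f_vs$AIC, -2 * f_vs$logLik + 2 * f_vs$df)

  f_ml <- gls_fit(d, "y", c("x1", "x2"), varstruct = TRUE, method = "ML")
  expect_false(isTRUE(all.equal(f_ml$logLik, f_vs$logLik)))
  expect_equal(f_ml$method, "ML")
  expect_equal(f_vs$method, "REML")
})

test_that("REML AICs with different fixed effects refuse to compare", {
  d <- make_het_data(30, c(1, 2), seed = 8)
  a <- gls_fit(d, "y", c("x1", "x2"), method = "REML")
  b <- gls_fit(d, "y", "x1", method = "REML")
  expect_error(compare_aic(a, b), "REML")
  am <- gls_fit(d, "y", c("x1", "x2"), method = "ML")
  bm <- gls_fit(d, "y", "x1", method = "ML")
  expect_silent(compare_aic(am, bm))
  expect_error(compare_aic(am, b), "method")
})

test_that("degenerate inputs fail cleanly", {
  d <- make_het_data(10, c(1, 2), seed = 9)
  d$x3 <- d$x1  # singular design
  expect_error(gls_fit(d, "y", c("x1", "x3")), "singular")
  d1 <- d[c(1:10, 11), ]  # second site has 1 observation
  expect_error(gls_fit(d1, "y", "x1", varstruct = TRUE), ">=2 observations")
  expect_error(gls_fit(d, "y", "nope"), "missing column")
})

test_that("backward selection drops nulls, keeps effects, respects marginality", {
  d <- withr::with_seed(10, {
    n <- 400
    dd <- data.frame(MAT = stats::rnorm(n), MAP = stats::rnorm(n),
                     x3 = stats::rnorm(n), x4 = stats::rnorm(n),
                     site = rep(sprintf("s%d", 1:8), each = n / 8))
    # true interaction, weak MAT main effect
    dd$y <- 1 + 0.05 * dd$MAT + 0.5 * dd$MAP + 0.45 * dd$MAT * dd$MAP +
      stats::rnorm(n, 0, 1)
    dd
  })
  m <- backward_select(d, "y", c("MAT", "MAP", "x3", "x4", "MAT:MAP"),
                       varstruct = FALSE)
  expect_true("MAT:MAP" %in% m$selected_terms)
  # marginality: MAT stays while the interaction is in the model, even
  # though its own main effect is weak
  expect_true(all(c("MAT", "MAP") %in% m$selected_terms))
  # the trace never removes a parent before its interaction
  removed <- m$trace$term[m$trace$accepted]
  if (length(removed) > 0) {
    expect_false(any(removed %in% c("MAT", "MAP")))
  }
})

test_that("selection returns the full model with a warning when nothing helps", {
  d <- withr::with_seed(11, {
    n <- 60
    dd <- data.frame(x1 = stats::rnorm(n), site = rep(c("a", "b"), n / 2))
    dd$y <- 1 + 0.26 * dd$x1 + stats::rnorm(n, 0, 1)
    dd
  })
  # x1 is weakly informative: p > 0.05 but AIC prefers keeping it
  m <- suppressWarnings(backward_select(d, "y", "x1", varstruct = FALSE))
  if (nrow(m$trace) > 0 && !any(m$trace$accepted)) {
    expect_equal(m$selected_terms, "x1")
    expect_warning(backward_select(d, "y", "x1", varstruct = FALSE),
                   "full model")
  }
  expect_s3_class(m$final, "gls_fit")
  expect_equal(m$final$method, "REML")
})

test_that("varstruct auto-choice picks heteroscedastic models when warranted", {
  d_het <- make_het_data(60, c(1, 4), seed = 12)
  m_het <- backward_select(d_het, "y", c("x1", "x2"), varstruct = "auto")
  expect_true(m_het$varstruct)
  d_hom <- make_het_data(60, c(1, 1), seed = 13)
  m_hom <- backward_select(d_hom, "y", c("x1", "x2"), varstruct = "auto")
  expect_false(m_hom$varstruct)
  expect_equal(nrow(m_het$varstruct_aic), 2L)
})
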