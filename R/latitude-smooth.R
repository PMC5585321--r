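# Nonlinear latitudinal trends: trait ~ s(|latitude|) as a penalized cubic
# regression spline with GCV smoothness selection (mgcv), with optional
# per-site precision weights taken from a preliminary unweighted fit. This
# is a deliberate simplification of a random-intercept additive model: the
# site component enters through variance weights only, so r^2 and p-values
# are comparable in scale but not identical to a full mixed-model fit.

#' Fit a penalized-spline latitudinal trend for one trait
#'
#' @param data Data frame with the trait, a latitude column (signed degrees;
#'   the absolute value is used) and a site column.
#' @param trait Trait column name (log-transformed automatically for `NP`
#'   and `SLA`, see [transform_response()]).
#' @param lat Latitude column name (default `"latitude"`).
#' @param site Site column name.
#' @param weights Use per-site inverse-variance weights estimated from a
#'   preliminary unweighted fit (default `TRUE`).
#' @param k Spline basis dimension (default 10 knots at latitude quantiles).
#' @param sp Optional fixed smoothing parameter; `NULL` selects by GCV. A
#'   very large value forces the fit to its penalty null space, i.e. an
#'   ordinary linear regression on latitude.
#' @return An object of class `latitude_smooth`: `edf`, `r_squared` (raw,
#'   working scale), `p_value` (approximate, Wald-type, tagged), `sp`,
#'   `curve` (tibble of fitted values on a latitude grid), `n`,
#'   `transform`, plus the underlying `mgcv::gam` fit.
#' @export
fit_latitude_smooth <- function(data, trait, lat = "latitude", site = "site",
                                weights = TRUE, k = 10, sp = NULL) {
  data <- as.data.frame(data)
  stopifnot(all(c(trait, lat, site) %in% names(data)))
  tr <- transform_response(data[[trait]], trait)
  dd <- data.frame(y = tr$values, alat = abs(data[[lat]]),
                   site = factor(data[[site]]))
  dd <- dd[complete.cases(dd), , drop = FALSE]
  if (nrow(dd) < 10L) abort("need at least 10 observations")
  if (length(unique(dd$alat)) < 3L) {
    abort("need at least 3 distinct latitudes")
  }
  k <- min(k, length(unique(dd$alat)))
  w <- rep(1, nrow(dd))
  if (weights) {
    pre <- mgcv::gam(y ~ s(alat, bs = "cr", k = k), data = dd,
                     method = "GCV.Cp")
    rs <- resid(pre)
    site_var <- tapply(rs, dd$site, function(r)
      if (length(r) >= 2L) var(r) else NA_real_)
    pooled <- mean(rs^2)
    site_var[is.na(site_var) | site_var <= 0] <- pooled
    w <- pooled / site_var[as.character(dd$site)]
    names(w) <- NULL
  }
  fit <- mgcv::gam(y ~ s(alat, bs = "cr", k = k), data = dd,
                   weights = w, sp = sp, method = "GCV.Cp")
  sm <- summary(fit)
  # working-scale r2: weighted (response-scale residuals, not the
  # sqrt(w)-scaled deviance residuals), so it stays in [0, 1]
  rs <- dd$y - fitted(fit)
  rss <- sum(w * rs^2)
  ybar <- sum(w * dd$y) / sum(w)
  tss <- sum(w * (dd$y - ybar)^2)
  grid <- seq(min(dd$alat), max(dd$alat), length.out = 200L)
  pred <- mgcv::predict.gam(fit, newdata = data.frame(alat = grid),
                            se.fit = TRUE)
  out <- list(
    trait = trait, fit = fit, edf = unname(sm$edf), sp = unname(fit$sp),
    r_squared = 1 - rss / tss, p_value = unname(sm$s.pv),
    p_value_type = "approx",
    curve = tibble(abs_latitude = grid, fitted = as.numeric(pred$fit),
                   se = as.numeric(pred$se.fit)),
    n = nrow(dd), transform = tr$transform, weights_used = weights,
    data = as_tibble(dd)
  )
  class(out) <- "latitude_smooth"
  out
}

#' @method print latitude_smooth
#' @export
print.latitude_smooth <- function(x, ...) {
  cat(sprintf(
    "Latitudinal smooth for %s (%s scale, n = %d)\n  edf = %.2f, r2 = %.3f, p = %.4g (approx), weights %s\n",
    x$trait, x$transform, x$n, x$edf, x$r_squared, x$p_value,
    if (x$weights_used) "on" else "off"))
  invisible(x)
}

#' @method glance latitude_smooth
#' @export
glance.latitude_smooth <- function(x, ...) {
  tibble(trait = x$trait, n = x$n, edf = x$edf, r_squared = x$r_squared,
         p_value = x$p_value, sp = x$sp, transform = x$transform,
         weights_used = x$weights_used)
}
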