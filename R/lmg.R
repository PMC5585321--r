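# LMG relative importance: the R^2 of a linear model decomposed as each
# predictor's sequential contribution averaged over all predictor
# orderings, computed by exact subset enumeration (feasible for <= 10
# predictors). For heteroscedastic fits the data are first whitened by the
# fitted per-site standard-deviation ratios, the minimal coherent extension
# of the metric to the variance-structure model; an interaction term enters
# as a predictor in its own right.

# R^2 of y on an intercept + the columns of X selected by `cols`
subset_r2 <- function(y, X, cols, tss) {
  if (length(cols) == 0L) return(0)
  qr_fit <- lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
  1 - sum(qr_fit$residuals^2) / tss
}

lmg_shares <- function(y, X) {
  p <- ncol(X)
  tss <- sum((y - mean(y))^2)
  n_masks <- bitwShiftL(1L, p)
  r2 <- numeric(n_masks)
  masks <- 0:(n_masks - 1L)
  bit_of <- function(mask, j) bitwAnd(bitwShiftR(mask, j - 1L), 1L) == 1L
  for (m in masks) {
    cols <- which(vapply(seq_len(p), function(j) bit_of(m, j), logical(1L)))
    r2[m + 1L] <- subset_r2(y, X, cols, tss)
  }
  sizes <- vapply(masks, function(m) sum(vapply(seq_len(p), function(j)
    bit_of(m, j), logical(1L))), numeric(1L))
  lmg <- numeric(p)
  for (j in seq_len(p)) {
    without_j <- masks[!vapply(masks, function(m) bit_of(m, j), logical(1L))]
    for (m in without_j) {
      k <- sizes[m + 1L]
      w <- 1 / (p * choose(p - 1L, k))
      lmg[j] <- lmg[j] + w * (r2[bitwOr(m, bitwShiftL(1L, j - 1L)) + 1L] -
                                r2[m + 1L])
    }
  }
  lmg
}

#' LMG decomposition of explained variance, with stratified bootstrap
#'
#' Decomposes the final model's R^2 into per-predictor shares (the average
#' sequential R^2 increase over all predictor orderings), normalised to sum
#' to 100. With `B > 0`, observations are resampled with replacement within
#' each site and percentile confidence intervals are attached.
#'
#' @param model A `trait_model` (from [backward_select()]) or `gls_fit`.
#' @param B Number of bootstrap resamples (0 = none).
#' @param seed Integer seed for the bootstrap (required when `B > 0`).
#' @param whiten Scale each observation by `1/delta_site` from the fitted
#'   variance structure before decomposing (default `TRUE`); set `FALSE` for
#'   the raw-scale decomposition.
#' @param conf Confidence level for percentile intervals.
#' @return A tibble with columns `term`, `lmg` (absolute R^2 contribution),
#'   `share` (percent of explained variance) and, when bootstrapped,
#'   `share_lo` and `share_hi`. Attributes: `r_squared`, `B`, `seed`.
#' @export
lmg_decomposition <- function(model, B = 0, seed = NULL, whiten = TRUE,
                              conf = 0.95) {
  fit <- if (inherits(model, "trait_model")) model$final else model
  stopifnot(inherits(fit, "gls_fit"))
  terms <- fit$predictors
  if (length(terms) == 0L) abort("final model has no predictors")
  if (length(terms) > 10L) {
    abort("more than 10 predictors: exact ordering enumeration not supported")
  }
  dd <- fit$data
  X <- model.matrix(stats::reformulate(terms), dd)[, -1L, drop = FALSE]
  y <- dd[[fit$response]]
  site <- dd[[fit$site]]
  w <- rep(1, nrow(dd))
  if (whiten && fit$varstruct) {
    d <- setNames(fit$deltas$delta, fit$deltas$site)
    w <- 1 / d[as.character(site)]
  }
  shares_of <- function(idx) {
    lm_y <- y[idx] * w[idx]
    lm_X <- X[idx, , drop = FALSE] * w[idx]
    raw <- lmg_shares(lm_y, lm_X)
    list(raw = raw, share = 100 * raw / sum(raw))
  }
  full <- shares_of(seq_along(y))
  out <- tibble(term = colnames(X), lmg = full$raw, share = full$share)
  if (B > 0L) {
    if (is.null(seed)) abort("a seed is required for the bootstrap")
    groups <- split(seq_along(y), site)
    boot <- withr::with_seed(seed, {
      vapply(seq_len(B), function(b) {
        idx <- unlist(lapply(groups, function(g)
          g[sample.int(length(g), length(g), replace = TRUE)]),
          use.names = FALSE)
        shares_of(idx)$share
      }, numeric(ncol(X)))
    })
    boot <- matrix(boot, nrow = ncol(X))
    a <- (1 - conf) / 2
    out$share_lo <- apply(boot, 1L, quantile, probs = a)
    out$share_hi <- apply(boot, 1L, quantile, probs = 1 - a)
  }
  attr(out, "r_squared") <- sum(full$raw)
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  attr(out, "whitened") <- whiten && fit$varstruct
  out
}
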