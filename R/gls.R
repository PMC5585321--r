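# Heteroscedastic generalized least squares (per-site variance ratios) and
# AIC backward selection. The engine profiles beta and sigma2 out of the
# Gaussian likelihood and numerically optimizes the per-site log variance
# ratios (bounded L-BFGS-B), under either maximum likelihood (for
# fixed-effect AIC comparisons) or restricted maximum likelihood (for
# variance-structure comparison and final inference). This module also owns
# the selection procedure, marginality handling and the AIC bookkeeping
# rules.

# Profiled (RE)ML engine. V = sigma2 * diag(delta_{s(i)}^2), delta_1 = 1.
# For fixed log-ratios the GLS estimate is a weighted least-squares fit
# (rows scaled by 1/delta); sigma2 is profiled as RSS_w/n (ML) or
# RSS_w/(n-k) (REML), leaving
#   logL_ML   = -1/2 [ n log(2 pi sigma2) + sum_i log delta_i^2 + n ]
#   logL_REML = -1/2 [ (n-k) log(2 pi sigma2) + sum_i log delta_i^2
#                      + log|X' W X| + (n-k) ]
# with W = diag(delta^-2); the REML constant matches nlme's convention so
# log-likelihoods are directly comparable.
gls_engine <- function(y, X, si, n_sites, varstruct, method) {
  n <- length(y)
  k <- ncol(X)
  if (qr(X)$rank < k) abort("singular design matrix")
  counts <- tabulate(si, nbins = n_sites)

  eval_at <- function(g) {
    logd <- c(0, g)
    w <- exp(-logd[si])
    fw <- lm.fit(X * w, y * w)
    rss <- sum(fw$residuals^2)
    sumlogd2 <- 2 * sum(counts * logd)
    if (method == "ML") {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi * s2) + sumlogd2 + n)
    } else {
      s2 <- rss / (n - k)
      XtWX <- crossprod(X * w)
      ld <- as.numeric(determinant(XtWX, logarithm = TRUE)$modulus)
      ll <- -0.5 * ((n - k) * log(2 * pi * s2) + sumlogd2 + ld + (n - k))
    }
    list(loglik = ll, s2 = s2, fit = fw, w = w, delta = exp(logd))
  }

  if (varstruct && n_sites > 1L) {
    # Ratios live on a bounded log scale: the per-group ML likelihood is
    # unbounded when a small group can be interpolated by the weighted fit
    # (its ratio then runs to 0), so the ratio is confined to a wide but
    # finite envelope and a boundary estimate is flagged.
    bound <- log(25)
    r0 <- lm.fit(X, y)$residuals
    s0 <- vapply(seq_len(n_sites), function(s) sd(r0[si == s]), numeric(1L))
    s0[!is.finite(s0) | s0 <= 0] <- sd(r0)
    g_start <- pmin(pmax(log(s0 / s0[1L])[-1L], -bound), bound)
    best <- NULL
    for (g0 in list(g_start, rep(0, n_sites - 1L))) {
      opt <- tryCatch(
        stats::optim(g0, function(g) -eval_at(g)$loglik,
                     method = "L-BFGS-B", lower = -bound, upper = bound,
                     control = list(maxit = 500)),
        error = function(e) NULL
      )
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
        best <- opt
      }
    }
    if (is.null(best)) {
      abort("variance-ratio optimization failed", class = "littertraits_gls_fail")
    }
    g_hat <- best$par
    if (any(abs(g_hat) >= bound - 1e-6)) {
      warn(paste0("variance ratio(s) at the boundary (1/25 or 25 times the ",
                  "reference site); the per-site likelihood may be degenerate"))
    }
  } else {
    g_hat <- rep(0, max(0L, n_sites - 1L))
  }
  at <- eval_at(g_hat)
  beta <- at$fit$coefficients
  XtWX <- crossprod(X * at$w)
  vcov_beta <- at$s2 * solve(XtWX)
  list(beta = beta, vcov = vcov_beta, sigma2 = at$s2, delta = at$delta,
       loglik = at$loglik, k_coef = k)
}

#' Fit a (possibly heteroscedastic) GLS model
#'
#' Linear regression whose residual variance is either common across sites
#' (`varstruct = FALSE`) or proportional to a per-site ratio `delta_s` with
#' the first site as reference (`varstruct = TRUE`). Coefficients are the
#' generalized least-squares solution at the optimized variance ratios;
#' inference uses t statistics on `n - k` degrees of freedom.
#'
#' @param data Data frame containing the response, predictors and site
#'   column. Rows with missing values in any used column are dropped
#'   (complete-case per model; n is reported).
#' @param response Response column name.
#' @param predictors Character vector of predictor terms; interactions may be
#'   written as `"A:B"`.
#' @param site Site (grouping) column name.
#' @param varstruct Logical: allow different residual spread per site.
#' @param method `"REML"` (default, for inference and variance-structure
#'   comparison) or `"ML"` (required for fixed-effect AIC comparison).
#' @return An object of class `gls_fit`: coefficients table, per-site
#'   variance ratios (`deltas`), `sigma2`, `logLik` (tagged with the
#'   method), `AIC`, `n`, `df`, and the model frame used.
#' @export
gls_fit <- function(data, response, predictors, site = "site",
                    varstruct = FALSE, method = c("REML", "ML")) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  vars <- unique(c(response, unlist(strsplit(predictors, ":", fixed = TRUE)),
                   site))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  dd <- data[complete.cases(data[vars]), vars, drop = FALSE]
  dd[[site]] <- factor(dd[[site]])
  n <- nrow(dd)
  k_coef <- length(predictors) + 1L
  if (n <= k_coef) abort("not enough complete observations for the design")
  if (varstruct) {
    few <- table(dd[[site]])
    if (any(few < 2L)) {
      abort(paste0("varstruct requires >=2 observations per site; offending: ",
                   paste(names(few)[few < 2L], collapse = ", ")))
    }
  }
  fml <- stats::reformulate(c("1", predictors))
  X <- model.matrix(fml, dd)
  y <- dd[[response]]
  si <- as.integer(dd[[site]])
  S <- nlevels(dd[[site]])
  eng <- gls_engine(y, X, si, S, varstruct, method)

  se <- sqrt(diag(eng$vcov))
  tval <- eng$beta / se
  resid_df <- n - eng$k_coef
  coefs <- tibble(
    term = colnames(X), estimate = unname(eng$beta),
    std_error = unname(se), statistic = unname(tval),
    p_value = 2 * pt(-abs(unname(tval)), df = resid_df)
  )
  deltas <- tibble(site = levels(dd[[site]]), delta = eng$delta)
  df_total <- eng$k_coef + (if (varstruct) S - 1L else 0L) + 1L
  out <- list(
    response = response, predictors = predictors, site = site,
    varstruct = varstruct, method = method, coefficients = coefs,
    deltas = deltas, sigma2 = eng$sigma2, logLik = eng$loglik,
    df = df_total, AIC = -2 * eng$loglik + 2 * df_total, n = n,
    resid_df = resid_df, data = as_tibble(dd)
  )
  class(out) <- "gls_fit"
  out
}

#' @method print gls_fit
#' @export
print.gls_fit <- function(x, ...) {
  cat(sprintf("GLS fit (%s): %s ~ %s\n", x$method, x$response,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("  n = %d, logLik = %.3f, AIC = %.2f, sigma2 = %.4g, varstruct = %s\n",
              x$n, x$logLik, x$AIC, x$sigma2, x$varstruct))
  print(as.data.frame(x$coefficients), digits = 4)
  invisible(x)
}

#' @method logLik gls_fit
#' @export
logLik.gls_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n, class = "logLik")
}

#' @method tidy gls_fit
#' @export
tidy.gls_fit <- function(x, ...) x$coefficients

#' @method glance gls_fit
#' @export
glance.gls_fit <- function(x, ...) {
  tibble(response = x$response, n = x$n, df = x$df, logLik = x$logLik,
         AIC = x$AIC, sigma2 = x$sigma2, method = x$method,
         varstruct = x$varstruct)
}

#' AIC of a GLS fit, with a guard against invalid comparisons
#'
#' `model_aic()` returns `-2 logLik + 2k`, where k counts regression
#' coefficients, free variance ratios, and the residual variance.
#' `compare_aic()` refuses to compare REML fits with different fixed-effect
#' sets: REML likelihoods are only comparable at a fixed design.
#'
#' @param fit,a,b `gls_fit` objects.
#' @return `model_aic`: numeric AIC. `compare_aic`: the AIC difference
#'   `model_aic(b) - model_aic(a)`.
#' @export
model_aic <- function(fit) {
  stopifnot(inherits(fit, "gls_fit"))
  fit$AIC
}

#' @rdname model_aic
#' @export
compare_aic <- function(a, b) {
  stopifnot(inherits(a, "gls_fit"), inherits(b, "gls_fit"))
  same_fixed <- identical(sort(a$predictors), sort(b$predictors))
  if ((a$method == "REML" || b$method == "REML") && !same_fixed) {
    abort(paste0("cannot compare models with different fixed effects by ",
                 "REML AIC; refit with method = 'ML'"))
  }
  if (a$method != b$method) {
    abort("cannot compare AIC across estimation methods")
  }
  model_aic(b) - model_aic(a)
}

# main-effect terms locked by a retained interaction (marginality)
locked_terms <- function(terms) {
  ints <- terms[grepl(":", terms, fixed = TRUE)]
  unique(unlist(strsplit(ints, ":", fixed = TRUE)))
}

#' Backward model selection by AIC with a significance stopping rule
#'
#' Starts from the full fixed-effects model. First the variance structure
#' (per-site ratios on/off) is chosen by REML AIC at the full design. Then,
#' iteratively, the least significant removable term (largest p; main
#' effects involved in a retained interaction are not removable) is dropped
#' and the reduction accepted only if the ML AIC strictly decreases; the
#' loop stops when every remaining term is significant at `alpha` or no
#' acceptable removal exists. The selected model is refit by REML for
#' inference.
#'
#' @param data Data frame with response, predictors, site column.
#' @param response Response column name.
#' @param predictors Character vector of candidate terms (interactions as
#'   `"A:B"`).
#' @param site Site column name.
#' @param varstruct `TRUE`, `FALSE`, or `"auto"` (choose by REML AIC).
#' @param alpha Significance level of the stopping rule.
#' @return An object of class `trait_model`: `final` (REML `gls_fit`),
#'   `trace` (tibble of attempted removals), `varstruct` (chosen),
#'   `varstruct_aic` (REML AICs of both options, when compared).
#' @export
backward_select <- function(data, response, predictors, site = "site",
                            varstruct = "auto", alpha = 0.05) {
  vs_aic <- tibble(varstruct = logical(), AIC = numeric())
  if (identical(varstruct, "auto")) {
    f_off <- gls_fit(data, response, predictors, site, varstruct = FALSE,
                     method = "REML")
    f_on <- tryCatch(
      gls_fit(data, response, predictors, site, varstruct = TRUE,
              method = "REML"),
      error = function(e) NULL
    )
    vs_aic <- tibble(
      varstruct = c(FALSE, TRUE),
      AIC = c(model_aic(f_off), if (is.null(f_on)) NA_real_ else model_aic(f_on))
    )
    use_vs <- !is.null(f_on) && model_aic(f_on) < model_aic(f_off)
  } else {
    use_vs <- isTRUE(varstruct)
  }

  terms <- predictors
  current <- gls_fit(data, response, terms, site, varstruct = use_vs,
                     method = "ML")
  trace <- tibble(step = integer(), term = character(), p_value = numeric(),
                  aic_before = numeric(), aic_after = numeric(),
                  accepted = logical())
  step <- 0L
  any_accepted <- FALSE
  stalled_insignificant <- FALSE
  repeat {
    if (length(terms) == 0L) break
    coefs <- current$coefficients
    coefs <- coefs[coefs$term != "(Intercept)", , drop = FALSE]
    locked <- locked_terms(terms)
    removable <- setdiff(terms, locked)
    if (length(removable) == 0L) break
    pvals <- setNames(coefs$p_value, coefs$term)[removable]
    insig <- pvals[!is.na(pvals) & pvals >= alpha]
    if (length(insig) == 0L) break
    # candidates in decreasing order of p; accept the first removal that
    # strictly lowers the ML AIC, stop when none does
    accepted_this_round <- FALSE
    for (cand in names(sort(insig, decreasing = TRUE))) {
      step <- step + 1L
      reduced_terms <- setdiff(terms, cand)
      reduced <- gls_fit(data, response, if (length(reduced_terms) == 0L)
        character(0) else reduced_terms, site, varstruct = use_vs,
        method = "ML")
      accept <- compare_aic(current, reduced) < 0
      trace <- dplyr::bind_rows(trace, tibble(
        step = step, term = cand, p_value = unname(pvals[cand]),
        aic_before = model_aic(current), aic_after = model_aic(reduced),
        accepted = accept))
      if (accept) {
        any_accepted <- TRUE
        terms <- reduced_terms
        current <- reduced
        accepted_this_round <- TRUE
        break
      }
    }
    if (!accepted_this_round) {
      stalled_insignificant <- TRUE
      break
    }
  }
  if (stalled_insignificant && !any_accepted) {
    warn("no removal improved AIC; returning the full model")
  }
  final <- gls_fit(data, response, if (length(terms) == 0L) character(0) else
    terms, site, varstruct = use_vs, method = "REML")
  out <- list(final = final, trace = trace, varstruct = use_vs,
              varstruct_aic = vs_aic, full_terms = predictors,
              selected_terms = terms, alpha = alpha)
  class(out) <- "trait_model"
  out
}

#' @method print trait_model
#' @export
print.trait_model <- function(x, ...) {
  cat("Backward-selected model (varstruct =", x$varstruct, ")\n")
  cat("  full terms:    ", paste(x$full_terms, collapse = " + "), "\n")
  cat("  selected terms:", paste(x$selected_terms, collapse = " + "), "\n")
  print(x$final)
  invisible(x)
}

#' @method tidy trait_model
#' @export
tidy.trait_model <- function(x, ...) tidy(x$final)

#' @method glance trait_model
#' @export
glance.trait_model <- function(x, ...) {
  dplyr::mutate(glance(x$final),
                n_removed = length(x$full_terms) - length(x$selected_terms))
}
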