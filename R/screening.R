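# Pre-modelling data hygiene: standardisation, outlier handling,
# collinearity screening (pairwise Pearson rule + VIF) and response
# transforms.

#' Convert a numeric vector to z-scores
#'
#' Centred to mean 0 and scaled to unit standard deviation (denominator
#' n - 1); the original centre and scale are kept as attributes so model
#' coefficients can be mapped back to raw units.
#'
#' @param values Numeric vector with at least two distinct non-missing values.
#' @return The standardized vector with attributes `center` and `scale`.
#' @export
zscore <- function(values) {
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2L) abort("cannot z-score a constant column")
  ctr <- mean(v)
  scl <- sd(v)
  out <- (values - ctr) / scl
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

#' Response transform by trait
#'
#' The N:P ratio and SLA are natural-log transformed (both show multiple
#' extreme observations within sites, violating homoscedasticity); all other
#' traits are modelled on their raw scale.
#'
#' @param values Numeric response vector.
#' @param trait Trait name; `"NP"` and `"SLA"` trigger the log transform.
#' @return A list with `values` (transformed) and `transform`
#'   (`"log"` or `"identity"`).
#' @export
transform_response <- function(values, trait) {
  if (trait %in% c("NP", "SLA")) {
    bad <- which(!is.na(values) & values <= 0)
    if (length(bad) > 0L) {
      abort(paste0("log transform of '", trait, "' impossible: non-positive ",
                   "value at observation(s) ", paste(bad, collapse = ", ")))
    }
    list(values = log(values), transform = "log")
  } else {
    list(values = values, transform = "identity")
  }
}

#' Apply explicit outlier exclusions and flag extreme values
#'
#' Observations named in `exclusions` (site, species, trait) have that trait
#' value set missing. Additionally, any remaining value more than 3 standard
#' deviations from its trait's grand mean is flagged in the report -- flagged
#' values are reported for inspection, never removed automatically.
#'
#' @param traits Trait table with `species` and `site` columns.
#' @param exclusions Data frame with columns `site`, `species`, `trait`
#'   (may be `NULL` or empty).
#' @param sd_limit Flagging threshold in standard deviations.
#' @return A list: `traits` (with exclusions applied), `excluded` (tibble of
#'   applied exclusions) and `flagged` (tibble: species, site, trait, value,
#'   z).
#' @export
flag_and_exclude_outliers <- function(traits, exclusions = NULL, sd_limit = 3) {
  traits <- as_tibble(traits)
  excluded <- tibble(site = character(), species = character(),
                     trait = character(), value = numeric())
  if (!is.null(exclusions) && nrow(as_tibble(exclusions)) > 0L) {
    exclusions <- as_tibble(exclusions)
    for (i in seq_len(nrow(exclusions))) {
      ex <- exclusions[i, ]
      row <- which(traits$site == ex$site & traits$species == ex$species)
      if (length(row) == 0L) {
        abort(paste0("exclusion refers to unknown observation: ",
                     ex$species, " at ", ex$site))
      }
      if (!ex$trait %in% names(traits)) {
        abort(paste0("exclusion refers to unknown trait: ", ex$trait))
      }
      excluded <- dplyr::bind_rows(excluded, tibble(
        site = ex$site, species = ex$species, trait = ex$trait,
        value = traits[[ex$trait]][row[1L]]))
      traits[[ex$trait]][row] <- NA_real_
    }
  }
  trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric, logical(1L))],
                        c("latitude", "abs_latitude"))
  flags <- purrr::map_dfr(trait_cols, function(tr) {
    v <- traits[[tr]]
    m <- mean(v, na.rm = TRUE)
    s <- sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) return(NULL)
    z <- (v - m) / s
    idx <- which(!is.na(z) & abs(z) > sd_limit)
    if (length(idx) == 0L) return(NULL)
    tibble(species = traits$species[idx], site = traits$site[idx],
           trait = tr, value = v[idx], z = z[idx])
  })
  list(traits = traits, excluded = excluded, flagged = flags)
}

#' Iterative pairwise-correlation screen for collinear predictors
#'
#' While any predictor pair has `|r| >=` the threshold, the predictor with
#' the most violating partners is dropped (ties broken by largest mean
#' absolute correlation with the other retained predictors, then
#' alphabetically). This reproduces the common "r >= 0.60" pre-screen used
#' before regression modelling.
#'
#' @param predictors Data frame of numeric predictor columns.
#' @param threshold Absolute Pearson correlation at/above which a pair is
#'   collinear (default 0.60).
#' @return A list: `retained` (character), `dropped` (tibble in drop order:
#'   predictor, n_partners, mean_abs_r).
#' @export
pearson_screen <- function(predictors, threshold = 0.60) {
  predictors <- as_tibble(predictors)
  stopifnot(ncol(predictors) >= 2L)
  keep <- names(predictors)
  dropped <- tibble(predictor = character(), n_partners = integer(),
                    mean_abs_r = numeric())
  repeat {
    if (length(keep) < 2L) break
    R <- abs(cor(predictors[keep], use = "pairwise.complete.obs"))
    diag(R) <- 0
    partners <- rowSums(R >= threshold)
    if (all(partners == 0L)) break
    mean_r <- rowSums(R) / (length(keep) - 1L)
    ord <- order(-partners, -mean_r, names(partners))
    victim <- names(partners)[ord[1L]]
    dropped <- dplyr::bind_rows(dropped, tibble(
      predictor = victim, n_partners = as.integer(partners[victim]),
      mean_abs_r = mean_r[victim]))
    keep <- setdiff(keep, victim)
  }
  list(retained = keep, dropped = dropped)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)`, with `R^2_j` from an ordinary regression of
#' predictor j on all the others. Perfectly collinear predictors report
#' `Inf`.
#'
#' @param design Data frame of numeric predictor columns (complete cases are
#'   used); needs more rows than columns.
#' @return A tibble with columns `predictor` and `vif`.
#' @export
vif <- function(design) {
  design <- as.data.frame(design)
  design <- design[complete.cases(design), , drop = FALSE]
  p <- ncol(design)
  if (nrow(design) <= p) abort("need more observations than predictors")
  out <- vapply(seq_len(p), function(j) {
    fit <- lm(design[[j]] ~ ., data = design[, -j, drop = FALSE])
    r2 <- 1 - sum(resid(fit)^2) / sum((design[[j]] - mean(design[[j]]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L))
  tibble(predictor = names(design), vif = out)
}
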