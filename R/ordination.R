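# PCA of z-scored traits and environment (multivariate "trait syndrome"
# view of the data).

#' Principal component analysis of z-scored variables
#'
#' Complete-case rows of the selected numeric columns are z-scored and
#' decomposed by SVD (equivalently, eigendecomposition of the correlation
#' matrix). The sign of each axis is fixed so that its largest-magnitude
#' loading is positive, making results reproducible across platforms.
#'
#' @param data A data frame of observations (species-at-site rows).
#' @param vars Character vector of columns to include; default: all numeric
#'   columns.
#' @return An object of class `trait_pca`: `loadings` (tibble, variable by
#'   axis), `scores` (tibble), `var_frac` (percent variance per axis,
#'   summing to 100), `n` (complete rows used), `vars`.
#' @export
trait_pca <- function(data, vars = NULL) {
  data <- as_tibble(data)
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1L))]
  }
  if (length(vars) < 2L) abort("need at least 2 variables")
  M <- as.data.frame(data[vars])
  cc <- complete.cases(M)
  M <- M[cc, , drop = FALSE]
  if (nrow(M) < 2L) abort("need at least 2 complete rows")
  Z <- vapply(M, function(col) as.numeric(zscore(col)), numeric(nrow(M)))
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  # sign convention: dominant loading positive within each axis
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  var_frac <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  axes <- paste0("PC", seq_along(var_frac))
  loadings <- as_tibble(pc$rotation, .name_repair = ~axes)
  loadings <- dplyr::bind_cols(tibble(variable = vars), loadings)
  scores <- as_tibble(pc$x, .name_repair = ~axes)
  scores <- dplyr::bind_cols(data[cc, setdiff(names(data), vars),
                                  drop = FALSE], scores)
  out <- list(loadings = loadings, scores = scores, var_frac = var_frac,
              n = nrow(M), vars = vars, sdev = pc$sdev)
  class(out) <- "trait_pca"
  out
}

#' @method print trait_pca
#' @export
print.trait_pca <- function(x, ...) {
  cat(sprintf("PCA of %d variables on %d complete rows\n", length(x$vars), x$n))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% (first two axes %.1f%%)\n",
              x$var_frac[1L], x$var_frac[2L], sum(x$var_frac[1:2])))
  invisible(x)
}

#' @method tidy trait_pca
#' @export
tidy.trait_pca <- function(x, ...) {
  tidyr::pivot_longer(x$loadings, -"variable", names_to = "axis",
                      values_to = "loading")
}

#' @method glance trait_pca
#' @export
glance.trait_pca <- function(x, ...) {
  tibble(axis = paste0("PC", seq_along(x$var_frac)),
         var_percent = x$var_frac,
         cum_percent = cumsum(x$var_frac))
}
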