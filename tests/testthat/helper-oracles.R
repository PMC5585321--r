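# Independent oracles used to cross-check the package implementations.
# These deliberately use naive algorithms (edge walking, dense matrix
# algebra, permutation enumeration) rather than the code paths under test.

# root-to-tip depth by explicit edge walking on the ape edge matrix
depth_oracle <- function(phy) {
  n_tip <- length(phy$tip.label)
  parent_of <- integer(n_tip + phy$Nnode)
  len_of <- numeric(n_tip + phy$Nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  len_of[phy$edge[, 2]] <- phy$edge.length
  root <- setdiff(unique(phy$edge[, 1]), phy$edge[, 2])
  out <- numeric(n_tip)
  for (i in seq_len(n_tip)) {
    d <- 0
    node <- i
    while (node != root) {
      d <- d + len_of[node]
      node <- parent_of[node]
    }
    out[i] <- d
  }
  names(out) <- phy$tip.label
  out
}

# Brownian covariance by pairwise shared-path inspection: for each pair of
# tips, sum the lengths of edges lying on both root paths.
vcv_oracle <- function(phy) {
  n_tip <- length(phy$tip.label)
  parent_of <- integer(n_tip + phy$Nnode)
  len_of <- numeric(n_tip + phy$Nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  len_of[phy$edge[, 2]] <- phy$edge.length
  root <- setdiff(unique(phy$edge[, 1]), phy$edge[, 2])
  path_of <- function(i) {
    nodes <- integer(0)
    while (i != root) {
      nodes <- c(nodes, i)
      i <- parent_of[i]
    }
    nodes
  }
  paths <- lapply(seq_len(n_tip), path_of)
  C <- matrix(0, n_tip, n_tip, dimnames = list(phy$tip.label, phy$tip.label))
  for (i in seq_len(n_tip)) {
    for (j in seq_len(n_tip)) {
      shared <- intersect(paths[[i]], paths[[j]])
      C[i, j] <- sum(len_of[shared])
    }
  }
  ord <- order(rownames(C))
  C[ord, ord]
}

# dense multivariate-normal log-density at given mean/covariance
dense_mvn_loglik <- function(x, mean, V) {
  n <- length(x)
  r <- x - mean
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(V)$modulus +
                       t(r) %*% solve(V, r)))
}

# dense restricted log-likelihood of a heteroscedastic linear model at
# given (sigma2, per-observation delta): the standard REML objective
# -1/2 [ (n-k) log 2pi + log|V| + log|X' V^-1 X| + r' V^-1 r ]
dense_reml_loglik <- function(y, X, delta_obs, sigma2) {
  n <- length(y)
  k <- ncol(X)
  V <- sigma2 * diag(delta_obs^2)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((n - k) * log(2 * pi) + determinant(V)$modulus +
                       determinant(t(X) %*% Vi %*% X)$modulus +
                       t(r) %*% Vi %*% r))
}

# LMG by brute-force enumeration of all predictor orderings
lmg_perm_oracle <- function(y, X) {
  p <- ncol(X)
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    f <- lm.fit(cbind(1, X[, cols, drop = FALSE]), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(rest) c(v[i], rest))), recursive = FALSE)
  }
  contrib <- numeric(p)
  all_perms <- perms(seq_len(p))
  for (ord in all_perms) {
    sofar <- integer(0)
    for (j in ord) {
      contrib[j] <- contrib[j] + (r2(c(sofar, j)) - r2(sofar))
      sofar <- c(sofar, j)
    }
  }
  contrib / length(all_perms)
}

# random non-ultrametric rooted tree (for exercising the chol likelihood
# path and distance bookkeeping on uneven depths)
random_uneven_tree <- function(n_tips, seed) {
  withr::with_seed(seed, {
    phy <- ape::rtree(n_tips)
    phy$edge.length <- stats::runif(nrow(phy$edge), 0.1, 3)
    phy
  })
}

# a star-like polytomy tree: one root with k pendant children
star_newick <- function(lengths, labels = NULL) {
  k <- length(lengths)
  if (is.null(labels)) labels <- paste0("t", seq_len(k))
  paste0("(", paste0(labels, ":", lengths, collapse = ","), ");")
}
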