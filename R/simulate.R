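# Seeded generators for synthetic study data: a pure-birth backbone tree
# with a genus/family taxonomy, site environments with realistic
# correlation structure, and trait tables with known regression
# coefficients, per-site variance ratios and (optionally) lambda-scaled
# phylogenetic effects -- every estimator in the package can be scored
# against the returned ground truth.

#' Default configuration for the synthetic study generator
#'
#' The defaults emulate the design of a 24-site global riparian litter
#' survey: sites between 43 degrees S and 64 degrees N, 3-7 species per
#' non-tropical site and 6-14 per tropical site (151 species in total),
#' r(MAT, MAP) near 0.63 among the site predictors and r(N, P) near 0.58
#' among traits, and trait scales matching field measurements (litter N
#' around 1 percent of dry mass, SLA around 150 on the log scale of about
#' 5).
#'
#' @param ... Named overrides of any default element.
#' @return A named list of generator settings.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_sites = 24L,
    lat_range = c(-43, 64),
    south_prob = 1 / 3,
    tropical_cut = 23.5,
    species_range_tropical = c(6L, 14L),
    species_range_other = c(3L, 7L),
    total_species = 151L,
    r_mat_map = 0.63,
    r_n_p = 0.58,
    birth_rate = 1,
    backbone_drop = 0.25,
    sla_missing = 0.08,
    delta_log_sd = 0.3,
    trait_models = default_trait_models()
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0L) {
    abort(paste0("unknown sim_config field(s): ", paste(bad, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  cfg
}

# True generating models per trait, on the scales field data arrive in.
# beta are effects per SD of the (z-scored) environmental predictor; `log`
# marks traits generated on the log scale and exponentiated.
default_trait_models <- function() {
  list(
    N = list(intercept = 1.03,
             beta = c(MAP = 0.20, soil_pH = 0.09),
             interaction = -0.07, sigma = 0.30, log = FALSE, min = 0.05),
    P = list(intercept = 0.046,
             beta = c(MAT = -0.004, soil_pH = 0.004, soil_N = 0.007),
             interaction = 0, sigma = 0.014, log = FALSE, min = 0.002),
    Mg = list(intercept = 4.39,
              beta = c(MAP = -0.88, soil_pH = -0.94, soil_N = -0.95),
              interaction = 0, sigma = 2.2, log = FALSE, min = 0.05),
    Tan = list(intercept = 8.79,
               beta = c(MAP = 4.42, MAT = -1.91, soil_pH = -1.26),
               interaction = -1.71, sigma = 6.0, log = FALSE, min = 0.05),
    SLA = list(intercept = 5.02,
               beta = c(MAT = -0.17, soil_N = -0.14),
               interaction = 0, sigma = 0.40, log = TRUE, min = NA)
  )
}

#' Simulate an ultrametric pure-birth tree with a synthetic taxonomy
#'
#' Tips are labelled with synthetic binomials grouped into genera of 1-5
#' consecutive tips (in tree traversal order, so genera are clades or
#' near-clades) and genera into families of 1-4 genera; this gives the
#' grafting machinery both single-congener and MRCA attachment cases.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate of the pure-birth process.
#' @param seed Integer seed.
#' @return A list: `tree` (ultrametric binary `phylo`) and `taxonomy`
#'   (tibble: species, genus, family).
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed) {
  stopifnot(n_tips >= 2L)
  withr::with_seed(seed, {
    phy <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
    ord <- reorder(phy, "cladewise")
    tip_order <- ord$edge[ord$edge[, 2L] <= n_tips, 2L]
    genus_sizes <- integer(0)
    while (sum(genus_sizes) < n_tips) {
      genus_sizes <- c(genus_sizes, sample.int(5L, 1L))
    }
    genus_sizes[length(genus_sizes)] <-
      genus_sizes[length(genus_sizes)] - (sum(genus_sizes) - n_tips)
    genus_sizes <- genus_sizes[genus_sizes > 0L]
    genus_id <- rep(seq_along(genus_sizes), genus_sizes)
    fam_sizes <- integer(0)
    while (sum(fam_sizes) < length(genus_sizes)) {
      fam_sizes <- c(fam_sizes, sample.int(4L, 1L))
    }
    fam_sizes[length(fam_sizes)] <-
      fam_sizes[length(fam_sizes)] - (sum(fam_sizes) - length(genus_sizes))
    fam_sizes <- fam_sizes[fam_sizes > 0L]
    fam_of_genus <- rep(seq_along(fam_sizes), fam_sizes)
    epithet <- stats::ave(genus_id, genus_id, FUN = seq_along)
    labels <- sprintf("Genus%03d_sp%02d", genus_id, epithet)
    phy$tip.label[tip_order] <- labels
    taxonomy <- tibble(
      species = labels,
      genus = sprintf("Genus%03d", genus_id),
      family = sprintf("Family%03d", fam_of_genus[genus_id])
    )
    list(tree = validate_phylo(phy), taxonomy = taxonomy)
  })
}

#' Simulate a trait under lambda-scaled Brownian motion
#'
#' One draw from `MVN(mu * 1, sigma2 * C(lambda))`, where `C` is the tree's
#' Brownian covariance and `C(lambda)` its lambda-rescaled version, via
#' Cholesky factorization.
#'
#' @param phy A rooted `phylo` tree.
#' @param lambda Phylogenetic signal in `[0, 1]`.
#' @param sigma2 Brownian rate (>= 0; 0 gives the constant vector `mu`).
#' @param mu Ancestral mean.
#' @param seed Integer seed.
#' @return A named numeric vector in sorted tip-label order.
#' @export
simulate_lambda_traits <- function(phy, lambda, sigma2 = 1, mu = 0, seed) {
  stopifnot(lambda >= 0, lambda <= 1, sigma2 >= 0)
  C <- phylo_vcv(phy)
  n <- nrow(C)
  if (sigma2 == 0) {
    return(setNames(rep(mu, n), rownames(C)))
  }
  V <- sigma2 * lambda_transform(C, lambda)
  withr::with_seed(seed, {
    R <- chol(V + diag(1e-12 * max(diag(V)), n))
    x <- drop(mu + crossprod(R, rnorm(n)))
    setNames(x, rownames(C))
  })
}

# Target correlation structure of the site environment, built from four
# latent factors -- latitudinal gradient (G), moisture (W), soil fertility
# (S), elevation (E) -- so the matrix is positive semi-definite by
# construction: temperature falls and temperature seasonality rises away
# from the equator, precipitation variables cohere, organic-rich soils sit
# at high latitudes, and high-elevation sites are disproportionately
# tropical. The configurable r(MAT, MAP) target (default 0.63, matching the
# value implied by the loadings) is injected afterwards; a large override
# is caught by the PSD repair.
env_cor_target <- function(r_mat_map = 0.63) {
  L <- rbind(
    abs_latitude = c(0.95, 0.00, 0.00, -0.20),
    altitude     = c(-0.20, 0.00, 0.00, 0.92),
    MAT          = c(-0.88, 0.33, 0.00, -0.28),
    MAP          = c(-0.40, 0.85, 0.00, 0.00),
    TS           = c(0.90, 0.00, 0.00, 0.00),
    PS           = c(-0.40, -0.25, 0.00, 0.00),
    PDQ          = c(-0.35, 0.70, 0.00, -0.15),
    soil_pH      = c(0.00, -0.55, -0.30, 0.00),
    soil_OC      = c(0.60, 0.00, 0.45, 0.00),
    soil_N       = c(0.25, 0.00, 0.60, 0.00)
  )
  R <- tcrossprod(L)
  diag(R) <- 1
  R["MAT", "MAP"] <- r_mat_map
  R["MAP", "MAT"] <- r_mat_map
  R
}

# nearest-PSD repair by eigenvalue clipping with unit-diagonal restoration
repair_psd <- function(R, max_dist = 0.1) {
  target <- R
  for (i in 1:50) {
    eg <- eigen(R, symmetric = TRUE)
    if (min(eg$values) > 1e-8) break
    vals <- pmax(eg$values, 1e-7)
    R <- eg$vectors %*% diag(vals) %*% t(eg$vectors)
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
  }
  dist <- max(abs(R - target))
  if (dist > max_dist) {
    abort(paste0("correlation targets infeasible: PSD repair moved entries by ",
                 signif(dist, 3)))
  }
  if (dist > 1e-10) {
    inform(paste0("correlation matrix repaired to PSD (max change ",
                  signif(dist, 3), ")"))
  }
  R
}

#' Simulate the site environment table
#'
#' Site latitudes are drawn so their absolute values are uniform over the
#' configured range (southern-hemisphere sites with probability
#' `south_prob`, capped at the southern range limit); the remaining
#' environmental variables come from a multivariate normal whose
#' correlation matrix embeds the configured targets (nearest-PSD repaired
#' if needed), then are mapped to field scales (MAT in degrees C, MAP in
#' mm, pH clamped to 3.5-8.5, and so on).
#'
#' @param config A [sim_config()] list.
#' @param seed Integer seed.
#' @return A tibble with one row per site: `site`, `latitude` (signed),
#'   `abs_latitude`, `altitude`, `MAT`, `MAP`, `TS`, `PS`, `PDQ`,
#'   `soil_pH`, `soil_OC`, `soil_N`, `tropical`.
#' @export
simulate_sites <- function(config = sim_config(), seed) {
  R <- repair_psd(env_cor_target(config$r_mat_map))
  n <- config$n_sites
  withr::with_seed(seed, {
    L <- chol(R)
    Z <- matrix(rnorm(n * ncol(R)), n) %*% L
    colnames(Z) <- colnames(R)
    clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
    abs_max <- max(abs(config$lat_range))
    south_max <- abs(min(config$lat_range))
    alat <- qunif(pnorm(Z[, "abs_latitude"]), 0, abs_max)
    south <- runif(n) < config$south_prob & alat <= south_max
    out <- tibble(
      site = sprintf("S%02d", seq_len(n)),
      latitude = ifelse(south, -alat, alat),
      abs_latitude = alat,
      altitude = clamp(700 + 550 * Z[, "altitude"], 0, 4500),
      MAT = clamp(15 + 8 * Z[, "MAT"], -5, 30),
      MAP = clamp(1400 + 650 * Z[, "MAP"], 150, 6000),
      TS = clamp(4500 + 2500 * Z[, "TS"], 200, 12000),
      PS = clamp(45 + 25 * Z[, "PS"], 5, 120),
      PDQ = clamp(180 + 130 * Z[, "PDQ"], 0, 800),
      soil_pH = clamp(5.8 + 1.0 * Z[, "soil_pH"], 3.5, 8.5),
      soil_OC = clamp(35 + 20 * Z[, "soil_OC"], 2, 120),
      soil_N = clamp(1.2 + 0.5 * Z[, "soil_N"], 0.1, 3)
    )
    out$tropical <- out$abs_latitude < config$tropical_cut
    out
  })
}

# draw species-per-site counts and nudge them to the configured total
species_counts <- function(tropical, config) {
  rng_t <- config$species_range_tropical
  rng_o <- config$species_range_other
  lo <- ifelse(tropical, rng_t[1L], rng_o[1L])
  hi <- ifelse(tropical, rng_t[2L], rng_o[2L])
  counts <- lo + vapply(hi - lo + 1L, function(m) sample.int(m, 1L) - 1L,
                        integer(1L))
  target <- config$total_species
  for (i in 1:10000) {
    diff <- sum(counts) - target
    if (diff == 0L) break
    if (diff > 0L) {
      room <- which(counts > lo)
      if (length(room) == 0L) break
      j <- room[sample.int(length(room), 1L)]
      counts[j] <- counts[j] - 1L
    } else {
      room <- which(counts < hi)
      if (length(room) == 0L) break
      j <- room[sample.int(length(room), 1L)]
      counts[j] <- counts[j] + 1L
    }
  }
  counts
}

#' Simulate a species-by-trait table over sites, with ground truth
#'
#' Each trait is generated from its configured linear model in the z-scored
#' environmental predictors (optionally with a MAT x MAP interaction),
#' plus heteroscedastic noise whose standard deviation is scaled by a
#' per-site ratio `delta_s`, plus (when a tree and a lambda-positive model
#' are supplied) a lambda-scaled Brownian species effect. N and P residuals
#' are drawn with the correlation needed to bring the overall r(N, P) to
#' its configured target given the realized environmental signal; N:P is
#' derived as N/P so the tabulated ratio is always consistent with its
#' parts.
#'
#' @param sites Site table from [simulate_sites()].
#' @param config A [sim_config()] list.
#' @param seed Integer seed.
#' @param tree Optional `phylo` supplying species names and the phylogeny
#'   for lambda-scaled species effects (`trait_models[[t]]$lambda`,
#'   `$sigma2_phylo`).
#' @return A list: `traits` (tibble: species, site, N, P, NP, Mg, Tan,
#'   SLA), `truth` (generating coefficients, per-site `delta`, residual
#'   correlation used, seed).
#' @export
simulate_trait_table <- function(sites, config = sim_config(), seed,
                                 tree = NULL) {
  sites <- as_tibble(sites)
  withr::with_seed(seed, {
    counts <- species_counts(sites$tropical, config)
    n_obs <- sum(counts)
    site_of <- rep(sites$site, counts)
    if (!is.null(tree)) {
      if (length(tree$tip.label) < n_obs) {
        abort("tree has fewer tips than species observations required")
      }
      species <- sample(tree$tip.label, n_obs)
    } else {
      species <- sprintf("species_%03d", seq_len(n_obs))
    }
    delta <- exp(rnorm(nrow(sites), 0, config$delta_log_sd))
    names(delta) <- sites$site
    env_obs <- sites[match(site_of, sites$site), ]
    zcol <- function(v) as.numeric(zscore(env_obs[[v]]))
    env_vars <- c("MAT", "MAP", "TS", "PS", "PDQ", "soil_pH", "soil_OC",
                  "soil_N", "abs_latitude", "altitude")
    Z <- vapply(env_vars, zcol, numeric(n_obs))
    zint <- Z[, "MAT"] * Z[, "MAP"]
    d_obs <- delta[site_of]

    signal_of <- function(m) {
      s <- rep(m$intercept, n_obs)
      for (v in names(m$beta)) s <- s + m$beta[[v]] * Z[, v]
      if (!is.null(m$interaction) && m$interaction != 0) {
        s <- s + m$interaction * zint
      }
      s
    }
    phylo_of <- function(m, sub_seed) {
      lam <- m$lambda %||% 0
      s2 <- m$sigma2_phylo %||% 0
      if (is.null(tree) || lam == 0 || s2 == 0) return(rep(0, n_obs))
      x <- simulate_lambda_traits(tree, lambda = lam, sigma2 = s2, mu = 0,
                                  seed = sub_seed)
      unname(x[species])
    }

    models <- config$trait_models
    sig <- lapply(models, signal_of)
    # residual correlation between N and P needed to hit the overall target
    sN <- sig$N + phylo_of(models$N, seed + 11L)
    sP <- sig$P + phylo_of(models$P, seed + 12L)
    vN <- var(sN) + models$N$sigma^2 * mean(d_obs^2)
    vP <- var(sP) + models$P$sigma^2 * mean(d_obs^2)
    rho <- (config$r_n_p * sqrt(vN * vP) - stats::cov(sN, sP)) /
      (models$N$sigma * models$P$sigma * mean(d_obs^2))
    if (is.na(rho)) rho <- 0
    if (abs(rho) > 0.99) {
      inform(paste0("required N-P residual correlation ", signif(rho, 3),
                    " clamped to +/-0.99"))
      rho <- sign(rho) * 0.99
    }
    eN <- rnorm(n_obs)
    eP <- rho * eN + sqrt(1 - rho^2) * rnorm(n_obs)
    draw <- function(m, s, eps) {
      y <- s + m$sigma * d_obs * eps
      if (isTRUE(m$log)) y <- exp(y)
      # reflect (not truncate) at the positivity floor: hard clamping would
      # tie values within a site and send its variance ratio to zero
      if (!is.na(m$min)) y <- m$min + abs(y - m$min)
      y
    }
    N <- draw(models$N, sN, eN)
    P <- draw(models$P, sP, eP)
    Mg <- draw(models$Mg, sig$Mg + phylo_of(models$Mg, seed + 13L),
               rnorm(n_obs))
    Tan <- draw(models$Tan, sig$Tan + phylo_of(models$Tan, seed + 14L),
                rnorm(n_obs))
    SLA <- draw(models$SLA, sig$SLA + phylo_of(models$SLA, seed + 15L),
                rnorm(n_obs))
    if (config$sla_missing > 0) {
      SLA[runif(n_obs) < config$sla_missing] <- NA_real_
    }
    traits <- tibble(species = species, site = site_of,
                     N = N, P = P, NP = N / P, Mg = Mg, Tan = Tan, SLA = SLA)
    truth <- list(
      trait_models = models,
      delta = tibble(site = sites$site, delta = unname(delta)),
      residual_cor_NP = rho,
      counts = tibble(site = sites$site, n_species = counts),
      seed = seed
    )
    list(traits = traits, truth = truth)
  })
}

#' Simulate a complete synthetic study
#'
#' Generates, from one seed, everything the pipeline consumes: a full
#' ultrametric species tree with taxonomy, a backbone with a fraction of
#' the study species removed (so grafting has work to do), the site
#' environment table, and the trait table with its ground truth.
#'
#' @param config A [sim_config()] list.
#' @param seed Integer seed; stage sub-seeds are derived by fixed offsets.
#' @return A list: `tree` (full species tree), `backbone` (tree with
#'   `backbone_drop` of the species removed), `taxonomy`, `sites`,
#'   `traits`, `truth`, `species` (study species vector).
#' @export
simulate_study <- function(config = sim_config(), seed) {
  sites <- simulate_sites(config, seed = seed + 1L)
  yule <- simulate_yule_tree(config$total_species, config$birth_rate,
                             seed = seed + 2L)
  tt <- simulate_trait_table(sites, config, seed = seed + 3L,
                             tree = yule$tree)
  species <- unique(tt$traits$species)
  backbone <- withr::with_seed(seed + 4L, {
    n_drop <- floor(config$backbone_drop * length(species))
    drop <- sample(species, n_drop)
    ape::drop.tip(yule$tree, drop)
  })
  list(tree = yule$tree, backbone = validate_phylo(backbone),
       taxonomy = yule$taxonomy, sites = sites, traits = tt$traits,
       truth = tt$truth, species = species)
}
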