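test_that("Yule trees are ultrametric, labelled, reproducible", {
  ys <- simulate_yule_tree(151, seed = 1)
  expect_equal(ape::Ntip(ys$tree), 151L)
  expect_true(is_ultrametric(ys$tree, tol = 1e-9))
  expect_true(ape::is.binary(ys$tree))
  expect_identical(write_newick(ys$tree),
                   write_newick(simulate_yule_tree(151, seed = 1)$tree))
  expect_false(identical(write_newick(ys$tree),
                         write_newick(simulate_yule_tree(151, seed = 2)$tree)))
})

test_that("the synthetic taxonomy groups tips into genera and families", {
  ys <- simulate_yule_tree(100, seed = 3)
  tax <- ys$taxonomy
  expect_equal(nrow(tax), 100L)
  expect_false(anyDuplicated(tax$species) > 0)
  sizes <- table(tax$genus)
  expect_true(all(sizes >= 1 & sizes <= 5))
  # every genus belongs to exactly one family
  expect_true(all(tapply(tax$family, tax$genus,
                         function(f) length(unique(f))) == 1))
  expect_setequal(tax$species, ys$tree$tip.label)
})

test_that("tree depth grows like log(n)/birth over replicates", {
  mean_depth <- function(n, reps) {
    mean(vapply(seq_len(reps), function(r) {
      max(root_to_tip_depths(simulate_yule_tree(n, 1, seed = 1000 * n + r)$tree)$depth)
    }, numeric(1)))
  }
  d50 <- mean_depth(50, 15)
  d400 <- mean_depth(400, 15)
  expect_gt(d400, d50)
  # pure-birth theory: E[depth] ~ ln(n)/b, so the ratio tracks ln(400)/ln(50)
  expect_equal(d400 / d50, log(400) / log(50), tolerance = 0.35)
})

test_that("lambda-scaled Brownian draws have the prescribed covariance", {
  phy <- read_newick("((A:1,B:1):1,C:2);")
  # sigma2 = 0 degenerates to the constant mean
  expect_equal(unname(simulate_lambda_traits(phy, 1, 0, 3.5, seed = 1)),
               rep(3.5, 3))
  # lambda = 1: cov(A, B) approaches C_AB = 1
  draws <- vapply(1:2000, function(r)
    simulate_lambda_traits(phy, 1, 1, 0, seed = r)[c("A", "B")],
    numeric(2))
  expect_equal(stats::cov(draws[1, ], draws[2, ]), 1, tolerance = 0.1)
  expect_equal(stats::var(draws[1, ]), 2, tolerance = 0.2)
  # lambda = 0: sister taxa decorrelate
  draws0 <- vapply(1:500, function(r)
    simulate_lambda_traits(phy, 0, 1, 0, seed = 10000 + r)[c("A", "B")],
    numeric(2))
  expect_lt(abs(stats::cor(draws0[1, ], draws0[2, ])), 0.1)
})

test_that("site tables hit the configured correlation targets at large n", {
  st <- simulate_sites(sim_config(n_sites = 500), seed = 5)
  expect_equal(stats::cor(st$MAT, st$MAP), 0.63, tolerance = 0.1)
  expect_lt(stats::cor(st$abs_latitude, st$MAT), -0.6)
  expect_true(all(st$soil_pH >= 3.5 & st$soil_pH <= 8.5))
  expect_true(all(st$MAP >= 0))
  expect_true(all(abs(st$latitude) <= 64))
  expect_true(all(st$latitude >= -43))
})

test_that("site tables have the study dimensions and are seed-stable", {
  st <- simulate_sites(sim_config(), seed = 6)
  expect_equal(nrow(st), 24L)
  expect_false(anyDuplicated(st$site) > 0)
  expect_identical(st, simulate_sites(sim_config(), seed = 6))
})

test_that("trait tables respect counts, positivity, and N:P consistency", {
  st <- simulate_sites(sim_config(), seed = 7)
  tt <- simulate_trait_table(st, sim_config(), seed = 8)
  tr <- tt$traits
  expect_equal(nrow(tr), 151L)
  counts <- table(tr$site)
  trop <- st$tropical[match(names(counts), st$site)]
  expect_true(all(counts[trop] >= 6 & counts[trop] <= 14))
  expect_true(all(counts[!trop] >= 3 & counts[!trop] <= 7))
  for (v in c("N", "P", "NP", "Mg", "Tan")) {
    expect_true(all(tr[[v]] > 0), info = v)
  }
  expect_equal(tr$NP, tr$N / tr$P, tolerance = 1e-12)
  expect_true(anyNA(tr$SLA))
  expect_identical(tr, simulate_trait_table(st, sim_config(), seed = 8)$traits)
  # ground truth carries everything needed to score the estimators
  expect_true(all(c("trait_models", "delta", "residual_cor_NP", "counts") %in%
                    names(tt$truth)))
})

test_that("trait-trait correlation hits its target; null config decorrelates", {
  cfg <- sim_config(n_sites = 200, total_species = 1500)
  st <- simulate_sites(cfg, seed = 9)
  tt <- simulate_trait_table(st, cfg, seed = 10)
  expect_equal(stats::cor(tt$traits$N, tt$traits$P), 0.58, tolerance = 0.1)

  null_models <- default_models <- cfg$trait_models
  for (nm in names(null_models)) {
    null_models[[nm]]$beta[] <- 0
    null_models[[nm]]$interaction <- 0
  }
  cfg0 <- sim_config(n_sites = 200, total_species = 1500, r_n_p = 0,
                     trait_models = null_models, delta_log_sd = 0)
  tt0 <- simulate_trait_table(simulate_sites(cfg0, seed = 11), cfg0, seed = 12)
  env0 <- simulate_sites(cfg0, seed = 11)
  m <- dplyr::inner_join(tt0$traits, env0, by = "site")
  for (v in c("MAT", "MAP", "soil_pH", "soil_N")) {
    expect_lt(abs(stats::cor(m$N, m[[v]])), 0.1)
  }
})

test_that("phylogenetic species effects can be switched on per trait", {
  cfg <- sim_config(n_sites = 12, total_species = 60)
  cfg$trait_models$N$lambda <- 1
  cfg$trait_models$N$sigma2_phylo <- 4
  st <- simulate_sites(cfg, seed = 13)
  ys <- simulate_yule_tree(60, seed = 14)
  tt <- simulate_trait_table(st, cfg, seed = 15, tree = ys$tree)
  f <- fit_lambda(tt$traits, ys$tree, trait = "N")
  expect_gt(f$lambda, 0.3)  # strong phylo component should be detected
})

test_that("simulate_study wires all pieces together consistently", {
  s <- simulate_study(sim_config(n_sites = 10, total_species = 50,
                                 species_range_other = c(3L, 7L)),
                      seed = 16)
  expect_setequal(names(s), c("tree", "backbone", "taxonomy", "sites",
                              "traits", "truth", "species"))
  expect_equal(length(s$species), nrow(s$traits))
  expect_lt(ape::Ntip(s$backbone), ape::Ntip(s$tree))
  expect_true(all(s$backbone$tip.label %in% s$tree$tip.label))
  expect_true(all(s$traits$species %in% s$taxonomy$species))
})
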