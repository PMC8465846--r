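test_that("BLUEs equal raw means on balanced data and recover injected effects", {
  tr <- balanced_trial(g = 5, b = 4, geno_effects = c(3, 7, 2, 9, 5),
                       block_effects = c(0, 1, -2, 3), noise_sd = 0)
  bl <- suppressWarnings(
    fit_blues(tr$traits, tr$plots, "single_location", location = "L1"))
  raw <- tapply(merge(tr$traits, tr$plots)$value,
                merge(tr$traits, tr$plots)$genotype_id, mean)
  expect_equal(bl$value, as.numeric(raw[bl$genotype_id]))

  # augmented design, additive block effects, no noise: exact recovery of
  # genotype contrasts
  au <- augmented_trial(noise_sd = 0)
  bl <- suppressWarnings(
    fit_blues(au$traits, au$plots, "single_location", location = "L1"))
  est <- setNames(bl$value, bl$genotype_id)
  truth <- au$geno[names(est)]
  expect_equal(est - mean(est), truth - mean(truth), tolerance = 1e-10)
})

test_that("single observation yields itself as its BLUE", {
  plots <- data.frame(plot_id = "p1", location = "L1", block = 1L,
                      genotype_id = "G1")
  traits <- data.frame(plot_id = "p1", trait = "Y", value = 4.2)
  bl <- fit_blues(traits, plots, "single_location", location = "L1")
  expect_equal(bl$value, 4.2)
})

test_that("BLUE contrasts are invariant to a constant added to one block", {
  au <- augmented_trial(noise_sd = 0.3, seed = 8)
  bl1 <- fit_blues(au$traits, au$plots, "single_location", location = "L1")
  shifted <- au$traits
  in_b2 <- shifted$plot_id %in% au$plots$plot_id[au$plots$block == 2]
  shifted$value[in_b2] <- shifted$value[in_b2] + 5
  bl2 <- fit_blues(shifted, au$plots, "single_location", location = "L1")
  d1 <- bl1$value - mean(bl1$value)
  d2 <- bl2$value - mean(bl2$value)
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("combined-scope BLUEs require two locations and average over cells", {
  au <- augmented_trial(noise_sd = 0)
  expect_error(fit_blues(au$traits, au$plots, "combined"), "2 locations")

  sim <- simulate_study(sim_config(n_hybrids = 20, n_females = 6,
                                   n_males = 5, seed = 4))
  bl <- fit_blues(sim$traits, sim$plots, "combined",
                  which_traits = c("YLD", "HD"))
  expect_setequal(unique(bl$trait), c("YLD", "HD"))
  expect_equal(unique(bl$level), "combined_blue")
  # every genotype that was observed gets a BLUE
  expect_setequal(unique(bl$genotype_id), unique(sim$plots$genotype_id))
})

test_that("variance components hit their limits and match method of moments", {
  # zero residual noise: sigma2_res at the boundary, sigma2_g near the
  # empirical genotype variance
  tr <- balanced_trial(g = 8, b = 3, geno_effects = rnorm(8, 10, 2),
                       block_effects = rep(0, 3), noise_sd = 0, seed = 2)
  vc <- estimate_variance_components(tr$traits, tr$plots, "Y",
                                     "single_location", location = "L1")
  expect_lt(vc$sigma2_res, 1e-6)
  expect_equal(vc$sigma2_g, var(tr$geno), tolerance = 1e-6)

  # all observations identical: every component zero
  con <- balanced_trial(g = 4, b = 2, geno_effects = rep(1, 4))
  vc0 <- estimate_variance_components(con$traits, con$plots, "Y",
                                      "single_location", location = "L1")
  expect_equal(vc0$sigma2_g, 0)
  expect_equal(vc0$sigma2_res, 0)
  expect_true(vc0$boundary)

  # REML and EMS method-of-moments agree on balanced noisy data
  tr <- balanced_trial(g = 12, b = 4, geno_effects = rnorm(12, 10, 1.5),
                       block_effects = c(0, 1, -1, 2), noise_sd = 0.8,
                       seed = 3)
  reml <- estimate_variance_components(tr$traits, tr$plots, "Y",
                                       "single_location", location = "L1")
  mom <- estimate_variance_components(tr$traits, tr$plots, "Y",
                                      "single_location", location = "L1",
                                      method = "mom")
  expect_equal(reml$sigma2_g, mom$sigma2_g, tolerance = 0.05)
  expect_equal(reml$sigma2_res, mom$sigma2_res, tolerance = 0.05)
})

test_that("heritability follows its formula in both scopes", {
  one <- list(sigma2_g = 1, sigma2_gxl = NA, sigma2_res = 0, n_bar = 3,
              l = 1)
  expect_equal(heritability(one, "single_location")$h2, 1)
  zero <- list(sigma2_g = 0, sigma2_gxl = NA, sigma2_res = 1, n_bar = 2,
               l = 1)
  expect_equal(heritability(zero, "single_location")$h2, 0)
  comb <- list(sigma2_g = 1, sigma2_gxl = 1, sigma2_res = 1, n_bar = 2,
               l = 3)
  expect_equal(heritability(comb, "combined")$h2, 1 / (1 + 1/3 + 1/6))

  # the single-location formula is the combined formula without the
  # interaction term at l = 1
  set.seed(13)
  for (rep in 1:50) {
    s2g <- runif(1, 0, 3); s2r <- runif(1, 0, 3); n <- runif(1, 1, 4)
    h_single <- heritability(list(sigma2_g = s2g, sigma2_gxl = NA,
                                  sigma2_res = s2r, n_bar = n, l = 1),
                             "single_location")$h2
    expect_equal(h_single, s2g / (s2g + 0 / 1 + s2r / (n * 1)))
  }
})

test_that("heritability is monotone in its components", {
  set.seed(17)
  for (rep in 1:50) {
    s2g <- runif(1, 0.1, 3); s2r <- runif(1, 0.1, 3); n <- runif(1, 1, 4)
    h <- function(g, r, nn) heritability(
      list(sigma2_g = g, sigma2_gxl = NA, sigma2_res = r, n_bar = nn,
           l = 1), "single_location")$h2
    expect_gt(h(s2g * 1.5, s2r, n), h(s2g, s2r, n))
    expect_lt(h(s2g, s2r * 1.5, n), h(s2g, s2r, n))
    expect_gt(h(s2g, s2r, n * 1.5), h(s2g, s2r, n))
  }
})

test_that("the heritability table covers locations and combined scope", {
  sim <- simulate_study(sim_config(n_hybrids = 20, n_females = 6,
                                   n_males = 5, seed = 4))
  ht <- heritability_table(sim$traits, sim$plots, which_traits = "YLD")
  expect_equal(nrow(ht), 4)  # 3 locations + combined
  expect_true(all(ht$h2 >= 0 & ht$h2 <= 1))
  comb <- ht[ht$scope == "combined", ]
  expect_equal(comb$l, 3)
  # h2 consistent with its own components under the formula
  expect_equal(comb$h2,
               comb$sigma2_g / (comb$sigma2_g + comb$sigma2_gxl / 3 +
                                  comb$sigma2_res / (comb$n_bar * 3)),
               tolerance = 1e-12)
})
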