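test_that("zero variances collapse every observation to the mean", {
  cfg <- generator_config(n_genotypes = 10, n_checks = 2, n_trials = 2,
                          blocks_per_trial = 2, traits = "TCC",
                          sigma2_g = 0, sigma2_ge = 0, sigma2_e = 0,
                          sigma2_env = c(TCC = 0), sigma2_block = c(TCC = 0),
                          missingness = list())
  sim <- simulate_trials(cfg, seed = 3)
  expect_equal(sim$data$plots$TCC,
               rep(unname(cfg$means["TCC"]), nrow(sim$data$plots)))
})

test_that("the same seed reproduces the dataset exactly", {
  cfg <- generator_config(n_genotypes = 20, n_checks = 3, n_trials = 3,
                          blocks_per_trial = c(2, 4))
  a <- simulate_trials(cfg, seed = 11)
  b <- simulate_trials(cfg, seed = 11)
  expect_identical(a$data$plots, b$data$plots)
  expect_identical(a$truth$genotype_effects, b$truth$genotype_effects)
  c <- simulate_trials(cfg, seed = 12)
  expect_false(identical(a$data$plots, c$data$plots))
})

test_that("genotype-effect draws match the configured components", {
  cfg <- generator_config(n_genotypes = 300, n_checks = 5, n_trials = 6,
                          blocks_per_trial = 3, traits = "TCC",
                          sigma2_g = 5.44, sigma2_ge = 0, sigma2_e = 2.16,
                          missingness = list())
  sim <- simulate_trials(cfg, seed = 21)
  g <- sim$truth$genotype_effects[grep("^G", rownames(
    sim$truth$genotype_effects)), "TCC"]
  expect_lt(abs(var(g) - 5.44) / 5.44, 0.15)
  expect_lt(abs(mean(g)), 0.5)
})

test_that("genotype effects converge to the configured correlation", {
  cfg <- generator_config(n_genotypes = 2000, n_checks = 2, n_trials = 2,
                          blocks_per_trial = 2)
  sim <- simulate_trials(cfg, seed = 8)
  R_emp <- cor(sim$truth$genotype_effects)
  R_cfg <- cfg$genetic_correlation
  expect_lt(max(abs(R_emp - R_cfg)), 0.08)
  expect_gt(R_emp["TCC", "PulpColor"], 0.6) # strong carotenoid/colour link
  expect_lt(abs(R_emp["TCC", "DMC.Grav"]), 0.1) # near-null with dry matter
})

test_that("missingness restricts traits to their measured trials", {
  cfg <- generator_config(n_genotypes = 15, n_checks = 2, n_trials = 5,
                          blocks_per_trial = 2,
                          traits = c("TCC", "DMC.Grav"),
                          missingness = list(TCC = 4:5))
  sim <- simulate_trials(cfg, seed = 2)
  pl <- sim$data$plots
  expect_true(all(is.na(pl$TCC[pl$trial_id %in% c("T01", "T02", "T03")])))
  expect_true(all(!is.na(pl$TCC[pl$trial_id %in% c("T04", "T05")])))
  expect_true(all(!is.na(pl$DMC.Grav)))
})

test_that("default preset mirrors the large-panel evaluation design", {
  cfg <- generator_config()
  expect_equal(cfg$n_genotypes, 265)
  expect_equal(cfg$n_trials, 21)
  expect_equal(cfg$blocks_per_trial, c(5, 22))
  expect_equal(unname(cfg$sigma2_g["TCC"]), 5.44)
  expect_equal(cfg$missingness$TCC, 20:21) # carotenoids in 2 trials only
  R <- cfg$genetic_correlation
  expect_true(all(eigen(R, only.values = TRUE)$values > -1e-10))
  expect_equal(unname(diag(R)), rep(1, length(trait_names())))
})

test_that("generator rejects invalid configurations", {
  expect_error(generator_config(n_checks = 0), "at least one check")
  expect_error(generator_config(n_genotypes = 3, n_checks = 5),
               "more checks")
  R <- diag(2); R[1, 2] <- R[2, 1] <- 1.5
  expect_error(generator_config(traits = c("TCC", "FRY"),
                                genetic_correlation = R),
               "positive semidefinite")
})

test_that("backfilled raw measurements invert the trait formulas", {
  cfg <- generator_config(
    n_genotypes = 25, n_checks = 3, n_trials = 2, blocks_per_trial = 2,
    traits = c("DMC.Grav", "DMC.OD", "TCC", "FRY", "ShY", "NRP", "StC"),
    # narrow spreads keep every draw inside the invertible range
    sigma2_g = c(2, 2, 0.25, 2, 2, 0.2, 2),
    sigma2_ge = c(0.5, 0.5, 0, 0.5, 0.5, 0.1, 0.5),
    sigma2_e = c(0.5, 0.5, 0.1, 0.5, 0.5, 0.1, 0.5),
    missingness = list())
  sim <- simulate_trials(cfg, seed = 14)
  ds <- backfill_raw_measurements(sim$data, seed = 14)
  derived <- derive_traits(ds$plots)
  for (tr in c("DMC.Grav", "DMC.OD", "TCC", "FRY", "ShY", "NRP", "StC",
               "HI", "DRY")) {
    expect_equal(derived[[tr]], ds$plots[[tr]], tolerance = 1e-9,
                 label = tr)
  }
  # spot-check one inversion by hand
  i <- 1
  expect_equal(dmc_gravimetric(ds$plots$weight_air[i],
                               ds$plots$weight_water[i]),
               ds$plots$DMC.Grav[i], tolerance = 1e-9)
})

test_that("backfill refuses trait values outside the invertible range", {
  ds <- tiny_dataset()
  ds$plots$DMC.Grav <- c(30, 30, 10, 30, 30, 30) # 10 % < 16.3 % floor
  expect_error(backfill_raw_measurements(ds), "16.3")
})
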