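test_that("design construction enumerates fixed and random structure", {
  ds <- tiny_dataset()
  d <- suppressWarnings(build_design(ds, "TCC"))
  # single trial: trial and GE terms dropped, block and genotype kept
  expect_setequal(d$terms, c("block", "genotype"))
  expect_equal(d$e, 1)
  expect_equal(nlevels(d$frame$checkf), 3) # test baseline + 2 checks
  expect_equal(levels(d$frame$checkf)[1], "test")
  expect_equal(sum(d$frame$tind), 2) # the two unreplicated clones
  expect_error(build_design(ds, "FRY"), "absent")
  expect_error(build_design(ds$plots[0, ], "TCC"))
})

test_that("trials lacking the trait are excluded from e", {
  cfg <- generator_config(n_genotypes = 20, n_checks = 3, n_trials = 21,
                          blocks_per_trial = 2, traits = "TCC")
  sim <- simulate_trials(cfg, seed = 4)
  d <- build_design(sim$data, "TCC")
  expect_equal(d$e, 2) # carotenoids measured in two trials only
})

test_that("REML matches closed-form ANOVA on balanced one-way designs", {
  for (seed in 1:3) {
    df <- balanced_oneway(g = 12, r = 4, mu = 10, sigma2_g = 4,
                          sigma2_e = 1, seed = seed)
    names(df)[names(df) == "y"] <- "TCC"
    fit <- quiet_fit(df, "TCC")
    oracle <- oneway_anova_oracle(
      data.frame(y = df$TCC, genotype_id = df$genotype_id))
    expect_equal(unname(fit$varcomp["genotype"]), oracle$sigma2_g,
                 tolerance = 1e-6)
    expect_equal(unname(fit$varcomp["residual"]), oracle$sigma2_e,
                 tolerance = 1e-6)
    expect_equal(fit$mu, oracle$mu, tolerance = 1e-6)
    b <- setNames(fit$blups$blup_plus_intercept, fit$blups$genotype)
    expect_equal(b, oracle$shrunken_mean[names(b)], tolerance = 1e-6)
  }
})

test_that("a zero genotype variance is estimated at the boundary", {
  cfg <- generator_config(n_genotypes = 200, n_checks = 4, n_trials = 3,
                          blocks_per_trial = 4, traits = "TCC",
                          sigma2_g = 0, sigma2_ge = 0, missingness = list())
  sim <- simulate_trials(cfg, seed = 6)
  fit <- quiet_fit(sim$data, "TCC")
  # truth is zero; the estimate sits at or near the boundary, far below
  # the residual variance
  expect_lt(fit$varcomp["genotype"], 0.15 * fit$varcomp["residual"])
  expect_true(fit$converged)
})

test_that("BLUPs shrink toward the mean and track the true effects", {
  cfg <- generator_config(n_genotypes = 150, n_checks = 4, n_trials = 3,
                          blocks_per_trial = 3, traits = "TCC",
                          missingness = list())
  sim <- simulate_trials(cfg, seed = 9)
  fit <- quiet_fit(sim$data, "TCC")
  pred <- predict(fit)
  truth <- sim$truth$genotype_effects[names(pred), "TCC"]
  expect_gt(cor(pred, truth), 0.8)
  # shrinkage: BLUP spread below raw genotype-mean spread
  pl <- sim$data$plots
  raw_means <- tapply(pl$TCC, pl$genotype_id, mean)[names(pred)]
  expect_lt(var(pred), var(raw_means))
  # BLUP deviations centre near zero
  expect_lt(abs(mean(fit$blups$blup)), 0.15)
})

test_that("component estimates are invariant to genotype relabeling", {
  cfg <- generator_config(n_genotypes = 40, n_checks = 3, n_trials = 2,
                          blocks_per_trial = 2, traits = "TCC",
                          missingness = list())
  sim <- simulate_trials(cfg, seed = 10)
  fit1 <- quiet_fit(sim$data, "TCC")
  ds2 <- sim$data
  perm <- setNames(sample(sprintf("X%03d", 1:40)),
                   sprintf("G%04d", 1:40))
  idx <- !ds2$germplasm$is_check
  ds2$germplasm$genotype_id[idx] <- perm[ds2$germplasm$genotype_id[idx]]
  tidx <- ds2$plots$genotype_id %in% names(perm)
  ds2$plots$genotype_id[tidx] <- perm[ds2$plots$genotype_id[tidx]]
  fit2 <- quiet_fit(ds2, "TCC")
  expect_equal(fit2$varcomp, fit1$varcomp, tolerance = 1e-6)
  expect_equal(sort(fit2$blups$blup), sort(fit1$blups$blup),
               tolerance = 1e-6)
})

test_that("deviance tests separate null from large variance terms", {
  # null genotype variance: tiny statistic, not significant
  cfg0 <- generator_config(n_genotypes = 40, n_checks = 3, n_trials = 2,
                           blocks_per_trial = 3, traits = "TCC",
                           sigma2_g = 0, sigma2_ge = 0,
                           missingness = list())
  sim0 <- simulate_trials(cfg0, seed = 13)
  f0 <- quiet_fit(sim0$data, "TCC")
  l0 <- suppressMessages(lrt_term(f0, "genotype"))
  expect_gte(l0$chi_square, 0)
  expect_false(l0$significant_at_1pct)
  # strong genotype variance: overwhelmingly significant
  cfg1 <- generator_config(n_genotypes = 80, n_checks = 3, n_trials = 2,
                           blocks_per_trial = 3, traits = "TCC",
                           missingness = list())
  sim1 <- simulate_trials(cfg1, seed = 13)
  f1 <- quiet_fit(sim1$data, "TCC")
  l1 <- suppressMessages(lrt_term(f1, "genotype"))
  expect_true(l1$significant_at_1pct)
  expect_equal(l1$chi_square,
               2 * (f1$loglik - (f1$loglik - l1$chi_square / 2)))
  expect_error(lrt_term(f1, "nope"))
})

test_that("blup_table assembles one row per test clone across traits", {
  cfg <- generator_config(n_genotypes = 25, n_checks = 3, n_trials = 3,
                          blocks_per_trial = 2,
                          traits = c("TCC", "DMC.Grav", "FRY"),
                          missingness = list(TCC = 2:3))
  sim <- simulate_trials(cfg, seed = 15)
  fits <- suppressWarnings(suppressMessages(fit_all_traits(sim$data)))
  bt <- blup_table(fits)
  expect_equal(nrow(bt), 25)
  expect_setequal(colnames(bt), c("genotype", "TCC", "DMC.Grav", "FRY"))
  expect_true(all(!is.na(bt$DMC.Grav)))
  # predictions line up with the per-fit tables
  expect_equal(setNames(bt$FRY, bt$genotype), predict(fits$FRY))
})

test_that("fit object methods expose the model sensibly", {
  ds <- tiny_dataset()
  fit <- quiet_fit(ds, "TCC")
  expect_s3_class(fit, "cassava_fit")
  expect_named(coef(fit)[1], "(Intercept)")
  expect_length(residuals(fit), 6)
  expect_output(print(fit), "variance components")
  expect_equal(unname(logLik(fit)[1]), fit$loglik, ignore_attr = TRUE)
})
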