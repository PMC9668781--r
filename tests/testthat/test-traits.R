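test_that("gravimetric DMC follows the Kawano regression", {
  # weight in water of 0 forces the ratio to 1: 158.3 - 142
  expect_equal(dmc_gravimetric(5, 0), 16.3)
  expect_equal(dmc_gravimetric(5.000, 0.528),
               158.3 * 5 / (5 - 0.528) - 142, tolerance = 1e-12)
  expect_equal(round(dmc_gravimetric(5.000, 0.528), 2), 34.99)
  expect_error(dmc_gravimetric(2.0, 2.0), "weight_air")
  expect_error(dmc_gravimetric(1.0, 1.5), "weight_air")
  expect_warning(dmc_gravimetric(5, 4.5), "outside")
  # strictly increasing in weight_water at fixed weight_air: a heavier
  # underwater weight means denser roots, hence more dry matter
  ww <- seq(0, 1.5, by = 0.1)
  expect_true(all(diff(dmc_gravimetric(rep(5, length(ww)), ww)) > 0))
})

test_that("oven-dry DMC is the humidity complement", {
  expect_equal(dmc_oven_dry(0), 100)
  expect_equal(dmc_oven_dry(100), 0)
  expect_equal(dmc_oven_dry(60.01), 39.99)
  expect_error(dmc_oven_dry(101), "\\[0, 100\\]")
  expect_error(dmc_oven_dry(-1), "\\[0, 100\\]")
})

test_that("harvest index is the root share of total biomass", {
  expect_equal(harvest_index(10, 10), 50)
  expect_equal(harvest_index(0, 5), 0)
  expect_equal(round(harvest_index(16.49, 18.57), 2), 47.03)
  expect_error(harvest_index(0, 0), "positive sum")
  # complementarity: swapping roots and shoots sums to 100
  f <- runif(20, 0.1, 40); s <- runif(20, 0.1, 40)
  expect_equal(harvest_index(f, s) + harvest_index(s, f), rep(100, 20))
})

test_that("dry root yield is fresh yield times dry matter fraction", {
  expect_equal(dry_root_yield(10, 0), 0)
  expect_equal(dry_root_yield(1, 100), 1)
  expect_equal(round(dry_root_yield(16.49, 34.22), 3), 5.643)
  f <- runif(20, 0, 40); d <- runif(20, 0, 100)
  expect_true(all(dry_root_yield(f, d) <= f))
  expect_error(dry_root_yield(-1, 50), ">= 0")
})

test_that("spectrophotometric TCC follows the Beer-Lambert form", {
  expect_equal(tcc_spectro(0, 50, 10), 0)
  expect_equal(tcc_spectro(0.5, 50, 10), 0.5 * 50 * 1e4 / (2592 * 10),
               tolerance = 1e-12)
  expect_equal(round(tcc_spectro(0.5, 50, 10), 4), 9.6451)
  # linear in absorbance and volume, inverse in mass
  expect_equal(tcc_spectro(1.0, 50, 10), 2 * tcc_spectro(0.5, 50, 10))
  expect_equal(tcc_spectro(0.5, 100, 10), 2 * tcc_spectro(0.5, 50, 10))
  expect_equal(tcc_spectro(0.5, 50, 20), tcc_spectro(0.5, 50, 10) / 2)
  expect_error(tcc_spectro(0.5, 0, 10), "extract_volume")
  expect_error(tcc_spectro(0.5, 50, -1), "sample_mass")
})

test_that("plot-to-hectare conversion scales with area", {
  expect_equal(yield_t_ha(0, 14.4), 0)
  expect_equal(yield_t_ha(20, 14.4), 20 / 1000 * 10000 / 14.4)
  expect_equal(round(yield_t_ha(20, 14.4), 2), 13.89)
  expect_equal(yield_t_ha(20, 7.2), 2 * yield_t_ha(20, 14.4))
  expect_error(yield_t_ha(20, 0), "plot_area")
})

test_that("roots per plant treats zero harvested plants as missing", {
  expect_equal(roots_per_plant(48, 16), 3)
  expect_true(is.na(roots_per_plant(10, 0)))
  expect_error(roots_per_plant(-1, 10), ">= 0")
})

test_that("cyanogenic classification splits sweet from bitter at 100", {
  expect_equal(classify_cyanogenic(100), "sweet")
  expect_equal(classify_cyanogenic(0), "sweet")
  expect_equal(classify_cyanogenic(100.01), "bitter")
  expect_error(classify_cyanogenic(-5), ">= 0")
})

test_that("derive_traits builds the full trait set from raw columns", {
  raw <- data.frame(
    trial_id = "T01", block_id = "B1", genotype_id = c("A", "B"),
    weight_air = c(5, 5), weight_water = c(0.528, 1.0),
    humidity = c(60.01, 65), plot_root_weight = c(20, 30),
    plot_shoot_weight = c(25, 20), n_roots = c(48, 64),
    n_plants_harvested = c(16, 16), absorbance = c(0.5, 0.2),
    extract_volume = 50, sample_mass = 10, starch_content = c(25, 28),
    pulp_color = c(3, 2), hcn_score = c(3, 7),
    stringsAsFactors = FALSE)
  out <- derive_traits(raw)
  expect_equal(out$DMC.Grav, dmc_gravimetric(c(5, 5), c(0.528, 1)))
  expect_equal(out$DMC.OD, c(39.99, 35))
  expect_equal(out$FRY, yield_t_ha(c(20, 30)))
  expect_equal(out$HI, harvest_index(out$FRY, out$ShY))
  expect_equal(out$DRY, dry_root_yield(out$FRY, out$DMC.Grav))
  expect_equal(out$NRP, c(3, 4))
  expect_equal(out$TCC, tcc_spectro(c(0.5, 0.2), 50, 10))
  expect_equal(out$StC, c(25, 28))
  expect_equal(out$PulpColor, c(3, 2))
  expect_equal(out$HCN, c(3, 7))
  # missing raw input leaves the trait missing, never zero
  raw$humidity[2] <- NA
  expect_true(is.na(derive_traits(raw)$DMC.OD[2]))
})
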