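test_that("simulation is reproducible from (config, seed)", {
  cfg <- plantation_config()
  a <- simulate_plantation(cfg, seed = 11)
  b <- simulate_plantation(cfg, seed = 11)
  expect_identical(a$table, b$table)
  c <- simulate_plantation(cfg, seed = 12)
  expect_false(identical(a$table$PRI, c$table$PRI))
})

test_that("the default design mirrors the two field layouts", {
  ds1 <- simulate_plantation(plantation_config(), seed = 1)$table
  expect_equal(nrow(ds1), 480L)
  expect_equal(nlevels(ds1$population), 4L)
  expect_equal(nlevels(ds1$family), 40L)
  expect_equal(nlevels(ds1$block), 6L)
  expect_setequal(levels(ds1$population), c("BOO", "CRI", "HRI", "SER"))
  ds2 <- simulate_plantation(
    plantation_config(n_populations = 12, replicates_per_family = 4),
    seed = 1)$table
  expect_equal(nrow(ds2), 480L)
  expect_equal(nlevels(ds2$population), 12L)
})

test_that("zero variances give trees exactly at their population mean", {
  cfg <- one_trait_config(0, 0, 0, sigma2_block = 0, amp = 2)
  sim <- simulate_plantation(cfg, seed = 5)
  mu <- sim$truth$population_means[as.character(sim$table$population), "Y"]
  expect_equal(sim$table$Y, unname(mu), tolerance = 1e-12)
})

test_that("drawn family effects match their target variance", {
  cfg <- one_trait_config(1, 0.5, 8.5, n_populations = 4,
                          families_per_population = 100,
                          replicates_per_family = 1)
  expect_equal(unique(cfg$traits$h2_true), 0.25)
  sim <- simulate_plantation(cfg, seed = 6)
  v <- var(as.vector(sim$truth$family_effects))  # 400 families
  expect_gt(v, 0.85)
  expect_lt(v, 1.15)
})

test_that("heritability targets imply the documented components", {
  cfg <- plantation_config()
  tr <- cfg$traits
  expect_equal(tr$h2_true, tr$target_h2, tolerance = 1e-12)
  expect_equal(tr$sigma2_fam, tr$target_h2 * tr$phen_var / 2.5)
  expect_equal(tr$sigma2_fam + tr$sigma2_famblock + tr$sigma2_err,
               tr$phen_var)
})

test_that("invalid correlation matrices are rejected", {
  G <- diag(7); G[1, 2] <- G[2, 1] <- 1.5  # not PSD
  dimnames(G) <- list(default_trait_specs()$trait,
                      default_trait_specs()$trait)
  expect_error(plantation_config(genetic_correlation = G), "PSD")
})

test_that("simulated spectra hit index targets exactly without noise", {
  sp <- simulate_spectra(0.2, 0.5, n_leaves = 1)[[1]]
  expect_equal(pri(sp), 0.2, tolerance = 1e-12)
  expect_equal(ndvi_mnd705(sp), 0.5, tolerance = 1e-12)
  sp2 <- simulate_spectra(-0.05, 0.3, n_leaves = 1)[[1]]
  expect_equal(pri(sp2), -0.05, tolerance = 1e-12)
  expect_equal(ndvi_mnd705(sp2), 0.3, tolerance = 1e-12)
  expect_true(all(sp$reflectance >= 0 & sp$reflectance <= 100))
  expect_error(simulate_spectra(1.2, 0.5), "target_pri")
  expect_error(simulate_spectra(0.2, 0.9), "outside")
})

test_that("noisy spectra recover the PRI target on average", {
  spectra <- simulate_spectra(0.15, 0.5, n_leaves = 1000, noise_sd = 0.5,
                              seed = 44)
  pris <- vapply(spectra, pri, numeric(1))
  se <- sd(pris) / sqrt(length(pris))
  expect_lt(abs(mean(pris) - 0.15), 3 * se + 1e-4)
})

test_that("future rasters are the current rasters plus the offsets", {
  rs <- simulate_climate_rasters(n_rows = 8, n_cols = 9,
                                 future_offsets = c(T_MAX = 2))
  expect_equal(rs$future$T_MAX$values, rs$current$T_MAX$values + 2)
  rs0 <- simulate_climate_rasters(
    n_rows = 8, n_cols = 9,
    future_offsets = setNames(rep(0, 7), climate_variables()))
  for (v in climate_variables()) {
    expect_identical(rs0$future[[v]]$values, rs0$current[[v]]$values)
  }
  # elliptical distribution mask cuts the corners
  rse <- simulate_climate_rasters(n_rows = 10, n_cols = 10,
                                  mask = "ellipse")
  expect_equal(rse$mask$values[1, 1], 0)
  expect_equal(rse$mask$values[5, 5], 1)
})

test_that("a zero-offset future yields an identically zero change map", {
  # end-to-end: generator -> population means -> GAM -> two projections
  cfg <- plantation_config(n_populations = 12, replicates_per_family = 4)
  sim <- simulate_plantation(cfg, seed = 13)
  pm <- population_means(sim$table)
  cl <- cfg$climate[match(pm$population, cfg$climate$population), ]
  fit <- fit_climate_gam(pm$SLA, cl, c("T_MAX", "P_MA"))
  rs <- simulate_climate_rasters(
    n_rows = 12, n_cols = 12,
    future_offsets = setNames(rep(0, 7), climate_variables()))
  cur <- predict_surface(fit, rs$current, "current", mask = rs$mask)
  fut <- predict_surface(fit, rs$future, "future", mask = rs$mask)
  cm <- change_map(cur, fut)
  expect_true(all(cm$grid$values[!is.na(cm$grid$values)] == 0))
})
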