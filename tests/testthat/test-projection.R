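climate12 <- synthetic_climate()

# small fitted GAM reused across tests
fit_small_gam <- function(seed = 30) {
  set.seed(seed)
  y <- 0.6 * scale(climate12$T_MAX)[, 1] +
    0.3 * scale(climate12$P_MA)[, 1] + rnorm(12, sd = 0.1)
  fit_climate_gam(y, climate12, c("T_MAX", "P_MA"))
}

test_that("constant rasters predict the fitted value at that climate", {
  fit <- fit_small_gam()
  cl1 <- climate12[3, ]  # one training population's climate
  stack <- list(
    T_MAX = raster_grid(matrix(cl1$T_MAX, 4, 5)),
    P_MA = raster_grid(matrix(cl1$P_MA, 4, 5))
  )
  surf <- predict_surface(fit, stack, scenario = "current")
  expect_equal(unique(as.vector(surf$grid$values)),
               predict(fit, cl1), tolerance = 1e-10)
  expect_false(any(surf$extrapolated))
  expect_error(predict_surface(fit, stack["T_MAX"], "current"),
               "input error")
})

test_that("cells outside the training range are flagged, still predicted", {
  fit <- fit_small_gam()
  tmax <- matrix(seq(20, 40, length.out = 12), 3, 4)  # range is 25.6-33.3
  stack <- list(T_MAX = raster_grid(tmax),
                P_MA = raster_grid(matrix(800, 3, 4)))
  surf <- predict_surface(fit, stack, "current")
  out <- tmax < min(climate12$T_MAX) | tmax > max(climate12$T_MAX)
  expect_identical(surf$extrapolated, out)
  expect_false(anyNA(surf$grid$values))
})

test_that("a 2-cell gradient matches direct evaluation at those points", {
  fit <- fit_small_gam()
  pts <- climate12[c(2, 9), c("T_MAX", "P_MA")]
  stack <- list(T_MAX = raster_grid(matrix(pts$T_MAX, 1, 2)),
                P_MA = raster_grid(matrix(pts$P_MA, 1, 2)))
  surf <- predict_surface(fit, stack, "current")
  expect_equal(as.vector(surf$grid$values), predict(fit, pts),
               tolerance = 1e-12)
})

test_that("prediction commutes with raster cropping", {
  fit <- fit_small_gam()
  set.seed(31)
  stack <- list(
    T_MAX = raster_grid(matrix(runif(48, 26, 33), 6, 8)),
    P_MA = raster_grid(matrix(runif(48, 600, 1100), 6, 8))
  )
  full <- predict_surface(fit, stack, "current")
  sub <- lapply(stack, crop_raster, rows = 2:4, cols = 3:7)
  part <- predict_surface(fit, sub, "current")
  expect_equal(part$grid$values, full$grid$values[2:4, 3:7],
               tolerance = 1e-12)
  expect_equal(part$grid$xll, full$grid$xll + 2)
  expect_equal(part$grid$yll, full$grid$yll + 2)
})

test_that("proportional change is (future - current) / current", {
  cur <- as_surface(matrix(2, 3, 3), "current")
  fut <- as_surface(matrix(3, 3, 3), "future")
  cm <- change_map(cur, fut)
  expect_true(all(cm$grid$values == 0.5))
  # identical surfaces give a zero map (and a same-tag warning)
  expect_warning(cm0 <- change_map(cur, cur), "scenario tag")
  expect_true(all(cm0$grid$values == 0))
})

test_that("near-zero current values are guarded, not infinite", {
  cur_vals <- matrix(c(1e-12, 1, 2, -1), 2, 2)
  cur <- as_surface(cur_vals, "current")
  fut <- as_surface(cur_vals + 1, "future")
  cm <- change_map(cur, fut)
  expect_true(cm$undefined[1, 1])
  expect_true(is.na(cm$grid$values[1, 1]))
  expect_false(any(cm$undefined[-1]))
  expect_true(all(is.finite(cm$grid$values[!cm$undefined])))
})

test_that("change summaries cover only defined, unmasked cells", {
  vals <- matrix(0, 4, 4)
  cm <- change_map(as_surface(vals + 2, "current"),
                   as_surface(vals + 2, "future"))
  s <- summarize_change(cm)
  expect_equal(s$mean, 0)
  expect_equal(s$range, c(0, 0))

  half <- matrix(rep(c(0.1, -0.1), each = 8), 4, 4)
  cur <- as_surface(matrix(1, 4, 4), "current")
  fut <- as_surface(1 + half, "future")
  s2 <- summarize_change(change_map(cur, fut))
  expect_equal(s2$mean, 0, tolerance = 1e-12)
  expect_equal(s2$share_increasing, 0.5)
  expect_equal(s2$share_decreasing, 0.5)

  # sentinel values under the extrapolation mask never leak into summaries
  extrap <- matrix(FALSE, 4, 4); extrap[1, ] <- TRUE
  cur3 <- as_surface(matrix(1, 4, 4), "current", extrapolated = extrap)
  fvals <- matrix(1.1, 4, 4); fvals[1, ] <- 1e6  # sentinel
  fut3 <- as_surface(fvals, "future")
  s3 <- summarize_change(change_map(cur3, fut3))
  expect_equal(s3$n_cells, 12)
  expect_equal(s3$mean, 0.1, tolerance = 1e-9)
  cm_empty <- change_map(cur3, fut3)
  cm_empty$extrapolated[] <- TRUE
  expect_error(summarize_change(cm_empty), "empty summary")
})

test_that("change maps are not antisymmetric under scenario swap", {
  a <- as_surface(matrix(2, 2, 2), "current")
  b <- as_surface(matrix(3, 2, 2), "future")
  ab <- change_map(a, b)$grid$values
  ba <- change_map(b, a)$grid$values
  expect_false(isTRUE(all.equal(ab, -ba)))  # +0.5 vs -1/3
})

test_that("identical scenarios give F near 0, p near 1", {
  set.seed(33)
  x <- matrix(rnorm(100), 10, 10)
  y <- 2 * x + matrix(rnorm(100, sd = 0.2), 10, 10)
  res <- decoupling_test(as_surface(x, "current"), as_surface(y, "current"),
                         as_surface(x, "future"), as_surface(y, "future"))
  expect_lt(res$F, 1e-20)
  expect_gt(res$p_value, 0.999)
  expect_equal(unname(res$slopes["current"]), unname(res$slopes["future"]))
})

test_that("the stacked-regression F equals the pooled z^2 oracle", {
  set.seed(34)
  x1 <- rnorm(60); y1 <- 1 + 1.2 * x1 + rnorm(60, sd = 0.5)
  x2 <- rnorm(60); y2 <- 1 + 0.8 * x2 + rnorm(60, sd = 0.5)
  res <- decoupling_test(as_surface(matrix(x1, 6, 10), "current"),
                         as_surface(matrix(y1, 6, 10), "current"),
                         as_surface(matrix(x2, 6, 10), "future"),
                         as_surface(matrix(y2, 6, 10), "future"))
  expect_equal(res$F, pooled_slope_f(x1, y1, x2, y2), tolerance = 1e-9)
})

test_that("clearly different slopes are detected; observed means compared", {
  set.seed(35)
  x <- rnorm(1000)
  cur_y <- 1.0 * x + rnorm(1000, sd = 0.3)
  fut_y <- 2.0 * x + rnorm(1000, sd = 0.3)
  obs <- data.frame(x = rnorm(12), y = NA)
  obs$y <- 1.0 * obs$x + rnorm(12, sd = 0.3)
  res <- decoupling_test(as_surface(matrix(x, 25, 40), "current"),
                         as_surface(matrix(cur_y, 25, 40), "current"),
                         as_surface(matrix(x, 25, 40), "future"),
                         as_surface(matrix(fut_y, 25, 40), "future"),
                         obs = obs)
  expect_lt(res$p_value, 1e-6)
  expect_equal(unname(res$slopes["future"]), 2, tolerance = 0.1)
  expect_equal(res$obs_slope, 1, tolerance = 0.35)
  expect_gt(res$obs_p, 1e-6)  # same true slope: rarely tiny p
})

test_that("extrapolated pixels are excluded unless requested", {
  set.seed(36)
  x <- matrix(rnorm(64), 8, 8)
  y <- x + matrix(rnorm(64, sd = 0.2), 8, 8)
  extrap <- matrix(FALSE, 8, 8); extrap[, 1:2] <- TRUE
  xs <- as_surface(x, "current", extrapolated = extrap)
  ys <- as_surface(y, "current")
  xf <- as_surface(x, "future"); yf <- as_surface(y, "future")
  res_excl <- decoupling_test(xs, ys, xf, yf)
  res_incl <- decoupling_test(xs, ys, xf, yf, include_extrapolated = TRUE)
  expect_equal(unname(res_excl$n["current"]), 48)
  expect_equal(unname(res_incl$n["current"]), 64)
})
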