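#' Predict a trait surface from a fitted trait-climate GAM
#'
#' Evaluates the fitted splines at every defined cell of a co-registered
#' climate raster stack, producing a raster of predicted trait values.
#' Cells where any covariate falls outside the fit's training range are
#' still predicted but flagged in the extrapolation mask, so downstream
#' summaries can exclude them.
#'
#' @param fit a `climate_gam` from [fit_climate_gam()].
#' @param stack named list of [raster_grid()]s containing every fitted
#'   variable (see [read_raster_stack()] / [harmonize_stack()]).
#' @param scenario character tag (e.g. `"current"`).
#' @param mask optional [raster_grid()]; cells with `NA` or 0 are excluded
#'   (a species-distribution mask).
#' @return A `trait_surface`: `grid` (predictions, `NA` outside the
#'   defined area), `extrapolated` (logical matrix), `scenario`, `vars`.
#' @export
predict_surface <- function(fit, stack, scenario, mask = NULL) {
  stopifnot(inherits(fit, "climate_gam"))
  missing_vars <- setdiff(fit$vars, names(stack))
  if (length(missing_vars) > 0L) {
    stop("input error: stack lacks variable layer(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  stack <- harmonize_stack(stack[fit$vars])
  ref <- stack[[1L]]
  defined <- !attr(stack, "mask")
  if (!is.null(mask)) {
    if (!same_georef(ref, mask)) {
      stop("species-distribution mask not co-registered with stack",
           call. = FALSE)
    }
    defined <- defined & !is.na(mask$values) & mask$values > 0
  }
  idx <- which(defined)
  newdata <- as.data.frame(lapply(stack, function(g) g$values[idx]))
  pred <- matrix(NA_real_, nrow(ref$values), ncol(ref$values))
  extrap <- matrix(FALSE, nrow(ref$values), ncol(ref$values))
  if (length(idx) > 0L) {
    pred[idx] <- predict(fit, newdata)
    out_of_range <- rep(FALSE, length(idx))
    for (v in fit$vars) {
      rng <- fit$ranges[[v]]
      out_of_range <- out_of_range |
        newdata[[v]] < rng[1L] | newdata[[v]] > rng[2L]
    }
    extrap[idx] <- out_of_range
  }
  structure(list(
    grid = raster_grid(pred, xll = ref$xll, yll = ref$yll,
                       cellsize = ref$cellsize, scenario = scenario,
                       nodata = ref$nodata),
    extrapolated = extrap, scenario = scenario, vars = fit$vars
  ), class = "trait_surface")
}

#' @export
print.trait_surface <- function(x, ...) {
  n_def <- sum(!is.na(x$grid$values))
  cat("Trait surface (", x$scenario, "): ", n_def, " predicted cells, ",
      sum(x$extrapolated), " flagged extrapolated\n", sep = "")
  invisible(x)
}

#' Proportional trait-change map between two scenarios
#'
#' Per-cell proportional change `(future - current) / current`. Cells with
#' `|current|` below a guard (a small fraction of the 95th percentile of
#' `|current|`) are marked undefined rather than producing huge ratios —
#' relevant for indices like PRI that cross zero.
#'
#' @param current,future `trait_surface`s from the same fit, co-registered.
#' @param guard relative guard on `|current|` (default `1e-6`).
#' @return A `prop_change_map`: `grid` (change values), `undefined`
#'   (logical matrix of guarded cells), `extrapolated` (union of the two
#'   scenarios' masks).
#' @export
change_map <- function(current, future, guard = 1e-6) {
  stopifnot(inherits(current, "trait_surface"),
            inherits(future, "trait_surface"))
  if (!same_georef(current$grid, future$grid)) {
    stop("surfaces are not co-registered", call. = FALSE)
  }
  if (identical(current$scenario, future$scenario)) {
    warning("both surfaces carry scenario tag '", current$scenario, "'",
            call. = FALSE)
  }
  cur <- current$grid$values
  fut <- future$grid$values
  scale95 <- quantile(abs(cur[!is.na(cur)]), 0.95, names = FALSE)
  thresh <- guard * scale95
  undefined <- !is.na(cur) & abs(cur) < thresh
  chg <- (fut - cur) / cur
  chg[undefined] <- NA_real_
  structure(list(
    grid = raster_grid(chg, xll = current$grid$xll, yll = current$grid$yll,
                       cellsize = current$grid$cellsize,
                       scenario = paste0(current$scenario, "->",
                                         future$scenario),
                       nodata = current$grid$nodata),
    undefined = undefined,
    extrapolated = current$extrapolated | future$extrapolated
  ), class = "prop_change_map")
}

#' Summary of a proportional-change map
#'
#' Range, mean, and shares of cells increasing/decreasing, over cells that
#' are defined, not guarded, and not extrapolated.
#'
#' @param map a `prop_change_map`.
#' @return List: `mean`, `range` (min, max), `share_increasing`,
#'   `share_decreasing`, `n_cells`.
#' @export
summarize_change <- function(map) {
  stopifnot(inherits(map, "prop_change_map"))
  v <- map$grid$values
  use <- !is.na(v) & !map$undefined & !map$extrapolated
  vals <- v[use]
  if (length(vals) == 0L) {
    stop("empty summary: no defined, non-extrapolated cells", call. = FALSE)
  }
  list(mean = mean(vals), range = range(vals),
       share_increasing = mean(vals > 0),
       share_decreasing = mean(vals < 0),
       n_cells = length(vals))
}

# Paired pixel values of two co-registered surfaces over usable cells.
surface_pairs <- function(xs, ys, include_extrapolated = FALSE) {
  if (!same_georef(xs$grid, ys$grid)) {
    stop("surfaces are not co-registered", call. = FALSE)
  }
  use <- !is.na(xs$grid$values) & !is.na(ys$grid$values)
  if (!include_extrapolated) {
    use <- use & !xs$extrapolated & !ys$extrapolated
  }
  data.frame(x = xs$grid$values[use], y = ys$grid$values[use])
}

#' Test for decoupling of a trait correlation between climate scenarios
#'
#' Regresses the y-trait surface on the x-trait surface over defined
#' pixels within each scenario and tests whether the two slopes differ:
#' the stacked regression `y ~ x * scenario` is fitted and the
#' scenario-by-x interaction is tested with a linear-hypothesis F test
#' (equivalent to the classical equal-slopes test with pooled residual
#' variance). Pixels are treated as independent observations; no spatial
#' autocorrelation correction is applied (recorded in the output).
#'
#' Optionally the current spatial slope is also compared against the slope
#' over observed population or family trait means (`obs`), assessing
#' whether the spatial pattern mirrors the measured genetic pattern.
#'
#' @param x_current,y_current `trait_surface`s for the first scenario.
#' @param x_future,y_future `trait_surface`s for the second scenario.
#' @param include_extrapolated include extrapolation-flagged pixels
#'   (default `FALSE`).
#' @param obs optional data.frame with columns `x`, `y` of observed means.
#' @return A `slope_test`: per-scenario `slopes`, `r_squared`, `n`; `F`,
#'   `p_value`, `df` for slope equality; and, when `obs` is given,
#'   `obs_slope`, `obs_F`, `obs_p`.
#' @export
decoupling_test <- function(x_current, y_current, x_future, y_future,
                            include_extrapolated = FALSE, obs = NULL) {
  cur <- surface_pairs(x_current, y_current, include_extrapolated)
  fut <- surface_pairs(x_future, y_future, include_extrapolated)
  if (nrow(cur) < 3L || nrow(fut) < 3L) {
    stop("need >= 3 defined pixels per scenario", call. = FALSE)
  }
  if (var(cur$x) == 0 || var(fut$x) == 0) {
    stop("degenerate x variance in a scenario", call. = FALSE)
  }
  fit_cur <- lm(y ~ x, data = cur)
  fit_fut <- lm(y ~ x, data = fut)
  stacked <- rbind(cbind(cur, scenario = "current"),
                   cbind(fut, scenario = "future"))
  stacked$scenario <- factor(stacked$scenario,
                             levels = c("current", "future"))
  fit_stack <- lm(y ~ x * scenario, data = stacked)
  lh <- car::linearHypothesis(fit_stack, "x:scenariofuture = 0")
  res <- structure(list(
    slopes = c(current = unname(coef(fit_cur)[2L]),
               future = unname(coef(fit_fut)[2L])),
    r_squared = c(current = summary(fit_cur)$r.squared,
                  future = summary(fit_fut)$r.squared),
    n = c(current = nrow(cur), future = nrow(fut)),
    F = lh$F[2L], p_value = lh$`Pr(>F)`[2L],
    df = c(lh$Df[2L], lh$Res.Df[2L]),
    spatial_independence_assumed = TRUE
  ), class = "slope_test")
  if (!is.null(obs)) {
    obs <- obs[complete.cases(obs[, c("x", "y")]), , drop = FALSE]
    if (nrow(obs) >= 3L && var(obs$x) > 0) {
      fit_obs <- lm(y ~ x, data = obs)
      st2 <- rbind(cbind(cur[, c("x", "y")], scenario = "current"),
                   cbind(obs[, c("x", "y")], scenario = "observed"))
      st2$scenario <- factor(st2$scenario,
                             levels = c("current", "observed"))
      f2 <- lm(y ~ x * scenario, data = st2)
      lh2 <- car::linearHypothesis(f2, "x:scenarioobserved = 0")
      res$obs_slope <- unname(coef(fit_obs)[2L])
      res$obs_r_squared <- summary(fit_obs)$r.squared
      res$obs_F <- lh2$F[2L]
      res$obs_p <- lh2$`Pr(>F)`[2L]
    }
  }
  res
}

#' @export
print.slope_test <- function(x, ...) {
  cat("Slope-equality (decoupling) test\n")
  cat("  current slope ", format(signif(x$slopes["current"], 4)),
      " (R^2 ", format(round(x$r_squared["current"], 3)), ", n ",
      x$n["current"], ")\n", sep = "")
  cat("  future  slope ", format(signif(x$slopes["future"], 4)),
      " (R^2 ", format(round(x$r_squared["future"], 3)), ", n ",
      x$n["future"], ")\n", sep = "")
  cat("  F(", x$df[1L], ", ", x$df[2L], ") = ", format(signif(x$F, 4)),
      ", p = ", format(signif(x$p_value, 3)), "\n", sep = "")
  if (!is.null(x$obs_slope)) {
    cat("  observed-means slope ", format(signif(x$obs_slope, 4)),
        "; vs current: F = ", format(signif(x$obs_F, 4)), ", p = ",
        format(signif(x$obs_p, 3)), "\n", sep = "")
  }
  invisible(x)
}
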