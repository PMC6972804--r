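#' Default trait specifications for the plantation generator
#'
#' One row per simulated trait: overall mean `mu`, within-population
#' phenotypic variance `phen_var` (the h^2 denominator: family +
#' family-by-block + error), target narrow-sense heritability `target_h2`,
#' the shares of `phen_var` given to the family-by-block interaction and
#' (relative to `phen_var`) to the block effect, and the deterministic
#' population-mean response: climate `driver`, amplitude `amp` (trait
#' units per driver SD) and `shape` (`"linear"` or `"sin"`).
#'
#' The defaults emulate the seven study traits at their published point
#' heritabilities (0.08-0.22) and field-realistic means and spreads.
#'
#' @return data.frame with one row per trait.
#' @export
default_trait_specs <- function() {
  data.frame(
    trait = c("PRI", "NDVI", "LS", "SLA", "d13C", "N_CONC", "WD"),
    mu = c(0.02, 0.55, 30, 5.5, -29, 1.4, 0.55),
    phen_var = c(1e-4, 2.5e-3, 36, 1, 1, 0.04, 3.6e-3),
    target_h2 = c(0.11, 0.15, 0.18, 0.08, 0.17, 0.22, 0.12),
    famblock_share = 0.10,
    block_share = 0.05,
    driver = c("P_MA", "T_MA", "T_MA", "T_MAX", "P_DM", "T_MA", "T_MAX"),
    amp = c(0.012, 0.03, 5, 0.7, 1.0, 0.12, -0.045),
    shape = "linear",
    stringsAsFactors = FALSE
  )
}

#' Default cross-trait genetic correlation matrix
#'
#' Correlations of family (additive) effects across the seven default
#' traits: +0.5 for d13C:PRI, LS:NDVI and SLA:N_CONC, -0.5 for WD:N_CONC
#' (the one negative study pair), 0 elsewhere. Positive semi-definite.
#'
#' @param traits trait names (default the seven).
#' @return Correlation matrix.
#' @export
default_genetic_correlation <- function(traits = default_trait_specs()$trait) {
  G <- diag(length(traits))
  dimnames(G) <- list(traits, traits)
  set_cor <- function(a, b, r) {
    if (a %in% traits && b %in% traits) {
      G[a, b] <<- r; G[b, a] <<- r
    }
  }
  set_cor("d13C", "PRI", 0.5)
  set_cor("LS", "NDVI", 0.5)
  set_cor("WD", "N_CONC", -0.5)
  set_cor("SLA", "N_CONC", 0.5)
  G
}

#' Configuration for the synthetic plantation generator
#'
#' Defines a half-sib provenance trial to simulate. The defaults mirror
#' the heritability dataset of the study design: 4 populations x 10
#' families x 12 replicates in 6 blocks (480 trees). Use
#' `n_populations = 12, replicates_per_family = 4` for the
#' trait-climate-modelling layout (also 480 trees).
#'
#' Per trait, the variance components are derived from the target
#' heritability: `sigma2_fam = target_h2 * phen_var / 2.5`,
#' `sigma2_famblock = famblock_share * phen_var`,
#' `sigma2_err = phen_var - sigma2_fam - sigma2_famblock`, and
#' `sigma2_block = block_share * phen_var`; or supplied directly via
#' columns `sigma2_fam`, `sigma2_famblock`, `sigma2_err`, `sigma2_block`
#' in `traits`. Population means are deterministic functions of each
#' population's climate-of-origin.
#'
#' @param n_blocks,n_populations,families_per_population,replicates_per_family
#'   design dimensions.
#' @param traits trait specification data.frame (see
#'   [default_trait_specs()]).
#' @param populations population names; defaults to the study populations
#'   (the four heritability populations when `n_populations = 4`).
#' @param climate data.frame of per-population climate (default
#'   [synthetic_climate()] for the chosen populations).
#' @param genetic_correlation,residual_correlation cross-trait correlation
#'   matrices for family effects and residuals (PSD, unit diagonal).
#' @return A `plantation_config` list.
#' @export
plantation_config <- function(n_blocks = 6, n_populations = 4,
                              families_per_population = 10,
                              replicates_per_family = 12,
                              traits = default_trait_specs(),
                              populations = NULL,
                              climate = NULL,
                              genetic_correlation = NULL,
                              residual_correlation = NULL) {
  stopifnot(n_blocks >= 1, n_populations >= 1,
            families_per_population >= 1, replicates_per_family >= 1)
  if (is.null(populations)) {
    all_pops <- population_climate()
    populations <- if (n_populations == 4L) {
      all_pops$population[all_pops$dataset1]
    } else if (n_populations <= nrow(all_pops)) {
      all_pops$population[seq_len(n_populations)]
    } else {
      sprintf("P%02d", seq_len(n_populations))
    }
  }
  stopifnot(length(populations) == n_populations)
  if (is.null(climate)) {
    climate <- if (all(populations %in% population_climate()$population)) {
      synthetic_climate(populations)
    } else {
      stop("supply a climate table for non-study population names",
           call. = FALSE)
    }
  }
  traits <- derive_components(traits)
  tn <- traits$trait
  if (is.null(genetic_correlation)) {
    genetic_correlation <- default_genetic_correlation(tn)
  }
  if (is.null(residual_correlation)) {
    residual_correlation <- diag(length(tn))
    dimnames(residual_correlation) <- list(tn, tn)
  }
  for (M in list(genetic_correlation, residual_correlation)) {
    if (!isSymmetric(unname(M)) || any(abs(diag(M) - 1) > 1e-12) ||
        min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("config error: correlation matrices must be symmetric PSD with ",
           "unit diagonal", call. = FALSE)
    }
  }
  structure(list(
    n_blocks = as.integer(n_blocks),
    n_populations = as.integer(n_populations),
    families_per_population = as.integer(families_per_population),
    replicates_per_family = as.integer(replicates_per_family),
    traits = traits, populations = populations, climate = climate,
    genetic_correlation = genetic_correlation,
    residual_correlation = residual_correlation
  ), class = "plantation_config")
}

# Fill sigma2_* columns from target h2 where not supplied explicitly.
derive_components <- function(traits) {
  traits <- as.data.frame(traits, stringsAsFactors = FALSE)
  stopifnot("trait" %in% names(traits), "mu" %in% names(traits))
  has <- function(col) col %in% names(traits) && !anyNA(traits[[col]])
  if (!all(vapply(c("sigma2_fam", "sigma2_famblock", "sigma2_err"),
                  has, logical(1)))) {
    stopifnot(all(c("target_h2", "phen_var") %in% names(traits)))
    vp <- traits$phen_var
    share <- if ("famblock_share" %in% names(traits)) {
      traits$famblock_share
    } else 0.10
    traits$sigma2_fam <- traits$target_h2 * vp / 2.5
    traits$sigma2_famblock <- share * vp
    traits$sigma2_err <- vp - traits$sigma2_fam - traits$sigma2_famblock
    if (any(traits$sigma2_err <= 0)) {
      stop("config error: target_h2/2.5 + famblock_share must be < 1",
           call. = FALSE)
    }
  }
  if (!has("sigma2_block")) {
    bshare <- if ("block_share" %in% names(traits)) {
      traits$block_share
    } else 0.05
    vp <- traits$sigma2_fam + traits$sigma2_famblock + traits$sigma2_err
    traits$sigma2_block <- bshare * vp
  }
  if (any(traits[, c("sigma2_fam", "sigma2_famblock", "sigma2_err",
                     "sigma2_block")] < 0)) {
    stop("config error: variance components must be >= 0", call. = FALSE)
  }
  traits$h2_true <- 2.5 * traits$sigma2_fam /
    (traits$sigma2_fam + traits$sigma2_famblock + traits$sigma2_err)
  traits
}

# Deterministic population effect per trait from climate-of-origin.
population_effects <- function(config) {
  cl <- config$climate
  idx <- match(config$populations, cl$population)
  tr <- config$traits
  eff <- matrix(0, config$n_populations, nrow(tr),
                dimnames = list(config$populations, tr$trait))
  for (t in seq_len(nrow(tr))) {
    drv <- tr$driver[t]
    if (is.na(drv) || !drv %in% names(cl)) next
    x <- cl[[drv]][idx]
    if (sd(x) == 0) next
    z <- (x - mean(x)) / sd(x)
    eff[, t] <- switch(tr$shape[t],
      linear = tr$amp[t] * z,
      sin = tr$amp[t] * sin(pi * (x - min(x)) / (max(x) - min(x))),
      stop("unknown population-mean shape '", tr$shape[t], "'",
           call. = FALSE))
  }
  eff
}

# Correlated Gaussian draws: n rows, columns with SDs `sds` and
# correlation `R` (PSD; zero-variance columns allowed).
draw_correlated <- function(n, sds, R) {
  k <- length(sds)
  Z <- matrix(rnorm(n * k), n, k)
  ev <- eigen(R, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k) %*% t(ev$vectors)
  (Z %*% L) * rep(sds, each = n)
}

#' Simulate a half-sib common-garden plantation
#'
#' Draws a full synthetic trial from a [plantation_config()]: each tree's
#' trait value is
#' `mu + population effect (deterministic from climate) + block + family +
#' block-by-family + residual`, all Gaussian with the configured
#' variances. Family effects are correlated across traits by the genetic
#' correlation matrix and residuals by the residual correlation matrix;
#' block and block-by-family effects are independent across traits.
#' The output is reproducible bit-for-bit from `(config, seed)`.
#'
#' @param config a [plantation_config()].
#' @param seed integer RNG seed.
#' @return A `synthetic_plantation`: `table` (a [trait_table()]), `truth`
#'   (population means, block/family/family-block effect draws, true
#'   variance components with `h2_true`), `config`, `seed`.
#' @export
simulate_plantation <- function(config, seed = 1L) {
  stopifnot(inherits(config, "plantation_config"))
  set.seed(seed)
  tr <- config$traits
  tn <- tr$trait
  B <- config$n_blocks
  Fpp <- config$families_per_population
  Rep <- config$replicates_per_family
  pops <- config$populations
  n_fam <- length(pops) * Fpp
  fam_ids <- as.vector(vapply(pops, function(p) {
    sprintf("%s_f%02d", p, seq_len(Fpp))
  }, character(Fpp)))
  fam_pop <- rep(pops, each = Fpp)

  pop_eff <- population_effects(config)
  block_eff <- vapply(tr$sigma2_block, function(v) {
    rnorm(B, sd = sqrt(v))
  }, numeric(B))
  dimnames(block_eff) <- list(sprintf("B%d", seq_len(B)), tn)
  fam_eff <- draw_correlated(n_fam, sqrt(tr$sigma2_fam),
                             config$genetic_correlation)
  dimnames(fam_eff) <- list(fam_ids, tn)
  fb_eff <- vapply(tr$sigma2_famblock, function(v) {
    rnorm(n_fam * B, sd = sqrt(v))
  }, numeric(n_fam * B))
  dimnames(fb_eff) <- list(as.vector(outer(fam_ids, seq_len(B),
                                           function(f, b) {
                                             paste0(f, ":B", b)
                                           })), tn)

  n_trees <- n_fam * Rep
  rows <- data.frame(
    fam_idx = rep(seq_len(n_fam), each = Rep),
    rep = rep(seq_len(Rep), times = n_fam)
  )
  # staggered block assignment: balanced when Rep is a multiple of B,
  # latinized across families otherwise
  rows$block <- ((rows$fam_idx + rows$rep - 2L) %% B) + 1L
  resid <- draw_correlated(n_trees, sqrt(tr$sigma2_err),
                           config$residual_correlation)

  values <- matrix(0, n_trees, length(tn), dimnames = list(NULL, tn))
  pop_idx <- match(fam_pop[rows$fam_idx], pops)
  fb_idx <- (rows$block - 1L) * n_fam + rows$fam_idx
  for (t in seq_along(tn)) {
    values[, t] <- tr$mu[t] + pop_eff[pop_idx, t] +
      block_eff[rows$block, t] + fam_eff[rows$fam_idx, t] +
      fb_eff[fb_idx, t] + resid[, t]
  }
  df <- data.frame(
    tree_id = sprintf("%s_r%02d", fam_ids[rows$fam_idx], rows$rep),
    block = sprintf("B%d", rows$block),
    population = fam_pop[rows$fam_idx],
    family = fam_ids[rows$fam_idx],
    stringsAsFactors = FALSE
  )
  for (t in seq_along(tn)) df[[tn[t]]] <- values[, t]
  structure(list(
    table = trait_table(df, traits = tn),
    truth = list(
      population_means = sweep(pop_eff, 2L, tr$mu, `+`),
      population_effects = pop_eff,
      block_effects = block_eff,
      family_effects = fam_eff,
      famblock_effects = fb_eff,
      components = tr[, c("trait", "sigma2_block", "sigma2_fam",
                          "sigma2_famblock", "sigma2_err", "h2_true")]
    ),
    config = config, seed = seed
  ), class = "synthetic_plantation")
}

#' @export
print.synthetic_plantation <- function(x, ...) {
  cat("Synthetic plantation (seed ", x$seed, "): ", sep = "")
  print(x$table)
  invisible(x)
}

#' Simulate leaf reflectance spectra with known index targets
#'
#' Constructs smooth leaf-like spectra whose band values at the index
#' wavelengths solve the two index equations exactly: with scale `c`,
#' `R531 = c (1 + p)` and `R570 = c (1 - p)` give PRI = `p`; with fixed
#' `R445` and `R705`, `R750` is solved from the mND705 equation to give
#' NDVI = `v`. Band-wise Gaussian noise (SD in % reflectance) is added on
#' top, so at `noise_sd = 0` the indices are recovered exactly.
#'
#' @param target_pri PRI target, |p| < 1.
#' @param target_ndvi mND705 target; must yield `R750` in (0, 100].
#' @param n_leaves number of leaf spectra (default 3).
#' @param noise_sd band-wise noise SD, % reflectance (default 0).
#' @param wavelengths integer nm grid (default 400:800).
#' @param tree_id identifier attached to the spectra.
#' @param seed optional RNG seed.
#' @return List of [reflectance_spectrum()]s.
#' @export
simulate_spectra <- function(target_pri, target_ndvi, n_leaves = 3,
                             noise_sd = 0, wavelengths = 400:800,
                             tree_id = "t01", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (abs(target_pri) >= 1) {
    stop("construction error: |target_pri| must be < 1", call. = FALSE)
  }
  req <- c(445, 531, 570, 705, 750)
  if (!all(req %in% wavelengths)) {
    stop("wavelength grid must cover bands ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  c0 <- 10; r445 <- 5; r705 <- 20
  r531 <- c0 * (1 + target_pri)
  r570 <- c0 * (1 - target_pri)
  if (abs(1 - target_ndvi) < 1e-9) {
    stop("construction error: target_ndvi = 1 is infeasible", call. = FALSE)
  }
  r750 <- (r705 * (1 + target_ndvi) - 2 * r445 * target_ndvi) /
    (1 - target_ndvi)
  if (!is.finite(r750) || r750 <= 0 || r750 > 100) {
    stop("construction error: target_ndvi = ", target_ndvi,
         " puts R750 outside (0, 100]", call. = FALSE)
  }
  anchors_wl <- c(400, 445, 531, 570, 650, 705, 750, 800)
  anchors_r <- c(4, r445, r531, r570, 15, r705, r750, r750)
  base <- stats::spline(anchors_wl, anchors_r, xout = wavelengths,
                        method = "natural")$y
  base[match(req, wavelengths)] <- c(r445, r531, r570, r705, r750)
  base <- pmin(pmax(base, 0.01), 100)
  lapply(seq_len(n_leaves), function(i) {
    refl <- base
    if (noise_sd > 0) {
      refl <- pmin(pmax(refl + rnorm(length(refl), sd = noise_sd), 0.01),
                   100)
    }
    reflectance_spectrum(wavelengths, refl, tree_id = tree_id,
                         leaf_id = sprintf("%s_leaf%d", tree_id, i))
  })
}

#' Convert a list of spectra to the long CSV layout
#'
#' @param spectra list of [reflectance_spectrum()]s.
#' @return data.frame with `tree_id`, `leaf_id`, `wavelength_nm`,
#'   `reflectance_pct`.
#' @export
spectra_to_long <- function(spectra) {
  do.call(rbind, lapply(spectra, function(sp) {
    data.frame(tree_id = sp$tree_id, leaf_id = sp$leaf_id,
               wavelength_nm = sp$wavelengths,
               reflectance_pct = sp$reflectance,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate co-registered current and future climate raster stacks
#'
#' Builds affine (planar-gradient) fields for each climate variable over
#' an `n_rows` x `n_cols` grid spanning the climate ranges of the study
#' populations, plus a future stack shifted by per-variable offsets
#' (defaults emulate a hotter, drier 2070 high-emissions scenario), and a
#' species-distribution mask raster. Precipitation is floored at zero.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param variables climate variable names (default all seven).
#' @param gradients named list `variable = c(lo, hi)` value ranges;
#'   defaults span the study populations' climate.
#' @param future_offsets named numeric per-variable deltas; defaults:
#'   T_MA +2.2, T_MAX +2.8, T_RANGE +0.5, P_MA -120, P_DM -4,
#'   P_RANGE +10, AI_inv +0.4. Zero for unnamed variables.
#' @param cellsize,xll,yll georeference (defaults: 0.05 degree cells over
#'   southwestern Australia).
#' @param mask `"all"` (every cell in the distribution) or `"ellipse"`
#'   (an inscribed elliptical distribution).
#' @return List with `current` and `future` (harmonized stacks of
#'   [raster_grid()]s) and `mask` (a 0/1 [raster_grid()]).
#' @export
simulate_climate_rasters <- function(n_rows = 30, n_cols = 30,
                                     variables = climate_variables(),
                                     gradients = NULL,
                                     future_offsets = NULL,
                                     cellsize = 0.05, xll = 115, yll = -35,
                                     mask = c("all", "ellipse")) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  mask <- match.arg(mask)
  cl <- synthetic_climate()
  default_grad <- lapply(variables, function(v) {
    if (v %in% names(cl)) range(cl[[v]]) else c(0, 1)
  })
  names(default_grad) <- variables
  if (!is.null(gradients)) default_grad[names(gradients)] <- gradients
  def_off <- c(T_MA = 2.2, T_MAX = 2.8, T_RANGE = 0.5, P_MA = -120,
               P_DM = -4, P_RANGE = 10, AI_inv = 0.4)
  offsets <- setNames(rep(0, length(variables)), variables)
  common <- intersect(variables, names(def_off))
  offsets[common] <- def_off[common]
  if (!is.null(future_offsets)) {
    offsets[names(future_offsets)] <- future_offsets
  }
  u <- matrix(rep((seq_len(n_cols) - 1) / max(1, n_cols - 1),
                  each = n_rows), n_rows, n_cols)
  w <- matrix(rep((n_rows - seq_len(n_rows)) / max(1, n_rows - 1),
                  times = n_cols), n_rows, n_cols)
  cur <- list()
  fut <- list()
  for (i in seq_along(variables)) {
    v <- variables[i]
    rng <- default_grad[[v]]
    a <- if (startsWith(v, "T")) 0.3 else 0.7
    field <- rng[1] + (rng[2] - rng[1]) * (a * u + (1 - a) * w)
    fld_fut <- field + offsets[[v]]
    if (v %in% c("P_MA", "P_DM", "P_RANGE")) {
      field <- pmax(field, 0); fld_fut <- pmax(fld_fut, 0)
    }
    cur[[v]] <- raster_grid(field, xll = xll, yll = yll,
                            cellsize = cellsize, scenario = "current")
    fut[[v]] <- raster_grid(fld_fut, xll = xll, yll = yll,
                            cellsize = cellsize, scenario = "future")
  }
  m <- matrix(1, n_rows, n_cols)
  if (mask == "ellipse") {
    rr <- (row(m) - (n_rows + 1) / 2) / (n_rows / 2)
    cc <- (col(m) - (n_cols + 1) / 2) / (n_cols / 2)
    m[rr^2 + cc^2 > 1] <- 0
  }
  list(current = harmonize_stack(cur), future = harmonize_stack(fut),
       mask = raster_grid(m, xll = xll, yll = yll, cellsize = cellsize))
}

#' Population-level trait means
#'
#' Mean trait value per population over all trees (used as the response
#' of the trait-climate GAMs, since climate-of-origin is constant within
#' a population).
#'
#' @param table a [trait_table()].
#' @param traits trait columns; default all.
#' @return data.frame with `population`, `n_trees`, one column per trait.
#' @export
population_means <- function(table, traits = NULL) {
  stopifnot(inherits(table, "trait_table"))
  if (is.null(traits)) traits <- attr(table, "traits")
  pops <- split(seq_len(nrow(table)), table$population, drop = TRUE)
  rows <- lapply(names(pops), function(p) {
    idx <- pops[[p]]
    out <- data.frame(population = p, n_trees = length(idx),
                      stringsAsFactors = FALSE)
    for (tr in traits) out[[tr]] <- mean(table[[tr]][idx], na.rm = TRUE)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
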