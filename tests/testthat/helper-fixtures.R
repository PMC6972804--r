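# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# Tiny hand-built trait table
tiny_table <- function() {
  trait_table(data.frame(
    tree_id = c("t1", "t2", "t3", "t4"),
    block = c("B1", "B2", "B1", "B2"),
    population = c("A", "A", "B", "B"),
    family = c("A_f1", "A_f1", "B_f1", "B_f1"),
    WD = c(0.5, 0.55, 0.6, 0.62)
  ))
}

# Single-trait generator config with explicit variance components
one_trait_config <- function(sigma2_fam, sigma2_famblock, sigma2_err,
                             sigma2_block = 0.3,
                             n_populations = 4,
                             families_per_population = 10,
                             replicates_per_family = 12,
                             n_blocks = 6, amp = 0, driver = "T_MAX") {
  tr <- data.frame(trait = "Y", mu = 10,
                   sigma2_fam = sigma2_fam,
                   sigma2_famblock = sigma2_famblock,
                   sigma2_err = sigma2_err,
                   sigma2_block = sigma2_block,
                   driver = driver, amp = amp, shape = "linear",
                   stringsAsFactors = FALSE)
  plantation_config(n_blocks = n_blocks, n_populations = n_populations,
                    families_per_population = families_per_population,
                    replicates_per_family = replicates_per_family,
                    traits = tr)
}

# Flat spectrum with chosen values at the index bands
flat_spectrum <- function(r445 = 5, r531 = 10, r570 = 10, r705 = 20,
                          r750 = 40, base = 8) {
  wl <- 400:800
  refl <- rep(base, length(wl))
  refl[match(c(445, 531, 570, 705, 750), wl)] <-
    c(r445, r531, r570, r705, r750)
  reflectance_spectrum(wl, refl)
}

# Wrap a numeric matrix as a trait surface (for projection tests)
as_surface <- function(values, scenario = "current",
                       extrapolated = NULL) {
  values <- as.matrix(values)
  if (is.null(extrapolated)) {
    extrapolated <- matrix(FALSE, nrow(values), ncol(values))
  }
  structure(list(grid = raster_grid(values, scenario = scenario),
                 extrapolated = extrapolated, scenario = scenario,
                 vars = character(0)),
            class = "trait_surface")
}

# Pooled-variance two-sample slope F statistic (algebraic oracle for the
# stacked-regression slope-equality test)
pooled_slope_f <- function(x1, y1, x2, y2) {
  f1 <- lm(y1 ~ x1); f2 <- lm(y2 ~ x2)
  rss <- sum(resid(f1)^2) + sum(resid(f2)^2)
  df2 <- length(x1) + length(x2) - 4L
  s2 <- rss / df2
  sxx1 <- sum((x1 - mean(x1))^2); sxx2 <- sum((x2 - mean(x2))^2)
  num <- (coef(f1)[2] - coef(f2)[2])^2
  unname(num / (s2 * (1 / sxx1 + 1 / sxx2)))
}
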