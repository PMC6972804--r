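# Simulated one-way half-sib layout wrapped as a trait table (one
# population per family block is not needed here; two populations keep the
# design valid)
oneway_table <- function(n_fam, n_rep, sd_fam, sd_err, seed) {
  set.seed(seed)
  fam_eff <- rnorm(n_fam, sd = sd_fam)
  df <- expand.grid(rep = seq_len(n_rep), fam = seq_len(n_fam))
  df$y <- fam_eff[df$fam] + rnorm(nrow(df), sd = sd_err)
  trait_table(data.frame(
    tree_id = sprintf("t%04d", seq_len(nrow(df))),
    block = sprintf("B%d", ((df$rep - 1) %% 6) + 1),
    population = ifelse(df$fam <= n_fam / 2, "P1", "P2"),
    family = sprintf("f%02d", df$fam),
    Y = df$y
  ))
}

test_that("REML matches the balanced nested ANOVA estimators", {
  # balanced populations / families(populations) x blocks with
  # interaction: expected-mean-square estimators are the closed-form
  # oracle whenever all REML estimates are interior
  set.seed(12)
  P <- 3; F0 <- 5; B <- 4; n <- 4
  d <- expand.grid(block = seq_len(B), fam0 = seq_len(F0),
                   pop = seq_len(P), rep = seq_len(n))
  d$fam <- (d$pop - 1) * F0 + d$fam0
  d$y <- 5 + rnorm(P, sd = 2)[d$pop] +
    rnorm(P * F0, sd = 1.5)[d$fam] +
    rnorm(B, sd = 1.2)[d$block] +
    rnorm(B * P * F0, sd = 0.9)[(d$fam - 1) * B + d$block] +
    rnorm(nrow(d), sd = 2)
  tt <- trait_table(data.frame(
    tree_id = sprintf("t%04d", seq_len(nrow(d))),
    block = sprintf("B%d", d$block),
    population = sprintf("P%d", d$pop),
    family = sprintf("f%02d", d$fam),
    Y = d$y
  ))
  d$popf <- factor(d$pop); d$famf <- factor(d$fam)
  d$blockf <- factor(d$block)
  a <- anova(lm(y ~ popf + famf + blockf + famf:blockf, data = d))
  ms_p <- a["popf", "Mean Sq"]
  ms_f <- a["famf", "Mean Sq"]
  ms_b <- a["blockf", "Mean Sq"]
  ms_bf <- a["famf:blockf", "Mean Sq"]
  ms_e <- a["Residuals", "Mean Sq"]
  oracle <- c(
    block = (ms_b - ms_bf) / (n * P * F0),
    population = (ms_p - ms_f) / (n * B * F0),
    family = (ms_f - ms_bf) / (n * B),
    family_block = (ms_bf - ms_e) / n,
    error = ms_e
  )
  expect_true(all(oracle > 0))  # interior case
  vc <- fit_random_model(tt, "Y", compute_vcov = FALSE)
  expect_false(any(vc$boundary))
  expect_equal(vc$components, oracle, tolerance = 1e-6)
})

test_that("REML is location invariant and scales as variance", {
  sim <- simulate_plantation(one_trait_config(1, 0.5, 8.5), seed = 5)
  vc1 <- fit_random_model(sim$table, "Y", compute_vcov = FALSE)
  shifted <- sim$table
  shifted$Y <- shifted$Y + 100
  vc2 <- fit_random_model(shifted, "Y", compute_vcov = FALSE)
  expect_equal(vc1$components, vc2$components, tolerance = 1e-5)
  scaled <- sim$table
  scaled$Y <- scaled$Y * 3
  vc3 <- fit_random_model(scaled, "Y", compute_vcov = FALSE)
  expect_equal(vc3$components, vc1$components * 9, tolerance = 1e-5)
})

test_that("degenerate data with no random variation hits the boundary", {
  sim <- simulate_plantation(one_trait_config(0, 0, 4, sigma2_block = 0),
                             seed = 9)
  vc <- fit_random_model(sim$table, "Y", compute_vcov = FALSE)
  expect_equal(unname(vc$components["family"]), 0)
  expect_true(vc$boundary[["family"]])
  # finite-sample REML may shift a little mass into the other components,
  # so the error component approximates (not equals) the sample variance
  expect_equal(unname(vc$components["error"]), var(sim$table$Y),
               tolerance = 0.1)
  expect_lt(sum(vc$components[c("block", "family", "family_block")]),
            0.15 * var(sim$table$Y))
})

test_that("the package's restricted log-likelihood matches the fit", {
  sim <- simulate_plantation(one_trait_config(1, 0.5, 8.5), seed = 21)
  vc <- fit_random_model(sim$table, "Y", compute_vcov = FALSE)
  ll <- reml_loglik(vc$components, vc$data)
  expect_equal(ll, vc$loglik, tolerance = 1e-8)
  # and the fitted point is a maximum: perturbations reduce it
  for (nm in c("family", "error")) {
    up <- vc$components; up[nm] <- up[nm] * 1.2
    expect_lt(reml_loglik(up, vc$data), ll)
  }
})

test_that("heritability follows the mixed-mating equation", {
  fake <- structure(list(
    trait = "Y",
    components = c(block = 0.3, population = 2, family = 1,
                   family_block = 0.5, error = 8.5),
    vcov = NULL, boundary = setNames(rep(FALSE, 5),
                                     c("block", "population", "family",
                                       "family_block", "error"))
  ), class = "varcomp_fit")
  h <- heritability(fake)
  expect_equal(h$h2, 2.5 * 1 / 10)
  expect_equal(heritability(fake, multiplier = 4)$h2, 0.4)
  fake0 <- fake
  fake0$components["family"] <- 0
  fake0$boundary["family"] <- TRUE
  expect_equal(heritability(fake0)$h2, 0)
})

test_that("delta-method SE agrees with parametric resampling", {
  sim <- simulate_plantation(one_trait_config(1, 0.5, 8.5), seed = 31)
  vc <- fit_random_model(sim$table, "Y")
  h <- heritability(vc)
  idx <- c("family", "family_block", "error")
  C <- vc$vcov[idx, idx]
  expect_false(anyNA(C))
  set.seed(99)
  L <- chol(C)
  draws <- matrix(rnorm(3000), 1000, 3) %*% L +
    rep(vc$components[idx], each = 1000)
  keep <- rowSums(draws < 0) == 0
  h2s <- 2.5 * draws[keep, 1] / rowSums(draws[keep, ])
  expect_equal(h$se, sd(h2s), tolerance = 0.15)
})

test_that("family LRT handles the boundary and orders log-likelihoods", {
  cfg <- one_trait_config(0, 0.5, 9.5)
  found_boundary <- FALSE
  for (s in 1:10) {
    sim <- simulate_plantation(cfg, seed = 100 + s)
    vc <- fit_random_model(sim$table, "Y", compute_vcov = FALSE)
    lrt <- lrt_family(vc)
    expect_gte(lrt$lrt_stat, 0)
    expect_gte(lrt$loglik_full, lrt$loglik_reduced - 1e-6)
    if (vc$boundary[["family"]]) {
      found_boundary <- TRUE
      expect_equal(lrt$lrt_stat, 0, tolerance = 1e-4)
      expect_equal(lrt$p_value, 0.5, tolerance = 1e-3)
      break
    }
  }
  expect_true(found_boundary)
  # mixture p is half the plain chi-square p
  sim <- simulate_plantation(one_trait_config(1.5, 0.5, 8), seed = 77)
  vc <- fit_random_model(sim$table, "Y", compute_vcov = FALSE)
  expect_equal(lrt_family(vc, mixture = TRUE)$p_value,
               0.5 * lrt_family(vc, mixture = FALSE)$p_value)
})

test_that("populations far apart get distinct letters; adjustment is
           conservative", {
  cfg <- one_trait_config(0.5, 0.3, 4, n_populations = 4,
                          families_per_population = 6,
                          replicates_per_family = 6, amp = 20)
  sim <- simulate_plantation(cfg, seed = 3)
  cmp <- diff_populations(sim$table, "Y")
  expect_gte(length(unique(cmp$letters)), 3L)
  expect_true(all(cmp$pairs$p_adj >= cmp$pairs$p_raw - 1e-12))
  expect_error(diff_populations(
    trait_table(tiny_table()[tiny_table()$population == "A", ]), "WD"),
    "design error")
})

test_that("identical populations usually share a letter", {
  cfg <- one_trait_config(0.4, 0.2, 4, n_populations = 2,
                          families_per_population = 8,
                          replicates_per_family = 4, amp = 0)
  shared <- vapply(1:200, function(s) {
    sim <- simulate_plantation(cfg, seed = 4000 + s)
    cmp <- diff_populations(sim$table, "Y")
    cmp$letters[1] == cmp$letters[2]
  }, logical(1))
  expect_gte(mean(shared), 0.93)
})

test_that("compact letters are consistent with the significance matrix", {
  sig <- matrix(FALSE, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  sig["A", "D"] <- sig["D", "A"] <- TRUE
  sig["A", "C"] <- sig["C", "A"] <- TRUE
  means <- c(A = 1, B = 2, C = 3, D = 4)
  lt <- compact_letters(sig, means)
  # groups sharing a letter must be non-significant pairs
  for (i in 1:3) for (j in (i + 1):4) {
    share <- any(strsplit(lt[i], "")[[1]] %in% strsplit(lt[j], "")[[1]])
    if (sig[i, j]) expect_false(share)
    else expect_true(share)
  }
})
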