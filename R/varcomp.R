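#' Fit the univariate random plantation model by REML
#'
#' Fits, for one trait, the fully random half-sib common-garden model
#' \deqn{y_{ijk} = \mu + b_i + p_j + f_{j(k)} + (b \times f)_{ik} + e_{ijk}}
#' with independent Gaussian random effects for block, population,
#' family-within-population and the block-by-family interaction, plus
#' residual error. Estimation is REML; variance components are constrained
#' non-negative and components estimated at (numerically) zero are flagged
#' as boundary. The asymptotic covariance of the five components is the
#' inverse observed information, obtained from a finite-difference Hessian
#' of the restricted log-likelihood at the estimates (boundary components
#' are excluded and get `NA` rows).
#'
#' The fit is deterministic given the data: fixed optimizer (bobyqa with
#' tight stopping rule `rhoend = 1e-12`) and fixed starting values.
#'
#' @param table a [trait_table()].
#' @param trait trait column name; rows with missing values are dropped
#'   (complete-case per fit) and the count is reported.
#' @param compute_vcov logical; compute the component covariance matrix
#'   (needed for delta-method standard errors). Default `TRUE`.
#' @return A `varcomp_fit` with elements `components` (named length-5
#'   vector: block, population, family, family_block, error), `loglik`
#'   (REML), `vcov`, `boundary`, `n`, `converged`, `model` (the underlying
#'   lme4 fit) and `data`.
#' @export
fit_random_model <- function(table, trait, compute_vcov = TRUE) {
  d <- model_data(table, trait)
  if (nlevels(droplevels(d$population)) < 2L ||
      nlevels(droplevels(d$block)) < 2L) {
    stop("design error: need >= 2 populations and >= 2 blocks", call. = FALSE)
  }
  fam_per_pop <- tapply(d$family, d$population, function(f) {
    length(unique(as.character(f)))
  })
  if (sum(fam_per_pop >= 2L, na.rm = TRUE) < 2L) {
    stop("design error: need >= 2 families in >= 2 populations",
         call. = FALSE)
  }
  fit <- fit_lmer_random(d)
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- setNames(numeric(5L),
                   c("block", "population", "family", "family_block",
                     "error"))
  grp_map <- c(block = "block", population = "population",
               family = "family", `block:family` = "family_block",
               Residual = "error")
  for (i in seq_len(nrow(vc))) {
    comp[grp_map[[vc$grp[i]]]] <- vc$vcov[i]
  }
  phen_var <- var(d$value)
  boundary_tol <- 1e-10 * phen_var
  boundary <- comp < boundary_tol
  comp[boundary] <- 0
  names(boundary) <- names(comp)
  conv <- is.null(fit@optinfo$conv$lme4$code) ||
    fit@optinfo$conv$lme4$code >= 0

  covmat <- NULL
  if (compute_vcov) {
    covmat <- varcomp_covariance(d, comp, boundary)
  }
  structure(list(
    trait = trait, components = comp, loglik = as.numeric(logLik(fit)),
    vcov = covmat, boundary = boundary, n = nrow(d),
    n_dropped = attr(d, "n_dropped"),
    n_iterations = fit@optinfo$feval %||% NA_integer_,
    converged = conv, model = fit, data = d
  ), class = "varcomp_fit")
}

# Shared complete-case model frame for one trait
model_data <- function(table, trait) {
  stopifnot(inherits(table, "trait_table"))
  if (!trait %in% attr(table, "traits")) {
    stop("unknown trait '", trait, "'", call. = FALSE)
  }
  d <- data.frame(value = table[[trait]], block = table$block,
                  population = table$population, family = table$family)
  keep <- !is.na(d$value)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " tree(s) with missing '", trait, "' dropped")
  }
  d <- droplevels(d[keep, , drop = FALSE])
  attr(d, "n_dropped") <- n_dropped
  d
}

fit_lmer_random <- function(d, drop_family = FALSE) {
  form <- if (drop_family) {
    value ~ 1 + (1 | block) + (1 | population) + (1 | block:family)
  } else {
    value ~ 1 + (1 | block) + (1 | population) + (1 | family) +
      (1 | block:family)
  }
  ctl <- lme4::lmerControl(
    optimizer = "bobyqa", optCtrl = list(rhoend = 1e-12),
    calc.derivs = FALSE,
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)
  )
  quiet_lmer(lme4::lmer(form, data = d, REML = TRUE, control = ctl))
}

# bobyqa reports code 3 ("trust region step failed") when pushed to very
# tight rhoend even at a converged optimum; with derivative checks off it
# is a precision artifact, so only that warning is muffled.
quiet_lmer <- function(expr) {
  withCallingHandlers(
    suppressMessages(expr),
    warning = function(w) {
      if (grepl("bobyqa", conditionMessage(w), fixed = TRUE)) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

#' Restricted log-likelihood of the random plantation model
#'
#' Direct dense evaluation of the REML log-likelihood at a given vector of
#' variance components, for the same model as [fit_random_model()]. Used
#' for the observed-information covariance of the components and as an
#' independent check on the fitted maximum.
#'
#' @param components named numeric vector (block, population, family,
#'   family_block, error), all >= 0, error > 0.
#' @param data model frame with columns `value`, `block`, `population`,
#'   `family` (as produced internally by [fit_random_model()]).
#' @param zzt optional precomputed list of relationship matrices (see
#'   [plantation_zzt()]); recomputed when `NULL`.
#' @return The restricted log-likelihood (a scalar), including all
#'   constants, so it is directly comparable to `logLik` of the lme4 fit.
#' @export
reml_loglik <- function(components, data, zzt = NULL) {
  if (is.null(zzt)) zzt <- plantation_zzt(data)
  y <- data$value
  n <- length(y)
  V <- diag(components[["error"]], n)
  for (nm in names(zzt)) {
    vi <- components[[nm]]
    if (vi > 0) V <- V + vi * zzt[[nm]]
  }
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  logdetV <- 2 * sum(log(diag(R)))
  ones <- rep(1, n)
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_1 <- backsolve(R, forwardsolve(t(R), ones))
  xvx <- sum(ones * Vi_1)
  yPy <- sum(y * Vi_y) - sum(ones * Vi_y)^2 / xvx
  -0.5 * ((n - 1) * log(2 * pi) + logdetV + log(xvx) + yPy)
}

#' Random-effect relationship matrices for the plantation design
#'
#' Returns the list of \eqn{Z Z'} matrices (one per random term: block,
#' population, family, block-by-family) for a model frame.
#'
#' @param data model frame with `block`, `population`, `family`.
#' @return Named list of symmetric incidence cross-product matrices.
#' @export
plantation_zzt <- function(data) {
  zzt_of <- function(f) {
    Z <- model.matrix(~ 0 + f)
    tcrossprod(Z)
  }
  list(
    block = zzt_of(droplevels(data$block)),
    population = zzt_of(droplevels(data$population)),
    family = zzt_of(droplevels(data$family)),
    family_block = zzt_of(droplevels(interaction(data$block, data$family)))
  )
}

# Observed-information covariance of the interior variance components via a
# central-difference Hessian of the restricted log-likelihood.
varcomp_covariance <- function(data, components, boundary, zzt = NULL) {
  if (is.null(zzt)) zzt <- plantation_zzt(data)
  nm <- names(components)
  interior <- which(!boundary)
  k <- length(interior)
  covmat <- matrix(NA_real_, 5L, 5L, dimnames = list(nm, nm))
  if (k == 0L) return(covmat)
  phen_var <- var(data$value)
  f <- function(v5) reml_loglik(setNames(v5, nm), data, zzt)
  x0 <- unname(components)
  h <- pmax(abs(x0), 0.01 * phen_var) * 1e-4
  H <- matrix(0, k, k)
  f0 <- f(x0)
  for (a in seq_len(k)) {
    i <- interior[a]
    xp <- x0; xp[i] <- x0[i] + h[i]
    xm <- x0; xm[i] <- max(x0[i] - h[i], 0)
    # one-sided fallback if the step would cross zero
    hi_m <- x0[i] - xm[i]
    H[a, a] <- (f(xp) - f0 - (f0 - f(xm)) * h[i] / hi_m) /
      (0.5 * (h[i] + hi_m) * h[i])
    if (a < k) {
      for (b in (a + 1L):k) {
        j <- interior[b]
        step <- function(si, sj) {
          x <- x0
          x[i] <- max(x0[i] + si * h[i], 0)
          x[j] <- max(x0[j] + sj * h[j], 0)
          f(x)
        }
        H[a, b] <- H[b, a] <-
          (step(1, 1) - step(1, -1) - step(-1, 1) + step(-1, -1)) /
          (4 * h[i] * h[j])
      }
    }
  }
  info <- -H
  ci <- tryCatch(solve(info), error = function(e) NULL)
  if (!is.null(ci)) covmat[interior, interior] <- ci
  covmat
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat("REML variance components for trait '", x$trait, "' (n = ", x$n,
      ")\n", sep = "")
  comp <- data.frame(variance = x$components,
                     boundary = ifelse(x$boundary, "yes", ""))
  print(comp, ...)
  cat("REML log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

#' Narrow-sense heritability from variance components
#'
#' Family (half-sib) heritability under a mixed mating system:
#' \deqn{\hat h^2 = m \; \sigma^2_{fam} / (\sigma^2_{fam} +
#'   \sigma^2_{fam \times block} + \sigma^2_{error})}
#' where the multiplier \eqn{m} is the reciprocal of the coefficient of
#' relationship among family members. The default `multiplier = 2.5`
#' (\eqn{\rho = 1/2.5}) corrects for roughly 30% selfing, as appropriate
#' for mixed-mating eucalypts; pure half-sibs would use 4. The denominator
#' deliberately excludes the block and population components.
#'
#' The standard error is first-order delta method using the asymptotic
#' covariance of (family, family-by-block, error) components.
#'
#' @param vc a `varcomp_fit` from [fit_random_model()].
#' @param multiplier relationship multiplier, default 2.5.
#' @return A `heritability` object: `h2`, `se`, `multiplier`, `boundary`
#'   (logical: family component at zero).
#' @export
heritability <- function(vc, multiplier = 2.5) {
  stopifnot(inherits(vc, "varcomp_fit"))
  vf <- vc$components[["family"]]
  vfb <- vc$components[["family_block"]]
  ve <- vc$components[["error"]]
  den <- vf + vfb + ve
  if (!is.finite(den) || den <= 0) {
    stop("degenerate variance components: zero phenotypic denominator",
         call. = FALSE)
  }
  h2 <- multiplier * vf / den
  se <- NA_real_
  if (!is.null(vc$vcov)) {
    idx <- c("family", "family_block", "error")
    C <- vc$vcov[idx, idx]
    g <- multiplier * c(vfb + ve, -vf, -vf) / den^2
    ok <- !is.na(diag(C))
    if (any(ok)) {
      C0 <- C
      C0[is.na(C0)] <- 0
      v <- drop(t(g) %*% C0 %*% g)
      if (is.finite(v) && v >= 0) se <- sqrt(v)
    }
  }
  structure(list(h2 = h2, se = se, multiplier = multiplier,
                 boundary = vc$boundary[["family"]],
                 components = vc$components, trait = vc$trait),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat("h^2(", x$trait, ") = ", format(round(x$h2, 3)), sep = "")
  if (is.finite(x$se)) cat(" +/-", format(round(x$se, 3)), "SE")
  if (x$boundary) cat("  [family variance at boundary]")
  cat("\n")
  invisible(x)
}

#' Likelihood-ratio test for the family variance component
#'
#' Refits the random plantation model without the family term and compares
#' restricted log-likelihoods: `stat = 2 (ll_full - ll_reduced)`, clamped
#' at zero. Because the null value lies on the boundary of the parameter
#' space, the reference distribution is the equal mixture
#' \eqn{0.5\chi^2_0 + 0.5\chi^2_1}, i.e. `p = 0.5 P(chisq_1 >= stat)`;
#' at `stat = 0` the p-value is 0.5. Set `mixture = FALSE` for a plain
#' \eqn{\chi^2_1} reference.
#'
#' @param vc a `varcomp_fit` for the full model.
#' @param mixture use the boundary mixture reference (default `TRUE`).
#' @return List with `lrt_stat`, `p_value`, `loglik_full`, `loglik_reduced`.
#' @export
lrt_family <- function(vc, mixture = TRUE) {
  stopifnot(inherits(vc, "varcomp_fit"))
  red <- fit_lmer_random(vc$data, drop_family = TRUE)
  ll_red <- as.numeric(logLik(red))
  stat <- max(0, 2 * (vc$loglik - ll_red))
  p <- pchisq(stat, df = 1L, lower.tail = FALSE)
  if (mixture) p <- 0.5 * p
  list(lrt_stat = stat, p_value = p,
       loglik_full = vc$loglik, loglik_reduced = ll_red)
}

#' One-call heritability analysis for a trait
#'
#' Convenience wrapper: REML fit, heritability with delta-method SE, and
#' the boundary-mixture likelihood-ratio test for the family component.
#'
#' @inheritParams fit_random_model
#' @inheritParams heritability
#' @inheritParams lrt_family
#' @return A `heritability` object extended with `lrt_stat`, `p_value`,
#'   and the `varcomp_fit` as element `fit`.
#' @export
estimate_heritability <- function(table, trait, multiplier = 2.5,
                                  mixture = TRUE) {
  vc <- fit_random_model(table, trait)
  h <- heritability(vc, multiplier = multiplier)
  lrt <- lrt_family(vc, mixture = mixture)
  h$lrt_stat <- lrt$lrt_stat
  h$p_value <- lrt$p_value
  h$fit <- vc
  h
}
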