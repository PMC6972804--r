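#' Population differentiation with Tukey all-pairs comparisons
#'
#' Fits the mixed differentiation model for one trait — population as a
#' fixed effect, family as a random effect — and performs all pairwise
#' population comparisons with a single-step max-|t| (Tukey-type)
#' adjustment over the contrasts, using the fixed-effect covariance from
#' the REML fit and a containment denominator df equal to
#' `n_populations * (mean families per population - 1)`. Populations are
#' summarised with a compact letter display: populations sharing a letter
#' are not significantly different at `alpha`.
#'
#' @param table a [trait_table()].
#' @param trait trait column name.
#' @param alpha significance level for the letter display (default 0.05).
#' @return A `pop_comparison`: data.frame `pairs` (estimate, SE, t,
#'   adjusted and raw p per population pair), `letters` (named character),
#'   `means` (estimated population means), `df`, `alpha`.
#' @export
diff_populations <- function(table, trait, alpha = 0.05) {
  d <- model_data(table, trait)
  d <- droplevels(d)
  npop <- nlevels(d$population)
  if (npop < 2L) {
    stop("design error: need >= 2 populations", call. = FALSE)
  }
  fam_per_pop <- tapply(as.character(d$family), d$population,
                        function(f) length(unique(f)))
  if (any(fam_per_pop < 2L)) {
    stop("design error: every population needs >= 2 families", call. = FALSE)
  }
  ctl <- lme4::lmerControl(
    optimizer = "bobyqa", optCtrl = list(rhoend = 1e-12),
    calc.derivs = FALSE,
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)
  )
  fit <- quiet_lmer(
    lme4::lmer(value ~ population + (1 | family), data = d, REML = TRUE,
               control = ctl)
  )
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  pops <- levels(d$population)
  # population means on the coefficient scale (treatment contrasts)
  Lmean <- cbind(1, rbind(0, diag(npop - 1L)))
  rownames(Lmean) <- pops
  means <- drop(Lmean %*% beta)
  # all-pairs contrasts on the means
  pairs_idx <- utils::combn(npop, 2L)
  K <- t(apply(pairs_idx, 2L, function(ij) {
    Lmean[ij[2L], ] - Lmean[ij[1L], ]
  }))
  rownames(K) <- apply(pairs_idx, 2L, function(ij) {
    paste(pops[ij[2L]], "-", pops[ij[1L]])
  })
  colnames(K) <- names(beta)
  df <- max(2L, round(npop * (mean(fam_per_pop) - 1)))
  g <- multcomp::glht(multcomp::parm(beta, V), linfct = K, df = df)
  s_adj <- summary(g)  # single-step max-|t|, multivariate t
  s_raw <- summary(g, test = multcomp::univariate())
  pairs <- data.frame(
    pair = rownames(K),
    pop_a = pops[pairs_idx[1L, ]],
    pop_b = pops[pairs_idx[2L, ]],
    estimate = as.numeric(s_adj$test$coefficients),
    se = as.numeric(s_adj$test$sigma),
    t = as.numeric(s_adj$test$tstat),
    p_adj = as.numeric(s_adj$test$pvalues),
    p_raw = as.numeric(s_raw$test$pvalues),
    stringsAsFactors = FALSE
  )
  sig <- matrix(FALSE, npop, npop, dimnames = list(pops, pops))
  for (m in seq_len(ncol(pairs_idx))) {
    is_sig <- pairs$p_adj[m] < alpha
    sig[pairs_idx[1L, m], pairs_idx[2L, m]] <- is_sig
    sig[pairs_idx[2L, m], pairs_idx[1L, m]] <- is_sig
  }
  letters <- compact_letters(sig, means)
  structure(list(trait = trait, pairs = pairs, letters = letters,
                 means = means, df = df, alpha = alpha, model = fit),
            class = "pop_comparison")
}

#' Compact letter display from a significance matrix
#'
#' Greedy insert-and-absorb assignment: groups are ordered by mean; a
#' single letter initially covers all groups; every significantly
#' different pair splits the letters containing both members; letter sets
#' that become subsets of others are absorbed. Groups sharing a letter are
#' not significantly different.
#'
#' @param sig logical matrix, `TRUE` where the pair differs significantly.
#' @param means numeric vector of group means (for ordering), with names
#'   matching `rownames(sig)`.
#' @return Named character vector of letter strings per group.
#' @export
compact_letters <- function(sig, means) {
  groups <- rownames(sig)
  ord <- order(means)
  sets <- list(seq_along(groups))
  for (a in seq_along(ord)[-length(ord)]) {
    for (b in (a + 1L):length(ord)) {
      i <- ord[a]; j <- ord[b]
      if (!sig[i, j]) next
      new_sets <- list()
      for (s in sets) {
        if (i %in% s && j %in% s) {
          s1 <- setdiff(s, i); s2 <- setdiff(s, j)
          if (length(s1)) new_sets <- c(new_sets, list(s1))
          if (length(s2)) new_sets <- c(new_sets, list(s2))
        } else {
          new_sets <- c(new_sets, list(s))
        }
      }
      # absorb subsets
      keep <- rep(TRUE, length(new_sets))
      for (u in seq_along(new_sets)) {
        for (v in seq_along(new_sets)) {
          if (u != v && keep[u] && keep[v] &&
              all(new_sets[[u]] %in% new_sets[[v]]) &&
              !(all(new_sets[[v]] %in% new_sets[[u]]) && u < v)) {
            keep[u] <- FALSE
          }
        }
      }
      sets <- new_sets[keep]
    }
  }
  # order letters by the smallest mean they cover
  set_min <- vapply(sets, function(s) min(rank(means)[s]), numeric(1))
  sets <- sets[order(set_min)]
  out <- setNames(rep("", length(groups)), groups)
  for (k in seq_along(sets)) {
    lab <- letters[(k - 1L) %% 26L + 1L]
    if (k > 26L) lab <- paste0(lab, (k - 1L) %/% 26L)
    for (i in sets[[k]]) out[i] <- paste0(out[i], lab)
  }
  out
}

#' @export
print.pop_comparison <- function(x, ...) {
  cat("Population differentiation for '", x$trait, "' (alpha = ", x$alpha,
      ", df = ", x$df, ")\n", sep = "")
  disp <- data.frame(mean = round(x$means, 4),
                     letters = x$letters[names(x$means)])
  print(disp[order(disp$mean), ])
  invisible(x)
}
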