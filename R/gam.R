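#' Cubic regression spline basis with curvature penalty
#'
#' Builds the basis and penalty for one smooth term as used by the
#' trait-climate models: a cubic regression spline with `k` basis
#' functions, knots at quantiles of the covariate, and the sum-to-zero
#' identifiability constraint absorbed (so the returned basis has `k - 1`
#' columns that each sum to zero over the data). The penalty matrix is the
#' integrated squared second derivative; straight lines lie in its null
#' space.
#'
#' @param x covariate values (>= `k` distinct values).
#' @param k basis dimension (default 3, the pipeline's smoothness bound).
#' @return List with `X` (basis matrix), `S` (penalty, symmetric PSD),
#'   `knots`, and `smooth` (the underlying mgcv smooth construct, usable
#'   for prediction).
#' @export
build_crs_basis <- function(x, k = 3) {
  if (length(unique(x)) < k) {
    stop("degeneracy error: need >= ", k, " distinct covariate values",
         call. = FALSE)
  }
  d <- data.frame(x = x)
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "cr", k = k), data = d,
                        absorb.cons = TRUE)[[1L]]
  list(X = sm$X, S = sm$S[[1L]], knots = sm$xp, smooth = sm)
}

#' Fit a bounded-smoothness GAM of a trait on climate
#'
#' Penalized regression of population-level trait means on up to three
#' climate covariates, each entering as a cubic regression spline with
#' basis dimension `k = 3` (at most two nonlinear effective df per term
#' after the identifiability constraint). Smoothing parameters are chosen
#' by GCV; the family is Gaussian with identity link, so deviance
#' explained equals variance explained. Per-term F statistics are the
#' Wald-type tests on the penalized coefficients reported by mgcv.
#'
#' @param y numeric response (trait means, one per population).
#' @param climate data.frame of climate variables (one row per response
#'   element).
#' @param vars character vector (length 1-3) of column names of `climate`.
#' @param k per-term basis dimension (default 3).
#' @param sp optional fixed smoothing parameters (recycled per term);
#'   `NULL` selects by GCV.
#' @return A `climate_gam`: the mgcv fit plus `vars`, `ranges` (training
#'   min/max per covariate, used for extrapolation masking), `r_squared`
#'   (adjusted), `dev_explained` (percent), `edf_total` and per-term
#'   `fstats`.
#' @export
fit_climate_gam <- function(y, climate, vars, k = 3, sp = NULL) {
  stopifnot(length(vars) >= 1L, length(vars) <= 3L,
            !anyDuplicated(vars), all(vars %in% names(climate)))
  n <- length(y)
  if (n <= 1L + length(vars)) {
    stop("too few observations for ", length(vars), " smooth term(s)",
         call. = FALSE)
  }
  d <- data.frame(y = y, climate[, vars, drop = FALSE])
  terms <- paste0("s(", vars, ", bs = \"cr\", k = ", k, ")")
  form <- as.formula(paste("y ~", paste(terms, collapse = " + ")))
  args <- list(formula = form, data = d, method = "GCV.Cp")
  if (!is.null(sp)) args$sp <- rep_len(sp, length(vars))
  fit <- do.call(mgcv::gam, args)
  edf_total <- sum(fit$edf) + 1L  # + intercept
  if (edf_total >= n) {
    stop("overfit error: total effective df (", round(edf_total, 2),
         ") >= n (", n, ")", call. = FALSE)
  }
  s <- summary(fit)
  ranges <- lapply(d[vars], range)
  structure(list(
    gam = fit, vars = vars, k = k, n = n,
    ranges = ranges,
    r_squared = s$r.sq,
    dev_explained = 100 * s$dev.expl,
    edf_total = edf_total,
    sp = fit$sp,
    fstats = data.frame(term = rownames(s$s.table),
                        edf = s$s.table[, "edf"],
                        F = s$s.table[, "F"],
                        p_value = s$s.table[, "p-value"],
                        row.names = NULL)
  ), class = "climate_gam")
}

#' @export
print.climate_gam <- function(x, ...) {
  cat("Trait-climate GAM:", paste(x$vars, collapse = " + "), "\n")
  cat("  n =", x$n, " adj. R^2 =", format(round(x$r_squared, 3)),
      " deviance explained =", format(round(x$dev_explained, 1)), "%\n")
  print(transform(x$fstats, edf = round(edf, 2), F = round(F, 3),
                  p_value = signif(p_value, 3)))
  invisible(x)
}

#' Predict from a trait-climate GAM
#'
#' @param object a `climate_gam`.
#' @param newdata data.frame containing the fitted climate variables.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.climate_gam <- function(object, newdata, ...) {
  as.numeric(predict(object$gam, newdata = newdata))
}

#' Exhaustive subset selection of climate covariates for one trait
#'
#' Fits every subset of 1 to `max_vars` of the candidate climate variables
#' (63 models for 7 candidates and `max_vars = 3`) and ranks candidates by
#' deviance explained; ties are broken by fewer variables, then
#' lexicographically. The winner is refitted and returned.
#'
#' @param y numeric response (trait means).
#' @param climate data.frame of candidate covariates.
#' @param candidates candidate variable names; default [climate_variables()]
#'   intersected with `names(climate)`.
#' @param max_vars maximum subset size (default 3).
#' @param k per-term basis dimension (default 3).
#' @return A `gam_selection`: `table` (one row per candidate subset with
#'   fit statistics, ranked), `winner` (a `climate_gam`), `n_candidates`.
#' @export
select_climate_gam <- function(y, climate, candidates = NULL, max_vars = 3,
                               k = 3) {
  if (is.null(candidates)) {
    candidates <- intersect(climate_variables(), names(climate))
  }
  stopifnot(length(candidates) >= 1L)
  subsets <- list()
  for (m in seq_len(min(max_vars, length(candidates)))) {
    cmb <- utils::combn(candidates, m, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  rows <- lapply(subsets, function(vs) {
    fit <- tryCatch(fit_climate_gam(y, climate, vs, k = k),
                    error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(vars = paste(vs, collapse = "+"), n_vars = length(vs),
                 dev_explained = NA_real_, r_squared = NA_real_,
                 edf_total = NA_real_, ok = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(vars = paste(vs, collapse = "+"), n_vars = length(vs),
                 dev_explained = fit$dev_explained,
                 r_squared = fit$r_squared,
                 edf_total = fit$edf_total, ok = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  if (!any(tab$ok)) {
    stop("selection error: no candidate model could be fitted",
         call. = FALSE)
  }
  ord <- order(-ifelse(tab$ok, tab$dev_explained, -Inf), tab$n_vars,
               tab$vars)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  winner_vars <- strsplit(tab$vars[1L], "+", fixed = TRUE)[[1L]]
  winner <- fit_climate_gam(y, climate, winner_vars, k = k)
  structure(list(table = tab, winner = winner,
                 n_candidates = nrow(tab)),
            class = "gam_selection")
}

#' @export
print.gam_selection <- function(x, ...) {
  cat("Exhaustive GAM selection over", x$n_candidates,
      "candidate subsets\n")
  cat("Winner:", paste(x$winner$vars, collapse = " + "),
      "(deviance explained ",
      format(round(x$winner$dev_explained, 1)), "%)\n")
  print(utils::head(x$table, 5L))
  invisible(x)
}
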