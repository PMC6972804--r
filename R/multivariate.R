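#' Family-mean matrix from a trait table
#'
#' Arithmetic mean per family of each trait (and, optionally, attached
#' per-population climate variables, constant within family). Families
#' with no non-missing value for a requested trait are dropped with a
#' warning.
#'
#' @param table a [trait_table()].
#' @param traits trait columns to average; default all.
#' @param climate optional data.frame with a `population` column plus
#'   climate variables to join onto each family row.
#' @return data.frame with `family`, `population`, `n_trees`, one column
#'   per trait (and climate variable).
#' @export
family_means <- function(table, traits = NULL, climate = NULL) {
  stopifnot(inherits(table, "trait_table"))
  if (is.null(traits)) traits <- attr(table, "traits")
  fams <- split(seq_len(nrow(table)), table$family, drop = TRUE)
  rows <- lapply(names(fams), function(f) {
    idx <- fams[[f]]
    out <- data.frame(family = f,
                      population = as.character(table$population[idx[1L]]),
                      n_trees = length(idx), stringsAsFactors = FALSE)
    for (tr in traits) {
      v <- table[[tr]][idx]
      out[[tr]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    out
  })
  fm <- do.call(rbind, rows)
  empty <- rowSums(!is.na(fm[, traits, drop = FALSE])) == 0L
  for (tr in traits) {
    n_empty <- sum(is.na(fm[[tr]]))
    if (n_empty > 0L) {
      warning("family/families with no '", tr, "' values dropped from that ",
              "column (", n_empty, ")", call. = FALSE)
    }
  }
  if (any(empty)) fm <- fm[!empty, , drop = FALSE]
  if (!is.null(climate)) {
    idx <- match(fm$population, climate$population)
    if (anyNA(idx)) {
      stop("climate table lacks population(s): ",
           paste(unique(fm$population[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    for (cv in setdiff(names(climate), "population")) {
      fm[[cv]] <- climate[[cv]][idx]
    }
  }
  rownames(fm) <- NULL
  fm
}

#' Principal components of a family-mean matrix
#'
#' Correlation-scale PCA by default (columns centred and scaled to unit
#' variance), since traits are on incommensurate scales; set
#' `standardize = FALSE` for covariance-scale. Axis signs follow a fixed
#' convention: the largest-magnitude loading of each axis is positive, so
#' results are reproducible across platforms.
#'
#' @param matrix data.frame or matrix of family means; non-numeric columns
#'   (`family`, `population`, `n_trees`) are carried through to the scores.
#' @param columns columns to include; default every numeric column except
#'   `n_trees`.
#' @param standardize scale columns to unit variance (default `TRUE`).
#' @return A `pca_result`: `loadings`, `scores`, `variance_explained`
#'   (percent per axis, summing to 100), `sdev`, plus row metadata.
#' @export
trait_pca <- function(matrix, columns = NULL, standardize = TRUE) {
  df <- as.data.frame(matrix)
  if (is.null(columns)) {
    columns <- names(df)[vapply(df, is.numeric, logical(1))]
    columns <- setdiff(columns, "n_trees")
  }
  X <- df[, columns, drop = FALSE]
  cc <- complete.cases(X)
  X <- as.matrix(X[cc, , drop = FALSE])
  if (nrow(X) < 3L || ncol(X) < 2L) {
    stop("PCA needs >= 3 complete rows and >= 2 columns", call. = FALSE)
  }
  if (standardize) {
    sds <- apply(X, 2L, sd)
    if (any(sds == 0)) {
      stop("degenerate column(s) under standardization: ",
           paste(columns[sds == 0], collapse = ", "), call. = FALSE)
    }
  }
  p <- prcomp(X, center = TRUE, scale. = standardize)
  # sign convention: largest |loading| per axis positive
  for (k in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, k]))
    if (p$rotation[i, k] < 0) {
      p$rotation[, k] <- -p$rotation[, k]
      p$x[, k] <- -p$x[, k]
    }
  }
  ve <- 100 * p$sdev^2 / sum(p$sdev^2)
  meta <- df[cc, setdiff(names(df), columns), drop = FALSE]
  structure(list(loadings = p$rotation, scores = p$x,
                 variance_explained = ve, sdev = p$sdev,
                 center = p$center, scale = p$scale,
                 meta = meta, columns = columns,
                 standardized = standardize),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA of", nrow(x$scores), "rows x", length(x$columns), "columns",
      if (x$standardized) "(correlation scale)\n" else "(covariance scale)\n")
  ve <- round(x$variance_explained, 1)
  cat("Variance explained (%):", paste(ve, collapse = ", "), "\n")
  cat("Axes 1+2:", round(sum(ve[1:2]), 1), "%\n")
  invisible(x)
}

#' Ordinary least-squares regression between two traits on family means
#'
#' The trait-correlation test of the pipeline: `y ~ x` over family means,
#' complete pairs only.
#'
#' @param matrix family-mean data.frame (see [family_means()]).
#' @param x,y trait column names (predictor, response).
#' @return A `trait_pair_fit`: `slope`, `intercept`, `r_squared`,
#'   `p_value` (two-sided slope test), `n`, and the underlying `lm`.
#' @export
fit_trait_pair <- function(matrix, x, y) {
  df <- as.data.frame(matrix)
  stopifnot(x %in% names(df), y %in% names(df))
  d <- data.frame(x = df[[x]], y = df[[y]])
  d <- d[complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3L) {
    stop("need >= 3 complete trait pairs", call. = FALSE)
  }
  if (var(d$x) == 0) {
    stop("degenerate predictor: zero variance in '", x, "'", call. = FALSE)
  }
  fit <- lm(y ~ x, data = d)
  s <- summary(fit)
  structure(list(x = x, y = y,
                 slope = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 r_squared = s$r.squared,
                 p_value = s$coefficients[2L, 4L],
                 n = nrow(d), model = fit),
            class = "trait_pair_fit")
}

#' @export
print.trait_pair_fit <- function(x, ...) {
  cat(x$y, " ~ ", x$x, ": slope = ", format(signif(x$slope, 4)),
      ", R^2 = ", format(round(x$r_squared, 3)),
      ", p = ", format(signif(x$p_value, 3)), ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' The four canonical trait-pair regressions
#'
#' Fits the study's four trait relationships on family means:
#' d13C ~ PRI, LS ~ NDVI, WD ~ N_CONC, SLA ~ N_CONC.
#'
#' @param matrix family-mean data.frame.
#' @param pairs 2-column character matrix (x, y); default the four pairs.
#' @return List of `trait_pair_fit`s named `"y~x"`.
#' @export
canonical_trait_pairs <- function(matrix, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- rbind(c("PRI", "d13C"), c("NDVI", "LS"),
                   c("N_CONC", "WD"), c("N_CONC", "SLA"))
  }
  fits <- apply(pairs, 1L, function(pr) {
    fit_trait_pair(matrix, x = pr[1L], y = pr[2L])
  })
  names(fits) <- paste0(pairs[, 2L], "~", pairs[, 1L])
  fits
}
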