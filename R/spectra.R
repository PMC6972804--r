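#' Leaf reflectance spectrum
#'
#' Percent reflectance on a strictly increasing integer wavelength grid
#' (nm). Field spectroradiometer output is 1 nm spacing; the grid must
#' cover the bands required by the indices (445, 531, 570, 705, 750 nm).
#'
#' @param wavelengths integer nm grid, strictly increasing.
#' @param reflectance percent reflectance, same length.
#' @param tree_id,leaf_id optional identifiers.
#' @return A `spectrum` object.
#' @export
reflectance_spectrum <- function(wavelengths, reflectance,
                                 tree_id = NA_character_,
                                 leaf_id = NA_character_) {
  stopifnot(length(wavelengths) == length(reflectance))
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  structure(list(wavelengths = as.numeric(wavelengths),
                 reflectance = as.numeric(reflectance),
                 tree_id = tree_id, leaf_id = leaf_id),
            class = "spectrum")
}

# Required band extraction: exact grid value, else nearest neighbour
# within +/- 2 nm (logged), else error.
band_value <- function(spectrum, band, tol_nm = 2) {
  i <- match(band, spectrum$wavelengths)
  if (is.na(i)) {
    d <- abs(spectrum$wavelengths - band)
    i <- which.min(d)
    if (d[i] > tol_nm) {
      stop("required band ", band, " nm absent from spectrum (nearest ",
           spectrum$wavelengths[i], " nm)", call. = FALSE)
    }
    message("band ", band, " nm missing; using nearest neighbour at ",
            spectrum$wavelengths[i], " nm")
  }
  spectrum$reflectance[i]
}

#' Band-wise mean of several leaf spectra from one tree
#'
#' Spectral indices are computed per tree from the mean spectrum over the
#' sampled leaves (band means first, indices second), not from per-leaf
#' indices.
#'
#' @param spectra list of [reflectance_spectrum()]s on identical grids.
#' @return A [reflectance_spectrum()] with attribute `n_leaves`.
#' @export
average_spectra <- function(spectra) {
  stopifnot(length(spectra) >= 1L)
  wl <- spectra[[1L]]$wavelengths
  for (sp in spectra[-1L]) {
    if (length(sp$wavelengths) != length(wl) ||
        any(sp$wavelengths != wl)) {
      stop("spectra alignment error: wavelength grids differ", call. = FALSE)
    }
  }
  refl <- rowMeans(vapply(spectra, `[[`, numeric(length(wl)), "reflectance"))
  out <- reflectance_spectrum(wl, refl, tree_id = spectra[[1L]]$tree_id)
  attr(out, "n_leaves") <- length(spectra)
  out
}

#' Photochemical reflectance index
#'
#' PRI = (R531 - R570) / (R531 + R570), a normalized difference of the
#' 531 nm xanthophyll-sensitive band against the 570 nm reference band.
#' Invariant under uniform rescaling of the spectrum.
#'
#' @param spectrum a [reflectance_spectrum()].
#' @return Unitless index in \[-1, 1\].
#' @export
pri <- function(spectrum) {
  r531 <- band_value(spectrum, 531)
  r570 <- band_value(spectrum, 570)
  den <- r531 + r570
  if (!is.finite(den) || den <= 0) {
    stop("degenerate spectrum: R531 + R570 must be positive", call. = FALSE)
  }
  (r531 - r570) / den
}

#' Modified red-edge NDVI (mND705)
#'
#' mND705 = (R750 - R705) / (R750 + R705 - 2 R445), a red-edge normalized
#' difference with a 445 nm correction term that makes the chlorophyll
#' estimate robust to leaf surface structure. Invariant under uniform
#' rescaling of the spectrum; with R445 = 0 it reduces to the plain
#' normalized difference of the 750 and 705 nm bands.
#'
#' @param spectrum a [reflectance_spectrum()].
#' @return Unitless index.
#' @export
ndvi_mnd705 <- function(spectrum) {
  r750 <- band_value(spectrum, 750)
  r705 <- band_value(spectrum, 705)
  r445 <- band_value(spectrum, 445)
  den <- r750 + r705 - 2 * r445
  if (!is.finite(den) || abs(den) < .Machine$double.eps * 100) {
    stop("degenerate spectrum: R750 + R705 - 2*R445 is zero", call. = FALSE)
  }
  (r750 - r705) / den
}

#' Per-tree spectral indices from a long-format spectra table
#'
#' Takes long-format spectra (`tree_id`, `leaf_id`, `wavelength_nm`,
#' `reflectance_pct`), averages the leaves of each tree band-wise, and
#' computes PRI and NDVI (mND705) from the averaged spectrum.
#'
#' @param spectra_long data.frame in long format.
#' @return data.frame with `tree_id`, `PRI`, `NDVI`, `n_leaves`.
#' @export
compute_spectral_indices <- function(spectra_long) {
  req <- c("tree_id", "leaf_id", "wavelength_nm", "reflectance_pct")
  if (!all(req %in% names(spectra_long))) {
    stop("spectra table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  by_tree <- split(spectra_long, spectra_long$tree_id)
  out <- lapply(by_tree, function(df) {
    leaves <- split(df, df$leaf_id)
    spectra <- lapply(leaves, function(lf) {
      lf <- lf[order(lf$wavelength_nm), ]
      reflectance_spectrum(lf$wavelength_nm, lf$reflectance_pct,
                           tree_id = df$tree_id[1L],
                           leaf_id = lf$leaf_id[1L])
    })
    avg <- average_spectra(spectra)
    data.frame(tree_id = df$tree_id[1L], PRI = pri(avg),
               NDVI = ndvi_mnd705(avg),
               n_leaves = length(spectra),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
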