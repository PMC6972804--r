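#' Leaf area from a binary flatbed scan
#'
#' Leaf scans are binary images (leaf = foreground/`TRUE` or 1) at a known
#' scanner resolution. The area is the foreground pixel count times the
#' physical pixel area, (25.4 / dpi)^2 mm^2 per pixel, reported in cm^2.
#'
#' @param image logical or 0/1 numeric matrix, leaf = foreground.
#' @param dpi scan resolution in dots per inch (> 0); flatbed leaf scans
#'   in this pipeline are 50 dpi.
#' @return Leaf area in cm^2.
#' @export
leaf_area_from_scan <- function(image, dpi = 50) {
  if (!is.numeric(dpi) || length(dpi) != 1L || dpi <= 0) {
    stop("dpi must be a positive scalar", call. = FALSE)
  }
  image <- as.matrix(image)
  n_fg <- sum(image > 0, na.rm = TRUE)
  if (n_fg == 0L) {
    stop("empty scan: no foreground pixels", call. = FALSE)
  }
  px_mm2 <- (25.4 / dpi)^2
  n_fg * px_mm2 / 100
}

#' Binarize a grey-level leaf scan
#'
#' Fixed-threshold binarization helper for grey-level scans in \[0, 1\];
#' values strictly above the threshold become foreground. With
#' `threshold = NULL` an Otsu threshold is computed via EBImage when
#' available.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param threshold scalar in (0, 1), or `NULL` for Otsu.
#' @param foreground_dark logical; `TRUE` (default) if the leaf is darker
#'   than the background (typical for scans against a white lid).
#' @return Logical matrix, leaf = `TRUE`.
#' @export
binarize_scan <- function(image, threshold = 0.5, foreground_dark = TRUE) {
  image <- as.matrix(image)
  if (is.null(threshold)) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("threshold = NULL requires the EBImage package for Otsu",
           call. = FALSE)
    }
    threshold <- EBImage::otsu(EBImage::Image(image))
  }
  if (foreground_dark) image < threshold else image > threshold
}

#' Specific leaf area
#'
#' SLA = leaf area per unit dry mass (mm^2/mg). For multi-leaf samples the
#' areas and masses are summed *before* division (pooled estimator), not
#' averaged as per-leaf ratios.
#'
#' @param total_area_mm2 summed leaf area, mm^2 (> 0).
#' @param dry_mass_mg summed dry mass, mg (> 0).
#' @return SLA in mm^2/mg (vectorised).
#' @export
sla <- function(total_area_mm2, dry_mass_mg) {
  if (any(!is.finite(total_area_mm2)) || any(!is.finite(dry_mass_mg)) ||
      any(total_area_mm2 <= 0) || any(dry_mass_mg <= 0)) {
    stop("sla: area and mass must be finite and positive", call. = FALSE)
  }
  total_area_mm2 / dry_mass_mg
}

#' Wood density from dry mass and displacement volume
#'
#' Basic density: oven-dry mass divided by green volume measured by water
#' displacement (g/cm^3).
#'
#' @param dry_mass_g dry mass, g (> 0).
#' @param volume_cm3 displacement volume, cm^3 (> 0).
#' @return Density in g/cm^3 (vectorised).
#' @export
wood_density <- function(dry_mass_g, volume_cm3) {
  if (any(!is.finite(dry_mass_g)) || any(!is.finite(volume_cm3)) ||
      any(dry_mass_g <= 0) || any(volume_cm3 <= 0)) {
    stop("wood_density: mass and volume must be finite and positive",
         call. = FALSE)
  }
  dry_mass_g / volume_cm3
}
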