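#' Inverse aridity index
#'
#' The aridity index (AI) is mean annual precipitation divided by mean
#' annual evapotranspiration. The pipeline works with its inverse,
#' evapotranspiration / precipitation, so that larger values mean a more
#' arid climate-of-origin.
#'
#' @param p_ma mean annual precipitation (mm), > 0.
#' @param evapotranspiration mean annual evapotranspiration (mm), > 0.
#' @return Unitless inverse aridity index (vectorised).
#' @export
inverse_aridity <- function(p_ma, evapotranspiration) {
  if (any(!is.finite(p_ma)) || any(!is.finite(evapotranspiration)) ||
      any(p_ma <= 0) || any(evapotranspiration <= 0)) {
    stop("inverse_aridity: inputs must be finite and positive",
         call. = FALSE)
  }
  evapotranspiration / p_ma
}

#' Climate-of-origin table for the twelve study populations
#'
#' Location and climate of the twelve source populations of the
#' *Corymbia calophylla* provenance trial: maximum temperature of the
#' warmest month (`T_MAX`, deg C), mean annual precipitation (`P_MA`, mm),
#' inverse aridity index (`AI_inv`) and precipitation of the driest month
#' (`P_DM`, mm), together with the family and tree counts of the two
#' field datasets. Four populations (BOO, CRI, HRI, SER) form dataset 1
#' (heritability); all twelve form dataset 2 (trait-climate modelling).
#'
#' The remaining three candidate climate variables (`T_MA`, `T_RANGE`,
#' `P_RANGE`) are not part of the published table; [synthetic_climate()]
#' derives deterministic synthetic complements for simulation work.
#'
#' @return data.frame with one row per population.
#' @export
population_climate <- function() {
  df <- data.frame(
    population = c("HRI", "MOG", "LUP", "SER", "CHID", "PEE",
                   "CRI", "KIN", "PLA", "BOO", "CAR", "BRA"),
    climate_group = rep(c("warm-dry", "warm-wet", "cool-dry", "cool-wet"),
                        each = 3L),
    latitude = c(-30.3114, -31.0986, -32.5207, -32.3527, -31.8682, -32.6846,
                 -34.6015, -34.0812, -34.6534, -34.6389, -34.4196, -33.9164),
    longitude = c(115.2016, 116.0509, 116.4990, 116.0764, 116.2229, 115.7427,
                  118.7427, 116.3304, 117.4991, 116.1238, 115.8213, 115.0833),
    T_MAX = c(31.7, 33.3, 31.6, 30.5, 32.2, 30.4,
              26.2, 27.7, 26.7, 25.6, 25.9, 26.1),
    P_MA = c(563, 579, 635, 1173, 900, 885, 579, 820, 733, 1159, 1106, 1072),
    AI_inv = c(2.56, 2.56, 2.22, 1.12, 1.54, 1.49,
               2.08, 1.49, 1.59, 0.95, 1.02, 1.04),
    P_DM = c(4, 10, 12, 12, 12, 10, 20, 19, 25, 24, 20, 11),
    dataset1 = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
                 TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    families_ds1 = c(9, NA, NA, 11, NA, NA, 8, NA, NA, 11, NA, NA),
    trees_ds1 = c(110, NA, NA, 123, NA, NA, 99, NA, NA, 136, NA, NA),
    families_ds2 = c(9, 10, 9, 11, 10, 8, 8, 10, 10, 10, 10, 9),
    trees_ds2 = c(36, 40, 40, 44, 40, 40, 32, 40, 40, 40, 40, 40),
    stringsAsFactors = FALSE
  )
  df
}

#' Full seven-variable climate set for simulation
#'
#' Extends [population_climate()] with deterministic synthetic values for
#' the three variables not available from the published climate table:
#' mean annual temperature (`T_MA`), temperature variation (`T_RANGE`) and
#' precipitation variation (`P_RANGE`). These are smooth functions of the
#' published variables chosen to be physically plausible for southwestern
#' Australia; they are synthetic complements for simulation, not observed
#' climate.
#'
#' @param populations optional character vector restricting the rows.
#' @return data.frame with `population` plus the seven [climate_variables()].
#' @export
synthetic_climate <- function(populations = NULL) {
  cl <- population_climate()
  if (!is.null(populations)) {
    idx <- match(populations, cl$population)
    if (anyNA(idx)) {
      stop("unknown population(s): ",
           paste(populations[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    cl <- cl[idx, , drop = FALSE]
  }
  out <- data.frame(
    population = cl$population,
    # annual mean: follows summer maximum, latitude, and coastal buffering
    T_MA = round(16.5 + 0.30 * (cl$T_MAX - 29) - 0.55 * (cl$latitude + 32.5)
                 - 1.2 * (cl$longitude - 116), 1),
    T_MAX = cl$T_MAX,
    # seasonal amplitude: grows with summer heat and continentality
    T_RANGE = round(8 + 0.5 * (cl$T_MAX - 25) +
                      1.5 * (cl$longitude - 115.5), 1),
    P_MA = cl$P_MA,
    P_DM = cl$P_DM,
    # wet-dry seasonal contrast, larger toward the (western) coast
    P_RANGE = pmax(round(45 + cl$P_MA / 8 - 2 * cl$P_DM +
                           20 * (116.5 - cl$longitude), 0), 10),
    AI_inv = cl$AI_inv,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
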