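#' Physical constants used throughout the package
#'
#' @description
#' Standard moist-air gas constants and unit-conversion factors:
#'
#' * `R_DRY_AIR`: specific gas constant of dry air, 287.058 J kg^-1 K^-1.
#' * `R_WATER_VAPOUR`: specific gas constant of water vapour, 461.52
#'   J kg^-1 K^-1. The ratio `R_DRY_AIR / R_WATER_VAPOUR` = 0.62198 converts
#'   vapour partial pressure to a dry-air-mass-based mixing ratio.
#' * `FLUX_UNIT_FACTOR`: 3.6. With the driving force in g m^-3
#'   (= µg cm^-3) and the transpiration rate E in mg cm^-2 h^-1
#'   (= 1000/3600 µg cm^-2 s^-1), a resistance in s cm^-1 is
#'   `r = FLUX_UNIT_FACTOR * delta_x / E`. The factor is forced by the
#'   units; it is defined once here and nowhere re-derived.
#' * `GAS_CONSTANT`: universal gas constant, 8.314 J mol^-1 K^-1, used by
#'   the Arrhenius temperature adjustment.
#'
#' @name constants
#' @aliases R_DRY_AIR R_WATER_VAPOUR FLUX_UNIT_FACTOR GAS_CONSTANT
#' @examples
#' # 1 g m^-3 driving force at E = 3.6 mg cm^-2 h^-1 is 1 s cm^-1
#' FLUX_UNIT_FACTOR * 1 / 3.6
NULL

#' @rdname constants
#' @export
R_DRY_AIR <- 287.058

#' @rdname constants
#' @export
R_WATER_VAPOUR <- 461.52

#' @rdname constants
#' @export
FLUX_UNIT_FACTOR <- 3.6

#' @rdname constants
#' @export
GAS_CONSTANT <- 8.314

# temperature window over which the saturation-pressure approximation is
# accepted; outside it the fit is unvalidated and we refuse to extrapolate
.PSAT_T_MIN <- -10
.PSAT_T_MAX <- 50

.DEFAULT_PRESSURE_PA <- 101325
.DEFAULT_WATER_ACTIVITY <- 0.985
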