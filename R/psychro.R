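#' Saturation vapour pressure of water in air
#'
#' Exponential-rational approximation of the saturation partial pressure of
#' water vapour as a function of air temperature, valid for the postharvest
#' temperature range of -10 to +50 degC.
#'
#' @param temperature_c Air temperature in degC. Vectorised.
#' @return Saturation vapour pressure in Pa, strictly increasing in
#'   temperature.
#' @examples
#' saturation_vapour_pressure(0)   # ~ 610.5 Pa
#' saturation_vapour_pressure(20)  # ~ 2337 Pa
#' @export
saturation_vapour_pressure <- function(temperature_c) {
  if (!is.numeric(temperature_c) || anyNA(temperature_c)) {
    stop("'temperature_c' must be numeric and non-missing", call. = FALSE)
  }
  if (any(temperature_c < .PSAT_T_MIN | temperature_c > .PSAT_T_MAX)) {
    stop(sprintf(
      "temperature outside the validity window [%g, %g] degC of the saturation-pressure approximation",
      .PSAT_T_MIN, .PSAT_T_MAX
    ), call. = FALSE)
  }
  exp((6.4142801 + 0.0996709 * temperature_c) /
        (1 + 0.004197225 * temperature_c))
}

#' Partial pressure of water vapour
#'
#' @param psat_pa Saturation vapour pressure in Pa.
#' @param relative_humidity_pct Relative humidity in percent, 0 to 100.
#' @return Partial vapour pressure in Pa.
#' @export
partial_pressure <- function(psat_pa, relative_humidity_pct) {
  if (any(relative_humidity_pct < 0 | relative_humidity_pct > 100)) {
    stop("relative humidity must lie in [0, 100] %", call. = FALSE)
  }
  psat_pa * (relative_humidity_pct / 100)
}

#' Mass-related water content (mixing ratio) of humid air
#'
#' Mass of water vapour per unit mass of dry air from the vapour partial
#' pressure and the barometric pressure.
#'
#' @param pvap_pa Partial pressure of water vapour in Pa.
#' @param pressure_pa Barometric pressure in Pa.
#' @return Mixing ratio in kg water per kg dry air.
#' @export
mass_water_content <- function(pvap_pa, pressure_pa) {
  if (any(pvap_pa < 0)) {
    stop("vapour partial pressure must be non-negative", call. = FALSE)
  }
  if (any(pvap_pa >= pressure_pa)) {
    stop("vapour partial pressure at or above barometric pressure is unphysical",
         call. = FALSE)
  }
  (R_DRY_AIR / R_WATER_VAPOUR) * pvap_pa / (pressure_pa - pvap_pa)
}

#' Density of humid air
#'
#' Ideal-gas density of the air/water-vapour mixture.
#'
#' @param x_mass Mixing ratio in kg water per kg dry air.
#' @param temperature_c Air temperature in degC.
#' @param pressure_pa Barometric pressure in Pa.
#' @return Density in kg m^-3.
#' @export
air_density <- function(x_mass, temperature_c, pressure_pa) {
  if (any(temperature_c <= -273.15)) {
    stop("absolute temperature must be positive", call. = FALSE)
  }
  if (any(x_mass < 0)) {
    stop("mixing ratio must be non-negative", call. = FALSE)
  }
  (1 + x_mass) * pressure_pa /
    ((R_DRY_AIR + R_WATER_VAPOUR * x_mass) * (273.15 + temperature_c))
}

#' Volume-related water content of humid air
#'
#' Converts the dry-air-mass-based mixing ratio to a volume-related water
#' content by multiplying with the humid-air density. The product is used as
#' the vapour concentration driving transpiration.
#'
#' @param x_mass Mixing ratio in kg water per kg dry air.
#' @param density Humid-air density in kg m^-3.
#' @return Volume-related water content in g m^-3.
#' @export
volume_water_content <- function(x_mass, density) {
  if (any(x_mass < 0) || any(density < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  x_mass * density * 1000
}

# vectorised forward chain; returns the volume-related water content only
.x_vol_chain <- function(temperature_c, relative_humidity_pct, pressure_pa) {
  psa <- saturation_vapour_pressure(temperature_c)
  pda <- partial_pressure(psa, relative_humidity_pct)
  xa <- mass_water_content(pda, pressure_pa)
  rho <- air_density(xa, temperature_c, pressure_pa)
  volume_water_content(xa, rho)
}

#' Full psychrometric state of humid air
#'
#' Chains the psychrometric relations to derive, from measured temperature,
#' relative humidity and barometric pressure, the saturation and partial
#' vapour pressures, the mixing ratio, the humid-air density and the
#' volume-related water content.
#'
#' @param temperature_c Air temperature in degC.
#' @param relative_humidity_pct Relative humidity in percent.
#' @param pressure_pa Barometric pressure in Pa (default 101325).
#' @return An object of class `air_state`: a list with fields
#'   `temperature_c`, `relative_humidity_pct`, `pressure_pa`, `psat_pa`,
#'   `pvap_pa`, `x_mass` (kg kg^-1), `density` (kg m^-3) and `x_vol`
#'   (g m^-3).
#' @examples
#' st <- air_state(20, 50, 101325)
#' st$x_vol  # ~ 8.7 g water per m^3
#' @export
air_state <- function(temperature_c, relative_humidity_pct,
                      pressure_pa = .DEFAULT_PRESSURE_PA) {
  psa <- saturation_vapour_pressure(temperature_c)
  pda <- partial_pressure(psa, relative_humidity_pct)
  xa <- mass_water_content(pda, pressure_pa)
  rho <- air_density(xa, temperature_c, pressure_pa)
  structure(
    list(
      temperature_c = temperature_c,
      relative_humidity_pct = relative_humidity_pct,
      pressure_pa = pressure_pa,
      psat_pa = psa,
      pvap_pa = pda,
      x_mass = xa,
      density = rho,
      x_vol = volume_water_content(xa, rho)
    ),
    class = "air_state"
  )
}

#' @export
print.air_state <- function(x, ...) {
  cat("Humid-air state\n")
  cat(sprintf("  temperature      %8.2f degC\n", x$temperature_c))
  cat(sprintf("  rel. humidity    %8.2f %%\n", x$relative_humidity_pct))
  cat(sprintf("  pressure         %8.0f Pa\n", x$pressure_pa))
  cat(sprintf("  psat             %8.1f Pa\n", x$psat_pa))
  cat(sprintf("  pvap             %8.1f Pa\n", x$pvap_pa))
  cat(sprintf("  mixing ratio     %10.6f kg/kg\n", x$x_mass))
  cat(sprintf("  density          %8.4f kg/m3\n", x$density))
  cat(sprintf("  water content    %8.3f g/m3\n", x$x_vol))
  invisible(x)
}

#' Relative humidity from a volume-related water content
#'
#' Inverse psychrometric solve: recovers the relative humidity that, at the
#' given temperature and pressure, produces the given volume-related water
#' content. Because both the mixing ratio and the humid-air density depend
#' on the vapour partial pressure, the inverse is obtained by fixed-point
#' iteration on the mixing ratio (relative tolerance 1e-9, at most 100
#' iterations; in practice convergence takes fewer than 10).
#'
#' @param x_vol Volume-related water content in g m^-3.
#' @param temperature_c Air temperature in degC.
#' @param pressure_pa Barometric pressure in Pa.
#' @return Relative humidity in percent such that
#'   `air_state(temperature_c, ., pressure_pa)$x_vol` reproduces `x_vol`.
#' @examples
#' humidity_from_volume_content(air_state(20, 50)$x_vol, 20)  # 50
#' @export
humidity_from_volume_content <- function(x_vol, temperature_c,
                                         pressure_pa = .DEFAULT_PRESSURE_PA) {
  if (any(x_vol < 0)) {
    stop("volume-related water content must be non-negative", call. = FALSE)
  }
  x_vol_sat <- .x_vol_chain(temperature_c, 100, pressure_pa)
  if (any(x_vol > x_vol_sat * (1 + 1e-9))) {
    stop(sprintf(
      "water content %.4g g/m3 exceeds saturation (%.4g g/m3) at %.2f degC: supersaturated",
      max(x_vol), min(x_vol_sat), min(temperature_c)
    ), call. = FALSE)
  }
  psa <- saturation_vapour_pressure(temperature_c)
  w <- x_vol / 1000  # kg water per m^3 moist air
  xa <- w * 0        # start at the dry-air density
  for (i in seq_len(100)) {
    rho <- air_density(xa, temperature_c, pressure_pa)
    xa_new <- w / rho
    done <- all(abs(xa_new - xa) <= 1e-9 * pmax(xa_new, 1e-30))
    xa <- xa_new
    if (done) break
  }
  ratio <- R_DRY_AIR / R_WATER_VAPOUR
  pda <- xa * pressure_pa / (ratio + xa)
  pmin(100 * pda / psa, 100)
}

#' Water-vapour concentration in the produce intercellular air
#'
#' The air in the intercellular spaces of fresh produce is at, or very close
#' to, saturation; its equilibrium relative humidity equals the tissue water
#' activity. This returns the volume-related water content of air at the
#' produce temperature and `100 * water_activity` percent relative humidity
#' -- the interior endpoint of the transpiration driving force.
#'
#' @param produce_temperature_c Produce temperature in degC.
#' @param water_activity Water activity of the tissue, in (0, 1]; 0.985 is
#'   the default for fresh apples without wilting signs.
#' @param pressure_pa Barometric pressure in Pa.
#' @return Volume-related water content in g m^-3.
#' @export
intercellular_water_content <- function(produce_temperature_c,
                                        water_activity = .DEFAULT_WATER_ACTIVITY,
                                        pressure_pa = .DEFAULT_PRESSURE_PA) {
  if (any(water_activity <= 0 | water_activity > 1)) {
    stop("water activity must lie in (0, 1]", call. = FALSE)
  }
  .x_vol_chain(produce_temperature_c, 100 * water_activity, pressure_pa)
}
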