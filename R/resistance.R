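#' Area-related transpiration rate from differential weighing
#'
#' @param delta_fm_mg Fresh-matter loss over the interval in mg (positive
#'   for mass loss). A negative value (mass gain, e.g. condensation) is
#'   accepted but flagged with a warning.
#' @param area_cm2 Produce surface area in cm^2.
#' @param delta_t_h Interval length in h.
#' @return Transpiration rate E in mg cm^-2 h^-1.
#' @examples
#' transpiration_rate(40, 200, 2)  # 0.1 mg cm^-2 h^-1
#' @export
transpiration_rate <- function(delta_fm_mg, area_cm2, delta_t_h) {
  if (any(area_cm2 <= 0)) stop("surface area must be positive", call. = FALSE)
  if (any(delta_t_h <= 0)) stop("time interval must be positive", call. = FALSE)
  if (any(delta_fm_mg < 0)) {
    warning("negative fresh-matter loss: mass gain over the interval (condensation?)",
            call. = FALSE)
  }
  delta_fm_mg / (area_cm2 * delta_t_h)
}

#' Total transpiration resistance from rate and driving force
#'
#' The diffusion model treats the water-vapour flux as a concentration
#' difference over a series resistance: `E = delta_x / r_tot` in consistent
#' units. With `x` in g m^-3 and `E` in mg cm^-2 h^-1 the resistance in
#' s cm^-1 is `FLUX_UNIT_FACTOR * (x_p - x_a) / E`.
#'
#' @param E Transpiration rate in mg cm^-2 h^-1; must be positive.
#' @param x_p Intercellular water-vapour concentration in g m^-3.
#' @param x_a Ambient water-vapour concentration in g m^-3.
#' @return Total resistance in s cm^-1.
#' @export
total_resistance <- function(E, x_p, x_a) {
  if (any(E <= 0)) {
    stop("transpiration rate must be positive to infer a resistance (no transpiration)",
         call. = FALSE)
  }
  if (any(x_p <= x_a)) {
    stop("intercellular concentration must exceed ambient (condensation regime)",
         call. = FALSE)
  }
  FLUX_UNIT_FACTOR * (x_p - x_a) / E
}

#' Tissue resistance by subtracting the boundary layer
#'
#' @param r_tot Total resistance in s cm^-1.
#' @param r_B Boundary-layer resistance in s cm^-1 (0 under forced
#'   convection above 2 m s^-1 or with a wetted surface).
#' @return Tissue resistance `r_tot - r_B` in s cm^-1. A negative result is
#'   an error, never clamped: it signals inconsistent protocol or climate
#'   inputs.
#' @export
tissue_resistance <- function(r_tot, r_B) {
  if (any(r_tot < 0) || any(r_B < 0)) {
    stop("resistances must be non-negative", call. = FALSE)
  }
  if (any(r_B > r_tot)) {
    stop(sprintf(
      "boundary-layer resistance (%.3g s/cm) exceeds total resistance (%.3g s/cm): inconsistent inputs",
      max(r_B), min(r_tot)), call. = FALSE)
  }
  r_tot - r_B
}

#' Boundary-layer resistance from paired free/stripped measurements
#'
#' The boundary layer of an individual fruit is measured by difference: one
#' run under free convection with the authentic boundary layer, and one run
#' with the boundary layer stripped (forced airflow above 2 m s^-1, or a
#' wetted surface). Both totals must come from the same fruit at the same
#' temperature.
#'
#' @param r_tot_free Total resistance with authentic boundary layer, s cm^-1.
#' @param r_tot_stripped Total resistance with the boundary layer removed,
#'   s cm^-1.
#' @return Boundary-layer resistance in s cm^-1.
#' @export
boundary_layer_by_difference <- function(r_tot_free, r_tot_stripped) {
  if (any(r_tot_free < r_tot_stripped)) {
    stop("stripped-boundary-layer total exceeds the free-convection total: protocol inconsistency",
         call. = FALSE)
  }
  r_tot_free - r_tot_stripped
}

#' Bulk boundary-layer resistance
#'
#' For fruit packed in a container the effective boundary-layer resistance
#' is the difference between the total resistance measured in the package
#' and the tissue resistance determined on individual fruit.
#'
#' @param r_tot_bulk Total resistance of the packaged fruit, s cm^-1.
#' @param r_T Tissue resistance from the individual-fruit protocol, s cm^-1.
#' @return Bulk boundary-layer resistance in s cm^-1.
#' @export
bulk_boundary_layer <- function(r_tot_bulk, r_T) {
  if (any(r_tot_bulk < r_T)) {
    stop("bulk total resistance below the tissue resistance: protocol inconsistency",
         call. = FALSE)
  }
  r_tot_bulk - r_T
}

#' Water-vapour concentration and relative humidity at the produce surface
#'
#' With the boundary-layer resistance known, the surface concentration
#' follows from the flux across the boundary layer alone:
#' `x_pS = x_a + E * r_B / FLUX_UNIT_FACTOR`. The surface relative humidity
#' is then recovered by the inverse psychrometric solve at the surface
#' temperature.
#'
#' @param E Transpiration rate in mg cm^-2 h^-1.
#' @param r_B Boundary-layer resistance in s cm^-1.
#' @param x_a Ambient water-vapour concentration in g m^-3.
#' @param surface_temperature_c Produce surface temperature in degC (use the
#'   measured produce temperature when available, else the air temperature).
#' @param pressure_pa Barometric pressure in Pa.
#' @return A list with `x_pS` (g m^-3) and `rh_surface_pct` (percent).
#' @export
surface_conditions <- function(E, r_B, x_a, surface_temperature_c,
                               pressure_pa = .DEFAULT_PRESSURE_PA) {
  if (any(r_B < 0)) stop("boundary-layer resistance must be non-negative",
                         call. = FALSE)
  if (any(E < 0)) stop("transpiration rate must be non-negative", call. = FALSE)
  x_pS <- x_a + E * r_B / FLUX_UNIT_FACTOR
  rh <- humidity_from_volume_content(x_pS, surface_temperature_c, pressure_pa)
  list(x_pS = x_pS, rh_surface_pct = rh)
}

#' Arrhenius temperature adjustment of a resistance
#'
#' All transpiration resistances are temperature dependent; where a
#' measurement at the temperature of interest is unavailable, an Arrhenius
#' relationship gives an approximate adjustment:
#' `r(T) = r_ref * exp[(Ea/R) * (1/T - 1/T_ref)]` with absolute
#' temperatures, so resistance increases as temperature falls.
#'
#' @param r_ref Resistance at the reference temperature, s cm^-1.
#' @param T_ref_c Reference temperature in degC.
#' @param T_target_c Target temperature in degC.
#' @param activation_energy_j_mol Activation energy Ea in J mol^-1; no
#'   universal default exists, supply a measured value or estimate one with
#'   [estimate_activation_energy()].
#' @return Adjusted resistance in s cm^-1.
#' @export
arrhenius_adjust <- function(r_ref, T_ref_c, T_target_c,
                             activation_energy_j_mol) {
  if (any(T_ref_c <= -273.15) || any(T_target_c <= -273.15)) {
    stop("absolute temperatures must be positive", call. = FALSE)
  }
  r_ref * exp((activation_energy_j_mol / GAS_CONSTANT) *
                (1 / (273.15 + T_target_c) - 1 / (273.15 + T_ref_c)))
}

#' Activation energy from resistances at several temperatures
#'
#' Least-squares slope of `log(r)` against inverse absolute temperature,
#' scaled by the universal gas constant.
#'
#' @param r_s_cm Resistances in s cm^-1, all positive.
#' @param temperature_c Matching temperatures in degC; at least two distinct
#'   values are required.
#' @return Activation energy in J mol^-1.
#' @examples
#' estimate_activation_energy(c(391, 750), c(20, 1))  # ~ 22.9 kJ/mol
#' @export
estimate_activation_energy <- function(r_s_cm, temperature_c) {
  if (length(r_s_cm) != length(temperature_c)) {
    stop("resistances and temperatures must have equal length", call. = FALSE)
  }
  if (length(r_s_cm) < 2 || length(unique(temperature_c)) < 2) {
    stop("at least two distinct temperatures are required", call. = FALSE)
  }
  if (any(r_s_cm <= 0)) stop("resistances must be positive", call. = FALSE)
  inv_T <- 1 / (273.15 + temperature_c)
  fit <- stats::lm(log(r_s_cm) ~ inv_T)
  unname(stats::coef(fit)[["inv_T"]]) * GAS_CONSTANT
}

#' Run a full measurement protocol on one weighing series
#'
#' End-to-end estimation: the transpiration rate from the weighing series,
#' the ambient vapour concentration from the time-weighted mean climate over
#' the weighing interval, the intercellular concentration from the produce
#' temperature and water activity, the total resistance, its partition into
#' tissue and boundary-layer components according to the protocol, and the
#' recovered surface humidity.
#'
#' Partitioning by protocol:
#' * `free`: `r_B` is the configured free-convection default (4.0 s cm^-1
#'   for apples when unset) and `r_T = r_tot - r_B`;
#' * `forced`, `wetted`: the boundary layer is stripped, `r_B = 0`,
#'   `r_T = r_tot`;
#' * `bulk`: the tissue resistance from the individual-fruit protocol must
#'   be supplied in the config and `r_B = r_tot - r_T`.
#'
#' Every substituted assumption (default boundary-layer resistance, default
#' barometric pressure, produce-temperature fallback to air temperature) is
#' reported via `message()` and recorded in the result's provenance.
#'
#' @param series A [weighing_series()].
#' @param climate A [climate_log()] covering the weighing interval.
#' @param item A [produce_item()].
#' @param config A [protocol_config()].
#' @return An object of class `resistance_result`: a list with the
#'   transpiration rate `E` (mg cm^-2 h^-1), concentrations `x_p`, `x_a`,
#'   `delta_x`, `x_pS` (g m^-3), resistances `r_tot`, `r_T`, `r_B`
#'   (s cm^-1), `rh_surface_pct`, the `protocol` tag and a `provenance`
#'   list (interval, duration, estimator, assumptions used).
#' @export
run_protocol <- function(series, climate, item, config) {
  stopifnot(inherits(series, "weighing_series"),
            inherits(climate, "climate_log"),
            inherits(item, "produce_item"),
            inherits(config, "protocol_config"))
  assumptions <- character(0)
  rec <- series$records
  t0 <- rec$timestamp[1]
  t1 <- rec$timestamp[nrow(rec)]
  duration_h <- as.numeric(difftime(t1, t0, units = "hours"))
  if (duration_h < config$min_duration_h) {
    warning(sprintf(
      "series spans %.1f h, below the recommended minimum of %g h for the '%s' protocol",
      duration_h, config$min_duration_h, config$protocol), call. = FALSE)
  }

  clim <- mean_climate(climate, t0, t1)
  pbar <- clim$pressure_pa
  if (is.na(pbar)) {
    pbar <- .DEFAULT_PRESSURE_PA
    assumptions <- c(assumptions, sprintf(
      "barometric pressure not logged; default %g Pa used", pbar))
  }

  # transpiration rate from the configured estimator
  A <- item$area_cm2
  if (config$estimator == "endpoint") {
    delta_fm_mg <- (rec$mass_g[1] - rec$mass_g[nrow(rec)]) * 1000
    if (delta_fm_mg < 0) {
      warning("mass gain over the series (condensation?)", call. = FALSE)
    }
    E <- delta_fm_mg / (A * duration_h)
  } else {
    t_h <- as.numeric(difftime(rec$timestamp, t0, units = "hours"))
    fit <- stats::lm(rec$mass_g ~ t_h)
    slope_g_h <- unname(stats::coef(fit)[["t_h"]])
    if (slope_g_h > 0) {
      warning("mass gain over the series (condensation?)", call. = FALSE)
    }
    E <- -slope_g_h * 1000 / A
  }

  aw <- if (!is.null(item$water_activity)) item$water_activity else config$aw
  Tp <- item$produce_temperature_c
  if (is.null(Tp)) {
    Tp <- clim$temperature_c
    assumptions <- c(assumptions, sprintf(
      "produce temperature not measured; mean air temperature %.2f degC substituted", Tp))
    surface_T_basis <- "air"
  } else {
    surface_T_basis <- "produce"
  }

  x_p <- intercellular_water_content(Tp, aw, pbar)
  x_a <- .x_vol_chain(clim$temperature_c, clim$relative_humidity_pct, pbar)
  r_tot <- total_resistance(E, x_p, x_a)

  if (config$protocol == "free") {
    r_B <- config$rb_default_s_cm
    if (is.null(r_B)) {
      if (identical(item$species, "apple")) {
        r_B <- 4.0
        assumptions <- c(assumptions,
          "free-convection boundary-layer resistance not supplied; apple default 4.0 s/cm used")
      } else {
        stop(sprintf(
          "no free-convection boundary-layer default for species '%s'; supply rb_default_s_cm or use a difference protocol",
          item$species), call. = FALSE)
      }
    }
    r_T <- tissue_resistance(r_tot, r_B)
  } else if (config$protocol %in% c("forced", "wetted")) {
    r_B <- 0
    r_T <- r_tot
  } else { # bulk
    if (is.null(config$r_tissue_s_cm)) {
      stop("bulk protocol requires the individually measured tissue resistance (r_tissue_s_cm)",
           call. = FALSE)
    }
    r_T <- config$r_tissue_s_cm
    r_B <- bulk_boundary_layer(r_tot, r_T)
  }

  surf <- surface_conditions(E, r_B, x_a, Tp, pbar)
  for (a in assumptions) message("assumption: ", a)

  structure(
    list(
      E = E, x_p = x_p, x_a = x_a, delta_x = x_p - x_a,
      r_tot = r_tot, r_T = r_T, r_B = r_B,
      x_pS = surf$x_pS, rh_surface_pct = surf$rh_surface_pct,
      protocol = config$protocol,
      provenance = list(
        item_id = item$item_id, species = item$species,
        interval = c(start = t0, end = t1), duration_h = duration_h,
        estimator = config$estimator,
        mean_temperature_c = clim$temperature_c,
        mean_relative_humidity_pct = clim$relative_humidity_pct,
        pressure_pa = pbar, water_activity = aw,
        produce_temperature_c = Tp,
        surface_rh_temperature_basis = surface_T_basis,
        assumptions = assumptions
      )
    ),
    class = "resistance_result"
  )
}

#' @export
print.resistance_result <- function(x, ...) {
  cat(sprintf("Transpiration resistance result ('%s' protocol, item '%s')\n",
              x$protocol, x$provenance$item_id))
  cat(sprintf("  E        %10.4f mg cm-2 h-1\n", x$E))
  cat(sprintf("  x_p      %10.3f g m-3\n", x$x_p))
  cat(sprintf("  x_a      %10.3f g m-3\n", x$x_a))
  cat(sprintf("  delta_x  %10.3f g m-3\n", x$delta_x))
  cat(sprintf("  r_tot    %10.2f s cm-1\n", x$r_tot))
  cat(sprintf("  r_T      %10.2f s cm-1\n", x$r_T))
  cat(sprintf("  r_B      %10.2f s cm-1\n", x$r_B))
  cat(sprintf("  x_pS     %10.3f g m-3 (surface rH %.1f %%)\n",
              x$x_pS, x$rh_surface_pct))
  if (length(x$provenance$assumptions) > 0) {
    cat("  assumptions:\n")
    for (a in x$provenance$assumptions) cat("   -", a, "\n")
  }
  invisible(x)
}
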