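#' Surface-area regression coefficients
#'
#' Loads the empirical regressions that predict produce surface area from
#' fresh mass and, where needed, simple geometric dimensions. One row per
#' species, with the calibrated mass range, the regression coefficients at
#' full published precision, the coefficient of determination and the number
#' of calibration samples.
#'
#' @return A data.frame with columns `species`, `mass_min_g`, `mass_max_g`,
#'   `intercept`, `coef_mass_g`, `coef_length_cm`, `coef_d1_mm`,
#'   `coef_d2_mm`, `coef_d3_mm`, `r_squared`, `n_samples`.
#' @export
surface_area_coefficients <- function() {
  path <- system.file("extdata", "surface_area_coefficients.csv",
                      package = "transpirest", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Produce surface area from mass and dimensions
#'
#' Evaluates the species-specific allometric regression. Predictors beyond
#' fresh mass are required only where the species' regression uses them:
#' white asparagus needs the spear length, carrot needs length and the mean
#' diameter over the root length, radish tubers need the height diameter and
#' the transverse diameter (the latter measured twice with a 90 degree
#' rotation; both measurements may be supplied and are averaged).
#'
#' A mass outside the species' calibrated range is accepted but triggers a
#' calibration-range warning: the regressions are empirical and carry no
#' extrapolation guarantee.
#'
#' @param species One of `"apple"`, `"white_asparagus"`, `"bell_pepper"`,
#'   `"carrot"`, `"radish_tuber"`, `"plum"`, `"strawberry"`.
#' @param mass_g Fresh mass in g.
#' @param length_cm Length in cm (asparagus, carrot).
#' @param d1_mm Mean diameter over the length in mm (carrot).
#' @param d2_mm Height diameter in mm (radish tuber).
#' @param d3_mm Transverse diameter in mm (radish tuber); a length-2 vector
#'   of the two rotated measurements is averaged.
#' @return Surface area in cm^2.
#' @examples
#' surface_area("apple", mass_g = 100)   # 166.68 cm^2
#' surface_area("radish_tuber", d2_mm = 25, d3_mm = c(24, 26))
#' @export
surface_area <- function(species, mass_g = NULL, length_cm = NULL,
                         d1_mm = NULL, d2_mm = NULL, d3_mm = NULL) {
  coefs <- surface_area_coefficients()
  row <- coefs[coefs$species == species, ]
  if (nrow(row) != 1) {
    stop(sprintf("unknown species '%s'; known species: %s", species,
                 paste(coefs$species, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(d3_mm) && length(d3_mm) > 1) d3_mm <- mean(d3_mm)

  preds <- list(mass_g = mass_g, length_cm = length_cm, d1_mm = d1_mm,
                d2_mm = d2_mm, d3_mm = d3_mm)
  betas <- c(mass_g = row$coef_mass_g, length_cm = row$coef_length_cm,
             d1_mm = row$coef_d1_mm, d2_mm = row$coef_d2_mm,
             d3_mm = row$coef_d3_mm)
  needed <- names(betas)[betas != 0]
  missing <- needed[vapply(preds[needed], is.null, logical(1))]
  if (length(missing) > 0) {
    stop(sprintf("species '%s' requires predictor(s): %s", species,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(mass_g)) {
    if (mass_g <= 0) stop("mass must be positive", call. = FALSE)
    if (mass_g < row$mass_min_g || mass_g > row$mass_max_g) {
      warning(sprintf(
        "mass %.1f g outside the calibrated range [%g, %g] g for %s; extrapolating the regression",
        mass_g, row$mass_min_g, row$mass_max_g, species), call. = FALSE)
    }
  }
  area <- row$intercept +
    sum(vapply(needed, function(p) betas[[p]] * preds[[p]], numeric(1)))
  if (area <= 0) {
    stop("regression returned a non-positive surface area; check the inputs",
         call. = FALSE)
  }
  area
}

#' A produce item with its transpiration-relevant properties
#'
#' Bundles the identity, mass, dimensions, surface area, water activity and
#' (optionally) the measured produce temperature of one fruit or vegetable,
#' or of one bulk container. If no measured surface area is supplied it is
#' estimated from the species regression via [surface_area()]; a
#' user-supplied measured area always takes precedence.
#'
#' @param item_id Label for the item.
#' @param species Species name; one of the calibrated species, or any other
#'   label if `area_cm2` is supplied directly.
#' @param mass_g Fresh mass in g.
#' @param length_cm,d1_mm,d2_mm,d3_mm Optional dimensions, see
#'   [surface_area()].
#' @param area_cm2 Measured surface area in cm^2, overriding the regression.
#' @param water_activity Tissue water activity, default 0.985.
#' @param produce_temperature_c Measured produce (surface) temperature in
#'   degC, e.g. from an infrared sensor; if `NULL` the mean air temperature
#'   is substituted during analysis.
#' @return An object of class `produce_item`.
#' @export
produce_item <- function(item_id, species, mass_g,
                         length_cm = NULL, d1_mm = NULL, d2_mm = NULL,
                         d3_mm = NULL, area_cm2 = NULL,
                         water_activity = .DEFAULT_WATER_ACTIVITY,
                         produce_temperature_c = NULL) {
  if (mass_g <= 0) stop("mass must be positive", call. = FALSE)
  if (water_activity <= 0 || water_activity > 1) {
    stop("water activity must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(area_cm2)) {
    area_cm2 <- surface_area(species, mass_g = mass_g, length_cm = length_cm,
                             d1_mm = d1_mm, d2_mm = d2_mm, d3_mm = d3_mm)
  } else if (area_cm2 <= 0) {
    stop("surface area must be positive", call. = FALSE)
  }
  structure(
    list(item_id = item_id, species = species, mass_g = mass_g,
         length_cm = length_cm, d1_mm = d1_mm, d2_mm = d2_mm, d3_mm = d3_mm,
         area_cm2 = area_cm2, water_activity = water_activity,
         produce_temperature_c = produce_temperature_c),
    class = "produce_item"
  )
}

#' @export
print.produce_item <- function(x, ...) {
  cat(sprintf("Produce item '%s' (%s): %.1f g, %.1f cm2, aw = %.3f\n",
              x$item_id, x$species, x$mass_g, x$area_cm2, x$water_activity))
  if (!is.null(x$produce_temperature_c)) {
    cat(sprintf("  produce temperature: %.2f degC\n", x$produce_temperature_c))
  }
  invisible(x)
}

#' Reference tissue and boundary-layer resistances
#'
#' Loads the bundled table of measured and literature transpiration
#' resistances for common fruit and vegetables (tissue-resistance ranges or
#' means with standard deviations, and boundary-layer resistances, all in
#' s cm^-1), used for plausibility checks and temperature-dependence
#' estimates.
#'
#' @return A data.frame with columns `produce`, `condition`,
#'   `temperature_c`, `r_tissue_lo_s_cm`, `r_tissue_hi_s_cm`,
#'   `r_tissue_sd_s_cm`, `r_boundary_lo_s_cm`, `r_boundary_hi_s_cm`,
#'   `source` (`"measurement"` or `"literature"`).
#' @export
reference_resistances <- function() {
  path <- system.file("extdata", "reference_resistances.csv",
                      package = "transpirest", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
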