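#' Model parameters for EMCC calculations
#'
#' Physical constants and tunable parameters shared by all free-energy
#' calculations. The gas constant (8.314 J mol^-1 K^-1) and Faraday constant
#' (96485.3 C mol^-1) are fixed; everything else is configurable.
#'
#' @param temperature_K Absolute temperature in kelvin. Default 293 K
#'   (roughly 20 degrees C, typical of temperate sediment).
#' @param loss_V_per_mm Linear potential drop per millimetre of conductor,
#'   in volts. Default 0.013 V/mm, within the 12.3--14.6 mV/mm range
#'   estimated for cable bacteria filaments. Set to 0 for a lossless
#'   conductor.
#' @param concentration_floor_M Smallest admissible activity in mol/L;
#'   concentrations at or below it are raised to it before any logarithm.
#'   Default 1e-9 M (1 nM), just below the 2--20 nM detection limit of the
#'   most sensitive microsensors -- the practical meaning of "zero".
#' @param energy_threshold_J_per_mol Feasibility threshold in J/mol: a
#'   reaction is deemed able to support microbial energy conservation when
#'   \eqn{\Delta G} is below it. Default -10000 J/mol (-10 kJ/mol), the
#'   assumed minimum for ATP synthesis.
#'
#' @return An object of class `"emcc_params"`: a list with the fields above
#'   plus the fixed `gas_constant` and `faraday_constant`.
#' @examples
#' emcc_params()
#' emcc_params(temperature_K = 277, loss_V_per_mm = 0.010)
#' @export
emcc_params <- function(temperature_K = 293,
                        loss_V_per_mm = 0.013,
                        concentration_floor_M = 1e-9,
                        energy_threshold_J_per_mol = -10000) {
  if (!is.finite(temperature_K) || temperature_K <= 0)
    stop("'temperature_K' must be positive", call. = FALSE)
  if (!is.finite(loss_V_per_mm) || loss_V_per_mm < 0)
    stop("'loss_V_per_mm' must be >= 0", call. = FALSE)
  if (!is.finite(concentration_floor_M) || concentration_floor_M <= 0)
    stop("'concentration_floor_M' must be > 0", call. = FALSE)
  structure(
    list(temperature_K = temperature_K,
         gas_constant = .GAS_CONSTANT,
         faraday_constant = .FARADAY,
         loss_V_per_mm = loss_V_per_mm,
         concentration_floor_M = concentration_floor_M,
         energy_threshold_J_per_mol = energy_threshold_J_per_mol),
    class = "emcc_params")
}

#' @export
print.emcc_params <- function(x, ...) {
  cat("EMCC model parameters\n")
  cat(sprintf("  temperature:          %g K\n", x$temperature_K))
  cat(sprintf("  conductor loss:       %g V/mm\n", x$loss_V_per_mm))
  cat(sprintf("  concentration floor:  %g M\n", x$concentration_floor_M))
  cat(sprintf("  energy threshold:     %g kJ/mol\n",
              x$energy_threshold_J_per_mol / 1000))
  invisible(x)
}

#' Describe the chemical state of one compartment
#'
#' One end of a concentration cell: the activities of the dissolved species
#' (relative to a 1 M standard state, so numerically mol/L) and the pH.
#' Proton activity is taken as exactly `10^-pH`; no activity-coefficient
#' corrections are applied.
#'
#' @param concentrations Named numeric vector of species activities in
#'   mol/L, e.g. `c(O2 = 3e-4)`. Species `"H2O"` and `"H+"` never need to be
#'   listed (see [redox_couple()] for their conventions).
#' @param pH Finite numeric pH.
#' @return An object of class `"compartment"`.
#' @examples
#' compartment(c(O2 = 3e-4), pH = 7)
#' @export
compartment <- function(concentrations = numeric(), pH = 7) {
  if (length(concentrations) &&
      (is.null(names(concentrations)) || any(!nzchar(names(concentrations)))))
    stop("'concentrations' must be a named vector", call. = FALSE)
  if (!is.finite(pH))
    stop("'pH' must be finite", call. = FALSE)
  structure(list(concentrations = concentrations, pH = as.numeric(pH)),
            class = "compartment")
}

#' @export
print.compartment <- function(x, ...) {
  cat(sprintf("Compartment (pH %.2f)\n", x$pH))
  if (length(x$concentrations)) {
    for (s in names(x$concentrations))
      cat(sprintf("  %-8s %g M\n", s, x$concentrations[[s]]))
  } else {
    cat("  (no species listed)\n")
  }
  invisible(x)
}

## raise every activity at or below the floor to the floor
.floor_compartment <- function(comp, params) {
  comp$concentrations <- pmax(comp$concentrations,
                              params$concentration_floor_M)
  comp
}

## activity of a couple species in a compartment; honours the H2O and H+
## naming conventions. coef = 0 species are never looked up.
.species_activity <- function(species, comp) {
  if (species == "H2O") return(1)
  if (species == "H+") return(10^(-comp$pH))
  conc <- if (species %in% names(comp$concentrations))
    comp$concentrations[[species]] else NULL
  if (is.null(conc) || is.na(conc))
    stop(sprintf("no concentration given for species '%s'", species),
         call. = FALSE)
  if (conc <= 0)
    stop(sprintf(
      "non-positive concentration for '%s'; apply the concentration floor first",
      species), call. = FALSE)
  conc
}
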