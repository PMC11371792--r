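## Free-energy and potential equations for a two-compartment concentration
## cell. The overall reaction, with "red"/"ox" subscripts tracking *where*
## each species sits (not its redox state), is
##
##   XHn,red + n H+_ox + X_ox  ->  XHn,ox + n H+_red + X_red
##
## and dG = RT ln Q + n F E D, where Q spans both compartments, E is the
## potential drop per mm of conductor and D the conductor length.

## activity of a species in its role inside the reaction quotient:
## H2O and H+ contribute 1 here (water via the aqueous-standard-state E0,
## the proton via the dedicated n_protons exponent)
.quotient_activity <- function(species, comp) {
  if (species %in% c("H2O", "H+")) return(1)
  .species_activity(species, comp)
}

#' Reaction quotient of a two-compartment concentration cell
#'
#' Computes
#' \deqn{Q = \frac{[XH_n]_{ox}^a \, [H^+]_{red}^p \, [X]_{red}^b}
#'            {[XH_n]_{red}^a \, [H^+]_{ox}^p \, [X]_{ox}^b}}
#' where \eqn{a}, \eqn{b} are the stoichiometric coefficients of the reduced
#' and oxidized species and \eqn{p} the proton count. The subscripts denote
#' the compartment in which each species is produced or consumed. Water has
#' activity 1 and, for the \eqn{H^+/H_2} couple, the proton-as-substrate
#' term is carried by the \eqn{p} exponent (see [redox_couple()]).
#'
#' @param couple A [redox_couple()].
#' @param red Compartment where the oxidation (electron-donating) reaction
#'   runs, a [compartment()].
#' @param ox Compartment where the reduction reaction runs.
#' @return A single positive number.
#' @examples
#' o2 <- preset_couple("oxygen")
#' reaction_quotient(o2,
#'                   red = compartment(c(O2 = 1e-9), pH = 7),
#'                   ox  = compartment(c(O2 = 3e-4), pH = 7))
#' @export
reaction_quotient <- function(couple, red, ox) {
  stopifnot(inherits(couple, "redox_couple"),
            inherits(red, "compartment"), inherits(ox, "compartment"))
  a <- couple$reduced_coef
  b <- couple$oxidized_coef
  p <- couple$n_protons
  ## cancelling pairs are differenced before summing, so identical
  ## activities cancel exactly and Q is 1 to the last bit
  log_q <-
    a * (log(.quotient_activity(couple$reduced, ox)) -
           log(.quotient_activity(couple$reduced, red))) +
    b * (log(.quotient_activity(couple$oxidized, red)) -
           log(.quotient_activity(couple$oxidized, ox))) +
    p * log(10) * (ox$pH - red$pH)
  exp(log_q)
}

#' Concentration-driven free energy, RT ln Q
#'
#' The part of \eqn{\Delta G} driven purely by concentration differences
#' between the two compartments: \eqn{RT \ln Q} in J/mol. Zero exactly when
#' the compartments present identical activities (\eqn{Q = 1}).
#'
#' @inheritParams reaction_quotient
#' @param params An [emcc_params()].
#' @return Free energy in J/mol.
#' @export
concentration_delta_g <- function(couple, red, ox, params = emcc_params()) {
  q <- reaction_quotient(couple, red, ox)
  params$gas_constant * params$temperature_K * log(q)
}

#' Potential lost along the conductor
#'
#' Assumes a linear drop in potential with distance:
#' \eqn{E_{loss} = E \cdot D} volts for a loss rate \eqn{E} (V/mm) and
#' conductor length \eqn{D} (mm).
#'
#' @param distance_mm Non-negative conductor length in millimetres.
#' @param params An [emcc_params()].
#' @return Potential loss in volts.
#' @examples
#' conductor_loss(2)  # 0.026 V at the default 13 mV/mm
#' @export
conductor_loss <- function(distance_mm, params = emcc_params()) {
  if (any(!is.finite(distance_mm)) || any(distance_mm < 0))
    stop("'distance_mm' must be non-negative", call. = FALSE)
  params$loss_V_per_mm * distance_mm
}

#' Free energy and cell potential of a concentration cell
#'
#' The central model quantity:
#' \deqn{\Delta G = RT \ln Q + n F E D}
#' with the cell potential derived canonically from it,
#' \eqn{\Delta E = -\Delta G / (nF)}. Activities at or below the
#' concentration floor are raised to the floor before the logarithm, so
#' zero readings never produce an infinite value.
#'
#' @inheritParams concentration_delta_g
#' @param distance_mm Non-negative conductor length in millimetres.
#' @return An object of class `"emcc_result"`: a list with
#'   `reaction_quotient` (Q), `conc_delta_g_J_per_mol` (RT ln Q), `loss_V`
#'   (E·D), `distance_mm`, `delta_g_J_per_mol`, `delta_e_V`
#'   (\eqn{-\Delta G/nF}) and `feasible` (\eqn{\Delta G} below the energy
#'   threshold).
#' @examples
#' ## oxygen cell: 300 uM at the oxidizing end, 1 nM at the reducing end,
#' ## pH 7 at both, 2 mm of conductor
#' emcc_delta_g(preset_couple("oxygen"),
#'              red = compartment(c(O2 = 1e-9), pH = 7),
#'              ox  = compartment(c(O2 = 3e-4), pH = 7),
#'              distance_mm = 2)
#' @export
emcc_delta_g <- function(couple, red, ox, distance_mm = 0,
                         params = emcc_params()) {
  red <- .floor_compartment(red, params)
  ox <- .floor_compartment(ox, params)
  q <- reaction_quotient(couple, red, ox)
  conc_dg <- params$gas_constant * params$temperature_K * log(q)
  loss_v <- conductor_loss(distance_mm, params)
  n <- couple$n_electrons
  f <- params$faraday_constant
  dg <- conc_dg + n * f * loss_v
  structure(
    list(couple = couple$name,
         reaction_quotient = q,
         conc_delta_g_J_per_mol = conc_dg,
         loss_V = loss_v,
         distance_mm = distance_mm,
         delta_g_J_per_mol = dg,
         delta_e_V = -dg / (n * f),
         feasible = dg < params$energy_threshold_J_per_mol,
         threshold_J_per_mol = params$energy_threshold_J_per_mol),
    class = "emcc_result")
}

#' @export
print.emcc_result <- function(x, ...) {
  cat(sprintf("EMCC result (%s, D = %g mm)\n", x$couple, x$distance_mm))
  cat(sprintf("  Q               = %.4g\n", x$reaction_quotient))
  cat(sprintf("  RT ln Q         = %.1f kJ/mol\n",
              x$conc_delta_g_J_per_mol / 1000))
  cat(sprintf("  E_loss          = %.3f V\n", x$loss_V))
  cat(sprintf("  delta G         = %.1f kJ/mol\n",
              x$delta_g_J_per_mol / 1000))
  cat(sprintf("  delta E         = %.3f V\n", x$delta_e_V))
  cat(sprintf("  feasible (< %.0f kJ/mol): %s\n",
              x$threshold_J_per_mol / 1000,
              if (x$feasible) "yes" else "no"))
  invisible(x)
}

#' Half-cell Nernst potentials of the two ends
#'
#' Decomposes the cell potential into the oxidation half (running in the
#' reduced compartment, standard potential sign-negated to mark the
#' reversal) and the reduction half (oxidized compartment):
#' \deqn{E_{ox} = -E^0 - \frac{RT}{nF}
#'       \ln\frac{[H^+]_{red}^p [X]_{red}^b}{[XH_n]_{red}^a}}
#' \deqn{E_{red} = E^0 - \frac{RT}{nF}
#'       \ln\frac{[XH_n]_{ox}^a}{[H^+]_{ox}^p [X]_{ox}^b}}
#' This single self-consistent convention guarantees
#' \eqn{E_{red} + E_{ox} = -RT\ln Q/(nF)} exactly, so that
#' \eqn{\Delta G = -nF(E_{red} + E_{ox} - E_{loss})} agrees with
#' [emcc_delta_g()] to machine precision. The individual values depend on
#' \eqn{E^0} and on which terms are grouped into which half; only their sum
#' is physically constrained, and only the sum should be compared across
#' conventions.
#'
#' @inheritParams concentration_delta_g
#' @return Named numeric vector `c(E_ox = , E_red = )` in volts.
#' @export
half_cell_potentials <- function(couple, red, ox, params = emcc_params()) {
  red <- .floor_compartment(red, params)
  ox <- .floor_compartment(ox, params)
  a <- couple$reduced_coef
  b <- couple$oxidized_coef
  p <- couple$n_protons
  rt_nf <- params$gas_constant * params$temperature_K /
    (couple$n_electrons * params$faraday_constant)
  e0 <- couple$standard_potential_V
  ln_ox_arg <- p * log(10^(-red$pH)) +
    b * log(.quotient_activity(couple$oxidized, red)) -
    a * log(.quotient_activity(couple$reduced, red))
  ln_red_arg <- a * log(.quotient_activity(couple$reduced, ox)) -
    p * log(10^(-ox$pH)) -
    b * log(.quotient_activity(couple$oxidized, ox))
  c(E_ox = -e0 - rt_nf * ln_ox_arg,
    E_red = e0 - rt_nf * ln_red_arg)
}

#' Longest conductor a cell can power
#'
#' With a linear conductor loss the free energy rises by \eqn{nFE} per
#' millimetre, so the largest distance at which \eqn{\Delta G} stays below
#' the feasibility threshold has the closed form
#' \deqn{D^* = \frac{\theta - RT\ln Q}{n F E}}
#' (clipped below at 0). When the conductor is lossless (`loss_V_per_mm =
#' 0`) and the cell is exergonic beyond the threshold, the distance is
#' unbounded and `Inf` is returned.
#'
#' @inheritParams concentration_delta_g
#' @return Distance in millimetres; `0` when even a point-contact cell
#'   fails the threshold, `Inf` when unbounded.
#' @examples
#' max_feasible_distance(preset_couple("oxygen"),
#'                       red = compartment(c(O2 = 1e-9), pH = 7),
#'                       ox  = compartment(c(O2 = 3e-4), pH = 7))
#' @export
max_feasible_distance <- function(couple, red, ox, params = emcc_params()) {
  conc_dg <- concentration_delta_g(couple,
                                   .floor_compartment(red, params),
                                   .floor_compartment(ox, params),
                                   params)
  thr <- params$energy_threshold_J_per_mol
  if (conc_dg >= thr) return(0)
  if (params$loss_V_per_mm == 0) return(Inf)
  (thr - conc_dg) /
    (couple$n_electrons * params$faraday_constant * params$loss_V_per_mm)
}

#' Free-energy gain per order of magnitude of concentration
#'
#' Each tenfold change of a single quotient species moves \eqn{RT\ln Q} by
#' \eqn{RT\ln 10} per unit stoichiometric exponent: about 5.6 kJ/mol at
#' 293 K. This is the sensitivity of the model to the choice of minimum
#' ("zero") concentration.
#'
#' @param params An [emcc_params()].
#' @param n_decades Number of orders of magnitude (may be fractional).
#' @return Energy in J/mol (positive magnitude).
#' @examples
#' per_decade_sensitivity()          # about 5609 J/mol
#' per_decade_sensitivity(n_decades = 6)
#' @export
per_decade_sensitivity <- function(params = emcc_params(), n_decades = 1) {
  params$gas_constant * params$temperature_K * log(10) * n_decades
}
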