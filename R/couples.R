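#' Define a split redox couple
#'
#' A redox couple describes the balanced half-reaction
#' \eqn{X + n\,H^+ + n\,e^- \rightarrow XH_n} that an electromicrobiological
#' concentration cell runs forward in one compartment and in reverse in the
#' other. `X` is the oxidized form of the substrate and `XHn` the reduced
#' form; `n_electrons` electrons and `n_protons` protons are transferred per
#' formula unit.
#'
#' Two species names carry fixed conventions in all quotient arithmetic:
#' \describe{
#'   \item{`"H2O"`}{activity 1 (the aqueous standard state is absorbed into
#'     the standard potential), so water never needs a concentration.}
#'   \item{`"H+"`}{when the proton itself is the oxidized form (the
#'     \eqn{H^+/H_2} couple), its contribution is carried entirely by the
#'     `n_protons` pH exponent and it is excluded from the `X` term, so it is
#'     not double-counted.}
#' }
#'
#' @param name Short label, e.g. `"O2/H2O"`.
#' @param n_electrons Positive integer, electrons transferred (\eqn{n}).
#' @param n_protons Non-negative integer, protons in the balanced
#'   half-reaction (4 for O2/H2O, 8 for SO4/H2S, 2 for H+/H2).
#' @param standard_potential_V Standard reduction potential \eqn{E^0} in
#'   volts vs. SHE at unit activities. For a concentration cell this cancels
#'   from \eqn{\Delta G}; it only enters the individual half-cell potentials.
#' @param oxidized Name of the oxidized species `X`.
#' @param reduced Name of the reduced species `XHn`.
#' @param oxidized_coef,reduced_coef Stoichiometric coefficients (>= 1).
#' @param water_stoich Non-negative count of water molecules in the balanced
#'   half-reaction (activity fixed at 1; recorded for bookkeeping).
#'
#' @return An object of class `"redox_couple"`.
#' @seealso [preset_couple()] for the oxygen, sulfide and hydrogen couples.
#' @examples
#' redox_couple("O2/H2O", n_electrons = 4, n_protons = 4,
#'              standard_potential_V = 0.818,
#'              oxidized = "O2", reduced = "H2O",
#'              reduced_coef = 2, water_stoich = 2)
#' @export
redox_couple <- function(name, n_electrons, n_protons, standard_potential_V,
                         oxidized, reduced,
                         oxidized_coef = 1L, reduced_coef = 1L,
                         water_stoich = 0L) {
  stopifnot(is.character(name), length(name) == 1L)
  n_electrons <- as.integer(n_electrons)
  n_protons <- as.integer(n_protons)
  if (is.na(n_electrons) || n_electrons < 1L)
    stop("'n_electrons' must be a positive integer", call. = FALSE)
  if (is.na(n_protons) || n_protons < 0L)
    stop("'n_protons' must be a non-negative integer", call. = FALSE)
  if (!is.finite(standard_potential_V))
    stop("'standard_potential_V' must be finite", call. = FALSE)
  if (oxidized_coef < 1 || reduced_coef < 1)
    stop("stoichiometric coefficients must be >= 1", call. = FALSE)
  if (water_stoich < 0)
    stop("'water_stoich' must be non-negative", call. = FALSE)
  structure(
    list(name = name,
         n_electrons = n_electrons,
         n_protons = n_protons,
         standard_potential_V = as.numeric(standard_potential_V),
         oxidized = as.character(oxidized),
         reduced = as.character(reduced),
         oxidized_coef = as.numeric(oxidized_coef),
         reduced_coef = as.numeric(reduced_coef),
         water_stoich = as.integer(water_stoich)),
    class = "redox_couple")
}

#' @export
print.redox_couple <- function(x, ...) {
  cat(sprintf("Redox couple: %s\n", x$name))
  cat(sprintf("  %g %s + %d H+ + %d e-  ->  %g %s\n",
              x$oxidized_coef, x$oxidized, x$n_protons, x$n_electrons,
              x$reduced_coef, x$reduced))
  cat(sprintf("  E0 = %.3f V vs. SHE\n", x$standard_potential_V))
  invisible(x)
}

#' Built-in redox couples
#'
#' The three couples examined in detail by the model: oxygen reduction
#' coupled to water splitting (`"oxygen"`), sulfate reduction coupled to
#' sulfide oxidation (`"sulfide"`), and proton reduction coupled to hydrogen
#' oxidation (`"hydrogen"`).
#'
#' The sulfate/sulfide standard potential (0.301 V) is a standard-table
#' value; it cancels from every concentration-cell quantity and is recorded
#' only so half-cell potentials are individually reportable.
#'
#' @param name One of `"oxygen"`, `"sulfide"`, `"hydrogen"`.
#' @return A [redox_couple()].
#' @examples
#' preset_couple("oxygen")
#' @export
preset_couple <- function(name = c("oxygen", "sulfide", "hydrogen")) {
  name <- match.arg(name)
  switch(name,
    oxygen = redox_couple("O2/H2O", n_electrons = 4L, n_protons = 4L,
                          standard_potential_V = 0.818,
                          oxidized = "O2", reduced = "H2O",
                          reduced_coef = 2, water_stoich = 2L),
    sulfide = redox_couple("SO4/H2S", n_electrons = 8L, n_protons = 8L,
                           standard_potential_V = 0.301,
                           oxidized = "SO4", reduced = "H2S",
                           water_stoich = 4L),
    hydrogen = redox_couple("H+/H2", n_electrons = 2L, n_protons = 2L,
                            standard_potential_V = 0,
                            oxidized = "H+", reduced = "H2"))
}
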