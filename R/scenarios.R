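## Theoretical gradient scenarios: a single species varying linearly with
## depth, all other species held constant (they cancel from the quotient),
## and dG computed between the reference point and every grid depth.

#' Specify a theoretical gradient scenario
#'
#' Describes a one-dimensional gradient of a single chemical species: linear
#' from its maximum to its minimum concentration across a penetration depth,
#' constant beyond it, with constant pH. One half of the reaction is pinned
#' at the reference depth and \eqn{\Delta G} is computed for cells
#' electrically connected from there to each depth.
#'
#' `orientation` fixes the profile shape and which end hosts which
#' half-reaction:
#' \describe{
#'   \item{`"consumed_at_reference"`}{the species is consumed at the
#'     reference (oxygen drawn down from the sediment surface): maximum
#'     concentration at the reference, declining to the minimum at the
#'     penetration depth.}
#'   \item{`"produced_at_reference"`}{a source at the reference (hydrogen
#'     seeping from a production surface): same declining shape, but the
#'     species is the electron donor, so the reducing end is the reference.}
#'   \item{`"produced_at_depth"`}{production at depth (sulfide rising from
#'     below): minimum at the reference, rising to the maximum at the
#'     penetration depth.}
#' }
#'
#' @param couple A [redox_couple()].
#' @param gradient_species Name of the single species that varies; must be
#'   the couple's oxidized or reduced species.
#' @param orientation See Details.
#' @param penetration_depth_mm Depth (mm) over which the species goes from
#'   maximum to minimum concentration (or vice versa).
#' @param c_max_M,c_min_M Maximum and minimum concentration (mol/L);
#'   `c_min_M` defaults to the 1 nM concentration floor.
#' @param constant_pH pH assumed throughout (default 7).
#' @param depth_step_mm Grid resolution (default 0.01 mm).
#' @param max_depth_mm Deepest grid point; defaults to 4x the penetration
#'   depth so the linear loss-dominated tail is visible.
#' @param reference_depth_mm Depth of the single-point half-reaction
#'   (default 0).
#' @return An object of class `"scenario_spec"`.
#' @seealso [preset_scenario()] for the oxygen, sulfide and hydrogen
#'   scenarios; [delta_g_vs_distance()].
#' @export
scenario_spec <- function(couple, gradient_species,
                          orientation = c("consumed_at_reference",
                                          "produced_at_reference",
                                          "produced_at_depth"),
                          penetration_depth_mm,
                          c_max_M,
                          c_min_M = 1e-9,
                          constant_pH = 7,
                          depth_step_mm = 0.01,
                          max_depth_mm = 4 * penetration_depth_mm,
                          reference_depth_mm = 0) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(couple, "redox_couple"))
  if (!gradient_species %in% c(couple$oxidized, couple$reduced))
    stop(sprintf("'%s' is not a species of couple %s",
                 gradient_species, couple$name), call. = FALSE)
  if (!(c_max_M > c_min_M && c_min_M > 0))
    stop("need c_max_M > c_min_M > 0", call. = FALSE)
  if (penetration_depth_mm <= 0)
    stop("'penetration_depth_mm' must be positive", call. = FALSE)
  if (depth_step_mm <= 0)
    stop("'depth_step_mm' must be positive", call. = FALSE)
  if (max_depth_mm < penetration_depth_mm)
    stop("'max_depth_mm' must be >= the penetration depth", call. = FALSE)
  structure(
    list(couple = couple, gradient_species = gradient_species,
         orientation = orientation,
         penetration_depth_mm = penetration_depth_mm,
         c_max_M = c_max_M, c_min_M = c_min_M,
         constant_pH = constant_pH,
         depth_step_mm = depth_step_mm, max_depth_mm = max_depth_mm,
         reference_depth_mm = reference_depth_mm),
    class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("EMCC gradient scenario: %s varying, couple %s\n",
              x$gradient_species, x$couple$name))
  cat(sprintf("  orientation: %s\n", x$orientation))
  cat(sprintf("  %g M to %g M over %g mm (grid 0..%g mm by %g mm)\n",
              x$c_max_M, x$c_min_M, x$penetration_depth_mm,
              x$max_depth_mm, x$depth_step_mm))
  cat(sprintf("  constant pH %g, reference at %g mm\n",
              x$constant_pH, x$reference_depth_mm))
  invisible(x)
}

## concentration of the gradient species at depth d (vectorized, exact)
.scenario_conc <- function(spec, d) {
  pen <- spec$penetration_depth_mm
  frac <- pmin(pmax(d / pen, 0), 1)
  rising <- spec$orientation == "produced_at_depth"
  conc <- if (rising)
    spec$c_min_M + (spec$c_max_M - spec$c_min_M) * frac
  else
    spec$c_max_M + (spec$c_min_M - spec$c_max_M) * frac
  ## pin the endpoints so the plateaus are exact despite the cancellation
  conc[frac >= 1] <- if (rising) spec$c_max_M else spec$c_min_M
  conc[frac <= 0] <- if (rising) spec$c_min_M else spec$c_max_M
  conc
}

#' Linear concentration profile of a scenario
#'
#' Evaluates the scenario's piecewise-linear concentration profile on its
#' depth grid: linear between the maximum and minimum concentration across
#' the penetration depth, constant beyond it. All values are at least
#' `c_min_M`.
#'
#' @param spec A [scenario_spec()].
#' @return A data frame with columns `depth_mm` and `conc_M`.
#' @examples
#' head(build_linear_profile(preset_scenario("oxygen")))
#' @export
build_linear_profile <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  depths <- seq(0, spec$max_depth_mm, by = spec$depth_step_mm)
  data.frame(depth_mm = depths, conc_M = .scenario_conc(spec, depths))
}

#' Free energy versus conductor length for a scenario
#'
#' For each grid depth `d`, forms two compartments from the gradient
#' species' concentrations at the reference depth and at `d` (constant pH,
#' all other species equal and cancelling), sets the conductor length to
#' `|d - reference|`, and evaluates [emcc_delta_g()]. The curve is 0 at the
#' reference, curved inside the gradient zone (concave when the species is
#' consumed at the reference, convex when produced at depth) and exactly
#' linear with slope \eqn{nFE} once the concentration is constant.
#'
#' @param spec A [scenario_spec()].
#' @param params An [emcc_params()].
#' @return A `"delta_g_profile"` object: a data frame with columns
#'   `depth_mm`, `conc_M`, `pH`, `delta_g_J_per_mol`, `feasible`, carrying
#'   the feasibility windows, the minimum and the generating context as
#'   attributes. See [feasible_window()] and [summary.delta_g_profile()].
#' @examples
#' prof <- delta_g_vs_distance(preset_scenario("oxygen"))
#' summary(prof)
#' @export
delta_g_vs_distance <- function(spec, params = emcc_params()) {
  stopifnot(inherits(spec, "scenario_spec"))
  grid <- build_linear_profile(spec)
  species <- spec$gradient_species
  ## non-gradient couple species are held equal in both compartments
  ## ("only alter the value of a single chemical species") and so cancel
  ## from Q; unit activity is used as the common value
  other <- setdiff(c(spec$couple$oxidized, spec$couple$reduced),
                   c(species, "H2O", "H+"))
  make_comp <- function(conc) {
    v <- c(conc, rep(1, length(other)))
    names(v) <- c(species, other)
    compartment(v, pH = spec$constant_pH)
  }
  c_ref <- max(.scenario_conc(spec, spec$reference_depth_mm),
               params$concentration_floor_M)
  ref_comp <- make_comp(c_ref)
  acceptor <- species == spec$couple$oxidized
  dg <- vapply(seq_len(nrow(grid)), function(i) {
    cd <- max(grid$conc_M[i], params$concentration_floor_M)
    d_comp <- make_comp(cd)
    ## reducing end: where the acceptor is scarce, or the donor abundant
    red_is_d <- if (acceptor) cd <= c_ref else cd > c_ref
    emcc_delta_g(spec$couple,
                 red = if (red_is_d) d_comp else ref_comp,
                 ox = if (red_is_d) ref_comp else d_comp,
                 distance_mm = abs(grid$depth_mm[i] - spec$reference_depth_mm),
                 params = params)$delta_g_J_per_mol
  }, numeric(1))
  .new_delta_g_profile(
    data.frame(depth_mm = grid$depth_mm, conc_M = grid$conc_M,
               pH = spec$constant_pH, delta_g_J_per_mol = dg,
               feasible = dg < params$energy_threshold_J_per_mol),
    couple = spec$couple, params = params,
    reference_depth_mm = spec$reference_depth_mm,
    source = sprintf("scenario:%s", species))
}

#' Built-in gradient scenarios
#'
#' The three scenarios examined by the model, with penetration depths and
#' maximum concentrations taken from observed literature values:
#' \describe{
#'   \item{`"oxygen"`}{O2/H2O couple (n = 4, 4 H+, E0 = 0.818 V); O2
#'     penetration 0.5 mm, maximum 300 uM, consumed at the reference.}
#'   \item{`"sulfide"`}{SO4/H2S couple (n = 8, 8 H+); most sulfide removed
#'     within the upper 7 mm, maximum 2 mM, produced at depth.}
#'   \item{`"hydrogen"`}{H+/H2 couple (n = 2, 2 H+, E0 = 0 V); H2 consumed
#'     within 1 mm of its production surface, maximum 2.5 uM.}
#' }
#' All use a 1 nM minimum concentration and constant pH 7.
#'
#' @param name One of `"oxygen"`, `"sulfide"`, `"hydrogen"`.
#' @param ... Overrides passed on to [scenario_spec()] (e.g.
#'   `penetration_depth_mm`, `depth_step_mm`).
#' @return A [scenario_spec()].
#' @examples
#' preset_scenario("sulfide")
#' @export
preset_scenario <- function(name, ...) {
  valid <- c("oxygen", "sulfide", "hydrogen")
  if (length(name) != 1L || !name %in% valid)
    stop(sprintf("unknown scenario '%s'; valid presets: %s",
                 paste(name, collapse = ","),
                 paste(valid, collapse = ", ")), call. = FALSE)
  base <- switch(name,
    oxygen = list(couple = preset_couple("oxygen"),
                  gradient_species = "O2",
                  orientation = "consumed_at_reference",
                  penetration_depth_mm = 0.5, c_max_M = 3e-4),
    sulfide = list(couple = preset_couple("sulfide"),
                   gradient_species = "H2S",
                   orientation = "produced_at_depth",
                   penetration_depth_mm = 7, c_max_M = 2e-3),
    hydrogen = list(couple = preset_couple("hydrogen"),
                    gradient_species = "H2",
                    orientation = "produced_at_reference",
                    penetration_depth_mm = 1, c_max_M = 2.5e-6))
  args <- utils::modifyList(base, list(...))
  do.call(scenario_spec, args)
}

#' Feasibility envelope over electron number and concentration span
#'
#' Sweeps a grid of electron numbers and concentration spans (in decades
#' above the concentration floor) through a 1 mm linear gradient and
#' reports, for each combination, the minimum free energy along the curve
#' and the longest conductor that stays below the feasibility threshold.
#' Larger spans lower the minimum linearly (about \eqn{RT\ln 10} = 5.6
#' kJ/mol per decade at 293 K); more electrons steepen the loss term, so
#' the maximum distance scales as \eqn{1/n}.
#'
#' @param n_electrons_list Positive integers.
#' @param decades_list Concentration spans in orders of magnitude (>= 1).
#' @param params An [emcc_params()].
#' @param gradient_mm Width of the gradient zone (default 1 mm).
#' @return A data frame with one row per combination: `n_electrons`,
#'   `decades`, `min_delta_g_J_per_mol`, `min_depth_mm`,
#'   `max_distance_mm`.
#' @examples
#' feasibility_envelope(c(1, 2, 4, 8), c(3, 6))
#' @export
feasibility_envelope <- function(n_electrons_list, decades_list,
                                 params = emcc_params(), gradient_mm = 1) {
  if (!length(n_electrons_list) || !length(decades_list))
    stop("electron and decade lists must be non-empty", call. = FALSE)
  if (any(decades_list < 1))
    stop("'decades_list' entries must be >= 1", call. = FALSE)
  grid <- expand.grid(n_electrons = as.integer(n_electrons_list),
                      decades = as.numeric(decades_list),
                      KEEP.OUT.ATTRS = FALSE)
  floor_m <- params$concentration_floor_M
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    n <- grid$n_electrons[i]
    k <- grid$decades[i]
    cpl <- redox_couple(sprintf("%de-", n), n_electrons = n, n_protons = 0L,
                        standard_potential_V = 0,
                        oxidized = "A", reduced = "AH")
    spec <- scenario_spec(cpl, "A", "consumed_at_reference",
                          penetration_depth_mm = gradient_mm,
                          c_max_M = floor_m * 10^k, c_min_M = floor_m)
    prof <- delta_g_vs_distance(spec, params)
    dstar <- max_feasible_distance(
      cpl,
      red = compartment(c(A = floor_m, AH = 1), pH = spec$constant_pH),
      ox = compartment(c(A = floor_m * 10^k, AH = 1),
                       pH = spec$constant_pH),
      params)
    imin <- which.min(prof$delta_g_J_per_mol)
    data.frame(n_electrons = n, decades = k,
               min_delta_g_J_per_mol = prof$delta_g_J_per_mol[imin],
               min_depth_mm = prof$depth_mm[imin],
               max_distance_mm = dstar)
  })
  do.call(rbind, rows)
}
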