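## Seeded synthetic microprofiles emulating sediment microsensor exports:
## monotone concentration decay or rise with depth, optional Gaussian pH
## excursion, truncated Gaussian sensor noise, and literal-zero readings
## below the detection limit.

## low end of the 2-20 nM detection range of current microsensors; readings
## at or below it become literal 0.0 when zero_below is requested
.DETECTION_LIMIT_UM <- 2e-3

#' Specify a synthetic microprofile
#'
#' Describes one synthetic concentration-plus-pH profile pair. The
#' noiseless `"linear"` shape reproduces the piecewise-linear scenario
#' profile of [build_linear_profile()] exactly; `"exponential_decay"` falls
#' geometrically from `c_max_uM` to the 1 nM floor at the penetration
#' depth; `"sigmoid_rise"` rises from the floor to `c_max_uM` around half
#' the penetration depth (sulfide-style production at depth).
#'
#' Sensor noise is Gaussian, truncated at zero (a microsensor cannot report
#' a physical negative concentration unless electronics drift, which the
#' cleaning floor handles anyway); the pH profile sits on a half-step
#' offset grid, as real pH and concentration sensors rarely sample the same
#' depths.
#'
#' @param species `"O2"`, `"H2S"` or `"H2"`.
#' @param shape `"linear"`, `"exponential_decay"` or `"sigmoid_rise"`.
#' @param penetration_depth_mm Depth over which the concentration completes
#'   its transition.
#' @param c_max_uM Maximum concentration in uM.
#' @param noise_sd_uM Standard deviation of the sensor noise in uM
#'   (default 0 = noiseless).
#' @param depth_step_mm,max_depth_mm Grid resolution and extent.
#' @param ph_baseline Constant pH about which any excursion is applied.
#' @param ph_excursion Optional `list(amplitude =, centre_mm =, width_mm =)`
#'   Gaussian-shaped pH dip (negative amplitude) or peak.
#' @param zero_below Emit literal `0.0` for readings at or below the 2 nM
#'   detection limit (exercises [apply_floor()]).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `"synth_spec"`.
#' @export
synth_spec <- function(species = c("O2", "H2S", "H2"),
                       shape = c("linear", "exponential_decay",
                                 "sigmoid_rise"),
                       penetration_depth_mm = 1.5,
                       c_max_uM = 300,
                       noise_sd_uM = 0,
                       depth_step_mm = 0.05,
                       max_depth_mm = 4 * penetration_depth_mm,
                       ph_baseline = 7,
                       ph_excursion = NULL,
                       zero_below = FALSE,
                       seed = 1L) {
  species <- match.arg(species)
  shape <- match.arg(shape)
  if (penetration_depth_mm <= 0 || penetration_depth_mm > max_depth_mm)
    stop("need 0 < penetration_depth_mm <= max_depth_mm", call. = FALSE)
  if (noise_sd_uM < 0) stop("'noise_sd_uM' must be >= 0", call. = FALSE)
  if (depth_step_mm <= 0) stop("'depth_step_mm' must be > 0", call. = FALSE)
  if (!is.null(ph_excursion) &&
      !all(c("amplitude", "centre_mm", "width_mm") %in% names(ph_excursion)))
    stop("'ph_excursion' needs amplitude, centre_mm and width_mm",
         call. = FALSE)
  structure(
    list(species = species, shape = shape,
         penetration_depth_mm = penetration_depth_mm,
         c_max_uM = c_max_uM, noise_sd_uM = noise_sd_uM,
         depth_step_mm = depth_step_mm, max_depth_mm = max_depth_mm,
         ph_baseline = ph_baseline, ph_excursion = ph_excursion,
         zero_below = isTRUE(zero_below), seed = as.integer(seed)),
    class = "synth_spec")
}

## evaluate the noiseless concentration curve (uM) at depths d (mm)
.synth_curve <- function(spec, d) {
  pen <- spec$penetration_depth_mm
  c_min <- 1e-3  # 1 nM floor, uM
  switch(spec$shape,
    linear = {
      frac <- pmin(pmax(d / pen, 0), 1)
      v <- spec$c_max_uM + (c_min - spec$c_max_uM) * frac
      v[frac >= 1] <- c_min  # exact plateau, matching the scenario profile
      v[frac <= 0] <- spec$c_max_uM
      v
    },
    exponential_decay =
      pmax(spec$c_max_uM * (c_min / spec$c_max_uM)^(d / pen), c_min),
    sigmoid_rise = {
      ## logistic normalized to hit c_min at 0 and c_max at the
      ## penetration depth exactly, constant beyond
      s <- function(z) 1 / (1 + exp(-10 * (z - 0.5)))
      frac <- pmin(pmax(d / pen, 0), 1)
      c_min + (spec$c_max_uM - c_min) * (s(frac) - s(0)) / (s(1) - s(0))
    })
}

## run expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic concentration/pH microprofile pair
#'
#' Deterministic given the spec's seed. Noise is Gaussian with standard
#' deviation `noise_sd_uM`, truncated at zero; with `zero_below = TRUE`,
#' noiseless curve values at or below the 2 nM detection limit are emitted
#' as literal `0.0` readings. The pH table is produced on a grid offset by
#' half a depth step, so the pair exercises [align_profiles()].
#'
#' @param spec A [synth_spec()].
#' @return A list with elements `conc` and `ph`, both [microprofile()]s.
#' @examples
#' p <- generate_profile(synth_spec("O2", "linear", noise_sd_uM = 1))
#' p$conc
#' @export
generate_profile <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  depths <- seq(0, spec$max_depth_mm, by = spec$depth_step_mm)
  truth <- .synth_curve(spec, depths)
  ph_depths <- seq(spec$depth_step_mm / 2, spec$max_depth_mm,
                   by = spec$depth_step_mm)
  ph_truth <- rep(spec$ph_baseline, length(ph_depths))
  if (!is.null(spec$ph_excursion)) {
    e <- spec$ph_excursion
    ph_truth <- ph_truth + e$amplitude *
      exp(-((ph_depths - e$centre_mm)^2) / (2 * e$width_mm^2))
  }
  .with_seed(spec$seed, {
    conc <- truth
    ph <- ph_truth
    if (spec$noise_sd_uM > 0) {
      conc <- pmax(conc + stats::rnorm(length(conc), 0, spec$noise_sd_uM), 0)
      ph <- ph + stats::rnorm(length(ph), 0, 0.01)
    }
    if (spec$zero_below)
      conc[truth <= .DETECTION_LIMIT_UM] <- 0
    site <- sprintf("synthetic %s profile (%s, seed %d)",
                    spec$species, spec$shape, spec$seed)
    list(conc = microprofile(depths, conc, kind = "concentration_uM",
                             species = spec$species, site = site),
         ph = microprofile(ph_depths, ph, kind = "pH", site = site))
  })
}

#' Write a battery of synthetic fixture files
#'
#' Writes a small set of canonical-format profile files covering the
#' cleaning rules the package implements: a clean concentration/pH pair, a
#' profile with literal zero readings below detection, a deep profile whose
#' tail hovers at a small non-zero offset (calling for
#' [plateau_override()]), and a pH profile missing its deepest reading
#' (calling for [fill_missing_ph()]). A `manifest.csv` lists every file
#' with its generating spec. Re-running with the same seed reproduces the
#' files byte for byte.
#'
#' @param directory Output directory (created if needed).
#' @param seed Base integer seed; each fixture derives its own from it.
#' @return The manifest as a data frame, invisibly; also written to
#'   `manifest.csv`.
#' @export
write_fixture_set <- function(directory, seed = 1L) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  specs <- list(
    o2_clean = synth_spec("O2", "linear", penetration_depth_mm = 1.5,
                          c_max_uM = 300, noise_sd_uM = 0.5,
                          seed = seed),
    o2_zeros = synth_spec("O2", "linear", penetration_depth_mm = 1,
                          c_max_uM = 300, zero_below = TRUE,
                          seed = seed + 1L),
    deep_plateau = synth_spec("O2", "exponential_decay",
                              penetration_depth_mm = 27, c_max_uM = 250,
                              noise_sd_uM = 0.7, depth_step_mm = 0.5,
                              max_depth_mm = 40, seed = seed + 2L),
    ph_gap = synth_spec("O2", "linear", penetration_depth_mm = 2,
                        c_max_uM = 150, noise_sd_uM = 0.3,
                        ph_excursion = list(amplitude = -0.4,
                                            centre_mm = 1, width_mm = 0.5),
                        seed = seed + 3L))
  rows <- list()
  add <- function(file, spec, kind, note) {
    rows[[length(rows) + 1L]] <<- data.frame(
      file = file, species = spec$species, kind = kind, shape = spec$shape,
      penetration_depth_mm = spec$penetration_depth_mm,
      c_max_uM = spec$c_max_uM, noise_sd_uM = spec$noise_sd_uM,
      seed = spec$seed, note = note)
  }
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    pair <- generate_profile(spec)
    if (nm == "ph_gap") {
      ## drop the deepest pH reading to emulate a truncated cast
      pair$ph$value[nrow(pair$ph)] <- NA
    }
    conc_file <- file.path(directory, paste0(nm, "_conc.csv"))
    ph_file <- file.path(directory, paste0(nm, "_ph.csv"))
    write_microprofile(pair$conc, conc_file)
    write_microprofile(pair$ph, ph_file)
    note <- switch(nm,
      o2_clean = "clean pair",
      o2_zeros = "literal 0 readings below detection",
      deep_plateau = "non-zero tail; plateau override applies",
      ph_gap = "deepest pH reading missing")
    add(basename(conc_file), spec, "concentration_uM", note)
    add(basename(ph_file), spec, "pH", note)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
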