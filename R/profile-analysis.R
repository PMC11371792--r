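## Turning a cleaned, aligned depth profile into a dG-vs-depth feasibility
## assessment: one half-reaction pinned at the reference depth, the other at
## each measured depth, with measured pH at both ends.

.new_delta_g_profile <- function(df, couple, params, reference_depth_mm,
                                 source = "") {
  thr <- params$energy_threshold_J_per_mol
  win <- .windows_from_flags(df$depth_mm, df$delta_g_J_per_mol < thr)
  imin <- which.min(df$delta_g_J_per_mol)
  structure(df,
            couple = couple, params = params,
            reference_depth_mm = reference_depth_mm,
            threshold_J_per_mol = thr,
            feasible_window_mm = win,
            min_delta_g_J_per_mol = df$delta_g_J_per_mol[imin],
            min_delta_g_depth_mm = df$depth_mm[imin],
            source = source,
            class = c("delta_g_profile", "data.frame"))
}

## maximal contiguous runs of TRUE, as depth intervals
.windows_from_flags <- function(depth, flag) {
  if (!any(flag))
    return(data.frame(from_mm = numeric(), to_mm = numeric()))
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(from_mm = depth[starts[keep]], to_mm = depth[ends[keep]])
}

#' Free energy versus depth for a measured profile
#'
#' For each depth `d` in an aligned profile, forms two compartments from
#' the gradient species' concentration and the measured pH at the reference
#' depth and at `d`, with the conductor length `|d - reference|`, and
#' evaluates [emcc_delta_g()]. The reducing and oxidizing ends are assigned
#' so the high-concentration end of the gradient species drives the forward
#' reaction: for an electron acceptor (O2) the oxidizing end is where its
#' concentration is high; for a donor (H2S, H2) the reducing end is. The
#' assignment is made once from the profile's overall gradient direction
#' and can be forced with `reference_is_oxidizing`.
#'
#' Couple species absent from the profile (e.g. sulfate against a measured
#' sulfide profile) are held at equal unit activity in both compartments
#' and cancel from the quotient.
#'
#' @param profile An `"aligned_profile"` from [align_profiles()] (columns
#'   `depth_mm`, `conc_uM`, `pH`).
#' @param couple A [redox_couple()]; the profile's species must be its
#'   oxidized or reduced form.
#' @param params An [emcc_params()].
#' @param reference_depth_mm Depth of the single-point half-reaction; must
#'   lie on the profile's grid.
#' @param reference_is_oxidizing Optional logical overriding the automatic
#'   end assignment.
#' @return A `"delta_g_profile"` object (see [delta_g_vs_distance()]).
#' @examples
#' conc <- microprofile(c(0, 1, 2), c(300, 10, 0.001), species = "O2")
#' ph <- microprofile(c(0, 2), c(7.2, 7.6), kind = "pH")
#' prof <- profile_delta_g(align_profiles(conc, ph), preset_couple("oxygen"))
#' summary(prof)
#' @export
profile_delta_g <- function(profile, couple, params = emcc_params(),
                            reference_depth_mm = 0,
                            reference_is_oxidizing = NULL) {
  stopifnot(inherits(profile, "aligned_profile"),
            inherits(couple, "redox_couple"))
  species <- attr(profile, "species")
  if (!species %in% c(couple$oxidized, couple$reduced))
    stop(sprintf("profile species '%s' is not part of couple %s",
                 species, couple$name), call. = FALSE)
  iref <- match(TRUE, abs(profile$depth_mm - reference_depth_mm) < 1e-9)
  if (is.na(iref)) {
    nearest <- profile$depth_mm[which.min(abs(profile$depth_mm -
                                                reference_depth_mm))]
    stop(sprintf("reference depth %g mm is not on the grid; nearest grid point is %g mm",
                 reference_depth_mm, nearest), call. = FALSE)
  }
  other <- setdiff(c(couple$oxidized, couple$reduced),
                   c(species, "H2O", "H+"))
  make_comp <- function(conc_uM, pH) {
    v <- c(max(conc_uM * 1e-6, params$concentration_floor_M),
           rep(1, length(other)))
    names(v) <- c(species, other)
    compartment(v, pH = pH)
  }
  if (is.null(reference_is_oxidizing)) {
    ## overall gradient direction: compare the reference to the far end
    ifar <- if (iref <= nrow(profile) / 2) nrow(profile) else 1L
    high_at_ref <- profile$conc_uM[iref] >= profile$conc_uM[ifar]
    acceptor <- species == couple$oxidized
    reference_is_oxidizing <- if (acceptor) high_at_ref else !high_at_ref
  }
  ref_comp <- make_comp(profile$conc_uM[iref], profile$pH[iref])
  dg <- vapply(seq_len(nrow(profile)), function(i) {
    d_comp <- make_comp(profile$conc_uM[i], profile$pH[i])
    emcc_delta_g(couple,
                 red = if (reference_is_oxidizing) d_comp else ref_comp,
                 ox = if (reference_is_oxidizing) ref_comp else d_comp,
                 distance_mm = abs(profile$depth_mm[i] - reference_depth_mm),
                 params = params)$delta_g_J_per_mol
  }, numeric(1))
  .new_delta_g_profile(
    data.frame(depth_mm = profile$depth_mm,
               conc_uM = profile$conc_uM, pH = profile$pH,
               delta_g_J_per_mol = dg,
               feasible = dg < params$energy_threshold_J_per_mol),
    couple = couple, params = params,
    reference_depth_mm = reference_depth_mm,
    source = sprintf("profile:%s%s", species,
                     if (nzchar(attr(profile, "site") %||% ""))
                       paste0("@", attr(profile, "site")) else ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Depth intervals where the cell clears the energy threshold
#'
#' Maximal contiguous grid intervals on which \eqn{\Delta G} is below the
#' feasibility threshold.
#'
#' @param profile A `"delta_g_profile"`.
#' @param threshold_J_per_mol Threshold in J/mol; defaults to the one the
#'   profile was computed with.
#' @return A data frame with columns `from_mm`, `to_mm` (zero rows when no
#'   depth is feasible).
#' @export
feasible_window <- function(profile,
                            threshold_J_per_mol =
                              attr(profile, "threshold_J_per_mol")) {
  stopifnot(inherits(profile, "delta_g_profile"))
  .windows_from_flags(profile$depth_mm,
                      profile$delta_g_J_per_mol < threshold_J_per_mol)
}

#' @export
print.delta_g_profile <- function(x, ...) {
  cat(sprintf("EMCC free-energy profile (%s), %d depths, reference %g mm\n",
              attr(x, "couple")$name, nrow(x),
              attr(x, "reference_depth_mm")))
  cat(sprintf("  min delta G: %.1f kJ/mol at %g mm; %d feasible window(s)\n",
              attr(x, "min_delta_g_J_per_mol") / 1000,
              attr(x, "min_delta_g_depth_mm"),
              nrow(attr(x, "feasible_window_mm"))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Summarize a free-energy profile
#'
#' Reports the minimum free energy (kJ/mol) and its depth, the feasible
#' windows and their total extent, and -- as a closed-form cross-check --
#' the longest conductor the profile's most favourable compartment pair
#' could power ([max_feasible_distance()] applied to the depth with the
#' strongest concentration term).
#'
#' @param object A `"delta_g_profile"`.
#' @param ... Unused.
#' @return A list of class `"summary.delta_g_profile"` with fields
#'   `min_delta_g_kJ_per_mol`, `min_depth_mm`, `feasible_window_mm`,
#'   `feasible_extent_mm`, `max_feasible_distance_mm`, `threshold_kJ_per_mol`.
#' @export
summary.delta_g_profile <- function(object, ...) {
  params <- attr(object, "params")
  couple <- attr(object, "couple")
  win <- attr(object, "feasible_window_mm")
  n <- couple$n_electrons
  f <- params$faraday_constant
  dist <- abs(object$depth_mm - attr(object, "reference_depth_mm"))
  conc_term <- object$delta_g_J_per_mol - n * f * params$loss_V_per_mm * dist
  best <- min(conc_term)
  thr <- attr(object, "threshold_J_per_mol")
  dstar <- if (best >= thr) 0
           else if (params$loss_V_per_mm == 0) Inf
           else (thr - best) / (n * f * params$loss_V_per_mm)
  structure(
    list(source = attr(object, "source"),
         couple = couple$name,
         min_delta_g_kJ_per_mol = round(
           attr(object, "min_delta_g_J_per_mol") / 1000, 1),
         min_depth_mm = attr(object, "min_delta_g_depth_mm"),
         feasible_window_mm = win,
         feasible_extent_mm = sum(win$to_mm - win$from_mm),
         max_feasible_distance_mm = dstar,
         threshold_kJ_per_mol = thr / 1000),
    class = "summary.delta_g_profile")
}

#' @export
print.summary.delta_g_profile <- function(x, ...) {
  cat(sprintf("EMCC profile summary (%s; %s)\n", x$couple, x$source))
  cat(sprintf("  min delta G:        %.1f kJ/mol at %g mm\n",
              x$min_delta_g_kJ_per_mol, x$min_depth_mm))
  cat(sprintf("  threshold:          %.1f kJ/mol\n", x$threshold_kJ_per_mol))
  if (nrow(x$feasible_window_mm)) {
    iv <- apply(x$feasible_window_mm, 1, function(r)
      sprintf("[%g, %g]", r[[1]], r[[2]]))
    cat(sprintf("  feasible windows:   %s mm (total %g mm)\n",
                paste(iv, collapse = ", "), x$feasible_extent_mm))
  } else {
    cat("  feasible windows:   none\n")
  }
  cat(sprintf("  closed-form bound:  %.2f mm max conductor\n",
              x$max_feasible_distance_mm))
  invisible(x)
}

#' @export
plot.delta_g_profile <- function(x, ...) {
  kj <- x$delta_g_J_per_mol / 1000
  thr <- attr(x, "threshold_J_per_mol") / 1000
  graphics::plot(x$depth_mm, kj, type = "l",
                 xlab = "depth (mm)",
                 ylab = expression(Delta * G ~ "(kJ/mol)"),
                 main = sprintf("EMCC free energy (%s)",
                                attr(x, "couple")$name), ...)
  graphics::abline(h = thr, lty = 2, col = "red3")
  graphics::abline(h = 0, lty = 3, col = "grey40")
  win <- attr(x, "feasible_window_mm")
  if (nrow(win)) {
    usr <- graphics::par("usr")
    graphics::rect(win$from_mm, usr[3], win$to_mm, thr,
                   col = grDevices::adjustcolor("steelblue", 0.15),
                   border = NA)
  }
  invisible(x)
}

#' Export a free-energy profile as delimited text
#'
#' Writes the per-depth table (`depth_mm`, the concentration column, `pH`,
#' `delta_g_kJ_per_mol`, `feasible`) and, optionally, a key-value summary
#' file next to it.
#'
#' @param x A `"delta_g_profile"`.
#' @param path Output path for the table (comma-delimited).
#' @param summary_path Optional path for a `key: value` summary file.
#' @return `path`, invisibly.
#' @export
write_delta_g_profile <- function(x, path, summary_path = NULL) {
  stopifnot(inherits(x, "delta_g_profile"))
  df <- as.data.frame(x)
  df$delta_g_kJ_per_mol <- df$delta_g_J_per_mol / 1000
  df$delta_g_J_per_mol <- NULL
  df <- df[c(setdiff(names(df), c("delta_g_kJ_per_mol", "feasible")),
             "delta_g_kJ_per_mol", "feasible")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(summary_path)) {
    s <- summary(x)
    win <- if (nrow(s$feasible_window_mm))
      paste(sprintf("[%g,%g]", s$feasible_window_mm$from_mm,
                    s$feasible_window_mm$to_mm), collapse = " ")
      else "none"
    writeLines(c(
      sprintf("couple: %s", s$couple),
      sprintf("source: %s", s$source),
      sprintf("min_delta_g_kJ_per_mol: %.1f", s$min_delta_g_kJ_per_mol),
      sprintf("min_depth_mm: %g", s$min_depth_mm),
      sprintf("feasible_windows_mm: %s", win),
      sprintf("feasible_extent_mm: %g", s$feasible_extent_mm),
      sprintf("max_feasible_distance_mm: %g", s$max_feasible_distance_mm),
      sprintf("threshold_kJ_per_mol: %g", s$threshold_kJ_per_mol)),
      summary_path)
  }
  invisible(path)
}
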