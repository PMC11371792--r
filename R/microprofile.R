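## Reading and cleaning sediment microsensor depth profiles. The canonical
## dialect is UTF-8 comma- or tab-delimited text with a header row, "#"
## comment lines, decimal points, and columns depth_mm + <species>_uM or pH.
## Canonical internal units are mm (depth, positive downward) and uM
## (concentration).

#' Construct a microprofile table
#'
#' A depth-indexed series of one measured quantity: either a concentration
#' in micromolar or pH. Depths are millimetres, positive downward (0 = the
#' sediment surface, negative = overlying water).
#'
#' @param depth_mm Numeric depths in mm.
#' @param value Measured values (uM for concentrations, pH units for pH);
#'   `NA` marks a missing reading.
#' @param kind `"concentration_uM"` or `"pH"`.
#' @param species Species name for concentration tables (e.g. `"O2"`);
#'   ignored for pH.
#' @param site Free-text site metadata.
#' @return A data frame of class `"microprofile"` with columns `depth_mm`
#'   and `value`, carrying `kind`, `species` and `site` attributes.
#' @export
microprofile <- function(depth_mm, value,
                         kind = c("concentration_uM", "pH"),
                         species = NULL, site = "") {
  kind <- match.arg(kind)
  if (length(depth_mm) != length(value))
    stop("'depth_mm' and 'value' must have the same length", call. = FALSE)
  if (kind == "concentration_uM" && is.null(species))
    stop("concentration tables need a 'species' name", call. = FALSE)
  ord <- order(depth_mm)
  structure(
    data.frame(depth_mm = as.numeric(depth_mm)[ord],
               value = as.numeric(value)[ord]),
    kind = kind, species = species, site = site,
    class = c("microprofile", "data.frame"))
}

## rebuild a microprofile from a plain data frame, keeping x's metadata
.rewrap <- function(df, x) {
  microprofile(df$depth_mm, df$value, kind = attr(x, "kind"),
               species = attr(x, "species"), site = attr(x, "site"))
}

#' @export
print.microprofile <- function(x, ...) {
  kind <- attr(x, "kind")
  lab <- if (kind == "pH") "pH" else
    sprintf("%s concentration (uM)", attr(x, "species"))
  cat(sprintf("Microprofile: %s, %d depths (%g to %g mm)\n",
              lab, nrow(x), min(x$depth_mm), max(x$depth_mm)))
  if (nzchar(attr(x, "site"))) cat(sprintf("  site: %s\n", attr(x, "site")))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat(sprintf("  ... %d more rows\n", nrow(x) - 8))
  invisible(x)
}

.detect_sep <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("'%s' is empty", path), call. = FALSE)
  if (grepl("\t", lines[[1]])) "\t" else ","
}

#' Read a microsensor depth profile from delimited text
#'
#' Parses a comma- or tab-delimited export (header row, optional `#`
#' comment lines) into a [microprofile()] in canonical units (mm, uM).
#' Rows are sorted by depth and duplicate depths collapsed by their mean.
#' Column names and units follow the canonical dialect (`depth_mm`,
#' `<species>_uM`, `pH`) but can be remapped for foreign exports via
#' `column_spec`.
#'
#' @param path Path to the file.
#' @param column_spec Optional list remapping foreign columns:
#'   `depth` and `value` (column names), `depth_unit` (`"mm"` or `"cm"`),
#'   `value_unit` (`"uM"`, `"mM"` or `"M"`; ignored for pH).
#' @param kind `"concentration_uM"`, `"pH"`, or `NULL` to infer from the
#'   column names (`*_uM` implies concentration, `pH` implies pH).
#' @param species Species name; inferred from a `<species>_uM` column name
#'   when possible.
#' @param site Site metadata attached to the table.
#' @return A [microprofile()].
#' @export
read_microprofile <- function(path, column_spec = list(), kind = NULL,
                              species = NULL, site = "") {
  if (!file.exists(path))
    stop(sprintf("file '%s' does not exist", path), call. = FALSE)
  sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", na.strings = c("NA", ""),
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!nrow(df)) stop(sprintf("'%s' contains no data rows", path),
                      call. = FALSE)

  depth_col <- column_spec$depth
  if (is.null(depth_col)) {
    depth_col <- grep("^depth", names(df), ignore.case = TRUE, value = TRUE)[1]
    if (is.na(depth_col))
      stop(sprintf("no depth column found in '%s'; name it 'depth_mm' or pass column_spec$depth",
                   path), call. = FALSE)
  }
  depth_unit <- column_spec$depth_unit
  if (is.null(depth_unit))
    depth_unit <- if (grepl("cm", depth_col, ignore.case = TRUE)) "cm" else "mm"
  if (!depth_unit %in% c("mm", "cm"))
    stop(sprintf("unknown depth unit '%s' (use mm or cm)", depth_unit),
         call. = FALSE)

  value_col <- column_spec$value
  if (is.null(value_col)) {
    conc_cols <- grep("_uM$", names(df), value = TRUE)
    value_col <- if (!is.null(kind) && kind == "pH") "pH"
                 else if (length(conc_cols)) conc_cols[[1]]
                 else if ("pH" %in% names(df)) "pH"
                 else NA_character_
    if (is.na(value_col) || !value_col %in% names(df))
      stop(sprintf("no value column found in '%s'; expected '<species>_uM' or 'pH'",
                   path), call. = FALSE)
  }
  if (!value_col %in% names(df))
    stop(sprintf("column '%s' not found in '%s'", value_col, path),
         call. = FALSE)
  if (is.null(kind))
    kind <- if (identical(value_col, "pH") ||
                grepl("ph", value_col, ignore.case = TRUE) &&
                !grepl("_uM$", value_col)) "pH" else "concentration_uM"
  if (is.null(species) && kind == "concentration_uM")
    species <- sub("_uM$", "", value_col)

  depth <- suppressWarnings(as.numeric(df[[depth_col]]))
  value <- suppressWarnings(as.numeric(df[[value_col]]))
  bad <- which(is.na(depth) & !is.na(df[[depth_col]]))
  if (length(bad))
    stop(sprintf("unparseable depth values in '%s' (data row %s)",
                 path, paste(utils::head(bad, 3), collapse = ", ")),
         call. = FALSE)
  if (depth_unit == "cm") depth <- depth * 10

  ## collapse replicate depths by their mean (NA-preserving)
  if (anyDuplicated(depth)) {
    agg <- tapply(value, depth, function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    depth <- as.numeric(names(agg))
    value <- as.numeric(agg)
  }
  conc_unit <- column_spec$value_unit
  if (!is.null(conc_unit) && kind == "concentration_uM") {
    scale <- switch(conc_unit, uM = 1, mM = 1e3, M = 1e6,
                    stop(sprintf("unknown concentration unit '%s' (use uM, mM or M)",
                                 conc_unit), call. = FALSE))
    value <- value * scale
  }
  microprofile(depth, value, kind = kind, species = species, site = site)
}

#' Write a microprofile in the canonical delimited format
#'
#' Writes `depth_mm` plus `<species>_uM` or `pH` columns, preceded by a
#' `#`-comment line carrying the site metadata. Values are printed at full
#' (17 significant digit) precision so a write/read round trip reproduces
#' the table bit for bit.
#'
#' @param x A [microprofile()].
#' @param path Output path.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_microprofile <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "microprofile"))
  value_name <- if (attr(x, "kind") == "pH") "pH"
                else paste0(attr(x, "species"), "_uM")
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  lines <- c(
    if (nzchar(attr(x, "site"))) sprintf("# site: %s", attr(x, "site")),
    paste("depth_mm", value_name, sep = sep),
    paste(fmt(x$depth_mm), fmt(x$value), sep = sep))
  writeLines(lines, path)
  invisible(path)
}

#' Keep only subsurface depths
#'
#' Retains measurements at depths at or below the sediment surface
#' (`depth_mm >= 0` in the downward-positive convention); readings in the
#' overlying water column are dropped. The surface itself is kept because
#' it is the usual reference point of the cell.
#'
#' @param x A [microprofile()].
#' @return The filtered [microprofile()].
#' @export
filter_subsurface <- function(x) {
  stopifnot(inherits(x, "microprofile"))
  out <- x[x$depth_mm >= 0, , drop = FALSE]
  if (!nrow(out))
    stop("no subsurface (depth >= 0 mm) measurements remain; check the depth sign convention",
         call. = FALSE)
  .rewrap(out, x)
}

#' Raise readings to the detection floor
#'
#' Replaces every concentration at or below the floor -- including literal
#' zero readings and negative excursions from sensor noise -- by the floor
#' value, so downstream logarithms stay finite. The default floor of
#' 1e-3 uM (1 nM) sits just below the detection limit of the most
#' sensitive microsensors.
#'
#' @param x A concentration [microprofile()].
#' @param floor_uM Floor in uM (default `1e-3`).
#' @return The floored [microprofile()]; the number of modified rows is
#'   attached as attribute `"n_floored"` and reported with a message.
#' @export
apply_floor <- function(x, floor_uM = 1e-3) {
  stopifnot(inherits(x, "microprofile"))
  if (attr(x, "kind") != "concentration_uM")
    stop("'apply_floor' applies to concentration tables only", call. = FALSE)
  modified <- !is.na(x$value) & x$value < floor_uM
  x$value[modified] <- floor_uM
  out <- .rewrap(x, x)
  attr(out, "n_floored") <- sum(modified)
  if (sum(modified))
    message(sprintf("apply_floor: raised %d reading(s) to %g uM",
                    sum(modified), floor_uM))
  out
}

#' Force a deep plateau to the detection floor
#'
#' Sets every reading at or below `from_depth_mm` to the floor. Used when a
#' sensor never settles to a stable zero at depth (e.g. hovering around
#' 0--2 uM for centimetres below the oxic zone, best read as a technical
#' offset): from the depth where the concentration is consistently at its
#' minimum, the true value is taken to be effectively zero.
#'
#' @param x A concentration [microprofile()].
#' @param from_depth_mm Depth (mm) from which the override applies.
#' @param floor_uM Floor in uM (default `1e-3`).
#' @return The modified [microprofile()] (unchanged, with a warning, when
#'   `from_depth_mm` lies beyond the deepest reading).
#' @export
plateau_override <- function(x, from_depth_mm, floor_uM = 1e-3) {
  stopifnot(inherits(x, "microprofile"))
  if (attr(x, "kind") != "concentration_uM")
    stop("'plateau_override' applies to concentration tables only",
         call. = FALSE)
  if (from_depth_mm > max(x$depth_mm)) {
    warning(sprintf("plateau depth %g mm is beyond the deepest reading (%g mm); nothing to override",
                    from_depth_mm, max(x$depth_mm)))
    return(x)
  }
  hit <- x$depth_mm >= from_depth_mm & !is.na(x$value)
  x$value[hit] <- floor_uM
  .rewrap(x, x)
}

#' Fill gaps in a pH profile
#'
#' Interior gaps (missing readings between measured depths) are linearly
#' interpolated. Edge gaps -- typically a missing deepest measurement --
#' are filled according to `strategy`: `"constant"` substitutes
#' `constant_value` (e.g. assuming a stable downcore trend would have
#' continued), `"extend"` carries the nearest measured value outward.
#'
#' @param x A pH [microprofile()] possibly containing `NA` values.
#' @param strategy `"constant"` or `"extend"`.
#' @param constant_value pH used for edge gaps under `"constant"`.
#' @return The filled [microprofile()] (no `NA` values remain).
#' @export
fill_missing_ph <- function(x, strategy = c("constant", "extend"),
                            constant_value = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(x, "microprofile"))
  if (attr(x, "kind") != "pH")
    stop("'fill_missing_ph' applies to pH tables only", call. = FALSE)
  measured <- !is.na(x$value)
  if (!any(measured))
    stop("no pH measurements to fill from", call. = FALSE)
  if (all(measured)) return(x)
  if (strategy == "constant" && is.null(constant_value))
    stop("strategy 'constant' needs a 'constant_value'", call. = FALSE)
  ## interior gaps: linear interpolation between flanking measurements
  interp <- stats::approx(x$depth_mm[measured], x$value[measured],
                          xout = x$depth_mm, method = "linear",
                          rule = 1)$y
  filled <- ifelse(is.na(x$value), interp, x$value)
  ## edge gaps (outside the measured range)
  edge <- is.na(filled)
  if (any(edge)) {
    filled[edge] <- if (strategy == "constant") constant_value else
      stats::approx(x$depth_mm[measured], x$value[measured],
                    xout = x$depth_mm[edge], method = "constant",
                    rule = 2, f = 0)$y
  }
  x$value <- filled
  .rewrap(x, x)
}

#' Join concentration and pH profiles on one depth grid
#'
#' Microsensors sample concentration and pH at different depths; this
#' interpolates the pH profile linearly onto the concentration table's
#' grid. Depths outside the pH range take the nearest measured pH.
#'
#' @param conc A concentration [microprofile()].
#' @param ph A pH [microprofile()] (gap-free; see [fill_missing_ph()]).
#' @return A data frame of class `"aligned_profile"` with columns
#'   `depth_mm`, `conc_uM`, `pH`, carrying the species and site attributes.
#' @export
align_profiles <- function(conc, ph) {
  stopifnot(inherits(conc, "microprofile"), inherits(ph, "microprofile"))
  if (attr(conc, "kind") != "concentration_uM" || attr(ph, "kind") != "pH")
    stop("'align_profiles' expects a concentration table and a pH table",
         call. = FALSE)
  if (min(ph$depth_mm) > max(conc$depth_mm) ||
      max(ph$depth_mm) < min(conc$depth_mm))
    stop("concentration and pH profiles cover disjoint depth ranges",
         call. = FALSE)
  if (anyNA(ph$value))
    stop("pH profile contains gaps; run fill_missing_ph() first",
         call. = FALSE)
  ph_i <- if (nrow(ph) == 1L) rep(ph$value, nrow(conc)) else
    stats::approx(ph$depth_mm, ph$value, xout = conc$depth_mm,
                  method = "linear", rule = 2)$y
  structure(
    data.frame(depth_mm = conc$depth_mm, conc_uM = conc$value, pH = ph_i),
    species = attr(conc, "species"), site = attr(conc, "site"),
    class = c("aligned_profile", "data.frame"))
}
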