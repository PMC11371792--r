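# Reading, cleaning and aligning microsensor depth profiles.

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("canonical files parse into sorted, unit-correct tables", {
  path <- write_lines_tmp(c("# site: test flume",
                            "depth_mm,O2_uM", "0,300", "1,10", "2,0"))
  tab <- read_microprofile(path)
  expect_s3_class(tab, "microprofile")
  expect_equal(tab$depth_mm, c(0, 1, 2))
  expect_equal(tab$value, c(300, 10, 0))
  expect_identical(attr(tab, "species"), "O2")
  expect_identical(attr(tab, "kind"), "concentration_uM")

  # shuffled rows come back sorted
  shuffled <- write_lines_tmp(c("depth_mm,O2_uM", "2,1", "0,300", "1,10"))
  expect_equal(read_microprofile(shuffled)$depth_mm, c(0, 1, 2))

  # tab-delimited dialect
  tsv <- write_lines_tmp(c("depth_mm\tO2_uM", "0\t300", "1\t10"))
  expect_equal(read_microprofile(tsv)$value, c(300, 10))

  # duplicate depths collapse by mean
  dup <- write_lines_tmp(c("depth_mm,O2_uM", "1,10", "1,20", "0,300"))
  tab <- read_microprofile(dup)
  expect_equal(tab$depth_mm, c(0, 1))
  expect_equal(tab$value, c(300, 15))
})

test_that("foreign columns and units are remapped into mm and uM", {
  path <- write_lines_tmp(c("depth_cm,oxygen", "0.0,0.3", "0.1,0.01"))
  tab <- read_microprofile(path,
                           column_spec = list(depth = "depth_cm",
                                              value = "oxygen",
                                              value_unit = "mM"),
                           species = "O2")
  expect_equal(tab$depth_mm, c(0, 1))   # cm -> mm
  expect_equal(tab$value, c(300, 10))   # mM -> uM
  expect_error(
    read_microprofile(path,
                      column_spec = list(depth = "depth_cm",
                                         value = "oxygen",
                                         value_unit = "ppm")),
    "unknown concentration unit")
})

test_that("unreadable inputs give descriptive errors", {
  expect_error(read_microprofile(tempfile()), "does not exist")
  empty <- write_lines_tmp("# just a comment")
  expect_error(read_microprofile(empty), "empty")
  headers_only <- write_lines_tmp("depth_mm,O2_uM")
  expect_error(read_microprofile(headers_only), "no data rows")
  bad_depth <- write_lines_tmp(c("depth_mm,O2_uM", "xx,300"))
  expect_error(read_microprofile(bad_depth), "unparseable depth")
  no_value <- write_lines_tmp(c("depth_mm,temp", "0,12"))
  expect_error(read_microprofile(no_value), "value column")
})

test_that("subsurface filtering keeps the surface and rejects empty results", {
  tab <- microprofile(c(-2, -1, 0, 1, 2), c(310, 305, 300, 10, 0),
                      species = "O2")
  kept <- filter_subsurface(tab)
  expect_equal(kept$depth_mm, c(0, 1, 2))
  all_neg <- microprofile(c(-3, -1), c(300, 300), species = "O2")
  expect_error(filter_subsurface(all_neg), "depth sign")
  all_pos <- microprofile(c(0.5, 1), c(10, 1), species = "O2")
  expect_equal(filter_subsurface(all_pos)$value, all_pos$value)
})

test_that("flooring raises zeros and negative noise, never lowers a value", {
  tab <- microprofile(0:2, c(300, 0, -0.4), species = "O2")
  out <- suppressMessages(apply_floor(tab))
  expect_equal(out$value, c(300, 0.001, 0.001))
  expect_identical(attr(out, "n_floored"), 2L)
  expect_true(all(out$value >= tab$value))
  # above-floor values and the exact boundary are untouched
  clean <- microprofile(0:1, c(5, 0.001), species = "O2")
  out2 <- apply_floor(clean)
  expect_equal(out2$value, clean$value)
  expect_identical(attr(out2, "n_floored"), 0L)
  ph <- microprofile(0:1, c(7, 8), kind = "pH")
  expect_error(apply_floor(ph), "concentration")
})

test_that("plateau override forces a hovering deep tail to the floor", {
  depths <- seq(0, 40, by = 1)
  vals <- ifelse(depths < 27, 250 * exp(-depths / 5), 1.5)
  tab <- microprofile(depths, vals, species = "O2")
  out <- plateau_override(tab, from_depth_mm = 27)
  expect_true(all(out$value[out$depth_mm >= 27] == 0.001))
  expect_equal(out$value[out$depth_mm < 27], vals[depths < 27])
  # from the surface: whole profile floored
  expect_true(all(plateau_override(tab, 0)$value == 0.001))
  # beyond the table: warning, unchanged
  expect_warning(untouched <- plateau_override(tab, 50), "beyond")
  expect_equal(untouched$value, tab$value)
})

test_that("pH gaps fill by interpolation inside and by strategy at the edges", {
  ph <- microprofile(c(0, 1, 2, 3, 4), c(7.2, 7.0, NA, 8.0, NA),
                     kind = "pH")
  const <- fill_missing_ph(ph, "constant", constant_value = 7.98)
  expect_equal(const$value, c(7.2, 7.0, 7.5, 8.0, 7.98))
  ext <- fill_missing_ph(ph, "extend")
  expect_equal(ext$value, c(7.2, 7.0, 7.5, 8.0, 8.0))
  # no gaps: unchanged
  full <- microprofile(0:2, c(7, 7.5, 8), kind = "pH")
  expect_equal(fill_missing_ph(full, "extend")$value, full$value)
  # all missing: nothing to fill from
  expect_error(fill_missing_ph(microprofile(0:1, c(NA, NA), kind = "pH"),
                               "extend"), "no pH measurements")
  expect_error(fill_missing_ph(ph, "constant"), "constant_value")
})

test_that("alignment interpolates pH onto the concentration grid", {
  conc <- microprofile(c(0, 1, 2), c(300, 10, 0.001), species = "O2")
  ph <- microprofile(c(0, 2), c(7, 8), kind = "pH")
  j <- align_profiles(conc, ph)
  expect_s3_class(j, "aligned_profile")
  expect_equal(j$pH, c(7, 7.5, 8))
  expect_equal(j$conc_uM, conc$value)
  # identical grids pass through
  ph2 <- microprofile(c(0, 1, 2), c(7, 7.4, 8), kind = "pH")
  expect_equal(align_profiles(conc, ph2)$pH, ph2$value)
  # beyond the pH range the boundary value extends
  conc3 <- microprofile(c(0, 1, 2, 3), c(300, 10, 1, 0.001),
                        species = "O2")
  expect_equal(align_profiles(conc3, ph)$pH, c(7, 7.5, 8, 8))
  # disjoint ranges are an error
  far_ph <- microprofile(c(10, 12), c(8, 8), kind = "pH")
  expect_error(align_profiles(conc, far_ph), "disjoint")
})

test_that("the cleaning chain is idempotent", {
  depths <- seq(-1, 30, by = 0.5)
  vals <- ifelse(depths < 0, 305,
                 ifelse(depths < 27, pmax(300 - 15 * depths, 0), 1.2))
  conc <- microprofile(depths, vals, species = "O2")
  clean_once <- function(x) {
    x <- filter_subsurface(x)
    x <- suppressMessages(apply_floor(x))
    plateau_override(x, 27)
  }
  once <- clean_once(conc)
  twice <- clean_once(once)
  expect_equal(as.data.frame(twice), as.data.frame(once))
})

test_that("write then read reproduces a table bit for bit", {
  tab <- microprofile(seq(0, 2, by = 0.3), c(300, 100, 30, 10, 3, 1, 0.3),
                      species = "O2", site = "roundtrip check")
  path <- withr::local_tempfile(fileext = ".csv")
  write_microprofile(tab, path)
  back <- read_microprofile(path)
  expect_identical(back$depth_mm, tab$depth_mm)
  expect_identical(back$value, tab$value)
  # NA values survive the round trip too
  ph <- microprofile(0:2, c(7, NA, 8), kind = "pH")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_microprofile(ph, path2)
  expect_identical(read_microprofile(path2, kind = "pH")$value, ph$value)
})
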