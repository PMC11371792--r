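# Core free-energy and potential equations for two-compartment cells.

test_that("reaction quotient expands the two-compartment quotient correctly", {
  w <- worked_oxygen()
  # pH terms cancel at equal pH; water activity 1
  expect_equal(reaction_quotient(w$couple, w$red, w$ox), 1e-9 / 3e-4,
               tolerance = 1e-12)
  # identical compartments
  same <- compartment(c(O2 = 5e-5), pH = 7.5)
  expect_equal(reaction_quotient(w$couple, same, same), 1)
  # proton-as-substrate couple: H+ carried by the p exponent only
  h2 <- preset_couple("hydrogen")
  q <- reaction_quotient(h2, red = compartment(c(H2 = 2.5e-6), 7),
                         ox = compartment(c(H2 = 1e-9), 7))
  expect_equal(q, (1e-9 * 1e-14) / (2.5e-6 * 1e-14), tolerance = 1e-12)
})

test_that("reaction quotient errors name the offending species", {
  w <- worked_oxygen()
  expect_error(reaction_quotient(w$couple, compartment(c(H2 = 1), 7), w$ox),
               "O2")
  expect_error(
    reaction_quotient(w$couple, compartment(c(O2 = 0), 7), w$ox),
    "floor")
})

test_that("concentration term is RT ln Q", {
  w <- worked_oxygen()
  p <- emcc_params()
  expect_equal(concentration_delta_g(w$couple, w$red, w$ox, p),
               8.314 * 293 * log(1e-9 / 3e-4), tolerance = 1e-12)
  # hand value: 2436.0 * ln(3.333e-6) = -30,722 J/mol
  expect_equal(concentration_delta_g(w$couple, w$red, w$ox, p),
               -30722, tolerance = 1e-4)
  same <- compartment(c(O2 = 1e-6), 7)
  expect_equal(concentration_delta_g(w$couple, same, same, p), 0)
  h2 <- preset_couple("hydrogen")
  expect_equal(
    concentration_delta_g(h2, compartment(c(H2 = 2.5e-6), 7),
                          compartment(c(H2 = 1e-9), 7), p),
    8.314 * 293 * log(4e-4), tolerance = 1e-9)
})

test_that("conductor loss is linear in distance and rejects negatives", {
  p <- emcc_params()
  expect_identical(conductor_loss(2, p), 0.026)
  expect_identical(conductor_loss(0, p), 0)
  expect_equal(conductor_loss(4.5, p), 0.0585)
  expect_error(conductor_loss(-1, p), "non-negative")
})

test_that("the oxygen worked example reproduces at full precision", {
  w <- worked_oxygen()
  res <- emcc_delta_g(w$couple, w$red, w$ox, distance_mm = 2)
  expect_equal(round(res$delta_e_V, 3), 0.054)
  expect_identical(res$loss_V, 0.026)
  # exact arithmetic gives -20.7 kJ/mol (the rounded-potential route -20.8)
  expect_equal(res$delta_g_J_per_mol / 1000, -20.7, tolerance = 0.01)
  expect_true(res$feasible)
  # same compartments at D = 0: pure concentration term
  res0 <- emcc_delta_g(w$couple, w$red, w$ox, distance_mm = 0)
  expect_equal(res0$delta_g_J_per_mol / 1000, -30.72, tolerance = 1e-3)
  # result invariants
  expect_equal(res$delta_g_J_per_mol,
               res$conc_delta_g_J_per_mol + 4 * 96485.3 * res$loss_V,
               tolerance = 1e-12)
  expect_equal(res$delta_e_V * (-4 * 96485.3), res$delta_g_J_per_mol,
               tolerance = 1e-12)
})

test_that("identical compartments at D = 0 give exactly zero", {
  same <- compartment(c(O2 = 1e-5), pH = 8)
  res <- emcc_delta_g(preset_couple("oxygen"), same, same, 0)
  expect_identical(res$delta_g_J_per_mol, 0)
  expect_identical(res$delta_e_V, 0)
  expect_false(res$feasible)
})

test_that("swapping compartments at D = 0 negates the free energy", {
  set.seed(42)
  for (i in 1:25) {
    cpl <- random_couple()
    a <- random_compartment()
    b <- random_compartment()
    fwd <- emcc_delta_g(cpl, a, b, 0)$delta_g_J_per_mol
    rev <- emcc_delta_g(cpl, b, a, 0)$delta_g_J_per_mol
    expect_equal(fwd, -rev, tolerance = 1e-9)
  }
})

test_that("free energy grows by nFE per millimetre of conductor", {
  w <- worked_oxygen()
  p <- emcc_params()
  dists <- seq(0, 10, by = 0.5)
  dg <- vapply(dists, function(d)
    emcc_delta_g(w$couple, w$red, w$ox, d, p)$delta_g_J_per_mol, numeric(1))
  slopes <- diff(dg) / diff(dists)
  expect_equal(slopes, rep(4 * 96485.3 * 0.013, length(slopes)),
               tolerance = 1e-9)
})

test_that("a tenfold change in one species moves RT ln Q by RT ln 10 per exponent", {
  p <- emcc_params()
  cpl <- redox_couple("t", 3, 2, 0.1, oxidized = "X", reduced = "XH",
                      oxidized_coef = 2, reduced_coef = 1)
  red <- compartment(c(X = 1e-6, XH = 1e-4), 7)
  ox <- compartment(c(X = 1e-3, XH = 1e-7), 7)
  base <- concentration_delta_g(cpl, red, ox, p)
  rtln10 <- 8.314 * 293 * log(10)
  # [X]_red sits in the numerator with exponent 2
  red2 <- compartment(c(X = 1e-5, XH = 1e-4), 7)
  expect_equal(concentration_delta_g(cpl, red2, ox, p) - base, 2 * rtln10,
               tolerance = 1e-9)
  # [XH]_ox sits in the numerator with exponent 1
  ox2 <- compartment(c(X = 1e-3, XH = 1e-6), 7)
  expect_equal(concentration_delta_g(cpl, red, ox2, p) - base, rtln10,
               tolerance = 1e-9)
  # [X]_ox sits in the denominator with exponent 2
  ox3 <- compartment(c(X = 1e-2, XH = 1e-7), 7)
  expect_equal(concentration_delta_g(cpl, red, ox3, p) - base, -2 * rtln10,
               tolerance = 1e-9)
})

test_that("pH shifts common to both ends cancel; a unit difference costs n_protons RT ln 10", {
  p <- emcc_params()
  cpl <- preset_couple("oxygen")
  red <- compartment(c(O2 = 1e-9), pH = 7)
  ox <- compartment(c(O2 = 3e-4), pH = 7)
  base <- concentration_delta_g(cpl, red, ox, p)
  shift <- concentration_delta_g(cpl, compartment(c(O2 = 1e-9), 8.3),
                                 compartment(c(O2 = 3e-4), 8.3), p)
  expect_equal(shift, base, tolerance = 1e-9)
  # lower pH at the reducing end (more protons there) inhibits the cell
  low_red <- concentration_delta_g(cpl, compartment(c(O2 = 1e-9), 6),
                                   compartment(c(O2 = 3e-4), 7), p)
  expect_equal(low_red - base, 4 * 8.314 * 293 * log(10), tolerance = 1e-9)
  expect_gt(low_red, base)
})

test_that("half-cell potentials sum to -RT ln Q / nF and match the cell energy", {
  w <- worked_oxygen()
  p <- emcc_params()
  hc <- half_cell_potentials(w$couple, w$red, w$ox, p)
  expect_equal(round(unname(hc["E_ox"] + hc["E_red"]), 3), 0.080)
  # consistency with the canonical path over random cells
  set.seed(7)
  for (i in 1:25) {
    cpl <- random_couple()
    a <- random_compartment()
    b <- random_compartment()
    d <- stats::runif(1, 0, 5)
    hc <- half_cell_potentials(cpl, a, b, p)
    res <- emcc_delta_g(cpl, a, b, d, p)
    lhs <- -cpl$n_electrons * 96485.3 *
      (hc[["E_red"]] + hc[["E_ox"]] - res$loss_V)
    expect_equal(lhs, res$delta_g_J_per_mol, tolerance = 1e-9)
  }
  # identical compartments: the halves cancel exactly
  same <- compartment(c(O2 = 1e-6), 7)
  hc0 <- half_cell_potentials(w$couple, same, same, p)
  expect_equal(unname(hc0["E_ox"] + hc0["E_red"]), 0, tolerance = 1e-12)
  # hydrogen example
  h2 <- half_cell_potentials(preset_couple("hydrogen"),
                             compartment(c(H2 = 2.5e-6), 7),
                             compartment(c(H2 = 1e-9), 7), p)
  expect_equal(unname(h2["E_ox"] + h2["E_red"]),
               -8.314 * 293 * log(4e-4) / (2 * 96485.3), tolerance = 1e-9)
})

test_that("maximum feasible distance has the closed form, with 0 and Inf edges", {
  w <- worked_oxygen()
  p <- emcc_params()
  expect_equal(max_feasible_distance(w$couple, w$red, w$ox, p),
               (-10000 - 8.314 * 293 * log(1e-9 / 3e-4)) /
                 (4 * 96485.3 * 0.013), tolerance = 1e-12)
  expect_equal(max_feasible_distance(w$couple, w$red, w$ox, p), 4.13,
               tolerance = 1e-3)
  same <- compartment(c(O2 = 1e-6), 7)
  expect_identical(max_feasible_distance(w$couple, same, same, p), 0)
  lossless <- emcc_params(loss_V_per_mm = 0)
  expect_identical(max_feasible_distance(w$couple, w$red, w$ox, lossless),
                   Inf)
})

test_that("per-decade sensitivity is RT ln 10 per order of magnitude", {
  p <- emcc_params()
  expect_equal(per_decade_sensitivity(p, 1), 8.314 * 293 * log(10),
               tolerance = 1e-12)
  expect_equal(round(per_decade_sensitivity(p, 1) / 1000, 1), 5.6)
  expect_identical(per_decade_sensitivity(p, 0), 0)
  expect_equal(per_decade_sensitivity(p, 6) / 1000, 33.7, tolerance = 1e-2)
})

test_that("emcc_delta_g matches an independent brute-force expansion", {
  set.seed(2024)
  p <- emcc_params()
  for (i in 1:120) {
    cpl <- random_couple()
    red <- random_compartment()
    ox <- random_compartment()
    d <- stats::runif(1, 0, 10)
    got <- emcc_delta_g(cpl, red, ox, d, p)$delta_g_J_per_mol
    want <- oracle_delta_g(cpl, red, ox, d, p)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("concentrations at or below the floor are raised before the logarithm", {
  cpl <- preset_couple("oxygen")
  res <- emcc_delta_g(cpl, red = compartment(c(O2 = 0), 7),
                      ox = compartment(c(O2 = 3e-4), 7), 0)
  expect_true(is.finite(res$delta_g_J_per_mol))
  expect_equal(res$reaction_quotient, 1e-9 / 3e-4, tolerance = 1e-12)
})

test_that("constructors validate their invariants", {
  expect_error(redox_couple("x", 0, 2, 0.1, "X", "XH"), "n_electrons")
  expect_error(redox_couple("x", 2, -1, 0.1, "X", "XH"), "n_protons")
  expect_error(redox_couple("x", 2, 2, Inf, "X", "XH"), "finite")
  expect_error(compartment(c(1e-5), 7), "named")
  expect_error(compartment(c(O2 = 1e-5), NaN), "finite")
  expect_error(emcc_params(temperature_K = -1), "positive")
  expect_error(emcc_params(concentration_floor_M = 0), "> 0")
})
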