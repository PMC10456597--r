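# chem_core: formula arithmetic, derivatization, ion m/z, isotope patterns

test_that("monoisotopic masses match tabulated worked examples", {
  expect_equal(monoisotopic_mass("C17H32O4Si3"), 384.1608, tolerance = 1e-4 / 384)
  expect_equal(monoisotopic_mass(elemental_formula()), 0)
  expect_equal(ion_mz("C9H27O4PSi3", "[M+H]+"), 315.1033, tolerance = 1e-4 / 315)
})

test_that("unsupported elements error with the symbol named", {
  expect_error(elemental_formula(Fe = 1), "Fe")
  expect_error(parse_formula("C2H6Xx2"), "Xx|parse")
  expect_error(monoisotopic_mass("C2Br1"), "Br")
})

test_that("formula strings round-trip through Hill order", {
  cases <- c("C17H32O4Si3", "C9H27O4PSi3", "H3PO4", "CH4N2O", "C16H32O2")
  for (s in cases) {
    f <- parse_formula(s)
    expect_identical(parse_formula(format_formula(f)), f)
  }
  # Hill order: C, H, then alphabetical
  expect_identical(format_formula(parse_formula("Si3O4H32C17")), "C17H32O4Si3")
  expect_identical(format_formula(parse_formula("")), "")
})

test_that("formula arithmetic is element-wise and never negative", {
  f <- parse_formula("C2H6O")
  expect_identical(format_formula(f + parse_formula("CH2")), "C3H8O")
  expect_identical(format_formula(f - parse_formula("H2O")), "C2H4")
  expect_error(f - parse_formula("N"), "negative")
})

test_that("derivatize performs TMS/MEOX net arithmetic", {
  expect_identical(format_formula(derivatize("C8H8O4", n_tms = 3)),
                   "C17H32O4Si3")
  d <- derivatize("H3PO4", n_tms = 3)
  expect_identical(format_formula(d), "C9H27O4PSi3")
  expect_equal(monoisotopic_mass(d), 314.0955, tolerance = 1e-4 / 314)
  # identity case
  f <- parse_formula("C6H12O6")
  expect_identical(derivatize(f, 0, 0), f)
  # per-group mass shifts
  base <- parse_formula("C6H12O6")
  expect_equal(monoisotopic_mass(derivatize(base, 1, 0)) - monoisotopic_mass(base),
               72.0395, tolerance = 0.0005 / 72)
  expect_equal(monoisotopic_mass(derivatize(base, 0, 1)) - monoisotopic_mass(base),
               29.0266, tolerance = 0.0005 / 29)
  # errors
  expect_error(derivatize("C6H12O6", -1), ">= 0")
  expect_error(derivatize("H3PO4", 4), "hydrogens")
})

test_that("derivatize is additive in the TMS count", {
  set.seed(11)
  for (f in random_formulas(20, seed = 11)) {
    a <- sample(0:2, 1); b <- sample(0:2, 1)
    if (f[["H"]] < a + b) next
    expect_identical(derivatize(f, a + b, 0), derivatize(derivatize(f, a, 0), b, 0))
  }
})

test_that("ion_mz applies species deltas without electron correction", {
  M <- "C17H32O4Si3"
  expect_equal(ion_mz(M, "[M]+"), monoisotopic_mass(M))
  expect_equal(ion_mz(M, "[M-CH3]+"), 369.1374, tolerance = 1e-4 / 369)
  expect_equal(ion_mz(M, "[M+TMS]+"), 457.2082, tolerance = 1e-4 / 457)
  expect_lt(ion_mz(M, "[M]+", electron_correction = TRUE), ion_mz(M, "[M]+"))
  expect_error(ion_mz("H2O", "[M-CH3]+"), "not applicable")
  expect_error(ion_mz(M, "[M+Na]+"), "unknown ion species")
})

test_that("pairwise species deltas are formula-independent constants", {
  for (f in random_formulas(25, seed = 4)) {
    expect_equal(ion_mz(f, "[M+H]+") - ion_mz(f, "[M-H]+"), 2.015650,
                 tolerance = 1e-5 / 2)
    expect_equal(ion_mz(f, "[M]+") - ion_mz(f, "[M-CH3]+"), 15.023475,
                 tolerance = 1e-5 / 15)
    expect_equal(ion_mz(f, "[M+TMS]+") - ion_mz(f, "[M]+"), 73.047352,
                 tolerance = 1e-5 / 73)
    expect_equal(ion_mz(f, "[M+C3H5]+") - ion_mz(f, "[M+C2H5]+"), 12.0,
                 tolerance = 1e-9)
  }
})

test_that("isotope_pattern matches the standard carbon constants", {
  p <- isotope_pattern("C", max_shift = 1)
  expect_equal(p$abundance, c(0.9893, 0.0107), tolerance = 1e-4)
  p0 <- isotope_pattern("H2O", max_shift = 0)
  expect_equal(p0$abundance, 1.0)
  expect_equal(p0$mass, monoisotopic_mass("H2O"), tolerance = 1e-9)
})

test_that("isotope_pattern abundances sum to 1 and masses increase", {
  for (f in random_formulas(10, seed = 7)) {
    p <- isotope_pattern(f, max_shift = 4)
    expect_equal(sum(p$abundance), 1, tolerance = 1e-9)
    expect_true(all(diff(p$mass) > 0))
  }
})

test_that("isotope_pattern agrees with the exhaustive multinomial oracle", {
  # value frozen from the pre-build enumeration oracle
  p <- isotope_pattern("C17H32O4Si3", max_shift = 4)
  expect_equal(p$abundance[2] / p$abundance[1], 0.34147384, tolerance = 1e-6)
  expect_equal(p$abundance[3] / p$abundance[1], 0.16223854, tolerance = 1e-6)
  cases <- list(c(C = 9, H = 27, O = 4, P = 1, Si = 3),
                c(C = 3, H = 7, N = 1, O = 2),
                c(C = 2, H = 6, S = 1),
                c(C = 6, H = 12, O = 6))
  for (cnt in cases) {
    o <- oracle_isotope_pattern(cnt, max_shift = 3)
    p <- isotope_pattern(elemental_formula(cnt), max_shift = 3)
    expect_equal(p$abundance, o$p, tolerance = 1e-6)
    expect_equal(p$mass, o$mass, tolerance = 1e-6)
  }
})
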