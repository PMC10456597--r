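# adduct_pattern: isotope grouping and molecular-ion detection

test_that("group_isotopes groups an isotopologue cluster and splits singletons", {
  s <- spectrum(c(369.137, 370.140, 371.137), c(100, 35, 15))
  g <- group_isotopes(s)
  expect_equal(unique(g$group), 1L)
  expect_identical(g$is_mono, c(TRUE, FALSE, FALSE))
  expect_equal(g$mz[g$is_mono], 369.137)

  s2 <- spectrum(c(100.0, 200.0), c(50, 100))
  g2 <- group_isotopes(s2)
  expect_equal(length(unique(g2$group)), 2L)
  expect_true(all(g2$is_mono))
})

test_that("a simulated isotope cluster reassembles into one group", {
  pat <- ion_isotope_pattern("C17H32O4Si3", "[M-CH3]+", max_shift = 3)
  s <- spectrum(pat$mass, 100 * pat$abundance / pat$abundance[1])
  g <- group_isotopes(s)
  expect_equal(length(unique(g$group)), 1L)
  expect_equal(sum(g$is_mono), 1L)
  expect_equal(nrow(g), nrow(pat))
})

test_that("the window excludes the +1.00783 spacing between cluster species", {
  # adjacent [M]+ / [M+H]+ monoisotopes must open separate groups
  m <- ion_mz("C9H27O4PSi3", "[M]+")
  s <- spectrum(c(m, m + 1.00783), c(50, 100))
  g <- group_isotopes(s)
  expect_equal(length(unique(g$group)), 2L)
})

test_that("the phosphoric-acid worked example detects [M+H]+ at M = 314.0953", {
  a <- detect_molecular_ion(phosphoric_toy())
  expect_false(a$rejected)
  expect_equal(a$neutral_mass, 314.0953, tolerance = 0.005 / 314)
  expect_identical(a$base_species, "[M+H]+")
  expect_equal(a$precursor_mz, 315.1031)
  expect_true(all(c("[M-CH3]+", "[M+H]+", "[M+C2H5]+", "[M+C3H5]+") %in%
                  a$species_found$species))
})

test_that("strict mode rejects unexplained high-mass ions; whitelist explains them", {
  s <- phosphoric_toy(extra_mz = 387.1428, extra_int = 20)
  a <- detect_molecular_ion(s)
  expect_true(a$rejected)
  expect_identical(a$reason, "unexplained high-mass ions")

  cfg <- detection_config(higher_mz_whitelist = "[M+TMS]+")
  a2 <- detect_molecular_ion(s, cfg)
  expect_false(a2$rejected)
  expect_true("[M+TMS]+" %in% a2$species_found$species)
  expect_equal(a2$neutral_mass, 314.0953, tolerance = 0.005 / 314)

  lenient <- detection_config(strict = FALSE)
  a3 <- detect_molecular_ion(s, lenient)
  expect_false(a3$rejected)
})

test_that("water loss is annotated but never anchors", {
  M <- "C9H27O4PSi3"
  s <- spectrum(c(ion_mz(M, "[M-H2O+H]+"), 299.0719, 315.1031, 343.1345),
                c(30, 100, 40, 3))
  a <- detect_molecular_ion(s)
  expect_false(a$rejected)
  expect_equal(a$neutral_mass, 314.0953, tolerance = 0.005 / 314)
  expect_true("[M-H2O+H]+" %in% a$species_found$species)
})

test_that("detection is deterministic and self-consistent", {
  s <- phosphoric_toy()
  a1 <- detect_molecular_ion(s)
  a2 <- detect_molecular_ion(s)
  expect_identical(a1, a2)
  scored <- a1$species_found[a1$species_found$species != "[M-H2O+H]+", ]
  for (k in seq_len(nrow(scored))) {
    expect_lt(abs(scored$mz[k] -
                  (a1$neutral_mass + species_delta_mass(scored$species[k]))),
              detection_config()$mz_tolerance)
  }
})

test_that("detector equals the exhaustive anchor-scan oracle on small spectra", {
  cfg <- detection_config()
  cmp <- default_compound_table()
  set.seed(303)
  n_checked <- 0L
  for (i in 1:25) {
    row <- cmp[sample.int(nrow(cmp), 1), ]
    sim <- simulate_spectrum(row, simulation_config())
    s <- sim$spectrum
    if (nrow(s$peaks) > 20) next
    a <- detect_molecular_ion(s, cfg)
    o <- oracle_detect(s, cfg)
    if (is.null(o)) {
      expect_true(a$rejected)
    } else {
      expect_equal(a$neutral_mass, o$neutral_mass, tolerance = 1e-9)
      expect_identical(a$base_species, o$base_species)
    }
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 10L)
})

test_that("raising the molecular floor never increases acceptances", {
  lib <- simulate_library(n = 60, config = simulation_config(seed = 99))
  floors <- c(0.01, 0.05, 0.2, 0.5)
  accepted <- vapply(floors, function(fl) {
    cfg <- detection_config(molecular_intensity_floor = fl)
    sum(!batch_detect(lib$spectra, cfg)$table$rejected)
  }, numeric(1))
  expect_true(all(diff(accepted) <= 0))
})

test_that("batch_detect aggregates counts and never aborts", {
  lib <- simulate_library(n = 12,
                          config = simulation_config(seed = 5, clean = TRUE))
  res <- batch_detect(lib$spectra)
  expect_equal(nrow(res$table), 12)
  expect_equal(res$summary$n_accepted, 12)
  expect_equal(sum(res$summary$base_species_counts), 12)
  # a degenerate single-peak spectrum becomes a flagged row, not an abort
  bad <- spectrum(100, 1, metadata = list(name = "degenerate"))
  res2 <- batch_detect(c(lib$spectra, list(bad)))
  expect_equal(nrow(res2$table), 13)
  expect_true(res2$table$rejected[13])
  expect_error(batch_detect(list()), "empty")
})

test_that("empty spectra error out of detection", {
  expect_error(detect_molecular_ion(spectrum(numeric(0), numeric(0))), "empty")
  expect_error(group_isotopes(spectrum(numeric(0), numeric(0))), "empty")
})
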