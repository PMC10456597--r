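# formula_assign: bounded decomposition, ranking, anchoring strategies

tiny_bounds <- function(...) {
  decomposition_bounds(C = c(0L, 12L), H = c(0L, 24L), N = c(0L, 3L),
                       O = c(0L, 6L), P = c(0L, 1L), S = c(0L, 1L),
                       Si = c(0L, 2L), si_mandatory = FALSE, ...)
}

test_that("methane is the sole decomposition of 16.0313 under tight bounds", {
  b <- decomposition_bounds(C = c(0L, 2L), H = c(0L, 6L), N = c(0L, 1L),
                            O = c(0L, 1L), P = c(0L, 0L), S = c(0L, 0L),
                            Si = c(0L, 0L), si_mandatory = FALSE)
  cand <- decompose_mass(16.0313, "[M]+", b)
  expect_equal(nrow(cand), 1)
  expect_identical(cand$formula, "CH4")
})

test_that("the worked-example [M-CH3]+ mass decomposes to the true formula", {
  b <- decomposition_bounds(tolerance_ppm = 5)
  cand <- decompose_mass(369.1374, "[M-CH3]+", b)
  expect_true("C17H32O4Si3" %in% cand$formula)
  # every candidate respects tolerance, rdbe, and the Si mandate
  expect_true(all(abs(cand$mass_error_ppm) <= 5))
  expect_true(all(cand$rdbe >= -0.5))
  expect_true(all(cand$Si >= 1))
})

test_that("decomposition equals the brute-force oracle on random masses", {
  set.seed(31)
  b <- tiny_bounds()
  bl <- list(C = b$C, H = b$H, N = b$N, O = b$O, P = b$P, S = b$S, Si = b$Si)
  for (i in 1:50) {
    target <- runif(1, 40, 300)
    cand <- decompose_mass(target, "[M]+", b)
    got <- sort(cand$formula)
    tol_da <- b$tolerance_ppm * 1e-6 * target
    want <- sort(vapply(oracle_decompose(target, tol_da, bl),
                        function(x) format_formula(elemental_formula(x)),
                        character(1)))
    expect_identical(got, want)
  }
})

test_that("empty candidate sets are valid returns", {
  b <- decomposition_bounds(C = c(0L, 0L), H = c(0L, 0L), N = c(0L, 0L),
                            O = c(0L, 0L), P = c(0L, 0L), S = c(0L, 0L),
                            Si = c(0L, 1L), si_mandatory = TRUE)
  cand <- decompose_mass(500, "[M]+", b)
  expect_equal(nrow(cand), 0)
})

test_that("ranking is monotone in explained fragments and deterministic", {
  s <- phosphoric_toy()
  cand <- decompose_mass(299.0719, "[M-CH3]+",
                         decomposition_bounds(tolerance_ppm = 10))
  r1 <- rank_candidates(cand, s)
  expect_equal(nrow(r1), nrow(cand))
  expect_true(all(diff(r1$rank_score) <= 1e-12))
  expect_identical(r1$formula, rank_candidates(cand, s)$formula)
  # single candidate ranks first trivially
  r2 <- rank_candidates(cand[cand$formula == "C9H27O4PSi3", ], s)
  expect_equal(nrow(r2), 1)
  # the true formula is present with sub-ppm error near the top
  rank_plain <- match("C9H27O4PSi3", r1$formula)
  expect_lte(rank_plain, 5)
  # fragment evidence is monotone: adding peaks the true formula explains
  # (TMSOH and water losses) can only improve its rank
  M <- monoisotopic_mass("C9H27O4PSi3")
  s3 <- spectrum(c(M - 90.0501, M - 15.0235 - 18.0106, 299.0719, 315.1031),
                 c(10, 5, 100, 40))
  r3 <- rank_candidates(cand, s3)
  expect_gte(r3$explained_fragments[r3$formula == "C9H27O4PSi3"], 3)
  expect_lte(match("C9H27O4PSi3", r3$formula), rank_plain)
})

test_that("fragment explanation subsumes common neutral losses", {
  # peaks at [M-CH3]+, [M-TMSOH+...]-style subformulas of C9H27O4PSi3
  counts <- c(C = 9L, H = 27L, N = 0L, O = 4L, P = 1L, S = 0L, Si = 3L)
  M <- monoisotopic_mass("C9H27O4PSi3")
  expect_true(cimion:::.peak_explained(M - 15.0235, counts, 10))   # -CH3
  expect_true(cimion:::.peak_explained(M - 90.0501, counts, 10))   # -TMSOH
  expect_true(cimion:::.peak_explained(M - 18.0106, counts, 10))   # -H2O
  expect_false(cimion:::.peak_explained(M + 50, counts, 10))
})

test_that("strategies anchor correctly and reject bad input", {
  s <- phosphoric_toy()
  a <- detect_molecular_ion(s)
  b <- decomposition_bounds(tolerance_ppm = 10)
  r_ch3 <- assign_with_strategy(s, a, "m_minus_ch3", bounds = b)
  expect_lte(match("C9H27O4PSi3", r_ch3$formula), 5)
  r_mol <- assign_with_strategy(s, a, "molecular_ion", bounds = b)
  expect_true("C9H27O4PSi3" %in% r_mol$formula)
  r_iso <- assign_with_strategy(s, a, "with_isotopes", bounds = b)
  expect_true("isotope_distance" %in% names(r_iso))

  # rejected assignment -> error
  bad <- detect_molecular_ion(phosphoric_toy(387.1428, 20))
  expect_true(bad$rejected)
  expect_error(assign_with_strategy(s, bad, "molecular_ion"), "rejected")

  # missing anchor species -> error naming it
  s2 <- spectrum(c(ion_mz("C9H27O4PSi3", "[M]+"), ion_mz("C9H27O4PSi3", "[M+H]+")),
                 c(50, 100))
  a2 <- detect_molecular_ion(s2)
  expect_false(a2$rejected)
  expect_error(assign_with_strategy(s2, a2, "m_minus_ch3"),
               "\\[M-CH3\\]\\+")
})

test_that("the true formula always appears for noise-free synthetic ions", {
  cmp <- default_compound_table()
  b <- decomposition_bounds(tolerance_ppm = 10)
  for (i in seq_len(nrow(cmp))) {
    d <- derivatized_compound(cmp$name[i], cmp$base_formula[i],
                              cmp$n_tms[i], cmp$n_meox[i])
    cand <- decompose_mass(ion_mz(d$formula, "[M-CH3]+"), "[M-CH3]+", b)
    expect_true(format_formula(d$formula) %in% cand$formula,
                label = paste("candidate set for", d$name))
  }
})
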