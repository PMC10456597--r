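# Bounded exhaustive accurate-mass decomposition over C/H/N/O/P/S/Si.
# A self-contained stand-in for an external formula-search engine: complete
# enumeration relative to the bounds, with valence (RDBE) and H/C plausibility
# filters, so candidate lists can be ranked locally or exported for SIRIUS.

#' Element-count bounds for mass decomposition
#'
#' Defaults cover TMS-derivatized metabolites up to roughly 1 kDa. Silicon
#' can be forced present (`si_mandatory`), the natural constraint for
#' TMS-derivatized analytes.
#'
#' @param C,H,N,O,P,S,Si integer vectors `c(min, max)` per element.
#' @param tolerance_ppm mass tolerance in ppm (default 10).
#' @param si_mandatory force at least one Si atom (default `TRUE`).
#' @return a `decomposition_bounds` list.
#' @export
decomposition_bounds <- function(C = c(0L, 60L), H = c(0L, 120L),
                                 N = c(0L, 10L), O = c(0L, 25L),
                                 P = c(0L, 4L), S = c(0L, 4L),
                                 Si = c(0L, 12L),
                                 tolerance_ppm = 10, si_mandatory = TRUE) {
  b <- list(C = C, H = H, N = N, O = O, P = P, S = S, Si = Si)
  for (el in names(b)) {
    if (length(b[[el]]) != 2L || b[[el]][1] > b[[el]][2] || b[[el]][1] < 0) {
      stop("bad bounds for ", el, call. = FALSE)
    }
  }
  stopifnot(tolerance_ppm > 0)
  if (si_mandatory) b$Si[1] <- max(b$Si[1], 1L)
  structure(c(b, list(tolerance_ppm = tolerance_ppm,
                      si_mandatory = isTRUE(si_mandatory))),
            class = "decomposition_bounds")
}

#' Ring-plus-double-bond equivalents
#'
#' Neutral-formula convention with Si counted tetravalent like carbon and
#' N, P trivalent: `1 + C + Si - H/2 + (N + P)/2`.
#'
#' @param f formula (object or Hill string).
#' @return RDBE (may be half-integral or negative).
#' @export
rdbe <- function(f) {
  f <- as_formula(f)
  1 + f[["C"]] + f[["Si"]] - f[["H"]] / 2 + (f[["N"]] + f[["P"]]) / 2
}

#' Decompose an observed m/z into candidate formulas
#'
#' Complete bounded enumeration of neutral formulas `M` whose ion
#' `ion_mz(M, species)` lies within `tolerance_ppm` of `target_mz`.
#' Enumeration loops over Si, P, S, N and O with mass-based pruning; for
#' each partial composition the C loop is vectorized and the H count is
#' solved directly from the mass remainder, so completeness relative to the
#' bounds is structural. Candidates are filtered by `rdbe(M) >= -0.5` and,
#' when carbon is present, `0.1 <= H/C <= 4`.
#'
#' @param target_mz observed m/z in Da (> 0).
#' @param species ion species the peak is assumed to be (the species delta
#'   is removed before decomposing the neutral).
#' @param bounds a [decomposition_bounds()].
#' @return data.frame of candidates sorted by `abs(mass_error_ppm)`:
#'   `formula` (Hill string), `neutral_mass`, `ion_mz`, `mass_error_ppm`
#'   (signed, observed minus theoretical), `rdbe`. Zero rows is a valid
#'   result.
#' @examples
#' decompose_mass(16.0313, "[M]+",
#'                decomposition_bounds(C = c(0, 2), H = c(0, 6), N = c(0, 1),
#'                                     O = c(0, 1), P = c(0, 0), S = c(0, 0),
#'                                     Si = c(0, 0), si_mandatory = FALSE))
#' @export
decompose_mass <- function(target_mz, species = "[M]+",
                           bounds = decomposition_bounds()) {
  stopifnot(inherits(bounds, "decomposition_bounds"), target_mz > 0)
  .check_species(species)
  neutral_target <- target_mz - species_delta_mass(species)
  tol <- bounds$tolerance_ppm * 1e-6 * target_mz
  # species applicability floor: the neutral must contain the subtracted atoms
  sp_sub <- .ION_SPECIES[[species]]$sub
  min_req <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  if (length(sp_sub)) min_req[names(sp_sub)] <- sp_sub

  m <- .MONO_MASS
  lo <- function(el) max(bounds[[el]][1], min_req[[el]])
  hi <- function(el, rem) min(bounds[[el]][2], floor((rem + tol) / m[[el]]))
  rng <- function(a, b) if (b < a) integer(0) else a:b

  res_C <- integer(0); res_H <- integer(0); res_N <- integer(0)
  res_O <- integer(0); res_P <- integer(0); res_S <- integer(0)
  res_Si <- integer(0); res_mass <- numeric(0)

  for (si in rng(lo("Si"), hi("Si", neutral_target))) {
    r1 <- neutral_target - si * m[["Si"]]
    for (p in rng(lo("P"), hi("P", r1))) {
      r2 <- r1 - p * m[["P"]]
      for (s in rng(lo("S"), hi("S", r2))) {
        r3 <- r2 - s * m[["S"]]
        for (nn in rng(lo("N"), hi("N", r3))) {
          r4 <- r3 - nn * m[["N"]]
          for (o in rng(lo("O"), hi("O", r4))) {
            r5 <- r4 - o * m[["O"]]
            cs <- rng(lo("C"), hi("C", r5))
            if (length(cs) == 0L) next
            rem <- r5 - cs * m[["C"]]
            h <- round(rem / m[["H"]])
            ok <- h >= max(bounds$H[1], min_req[["H"]]) & h <= bounds$H[2] &
                  abs(rem - h * m[["H"]]) <= tol & rem > -tol
            if (any(ok)) {
              res_C <- c(res_C, cs[ok]); res_H <- c(res_H, h[ok])
              res_N <- c(res_N, rep(nn, sum(ok)))
              res_O <- c(res_O, rep(o, sum(ok)))
              res_P <- c(res_P, rep(p, sum(ok)))
              res_S <- c(res_S, rep(s, sum(ok)))
              res_Si <- c(res_Si, rep(si, sum(ok)))
              res_mass <- c(res_mass,
                            cs[ok] * m[["C"]] + h[ok] * m[["H"]] +
                            nn * m[["N"]] + o * m[["O"]] + p * m[["P"]] +
                            s * m[["S"]] + si * m[["Si"]])
            }
          }
        }
      }
    }
  }
  if (length(res_C) == 0L) return(.empty_candidates())
  # valence and composition plausibility
  rdbe_v <- 1 + res_C + res_Si - res_H / 2 + (res_N + res_P) / 2
  hc_ok <- res_C == 0L | (res_H / pmax(res_C, 1) >= 0.1 &
                          res_H / pmax(res_C, 1) <= 4)
  keep <- rdbe_v >= -0.5 & hc_ok
  if (!any(keep)) return(.empty_candidates())
  res <- data.frame(C = res_C, H = res_H, N = res_N, O = res_O, P = res_P,
                    S = res_S, Si = res_Si, neutral_mass = res_mass,
                    rdbe = rdbe_v)[keep, , drop = FALSE]
  delta <- species_delta_mass(species)
  res$ion_mz <- res$neutral_mass + delta
  res$mass_error_ppm <- (target_mz - res$ion_mz) / target_mz * 1e6
  res$formula <- apply(res[, c("C", "H", "N", "O", "P", "S", "Si")], 1,
                       function(x) format_formula(elemental_formula(x)))
  res <- res[order(abs(res$mass_error_ppm), res$formula), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("formula", "C", "H", "N", "O", "P", "S", "Si",
          "neutral_mass", "ion_mz", "mass_error_ppm", "rdbe")]
}

.empty_candidates <- function() {
  data.frame(formula = character(0), C = integer(0), H = integer(0),
             N = integer(0), O = integer(0), P = integer(0), S = integer(0),
             Si = integer(0), neutral_mass = numeric(0), ion_mz = numeric(0),
             mass_error_ppm = numeric(0), rdbe = numeric(0))
}
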