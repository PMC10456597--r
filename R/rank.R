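# Ranking of decomposition candidates. The score combines accurate-mass
# agreement with the number of spectrum peaks explainable as subformula
# cations of the candidate (methyl loss, TMSOH loss, water loss, or any
# formal subformula), optionally plus an isotope-pattern agreement term.
# Weights apply after per-spectrum min-max scaling. This is a transparent
# local ranker, not a reimplementation of fragmentation-tree scoring.

# Is mz explainable as a subformula cation of `counts` (named int vector)?
.peak_explained <- function(mz, counts, tolerance_ppm) {
  b <- decomposition_bounds(C = c(0L, counts[["C"]]), H = c(0L, counts[["H"]]),
                            N = c(0L, counts[["N"]]), O = c(0L, counts[["O"]]),
                            P = c(0L, counts[["P"]]), S = c(0L, counts[["S"]]),
                            Si = c(0L, counts[["Si"]]),
                            tolerance_ppm = tolerance_ppm,
                            si_mandatory = FALSE)
  nrow(decompose_mass(mz, "[M]+", b)) > 0L
}

#' Rank formula candidates against a spectrum
#'
#' `rank_score = w_mass * scaled(-|mass_error_ppm|) +
#'  w_fragments * scaled(explained_fragments)`, where a monoisotopic peak of
#' the spectrum counts as explained when some subformula of the candidate
#' matches it as a cation within tolerance (this subsumes the common neutral
#' losses CH3, TMSOH and H2O). Scaling is min-max across the candidate list.
#' Ties break by lower `|mass_error_ppm|`, then lexicographic formula, and
#' the sort is stable, so ranking is deterministic.
#'
#' @param candidates data.frame from [decompose_mass()].
#' @param s the spectrum the target peak came from.
#' @param config [detection_config()] supplying the noise floor used to pick
#'   which peaks are worth explaining.
#' @param weights named vector with elements `mass`, `fragments` (and
#'   optionally `isotope`, used by [assign_with_strategy()]); default 1 each.
#' @param tolerance_ppm tolerance for fragment explanation (default 10).
#' @param max_fragments explain at most this many of the most intense
#'   monoisotopic peaks (default 20, a runtime guard).
#' @return `candidates` with `explained_fragments` and `rank_score` columns,
#'   ordered best first.
#' @export
rank_candidates <- function(candidates, s, config = detection_config(),
                            weights = c(mass = 1, fragments = 1),
                            tolerance_ppm = 10, max_fragments = 20L) {
  if (nrow(candidates) == 0L) {
    candidates$explained_fragments <- integer(0)
    candidates$rank_score <- numeric(0)
    return(candidates)
  }
  groups <- group_isotopes(s, config)
  rel <- groups$intensity / max(groups$intensity)
  sel <- groups$is_mono & rel >= config$noise_floor
  frag_mz <- groups$mz[sel]
  if (length(frag_mz) > max_fragments) {
    frag_mz <- frag_mz[order(-rel[sel])][seq_len(max_fragments)]
  }
  expl <- integer(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cnt <- c(C = candidates$C[i], H = candidates$H[i], N = candidates$N[i],
             O = candidates$O[i], P = candidates$P[i], S = candidates$S[i],
             Si = candidates$Si[i])
    expl[i] <- sum(vapply(frag_mz, .peak_explained, logical(1),
                          counts = cnt, tolerance_ppm = tolerance_ppm))
  }
  candidates$explained_fragments <- expl
  scaled <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(0.5, length(x)) else (x - r[1]) / diff(r)
  }
  w_mass <- if ("mass" %in% names(weights)) weights[["mass"]] else 1
  w_frag <- if ("fragments" %in% names(weights)) weights[["fragments"]] else 1
  score <- w_mass * scaled(-abs(candidates$mass_error_ppm)) +
           w_frag * scaled(expl)
  if (!is.null(candidates$isotope_distance)) {
    w_iso <- if ("isotope" %in% names(weights)) weights[["isotope"]] else 1
    score <- score + w_iso * scaled(-candidates$isotope_distance)
  }
  candidates$rank_score <- score
  ord <- order(-score, abs(candidates$mass_error_ppm), candidates$formula)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# observed isotope-group ratios (A+1/A, A+2/A) for the group containing
# the peak closest to anchor_mz
.observed_isotope_ratios <- function(s, anchor_mz, config, max_shift = 2L) {
  groups <- group_isotopes(s, config)
  i <- which.min(abs(groups$mz - anchor_mz))
  g <- groups[groups$group == groups$group[i], , drop = FALSE]
  mono <- g$intensity[1]
  k <- seq_len(min(nrow(g) - 1L, max_shift))
  if (length(k) == 0L) return(numeric(0))
  stats::setNames(g$intensity[k + 1L] / mono, k)
}

#' Assign formulas with a chosen anchoring strategy
#'
#' Three strategies mirror the ways a recognized CI pattern can seed formula
#' calculation:
#' \describe{
#'   \item{`m_minus_ch3`}{decompose the observed `[M-CH3]+` peak. This ion
#'     is free of isotope contamination from neighboring species (it can
#'     only arise from the monoisotopic molecular ion), which is why it is
#'     the preferred anchor.}
#'   \item{`molecular_ion`}{decompose the base-species peak of the
#'     `[M-H]+`/`[M]+`/`[M+H]+` cluster.}
#'   \item{`with_isotopes`}{as `molecular_ion`, but add an isotope-pattern
#'     agreement term comparing the observed isotope-group ratios at the
#'     anchor to each candidate's theoretical pattern. When the cluster
#'     species overlap within unit resolution (the 13C isotopologue of one
#'     species coinciding with the monoisotope of the next), the observed
#'     ratios are inflated and this term actively misleads the ranking —
#'     the known failure mode of isotope-assisted scoring on CI clusters.}
#' }
#'
#' @param s the spectrum.
#' @param assignment an accepted `molecular_ion_assignment` for `s`.
#' @param strategy one of `"m_minus_ch3"`, `"molecular_ion"`,
#'   `"with_isotopes"`.
#' @param bounds a [decomposition_bounds()].
#' @param config a [detection_config()].
#' @param weights see [rank_candidates()]; `isotope` weight defaults to 1.
#' @param max_candidates keep only this many decomposition candidates
#'   (smallest mass error first) before the expensive ranking terms are
#'   computed; `Inf` keeps all.
#' @param max_fragments passed to [rank_candidates()].
#' @return ranked candidate data.frame (see [rank_candidates()]); for
#'   `with_isotopes` an `isotope_distance` column is included.
#' @export
assign_with_strategy <- function(s, assignment,
                                 strategy = c("m_minus_ch3", "molecular_ion",
                                              "with_isotopes"),
                                 bounds = decomposition_bounds(),
                                 config = detection_config(),
                                 weights = c(mass = 1, fragments = 1,
                                             isotope = 1),
                                 max_candidates = Inf,
                                 max_fragments = 20L) {
  strategy <- match.arg(strategy)
  if (!inherits(assignment, "molecular_ion_assignment")) {
    stop("assignment must come from detect_molecular_ion()", call. = FALSE)
  }
  if (assignment$rejected) {
    stop("cannot assign formulas to a rejected spectrum (",
         assignment$reason, ")", call. = FALSE)
  }
  sf <- assignment$species_found
  anchor_species <- if (strategy == "m_minus_ch3") "[M-CH3]+"
                    else assignment$base_species
  if (!anchor_species %in% sf$species) {
    stop("strategy anchor species ", anchor_species,
         " not present in species_found", call. = FALSE)
  }
  anchor_mz <- sf$mz[match(anchor_species, sf$species)]
  cand <- decompose_mass(anchor_mz, anchor_species, bounds)
  if (is.finite(max_candidates) && nrow(cand) > max_candidates) {
    cand <- cand[seq_len(max_candidates), , drop = FALSE]
  }
  if (strategy == "with_isotopes" && nrow(cand) > 0L) {
    obs <- .observed_isotope_ratios(s, anchor_mz, config)
    dist <- numeric(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      pat <- ion_isotope_pattern(parse_formula(cand$formula[i]),
                                 anchor_species, max_shift = 2L)
      theo <- stats::setNames(pat$abundance[-1] / pat$abundance[1],
                              pat$shift[-1])
      ks <- union(names(obs), names(theo))
      ov <- stats::setNames(numeric(length(ks)), ks)
      tv <- ov
      ov[names(obs)] <- obs
      tv[names(theo)] <- theo
      dist[i] <- sum(abs(ov - tv))
    }
    cand$isotope_distance <- dist
  }
  rank_candidates(cand, s, config, weights,
                  tolerance_ppm = bounds$tolerance_ppm,
                  max_fragments = max_fragments)
}
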