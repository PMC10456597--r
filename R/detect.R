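# Recognition of the methane-CI molecular-ion pattern. Under CI, TMS
# derivatives show a characteristic set of ions around the intact molecule:
# a strong [M-CH3]+ fragment (often the base peak), the molecular cluster
# [M-H]+/[M]+/[M+H]+ at variable but usually >5%-of-base-peak intensity, and
# the reagent adducts [M+C2H5]+/[M+C3H5]+ mostly below 5%. The detector
# groups isotopologue peaks, then scans anchor hypotheses against the exact
# inter-species mass deltas and returns the best-supported neutral mass.

.DELTA_CH3 <- 15.0234751 # [M]+ minus [M-CH3]+

#' Detection configuration
#'
#' @param mz_tolerance matching tolerance in Da (default 0.005, roughly 3x
#'   the mDa-level accuracy a QTOF delivers on these ions).
#' @param molecular_intensity_floor minimum relative intensity (fraction of
#'   base peak) at which at least one molecular-cluster species must appear
#'   (default 0.05, the ">5% bp" rule).
#' @param adduct_intensity_floor minimum relative intensity for the
#'   confirming adducts (default 0.001; adducts sit below 5% bp).
#' @param noise_floor peaks below this fraction of the base peak are ignored
#'   as candidates (default 0.001).
#' @param higher_mz_whitelist ion species permitted above `[M+C3H5]+`
#'   without triggering rejection; default `character(0)` (strict). Pass
#'   `"[M+TMS]+"` to accept the rearrangement adduct.
#' @param require_adducts if `TRUE`, at least one of `[M+C2H5]+`/
#'   `[M+C3H5]+` must be present for acceptance (default `FALSE`: adducts
#'   confirm but are not required).
#' @param strict if `FALSE`, unexplained ions above `[M+C3H5]+` are
#'   tolerated instead of causing rejection.
#' @return a `detection_config` list.
#' @export
detection_config <- function(mz_tolerance = 0.005,
                             molecular_intensity_floor = 0.05,
                             adduct_intensity_floor = 0.001,
                             noise_floor = 0.001,
                             higher_mz_whitelist = character(0),
                             require_adducts = FALSE,
                             strict = TRUE) {
  stopifnot(mz_tolerance > 0,
            molecular_intensity_floor > 0, molecular_intensity_floor <= 1,
            adduct_intensity_floor > 0, adduct_intensity_floor <= 1,
            noise_floor > 0, noise_floor <= 1)
  if (length(higher_mz_whitelist)) {
    vapply(higher_mz_whitelist, .check_species, character(1))
  }
  structure(list(mz_tolerance = mz_tolerance,
                 molecular_intensity_floor = molecular_intensity_floor,
                 adduct_intensity_floor = adduct_intensity_floor,
                 noise_floor = noise_floor,
                 higher_mz_whitelist = higher_mz_whitelist,
                 require_adducts = isTRUE(require_adducts),
                 strict = isTRUE(strict)),
            class = "detection_config")
}

#' Group isotopologue peaks
#'
#' Greedy ascending-m/z grouping: a peak joins an open group when its
#' distance to that group's last member lies in `[0.996, 1.007]` and its
#' intensity does not exceed the group's monoisotopic member. The window
#' covers the 13C (+1.00336) and 29Si (+0.99957) spacings while excluding
#' the +1.00783 spacing between [M]+ and [M+H]+, so adjacent molecular
#' species open separate groups. Groups keep at most three members beyond
#' the monoisotopic peak. Every peak lands in exactly one group.
#'
#' @param s a non-empty spectrum.
#' @param config a [detection_config()].
#' @return data.frame with one row per peak: `mz`, `intensity`, `group`
#'   (integer id), `is_mono` (monoisotopic member of its group).
#' @export
group_isotopes <- function(s, config = detection_config()) {
  stopifnot(inherits(s, "ci_spectrum"))
  if (nrow(s$peaks) == 0L) stop("empty spectrum", call. = FALSE)
  mz <- s$peaks$mz
  inten <- s$peaks$intensity
  n <- length(mz)
  group <- integer(n)
  # open groups tracked as: id, last mz, mono intensity, size
  open <- list()
  next_id <- 1L
  for (i in seq_len(n)) {
    # drop groups no longer reachable
    if (length(open)) {
      open <- Filter(function(g) mz[i] - g$last <= 1.007 + 1e-12, open)
    }
    best <- NULL; best_dev <- Inf
    for (g in open) {
      d <- mz[i] - g$last
      if (d >= 0.996 && d <= 1.007 && inten[i] <= g$mono_int && g$size < 4L) {
        dev <- abs(d - 1.00336)
        if (dev < best_dev) { best <- g$id; best_dev <- dev }
      }
    }
    if (is.null(best)) {
      group[i] <- next_id
      open[[length(open) + 1L]] <- list(id = next_id, last = mz[i],
                                        mono_int = inten[i], size = 1L)
      next_id <- next_id + 1L
    } else {
      group[i] <- best
      for (k in seq_along(open)) {
        if (open[[k]]$id == best) {
          open[[k]]$last <- mz[i]
          open[[k]]$size <- open[[k]]$size + 1L
          break
        }
      }
    }
  }
  is_mono <- !duplicated(group)
  data.frame(mz = mz, intensity = inten, group = group, is_mono = is_mono)
}

# Evaluate one neutral-mass hypothesis against the monoisotopic candidate
# peaks. Returns NULL when the hypothesis finds no molecular species.
.evaluate_hypothesis <- function(M, cand_mz, cand_rel, config) {
  tol <- config$mz_tolerance
  find_peak <- function(target) {
    d <- abs(cand_mz - target)
    i <- which.min(d)
    if (length(i) && d[i] <= tol) i else NA_integer_
  }
  species <- character(0); obs_mz <- numeric(0); obs_rel <- numeric(0)
  for (sp in c("[M-CH3]+", .MOLECULAR_SPECIES, .ADDUCT_SPECIES)) {
    floor_sp <- if (sp %in% .ADDUCT_SPECIES) config$adduct_intensity_floor
                else config$noise_floor
    i <- find_peak(M + species_delta_mass(sp))
    if (!is.na(i) && cand_rel[i] >= floor_sp) {
      species <- c(species, sp)
      obs_mz <- c(obs_mz, cand_mz[i])
      obs_rel <- c(obs_rel, cand_rel[i])
    }
  }
  mol <- intersect(species, .MOLECULAR_SPECIES)
  if (length(mol) == 0L) return(NULL)
  mol_rel <- obs_rel[match(mol, species)]
  if (max(mol_rel) < config$molecular_intensity_floor) return(NULL)
  # acceptance: anchor fragment plus >=1 more species, or >=2 cluster members
  ok <- ("[M-CH3]+" %in% species && length(species) >= 2L) || length(mol) >= 2L
  if (!ok) return(NULL)
  if (config$require_adducts && !any(species %in% .ADDUCT_SPECIES)) return(NULL)
  # annotate (never score) the water-loss ion
  iw <- find_peak(M + species_delta_mass("[M-H2O+H]+"))
  if (!is.na(iw) && cand_rel[iw] >= config$noise_floor &&
      !cand_mz[iw] %in% obs_mz) {
    species <- c(species, "[M-H2O+H]+")
    obs_mz <- c(obs_mz, cand_mz[iw]); obs_rel <- c(obs_rel, cand_rel[iw])
  }
  scored <- setdiff(species, "[M-H2O+H]+")
  base_sp <- mol[which.max(mol_rel)]
  neutral <- mean(obs_mz[match(scored, species)] -
                  vapply(scored, species_delta_mass, numeric(1)))
  list(neutral_mass = neutral,
       species = species, obs_mz = obs_mz, obs_rel = obs_rel,
       score = length(scored),
       sum_rel = sum(obs_rel[match(scored, species)]),
       base_species = base_sp,
       precursor_mz = obs_mz[match(base_sp, species)])
}

.new_assignment <- function(name, hyp = NULL, rejected = FALSE, reason = NA_character_) {
  structure(
    list(name = name,
         neutral_mass = if (is.null(hyp)) NA_real_ else hyp$neutral_mass,
         species_found = if (is.null(hyp)) data.frame(
           species = character(0), mz = numeric(0), relative_intensity = numeric(0))
           else data.frame(species = hyp$species, mz = hyp$obs_mz,
                           relative_intensity = hyp$obs_rel),
         base_species = if (is.null(hyp)) NA_character_ else hyp$base_species,
         precursor_mz = if (is.null(hyp)) NA_real_ else hyp$precursor_mz,
         score = if (is.null(hyp)) 0L else hyp$score,
         rejected = rejected, reason = reason),
    class = "molecular_ion_assignment")
}

#' Detect the molecular ion in a CI spectrum
#'
#' Scans every isotope-group monoisotopic peak above the noise floor as a
#' possible `[M-CH3]+` anchor (hypothetical M at +15.0235) and, as a
#' fallback, as a possible member of the `[M-H]+`/`[M]+`/`[M+H]+` cluster.
#' Each hypothesis is scored by the number of distinct ion species found at
#' their exact mass offsets (ties broken by summed relative intensity, then
#' by larger M). An accepted assignment needs either the `[M-CH3]+` anchor
#' plus one more species, or two members of the molecular cluster, and at
#' least one cluster member at or above `molecular_intensity_floor`.
#'
#' In strict mode, any candidate peak above the `[M+C3H5]+` position that is
#' not explained by a whitelisted species (e.g. the `[M+TMS]+` rearrangement
#' adduct) rejects the spectrum with reason `"unexplained high-mass ions"`,
#' mirroring how unexplained high-m/z ions defeat the pattern in practice.
#'
#' @param s a centroided spectrum with at least 2 peaks.
#' @param config a [detection_config()].
#' @return a `molecular_ion_assignment`: `neutral_mass` (Da),
#'   `species_found` (data.frame of species, observed m/z, relative
#'   intensity), `base_species` (most intense cluster member),
#'   `precursor_mz`, `rejected`, `reason`.
#' @examples
#' s <- spectrum(c(299.0719, 315.1031, 343.1345, 355.1342),
#'               c(100, 40, 3, 2), metadata = list(name = "phosphoric acid 3TMS"))
#' detect_molecular_ion(s)
#' @export
detect_molecular_ion <- function(s, config = detection_config()) {
  stopifnot(inherits(s, "ci_spectrum"))
  if (nrow(s$peaks) == 0L) stop("empty spectrum", call. = FALSE)
  nm <- if (is.null(s$metadata$name)) NA_character_ else s$metadata$name
  if (nrow(s$peaks) < 2L) {
    return(.new_assignment(nm, rejected = TRUE, reason = "no pattern"))
  }
  groups <- group_isotopes(s, config)
  rel <- groups$intensity / max(groups$intensity)
  cand <- groups$is_mono & rel >= config$noise_floor
  cand_mz <- groups$mz[cand]
  cand_rel <- rel[cand]

  hyps <- list()
  for (i in seq_along(cand_mz)) {
    for (anchor in c("[M-CH3]+", .MOLECULAR_SPECIES)) {
      M <- cand_mz[i] - species_delta_mass(anchor)
      h <- .evaluate_hypothesis(M, cand_mz, cand_rel, config)
      if (!is.null(h)) hyps[[length(hyps) + 1L]] <- h
    }
  }
  if (length(hyps) == 0L) {
    return(.new_assignment(nm, rejected = TRUE, reason = "no pattern"))
  }
  # dedupe hypotheses converging on the same neutral mass
  key <- round(vapply(hyps, `[[`, numeric(1), "neutral_mass") / config$mz_tolerance)
  hyps <- hyps[!duplicated(key)]
  ord <- order(-vapply(hyps, `[[`, numeric(1), "score"),
               -vapply(hyps, `[[`, numeric(1), "sum_rel"),
               -vapply(hyps, `[[`, numeric(1), "neutral_mass"))
  best <- hyps[[ord[1]]]

  # strict-mode screen for unexplained ions above [M+C3H5]+
  if (config$strict) {
    M <- best$neutral_mass
    ceiling_mz <- M + species_delta_mass("[M+C3H5]+")
    high <- cand_mz > ceiling_mz + config$mz_tolerance
    if (any(high)) {
      # whitelisted species first, so their isotopologues are explained too
      for (sp in config$higher_mz_whitelist) {
        target <- M + species_delta_mass(sp)
        hit <- abs(cand_mz[high] - target) <= config$mz_tolerance
        if (any(hit)) {
          j <- which(high)[hit][1]
          if (!cand_mz[j] %in% best$obs_mz) {
            best$species <- c(best$species, sp)
            best$obs_mz <- c(best$obs_mz, cand_mz[j])
            best$obs_rel <- c(best$obs_rel, cand_rel[j])
          }
        }
      }
      # a high peak is explained if it sits at a found (or whitelisted) ion,
      # or at an isotopologue spacing above one: a peak k nominal units up
      # is an A+k member even when grouping missed it (30Si pulls the
      # A+2 - A+1 spacing below the group window)
      explains <- function(mzv) {
        d <- mzv - best$obs_mz
        k <- round(d)
        any(abs(d) <= config$mz_tolerance |
            (k >= 1 & k <= 3 &
             d >= k * 0.9920 - config$mz_tolerance &
             d <= k * 1.0050 + config$mz_tolerance))
      }
      explained <- vapply(cand_mz[high], explains, logical(1))
      if (!all(explained)) {
        a <- .new_assignment(nm, best, rejected = TRUE,
                             reason = "unexplained high-mass ions")
        return(a)
      }
    }
  }
  .new_assignment(nm, best)
}

#' @export
print.molecular_ion_assignment <- function(x, ...) {
  if (x$rejected) {
    cat(sprintf("<assignment> %s: REJECTED (%s)\n",
                if (is.na(x$name)) "(unnamed)" else x$name, x$reason))
  } else {
    cat(sprintf("<assignment> %s: M = %.4f Da, precursor %s at m/z %.4f\n",
                if (is.na(x$name)) "(unnamed)" else x$name,
                x$neutral_mass, x$base_species, x$precursor_mz))
  }
  if (nrow(x$species_found) > 0) {
    for (k in seq_len(nrow(x$species_found))) {
      cat(sprintf("  %-11s m/z %9.4f  %5.1f%% bp\n",
                  x$species_found$species[k], x$species_found$mz[k],
                  100 * x$species_found$relative_intensity[k]))
    }
  }
  invisible(x)
}

#' Detect molecular ions for a batch of spectra
#'
#' Per-spectrum errors are captured as flagged rows (`reason = "error: ..."`),
#' never aborting the batch.
#'
#' @param spectra non-empty list of spectra.
#' @param config a [detection_config()].
#' @return list with `assignments` (list of `molecular_ion_assignment`),
#'   `table` (one data.frame row per spectrum) and `summary` (counts of base
#'   species among accepted spectra and of rejection reasons; percentages
#'   are reported against both the accepted and the total denominator, since
#'   the two conventions coexist in practice).
#' @export
batch_detect <- function(spectra, config = detection_config()) {
  spectra <- .as_spectra_list(spectra)
  if (length(spectra) == 0L) stop("empty batch", call. = FALSE)
  assignments <- vector("list", length(spectra))
  for (k in seq_along(spectra)) {
    assignments[[k]] <- tryCatch(
      detect_molecular_ion(spectra[[k]], config),
      error = function(e) {
        nm <- spectra[[k]]$metadata$name
        .new_assignment(if (is.null(nm)) NA_character_ else nm,
                        rejected = TRUE,
                        reason = paste0("error: ", conditionMessage(e)))
      })
  }
  tab <- do.call(rbind, lapply(assignments, function(a) {
    data.frame(name = a$name,
               neutral_mass = a$neutral_mass,
               precursor_mz = a$precursor_mz,
               base_species = a$base_species,
               n_species = nrow(a$species_found),
               species_found = paste(a$species_found$species, collapse = ";"),
               rejected = a$rejected,
               reason = a$reason)
  }))
  acc <- tab[!tab$rejected, , drop = FALSE]
  base_counts <- table(factor(acc$base_species, levels = .MOLECULAR_SPECIES))
  reasons <- table(tab$reason[tab$rejected])
  summary <- list(
    n_total = nrow(tab),
    n_accepted = nrow(acc),
    base_species_counts = base_counts,
    base_species_pct_of_accepted = if (nrow(acc)) base_counts / nrow(acc) else base_counts,
    base_species_pct_of_total = base_counts / nrow(tab),
    rejection_reasons = reasons)
  list(assignments = assignments, table = tab, summary = summary)
}
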