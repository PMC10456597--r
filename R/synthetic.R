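# Synthetic methane-CI spectra with known ground truth. The generator
# emulates the observed statistics of CI spectra of TMS derivatives: base
# species priors over the molecular cluster, adduct co-occurrence rates,
# occasional water loss, ~15% "hard" spectra (unexplained high-mass ions or
# intensities lost in noise), QTOF-level mass error, and optional
# unit-resolution merging of the overlapping cluster isotopologues. It makes
# no claim of instrument fidelity beyond those statistics.

#' Default compound table
#'
#' Around twenty metabolites with literature base formulas and typical
#' TMS/MEOX derivatization counts, including the three compounds used as
#' worked examples throughout the package documentation.
#'
#' @return data.frame with columns `name`, `base_formula`, `n_tms`, `n_meox`.
#' @export
default_compound_table <- function() {
  df <- data.frame(
    name = c("3,4-dihydroxyphenylacetic acid", "phosphoric acid",
             "2,5-dihydroxyphenylacetic acid", "glycine", "L-alanine",
             "L-serine", "L-threonine", "L-glutamic acid", "L-tyrosine",
             "lactic acid", "succinic acid", "fumaric acid", "malic acid",
             "citric acid", "glycerol", "urea", "uracil", "palmitic acid",
             "myo-inositol", "D-glucose", "D-fructose", "pyruvic acid"),
    base_formula = c("C8H8O4", "H3PO4", "C8H8O4", "C2H5NO2", "C3H7NO2",
                     "C3H7NO3", "C4H9NO3", "C5H9NO4", "C9H11NO3",
                     "C3H6O3", "C4H6O4", "C4H4O4", "C4H6O5", "C6H8O7",
                     "C3H8O3", "CH4N2O", "C4H4N2O2", "C16H32O2",
                     "C6H12O6", "C6H12O6", "C6H12O6", "C3H4O3"),
    n_tms = c(3L, 3L, 3L, 3L, 2L, 3L, 3L, 3L, 3L, 2L, 2L, 2L, 3L, 4L,
              3L, 2L, 2L, 1L, 6L, 5L, 5L, 1L),
    n_meox = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L,
               0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L))
  df
}

#' Simulation configuration
#'
#' Defaults state the world the generator emulates: 74%/7%/4% of spectra
#' have `[M+H]+`/`[M-H]+`/`[M]+` as the most intense molecular species and
#' 15% are "hard" (either carrying unexplained ions above `[M+C3H5]+`,
#' 37/51 of the hard mass, or too weak to rise above noise, 14/51); the
#' `[M-CH3]+` fragment appears in 84% of spectra, with `[M+C2H5]+` and
#' `[M+C3H5]+` co-occurring 90% and 84% of the time given `[M-CH3]+`; water
#' loss appears in 6%; mass error is Gaussian with sd 2.8 ppm.
#'
#' @param seed integer seed fixing the full output stream, or `NULL`.
#' @param p_base_species named probabilities for the base species of
#'   well-behaved spectra (need not sum to 1; the remainder to 1 is the
#'   probability of a "hard" spectrum).
#' @param p_hard_contaminant given a hard spectrum, probability it is of the
#'   unexplained-high-mass kind (the rest are too-weak spectra).
#' @param p_m_minus_ch3 probability the `[M-CH3]+` fragment is present.
#' @param p_c2h5,p_c3h5 adduct probabilities given `[M-CH3]+`.
#' @param p_water_loss probability of a `[M-H2O+H]+` ion.
#' @param p_tms_adduct probability of a benign `[M+TMS]+` adduct on
#'   well-behaved spectra (default 0; hard contaminant spectra always get
#'   one).
#' @param mass_error_sd_ppm Gaussian m/z jitter, ppm.
#' @param noise_mean_peaks Poisson mean count of noise peaks, placed below
#'   the molecular region (real contaminants above `[M+C3H5]+` are produced
#'   only by the hard-contaminant mechanism, so strict-mode rejection is
#'   attributable).
#' @param noise_intensity_range relative-intensity range of noise peaks.
#' @param max_isotope_shift isotopologue depth per ion (default 2).
#' @param merge_isotope_clusters sum the molecular-cluster isotopologues
#'   into shared unit-resolution bins, reproducing the 13C overlap between
#'   adjacent cluster species that a QTOF cannot resolve.
#' @param clean noise-free mode: all six canonical species, zero mass error,
#'   monoisotopic peaks only; used for exact worked examples.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = NULL,
                              p_base_species = c("[M+H]+" = 0.74,
                                                 "[M-H]+" = 0.07,
                                                 "[M]+" = 0.04),
                              p_hard_contaminant = 37 / 51,
                              p_m_minus_ch3 = 290 / 345,
                              p_c2h5 = 0.90, p_c3h5 = 0.84,
                              p_water_loss = 0.06,
                              p_tms_adduct = 0,
                              mass_error_sd_ppm = 2.8,
                              noise_mean_peaks = 5,
                              noise_intensity_range = c(0.001, 0.02),
                              max_isotope_shift = 2L,
                              merge_isotope_clusters = FALSE,
                              clean = FALSE) {
  probs <- c(p_base_species, p_hard_contaminant, p_m_minus_ch3, p_c2h5,
             p_c3h5, p_water_loss, p_tms_adduct)
  if (any(probs < 0) || any(probs > 1) || sum(p_base_species) > 1 + 1e-9) {
    stop("probabilities must lie in [0, 1] and base-species priors must sum to <= 1",
         call. = FALSE)
  }
  stopifnot(all(names(p_base_species) %in% .MOLECULAR_SPECIES),
            mass_error_sd_ppm >= 0, max_isotope_shift >= 0L)
  structure(list(seed = seed, p_base_species = p_base_species,
                 p_hard_contaminant = p_hard_contaminant,
                 p_m_minus_ch3 = p_m_minus_ch3, p_c2h5 = p_c2h5,
                 p_c3h5 = p_c3h5, p_water_loss = p_water_loss,
                 p_tms_adduct = p_tms_adduct,
                 mass_error_sd_ppm = mass_error_sd_ppm,
                 noise_mean_peaks = noise_mean_peaks,
                 noise_intensity_range = noise_intensity_range,
                 max_isotope_shift = as.integer(max_isotope_shift),
                 merge_isotope_clusters = isTRUE(merge_isotope_clusters),
                 clean = isTRUE(clean)),
            class = "simulation_config")
}

# log-uniform draw within a relative-intensity band
.runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Simulate one CI spectrum
#'
#' @param compound a [derivatized_compound()] (or a row-like list with
#'   `name`, `base_formula`, `n_tms`, `n_meox`).
#' @param config a [simulation_config()]. If `config$seed` is set, the RNG
#'   is seeded here, making the call self-contained and reproducible.
#' @return list with `spectrum` (a [spectrum()]) and `truth` (one-row
#'   data.frame: name, formula, neutral_mass, base_species,
#'   has_m_minus_ch3, contaminant, weak).
#' @export
simulate_spectrum <- function(compound, config = simulation_config()) {
  if (!inherits(compound, "derivatized_compound")) {
    compound <- derivatized_compound(compound$name, compound$base_formula,
                                     compound$n_tms, compound$n_meox)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  M <- compound$formula
  neutral_mass <- compound$neutral_mass
  label <- sprintf("%s %dTMS%s", compound$name, compound$n_tms,
                   if (compound$n_meox > 0)
                     sprintf(" %dMEOX", compound$n_meox) else "")

  if (config$clean) {
    species <- c("[M-CH3]+", "[M-H]+", "[M]+", "[M+H]+",
                 "[M+C2H5]+", "[M+C3H5]+")
    inten <- c(100, 8, 10, 40, 3, 2)
    mz <- vapply(species, function(sp) ion_mz(M, sp), numeric(1))
    s <- spectrum(mz, inten, metadata = list(name = label))
    truth <- data.frame(name = label, formula = format_formula(M),
                        neutral_mass = neutral_mass,
                        base_species = "[M+H]+", has_m_minus_ch3 = TRUE,
                        contaminant = FALSE, weak = FALSE)
    return(list(spectrum = s, truth = truth))
  }

  # spectrum category
  p_hard <- 1 - sum(config$p_base_species)
  u <- stats::runif(1)
  hard <- u < p_hard
  contaminant <- hard && stats::runif(1) < config$p_hard_contaminant
  weak <- hard && !contaminant
  base_species <- sample(names(config$p_base_species), 1,
                         prob = config$p_base_species)

  # ion set with monoisotopic relative intensities
  sp_int <- c()
  base_level <- stats::runif(1, 0.15, 0.9)
  others <- setdiff(.MOLECULAR_SPECIES, base_species)
  sp_int[base_species] <- base_level
  sp_int[others] <- base_level * stats::runif(2, 0.2, 0.8)
  has_mch3 <- stats::runif(1) < config$p_m_minus_ch3
  if (has_mch3) {
    sp_int["[M-CH3]+"] <- 1.0
    if (stats::runif(1) < config$p_c2h5)
      sp_int["[M+C2H5]+"] <- .runif_log(1, 0.005, 0.045)
    if (stats::runif(1) < config$p_c3h5)
      sp_int["[M+C3H5]+"] <- .runif_log(1, 0.005, 0.045)
  }
  if (stats::runif(1) < config$p_water_loss)
    sp_int["[M-H2O+H]+"] <- .runif_log(1, 0.01, 0.1)
  if (contaminant || stats::runif(1) < config$p_tms_adduct)
    sp_int["[M+TMS]+"] <- stats::runif(1, 0.05, 0.2)

  # expand each ion to its isotopologues
  mk_peaks <- function(sp, inten) {
    pat <- ion_isotope_pattern(M, sp, max_shift = config$max_isotope_shift)
    data.frame(mz = pat$mass, intensity = inten * pat$abundance / pat$abundance[1],
               cluster = if (sp %in% .MOLECULAR_SPECIES) "mol" else sp)
  }
  pk <- do.call(rbind, lapply(names(sp_int), function(sp)
    mk_peaks(sp, sp_int[[sp]])))

  if (config$merge_isotope_clusters) {
    mol <- pk[pk$cluster == "mol", , drop = FALSE]
    rest <- pk[pk$cluster != "mol", , drop = FALSE]
    bin <- round(mol$mz)
    merged <- do.call(rbind, lapply(split(mol, bin), function(d) {
      data.frame(mz = sum(d$mz * d$intensity) / sum(d$intensity),
                 intensity = sum(d$intensity), cluster = "mol")
    }))
    pk <- rbind(rest, merged)
  }
  pk$cluster <- NULL

  if (weak) {
    # molecular pattern drowned in noise: shrink it and let a noise peak
    # dominate the spectrum
    pk$intensity <- pk$intensity * stats::runif(1, 2e-4, 8e-4)
    pk <- rbind(pk, data.frame(mz = stats::runif(1, 50, neutral_mass - 30),
                               intensity = 1.0))
  }

  # noise peaks, kept below the molecular region
  n_noise <- stats::rpois(1, config$noise_mean_peaks)
  if (n_noise > 0) {
    pk <- rbind(pk, data.frame(
      mz = stats::runif(n_noise, 50, max(60, neutral_mass - 30)),
      intensity = .runif_log(n_noise, config$noise_intensity_range[1],
                             config$noise_intensity_range[2])))
  }

  # QTOF mass error
  if (config$mass_error_sd_ppm > 0) {
    pk$mz <- pk$mz * (1 + stats::rnorm(nrow(pk), 0,
                                       config$mass_error_sd_ppm * 1e-6))
  }
  pk$intensity <- 100 * pk$intensity / max(pk$intensity)

  s <- spectrum(pk$mz, pk$intensity, metadata = list(name = label))
  truth <- data.frame(name = label, formula = format_formula(M),
                      neutral_mass = neutral_mass,
                      base_species = base_species,
                      has_m_minus_ch3 = has_mch3,
                      contaminant = contaminant, weak = weak)
  list(spectrum = s, truth = truth)
}

#' Simulate a spectral library with ground truth
#'
#' Draws `n` spectra from `compound_table` (with replacement, uniform over
#' rows), appending a running index to each record name so joins on name are
#' unique. Optionally writes an MSP file and a ground-truth CSV directly
#' usable by the detect/assign/evaluate pipeline.
#'
#' @param compound_table data.frame like [default_compound_table()].
#' @param n number of spectra (>= 1).
#' @param config a [simulation_config()]; its `seed` is applied once, before
#'   the first spectrum.
#' @param msp_path,truth_path optional output file paths.
#' @return list with `spectra` (list of spectra) and `truth` (data.frame).
#' @export
simulate_library <- function(compound_table = default_compound_table(), n,
                             config = simulation_config(),
                             msp_path = NULL, truth_path = NULL) {
  if (nrow(compound_table) == 0L) stop("empty compound table", call. = FALSE)
  stopifnot(n >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  inner <- config
  inner$seed <- NULL
  idx <- sample.int(nrow(compound_table), n, replace = TRUE)
  spectra <- vector("list", n)
  truth <- vector("list", n)
  for (k in seq_len(n)) {
    row <- compound_table[idx[k], ]
    sim <- simulate_spectrum(row, inner)
    uid <- sprintf("%s#%04d", sim$truth$name, k)
    sim$spectrum$metadata$name <- uid
    sim$truth$name <- uid
    spectra[[k]] <- sim$spectrum
    truth[[k]] <- sim$truth
  }
  truth <- do.call(rbind, truth)
  if (!is.null(msp_path)) write_msp(spectra, msp_path)
  if (!is.null(truth_path)) utils::write.csv(truth, truth_path,
                                             row.names = FALSE)
  list(spectra = spectra, truth = truth)
}
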