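# Ion species observed for TMS derivatives under methane CI. Every species
# is a singly charged cation; its delta is a signed formula change relative
# to the neutral molecule M, kept as separate "add" and "subtract" bags so
# ordinary formula arithmetic (which forbids negative counts) applies.
.ION_SPECIES <- list(
  "[M-CH3]+"   = list(add = c(),                     sub = c(C = 1L, H = 3L)),
  "[M-H]+"     = list(add = c(),                     sub = c(H = 1L)),
  "[M]+"       = list(add = c(),                     sub = c()),
  "[M+H]+"     = list(add = c(H = 1L),               sub = c()),
  "[M+C2H5]+"  = list(add = c(C = 2L, H = 5L),       sub = c()),
  "[M+C3H5]+"  = list(add = c(C = 3L, H = 5L),       sub = c()),
  "[M+TMS]+"   = list(add = c(C = 3L, H = 9L, Si = 1L), sub = c()),
  "[M-H2O+H]+" = list(add = c(H = 1L),               sub = c(H = 2L, O = 1L))
)

# the molecular-ion cluster centered on intact M
.MOLECULAR_SPECIES <- c("[M-H]+", "[M]+", "[M+H]+")
# reagent-gas adducts used as confirming evidence
.ADDUCT_SPECIES <- c("[M+C2H5]+", "[M+C3H5]+")

#' Known ion species labels
#'
#' The methane-CI species recognized for TMS derivatives: the methyl-loss
#' fragment `[M-CH3]+`, the molecular cluster `[M-H]+`/`[M]+`/`[M+H]+`, the
#' reagent adducts `[M+C2H5]+`/`[M+C3H5]+`, the rearrangement adduct
#' `[M+TMS]+`, and the water-loss ion `[M-H2O+H]+`.
#'
#' @return character vector of labels.
#' @export
ion_species_labels <- function() names(.ION_SPECIES)

.check_species <- function(species) {
  if (!species %in% names(.ION_SPECIES)) {
    stop("unknown ion species '", species, "'; known: ",
         paste(names(.ION_SPECIES), collapse = ", "), call. = FALSE)
  }
  species
}

#' Mass delta of an ion species relative to neutral M
#'
#' @param species a label from [ion_species_labels()].
#' @param electron_correction subtract the electron mass from the cation?
#'   Default `FALSE`: the convention here is that cation m/z equals plain
#'   neutral-formula arithmetic, which is how theoretical values are tabulated
#'   for this instrument class.
#' @return signed mass delta in Da.
#' @export
species_delta_mass <- function(species, electron_correction = FALSE) {
  .check_species(species)
  sp <- .ION_SPECIES[[species]]
  add <- if (length(sp$add)) sum(sp$add * .MONO_MASS[names(sp$add)]) else 0
  sub <- if (length(sp$sub)) sum(sp$sub * .MONO_MASS[names(sp$sub)]) else 0
  add - sub - if (electron_correction) .ELECTRON_MASS else 0
}

#' Ion formula for a neutral molecule and species
#'
#' @param neutral neutral formula (object or Hill string).
#' @inheritParams species_delta_mass
#' @return the cation's `elemental_formula`.
#' @export
ion_formula <- function(neutral, species) {
  .check_species(species)
  neutral <- as_formula(neutral)
  sp <- .ION_SPECIES[[species]]
  out <- neutral
  if (length(sp$add)) out <- formula_add(out, elemental_formula(sp$add))
  if (length(sp$sub)) {
    out <- tryCatch(formula_subtract(out, elemental_formula(sp$sub)),
                    error = function(e) {
                      stop("species ", species, " not applicable to ",
                           format_formula(neutral), ": ", conditionMessage(e),
                           call. = FALSE)
                    })
  }
  out
}

#' Theoretical m/z of an ion species
#'
#' All species are singly charged, so m/z equals the ion mass. By default no
#' electron-mass correction is applied (see [species_delta_mass()]).
#'
#' @inheritParams ion_formula
#' @inheritParams species_delta_mass
#' @return m/z in Da.
#' @examples
#' ion_mz("C17H32O4Si3", "[M-CH3]+") # 369.1374
#' ion_mz("C9H27O4PSi3", "[M+H]+")   # 315.1033
#' @export
ion_mz <- function(neutral, species, electron_correction = FALSE) {
  f <- ion_formula(neutral, species) # validates applicability
  monoisotopic_mass(f) - if (electron_correction) .ELECTRON_MASS else 0
}

# delta in Da for detection arithmetic where no formula is known
.species_mz_from_neutral_mass <- function(neutral_mass, species) {
  neutral_mass + species_delta_mass(species)
}
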