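# Per-element isotopologue distribution aggregated on nominal-mass shift,
# built by convolving one atom at a time. Each bin k holds the summed
# probability of all isotopologues whose nominal mass exceeds the
# monoisotopic nominal mass by k, and the abundance-weighted mean exact mass.

.atom_dist <- function(sym) {
  el <- .ISOTOPES[[sym]]
  shift <- round(el$mass) - round(el$mass[1])
  list(shift = shift, mass = el$mass, p = el$abundance)
}

# convolve a binned distribution (p, m = weighted mass) with one atom
.convolve_atom <- function(p, m, atom, max_shift) {
  n <- max_shift + 1L
  p2 <- numeric(n)
  pm2 <- numeric(n) # probability-weighted mass accumulator
  for (j in seq_along(atom$p)) {
    s <- atom$shift[j]
    if (s > max_shift) next
    idx <- seq_len(n - s)
    p2[idx + s] <- p2[idx + s] + p[idx] * atom$p[j]
    pm2[idx + s] <- pm2[idx + s] + (p[idx] * (m[idx] + atom$mass[j])) * atom$p[j]
  }
  list(p = p2, m = ifelse(p2 > 0, pm2 / p2, 0))
}

#' Isotope pattern of a formula
#'
#' Aggregated isotopologue distribution of a formula, binned by nominal-mass
#' shift relative to the monoisotopic peak (A, A+1, A+2, ...). Contributions
#' that share a nominal shift (e.g. 13C and 29Si within A+1) are merged,
#' which is what a unit-resolution grouping of centroided peaks observes.
#' Truncated at `max_shift` and renormalized to sum to 1.
#'
#' @param f formula (object or Hill string).
#' @param max_shift largest nominal shift retained (default 3).
#' @return data.frame with columns `shift`, `mass` (abundance-weighted exact
#'   mass of the bin, Da) and `abundance` (summing to 1).
#' @examples
#' isotope_pattern("C", max_shift = 1) # 0.9893 / 0.0107
#' @export
isotope_pattern <- function(f, max_shift = 3L) {
  f <- as_formula(f)
  if (max_shift < 0) stop("max_shift must be >= 0", call. = FALSE)
  n <- max_shift + 1L
  p <- c(1, numeric(max_shift))
  m <- numeric(n)
  for (sym in names(f)) {
    cnt <- f[[sym]]
    if (cnt == 0L) next
    atom <- .atom_dist(sym)
    for (i in seq_len(cnt)) {
      res <- .convolve_atom(p, m, atom, max_shift)
      p <- res$p; m <- res$m
    }
  }
  keep <- p > 0
  p <- p[keep] / sum(p[keep])
  data.frame(shift = (seq_len(n) - 1L)[keep], mass = m[keep], abundance = p)
}

#' Isotope pattern of an ion
#'
#' Convenience wrapper: pattern of the cation formula, with bin masses
#' reported on the m/z scale (no electron correction by default).
#'
#' @inheritParams ion_mz
#' @param max_shift largest nominal shift retained.
#' @export
ion_isotope_pattern <- function(neutral, species, max_shift = 3L,
                                electron_correction = FALSE) {
  pat <- isotope_pattern(ion_formula(neutral, species), max_shift)
  if (electron_correction) pat$mass <- pat$mass - .ELECTRON_MASS
  pat
}
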