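# Monoisotopic masses and isotope abundances.
# Values: CODATA/NIST Atomic Weights and Isotopic Compositions (2021),
# truncated at >= 9 decimals. The first row of each element is the most
# abundant (monoisotopic) isotope.
.ELEMENTS <- c("C", "H", "N", "O", "P", "S", "Si")

.MONO_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Si = 27.9769265325
)

.ELECTRON_MASS <- 0.000548579909

.ISOTOPES <- list(
  H  = list(mass = c(1.00782503207, 2.01410177785),
            abundance = c(0.999885, 0.000115)),
  C  = list(mass = c(12.0, 13.0033548378),
            abundance = c(0.9893, 0.0107)),
  N  = list(mass = c(14.0030740048, 15.0001088982),
            abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.9949146196, 16.9991317012, 17.9991610041),
            abundance = c(0.99757, 0.00038, 0.00205)),
  P  = list(mass = 30.97376163, abundance = 1.0),
  S  = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Si = list(mass = c(27.9769265325, 28.9764946653, 29.9737701370),
            abundance = c(0.92223, 0.04685, 0.03092))
)

#' Construct an elemental formula
#'
#' An elemental formula is a named integer vector of element counts over the
#' supported set C, H, N, O, P, S, Si, carried in Hill order (carbon first,
#' then hydrogen, then the remaining elements alphabetically). All arithmetic
#' on formulas is element-wise.
#'
#' @param ... element counts by name, e.g. `elemental_formula(C = 17, H = 32,
#'   O = 4, Si = 3)`, or a single named numeric vector.
#' @return an object of class `elemental_formula`.
#' @examples
#' elemental_formula(C = 8, H = 8, O = 4)
#' @export
elemental_formula <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    counts <- args[[1]]
  } else {
    counts <- unlist(args)
  }
  if (length(counts) == 0L) counts <- integer(0)
  syms <- names(counts)
  bad <- setdiff(syms, .ELEMENTS)
  if (length(bad) > 0L) {
    stop("unsupported element symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  full <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  full[syms] <- as.integer(round(counts))
  structure(full, class = "elemental_formula")
}

.hill_order <- function() c("C", "H", "N", "O", "P", "S", "Si")

#' Parse a Hill-order formula string
#'
#' @param x a string such as `"C17H32O4Si3"`. An empty string is the empty
#'   formula.
#' @return an `elemental_formula`.
#' @examples
#' parse_formula("C9H27O4PSi3")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  if (x == "" || x == "0") return(elemental_formula())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", x)[[1]]
  tokens <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  if (sum(nchar(tokens)) != nchar(x)) {
    stop("cannot parse formula string: '", x, "'", call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", tokens)
  nums <- sub("^[A-Z][a-z]?", "", tokens)
  cnt <- ifelse(nums == "", 1L, suppressWarnings(as.integer(nums)))
  counts <- tapply(cnt, syms, sum)
  elemental_formula(stats::setNames(as.integer(counts), names(counts)))
}

#' Format a formula as a Hill-order string
#'
#' @param f an `elemental_formula`.
#' @return a string; the empty formula formats as `""`.
#' @export
format_formula <- function(f) {
  f <- as_formula(f)
  parts <- character(0)
  for (sym in .hill_order()) {
    n <- f[[sym]]
    if (n == 0L) next
    parts <- c(parts, paste0(sym, if (n > 1L) n else ""))
  }
  paste(parts, collapse = "")
}

#' @export
format.elemental_formula <- function(x, ...) format_formula(x)

#' @export
print.elemental_formula <- function(x, ...) {
  s <- format_formula(x)
  cat("<formula> ", if (s == "") "(empty)" else s,
      sprintf("  [%.6f Da]\n", monoisotopic_mass(x)), sep = "")
  invisible(x)
}

as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  if (is.numeric(f) && !is.null(names(f))) return(elemental_formula(f))
  stop("cannot interpret object as an elemental formula", call. = FALSE)
}

#' Formula addition and subtraction
#'
#' Element-wise; subtraction that would drive any count negative is an error
#' (formulas are bags of atoms, not signed vectors).
#'
#' @param f,g formulas (objects, strings, or named count vectors).
#' @return an `elemental_formula`.
#' @export
formula_add <- function(f, g) {
  f <- as_formula(f); g <- as_formula(g)
  elemental_formula(unclass(f) + unclass(g))
}

#' @rdname formula_add
#' @export
formula_subtract <- function(f, g) {
  f <- as_formula(f); g <- as_formula(g)
  d <- unclass(f) - unclass(g)
  if (any(d < 0)) {
    bad <- names(d)[d < 0]
    stop("subtraction yields negative count for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  elemental_formula(d)
}

#' @export
`+.elemental_formula` <- function(e1, e2) formula_add(e1, e2)

#' @export
`-.elemental_formula` <- function(e1, e2) formula_subtract(e1, e2)

#' @export
`==.elemental_formula` <- function(e1, e2) {
  all(unclass(as_formula(e1)) == unclass(as_formula(e2)))
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the most-abundant-isotope mass. The empty
#' formula has mass 0.
#'
#' @param f formula (object or Hill string).
#' @return mass in Da.
#' @examples
#' monoisotopic_mass("C17H32O4Si3") # 384.1608
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula(f)
  sum(unclass(f) * .MONO_MASS[names(f)])
}

# net composition change per TMS group: -H +Si(CH3)3
.TMS_NET <- c(C = 3L, H = 8L, Si = 1L)
# net composition change per methoximation: C=O -> C=N-OCH3, i.e. +CH3N
.MEOX_NET <- c(C = 1L, H = 3L, N = 1L)

#' Derivatized formula from base formula and group counts
#'
#' Each trimethylsilyl (TMS) group replaces one active hydrogen with
#' Si(CH3)3, a net change of +C3H8Si (+72.0395 Da). Each methoximation
#' (MEOX) converts a carbonyl to a methyloxime, a net change of +CH3N
#' (+29.0266 Da). The number of groups is taken as input; perception of
#' active hydrogens from structure is out of scope.
#'
#' @param base base formula of the underivatized compound.
#' @param n_tms number of TMS groups (each consumes one hydrogen of `base`).
#' @param n_meox number of methoxime groups.
#' @return the derivatized `elemental_formula`.
#' @examples
#' derivatize("C8H8O4", n_tms = 3) # C17H32O4Si3
#' @export
derivatize <- function(base, n_tms = 0L, n_meox = 0L) {
  base <- as_formula(base)
  if (n_tms < 0 || n_meox < 0) stop("group counts must be >= 0", call. = FALSE)
  if (base[["H"]] < n_tms) {
    stop("base formula has ", base[["H"]], " hydrogens but ", n_tms,
         " TMS groups were requested (each replaces one active H)",
         call. = FALSE)
  }
  out <- unclass(base)
  out[names(.TMS_NET)] <- out[names(.TMS_NET)] + n_tms * .TMS_NET
  out[names(.MEOX_NET)] <- out[names(.MEOX_NET)] + n_meox * .MEOX_NET
  elemental_formula(out)
}

#' A derivatized compound record
#'
#' @param name compound name.
#' @param base_formula base (underivatized) formula.
#' @param n_tms,n_meox derivatization group counts.
#' @return a `derivatized_compound` list with the derivatized formula and its
#'   neutral monoisotopic mass precomputed.
#' @export
derivatized_compound <- function(name, base_formula, n_tms = 0L, n_meox = 0L) {
  base <- as_formula(base_formula)
  deriv <- derivatize(base, n_tms, n_meox)
  structure(
    list(name = name, base_formula = base, n_tms = as.integer(n_tms),
         n_meox = as.integer(n_meox), formula = deriv,
         neutral_mass = monoisotopic_mass(deriv)),
    class = "derivatized_compound")
}

#' @export
print.derivatized_compound <- function(x, ...) {
  cat(sprintf("<compound> %s: %s + %dTMS + %dMEOX -> %s (%.4f Da)\n",
              x$name, format_formula(x$base_formula), x$n_tms, x$n_meox,
              format_formula(x$formula), x$neutral_mass))
  invisible(x)
}
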