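# Readers and writers for the text formats the CI workflow touches:
# NIST-style MSP in/out, flat CSV out, MGF out (precursor-annotated), and
# the SIRIUS ".ms" input format. All writers are deterministic byte-for-byte
# for a fixed input; encoding is UTF-8 with "." as the decimal mark.

#' Read spectra from an MSP file
#'
#' Accepts NIST-style MSP: records start with `Name:`, carry arbitrary
#' `Key: value` header fields (preserved verbatim), then `Num Peaks: N`
#' followed by N m/z-intensity pairs separated by whitespace or semicolons,
#' records separated by blank lines.
#'
#' @param path file path (or connection) to read.
#' @return list of [spectrum()] objects; empty input gives an empty list.
#' @export
read_msp <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    # header block
    meta <- list()
    num_peaks <- NA_integer_
    record_name <- NULL
    while (i <= n && trimws(lines[i]) != "") {
      ln <- lines[i]
      m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
      if (length(m) == 0L) {
        stop("line ", i, ": expected 'Key: value' header, got '", ln, "'",
             call. = FALSE)
      }
      key <- trimws(m[2]); val <- m[3]
      if (tolower(key) == "num peaks") {
        num_peaks <- suppressWarnings(as.integer(val))
        if (is.na(num_peaks)) {
          stop("line ", i, ": unparseable Num Peaks value '", val, "'",
               call. = FALSE)
        }
        i <- i + 1L
        break
      }
      if (tolower(key) == "name") {
        record_name <- val
        meta$name <- val
      } else {
        meta[[key]] <- val
      }
      i <- i + 1L
    }
    if (is.na(num_peaks)) {
      stop("record '", if (is.null(record_name)) "?" else record_name,
           "': missing 'Num Peaks' line", call. = FALSE)
    }
    # peak block: read until blank line or EOF, tokens are "mz int" pairs
    mz <- numeric(0); inten <- numeric(0)
    while (i <= n && trimws(lines[i]) != "") {
      toks <- strsplit(gsub(";", " ", lines[i]), "[[:space:]]+")[[1]]
      toks <- toks[toks != ""]
      if (length(toks) %% 2L != 0L) {
        stop("line ", i, ": odd number of peak tokens", call. = FALSE)
      }
      vals <- suppressWarnings(as.numeric(toks))
      if (any(is.na(vals))) {
        stop("line ", i, ": unparseable peak pair in '", lines[i], "'",
             call. = FALSE)
      }
      k <- length(vals) / 2L
      mz <- c(mz, vals[2L * seq_len(k) - 1L])
      inten <- c(inten, vals[2L * seq_len(k)])
      i <- i + 1L
    }
    if (length(mz) != num_peaks) {
      stop("record '", if (is.null(record_name)) "?" else record_name,
           "': declared Num Peaks ", num_peaks, " but found ", length(mz),
           call. = FALSE)
    }
    spectra[[length(spectra) + 1L]] <- spectrum(mz, inten, metadata = meta)
  }
  spectra
}

.fmt_num <- function(x, digits = 9) {
  # fixed, locale-independent numeric formatting; trailing zeros trimmed
  s <- formatC(x, format = "f", digits = digits)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Write spectra to MSP
#'
#' Emits `Name:` first, other metadata keys in their stored order, then
#' `Num Peaks:` and one `mz intensity` pair per line.
#'
#' @param spectra list of [spectrum()] objects (a bare spectrum is accepted).
#' @param path output file path; use `""` to return the text invisibly only.
#' @return the text lines, invisibly.
#' @export
write_msp <- function(spectra, path = "") {
  spectra <- .as_spectra_list(spectra)
  out <- character(0)
  for (s in spectra) {
    meta <- s$metadata
    nm <- if (is.null(meta$name)) "unknown" else meta$name
    out <- c(out, paste0("Name: ", nm))
    for (key in setdiff(names(meta), "name")) {
      out <- c(out, paste0(key, ": ", meta[[key]]))
    }
    out <- c(out, paste0("Num Peaks: ", nrow(s$peaks)))
    if (nrow(s$peaks) > 0) {
      out <- c(out, paste(.fmt_num(s$peaks$mz), .fmt_num(s$peaks$intensity)))
    }
    out <- c(out, "")
  }
  if (!identical(path, "")) writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

#' Write spectra to flat CSV
#'
#' One row per peak with columns `name`, `mz`, `intensity`; names containing
#' commas or quotes are quoted per the CSV standard.
#'
#' @inheritParams write_msp
#' @return the data.frame written, invisibly.
#' @export
write_spectra_csv <- function(spectra, path = "") {
  spectra <- .as_spectra_list(spectra)
  rows <- lapply(spectra, function(s) {
    if (nrow(s$peaks) == 0L) return(NULL)
    nm <- if (is.null(s$metadata$name)) "unknown" else s$metadata$name
    data.frame(name = nm, mz = s$peaks$mz, intensity = s$peaks$intensity)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(name = character(0), mz = numeric(0),
                                    intensity = numeric(0))
  if (!identical(path, "")) {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(df)
}

#' Write assigned spectra to MGF
#'
#' Each spectrum must carry a molecular-ion assignment (see
#' [detect_molecular_ion()]); its precursor m/z becomes `PEPMASS`, the
#' compound name the `TITLE`, and the charge is fixed at `1+`.
#'
#' @param spectra list of spectra.
#' @param assignments list of `molecular_ion_assignment` objects, parallel to
#'   `spectra` (or a single one for a single spectrum).
#' @param path output file path; `""` returns text only.
#' @return the text lines, invisibly.
#' @export
write_mgf <- function(spectra, assignments, path = "") {
  spectra <- .as_spectra_list(spectra)
  if (inherits(assignments, "molecular_ion_assignment")) {
    assignments <- list(assignments)
  }
  if (length(assignments) != length(spectra)) {
    stop("need one assignment per spectrum", call. = FALSE)
  }
  out <- character(0)
  for (k in seq_along(spectra)) {
    s <- spectra[[k]]; a <- assignments[[k]]
    if (is.null(a) || !inherits(a, "molecular_ion_assignment") || a$rejected) {
      stop("spectrum ", k, " has no accepted molecular-ion assignment",
           call. = FALSE)
    }
    nm <- if (is.null(s$metadata$name)) "unknown" else s$metadata$name
    out <- c(out,
             "BEGIN IONS",
             paste0("TITLE=", nm),
             paste0("PEPMASS=", .fmt_num(a$precursor_mz, 5)),
             "CHARGE=1+",
             paste(.fmt_num(s$peaks$mz), .fmt_num(s$peaks$intensity)),
             "END IONS",
             "")
  }
  if (!identical(path, "")) writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

#' Write a SIRIUS MS input file
#'
#' Emits the minimal `.ms` grammar consumed by SIRIUS: `>compound`,
#' `>parentmass`, `>ionization` (the assigned adduct text) and a `>ms1` peak
#' block. Output is bit-stable for fixed input.
#'
#' @param s a spectrum.
#' @param assignment an accepted `molecular_ion_assignment`.
#' @param formula_hint optional neutral formula written as `>formula`.
#' @param path output file path; `""` returns text only.
#' @return the text lines, invisibly.
#' @export
write_sirius_ms <- function(s, assignment, formula_hint = NULL, path = "") {
  stopifnot(inherits(s, "ci_spectrum"))
  if (is.null(assignment) || !inherits(assignment, "molecular_ion_assignment") ||
      assignment$rejected) {
    stop("an accepted molecular-ion assignment is required", call. = FALSE)
  }
  nm <- if (is.null(s$metadata$name)) "unknown" else s$metadata$name
  out <- c(
    paste0(">compound ", nm),
    paste0(">parentmass ", .fmt_num(assignment$precursor_mz, 5)),
    paste0(">ionization ", assignment$base_species)
  )
  if (!is.null(formula_hint)) {
    out <- c(out, paste0(">formula ", format_formula(as_formula(formula_hint))))
  }
  out <- c(out, "", ">ms1",
           paste(.fmt_num(s$peaks$mz), .fmt_num(s$peaks$intensity)))
  if (!identical(path, "")) writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

.as_spectra_list <- function(spectra) {
  if (inherits(spectra, "ci_spectrum")) return(list(spectra))
  if (!is.list(spectra) || !all(vapply(spectra, inherits, TRUE, "ci_spectrum"))) {
    stop("expected a ci_spectrum or a list of them", call. = FALSE)
  }
  spectra
}
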