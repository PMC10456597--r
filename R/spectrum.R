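#' Construct a centroided spectrum
#'
#' The unit of all detection work: an ordered peak list plus free-form
#' metadata. Peaks are sorted ascending by m/z at construction; intensities
#' are kept in the units given (normalization to the base peak happens only
#' inside detection).
#'
#' @param mz numeric vector of m/z values (Da).
#' @param intensity numeric vector of non-negative intensities.
#' @param metadata named list of free-text fields (`name`, retention index,
#'   etc.), preserved verbatim by the writers.
#' @return an object of class `ci_spectrum`.
#' @export
spectrum <- function(mz, intensity, metadata = list()) {
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length", call. = FALSE)
  }
  if (any(intensity < 0)) stop("negative intensities", call. = FALSE)
  if (any(!is.finite(mz)) || any(!is.finite(intensity))) {
    stop("non-finite peak values", call. = FALSE)
  }
  ord <- order(mz)
  structure(
    list(peaks = data.frame(mz = as.numeric(mz[ord]),
                            intensity = as.numeric(intensity[ord])),
         metadata = metadata),
    class = "ci_spectrum")
}

#' @export
print.ci_spectrum <- function(x, ...) {
  nm <- x$metadata$name
  cat(sprintf("<spectrum> %s: %d peaks", if (is.null(nm)) "(unnamed)" else nm,
              nrow(x$peaks)))
  if (nrow(x$peaks) > 0) {
    bp <- base_peak(x)
    cat(sprintf(", m/z %.4f-%.4f, base peak %.4f",
                min(x$peaks$mz), max(x$peaks$mz), bp$mz))
  }
  cat("\n")
  invisible(x)
}

#' Base peak of a spectrum
#'
#' @param s a `ci_spectrum` with at least one peak.
#' @return list with `mz` and `intensity` of the most intense peak (first by
#'   m/z on ties).
#' @export
base_peak <- function(s) {
  stopifnot(inherits(s, "ci_spectrum"))
  if (nrow(s$peaks) == 0L) stop("empty spectrum has no base peak", call. = FALSE)
  i <- which.max(s$peaks$intensity)
  list(mz = s$peaks$mz[i], intensity = s$peaks$intensity[i])
}

# relative intensities on a 0..1 base-peak scale
.relative_intensity <- function(s) {
  bp <- base_peak(s)
  s$peaks$intensity / bp$intensity
}

#' @export
length.ci_spectrum <- function(x) nrow(x$peaks)
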