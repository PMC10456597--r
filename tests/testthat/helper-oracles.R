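# Independent oracles. These deliberately use different algorithms from the
# package code paths they check: exhaustive enumeration instead of
# incremental convolution, plain nested loops instead of pruned recursion,
# and a from-scratch MGF parser.

# --- isotope pattern oracle: exact multinomial enumeration ------------------
.oracle_iso <- list(
  H  = list(m = c(1.00782503207, 2.01410177785), p = c(0.999885, 0.000115)),
  C  = list(m = c(12.0, 13.0033548378), p = c(0.9893, 0.0107)),
  N  = list(m = c(14.0030740048, 15.0001088982), p = c(0.99636, 0.00364)),
  O  = list(m = c(15.9949146196, 16.9991317012, 17.9991610041),
            p = c(0.99757, 0.00038, 0.00205)),
  P  = list(m = 30.97376163, p = 1.0),
  S  = list(m = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
            p = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Si = list(m = c(27.9769265325, 28.9764946653, 29.9737701370),
            p = c(0.92223, 0.04685, 0.03092))
)

.oracle_compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- NULL
  for (i in 0:n) out <- rbind(out, cbind(i, .oracle_compositions(n - i, k - 1)))
  out
}

# abundance by nominal shift, exact multinomial probabilities
oracle_isotope_pattern <- function(counts, max_shift) {
  acc <- data.frame(shift = 0, mass = 0, p = 1)
  for (sym in names(counts)) {
    n <- counts[[sym]]
    if (n == 0) next
    el <- .oracle_iso[[sym]]
    cmp <- .oracle_compositions(n, length(el$p))
    d <- data.frame(
      shift = as.vector(cmp %*% (round(el$m) - round(el$m[1]))),
      mass = as.vector(cmp %*% el$m),
      p = exp(apply(cmp, 1, function(cc)
        lgamma(n + 1) - sum(lgamma(cc + 1)) + sum(cc * log(el$p)))))
    acc <- do.call(rbind, lapply(seq_len(nrow(acc)), function(i)
      data.frame(shift = acc$shift[i] + d$shift,
                 mass = acc$mass[i] + d$mass, p = acc$p[i] * d$p)))
    acc <- do.call(rbind, lapply(split(acc, acc$shift), function(x)
      data.frame(shift = x$shift[1],
                 mass = sum(x$mass * x$p) / sum(x$p), p = sum(x$p))))
  }
  acc <- acc[acc$shift <= max_shift, , drop = FALSE]
  acc <- acc[order(acc$shift), ]
  acc$p <- acc$p / sum(acc$p)
  acc
}

# --- decomposition oracle: unpruned nested loops ----------------------------
.oracle_mono <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                  O = 15.9949146196, P = 30.97376163, S = 31.97207100,
                  Si = 27.9769265325)

oracle_decompose <- function(neutral_target, tol_da, bounds_list) {
  g <- expand.grid(C = bounds_list$C[1]:bounds_list$C[2],
                   H = bounds_list$H[1]:bounds_list$H[2],
                   N = bounds_list$N[1]:bounds_list$N[2],
                   O = bounds_list$O[1]:bounds_list$O[2],
                   P = bounds_list$P[1]:bounds_list$P[2],
                   S = bounds_list$S[1]:bounds_list$S[2],
                   Si = bounds_list$Si[1]:bounds_list$Si[2])
  m <- as.matrix(g) %*% .oracle_mono[colnames(g)]
  r <- 1 + g$C + g$Si - g$H / 2 + (g$N + g$P) / 2
  hc_ok <- g$C == 0 | (g$H / pmax(g$C, 1) >= 0.1 & g$H / pmax(g$C, 1) <= 4)
  keep <- abs(m - neutral_target) <= tol_da & r >= -0.5 & hc_ok
  lapply(which(keep), function(i) unlist(g[i, ]))
}

# --- exhaustive detection oracle -------------------------------------------
# Considers every monoisotopic candidate peak under every anchor species and
# applies the same scoring rules; used to confirm the detector's scan is
# exhaustive on small spectra.
oracle_detect <- function(s, config) {
  groups <- group_isotopes(s, config)
  rel <- groups$intensity / max(groups$intensity)
  sel <- groups$is_mono & rel >= config$noise_floor
  cand_mz <- groups$mz[sel]
  cand_rel <- rel[sel]
  anchors <- c("[M-CH3]+", "[M-H]+", "[M]+", "[M+H]+")
  best <- NULL
  for (mzv in cand_mz) for (a in anchors) {
    M <- mzv - species_delta_mass(a)
    h <- cimion:::.evaluate_hypothesis(M, cand_mz, cand_rel, config)
    if (is.null(h)) next
    if (is.null(best) ||
        h$score > best$score ||
        (h$score == best$score && h$sum_rel > best$sum_rel) ||
        (h$score == best$score && h$sum_rel == best$sum_rel &&
         h$neutral_mass > best$neutral_mass)) {
      best <- h
    }
  }
  best
}

# --- independent MGF parser -------------------------------------------------
oracle_parse_mgf <- function(lines) {
  out <- list()
  cur <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "BEGIN IONS") {
      cur <- list(meta = list(), mz = numeric(0), intensity = numeric(0))
    } else if (ln == "END IONS") {
      out[[length(out) + 1L]] <- cur
      cur <- NULL
    } else if (!is.null(cur)) {
      if (grepl("=", ln, fixed = TRUE)) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        cur$meta[[kv[1]]] <- paste(kv[-1], collapse = "=")
      } else if (ln != "") {
        v <- as.numeric(strsplit(ln, "[[:space:]]+")[[1]])
        cur$mz <- c(cur$mz, v[1])
        cur$intensity <- c(cur$intensity, v[2])
      }
    }
  }
  out
}

# --- random formula generator for property suites ---------------------------
random_formulas <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    elemental_formula(C = sample(1:30, 1), H = sample(4:60, 1),
                      N = sample(0:5, 1), O = sample(0:10, 1),
                      P = sample(0:2, 1), S = sample(0:2, 1),
                      Si = sample(0:6, 1))
  })
}

phosphoric_toy <- function(extra_mz = NULL, extra_int = NULL) {
  spectrum(c(299.0719, 315.1031, 343.1345, 355.1342, extra_mz),
           c(100, 40, 3, 2, extra_int),
           metadata = list(name = "phosphoric acid 3TMS"))
}
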