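# Scoring of detection and formula assignment against ground truth.

#' Score molecular-ion detection against ground truth
#'
#' A spectrum counts as recognized when its assignment is not rejected and
#' the deduced neutral mass lies within `tolerance` of the true mass.
#' Unmatched names are flagged, never fatal.
#'
#' @param assignment_table data.frame from [batch_detect()] (`$table`).
#' @param truth data.frame with at least `name`, `neutral_mass` (and
#'   optionally `base_species`).
#' @param tolerance Da tolerance for "correct neutral mass" (default 0.005,
#'   the detection default; reported in the output).
#' @return an `evaluation_report` list: `n_total`, `n_recognized`,
#'   `recognition_rate`, `base_species_counts` (detected, among recognized),
#'   `base_species_agreement` (fraction of recognized whose detected base
#'   species matches truth, when truth carries one), `rejection_reasons`,
#'   `unmatched` (names missing from truth), `per_compound` (row-level
#'   table), `tolerance`.
#' @export
score_detection <- function(assignment_table, truth, tolerance = 0.005) {
  at <- assignment_table
  j <- match(at$name, truth$name)
  unmatched <- at$name[is.na(j)]
  df <- at[!is.na(j), , drop = FALSE]
  tr <- truth[j[!is.na(j)], , drop = FALSE]
  correct_mass <- !df$rejected &
    abs(df$neutral_mass - tr$neutral_mass) <= tolerance
  correct_mass[is.na(correct_mass)] <- FALSE
  per <- data.frame(name = df$name,
                    detected_mass = df$neutral_mass,
                    true_mass = tr$neutral_mass,
                    detected_base = df$base_species,
                    rejected = df$rejected,
                    reason = df$reason,
                    recognized = correct_mass)
  base_agree <- NA_real_
  if ("base_species" %in% names(tr) && any(correct_mass)) {
    base_agree <- mean(df$base_species[correct_mass] ==
                       tr$base_species[correct_mass])
  }
  rep <- list(kind = "detection",
              n_total = nrow(df),
              n_recognized = sum(correct_mass),
              recognition_rate = if (nrow(df)) sum(correct_mass) / nrow(df) else NA_real_,
              base_species_counts = table(df$base_species[correct_mass]),
              base_species_agreement = base_agree,
              rejection_reasons = table(df$reason[df$rejected]),
              unmatched = unmatched,
              per_compound = per,
              tolerance = tolerance)
  structure(rep, class = "evaluation_report")
}

#' Score formula ranking against ground truth
#'
#' The rank of the true derivatized formula is found by strict element-count
#' equality (isomeric formulas at the same mass are exactly what ranking
#' must separate, so mass equality would be meaningless). Aggregates top-k
#' rates for k in 1, 3, 5, 10 plus the no-hit fraction; top-k monotonicity
#' is asserted on every report.
#'
#' @param candidate_lists named list (by compound name) of ranked candidate
#'   data.frames from [assign_with_strategy()] (or anything with a `formula`
#'   column in rank order).
#' @param truth data.frame with `name` and `formula` (Hill strings).
#' @return an `evaluation_report`: `n_total`, `topk` (named rates),
#'   `no_hit_rate`, `per_compound` (name, true formula, rank — `NA` = no
#'   hit).
#' @export
score_formula_ranks <- function(candidate_lists, truth) {
  nms <- names(candidate_lists)
  ranks <- rep(NA_integer_, length(nms))
  for (i in seq_along(nms)) {
    j <- match(nms[i], truth$name)
    if (is.na(j)) next
    want <- as_formula(truth$formula[j])
    got <- candidate_lists[[i]]$formula
    hit <- which(vapply(got, function(f) as_formula(f) == want, logical(1)))
    if (length(hit)) ranks[i] <- hit[1]
  }
  n <- length(ranks)
  topk <- vapply(c(1, 3, 5, 10), function(k)
    sum(!is.na(ranks) & ranks <= k) / n, numeric(1))
  names(topk) <- paste0("top", c(1, 3, 5, 10))
  if (any(diff(topk) < 0)) stop("top-k rates must be monotone", call. = FALSE)
  structure(list(kind = "formula_ranking",
                 n_total = n,
                 topk = topk,
                 no_hit_rate = mean(is.na(ranks)),
                 per_compound = data.frame(name = nms, rank = ranks)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  if (x$kind == "detection") {
    cat(sprintf("<evaluation: detection>  n = %d, recognized = %d (%.1f%%), tolerance %.4g Da\n",
                x$n_total, x$n_recognized, 100 * x$recognition_rate,
                x$tolerance))
    if (length(x$base_species_counts)) {
      cat("  base species among recognized:\n")
      for (nm in names(x$base_species_counts)) {
        cat(sprintf("    %-11s %4d (%.0f%% of recognized, %.0f%% of total)\n",
                    nm, x$base_species_counts[[nm]],
                    100 * x$base_species_counts[[nm]] / max(x$n_recognized, 1),
                    100 * x$base_species_counts[[nm]] / max(x$n_total, 1)))
      }
    }
    if (length(x$rejection_reasons)) {
      cat("  rejections:\n")
      for (nm in names(x$rejection_reasons)) {
        cat(sprintf("    %-28s %4d\n", nm, x$rejection_reasons[[nm]]))
      }
    }
  } else {
    cat(sprintf("<evaluation: formula ranking>  n = %d\n", x$n_total))
    for (nm in names(x$topk)) {
      cat(sprintf("  %-6s %.1f%%\n", nm, 100 * x$topk[[nm]]))
    }
    cat(sprintf("  no hit %.1f%%\n", 100 * x$no_hit_rate))
  }
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `evaluation_report`.
#' @param path output path.
#' @return the path, invisibly. Requires the `jsonlite` package.
#' @export
write_report_json <- function(report, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for JSON output", call. = FALSE)
  }
  x <- report[setdiff(names(report), "per_compound")]
  x$base_species_counts <- as.list(x$base_species_counts)
  x$rejection_reasons <- as.list(x$rejection_reasons)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
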