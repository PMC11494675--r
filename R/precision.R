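#' Between-run (intermediate) precision statistics
#'
#' Summarizes a runs-by-replicates design: the grand mean of all
#' measurements, the between-run SD, and the coefficient of variation
#' \code{CV = 100 * S_b / grand_mean}. By default \code{S_b} is the sample SD
#' (denominator \code{n_runs - 1}) of the per-run means; alternatives:
#' \code{"pooled"} (SD of all individual measurements) and \code{"anova"}
#' (square root of the one-way ANOVA between-run variance component,
#' truncated at zero). Within-run repeatability (root mean within-run
#' variance) is reported alongside.
#'
#' @param values Numeric vector of measurements.
#' @param runs Run/plate label per measurement.
#' @param s_b What \code{S_b} estimates: \code{"run_means"} (default),
#'   \code{"pooled"}, or \code{"anova"}.
#' @return A one-row data.frame: \code{grand_mean}, \code{s_b}, \code{cv},
#'   \code{s_within}, \code{n_runs}, \code{n_replicates_per_run}.
#' @examples
#' betweenRunStats(c(0, 2, 1, 3, 2, 4), rep(1:3, each = 2))  # S_b = 1, CV = 50
#' @export
betweenRunStats <- function(values, runs,
                            s_b = c("run_means", "pooled", "anova")) {
  s_b <- match.arg(s_b)
  runs <- factor(runs)
  if (nlevels(runs) < 2L)
    stop("between-run SD undefined: need >= 2 runs")
  if (length(values) != length(runs)) stop("values and runs differ in length")
  run_means <- tapply(values, runs, mean)
  nrep <- tapply(values, runs, length)
  grand <- mean(values)
  within_var <- tapply(values, runs, function(v)
    if (length(v) > 1) stats::var(v) else NA_real_)
  s_within <- sqrt(mean(within_var, na.rm = TRUE))
  sb <- switch(s_b,
    run_means = stats::sd(run_means),
    pooled = stats::sd(values),
    anova = {
      k <- nlevels(runs)
      msb <- sum(nrep * (run_means - grand)^2) / (k - 1)
      msw <- sum((nrep - 1) * within_var, na.rm = TRUE) / (length(values) - k)
      n0 <- (length(values) - sum(nrep^2) / length(values)) / (k - 1)
      sqrt(max((msb - msw) / n0, 0))
    })
  cv <- if (grand > 0) 100 * sb / grand else 0
  if (sb == 0) cv <- 0
  data.frame(grand_mean = grand, s_b = sb, cv = cv,
             s_within = if (is.nan(s_within)) NA_real_ else s_within,
             n_runs = nlevels(runs),
             n_replicates_per_run = mean(nrep))
}

#' Per-standard precision table
#'
#' Computes \code{\link{betweenRunStats}} for every glycan peak and every
#' derived trait of each reference standard in the table, reproducing the
#' layout of a between-run precision report (one block per plasma-pool
#' standard). Derived-trait precision is computed on per-replicate trait
#' values, not on traits of averaged peaks. Precision is evaluated on
#' total-area-normalized (not batch-corrected) values: correcting by plate
#' would remove the very between-run signal being measured.
#'
#' @param x A \linkS4class{GlycanExperiment} in state \code{"normalized"}
#'   containing the standard measurements (rows with
#'   \code{is_standard = TRUE} are used when present, otherwise all rows).
#' @param panel Panel for the derived traits; defaults to the attached panel.
#'   \code{NULL} panel skips traits.
#' @param standard_key colData column identifying the standard/pool
#'   (default \code{"subject_id"}).
#' @param run_key colData column identifying the run/plate (default
#'   \code{"plate_id"}).
#' @param s_b Passed to \code{\link{betweenRunStats}}.
#' @return data.frame with one row per (standard, peak) and (standard,
#'   trait): \code{standard}, \code{trait}, \code{is_derived},
#'   \code{grand_mean}, \code{s_b}, \code{cv}, \code{s_within},
#'   \code{n_runs}, \code{n_replicates_per_run}. Standards measured on fewer
#'   than half the plates are noted in \code{attr(, "warnings")}.
#' @export
precisionTable <- function(x, panel = glycanPanel(x),
                           standard_key = "subject_id",
                           run_key = "plate_id",
                           s_b = c("run_means", "pooled", "anova")) {
  s_b <- match.arg(s_b)
  .stopState(x, "normalized", "precisionTable")
  cd <- as.data.frame(colData(x))
  use <- if (any(cd$is_standard %in% TRUE)) which(cd$is_standard %in% TRUE)
         else seq_len(nrow(cd))
  if (!length(use)) stop("no standard measurements in the table")
  x <- x[, use]
  cd <- cd[use, , drop = FALSE]
  stds <- unique(cd[[standard_key]])
  all_runs <- unique(cd[[run_key]])
  warnings <- character()
  tables <- list(peaks = assay(x, "abundance"))
  if (!is.null(panel) && length(panelTraits(panel)))
    tables$traits <- assay(computeDerivedTraits(x, panel), "abundance")
  out <- list()
  for (std in stds) {
    j <- which(cd[[standard_key]] == std)
    runs_here <- unique(cd[[run_key]][j])
    if (length(runs_here) < 2L)
      stop("standard '", std, "' measured on fewer than 2 runs")
    if (length(runs_here) < length(all_runs) / 2)
      warnings <- c(warnings, sprintf(
        "standard '%s' missing on more than half of the runs (%d of %d)",
        std, length(runs_here), length(all_runs)))
    for (kind in names(tables)) {
      mat <- tables[[kind]]
      for (i in seq_len(nrow(mat))) {
        res <- betweenRunStats(mat[i, j], cd[[run_key]][j], s_b = s_b)
        out[[length(out) + 1L]] <- cbind(
          data.frame(standard = std, trait = rownames(mat)[i],
                     is_derived = kind == "traits"), res)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "warnings") <- warnings
  res
}

#' Relative-abundance-tiered precision acceptance criteria
#'
#' The default tiers grade a peak's CV against a limit chosen by its relative
#' abundance: RA > 3\% requires CV < 5\%; 0.5--3\% requires CV < 10\%;
#' RA < 0.5\% requires CV < 15\%.
#'
#' @return data.frame with columns \code{ra_min}, \code{ra_max},
#'   \code{cv_limit} (tiers are half-open intervals \code{(ra_min, ra_max]}).
#' @export
defaultPrecisionCriteria <- function() {
  data.frame(ra_min = c(3, 0.5, 0), ra_max = c(Inf, 3, 0.5),
             cv_limit = c(5, 10, 15))
}

#' Grade a precision table against tiered acceptance criteria
#'
#' Each row is assigned the tier containing its grand mean (relative
#' abundance) and graded pass/fail by that tier's CV limit.
#'
#' @param result Output of \code{\link{precisionTable}} (or any data.frame
#'   with \code{grand_mean} and \code{cv}).
#' @param criteria Tier table as in \code{\link{defaultPrecisionCriteria}};
#'   tiers must cover (0, Inf) without overlap.
#' @return \code{result} with added columns \code{cv_limit} and \code{grade}
#'   (\code{"pass"}/\code{"fail"}); pass/fail counts in
#'   \code{attr(, "summary")}.
#' @export
gradePrecision <- function(result, criteria = defaultPrecisionCriteria()) {
  criteria <- criteria[order(criteria$ra_min), , drop = FALSE]
  if (criteria$ra_min[1] != 0 || !is.infinite(criteria$ra_max[nrow(criteria)]))
    stop("configuration error: criteria tiers must cover (0, Inf)")
  if (nrow(criteria) > 1 &&
      any(criteria$ra_max[-nrow(criteria)] != criteria$ra_min[-1]))
    stop("configuration error: criteria tiers overlap or leave gaps")
  tier <- vapply(result$grand_mean, function(ra)
    which(ra > criteria$ra_min & ra <= criteria$ra_max)[1], integer(1))
  result$cv_limit <- criteria$cv_limit[tier]
  result$grade <- ifelse(result$cv < result$cv_limit, "pass", "fail")
  attr(result, "summary") <- table(factor(result$grade,
                                          levels = c("pass", "fail")))
  result
}
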