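#' Resolved run configuration
#'
#' Bundles and validates the switches of a pipeline run; the resolved
#' configuration is serialized next to every output for reproducibility.
#'
#' @param mode \code{"precision"}, \code{"cohort"} or \code{"subject"}.
#' @param input Input CSV path, or NULL to simulate.
#' @param panel Panel name or config path.
#' @param out_dir Output directory (created if needed).
#' @param batch_correction Apply empirical-Bayes batch correction (cohort
#'   mode).
#' @param rank_normal Rank-normalize traits before cohort testing.
#' @param zero_policy Zero handling for the log transform.
#' @param alpha Significance level.
#' @param adjust Multiple-testing method.
#' @param threshold,decile Extreme-value flagging parameters.
#' @param stratify colData column(s) for stratified testing.
#' @param seed RNG seed for simulated inputs.
#' @param plots Write per-trait trajectory figures (requires ggplot2).
#' @return A validated list of class \code{"glycostab_config"}.
#' @export
runConfig <- function(mode, input = NULL, panel = "cge_lif_27",
                      out_dir = "glycostab_out", batch_correction = TRUE,
                      rank_normal = TRUE, zero_policy = "half-min",
                      alpha = 0.05, adjust = "BH", threshold = 0.09,
                      decile = 0.10, stratify = "sex", seed = 1,
                      plots = FALSE) {
  if (!mode %in% c("precision", "cohort", "subject"))
    stop("config error: unknown mode '", mode, "'")
  structure(list(mode = mode, input = input, panel = panel,
                 out_dir = out_dir, batch_correction = batch_correction,
                 rank_normal = rank_normal, zero_policy = zero_policy,
                 alpha = alpha, adjust = adjust, threshold = threshold,
                 decile = decile, stratify = stratify, seed = seed,
                 plots = plots),
            class = "glycostab_config")
}

.writeConfig <- function(config, out_dir) {
  rec <- c(unclass(config),
           list(package_version = as.character(utils::packageVersion("glycostab")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                              pretty = TRUE),
             file.path(out_dir, "config.json"))
}

.loadInput <- function(config, panel) {
  if (!is.null(config$input)) {
    if (!file.exists(config$input))
      stop("data error: input file not found: ", config$input)
    tab <- readPeakTable(config$input, panel)
    if (!ncol(tab)) stop("data error: input '", config$input, "' is empty")
    totalAreaNormalize(tab)
  } else if (config$mode == "precision") {
    simulatePrecisionExperiment(precisionDesign(seed = config$seed), panel)
  } else if (config$mode == "cohort") {
    simulateCohort(cohortDesign(seed = config$seed), panel)
  } else {
    simulateLongitudinalSubject(fiveYearDesign(seed = config$seed), panel)
  }
}

#' Run the precision experiment end to end
#'
#' Loads (or simulates) the plasma-pool standards, computes the per-standard
#' between-run precision table for all peaks and derived traits, grades it
#' against the tiered acceptance criteria, and writes \code{precision.csv},
#' a short \code{report.md} and the resolved \code{config.json}.
#'
#' @param config A \code{\link{runConfig}} with \code{mode = "precision"}.
#' @return Invisibly, the graded precision data.frame.
#' @export
runPrecisionExperiment <- function(config) {
  stopifnot(inherits(config, "glycostab_config"))
  if (config$mode != "precision") stop("config error: mode must be 'precision'")
  panel <- loadPanel(config$panel)
  tab <- .loadInput(config, panel)
  res <- gradePrecision(precisionTable(tab, panel))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out_csv <- file.path(config$out_dir, "precision.csv")
  utils::write.csv(res, out_csv, row.names = FALSE)
  smry <- attr(res, "summary")
  fails <- res[res$grade == "fail", ]
  md <- c("# Between-run precision report", "",
          sprintf("- measurements: %d", ncol(tab)),
          sprintf("- standards: %d", length(unique(res$standard))),
          sprintf("- results: %d (pass %d, fail %d)", nrow(res),
                  smry[["pass"]], smry[["fail"]]),
          "",
          if (nrow(fails)) c("## Failing traits", "",
                             sprintf("- %s (standard %s): RA %.3f%%, CV %.2f%% (limit %g%%)",
                                     fails$trait, fails$standard,
                                     fails$grand_mean, fails$cv,
                                     fails$cv_limit))
          else "All traits meet the tiered CV criteria.")
  writeLines(md, file.path(config$out_dir, "report.md"))
  .writeConfig(config, config$out_dir)
  invisible(res)
}

#' Run a stability experiment end to end
#'
#' Cohort mode: total-area normalization, log transform, optional
#' empirical-Bayes batch correction over plates, back-transform, derived
#' traits, optional stratified rank-normalization, mixed-model time effects
#' with multiple-testing adjustment; extreme-value and swap flags are
#' computed on baseline-relative trajectories. Subject mode: normalization,
#' traits, baseline normalization and per-trait OLS trends. Writes
#' \code{stability.csv}, \code{flags.csv}, \code{config.json} and optionally
#' per-trait trajectory figures.
#'
#' @param config A \code{\link{runConfig}} with \code{mode = "cohort"} or
#'   \code{"subject"}.
#' @return Invisibly, a list with \code{results} and \code{flags}.
#' @export
runStabilityExperiment <- function(config) {
  stopifnot(inherits(config, "glycostab_config"))
  if (!config$mode %in% c("cohort", "subject"))
    stop("config error: mode must be 'cohort' or 'subject'")
  panel <- loadPanel(config$panel)
  tab <- .loadInput(config, panel)
  n_subj <- length(unique(colData(tab)$subject_id))
  if (config$mode == "cohort" && n_subj < 2L)
    stop("cohort mode needs >= 2 subjects; use mode = 'subject' for a ",
         "single longitudinal series")

  if (config$mode == "cohort" && config$batch_correction) {
    lg <- logTransform(tab, zero_policy = config$zero_policy)
    tab <- backTransform(ebBatchCorrect(lg)$corrected)
  }
  traits <- computeDerivedTraits(tab, panel)
  rel <- baselineNormalize(traits)

  if (config$mode == "cohort") {
    testtab <- if (config$rank_normal)
      rankNormalizeTraits(traits, stratify = config$stratify) else rel
    results <- fitMixedTimeEffect(testtab, stratify = config$stratify,
                                  alpha = config$alpha,
                                  adjust = config$adjust)
  } else {
    results <- fitSubjectTrend(rel, alpha = config$alpha,
                               adjust = config$adjust)
  }
  flags <- flagExtremes(rel, threshold = config$threshold,
                        decile = config$decile)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(results, file.path(config$out_dir, "stability.csv"),
                   row.names = FALSE)
  utils::write.csv(flags, file.path(config$out_dir, "flags.csv"),
                   row.names = FALSE)
  .writeConfig(config, config$out_dir)
  if (isTRUE(config$plots)) {
    figdir <- file.path(config$out_dir, "figures")
    dir.create(figdir, showWarnings = FALSE)
    plotTrajectories(rel, results, dir = figdir)
  }
  invisible(list(results = results, flags = flags))
}

#' Per-trait trajectory figures
#'
#' One figure per derived trait: baseline-normalized value against time, one
#' line per subject. The title is colored by the adjusted test outcome
#' (green: significant increase, red: significant decrease, black: stable).
#'
#' @param rel Baseline-relative trait table.
#' @param results Output of \code{\link{fitMixedTimeEffect}} or
#'   \code{\link{fitSubjectTrend}} (used for the title colors); may be NULL.
#' @param dir Output directory for PNG files; NULL returns the plot list.
#' @return Invisibly, a named list of ggplot objects.
#' @export
plotTrajectories <- function(rel, results = NULL, dir = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for trajectory figures")
  cd <- as.data.frame(colData(rel))
  mat <- assay(rel, "abundance")
  plots <- list()
  for (tr in rownames(mat)) {
    df <- data.frame(subject = cd$subject_id, time = cd$time_days,
                     value = mat[tr, ])
    col <- "black"
    if (!is.null(results)) {
      dirs <- unique(results$direction[results$trait == tr])
      if (identical(dirs, "increase")) col <- "darkgreen"
      if (identical(dirs, "decrease")) col <- "red"
    }
    p <- ggplot2::ggplot(df, ggplot2::aes(x = time, y = value,
                                          group = subject)) +
      ggplot2::geom_line(alpha = 0.4) +
      ggplot2::geom_hline(yintercept = 1, linetype = 2) +
      ggplot2::labs(title = tr, x = "time (days)",
                    y = "normalized relative abundance") +
      ggplot2::theme_minimal() +
      ggplot2::theme(plot.title = ggplot2::element_text(colour = col))
    plots[[tr]] <- p
    if (!is.null(dir))
      suppressMessages(ggplot2::ggsave(
        file.path(dir, paste0(tr, ".png")), p,
        width = 6, height = 4, dpi = 120))
  }
  invisible(plots)
}
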