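#' Baseline-normalize subject trajectories
#'
#' Divides every trait value of a subject by that subject's value at the
#' earliest time point, the y-axis convention of trajectory plots: the
#' baseline row becomes exactly 1 for every trait and later values are
#' fractions of baseline. Invariant to rescaling a subject's whole series.
#'
#' @param x A \linkS4class{GlycanExperiment} in state \code{"traits"} with
#'   \code{subject_id} and \code{time_days} metadata.
#' @return The table with baseline-relative values;
#'   \code{metadata(x)$baseline_relative} is set to \code{TRUE}.
#' @export
baselineNormalize <- function(x) {
  .stopState(x, "traits", "baselineNormalize")
  cd <- as.data.frame(colData(x))
  if (anyNA(cd$time_days)) stop("time_days required for every measurement")
  mat <- assay(x, "abundance")
  for (subj in unique(cd$subject_id)) {
    j <- which(cd$subject_id == subj)
    base <- j[which.min(cd$time_days[j])]
    b <- mat[, base]
    if (any(b <= 0)) {
      tr <- rownames(mat)[which(b <= 0)[1]]
      stop("zero baseline for subject '", subj, "', trait '", tr, "'")
    }
    mat[, j] <- mat[, j, drop = FALSE] / b
  }
  assay(x, "abundance") <- mat
  metadata(x)$baseline_relative <- TRUE
  x
}

.direction <- function(est, p_adj, alpha) {
  ifelse(p_adj >= alpha, "stable", ifelse(est > 0, "increase", "decrease"))
}

#' Cohort time effects from a linear mixed model
#'
#' Fits, per trait and per stratum, the repeated-measures model
#' \code{value ~ time + (1 | subject)} by REML (random intercept per subject,
#' time in days as a fixed effect) and tests the time coefficient with a
#' Wald-type t test (Satterthwaite degrees of freedom). Singular fits (zero
#' between-subject variance) fall back to ordinary least squares with a
#' recorded warning. P-values are adjusted across the traits within each
#' stratum (the multiple-testing family).
#'
#' @param x A \linkS4class{GlycanExperiment} in state \code{"rank_normal"} or
#'   \code{"traits"} (e.g. baseline-relative values).
#' @param stratify Optional colData column(s) defining analysis strata (e.g.
#'   \code{"sex"}); \code{NULL} analyses all measurements together.
#' @param traits Traits to test; default all rows.
#' @param alpha Significance level for the direction label.
#' @param adjust Multiple-testing method: \code{"BH"} (default) or
#'   \code{"bonferroni"}.
#' @return data.frame with one row per (stratum, trait): \code{trait},
#'   \code{stratum}, \code{time_effect} (per day), \code{se}, \code{p_value},
#'   \code{p_adjusted}, \code{direction}
#'   (\code{increase}/\code{decrease}/\code{stable}), \code{model}
#'   (\code{"mixed"}/\code{"ols"}), \code{n_subjects}, \code{n_observations}.
#' @export
fitMixedTimeEffect <- function(x, stratify = NULL, traits = NULL,
                               alpha = 0.05, adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  .stopState(x, c("rank_normal", "traits"), "fitMixedTimeEffect")
  cd <- as.data.frame(colData(x))
  if (anyNA(cd$time_days)) stop("time_days required for every measurement")
  mat <- assay(x, "abundance")
  if (is.null(traits)) traits <- rownames(mat)
  strata <- if (is.null(stratify)) factor(rep("all", ncol(mat)))
            else interaction(cd[stratify], drop = TRUE)
  out <- list()
  for (s in levels(strata)) {
    j <- which(strata == s)
    subj <- cd$subject_id[j]
    if (length(unique(subj)) < 2L)
      stop("stratum '", s, "' has a single subject; use fitSubjectTrend")
    rows <- list()
    for (tr in traits) {
      df <- data.frame(y = mat[tr, j], time = cd$time_days[j],
                       subject = factor(subj))
      fit <- tryCatch(
        suppressMessages(lmerTest::lmer(y ~ time + (1 | subject), data = df,
                                        REML = TRUE)),
        error = function(e) NULL)
      use_ols <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
      if (!use_ols) {
        co <- stats::coef(summary(fit))["time", ]
        est <- co[["Estimate"]]; se <- co[["Std. Error"]]
        p <- co[["Pr(>|t|)"]]
        model <- "mixed"
      } else {
        ols <- stats::lm(y ~ time, data = df)
        co <- stats::coef(summary(ols))["time", ]
        est <- co[["Estimate"]]; se <- co[["Std. Error"]]
        p <- co[["Pr(>|t|)"]]
        model <- "ols"
        warning("singular mixed fit for trait '", tr, "' in stratum '", s,
                "'; ordinary least squares used")
      }
      rows[[tr]] <- data.frame(trait = tr, stratum = s, time_effect = est,
                               se = se, p_value = p, model = model,
                               n_subjects = length(unique(subj)),
                               n_observations = length(j))
    }
    res <- do.call(rbind, rows)
    res$p_adjusted <- adjustPvalues(res$p_value, method = adjust)
    res$direction <- .direction(res$time_effect, res$p_adjusted, alpha)
    out[[s]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("trait", "stratum", "time_effect", "se", "p_value", "p_adjusted",
          "direction", "model", "n_subjects", "n_observations")]
}

#' Single-subject trend estimation
#'
#' Ordinary least-squares regression of each (typically baseline-relative)
#' trait on days since baseline for one subject's longitudinal series.
#'
#' @param x A \linkS4class{GlycanExperiment} in state \code{"traits"}
#'   containing a single subject with at least three time points.
#' @param traits Traits to fit; default all rows.
#' @param alpha Significance level for the direction label.
#' @param adjust Multiple-testing method across the fitted traits.
#' @return data.frame as in \code{\link{fitMixedTimeEffect}} with
#'   \code{model = "ols"} and the subject id as \code{stratum}.
#' @export
fitSubjectTrend <- function(x, traits = NULL, alpha = 0.05,
                            adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  .stopState(x, "traits", "fitSubjectTrend")
  cd <- as.data.frame(colData(x))
  subj <- unique(cd$subject_id)
  if (length(subj) != 1L)
    stop("fitSubjectTrend expects a single subject, got ", length(subj))
  if (ncol(x) < 3L) stop("need >= 3 time points, got ", ncol(x))
  mat <- assay(x, "abundance")
  if (is.null(traits)) traits <- rownames(mat)
  rows <- lapply(traits, function(tr) {
    fit <- stats::lm(mat[tr, ] ~ cd$time_days)
    co <- stats::coef(summary(fit))
    if (nrow(co) < 2L || anyNA(co[2, 1:2])) {
      est <- if (nrow(co) >= 2) co[2, 1] else 0
      data.frame(trait = tr, stratum = as.character(subj),
                 time_effect = ifelse(is.na(est), 0, est),
                 se = NA_real_, p_value = 1, model = "ols",
                 n_subjects = 1L, n_observations = ncol(x))
    } else {
      data.frame(trait = tr, stratum = as.character(subj),
                 time_effect = co[2, "Estimate"], se = co[2, "Std. Error"],
                 p_value = co[2, "Pr(>|t|)"], model = "ols",
                 n_subjects = 1L, n_observations = ncol(x))
    }
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- adjustPvalues(res$p_value, method = adjust)
  res$direction <- .direction(res$time_effect, res$p_adjusted, alpha)
  rownames(res) <- NULL
  res[, c("trait", "stratum", "time_effect", "se", "p_value", "p_adjusted",
          "direction", "model", "n_subjects", "n_observations")]
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg by default (\code{"bonferroni"} optional); a thin,
#' validating wrapper around \code{\link[stats]{p.adjust}}. Adjusted values
#' are monotone and never below the raw p-values.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param method \code{"BH"} or \code{"bonferroni"}.
#' @return Adjusted p-values.
#' @export
adjustPvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Flag extreme values and probable sample swaps
#'
#' Scans baseline-relative trait trajectories for outlying measurements.
#' Four rules, applied to the deviation \code{v - 1} from baseline:
#' \itemize{
#'   \item \code{decile_top} / \code{decile_bottom}: values in the global
#'     top/bottom \code{decile} of all normalized results;
#'   \item \code{threshold_exceed}: \code{|v - 1| >= threshold} (default 9\%
#'     of the initial measurement);
#'   \item \code{transient_spike}: a threshold-exceeding point whose previous
#'     and next observations of the same subject are both within threshold;
#'   \item \code{swap_candidate}: a (subject, time point) where at least
#'     \code{swap_min_traits} of the traits exceed the threshold and G0 and
#'     G2 deviate in opposite directions -- the signature of two exchanged
#'     samples, since no plausible biological change moves a glycome against
#'     its own galactosylation axis in one visit.
#' }
#'
#' @param x Baseline-relative \linkS4class{GlycanExperiment} (see
#'   \code{\link{baselineNormalize}}).
#' @param threshold Deviation fraction for \code{threshold_exceed}
#'   (default 0.09).
#' @param decile Tail fraction for the decile rules (default 0.10).
#' @param swap_min_traits Minimum number of simultaneously exceeding traits
#'   for a swap candidate (default 4 of the 6 derived traits).
#' @return data.frame of flags: \code{subject_id}, \code{trait} (NA for
#'   swap candidates, which concern the whole time point), \code{time_days},
#'   \code{value}, \code{deviation}, \code{kind}. Zero rows when nothing is
#'   flagged.
#' @export
flagExtremes <- function(x, threshold = 0.09, decile = 0.10,
                         swap_min_traits = 4L) {
  .stopState(x, "traits", "flagExtremes")
  if (!isTRUE(metadata(x)$baseline_relative))
    stop("flagExtremes expects baseline-normalized trajectories ",
         "(run baselineNormalize first)")
  cd <- as.data.frame(colData(x))
  mat <- assay(x, "abundance")
  long <- data.frame(
    subject_id = rep(cd$subject_id, each = nrow(mat)),
    trait = rep(rownames(mat), ncol(mat)),
    time_days = rep(cd$time_days, each = nrow(mat)),
    value = as.vector(mat))
  long$deviation <- long$value - 1
  lo <- stats::quantile(long$value, decile)
  hi <- stats::quantile(long$value, 1 - decile)
  flags <- list()
  emit <- function(rows, kind) {
    if (nrow(rows))
      flags[[length(flags) + 1L]] <<- cbind(rows, kind = kind)
  }
  emit(long[long$value >= hi, ], "decile_top")
  emit(long[long$value <= lo, ], "decile_bottom")
  exceed <- abs(long$deviation) >= threshold
  emit(long[exceed, ], "threshold_exceed")
  # transient spikes: both neighbours of the same subject/trait within band
  for (k in which(exceed)) {
    sj <- long$subject_id[k]; tr <- long$trait[k]
    series <- long[long$subject_id == sj & long$trait == tr, ]
    series <- series[order(series$time_days), ]
    pos <- match(long$time_days[k], series$time_days)
    if (!is.na(pos) && pos > 1 && pos < nrow(series) &&
        abs(series$deviation[pos - 1]) < threshold &&
        abs(series$deviation[pos + 1]) < threshold)
      emit(long[k, , drop = FALSE], "transient_spike")
  }
  # swap candidates per (subject, time point)
  key <- paste(long$subject_id, long$time_days, sep = "\r")
  for (kk in unique(key[exceed])) {
    pt <- long[key == kk, ]
    n_exceed <- sum(abs(pt$deviation) >= threshold)
    g0 <- pt$deviation[pt$trait == "G0"]
    g2 <- pt$deviation[pt$trait == "G2"]
    if (n_exceed >= swap_min_traits && length(g0) == 1 && length(g2) == 1 &&
        g0 * g2 < 0) {
      worst <- pt[which.max(abs(pt$deviation)), ]
      worst$trait <- NA_character_
      emit(worst, "swap_candidate")
    }
  }
  if (!length(flags))
    return(data.frame(subject_id = character(), trait = character(),
                      time_days = numeric(), value = numeric(),
                      deviation = numeric(), kind = character()))
  res <- do.call(rbind, flags)
  rownames(res) <- NULL
  res
}
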