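#' Reference between-run precision tables
#'
#' The published between-run precision report for the three plasma-pool
#' standards on the 27-peak CGE-LIF panel: per standard and per peak/trait the
#' grand mean (relative abundance, \%), the between-run SD and the CV (\%).
#' Shipped as plain-text package data; used both as the simulation baseline
#' and as the calibration source for default analytical noise.
#'
#' @return data.frame with columns \code{standard} (4, 5, 6), \code{trait},
#'   \code{grand_mean}, \code{s_b}, \code{cv}.
#' @export
referencePrecisionTables <- function() {
  utils::read.csv(system.file("extdata", "precision_reference_cge.csv",
                              package = "glycostab"))
}

#' Reference peak composition of a plasma-pool standard
#'
#' @param standard Which plasma pool (4, 5 or 6).
#' @return Named numeric vector of the 27 peak grand means (sums to 100
#'   within printing precision).
#' @export
referenceComposition <- function(standard = 4) {
  ref <- referencePrecisionTables()
  ref <- ref[ref$standard == standard & grepl("^GP", ref$trait), ]
  stats::setNames(ref$grand_mean, ref$trait)
}

#' Per-peak analytical noise calibrated from the reference tables
#'
#' Log-scale noise SDs derived from the published per-peak between-run CVs
#' (\code{cv / 100}): small multiplicative noise has CV approximately equal
#' to its log-SD, so simulating with these magnitudes reproduces the printed
#' CV ranges.
#'
#' @param standard Which plasma pool's CV column to use.
#' @return Named numeric vector of per-peak log-scale SDs.
#' @export
referenceNoiseSD <- function(standard = 4) {
  ref <- referencePrecisionTables()
  ref <- ref[ref$standard == standard & grepl("^GP", ref$trait), ]
  stats::setNames(ref$cv / 100, ref$trait)
}

.designParam <- function(design, name, default = NULL)
  design@params[[name]] %||% default

.resolveSigma <- function(sigma, peaks, default) {
  out <- default
  if (is.null(sigma)) return(out)
  if (is.null(names(sigma))) {
    rep(as.numeric(sigma), length.out = length(peaks)) |>
      stats::setNames(peaks)
  } else {
    out[names(sigma)] <- sigma
    out
  }
}

#' Design for a plasma-pool precision experiment
#'
#' Defaults emulate the published design: 3 plasma pools analysed in
#' tetraplicate across 26 plates (one plate per day of analysis), i.e. 104
#' replicates per pool and 312 measurements overall.
#'
#' @param n_pools Number of plasma-pool standards.
#' @param n_plates Number of plates/runs.
#' @param n_replicates Replicates of each pool per plate.
#' @param sigma_plate,sigma_replicate Log-scale noise SDs: scalar, or named
#'   per-peak vector overriding the defaults calibrated from the reference
#'   tables (plate effect 0.9x the reference CV, replicate noise 1.0x).
#' @param seed RNG seed.
#' @return A \linkS4class{SimDesign} of kind \code{"precision"}.
#' @export
precisionDesign <- function(n_pools = 3, n_plates = 26, n_replicates = 4,
                            sigma_plate = NULL, sigma_replicate = NULL,
                            seed = 1) {
  stopifnot(n_pools >= 1, n_plates >= 2, n_replicates >= 1)
  new("SimDesign", kind = "precision",
      params = list(n_pools = n_pools, n_plates = n_plates,
                    n_replicates = n_replicates, sigma_plate = sigma_plate,
                    sigma_replicate = sigma_replicate, seed = seed))
}

#' Simulate a plasma-pool precision experiment
#'
#' Each measurement is the pool's reference composition perturbed by a
#' per-(plate, peak) multiplicative log-normal plate effect and a per-(
#' measurement, peak) replicate noise, then renormalized to 100. Pools reuse
#' the three published standards' compositions (recycled if more pools are
#' requested).
#'
#' @param design A \linkS4class{SimDesign} from \code{\link{precisionDesign}}.
#' @param panel Panel for the peak vocabulary (default the built-in CGE-LIF
#'   panel).
#' @return A \linkS4class{GlycanExperiment} in state \code{"normalized"} with
#'   one column per measurement; \code{subject_id} holds the pool label,
#'   \code{plate_id} the plate, \code{is_standard} is TRUE.
#' @export
simulatePrecisionExperiment <- function(design,
                                        panel = loadPanel("cge_lif_27")) {
  stopifnot(is(design, "SimDesign"), design@kind == "precision")
  p <- design@params
  set.seed(p$seed)
  peaks <- panelPeaks(panel)
  refs <- lapply(c(4, 5, 6), referenceComposition)
  base_sd <- referenceNoiseSD(4)
  if (!all(peaks %in% names(refs[[1]])))
    stop("precision simulation requires the 27-peak CGE-LIF vocabulary")
  s_plate <- .resolveSigma(p$sigma_plate, peaks, 0.9 * base_sd[peaks])
  s_rep <- .resolveSigma(p$sigma_replicate, peaks, base_sd[peaks])
  cols <- list(); meta <- list()
  for (pool in seq_len(p$n_pools)) {
    comp <- refs[[(pool - 1) %% 3 + 1]][peaks]
    for (plate in seq_len(p$n_plates)) {
      plate_eff <- exp(stats::rnorm(length(peaks), 0, s_plate))
      for (rep_i in seq_len(p$n_replicates)) {
        noise <- exp(stats::rnorm(length(peaks), 0, s_rep))
        v <- comp * plate_eff * noise
        cols[[length(cols) + 1L]] <- 100 * v / sum(v)
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = sprintf("pool%d_p%02d_r%d", pool, plate, rep_i),
          subject_id = paste0("pool", pool),
          plate_id = sprintf("plate%02d", plate), replicate = rep_i,
          time_days = 0, sex = NA, cohort = "precision",
          is_standard = TRUE)
      }
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- peaks
  ge <- GlycanExperiment(mat, do.call(rbind, meta), panel = panel,
                         state = "normalized")
  metadata(ge)$design <- design
  ge
}

.driverGroups <- function(panel) {
  trs <- panelTraits(panel)
  need <- c("G0", "G2", "S")
  if (!all(need %in% names(trs)))
    stop("panel must define G0, G2 and S traits for simulation")
  groups <- lapply(trs[need], function(tr) names(tr@numerator))
  groups$G1 <- setdiff(panelPeaks(panel), unlist(groups))
  groups[c("G0", "G1", "G2", "S")]
}

#' Design for a short-term cohort experiment
#'
#' Defaults emulate the 90-day young-cohort design (10 males and 28 females
#' sampled on days 0/30/60/90); see \code{\link{cpwcDesign}} for the weekly
#' premenopausal-women design. Inter-individual variation is generated from a
#' latent ageing/galactosylation axis (raising G0 while lowering G2 and S),
#' an independent bisection axis on the bisected peaks, a sialylation axis,
#' plus per-group and per-peak idiosyncrasies -- all multiplicative on the
#' peak scale so that closure induces the mild negative correlations of real
#' compositional data. Magnitudes are order-of-magnitude choices consistent
#' with between-individual trait variation reported for adult IgG glycomes.
#'
#' @param n_male,n_female Cohort composition.
#' @param schedule Sampling days (strictly increasing, baseline first).
#' @param cyclic Apply a menstrual-cycle modulation to female subjects:
#'   sinusoid on the G0 (positive) and G2/S (negative) trait groups with
#'   subject-specific cycle length ~ U[27, 31] days and random phase.
#' @param cyclic_amplitude Peak-scale amplitude of the modulation.
#' @param trend Named per-day multiplicative slopes on the trait scale for
#'   any of G0, G1, G2, S (and F, applied first-order through the
#'   non-fucosylated peaks), e.g. \code{c(G0 = -0.001, G2 = 0.0012)}.
#' @param sigma_age,sigma_bisection,sigma_sialylation,sigma_group,sigma_peak
#'   Log-scale SDs of the subject-effect components.
#' @param sigma_analytical Per-measurement per-peak noise: scalar or named
#'   vector; default calibrated from the reference tables.
#' @param sigma_plate Per-plate per-peak effect SD (plates assigned
#'   round-robin for batch-effect testing).
#' @param n_plates Number of plates samples are spread over.
#' @param missing_rate Fraction of measurements dropped uniformly at random
#'   (baseline visits are kept so every subject has a defined baseline).
#' @param seed RNG seed.
#' @return A \linkS4class{SimDesign} of kind \code{"cohort"}.
#' @export
cohortDesign <- function(n_male = 10, n_female = 28,
                         schedule = c(0, 30, 60, 90),
                         cyclic = TRUE, cyclic_amplitude = 0.015,
                         trend = NULL,
                         sigma_age = 0.35, sigma_bisection = 0.15,
                         sigma_sialylation = 0.08, sigma_group = 0.10,
                         sigma_peak = 0.05, sigma_analytical = NULL,
                         sigma_plate = 0.01, n_plates = 8,
                         missing_rate = 0, seed = 1) {
  new("SimDesign", kind = "cohort",
      params = list(n_male = n_male, n_female = n_female, schedule = schedule,
                    cyclic = cyclic, cyclic_amplitude = cyclic_amplitude,
                    trend = trend, sigma_age = sigma_age,
                    sigma_bisection = sigma_bisection,
                    sigma_sialylation = sigma_sialylation,
                    sigma_group = sigma_group, sigma_peak = sigma_peak,
                    sigma_analytical = sigma_analytical,
                    sigma_plate = sigma_plate, n_plates = n_plates,
                    missing_rate = missing_rate, seed = seed))
}

#' Design for the weekly premenopausal-women cohort
#'
#' 70 women sampled weekly for 12 weeks with menstrual-cycle modulation and
#' ~5.4\% missingness (so the expected number of measurements is about 795).
#'
#' @param ... Overrides passed to \code{\link{cohortDesign}}.
#' @return A \linkS4class{SimDesign} of kind \code{"cohort"}.
#' @export
cpwcDesign <- function(...) {
  args <- list(n_male = 0, n_female = 70, schedule = seq(0, 77, by = 7),
               missing_rate = 0.054, ...)
  do.call(cohortDesign, args[!duplicated(names(args), fromLast = TRUE)])
}

#' Simulate a short-term cohort experiment
#'
#' Subject baselines are drawn around the reference composition from the
#' latent-axis model of \code{\link{cohortDesign}}; visits add the optional
#' menstrual-cycle modulation (females), the optional global trend, a plate
#' effect (round-robin plate assignment) and analytical noise; measurements
#' are renormalized to 100 and optionally thinned at random.
#'
#' @param design A \linkS4class{SimDesign} from \code{\link{cohortDesign}} or
#'   \code{\link{cpwcDesign}}.
#' @param panel Peak vocabulary (default built-in CGE-LIF panel).
#' @return A \linkS4class{GlycanExperiment} in state \code{"normalized"};
#'   the generating truth (trend, subject effects) is stored in
#'   \code{metadata()$truth}.
#' @export
simulateCohort <- function(design, panel = loadPanel("cge_lif_27")) {
  stopifnot(is(design, "SimDesign"), design@kind == "cohort")
  p <- design@params
  set.seed(p$seed)
  peaks <- panelPeaks(panel)
  ref <- referenceComposition(4)
  if (!all(peaks %in% names(ref)))
    stop("cohort simulation requires the 27-peak CGE-LIF vocabulary")
  ref <- ref[peaks]
  groups <- .driverGroups(panel)
  grp_of <- stats::setNames(rep(names(groups), lengths(groups)),
                            unlist(groups))[peaks]
  age_load <- c(G0 = 1, G1 = 0, G2 = -0.9, S = -0.7)[grp_of]
  bis_peaks <- names(panelTraits(panel)$B@numerator)
  fuc_trait <- panelTraits(panel)$F
  nonfuc <- setdiff(peaks, names(fuc_trait@numerator))
  f0 <- sum(ref[names(fuc_trait@numerator)]) / sum(ref)
  s_ana <- .resolveSigma(p$sigma_analytical, peaks, referenceNoiseSD(4)[peaks])
  s_plate <- .resolveSigma(p$sigma_plate, peaks,
                           stats::setNames(rep(0.01, length(peaks)), peaks))

  sexes <- c(rep("M", p$n_male), rep("F", p$n_female))
  n_subj <- length(sexes)
  if (!n_subj) stop("cohort has no subjects")
  subj_ids <- sprintf("S%03d", seq_len(n_subj))
  # latent subject effects (log scale, per peak)
  subj_log <- matrix(0, n_subj, length(peaks),
                     dimnames = list(subj_ids, peaks))
  age_score <- stats::rnorm(n_subj, 0, p$sigma_age)
  for (k in seq_len(n_subj)) {
    grp_eff <- stats::rnorm(length(groups), 0, p$sigma_group)
    names(grp_eff) <- names(groups)
    subj_log[k, ] <- age_score[k] * age_load +
      stats::rnorm(1, 0, p$sigma_bisection) * (peaks %in% bis_peaks) +
      stats::rnorm(1, 0, p$sigma_sialylation) * (grp_of == "S") +
      grp_eff[grp_of] +
      stats::rnorm(length(peaks), 0, p$sigma_peak)
  }
  cycle_len <- stats::runif(n_subj, 27, 31)
  cycle_phase <- stats::runif(n_subj, 0, 1) * cycle_len

  # plate effects, plates assigned round-robin over measurements
  plate_ids <- sprintf("plate%02d", seq_len(p$n_plates))
  plate_log <- matrix(stats::rnorm(p$n_plates * length(peaks), 0, s_plate),
                      p$n_plates, length(peaks), byrow = TRUE,
                      dimnames = list(plate_ids, peaks))

  trend <- p$trend
  trend_log <- function(t) {
    lg <- stats::setNames(numeric(length(peaks)), peaks)
    if (is.null(trend)) return(lg)
    for (g in intersect(names(trend), names(groups)))
      lg[groups[[g]]] <- lg[groups[[g]]] + trend[[g]] * t
    if ("F" %in% names(trend))
      lg[nonfuc] <- lg[nonfuc] - trend[["F"]] * t / (1 - f0)
    lg
  }

  cols <- list(); meta <- list()
  m <- 0L
  for (k in seq_len(n_subj)) {
    for (i in seq_along(p$schedule)) {
      t <- p$schedule[i]
      m <- m + 1L
      # balanced round-robin: every visit is spread across all plates
      plate <- plate_ids[((k - 1L) + (i - 1L)) %% p$n_plates + 1L]
      lg <- subj_log[k, ] + plate_log[plate, ] + trend_log(t) +
        stats::rnorm(length(peaks), 0, s_ana)
      if (isTRUE(p$cyclic) && sexes[k] == "F") {
        cyc <- p$cyclic_amplitude *
          sin(2 * pi * (t - cycle_phase[k]) / cycle_len[k])
        lg <- lg + cyc * c(G0 = 1, G1 = 0, G2 = -1, S = -1)[grp_of]
      }
      v <- ref * exp(lg)
      cols[[m]] <- 100 * v / sum(v)
      meta[[m]] <- data.frame(
        sample_id = sprintf("%s_d%03d", subj_ids[k], as.integer(round(t))),
        subject_id = subj_ids[k], plate_id = plate, replicate = 1L,
        time_days = t, sex = sexes[k], cohort = "cohort",
        is_standard = FALSE)
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- peaks
  cd <- do.call(rbind, meta)
  if (p$missing_rate > 0) {
    drop <- stats::runif(ncol(mat)) < p$missing_rate & cd$time_days > 0
    mat <- mat[, !drop, drop = FALSE]
    cd <- cd[!drop, , drop = FALSE]
  }
  ge <- GlycanExperiment(mat, cd, panel = panel, state = "normalized")
  metadata(ge)$design <- design
  metadata(ge)$truth <- list(trend = trend, age_score = age_score,
                             cycle_len = cycle_len)
  ge
}

#' Design for a multi-year single-subject series
#'
#' @param schedule Sampling days from baseline (strictly increasing).
#' @param trend Named per-day slopes of the baseline-normalized trait
#'   trajectories for G0, G2 and S (the constrained trait groups); the
#'   remaining neutral (G1) peaks absorb the closure remainder, so with zero
#'   noise the realized baseline-normalized G0/G2/S series equal
#'   \code{1 + slope * day} exactly.
#' @param interventions List of episodes, each a list with \code{start}
#'   (day), \code{duration} (days), \code{multiplier} (named per-group
#'   factors applied to the trait trajectory during the window, e.g.
#'   \code{c(G0 = 0.92, S = 1.08, G2 = 1.06)} for a counter-ageing episode)
#'   and \code{half_life} (days; the excess decays exponentially after the
#'   window).
#' @param sigma_analytical Scalar (or named per-peak) log-scale analytical
#'   noise SD.
#' @param seed RNG seed.
#' @return A \linkS4class{SimDesign} of kind \code{"longitudinal"}.
#' @export
longitudinalDesign <- function(schedule, trend, interventions = list(),
                               sigma_analytical = 0.015, seed = 1) {
  for (iv in interventions) {
    if (iv$start < min(schedule) || iv$start + iv$duration > max(schedule))
      stop("intervention window [", iv$start, ", ", iv$start + iv$duration,
           "] lies outside the schedule span")
  }
  new("SimDesign", kind = "longitudinal",
      params = list(schedule = schedule, trend = trend,
                    interventions = interventions,
                    sigma_analytical = sigma_analytical, seed = seed))
}

#' Five-year quarterly design with the published ageing drift
#'
#' Quarterly sampling (91.25-day steps, 21 samples over 1825 days) with the
#' reported per-day time effects of the 5-year experiment: G0 +0.000051,
#' S -0.000073, G2 -0.000051 (baseline-normalized scale per day).
#'
#' @param ... Overrides passed to \code{\link{longitudinalDesign}}.
#' @export
fiveYearDesign <- function(...) {
  args <- list(schedule = round(91.25 * 0:20),
               trend = c(G0 = 0.000051, S = -0.000073, G2 = -0.000051), ...)
  do.call(longitudinalDesign, args[!duplicated(names(args), fromLast = TRUE)])
}

#' Ten-year three-weekly design with ageing drift and two interventions
#'
#' Sampling every 21 days over 3650 days with the reported 10-year per-day
#' time effects (G0 +0.000014, S -0.000026, G2 -0.000008) and two
#' counter-ageing intervention episodes.
#'
#' @param ... Overrides passed to \code{\link{longitudinalDesign}}.
#' @export
tenYearDesign <- function(...) {
  args <- list(
    schedule = seq(0, 3650, by = 21),
    trend = c(G0 = 0.000014, S = -0.000026, G2 = -0.000008),
    interventions = list(
      list(start = 1300, duration = 120,
           multiplier = c(G0 = 0.92, S = 1.08, G2 = 1.06), half_life = 60),
      list(start = 3300, duration = 120,
           multiplier = c(G0 = 0.94, S = 1.06, G2 = 1.04), half_life = 60)),
    ...)
  do.call(longitudinalDesign, args[!duplicated(names(args), fromLast = TRUE)])
}

#' Simulate a single-subject longitudinal series
#'
#' Constructs peak trajectories whose baseline-normalized G0, G2 and S trait
#' series follow the designed linear trends (times any intervention episode
#' factor) exactly under zero noise: the constrained groups' peaks are scaled
#' by the target trait multiplier and the neutral remainder group absorbs the
#' closure balance. Analytical noise is multiplicative log-normal per peak,
#' after which each measurement is renormalized to 100.
#'
#' @param design A \linkS4class{SimDesign} from
#'   \code{\link{longitudinalDesign}}, \code{\link{fiveYearDesign}} or
#'   \code{\link{tenYearDesign}}.
#' @param panel Peak vocabulary (default built-in CGE-LIF panel).
#' @param subject_id Subject label.
#' @return A \linkS4class{GlycanExperiment} in state \code{"normalized"};
#'   generating trends in \code{metadata()$truth}.
#' @export
simulateLongitudinalSubject <- function(design,
                                        panel = loadPanel("cge_lif_27"),
                                        subject_id = "LT1") {
  stopifnot(is(design, "SimDesign"), design@kind == "longitudinal")
  p <- design@params
  set.seed(p$seed)
  peaks <- panelPeaks(panel)
  ref <- referenceComposition(4)
  if (!all(peaks %in% names(ref)))
    stop("longitudinal simulation requires the 27-peak CGE-LIF vocabulary")
  ref <- ref[peaks]
  groups <- .driverGroups(panel)
  w <- vapply(groups, function(g) sum(ref[g]) / sum(ref), numeric(1))
  constrained <- intersect(names(p$trend), c("G0", "G2", "S"))
  s_ana <- .resolveSigma(p$sigma_analytical, peaks,
                         stats::setNames(rep(0.015, length(peaks)), peaks))

  iv_factor <- function(g, t) {
    f <- 1
    for (iv in p$interventions) {
      mult <- iv$multiplier[g]
      if (is.na(mult)) next
      end <- iv$start + iv$duration
      if (t >= iv$start && t <= end) f <- f * mult
      else if (t > end)
        f <- f * (1 + (mult - 1) * exp(-(t - end) * log(2) / iv$half_life))
    }
    f
  }

  cols <- list(); meta <- list()
  for (i in seq_along(p$schedule)) {
    t <- p$schedule[i]
    m <- stats::setNames(rep(1, length(groups)), names(groups))
    for (g in constrained)
      m[g] <- (1 + p$trend[[g]] * t) * iv_factor(g, t)
    if (any(m <= 0)) stop("trait multiplier fell to zero at day ", t)
    # neutral remainder keeps total area exactly closed
    rest <- setdiff(names(groups), constrained)
    if (length(rest) != 1L)
      stop("exactly one unconstrained trait group is required, got: ",
           paste(rest, collapse = ", "))
    m[rest] <- (1 - sum(w[constrained] * m[constrained])) / w[rest]
    if (m[rest] <= 0)
      stop("closure remainder fell to zero at day ", t,
           " (trends too strong for the composition)")
    fac <- stats::setNames(rep(names(groups), lengths(groups)),
                           unlist(groups))[peaks]
    v <- ref * m[fac] * exp(stats::rnorm(length(peaks), 0, s_ana))
    cols[[i]] <- 100 * v / sum(v)
    meta[[i]] <- data.frame(
      sample_id = sprintf("%s_d%04d", subject_id, as.integer(round(t))),
      subject_id = subject_id, plate_id = NA, replicate = 1L,
      time_days = t, sex = "M", cohort = "longitudinal",
      is_standard = FALSE)
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- peaks
  ge <- GlycanExperiment(mat, do.call(rbind, meta), panel = panel,
                         state = "normalized")
  metadata(ge)$design <- design
  metadata(ge)$truth <- list(trend = p$trend,
                             interventions = p$interventions)
  ge
}

#' Exchange two subjects' measurements at one time point
#'
#' Swaps the peak values of the two measurements while leaving the sample
#' metadata untouched -- emulating a pre-analytical sample switch. The truth
#' record accumulates in \code{metadata()$swap_truth} for evaluating
#' \code{\link{flagExtremes}} downstream.
#'
#' @param x A \linkS4class{GlycanExperiment}.
#' @param subject_a,subject_b Subject IDs; both must have a measurement at
#'   \code{time_point}.
#' @param time_point Day of the exchanged visit.
#' @return The modified table. Swapping the same pair twice restores the
#'   original.
#' @export
injectSampleSwap <- function(x, subject_a, subject_b, time_point) {
  cd <- colData(x)
  ja <- which(cd$subject_id == subject_a & cd$time_days == time_point)
  jb <- which(cd$subject_id == subject_b & cd$time_days == time_point)
  if (length(ja) != 1L || length(jb) != 1L)
    stop("both subjects need exactly one measurement at day ", time_point,
         " (", subject_a, ": ", length(ja), ", ", subject_b, ": ",
         length(jb), ")")
  mat <- assay(x, "abundance")
  tmp <- mat[, ja]
  mat[, ja] <- mat[, jb]
  mat[, jb] <- tmp
  assay(x, "abundance") <- mat
  metadata(x)$swap_truth <- rbind(
    metadata(x)$swap_truth,
    data.frame(subject_a = subject_a, subject_b = subject_b,
               time_days = time_point))
  x
}
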