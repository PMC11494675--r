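#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData
#'   colData<- assayNames
NULL

.PROCESSING_STATES <- c("raw", "normalized", "log", "batch_corrected",
                        "traits", "rank_normal")

#' Derived glycan trait definition
#'
#' A derived trait aggregates glycan peaks that share a structural feature
#' (e.g. agalactosylation, sialylation, bisecting GlcNAc). The trait value is
#' \code{scale * sum(w_i * peak_i) / sum(denominator peaks)}, where the
#' denominator \code{"TOTAL"} denotes the (already normalized) total area so
#' that the trait is a plain weighted sum of relative areas. Numerator weights
#' default to 1; a weight above 1 represents a peak that co-elutes more than
#' one structure belonging to the trait.
#'
#' @slot trait Trait label, e.g. \code{"G0"}.
#' @slot numerator Named numeric vector of peak weights.
#' @slot denominator Either \code{"TOTAL"} or a character vector of peak IDs.
#' @slot scale Numeric multiplier (1 for plain sums of percentages, 100 when a
#'   peak-set denominator is used).
#' @exportClass DerivedTraitDef
setClass("DerivedTraitDef",
         representation(trait = "character", numerator = "numeric",
                        denominator = "character", scale = "numeric"))

setValidity("DerivedTraitDef", function(object) {
  msg <- character()
  if (length(object@trait) != 1L || !nzchar(object@trait))
    msg <- c(msg, "'trait' must be a single non-empty label")
  if (length(object@numerator) == 0L)
    msg <- c(msg, sprintf("trait '%s': numerator must be non-empty", object@trait))
  if (is.null(names(object@numerator)) || any(!nzchar(names(object@numerator))))
    msg <- c(msg, sprintf("trait '%s': numerator peaks must be named", object@trait))
  if (any(object@numerator <= 0))
    msg <- c(msg, sprintf("trait '%s': numerator weights must be positive", object@trait))
  if (length(object@scale) != 1L || object@scale <= 0)
    msg <- c(msg, sprintf("trait '%s': scale must be a positive scalar", object@trait))
  if (!identical(object@denominator, "TOTAL")) {
    missing <- setdiff(names(object@numerator), object@denominator)
    if (length(missing))
      msg <- c(msg, sprintf(
        "trait '%s': numerator peaks not in denominator: %s",
        object@trait, paste(missing, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Glycan peak panel
#'
#' The peak vocabulary of a glycan profiling platform together with the
#' derived-trait definitions over it. Built-in panels: \code{"cge_lif_27"}
#' (27 CGE-LIF electropherogram peaks) and \code{"uplc_24"} (24 HILIC-UPLC
#' chromatogram peaks), each with the six standard derived traits G0, G1, G2,
#' S, B and F.
#'
#' @slot name Panel label.
#' @slot peaks Ordered character vector of unique peak identifiers.
#' @slot traits List of \linkS4class{DerivedTraitDef}.
#' @slot galactosylationExcluded Peaks deliberately outside the G0/G1/G2
#'   classification (e.g. sialylated or oligomannose peaks).
#' @exportClass GlycanPanel
setClass("GlycanPanel",
         representation(name = "character", peaks = "character",
                        traits = "list",
                        galactosylationExcluded = "character"))

setValidity("GlycanPanel", function(object) {
  msg <- character()
  if (length(object@name) != 1L) msg <- c(msg, "'name' must be a single label")
  if (anyDuplicated(object@peaks))
    msg <- c(msg, "peak identifiers must be unique")
  for (tr in object@traits) {
    if (!is(tr, "DerivedTraitDef")) {
      msg <- c(msg, "all trait definitions must be DerivedTraitDef objects")
      next
    }
    bad <- setdiff(names(tr@numerator), object@peaks)
    if (length(bad))
      msg <- c(msg, sprintf("trait '%s' references missing peak(s): %s",
                            tr@trait, paste(bad, collapse = ", ")))
    if (!identical(tr@denominator, "TOTAL")) {
      bad <- setdiff(tr@denominator, object@peaks)
      if (length(bad))
        msg <- c(msg, sprintf("trait '%s' denominator references missing peak(s): %s",
                              tr@trait, paste(bad, collapse = ", ")))
    }
  }
  extra <- setdiff(object@galactosylationExcluded, object@peaks)
  if (length(extra))
    msg <- c(msg, sprintf("galactosylationExcluded references missing peak(s): %s",
                          paste(extra, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Container for glycan peak and derived-trait tables
#'
#' A \linkS4class{SummarizedExperiment} holding one \code{"abundance"} assay
#' (features in rows: glycan peaks, or derived traits after
#' \code{\link{computeDerivedTraits}}; one column per measurement) plus the
#' sample metadata in \code{colData} (\code{sample_id}, \code{subject_id},
#' \code{plate_id}, \code{replicate}, \code{time_days}, \code{date},
#' \code{sex}, \code{cohort}, \code{is_standard}). The processing state of the
#' values (\code{"raw"}, \code{"normalized"}, \code{"log"},
#' \code{"batch_corrected"}, \code{"traits"}, \code{"rank_normal"}) is kept in
#' the object metadata and gates the preprocessing pipeline; see
#' \code{\link{processingState}}.
#'
#' @exportClass GlycanExperiment
setClass("GlycanExperiment", contains = "SummarizedExperiment")

setValidity("GlycanExperiment", function(object) {
  msg <- character()
  if (!"abundance" %in% assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  st <- metadata(object)$state
  if (is.null(st) || !st %in% .PROCESSING_STATES)
    msg <- c(msg, sprintf("metadata 'state' must be one of: %s",
                          paste(.PROCESSING_STATES, collapse = ", ")))
  if (!"sample_id" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'sample_id'")
  if (length(msg)) msg else TRUE
})

#' Empirical-Bayes batch model
#'
#' Parameters estimated by \code{\link{ebBatchCorrect}}: the per-feature
#' standardization fit (grand means, covariate coefficients and pooled
#' variance), the shrunken per-(batch, feature) location (\code{gammaStar})
#' and scale (\code{delta2Star}) adjustments, the per-batch prior
#' hyperparameters, and convergence metadata.
#'
#' @slot features Feature (peak) identifiers.
#' @slot batches Batch levels.
#' @slot grandMean Per-feature weighted grand mean of the batch means.
#' @slot beta Covariate coefficient matrix (covariates x features; 0 rows when
#'   no covariates were supplied).
#' @slot varPooled Per-feature pooled residual variance.
#' @slot gammaHat,delta2Hat Raw per-(batch, feature) location/scale estimates.
#' @slot gammaStar,delta2Star Posterior (shrunken) location/scale adjustments.
#' @slot hyper Per-batch prior hyperparameters (gamma_bar, tau2, a_prior,
#'   b_prior).
#' @slot iterations Per-batch iteration counts of the EB fixed-point solver.
#' @slot tolerance Convergence tolerance used.
#' @slot skipped Features passed through unadjusted (too few distinct values).
#' @exportClass BatchModel
setClass("BatchModel",
         representation(features = "character", batches = "character",
                        grandMean = "numeric", beta = "matrix",
                        varPooled = "numeric",
                        gammaHat = "matrix", delta2Hat = "matrix",
                        gammaStar = "matrix", delta2Star = "matrix",
                        hyper = "list", iterations = "numeric",
                        tolerance = "numeric", skipped = "character"))

setValidity("BatchModel", function(object) {
  if (length(object@delta2Star) && any(object@delta2Star <= 0))
    return("all delta2Star entries must be positive")
  TRUE
})

#' Synthetic experiment design
#'
#' Parameterization of a simulated glycan profiling experiment. Construct with
#' \code{\link{precisionDesign}}, \code{\link{cohortDesign}} or
#' \code{\link{longitudinalDesign}}; consume with
#' \code{\link{simulatePrecisionExperiment}}, \code{\link{simulateCohort}} or
#' \code{\link{simulateLongitudinalSubject}}.
#'
#' @slot kind One of \code{"precision"}, \code{"cohort"},
#'   \code{"longitudinal"}.
#' @slot params Named list of design parameters (see the constructors).
#' @exportClass SimDesign
setClass("SimDesign", representation(kind = "character", params = "list"))

setValidity("SimDesign", function(object) {
  msg <- character()
  if (!object@kind %in% c("precision", "cohort", "longitudinal"))
    msg <- c(msg, "kind must be 'precision', 'cohort' or 'longitudinal'")
  p <- object@params
  sds <- unlist(p[grep("^sigma", names(p))], use.names = FALSE)
  if (length(sds) && any(sds < 0)) msg <- c(msg, "all noise SDs must be >= 0")
  if (!is.null(p$missing_rate) &&
      (p$missing_rate < 0 || p$missing_rate >= 1))
    msg <- c(msg, "missing_rate must be in [0, 1)")
  if (!is.null(p$schedule) && any(diff(p$schedule) <= 0))
    msg <- c(msg, "schedule must be strictly increasing")
  if (length(msg)) msg else TRUE
})
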