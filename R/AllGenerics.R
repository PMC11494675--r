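#' Processing state of a glycan table
#'
#' The pipeline stages stamp their output so that downstream operations can
#' refuse inputs in the wrong state (e.g. batch correction requires
#' log-transformed values).
#'
#' @param x A \linkS4class{GlycanExperiment}.
#' @param value One of \code{"raw"}, \code{"normalized"}, \code{"log"},
#'   \code{"batch_corrected"}, \code{"traits"}, \code{"rank_normal"}.
#' @return The state label (getter) or the modified object (setter).
#' @export
setGeneric("processingState", function(x) standardGeneric("processingState"))

#' @rdname processingState
#' @export
setGeneric("processingState<-",
           function(x, value) standardGeneric("processingState<-"))

#' Panel attached to a glycan table
#'
#' @param x A \linkS4class{GlycanExperiment}.
#' @return The \linkS4class{GlycanPanel} carried in the object metadata, or
#'   \code{NULL}.
#' @export
setGeneric("glycanPanel", function(x) standardGeneric("glycanPanel"))

#' @rdname glycanPanel
#' @param value A \linkS4class{GlycanPanel}.
#' @export
setGeneric("glycanPanel<-", function(x, value) standardGeneric("glycanPanel<-"))

#' Peak identifiers of a panel
#'
#' @param x A \linkS4class{GlycanPanel}.
#' @return Character vector of peak IDs.
#' @export
setGeneric("panelPeaks", function(x) standardGeneric("panelPeaks"))

#' Derived-trait definitions of a panel
#'
#' @param x A \linkS4class{GlycanPanel}.
#' @return Named list of \linkS4class{DerivedTraitDef}.
#' @export
setGeneric("panelTraits", function(x) standardGeneric("panelTraits"))
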