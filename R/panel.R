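#' Construct a derived-trait definition
#'
#' @param trait Trait label (e.g. \code{"G0"}).
#' @param numerator Named numeric vector of peak weights, or a character
#'   vector of peak IDs (all weights 1).
#' @param denominator \code{"TOTAL"} (default) or a character vector of peak
#'   IDs.
#' @param scale Multiplier applied to the ratio/sum. Defaults to 1 for
#'   \code{"TOTAL"} (values are already percentages) and 100 otherwise.
#' @return A \linkS4class{DerivedTraitDef}.
#' @export
derivedTraitDef <- function(trait, numerator, denominator = "TOTAL",
                            scale = NULL) {
  if (is.character(numerator))
    numerator <- stats::setNames(rep(1, length(numerator)), numerator)
  if (is.list(numerator))
    numerator <- unlist(numerator)
  if (is.null(scale))
    scale <- if (identical(denominator, "TOTAL")) 1 else 100
  new("DerivedTraitDef", trait = trait, numerator = numerator,
      denominator = denominator, scale = as.numeric(scale))
}

#' Construct a glycan panel
#'
#' @param name Panel label.
#' @param peaks Ordered character vector of unique peak identifiers.
#' @param traits List of \linkS4class{DerivedTraitDef}.
#' @param galactosylationExcluded Peaks outside the G0/G1/G2 classification.
#' @return A validated \linkS4class{GlycanPanel}.
#' @export
GlycanPanel <- function(name, peaks, traits = list(),
                        galactosylationExcluded = character()) {
  names(traits) <- vapply(traits, function(tr) tr@trait, character(1))
  new("GlycanPanel", name = name, peaks = as.character(peaks),
      traits = traits,
      galactosylationExcluded = as.character(galactosylationExcluded))
}

.builtinPanelFile <- function(name) {
  system.file("extdata", "panels", paste0(name, ".yaml"),
              package = "glycostab", mustWork = FALSE)
}

#' Load a glycan panel from a config file or by built-in name
#'
#' Panel configurations are YAML (or JSON) files with keys \code{name},
#' \code{peaks}, \code{traits} (each with \code{trait}, \code{numerator},
#' optional \code{denominator} and \code{scale}) and optional
#' \code{galactosylation_excluded}. The built-in panels \code{"cge_lif_27"}
#' and \code{"uplc_24"} are loadable by name without a path.
#'
#' @param path Path to a panel config file, or a built-in panel name.
#' @return A validated \linkS4class{GlycanPanel}.
#' @examples
#' panel <- loadPanel("cge_lif_27")
#' length(panelPeaks(panel))   # 27
#' names(panelTraits(panel))   # G0 G1 G2 S B F
#' @export
loadPanel <- function(path) {
  file <- path
  if (!file.exists(file)) {
    builtin <- .builtinPanelFile(path)
    if (nzchar(builtin) && file.exists(builtin)) {
      file <- builtin
    } else {
      stop("panel config not found: '", path,
           "' (not a file and not a built-in panel)")
    }
  }
  cfg <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::fromJSON(file, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(file)
  }
  if (is.null(cfg$name) || is.null(cfg$peaks))
    stop("panel config must declare 'name' and 'peaks'")
  if (anyDuplicated(cfg$peaks))
    stop("panel config '", cfg$name, "': duplicated peak identifiers")
  traits <- lapply(cfg$traits, function(tr) {
    def <- derivedTraitDef(tr$trait, tr$numerator,
                           denominator = tr$denominator %||% "TOTAL",
                           scale = tr$scale)
    bad <- setdiff(names(def@numerator), cfg$peaks)
    if (length(bad))
      stop("panel config '", cfg$name, "': trait '", tr$trait,
           "' references missing peak(s): ", paste(bad, collapse = ", "))
    def
  })
  GlycanPanel(cfg$name, unlist(cfg$peaks), traits,
              galactosylationExcluded =
                as.character(unlist(cfg$galactosylation_excluded)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname panelPeaks
setMethod("panelPeaks", "GlycanPanel", function(x) x@peaks)

#' @rdname panelTraits
setMethod("panelTraits", "GlycanPanel", function(x) x@traits)

setMethod("show", "GlycanPanel", function(object) {
  cat("GlycanPanel '", object@name, "': ", length(object@peaks), " peaks, ",
      length(object@traits), " derived traits (",
      paste(names(object@traits), collapse = ", "), ")\n", sep = "")
})

setMethod("show", "DerivedTraitDef", function(object) {
  num <- paste0(names(object@numerator),
                ifelse(object@numerator != 1,
                       paste0(" x", object@numerator), ""))
  den <- if (identical(object@denominator, "TOTAL")) "TOTAL"
         else paste(object@denominator, collapse = "+")
  cat("DerivedTraitDef ", object@trait, " = ", object@scale, " * (",
      paste(num, collapse = " + "), ") / ", den, "\n", sep = "")
})
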