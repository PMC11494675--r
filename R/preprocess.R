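#' Total-area normalization
#'
#' Expresses each measurement's peak areas as a percentage of its total
#' integrated area, the standard closure operation for relative glycan
#' abundances. Idempotent and invariant to rescaling a measurement by any
#' positive constant.
#'
#' @param x A \linkS4class{GlycanExperiment} in state \code{"raw"} or
#'   \code{"normalized"}.
#' @return The table with every column scaled to sum to 100, state
#'   \code{"normalized"}.
#' @export
totalAreaNormalize <- function(x) {
  .stopState(x, c("raw", "normalized"), "totalAreaNormalize")
  mat <- assay(x, "abundance")
  sums <- colSums(mat)
  if (any(sums <= 0)) {
    bad <- colData(x)$sample_id[which(sums <= 0)[1]]
    stop("data error: all-zero peak row for sample '", bad, "'")
  }
  assay(x, "abundance") <- sweep(mat, 2, sums / 100, "/")
  metadata(x)$state <- "normalized"
  x
}

#' Natural-log transform of normalized peak areas
#'
#' Zeros are handled according to \code{zero_policy}: \code{"half-min"}
#' substitutes half the smallest positive value observed for that peak across
#' measurements (the default; zeros occur in low-abundance peaks),
#' \code{"offset"} substitutes a fixed \code{offset}, and \code{"error"}
#' refuses zeros.
#'
#' @param x A \linkS4class{GlycanExperiment} in state \code{"normalized"}.
#' @param zero_policy One of \code{"half-min"}, \code{"offset"},
#'   \code{"error"}.
#' @param offset Substitution value for \code{zero_policy = "offset"}.
#' @return The table with \code{log()} applied elementwise, state
#'   \code{"log"}.
#' @seealso \code{\link{backTransform}}, its inverse on normalized tables.
#' @export
logTransform <- function(x, zero_policy = c("half-min", "offset", "error"),
                         offset = 1e-3) {
  .stopState(x, "normalized", "logTransform")
  zero_policy <- match.arg(zero_policy)
  mat <- assay(x, "abundance")
  if (any(mat == 0)) {
    if (zero_policy == "error") {
      feat <- rownames(mat)[which(rowSums(mat == 0) > 0)[1]]
      stop("domain error: zero value in feature '", feat,
           "' with zero_policy = 'error'")
    }
    for (i in which(rowSums(mat == 0) > 0)) {
      pos <- mat[i, mat[i, ] > 0]
      sub <- if (zero_policy == "half-min") {
        if (!length(pos))
          stop("domain error: feature '", rownames(mat)[i],
               "' is all zero; cannot apply half-min policy")
        min(pos) / 2
      } else offset
      mat[i, mat[i, ] == 0] <- sub
    }
  }
  assay(x, "abundance") <- log(mat)
  metadata(x)$state <- "log"
  x
}

#' Back-transform to the normalized scale
#'
#' Exponentiates and re-applies total-area normalization, undoing
#' \code{\link{logTransform}} (and restoring closure after batch correction).
#'
#' @param x A \linkS4class{GlycanExperiment} in state \code{"log"} or
#'   \code{"batch_corrected"}.
#' @return The table on the original percentage scale, state
#'   \code{"normalized"}.
#' @export
backTransform <- function(x) {
  .stopState(x, c("log", "batch_corrected"), "backTransform")
  assay(x, "abundance") <- exp(assay(x, "abundance"))
  metadata(x)$state <- "raw"
  totalAreaNormalize(x)
}

#' Compute derived glycan traits
#'
#' Aggregates peaks sharing a structural feature into the panel's derived
#' traits (typically G0, G1, G2, S, B, F), computed per measurement on the
#' normalized percentage scale: \code{scale * sum(w_i * peak_i)} for
#' denominator \code{"TOTAL"}, otherwise
#' \code{scale * sum(numerator)/sum(denominator)}.
#'
#' @param x A \linkS4class{GlycanExperiment} in state \code{"normalized"}.
#' @param panel A \linkS4class{GlycanPanel}; defaults to the panel attached to
#'   \code{x}.
#' @return A \linkS4class{GlycanExperiment} with one row per derived trait,
#'   state \code{"traits"}; sample metadata carried over unchanged.
#' @export
computeDerivedTraits <- function(x, panel = glycanPanel(x)) {
  .stopState(x, "normalized", "computeDerivedTraits")
  if (is.null(panel)) stop("no panel attached to the table or supplied")
  mat <- assay(x, "abundance")
  traits <- panelTraits(panel)
  if (!length(traits)) stop("panel '", panel@name, "' defines no traits")
  vals <- matrix(NA_real_, nrow = length(traits), ncol = ncol(mat),
                 dimnames = list(names(traits), colnames(mat)))
  for (tr in traits) {
    missing <- setdiff(names(tr@numerator), rownames(mat))
    if (length(missing))
      stop("configuration error: trait '", tr@trait,
           "' references peak(s) absent from the table: ",
           paste(missing, collapse = ", "))
    num <- drop(tr@numerator %*% mat[names(tr@numerator), , drop = FALSE])
    if (identical(tr@denominator, "TOTAL")) {
      vals[tr@trait, ] <- tr@scale * num
    } else {
      den <- colSums(mat[tr@denominator, , drop = FALSE])
      vals[tr@trait, ] <- ifelse(den > 0, tr@scale * num / den, 0)
    }
  }
  out <- GlycanExperiment(vals, as.data.frame(colData(x)), panel = panel,
                          state = "traits")
  metadata(out) <- c(metadata(out),
                     metadata(x)[setdiff(names(metadata(x)),
                                         c("state", "panel"))])
  out
}

#' Inverse rank-normal transform
#'
#' Maps values to standard-normal quantiles of their plotting positions:
#' \code{z_i = qnorm((r_i - c) / (n - 2c + 1))} with average ranks for ties
#' and the Blom offset \code{c = 3/8} by default. The result has mean ~0 and
#' SD ~1.
#'
#' @param values Numeric vector, length >= 2; ties allowed.
#' @param offset Plotting-position constant \code{c}.
#' @return Numeric vector of z-scores.
#' @examples
#' rankInverseNormal(c(3, 1, 2))   # 0.8694 -0.8694 0.0000
#' @export
rankInverseNormal <- function(values, offset = 3 / 8) {
  if (length(values) < 2) stop("need at least two values")
  if (anyNA(values)) stop("NA values are not supported")
  if (diff(range(values)) == 0)
    stop("constant vector: all ranks tied, transform undefined")
  r <- rank(values, ties.method = "average")
  n <- length(values)
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Rank-normalize derived traits within analysis strata
#'
#' Applies \code{\link{rankInverseNormal}} to each trait separately within
#' each stratum (e.g. within sex), matching stratified downstream testing and
#' preventing cross-group leakage.
#'
#' @param x A \linkS4class{GlycanExperiment} in state \code{"traits"}.
#' @param stratify Optional colData column name(s) defining the strata;
#'   \code{NULL} treats the whole table as one stratum.
#' @param offset Plotting-position constant, see
#'   \code{\link{rankInverseNormal}}.
#' @return The table with z-scored trait values, state \code{"rank_normal"}.
#' @export
rankNormalizeTraits <- function(x, stratify = NULL, offset = 3 / 8) {
  .stopState(x, "traits", "rankNormalizeTraits")
  mat <- assay(x, "abundance")
  cd <- as.data.frame(colData(x))
  strata <- if (is.null(stratify)) rep("all", ncol(mat))
            else interaction(cd[stratify], drop = TRUE)
  for (s in unique(strata)) {
    j <- which(strata == s)
    for (i in seq_len(nrow(mat)))
      mat[i, j] <- rankInverseNormal(mat[i, j], offset = offset)
  }
  assay(x, "abundance") <- mat
  metadata(x)$state <- "rank_normal"
  metadata(x)$rank_normal_strata <- stratify
  x
}
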