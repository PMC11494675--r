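#' Parametric empirical-Bayes batch correction
#'
#' Location/scale batch-effect adjustment of log-scale peak values, the
#' standard parametric empirical-Bayes approach for removing plate effects
#' from omics feature matrices. Per feature, a mean model with batch
#' indicators (and optional covariates) is fitted and residuals are
#' standardized by the pooled SD; per (batch, feature) the standardized batch
#' mean and variance are shrunk toward moment-matched normal /
#' inverse-gamma priors by iterating the posterior fixed-point equations;
#' the standardized data are then adjusted by the shrunken location and
#' scale and the covariate fit and pooled scale are restored.
#'
#' A single batch yields the identity transform (with a warning). Features
#' with fewer than two distinct values in some batch are passed through
#' unadjusted (with a warning). Shape and ordering of the table are
#' preserved.
#'
#' @param x A \linkS4class{GlycanExperiment} in state \code{"log"}.
#' @param batch colData column naming the batch/plate (default
#'   \code{"plate_id"}).
#' @param covariates Optional character vector of colData columns to protect
#'   in the mean model (e.g. \code{c("time_days", "sex")}).
#' @param tol Convergence tolerance of the EB fixed-point iteration.
#' @param maxit Maximum iterations before the fit is declared non-convergent.
#' @return A list with \code{corrected} (the adjusted
#'   \linkS4class{GlycanExperiment}, state \code{"batch_corrected"}) and
#'   \code{model} (a \linkS4class{BatchModel}).
#' @export
ebBatchCorrect <- function(x, batch = "plate_id", covariates = NULL,
                           tol = 1e-6, maxit = 500L) {
  .stopState(x, "log", "ebBatchCorrect")
  cd <- as.data.frame(colData(x))
  if (!batch %in% colnames(cd)) stop("batch column '", batch, "' not found")
  bf <- factor(cd[[batch]])
  Y <- assay(x, "abundance")
  G <- nrow(Y)
  feats <- rownames(Y) %||% paste0("feature", seq_len(G))
  levs <- levels(bf)

  if (length(levs) < 2L) {
    warning("single batch: batch correction is the identity transform")
    metadata(x)$state <- "batch_corrected"
    zero <- matrix(0, 1, G, dimnames = list(levs, feats))
    one <- matrix(1, 1, G, dimnames = list(levs, feats))
    model <- new("BatchModel", features = feats, batches = levs,
                 grandMean = rowMeans(Y),
                 beta = matrix(0, 0, G), varPooled = apply(Y, 1, stats::var),
                 gammaHat = zero, delta2Hat = one, gammaStar = zero,
                 delta2Star = one, hyper = list(), iterations = 0,
                 tolerance = tol, skipped = character())
    return(list(corrected = x, model = model))
  }
  nb <- table(bf)
  if (any(nb < 2L))
    stop("each batch needs >= 2 measurements; too small: ",
         paste(levs[nb < 2], collapse = ", "))

  # features a batch measures with < 2 distinct values cannot be standardized
  skipped <- feats[vapply(seq_len(G), function(i)
    any(tapply(Y[i, ], bf, function(v) length(unique(v))) < 2L), logical(1))]
  if (length(skipped))
    warning("feature(s) passed through unadjusted (constant within a batch): ",
            paste(skipped, collapse = ", "))
  keep <- setdiff(feats, skipped)
  Yk <- Y[keep, , drop = FALSE]

  Xb <- stats::model.matrix(~ bf - 1)
  Xc <- NULL
  if (!is.null(covariates) && length(covariates)) {
    Xc <- stats::model.matrix(
      stats::reformulate(covariates), data = cd)[, -1, drop = FALSE]
  }
  X <- cbind(Xb, Xc)
  nB <- ncol(Xb)
  N <- ncol(Yk)

  Bhat <- solve(crossprod(X), crossprod(X, t(Yk)))        # p x G
  grand <- drop(crossprod(as.numeric(nb) / N, Bhat[seq_len(nB), , drop = FALSE]))
  fitted <- t(X %*% Bhat)
  varPooled <- rowSums((Yk - fitted)^2) / N
  if (any(varPooled <= 0))
    stop("zero pooled variance for feature(s): ",
         paste(keep[varPooled <= 0], collapse = ", "))
  standMean <- matrix(grand, nrow(Yk), N)
  if (!is.null(Xc) && ncol(Xc))
    standMean <- standMean +
      t(X[, -seq_len(nB), drop = FALSE] %*% Bhat[-seq_len(nB), , drop = FALSE])
  Z <- (Yk - standMean) / sqrt(varPooled)

  gammaHat <- t(vapply(levs, function(b)
    rowMeans(Z[, bf == b, drop = FALSE]), numeric(nrow(Z))))
  delta2Hat <- t(vapply(levs, function(b)
    apply(Z[, bf == b, drop = FALSE], 1, stats::var), numeric(nrow(Z))))
  if (nrow(Z) == 1L) {   # vapply drops to vector shape
    gammaHat <- matrix(gammaHat, ncol = 1)
    delta2Hat <- matrix(delta2Hat, ncol = 1)
  }
  dimnames(gammaHat) <- dimnames(delta2Hat) <- list(levs, keep)

  gammaStar <- gammaHat
  delta2Star <- delta2Hat
  hyper <- list()
  iterations <- stats::setNames(numeric(length(levs)), levs)
  for (b in seq_along(levs)) {
    n <- as.numeric(nb[b])
    g.hat <- gammaHat[b, ]
    d.hat <- delta2Hat[b, ]
    gbar <- mean(g.hat)
    t2 <- stats::var(g.hat)
    m <- mean(d.hat); s2 <- stats::var(d.hat)
    aprior <- (2 * s2 + m^2) / s2
    bprior <- (m * s2 + m^3) / s2
    hyper[[levs[b]]] <- list(gamma_bar = gbar, tau2 = t2,
                             a_prior = aprior, b_prior = bprior)
    if (!is.finite(t2) || t2 <= 0 || !is.finite(aprior) || !is.finite(bprior)) {
      # too few features to moment-match priors: fall back to raw estimates
      gammaStar[b, ] <- g.hat
      delta2Star[b, ] <- d.hat
      next
    }
    Zb <- Z[, bf == levs[b], drop = FALSE]
    sum2const <- rowSums(Zb^2)
    g.old <- g.hat
    d.old <- d.hat
    it <- 0L
    repeat {
      it <- it + 1L
      g.new <- (t2 * n * g.hat + d.old * gbar) / (t2 * n + d.old)
      sum2 <- sum2const - 2 * g.new * n * g.hat + n * g.new^2
      d.new <- (0.5 * sum2 + bprior) / (n / 2 + aprior - 1)
      change <- max(abs(g.new - g.old), abs(d.new - d.old))
      g.old <- g.new
      d.old <- d.new
      if (change < tol) break
      if (it >= maxit)
        stop("EB iteration failed to converge for batch '", levs[b], "'")
    }
    iterations[b] <- it
    gammaStar[b, ] <- g.old
    delta2Star[b, ] <- d.old
  }

  Zadj <- Z
  for (b in seq_along(levs)) {
    j <- bf == levs[b]
    Zadj[, j] <- (Z[, j, drop = FALSE] - gammaStar[b, ]) /
      sqrt(delta2Star[b, ])
  }
  Yadj <- Zadj * sqrt(varPooled) + standMean
  Y[keep, ] <- Yadj
  assay(x, "abundance") <- Y
  metadata(x)$state <- "batch_corrected"

  beta <- if (!is.null(Xc) && ncol(Xc))
    Bhat[-seq_len(nB), , drop = FALSE] else matrix(0, 0, length(keep))
  model <- new("BatchModel", features = keep, batches = levs,
               grandMean = stats::setNames(grand, keep), beta = beta,
               varPooled = stats::setNames(varPooled, keep),
               gammaHat = gammaHat, delta2Hat = delta2Hat,
               gammaStar = gammaStar, delta2Star = delta2Star,
               hyper = hyper, iterations = iterations, tolerance = tol,
               skipped = skipped)
  list(corrected = x, model = model)
}

#' Serialize a BatchModel to JSON
#'
#' @param model A \linkS4class{BatchModel}.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly when \code{path} is given.
#' @export
batchModelToJSON <- function(model, path = NULL) {
  obj <- list(features = model@features, batches = model@batches,
              grand_mean = as.list(model@grandMean),
              var_pooled = as.list(model@varPooled),
              gamma_star = apply(model@gammaStar, 1, as.list, simplify = FALSE),
              delta2_star = apply(model@delta2Star, 1, as.list, simplify = FALSE),
              hyper = model@hyper,
              iterations = as.list(model@iterations),
              tolerance = model@tolerance, skipped = model@skipped)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

setMethod("show", "BatchModel", function(object) {
  cat("BatchModel: ", length(object@features), " features, ",
      length(object@batches), " batches",
      if (length(object@skipped))
        paste0(" (", length(object@skipped), " skipped)"), "\n", sep = "")
})
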