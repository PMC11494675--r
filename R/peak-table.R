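.META_COLS <- c("sample_id", "subject_id", "plate_id", "replicate",
                "time_days", "date", "sex", "cohort", "is_standard")

#' Construct a GlycanExperiment from a matrix and sample metadata
#'
#' @param abundance Numeric matrix, features (peaks or traits) in rows,
#'   measurements in columns.
#' @param sampleData data.frame (or DataFrame) of per-measurement metadata;
#'   missing standard columns are filled with NA.
#' @param panel Optional \linkS4class{GlycanPanel} carried along in metadata.
#' @param state Processing state flag; \code{"raw"} by default.
#' @return A \linkS4class{GlycanExperiment}.
#' @export
GlycanExperiment <- function(abundance, sampleData, panel = NULL,
                             state = "raw") {
  abundance <- as.matrix(abundance)
  sampleData <- as.data.frame(sampleData, stringsAsFactors = FALSE)
  for (col in .META_COLS)
    if (!col %in% colnames(sampleData)) sampleData[[col]] <- NA
  sampleData$is_standard <- sampleData$is_standard %in% TRUE
  cd <- S4Vectors::DataFrame(sampleData)
  rownames(cd) <- NULL
  se <- SummarizedExperiment(assays = list(abundance = abundance),
                             colData = cd)
  md <- list(state = state)
  if (!is.null(panel)) md$panel <- panel
  metadata(se) <- md
  new("GlycanExperiment", se)
}

#' @rdname processingState
setMethod("processingState", "GlycanExperiment",
          function(x) metadata(x)$state)

#' @rdname processingState
setMethod("processingState<-", "GlycanExperiment", function(x, value) {
  metadata(x)$state <- value
  validObject(x)
  x
})

#' @rdname glycanPanel
setMethod("glycanPanel", "GlycanExperiment", function(x) metadata(x)$panel)

#' @rdname glycanPanel
setMethod("glycanPanel<-", "GlycanExperiment", function(x, value) {
  metadata(x)$panel <- value
  x
})

setMethod("show", "GlycanExperiment", function(object) {
  cat("GlycanExperiment: ", nrow(object), " features x ", ncol(object),
      " measurements [state: ", processingState(object), "]\n", sep = "")
  pn <- glycanPanel(object)
  if (!is.null(pn)) cat("  panel: ", pn@name, "\n", sep = "")
  ns <- length(unique(stats::na.omit(colData(object)$subject_id)))
  if (ns > 0) cat("  subjects: ", ns, "\n", sep = "")
})

.stopState <- function(x, expected, op) {
  st <- processingState(x)
  if (!st %in% expected)
    stop(op, " requires state ", paste(sQuote(expected), collapse = " or "),
         ", got ", sQuote(st))
  invisible(st)
}

#' Read a peak table from CSV/TSV
#'
#' Reads a wide measurement table: metadata columns (\code{sample_id} plus any
#' of \code{subject_id}, \code{plate_id}, \code{replicate},
#' \code{time_days}, \code{date}, \code{sex}, \code{cohort},
#' \code{is_standard}) and one column per panel peak. Peak columns are matched
#' case-insensitively. When \code{time_days} is absent but \code{date}
#' (ISO-8601) is present, \code{time_days} is computed per subject as days
#' since that subject's first date. Missing optional metadata become NA; row
#' order is preserved.
#'
#' @param path CSV or TSV file (delimiter sniffed by \code{data.table::fread}).
#' @param panel A \linkS4class{GlycanPanel}; all its peaks must be present as
#'   columns.
#' @return A \linkS4class{GlycanExperiment} in state \code{"raw"}.
#' @export
readPeakTable <- function(path, panel) {
  dt <- data.table::fread(path, data.table = FALSE, check.names = FALSE)
  lower <- tolower(colnames(dt))
  idx <- match(tolower(panelPeaks(panel)), lower)
  if (anyNA(idx)) {
    missing <- panelPeaks(panel)[is.na(idx)]
    stop("schema error: peak column(s) missing from '", path, "': ",
         paste(missing, collapse = ", "))
  }
  peakmat <- as.matrix(dt[, idx, drop = FALSE])
  if (nrow(peakmat)) {
    storage.mode(peakmat) <- "double"
    neg <- which(peakmat < 0, arr.ind = TRUE)
    if (length(neg))
      stop("data error: negative peak value at row ", neg[1, 1],
           " (peak ", panelPeaks(panel)[neg[1, 2]], ")")
  }
  rownames(peakmat) <- NULL
  meta <- dt[, setdiff(seq_along(dt), idx), drop = FALSE]
  midx <- match(.META_COLS, tolower(colnames(meta)))
  sampleData <- data.frame(row.names = seq_len(nrow(dt)))
  for (k in seq_along(.META_COLS)) {
    sampleData[[.META_COLS[k]]] <-
      if (is.na(midx[k])) rep(NA, nrow(dt)) else meta[[midx[k]]]
  }
  if (!is.null(sampleData$date) && !all(is.na(sampleData$date)))
    sampleData$date <- as.Date(sampleData$date)
  if (all(is.na(sampleData$time_days)) && !all(is.na(sampleData$date))) {
    first <- tapply(sampleData$date, sampleData$subject_id, min)
    sampleData$time_days <-
      as.numeric(sampleData$date - first[as.character(sampleData$subject_id)])
  }
  sampleData$is_standard <- sampleData$is_standard %in% c(TRUE, "TRUE", "true", 1)
  ge <- GlycanExperiment(t(peakmat), sampleData, panel = panel, state = "raw")
  rownames(ge) <- panelPeaks(panel)
  ge
}

#' Write a peak table to CSV
#'
#' Inverse of \code{\link{readPeakTable}}: metadata columns followed by one
#' column per feature, one row per measurement.
#'
#' @param x A \linkS4class{GlycanExperiment}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePeakTable <- function(x, path) {
  meta <- as.data.frame(colData(x))
  out <- cbind(meta, as.data.frame(t(assay(x, "abundance"))))
  data.table::fwrite(out, path)
  invisible(path)
}

#' Validate a peak table against its contracts
#'
#' Checks content invariants without mutating or throwing: duplicated
#' (sample_id, replicate) pairs, negative peak values, negative time_days,
#' replicate indices below 1, and (for state \code{"normalized"}) per-sample
#' peak sums away from 100 beyond 1e-9 relative tolerance. An empty report
#' means the table is valid.
#'
#' @param x A \linkS4class{GlycanExperiment}.
#' @param panel Optional \linkS4class{GlycanPanel}; when given, feature names
#'   are checked against the panel peaks (ignored for trait tables).
#' @return data.frame with columns \code{kind}, \code{sample_id},
#'   \code{detail}; zero rows when valid.
#' @export
validateTable <- function(x, panel = NULL) {
  findings <- list()
  add <- function(kind, sample_id, detail)
    findings[[length(findings) + 1L]] <<-
      data.frame(kind = kind, sample_id = as.character(sample_id),
                 detail = detail, stringsAsFactors = FALSE)
  cd <- colData(x)
  mat <- assay(x, "abundance")
  key <- paste(cd$sample_id, cd$replicate, sep = "\r")
  dup <- duplicated(key) & !is.na(cd$sample_id)
  for (i in which(dup))
    add("duplicate", cd$sample_id[i],
        sprintf("duplicated (sample_id, replicate) pair: (%s, %s)",
                cd$sample_id[i], cd$replicate[i]))
  negcols <- which(apply(mat < 0, 2, any))
  for (j in negcols)
    add("negative_value", cd$sample_id[j],
        sprintf("negative value in feature(s): %s",
                paste(rownames(mat)[mat[, j] < 0], collapse = ", ")))
  bad_t <- which(!is.na(cd$time_days) & cd$time_days < 0)
  for (j in bad_t)
    add("negative_time", cd$sample_id[j],
        sprintf("time_days = %s", cd$time_days[j]))
  bad_r <- which(!is.na(cd$replicate) & cd$replicate < 1)
  for (j in bad_r)
    add("bad_replicate", cd$sample_id[j],
        sprintf("replicate index %s < 1", cd$replicate[j]))
  if (identical(processingState(x), "normalized")) {
    sums <- colSums(mat)
    off <- which(abs(sums - 100) > 1e-9 * 100)
    for (j in off)
      add("sum_violation", cd$sample_id[j],
          sprintf("peak sum %.6f != 100", sums[j]))
  }
  if (!is.null(panel) &&
      !processingState(x) %in% c("traits", "rank_normal")) {
    missing <- setdiff(panelPeaks(panel), rownames(mat))
    if (length(missing))
      add("missing_peak", NA,
          sprintf("panel peak(s) absent: %s", paste(missing, collapse = ", ")))
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(kind = character(), sample_id = character(),
                  detail = character(), stringsAsFactors = FALSE)
}
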