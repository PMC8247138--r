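## S4 classes and accessors for the longitudinal ASV data model.

DIET_LEVELS <- c("FV", "TV", "NR")
PHASE_LEVELS <- c("outbound", "return", "followup")

#' LongitudinalASVTable: ASV counts with longitudinal sample annotation
#'
#' A \linkS4class{SummarizedExperiment} subclass holding an ASV-by-sample
#' integer count matrix (assay \code{"counts"}) together with per-sample
#' metadata: \code{subject}, \code{day} (days since mission start, 1-based),
#' \code{diet} (\code{FV}/\code{TV}/\code{NR}), \code{phase}
#' (\code{outbound}/\code{return}/\code{followup}) and the derived
#' \code{in_isolation} flag (\code{day <= isolationEnd(x)}).
#'
#' Validity enforces: unique ASV and sample identifiers, integer
#' non-negative counts, every sample column sum positive, unique
#' (subject, day) pairs, \code{day >= 1}, \code{diet == "NR"} exactly for
#' follow-up samples, and \code{in_isolation} consistent with the stored
#' isolation end day.
#'
#' @export
setClass("LongitudinalASVTable", contains = "SummarizedExperiment")

setValidity("LongitudinalASVTable", function(object) {
  msg <- character()
  cts <- SummarizedExperiment::assay(object, "counts")
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject", "day", "diet", "phase", "in_isolation")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain:", paste(need, collapse = ", ")))
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "ASV ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (any(cts < 0) || any(cts != round(cts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (ncol(cts) > 0 && any(colSums(cts) == 0))
    msg <- c(msg, "every sample column must have a positive total count")
  if (any(cd$day < 1)) msg <- c(msg, "day must be >= 1")
  if (anyDuplicated(paste(cd$subject, cd$day)))
    msg <- c(msg, "(subject, day) pairs must be unique")
  if (!all(cd$diet %in% DIET_LEVELS))
    msg <- c(msg, "diet must be one of FV, TV, NR")
  if (!all(cd$phase %in% PHASE_LEVELS))
    msg <- c(msg, "phase must be one of outbound, return, followup")
  if (any((cd$diet == "NR") != (cd$phase == "followup")))
    msg <- c(msg, "diet NR must coincide exactly with phase followup")
  iso <- isolationEnd(object)
  if (!identical(as.logical(cd$in_isolation), as.logical(cd$day <= iso)))
    msg <- c(msg, "in_isolation must equal (day <= isolation end)")
  if (length(msg)) msg else TRUE
})

#' Construct a LongitudinalASVTable
#'
#' @param counts integer matrix, ASVs in rows (rownames = ASV ids), samples
#'   in columns (colnames = sample ids).
#' @param sampleData data.frame with one row per sample and columns
#'   \code{sample_id}, \code{subject}, \code{day}, \code{diet}, \code{phase}.
#'   Rows are matched to count columns by \code{sample_id}.
#' @param isolationEnd last day of the isolation period (default 520);
#'   used to derive the \code{in_isolation} flag.
#' @return a validated \linkS4class{LongitudinalASVTable} with samples
#'   ordered by (subject, day).
#' @export
LongitudinalASVTable <- function(counts, sampleData, isolationEnd = 520) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    stop("count matrix must have sample ids as colnames")
  if (!all(c("sample_id", "subject", "day", "diet", "phase") %in%
           colnames(sampleData)))
    stop("sampleData needs columns sample_id, subject, day, diet, phase")
  missing <- setdiff(colnames(counts), sampleData$sample_id)
  if (length(missing))
    stop("no metadata row for sample(s): ", paste(missing, collapse = ", "))
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("negative or non-integer count at ASV '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "integer"
  sampleData <- sampleData[match(colnames(counts), sampleData$sample_id), ]
  ord <- order(sampleData$subject, sampleData$day)
  counts <- counts[, ord, drop = FALSE]
  sampleData <- sampleData[ord, ]
  cd <- S4Vectors::DataFrame(
    subject = as.character(sampleData$subject),
    day = as.integer(sampleData$day),
    diet = as.character(sampleData$diet),
    phase = as.character(sampleData$phase),
    in_isolation = as.integer(sampleData$day) <= isolationEnd,
    row.names = sampleData$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd,
    metadata = list(isolation_end = isolationEnd))
  new("LongitudinalASVTable", se)
}

#' @describeIn LongitudinalASVTable ASV identifiers (rownames).
#' @param x a \code{LongitudinalASVTable}.
#' @export
asvIds <- function(x) rownames(x)

#' @describeIn LongitudinalASVTable sample identifiers (colnames).
#' @export
sampleIds <- function(x) colnames(x)

#' @describeIn LongitudinalASVTable subject id per sample.
#' @export
subjects <- function(x) SummarizedExperiment::colData(x)$subject

#' @describeIn LongitudinalASVTable sampling day per sample.
#' @export
sampleDays <- function(x) SummarizedExperiment::colData(x)$day

#' @describeIn LongitudinalASVTable diet code per sample.
#' @export
diets <- function(x) SummarizedExperiment::colData(x)$diet

#' @describeIn LongitudinalASVTable mission phase per sample.
#' @export
phases <- function(x) SummarizedExperiment::colData(x)$phase

#' @describeIn LongitudinalASVTable last day of the isolation period.
#' @export
isolationEnd <- function(x) {
  ie <- S4Vectors::metadata(x)$isolation_end
  if (is.null(ie)) 520 else ie
}

setMethod("show", "LongitudinalASVTable", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("LongitudinalASVTable:", nrow(object), "ASVs x", ncol(object),
      "samples\n")
  cat("  subjects:", length(unique(cd$subject)),
      " days:", length(unique(cd$day)),
      sprintf(" span: %d-%d\n", min(cd$day), max(cd$day)))
  cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
})

#' DiversitySeries: temporal series of community divergence
#'
#' Holds either a within-subject turnover series (one value per subject per
#' consecutive-timepoint transition, assigned to the later day) or a
#' between-subjects series (one value per timepoint: the mean of all
#' pairwise distances among subjects sampled that day).
#'
#' @slot kind \code{"within_subject"} or \code{"between_subjects"}.
#' @slot index name of the dissimilarity index used.
#' @slot points data.frame with columns \code{subject} (or \code{"ALL"}),
#'   \code{day}, \code{value}.
#' @export
setClass("DiversitySeries",
         representation(kind = "character", index = "character",
                        points = "data.frame"))

setValidity("DiversitySeries", function(object) {
  msg <- character()
  if (!object@kind %in% c("within_subject", "between_subjects"))
    msg <- c(msg, "kind must be within_subject or between_subjects")
  if (!all(c("subject", "day", "value") %in% colnames(object@points)))
    msg <- c(msg, "points needs columns subject, day, value")
  v <- object@points$value
  if (length(v) && (any(v < -1e-9) || any(v > 1 + 1e-9)))
    msg <- c(msg, "values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

DiversitySeries <- function(kind, index, points) {
  new("DiversitySeries", kind = kind, index = index,
      points = as.data.frame(points))
}

setMethod("show", "DiversitySeries", function(object) {
  cat("DiversitySeries (", object@kind, ", ", object@index, "): ",
      nrow(object@points), " points\n", sep = "")
})

#' @describeIn DiversitySeries the points data.frame.
#' @param x a \code{DiversitySeries}.
#' @export
seriesPoints <- function(x) x@points

#' @describeIn DiversitySeries the series kind.
#' @export
seriesKind <- function(x) x@kind

#' Segmentation: change-point structure of a temporal series
#'
#' @slot changepoint_days strictly increasing numeric vector of change-point
#'   days (a change-point at day d closes its segment at d inclusive);
#'   possibly empty.
#' @slot segments data.frame with \code{start_day}, \code{end_day}
#'   partitioning the observation span.
#' @slot fitness inverse summed segment RMSE of the accepted segmentation.
#' @slot ga_trace data.frame of best fitness per GA generation (may be
#'   empty when no refinement was run).
#' @export
setClass("Segmentation",
         representation(changepoint_days = "numeric", segments = "data.frame",
                        fitness = "numeric", ga_trace = "data.frame"))

setValidity("Segmentation", function(object) {
  cps <- object@changepoint_days
  if (length(cps) > 1 && any(diff(cps) <= 0))
    return("changepoint_days must be strictly increasing")
  seg <- object@segments
  if (!all(c("start_day", "end_day") %in% colnames(seg)))
    return("segments needs start_day, end_day")
  if (nrow(seg) != length(cps) + 1)
    return("number of segments must be number of changepoints + 1")
  TRUE
})

Segmentation <- function(changepoint_days, span, fitness = NA_real_,
                         ga_trace = data.frame()) {
  cps <- sort(unique(as.numeric(changepoint_days)))
  bounds <- c(span[1], cps, span[2])
  segments <- data.frame(start_day = head(bounds, -1), end_day = bounds[-1])
  ## interior starts are exclusive: segment k covers (cp_{k-1}, cp_k]
  new("Segmentation", changepoint_days = cps, segments = segments,
      fitness = as.numeric(fitness), ga_trace = as.data.frame(ga_trace))
}

setMethod("show", "Segmentation", function(object) {
  cat("Segmentation:", length(object@changepoint_days), "change-point(s)")
  if (length(object@changepoint_days))
    cat(" at day(s)", paste(object@changepoint_days, collapse = ", "))
  cat("\n  fitness (1/sum RMSE):", format(object@fitness, digits = 5), "\n")
})

#' @describeIn Segmentation change-point days.
#' @param x a \code{Segmentation}.
#' @export
changepointDays <- function(x) x@changepoint_days

#' @describeIn Segmentation segment table.
#' @export
segmentTable <- function(x) x@segments

#' Assign observation days to segments
#'
#' A change-point at day d closes its segment at d inclusive (matching the
#' convention that the second segment of a 1-720 span with change-points at
#' 123 and 480 covers days 124-480).
#'
#' @param seg a \code{Segmentation}.
#' @param days numeric vector of observation days.
#' @return integer segment index per day.
#' @export
segmentOf <- function(seg, days) {
  cps <- changepointDays(seg)
  findInterval(days, c(-Inf, cps), left.open = TRUE)
}
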