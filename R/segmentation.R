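#' Construct a Segmentation from intervals
#'
#' @param state character vector of interval labels.
#' @param start integer vector of 0-based inclusive starts.
#' @param end integer vector of exclusive ends.
#' @return A [Segmentation-class] object.
#' @examples
#' segmentation(c("diagnosis", "cutting"), c(0, 10), c(10, 25))
#' @export
segmentation <- function(state, start, end) {
  new("Segmentation", state = as.character(state),
      start = as.integer(start), end = as.integer(end))
}

#' Build a Segmentation from per-frame labels
#'
#' Run-length encodes a per-frame label vector into contiguous half-open
#' intervals.
#'
#' @param labels character (or factor) vector of per-frame activity labels.
#' @return A [Segmentation-class] object.
#' @examples
#' segmentationFromLabels(c("a", "a", "b", "b", "b"))
#' @export
segmentationFromLabels <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("labels must be non-empty")
  r <- rle(labels)
  end <- cumsum(r$lengths)
  start <- c(0L, end[-length(end)])
  segmentation(r$values, start, end)
}

#' Read/write segmentations as CSV
#'
#' `writeSegmentationCSV` stores the interval form (columns `state`, `start`,
#' `end`); `readSegmentationCSV` reads it back. `writeFrameLabelsCSV` stores
#' the per-frame form (columns `frame`, `activity`, 0-based frames);
#' `readFrameLabelsCSV` reads that back into a Segmentation.
#'
#' @param seg a [Segmentation-class] object.
#' @param path file path.
#' @return The read functions return a [Segmentation-class]; the write
#'   functions return `path` invisibly.
#' @name segmentationIO
NULL

#' @rdname segmentationIO
#' @export
writeSegmentationCSV <- function(seg, path) {
  write.csv(intervals(seg), path, row.names = FALSE)
  invisible(path)
}

#' @rdname segmentationIO
#' @export
readSegmentationCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  segmentation(df$state, df$start, df$end)
}

#' @rdname segmentationIO
#' @export
writeFrameLabelsCSV <- function(seg, path) {
  lab <- frameLabels(seg)
  write.csv(data.frame(frame = seq_along(lab) - 1L, activity = lab),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname segmentationIO
#' @export
readFrameLabelsCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  segmentationFromLabels(df$activity[order(df$frame)])
}
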