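#' Intersection-over-union of one activity between two segmentations
#'
#' IoU is computed on frame sets: the number of frames labeled with the
#' activity in both segmentations divided by the number labeled in either.
#' This makes the score symmetric and invariant to how intervals are split.
#' When the activity occurs in neither segmentation the score is 1 by
#' convention (nothing to disagree about); when it occurs in exactly one, 0.
#'
#' @param pred,truth [Segmentation-class] objects covering the same frames.
#' @param activity activity name.
#' @return IoU in `[0, 1]`.
#' @examples
#' p <- segmentation(c("a", "b"), c(0, 10), c(10, 20))
#' t <- segmentation(c("b", "a", "b"), c(0, 5, 15), c(5, 15, 20))
#' activityIoU(p, t, "a")  # 5 / 15
#' @export
activityIoU <- function(pred, truth, activity) {
  if (trajectoryLength(pred) != trajectoryLength(truth))
    stop("pred and truth must cover the same frame range")
  p <- frameLabels(pred) == activity
  g <- frameLabels(truth) == activity
  union <- sum(p | g)
  if (union == 0L) return(1)
  sum(p & g) / union
}

#' Mean and spread of per-trajectory IoU values
#'
#' @param values numeric vector of per-trajectory IoU values (nonempty).
#' @param sample use the sample (n-1) standard deviation (default `TRUE`,
#'   matching the conventional "mean (sd)" reporting); `FALSE` uses the
#'   population formula. A singleton list yields sd 0.
#' @return Named numeric vector `c(mean = ..., sd = ...)`.
#' @examples
#' meanIoU(c(0.1, 0.4, 0.7))  # mean 0.4, sd 0.3
#' @export
meanIoU <- function(values, sample = TRUE) {
  if (!length(values)) stop("values must be nonempty")
  m <- mean(values)
  s <- if (length(values) == 1L) 0
  else if (sample) sd(values)
  else sqrt(mean((values - m)^2))
  c(mean = m, sd = s)
}

#' Evaluate one model's decodings against ground truth
#'
#' @param decodings list of [Segmentation-class] (one per trajectory).
#' @param truth list of [Segmentation-class], aligned with `decodings`.
#' @param activities activities to score (default all in the truth).
#' @param model model identifier.
#' @param excludeBothAbsent drop trajectories where the activity occurs in
#'   neither segmentation from that activity's mean (default `FALSE`:
#'   both-absent counts as IoU 1).
#' @return An [EvalReport-class].
#' @export
evaluateSegmentations <- function(decodings, truth, activities = NULL,
                                  model = "model",
                                  excludeBothAbsent = FALSE) {
  if (length(decodings) != length(truth))
    stop("decodings and truth must have the same length")
  if (is.null(activities))
    activities <- unique(unlist(lapply(truth, function(s) s@state)))
  rows <- list()
  correct <- 0; total <- 0
  for (i in seq_along(decodings)) {
    pl <- frameLabels(decodings[[i]])
    tl <- frameLabels(truth[[i]])
    correct <- correct + sum(pl == tl)
    total <- total + length(tl)
    for (a in activities) {
      occurs <- a %in% decodings[[i]]@state || a %in% truth[[i]]@state
      rows[[length(rows) + 1L]] <- data.frame(
        trajectory = i, activity = a,
        iou = activityIoU(decodings[[i]], truth[[i]], a),
        occurs = occurs)
    }
  }
  per <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(activities, function(a) {
    sub <- per[per$activity == a, ]
    if (excludeBothAbsent) sub <- sub[sub$occurs, ]
    if (!nrow(sub))
      return(data.frame(activity = a, mean_iou = NA_real_, sd_iou = NA_real_,
                        n = 0L))
    ms <- meanIoU(sub$iou)
    data.frame(activity = a, mean_iou = ms[["mean"]], sd_iou = ms[["sd"]],
               n = nrow(sub))
  }))
  new("EvalReport", model = model, perTrajectory = per[, 1:3],
      summary = summ, frameAccuracy = correct / total)
}

#' Compare several models' decodings
#'
#' Produces a side-by-side table of per-activity mean IoU (with standard
#' deviations) for all models and, optionally, timeline plots of the
#' segmentations.
#'
#' @param decodings named list: model name -> list of
#'   [Segmentation-class] decodings.
#' @param truth list of ground-truth [Segmentation-class] objects.
#' @param activities activities to score (default all in the truth).
#' @param plotFile optional PNG path for segmentation timeline plots.
#' @return List with `reports` (named list of [EvalReport-class]) and
#'   `table` (data.frame: activity x model mean IoU and sd).
#' @export
compareModels <- function(decodings, truth, activities = NULL,
                          plotFile = NULL) {
  if (is.null(names(decodings)) || any(names(decodings) == ""))
    stop("decodings must be a named list (one entry per model)")
  reports <- lapply(names(decodings), function(nm)
    evaluateSegmentations(decodings[[nm]], truth, activities, model = nm))
  names(reports) <- names(decodings)
  tab <- NULL
  for (nm in names(reports)) {
    s <- reports[[nm]]@summary
    cols <- data.frame(s$mean_iou, s$sd_iou)
    names(cols) <- paste0(nm, c("_mean_iou", "_sd_iou"))
    tab <- if (is.null(tab)) cbind(data.frame(activity = s$activity), cols)
    else cbind(tab, cols)
  }
  if (!is.null(plotFile))
    plotSegmentations(c(list(truth = truth), decodings), plotFile)
  list(reports = reports, table = tab)
}

#' Timeline plot of segmentations
#'
#' Draws horizontal bar timelines of per-trajectory segmentations, one row
#' per (trajectory, model), colored by activity.
#'
#' @param segLists named list: model name -> list of [Segmentation-class].
#' @param file PNG output path.
#' @param states activity color ordering (default [activityStates()]).
#' @return `file`, invisibly.
#' @export
plotSegmentations <- function(segLists, file, states = activityStates()) {
  nModels <- length(segLists)
  nTraj <- length(segLists[[1L]])
  cols <- grDevices::hcl.colors(length(states), "Dark 3")
  names(cols) <- states
  grDevices::png(file, width = 900,
                 height = 60 * nTraj * nModels / 2 + 120)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 8, 2, 1))
  maxT <- max(vapply(segLists[[1L]], trajectoryLength, numeric(1L)))
  nRows <- nTraj * nModels
  graphics::plot(NULL, xlim = c(0, maxT), ylim = c(0, nRows),
                 xlab = "frame", ylab = "", yaxt = "n",
                 main = "Decoded activity timelines")
  labs <- character(nRows)
  row <- 0L
  for (i in seq_len(nTraj)) {
    for (m in seq_len(nModels)) {
      seg <- segLists[[m]][[i]]
      df <- intervals(seg)
      graphics::rect(df$start, nRows - row - 0.9, df$end, nRows - row - 0.1,
                     col = cols[df$state], border = NA)
      labs[nRows - row] <- sprintf("t%d %s", i, names(segLists)[m])
      row <- row + 1L
    }
  }
  graphics::axis(2, at = seq_len(nRows) - 0.5, labels = labs, las = 2,
                 cex.axis = 0.6)
  graphics::legend("bottomright", legend = states, fill = cols, cex = 0.7,
                   bg = "white")
  invisible(file)
}

#' Write an evaluation report as CSV / JSON
#'
#' @param report an [EvalReport-class].
#' @param csvPath,jsonPath output paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
writeEvalReport <- function(report, csvPath = NULL, jsonPath = NULL) {
  written <- character(0)
  if (!is.null(csvPath)) {
    write.csv(report@summary, csvPath, row.names = FALSE)
    written <- c(written, csvPath)
  }
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(model = report@model, frame_accuracy = report@frameAccuracy,
           summary = report@summary, per_trajectory = report@perTrajectory),
      jsonPath, digits = NA, auto_unbox = TRUE, dataframe = "rows")
    written <- c(written, jsonPath)
  }
  invisible(written)
}
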