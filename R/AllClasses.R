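#' Canonical activity state space of a hysteroscopic myomectomy
#'
#' The six activities of the simulated procedure, in their fixed canonical
#' order. The order defines the index-to-name mapping used throughout the
#' package (transition matrices, emission tables, duration parameters).
#'
#' @return Character vector of length 6.
#' @examples
#' activityStates()
#' @export
activityStates <- function() {
  c("diagnosis", "position hysteroscope", "cutting", "coagulation",
    "clear view", "handle chips")
}

#' @title Segmentation of a trajectory into activity intervals
#'
#' @description An ordered, contiguous, gap-free partition of the frame range
#' `[0, tau)` into half-open intervals `[start, end)`, each carrying an
#' activity label. Zero-based frame indexing is used throughout so that a
#' segmentation maps one-to-one onto per-frame label vectors. Consecutive
#' intervals always carry different labels.
#'
#' @slot state character vector of interval labels.
#' @slot start integer vector of interval starts (0-based, inclusive).
#' @slot end integer vector of interval ends (exclusive).
#'
#' @seealso [segmentation()], [segmentationFromLabels()], [frameLabels()]
#' @export
setClass("Segmentation",
         representation(state = "character", start = "integer",
                        end = "integer"))

setValidity("Segmentation", function(object) {
  n <- length(object@state)
  if (length(object@start) != n || length(object@end) != n)
    return("state, start and end must have equal length")
  if (n == 0L) return("a Segmentation must contain at least one interval")
  if (object@start[1L] != 0L) return("first interval must start at frame 0")
  if (any(object@end <= object@start))
    return("every interval must satisfy end > start")
  if (n > 1L) {
    if (any(object@start[-1L] != object@end[-n]))
      return("intervals must be contiguous and gap-free")
    if (any(object@state[-1L] == object@state[-n]))
      return("consecutive intervals must carry different states")
  }
  TRUE
})

#' @title Explicit-duration hidden semi-Markov model parameterization
#'
#' @description Full parameterization of an explicit-duration HSMM over a
#' finite activity state space: initial distribution, zero-diagonal
#' row-stochastic transition matrix, per-state negative-binomial duration
#' parameters, per-state per-channel categorical emission tables, and the
#' duration truncation bound `dMax`. State dwell times are governed solely by
#' the duration model (no self-transitions); the dwell-time distribution is a
#' negative binomial shifted to support `{1, 2, ...}` and renormalized over
#' `{1, ..., dMax}`.
#'
#' @slot states character vector of state names (fixed order).
#' @slot initial numeric initial state distribution.
#' @slot transitions numeric matrix, rows sum to 1, zero diagonal.
#' @slot durations numeric matrix with columns `r` (size) and `p`
#'   (success probability) of the per-state negative binomial.
#' @slot emissions list: one entry per state, each a list with one
#'   probability vector per sensor channel (symbols are 1-based integers).
#' @slot dMax integer maximum modeled dwell time in frames.
#'
#' @seealso [hsmmSpec()], [viterbiDecode()], [sequenceLogLik()]
#' @export
setClass("HSMMSpec",
         representation(states = "character", initial = "numeric",
                        transitions = "matrix", durations = "matrix",
                        emissions = "list", dMax = "integer"))

setValidity("HSMMSpec", function(object) {
  S <- length(object@states)
  tol <- 1e-12
  if (S < 1L) return("at least one state is required")
  if (anyDuplicated(object@states)) return("state names must be unique")
  if (length(object@initial) != S) return("initial must have one entry per state")
  if (!isProbVector(object@initial, tol)) return("initial must sum to 1")
  if (!all(dim(object@transitions) == c(S, S)))
    return("transitions must be a square states x states matrix")
  if (any(abs(diag(object@transitions)) > 0))
    return("transitions must have a zero diagonal (no self-transitions)")
  if (S > 1L) {
    if (any(object@transitions < 0) ||
        any(abs(rowSums(object@transitions) - 1) > 1e-9))
      return("each transition row must be a probability vector")
  }
  if (!all(dim(object@durations) == c(S, 2L)))
    return("durations must be a states x 2 matrix with columns r and p")
  r <- object@durations[, 1L]; p <- object@durations[, 2L]
  if (any(r <= 0)) return("duration r parameters must be positive")
  if (any(p <= 0 | p >= 1)) return("duration p parameters must lie in (0,1)")
  if (length(object@emissions) != S)
    return("emissions must hold one channel list per state")
  nch <- vapply(object@emissions, length, 1L)
  if (length(unique(nch)) != 1L)
    return("all states must define the same number of emission channels")
  for (s in seq_len(S)) {
    for (c in seq_along(object@emissions[[s]])) {
      tab <- object@emissions[[s]][[c]]
      if (!isProbVector(tab, tol))
        return(sprintf("emission table for state '%s', channel %d must sum to 1",
                       object@states[s], c))
    }
  }
  if (length(unique(lapply(seq_len(nch[1L]), function(c)
    vapply(object@emissions, function(e) length(e[[c]]), 1L)))) >= 1L) {
    for (c in seq_len(nch[1L])) {
      ks <- vapply(object@emissions, function(e) length(e[[c]]), 1L)
      if (length(unique(ks)) != 1L)
        return(sprintf("channel %d must have the same symbol count in every state", c))
    }
  }
  if (object@dMax < 1L) return("dMax must be >= 1")
  TRUE
})

#' @title Configuration of the synthetic trajectory generator
#'
#' @description Parameterizes the generator that emulates simulator
#' trajectories of a hysteroscopic myomectomy: an activity transition graph
#' with negative-binomial dwell times, activity-conditional categorical
#' sensor channels (with optional forced emission ambiguity between activity
#' pairs), and a toy rendered video whose global intensity drifts with
#' surgery progress and which displays a localized bright "tool" blob from
#' the end of the diagnosis activity onward.
#'
#' @slot nTrajectories integer number of trajectories.
#' @slot frameRate frames per second (metadata; 2 by default).
#' @slot states character activity names.
#' @slot activityGraph row-stochastic transition matrix (zero diagonal; the
#'   terminal activity's row is all zero and marks absorption).
#' @slot initialDistribution probability vector over states.
#' @slot durationParams states x 2 matrix (columns `r`, `p`).
#' @slot sensorSpec per-state list of per-channel categorical tables.
#' @slot ambiguityPairs list of length-2 character vectors; the second
#'   activity of each pair copies the first's emission tables exactly.
#' @slot videoSize pixels per side of the square grayscale frames.
#' @slot driftRange numeric length-2: mean-intensity at progress 0 and 1.
#' @slot blobAmplitude added intensity of the tool blob.
#' @slot noiseSd standard deviation of additive pixel noise.
#' @slot illumSd standard deviation of the per-trajectory illumination
#'   offset (constant within a trajectory).
#' @slot terminalActivity activity that ends every trajectory.
#' @slot minInitialRun minimum dwell (frames) of the initial activity; the
#'   opening diagnostic inspection cannot be sub-second.
#' @slot maxFrames hard cap on trajectory length (guards runaways).
#' @slot seed master seed.
#'
#' @seealso [generatorConfig()], [generateDataset()]
#' @export
setClass("GeneratorConfig",
         representation(nTrajectories = "integer", frameRate = "numeric",
                        states = "character", activityGraph = "matrix",
                        initialDistribution = "numeric",
                        durationParams = "matrix", sensorSpec = "list",
                        ambiguityPairs = "list", videoSize = "integer",
                        driftRange = "numeric", blobAmplitude = "numeric",
                        noiseSd = "numeric", illumSd = "numeric",
                        terminalActivity = "character",
                        minInitialRun = "integer",
                        maxFrames = "integer", seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  S <- length(object@states)
  tol <- 1e-12
  if (object@nTrajectories < 0L) return("nTrajectories must be >= 0")
  if (!isProbVector(object@initialDistribution, tol))
    return("initialDistribution must sum to 1 within 1e-12")
  if (!all(dim(object@activityGraph) == c(S, S)))
    return("activityGraph must be states x states")
  if (any(abs(diag(object@activityGraph)) > 0))
    return("activityGraph must have no self-loops")
  rs <- rowSums(object@activityGraph)
  if (any(object@activityGraph < 0) || any(abs(rs - 1) > 1e-9 & abs(rs) > tol))
    return("each activityGraph row must sum to 1 (or to 0 for the terminal activity)")
  if (length(object@sensorSpec) != S)
    return("sensorSpec needs one channel list per activity")
  for (s in seq_len(S)) {
    for (c in seq_along(object@sensorSpec[[s]])) {
      if (!isProbVector(object@sensorSpec[[s]][[c]], tol))
        return(sprintf("sensor table for '%s' channel %d must sum to 1 within 1e-12",
                       object@states[s], c))
    }
  }
  for (pair in object@ambiguityPairs) {
    if (length(pair) != 2L || !all(pair %in% object@states))
      return("every ambiguity pair must name two known activities")
    i <- match(pair[1L], object@states); j <- match(pair[2L], object@states)
    if (!identical(object@sensorSpec[[i]], object@sensorSpec[[j]]))
      return(sprintf("ambiguity pair (%s, %s) must share identical emission tables",
                     pair[1L], pair[2L]))
  }
  if (object@videoSize < 8L)
    return("videoSize must be >= 8 (the tool blob cannot be rendered below that)")
  r <- object@durationParams[, 1L]; p <- object@durationParams[, 2L]
  if (any(r <= 0) || any(p <= 0 | p >= 1))
    return("duration parameters require r > 0 and p in (0,1)")
  if (!(object@terminalActivity %in% object@states))
    return("terminalActivity must be one of the states")
  if (object@minInitialRun < 1L) return("minInitialRun must be >= 1")
  TRUE
})

#' @title One synthetic simulator trajectory
#'
#' @description Bundles the per-frame activity labels, the time-aligned
#' categorical sensor stream, the rendered grayscale video and the planted
#' event times of a single generated trajectory. All three modalities share
#' the same length `tau`.
#'
#' @slot activities character vector of per-frame activity labels.
#' @slot sensors integer matrix, frames x channels, 1-based symbols.
#' @slot video numeric array `tau x size x size` with intensities in `[0,1]`.
#' @slot eventTimes named integer vector of 0-based event frame indices
#'   (includes `diagnosis_end` and, when a cutting activity occurs,
#'   `first_cut_end`).
#' @slot seed the trajectory-level seed used to generate it.
#' @export
setClass("SyntheticTrajectory",
         representation(activities = "character", sensors = "matrix",
                        video = "array", eventTimes = "integer",
                        seed = "integer"))

setValidity("SyntheticTrajectory", function(object) {
  tau <- length(object@activities)
  if (tau < 1L) return("trajectory must contain at least one frame")
  if (nrow(object@sensors) != tau) return("sensors and activities must align")
  if (dim(object@video)[1L] != tau) return("video and activities must align")
  if ("diagnosis_end" %in% names(object@eventTimes)) {
    de <- object@eventTimes[["diagnosis_end"]]
    first <- match(TRUE, object@activities != object@activities[1L])
    recomputed <- if (is.na(first)) tau else first - 1L
    if (de != recomputed)
      return("diagnosis_end must equal the first frame whose activity differs from the initial one")
  }
  TRUE
})

#' @title Multivariate trace of internal network activations
#'
#' @description Per-frame values of one source inside the trained
#' remaining-surgery-progress model (a layer output or a recurrent gate
#' activation) for a single trajectory: a `tau x width` matrix.
#'
#' @slot source character identifier of the layer/gate.
#' @slot values numeric matrix, frames x units.
#' @slot trajectoryId character identifier of the trajectory.
#' @export
setClass("RepresentationTrace",
         representation(source = "character", values = "matrix",
                        trajectoryId = "character"))

setValidity("RepresentationTrace", function(object) {
  if (!is.numeric(object@values)) return("values must be numeric")
  if (nrow(object@values) < 1L) return("trace must contain at least one frame")
  if (any(!is.finite(object@values))) return("trace values must be finite")
  TRUE
})

#' @title Change-point detection configuration
#'
#' @description Settings for PELT with a kernelized mean-change segment cost.
#' The linear kernel reduces the cost to the within-segment sum of squared
#' deviations from the segment mean; the RBF kernel uses a Gaussian kernel
#' with the given (or median-heuristic) bandwidth.
#'
#' @slot kernel `"linear"` or `"rbf"`.
#' @slot bandwidth positive bandwidth of the RBF kernel (`NA` requests the
#'   median heuristic).
#' @slot penalty nonnegative per-change-point penalty.
#' @slot minSegment minimum segment length in frames.
#' @slot standardize standardize each channel to zero mean / unit variance
#'   over the trajectory before costing.
#' @export
setClass("CPConfig",
         representation(kernel = "character", bandwidth = "numeric",
                        penalty = "numeric", minSegment = "integer",
                        standardize = "logical"))

setValidity("CPConfig", function(object) {
  if (!object@kernel %in% c("linear", "rbf"))
    return("kernel must be 'linear' or 'rbf'")
  if (object@penalty < 0) return("penalty must be >= 0")
  if (object@kernel == "rbf" && !is.na(object@bandwidth) &&
      object@bandwidth <= 0)
    return("bandwidth must be positive for the rbf kernel")
  if (object@minSegment < 1L) return("minSegment must be >= 1")
  TRUE
})

#' @title Result of change-point detection
#'
#' @description Change points are reported as the 0-based first index of each
#' new segment, strictly increasing and strictly inside `(0, tau)`.
#' `totalCost` is the penalized objective attained (sum of segment costs plus
#' penalty times the number of change points).
#'
#' @slot changepoints integer vector of segment-start indices.
#' @slot totalCost numeric attained objective value.
#' @export
setClass("CPResult",
         representation(changepoints = "integer", totalCost = "numeric"))

#' @title Latched binary event indicator
#'
#' @description A binary per-frame observable that switches from 0 to 1 at a
#' detected event onset and stays at 1 afterwards (non-decreasing by
#' construction). `onset` is the 0-based frame of the first 1, or `NA` if the
#' event was never detected.
#'
#' @slot values integer vector of 0/1.
#' @slot onset integer onset frame or `NA`.
#' @export
setClass("EventIndicator",
         representation(values = "integer", onset = "integer"))

setValidity("EventIndicator", function(object) {
  v <- object@values
  if (!all(v %in% c(0L, 1L))) return("indicator values must be 0/1")
  if (any(diff(v) < 0L)) return("indicator must be non-decreasing (latched)")
  on <- object@onset
  first <- match(1L, v)
  if (is.na(on)) {
    if (!is.na(first)) return("onset NA but the indicator contains a 1")
  } else {
    if (is.na(first) || first - 1L != on)
      return("onset must equal the 0-based index of the first 1")
  }
  TRUE
})

#' @title Remaining-surgery-progress model
#'
#' @description A compact sequence-regression network: a small convolutional
#' encoder maps each grayscale frame to a feature vector, a gated recurrent
#' decoder (GRU or LSTM) summarizes the history, and a three-layer MLP head
#' with PReLU activations and a final sigmoid outputs the predicted remaining
#' surgery progress in `(0, 1)` for every frame.
#'
#' @slot spec list of architecture hyperparameters (see [rspModelSpec()]).
#' @slot params named list of weight arrays.
#' @slot history data.frame of per-epoch train/validation MAE (empty before
#'   training).
#' @export
setClass("RSPModel",
         representation(spec = "list", params = "list", history = "data.frame"))

#' @title Segmentation evaluation report
#'
#' @description Per-trajectory per-activity intersection-over-union scores
#' together with their across-trajectory mean and standard deviation and the
#' overall frame accuracy, for one model.
#'
#' @slot model character model identifier.
#' @slot perTrajectory data.frame with columns trajectory, activity, iou.
#' @slot summary data.frame with columns activity, mean_iou, sd_iou, n.
#' @slot frameAccuracy numeric overall fraction of correctly labeled frames.
#' @export
setClass("EvalReport",
         representation(model = "character", perTrajectory = "data.frame",
                        summary = "data.frame", frameAccuracy = "numeric"))
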