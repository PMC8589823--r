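#' @title Accessor generics
#' @description Accessors for the package's S4 containers.
#' @param object an object of the documented class.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("activities", function(object, ...) standardGeneric("activities"))

#' @rdname accessors
#' @export
setGeneric("sensors", function(object, ...) standardGeneric("sensors"))

#' @rdname accessors
#' @export
setGeneric("video", function(object, ...) standardGeneric("video"))

#' @rdname accessors
#' @export
setGeneric("eventTimes", function(object, ...) standardGeneric("eventTimes"))

#' @rdname accessors
#' @export
setGeneric("trajectoryLength", function(object, ...)
  standardGeneric("trajectoryLength"))

#' @rdname accessors
#' @export
setGeneric("intervals", function(object, ...) standardGeneric("intervals"))

#' @rdname accessors
#' @export
setGeneric("frameLabels", function(object, ...) standardGeneric("frameLabels"))

#' @rdname accessors
#' @export
setGeneric("nStates", function(object, ...) standardGeneric("nStates"))

#' @rdname accessors
#' @export
setGeneric("states", function(object, ...) standardGeneric("states"))

#' @rdname accessors
#' @export
setGeneric("changepoints", function(object, ...)
  standardGeneric("changepoints"))

#' @rdname accessors
#' @export
setGeneric("onset", function(object, ...) standardGeneric("onset"))

#' @rdname accessors
#' @export
setGeneric("traceValues", function(object, ...) standardGeneric("traceValues"))

#' @rdname accessors
#' @export
setGeneric("traceSource", function(object, ...) standardGeneric("traceSource"))

## ---- methods ----

#' @rdname accessors
#' @export
setMethod("activities", "SyntheticTrajectory", function(object, ...)
  object@activities)

#' @rdname accessors
#' @export
setMethod("sensors", "SyntheticTrajectory", function(object, ...)
  object@sensors)

#' @rdname accessors
#' @export
setMethod("video", "SyntheticTrajectory", function(object, ...) object@video)

#' @rdname accessors
#' @export
setMethod("eventTimes", "SyntheticTrajectory", function(object, ...)
  object@eventTimes)

#' @rdname accessors
#' @export
setMethod("trajectoryLength", "SyntheticTrajectory", function(object, ...)
  length(object@activities))

#' @rdname accessors
#' @export
setMethod("intervals", "Segmentation", function(object, ...) {
  data.frame(state = object@state, start = object@start, end = object@end,
             stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("trajectoryLength", "Segmentation", function(object, ...)
  object@end[length(object@end)])

#' @rdname accessors
#' @export
setMethod("frameLabels", "Segmentation", function(object, ...)
  rep(object@state, object@end - object@start))

#' @rdname accessors
#' @export
setMethod("states", "HSMMSpec", function(object, ...) object@states)

#' @rdname accessors
#' @export
setMethod("nStates", "HSMMSpec", function(object, ...)
  length(object@states))

#' @rdname accessors
#' @export
setMethod("changepoints", "CPResult", function(object, ...)
  object@changepoints)

#' @rdname accessors
#' @export
setMethod("onset", "EventIndicator", function(object, ...) object@onset)

#' @rdname accessors
#' @export
setMethod("traceValues", "RepresentationTrace", function(object, ...)
  object@values)

#' @rdname accessors
#' @export
setMethod("traceSource", "RepresentationTrace", function(object, ...)
  object@source)

## ---- show methods ----

setMethod("show", "Segmentation", function(object) {
  cat(sprintf("Segmentation: %d interval(s), %d frames\n",
              length(object@state), trajectoryLength(object)))
  df <- intervals(object)
  print(head(df, 10L), row.names = FALSE)
  if (nrow(df) > 10L) cat(sprintf("... and %d more\n", nrow(df) - 10L))
})

setMethod("show", "HSMMSpec", function(object) {
  cat(sprintf("Explicit-duration HSMM: %d states, %d channel(s), dMax = %d\n",
              length(object@states), length(object@emissions[[1L]]),
              object@dMax))
  cat("states:", paste(object@states, collapse = ", "), "\n")
})

setMethod("show", "SyntheticTrajectory", function(object) {
  cat(sprintf("SyntheticTrajectory: %d frames, %d sensor channel(s), %dx%d video\n",
              length(object@activities), ncol(object@sensors),
              dim(object@video)[2L], dim(object@video)[3L]))
  et <- object@eventTimes
  if (length(et))
    cat("events:", paste(sprintf("%s=%d", names(et), et), collapse = ", "), "\n")
})

setMethod("show", "RepresentationTrace", function(object) {
  cat(sprintf("RepresentationTrace '%s' (%s): %d frames x %d unit(s)\n",
              object@source, object@trajectoryId, nrow(object@values),
              ncol(object@values)))
})

setMethod("show", "CPResult", function(object) {
  cat(sprintf("CPResult: %d change point(s), total cost %.4f\n",
              length(object@changepoints), object@totalCost))
  if (length(object@changepoints))
    cat("at:", paste(object@changepoints, collapse = ", "), "\n")
})

setMethod("show", "EventIndicator", function(object) {
  cat(sprintf("EventIndicator: %d frames, onset %s\n", length(object@values),
              if (is.na(object@onset)) "none" else object@onset))
})

setMethod("show", "RSPModel", function(object) {
  sp <- object@spec
  cat(sprintf("RSP model: %s encoder (%dpx, width %d) -> %s decoder (%d x %d) -> MLP head\n",
              sp$encoder, sp$inputSize, sp$encoderWidth, sp$decoder,
              sp$decoderLayers, sp$decoderWidth))
  if (nrow(object@history))
    cat(sprintf("trained %d epoch(s); final val MAE %.4f\n",
                nrow(object@history),
                object@history$val_mae[nrow(object@history)]))
  else cat("untrained (random initialization)\n")
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport for '%s' (frame accuracy %.4f)\n", object@model,
              object@frameAccuracy))
  print(object@summary, row.names = FALSE)
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(
    "GeneratorConfig: %d trajectories, %d activities, %d sensor channel(s), %dx%d video, seed %d\n",
    object@nTrajectories, length(object@states),
    length(object@sensorSpec[[1L]]), object@videoSize, object@videoSize,
    object@seed))
})
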