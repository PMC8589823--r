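## Default study conditions of the synthetic benchmark. The generator
## emulates a cohort of hysteroscopic myomectomy simulator trajectories:
## every trajectory opens with a diagnostic inspection, then alternates
## operative activities (position hysteroscope, cutting, coagulation, clear
## view) and terminates with chip removal ("handle chips"). Dwell times are
## negative binomial (large intersample variance); sensor channels mimic
## pedal/valve/position-derived categorical observables; the pedal-free
## activities (diagnosis, position hysteroscope, handle chips) are given
## identical sensor emissions, reproducing the ambiguity that makes the
## diagnosis/position boundary invisible to sensors alone.

defaultActivityGraph <- function(states = activityStates()) {
  A <- matrix(0, 6, 6, dimnames = list(states, states))
  A["diagnosis", "position hysteroscope"] <- 1
  A["position hysteroscope", c("cutting", "coagulation", "clear view",
                               "handle chips")] <- c(0.80, 0.05, 0.05, 0.10)
  A["cutting", c("coagulation", "clear view", "position hysteroscope",
                 "handle chips")] <- c(0.30, 0.20, 0.25, 0.25)
  A["coagulation", c("cutting", "clear view", "position hysteroscope",
                     "handle chips")] <- c(0.35, 0.15, 0.25, 0.25)
  A["clear view", c("cutting", "coagulation", "position hysteroscope",
                    "handle chips")] <- c(0.40, 0.05, 0.30, 0.25)
  A   # terminal "handle chips" row stays zero (absorbing)
}

## (r, p) per activity, chosen so dwell-time means (in frames at 2 fps) are
## diagnosis 16, position 4, cutting 6, coagulation 4, clear view 4, handle
## chips 9. Small r (high dispersion) on diagnosis and handle chips reflects
## the large intersample variance of those phases. p = r / (r + mean - 1).
defaultDurationParams <- function(states = activityStates()) {
  r <- c(3, 4, 3, 2, 2, 2)
  m <- c(16, 4, 6, 4, 4, 9)
  out <- cbind(r = r, p = r / (r + m - 1))
  rownames(out) <- states
  out
}

## 4 categorical channels: cutting pedal {off,on}, coagulation pedal
## {off,on}, outflow valve {closed,half,open}, tool position zone {1..4}.
defaultSensorSpec <- function(states = activityStates()) {
  base <- list(c(0.95, 0.05), c(0.95, 0.05), c(0.70, 0.20, 0.10),
               c(0.40, 0.30, 0.20, 0.10))
  spec <- list(
    "diagnosis" = base,
    "position hysteroscope" = base,
    "cutting" = list(c(0.10, 0.90), c(0.90, 0.10), c(0.10, 0.60, 0.30),
                     c(0.10, 0.20, 0.40, 0.30)),
    "coagulation" = list(c(0.85, 0.15), c(0.10, 0.90), c(0.20, 0.30, 0.50),
                         c(0.10, 0.30, 0.40, 0.20)),
    "clear view" = list(c(0.90, 0.10), c(0.85, 0.15), c(0.10, 0.20, 0.70),
                        c(0.20, 0.40, 0.30, 0.10)),
    "handle chips" = base)
  spec[states]
}

#' Construct a synthetic-data generator configuration
#'
#' Builds a validated [GeneratorConfig-class]. The defaults are the
#' package's standard benchmark conditions: 38 trajectories over the six
#' myomectomy activities, negative-binomial dwell times (diagnosis the
#' longest and most variable activity), four categorical sensor channels
#' with identical emissions for the pedal-free activities (diagnosis,
#' position hysteroscope, handle chips), 16x16 grayscale video at 2 fps
#' whose mean intensity drifts with surgery progress and which shows a
#' bright tool blob from the end of the diagnosis onward.
#'
#' For every pair in `ambiguityPairs` the second activity's sensor tables
#' are overwritten with an exact copy of the first's before validation.
#'
#' @param nTrajectories number of trajectories (default 38).
#' @param frameRate frames per second (default 2).
#' @param states activity names (default [activityStates()]).
#' @param activityGraph allowed-transition matrix; the terminal activity's
#'   row must be all zero.
#' @param initialDistribution probability vector over states (default: all
#'   mass on diagnosis).
#' @param durationParams states x 2 matrix with columns `r`, `p`.
#' @param sensorSpec per-state list of per-channel categorical tables.
#' @param ambiguityPairs list of length-2 character vectors of activities
#'   forced to share emissions (default: position hysteroscope and handle
#'   chips both copy the diagnosis tables).
#' @param videoSize pixels per side (>= 8, default 16).
#' @param driftRange mean-intensity range over surgery progress.
#' @param blobAmplitude intensity of the tool blob (default 0.7).
#' @param noiseSd additive pixel noise standard deviation (default 0.02).
#' @param illumSd standard deviation of the per-trajectory illumination
#'   offset (default 0.04), emulating lighting variation between
#'   recordings; it keeps single-frame intensity from being a perfect
#'   progress readout, so visual milestones stay informative.
#' @param terminalActivity absorbing final activity (default handle chips;
#'   set to `NA` to disable absorption and cut at `maxFrames`).
#' @param minInitialRun minimum dwell of the opening activity in frames
#'   (default 4, i.e. 2 seconds at 2 fps): a trajectory cannot open with a
#'   sub-second diagnostic glance.
#' @param maxFrames hard length cap per trajectory (default 400).
#' @param seed master seed (default 1).
#' @return A [GeneratorConfig-class] object.
#' @examples
#' cfg <- generatorConfig(nTrajectories = 2)
#' cfg
#' @export
generatorConfig <- function(nTrajectories = 38L, frameRate = 2,
                            states = activityStates(),
                            activityGraph = defaultActivityGraph(states),
                            initialDistribution =
                              as.numeric(states == "diagnosis"),
                            durationParams = defaultDurationParams(states),
                            sensorSpec = defaultSensorSpec(states),
                            ambiguityPairs = list(
                              c("diagnosis", "position hysteroscope"),
                              c("diagnosis", "handle chips")),
                            videoSize = 16L, driftRange = c(0.25, 0.65),
                            blobAmplitude = 0.7, noiseSd = 0.02,
                            illumSd = 0.04,
                            terminalActivity = "handle chips",
                            minInitialRun = 4L,
                            maxFrames = 400L, seed = 1L) {
  for (pair in ambiguityPairs) {
    i <- match(pair[1L], states); j <- match(pair[2L], states)
    if (is.na(i) || is.na(j))
      stop("ambiguity pair names unknown activity: ", paste(pair, collapse = ", "))
    sensorSpec[[j]] <- sensorSpec[[i]]
  }
  if (is.na(terminalActivity)) terminalActivity <- states[length(states)]
  new("GeneratorConfig", nTrajectories = as.integer(nTrajectories),
      frameRate = as.numeric(frameRate), states = states,
      activityGraph = as.matrix(activityGraph),
      initialDistribution = as.numeric(initialDistribution),
      durationParams = as.matrix(durationParams), sensorSpec = sensorSpec,
      ambiguityPairs = ambiguityPairs, videoSize = as.integer(videoSize),
      driftRange = as.numeric(driftRange),
      blobAmplitude = as.numeric(blobAmplitude),
      noiseSd = as.numeric(noiseSd), illumSd = as.numeric(illumSd),
      terminalActivity = as.character(terminalActivity),
      minInitialRun = as.integer(minInitialRun),
      maxFrames = as.integer(maxFrames), seed = as.integer(seed))
}

#' Sample an activity sequence from the transition graph
#'
#' Draws a sequence of (activity, duration) runs: the first activity from
#' the initial distribution, dwell times from each activity's shifted
#' negative binomial (support `d >= 1`), successors from the activity
#' graph rows. Generation stops when the terminal activity's run completes
#' or `maxFrames` is reached (the last run is then truncated). Successive
#' runs always differ because the graph has no self-loops.
#'
#' @param config a [GeneratorConfig-class].
#' @param seed optional integer seed.
#' @return A [Segmentation-class]; per-frame labels via [frameLabels()].
#' @export
sampleActivitySequence <- function(config, seed = NULL) {
  withSeed(seed, {
    S <- length(config@states)
    r <- config@durationParams[, 1L]; p <- config@durationParams[, 2L]
    term <- match(config@terminalActivity, config@states)
    runs <- integer(0); durs <- integer(0)
    t <- 0L
    s <- sample.int(S, 1L, prob = config@initialDistribution)
    first <- TRUE
    repeat {
      d <- 1L + rnbinom(1L, size = r[s], prob = p[s])
      if (first) {
        d <- d + config@minInitialRun - 1L   # opening dwell has a floor
        first <- FALSE
      }
      d <- min(d, config@maxFrames - t)
      runs <- c(runs, s); durs <- c(durs, d)
      t <- t + d
      if (s == term || t >= config@maxFrames) break
      row <- config@activityGraph[s, ]
      if (sum(row) <= 0)
        stop(sprintf("activity '%s' has no outgoing transitions but is not the terminal activity",
                     config@states[s]))
      s <- sample.int(S, 1L, prob = row)
    }
    ends <- cumsum(durs)
    segmentation(config@states[runs], c(0L, ends[-length(ends)]), ends)
  })
}

#' Render the categorical sensor stream of an activity sequence
#'
#' Draws one symbol per frame and channel from the frame's
#' activity-conditional categorical distribution; channels are conditionally
#' independent given the activity.
#'
#' @param activities per-frame character labels (or a [Segmentation-class]).
#' @param config a [GeneratorConfig-class].
#' @param seed optional integer seed.
#' @return Integer matrix, frames x channels, of 1-based symbols.
#' @export
renderSensorStream <- function(activities, config, seed = NULL) {
  if (is(activities, "Segmentation")) activities <- frameLabels(activities)
  if (!length(activities)) stop("activity sequence must be non-empty")
  idx <- match(activities, config@states)
  if (anyNA(idx))
    stop("activity without sensor specification: ",
         activities[which(is.na(idx))[1L]])
  nch <- length(config@sensorSpec[[1L]])
  withSeed(seed, {
    out <- matrix(0L, length(activities), nch)
    for (c in seq_len(nch)) {
      for (s in unique(idx)) {
        tab <- config@sensorSpec[[s]][[c]]
        if (is.null(tab))
          stop(sprintf("missing channel %d distribution for activity '%s'",
                       c, config@states[s]))
        rows <- which(idx == s)
        out[rows, c] <- sample.int(length(tab), length(rows),
                                   replace = TRUE, prob = tab)
      }
    }
    out
  })
}

## Planted event times (0-based frames) recomputed from per-frame labels.
plantedEventTimes <- function(activities) {
  out <- integer(0)
  first <- match(TRUE, activities != activities[1L])
  if (!is.na(first)) out["diagnosis_end"] <- first - 1L
  cutIdx <- which(activities == "cutting")
  if (length(cutIdx)) {
    endFirstCut <- cutIdx[1L]
    while (endFirstCut < length(activities) &&
           activities[endFirstCut + 1L] == "cutting")
      endFirstCut <- endFirstCut + 1L
    out["first_cut_end"] <- endFirstCut   # 0-based first frame after the run
  }
  out
}

#' Render the toy surgical video of an activity sequence
#'
#' Produces `tau` grayscale frames whose mean intensity drifts linearly with
#' surgery progress `t / tau` (so remaining progress is learnable), shifted
#' by a per-trajectory illumination offset, with a bright square "tool" blob
#' covering the bottom-right part of the image from
#' `eventTimes["diagnosis_end"]` onward (the visual cue that the diagnostic
#' inspection has ended) and additive Gaussian pixel noise. All intensities
#' are clipped to `[0, 1]`.
#'
#' @param activities per-frame character labels (or a [Segmentation-class]).
#' @param eventTimes named integer vector; `diagnosis_end` (0-based) places
#'   the blob. Missing `diagnosis_end` renders no blob.
#' @param config a [GeneratorConfig-class].
#' @param seed optional integer seed.
#' @return Numeric array `tau x size x size`.
#' @export
renderVideo <- function(activities, eventTimes, config, seed = NULL) {
  if (is(activities, "Segmentation")) activities <- frameLabels(activities)
  tau <- length(activities)
  if (!tau) stop("activity sequence must be non-empty")
  size <- config@videoSize
  if (size < 8L) stop("videoSize must be >= 8 to render the tool blob")
  de <- if ("diagnosis_end" %in% names(eventTimes))
    eventTimes[["diagnosis_end"]] else NA_integer_
  if (!is.na(de) && (de < 0L || de > tau))
    stop("diagnosis_end event time is inconsistent with the activity sequence")
  withSeed(seed, {
    vid <- array(0, dim = c(tau, size, size))
    offset <- if (config@illumSd > 0) rnorm(1L, 0, config@illumSd) else 0
    base <- offset + config@driftRange[1L] +
      (config@driftRange[2L] - config@driftRange[1L]) * (seq_len(tau) / tau)
    b <- max(4L, round(0.4 * size))
    blobRows <- (size - b + 1L):size
    for (t in seq_len(tau)) {
      frame <- matrix(base[t], size, size)
      if (!is.na(de) && t - 1L >= de)
        frame[blobRows, blobRows] <- frame[blobRows, blobRows] +
          config@blobAmplitude
      if (config@noiseSd > 0)
        frame <- frame + matrix(rnorm(size * size, 0, config@noiseSd),
                                size, size)
      vid[t, , ] <- pmin(pmax(frame, 0), 1)
    }
    vid
  })
}

#' Generate a reproducible synthetic dataset
#'
#' Generates `nTrajectories` independent trajectories. Each trajectory uses
#' its own seed derived from the master seed and its index by a fixed
#' counter scheme, so regeneration from the manifest is bit-identical and
#' independent of generation order.
#'
#' @param config a [GeneratorConfig-class].
#' @return List with elements `trajectories` (list of
#'   [SyntheticTrajectory-class]) and `manifest` (data.frame with columns
#'   trajectory, seed, tau, diagnosis_end, first_cut_end).
#' @examples
#' ds <- generateDataset(generatorConfig(nTrajectories = 2, seed = 7))
#' ds$manifest
#' @export
generateDataset <- function(config) {
  n <- config@nTrajectories
  trajectories <- vector("list", n)
  manifest <- data.frame(trajectory = integer(0), seed = integer(0),
                         tau = integer(0), diagnosis_end = integer(0),
                         first_cut_end = integer(0))
  for (i in seq_len(n)) {
    s <- childSeed(config@seed, i)
    trajectories[[i]] <- generateTrajectory(config, s)
    et <- trajectories[[i]]@eventTimes
    manifest <- rbind(manifest, data.frame(
      trajectory = i, seed = s,
      tau = length(trajectories[[i]]@activities),
      diagnosis_end = if ("diagnosis_end" %in% names(et))
        et[["diagnosis_end"]] else NA_integer_,
      first_cut_end = if ("first_cut_end" %in% names(et))
        et[["first_cut_end"]] else NA_integer_))
  }
  list(trajectories = trajectories, manifest = manifest)
}

#' Generate a single trajectory
#'
#' @param config a [GeneratorConfig-class].
#' @param seed trajectory seed.
#' @return A [SyntheticTrajectory-class].
#' @export
generateTrajectory <- function(config, seed) {
  seg <- sampleActivitySequence(config, seed = childSeed(seed, 1L))
  labels <- frameLabels(seg)
  et <- plantedEventTimes(labels)
  sensorsM <- renderSensorStream(labels, config, seed = childSeed(seed, 2L))
  vid <- renderVideo(labels, et, config, seed = childSeed(seed, 3L))
  new("SyntheticTrajectory", activities = labels, sensors = sensorsM,
      video = vid, eventTimes = et, seed = as.integer(seed))
}

#' Scale the mean dwell times of a duration parameterization
#'
#' Multiplies every activity's mean dwell time (above the 1-frame floor) by
#' `factor`, keeping the dispersion shape parameter `r` fixed: the new
#' success probability is `r / (r + factor * (mean - 1))`. Used to derive
#' longer-trajectory cohorts (e.g. the model-comparison benchmark, where the
#' single annotated sequence must contain enough frames per activity to
#' initialize the emission tables) from the same procedure model.
#'
#' @param durationParams states x 2 matrix with columns `r`, `p`.
#' @param factor positive scale factor on the mean dwell time.
#' @return A matrix of the same shape.
#' @export
scaleDurationParams <- function(durationParams, factor) {
  if (factor <= 0) stop("factor must be positive")
  r <- durationParams[, 1L]
  m <- 1 + r * (1 - durationParams[, 2L]) / durationParams[, 2L]
  m2 <- 1 + factor * (m - 1)
  out <- cbind(r = r, p = r / (r + m2 - 1))
  rownames(out) <- rownames(durationParams)
  out
}

#' Expected trajectory length under a generator configuration
#'
#' Closed-form expectation of the frame count `tau`, ignoring the
#' `maxFrames` cap: expected visit counts of the transient activities from
#' the fundamental matrix of the absorbing transition chain, weighted by the
#' negative-binomial mean dwell times, plus one terminal visit.
#'
#' @param config a [GeneratorConfig-class].
#' @return Expected number of frames (numeric scalar).
#' @export
expectedTrajectoryLength <- function(config) {
  S <- length(config@states)
  term <- match(config@terminalActivity, config@states)
  r <- config@durationParams[, 1L]; p <- config@durationParams[, 2L]
  meanDur <- 1 + r * (1 - p) / p
  trans <- setdiff(seq_len(S), term)
  Q <- config@activityGraph[trans, trans, drop = FALSE]
  visits <- solve(t(diag(length(trans)) - Q),
                  config@initialDistribution[trans])
  sum(visits * meanDur[trans]) + meanDur[term] + config@minInitialRun - 1
}

#' Serialize / deserialize a generator configuration as JSON
#'
#' @param config a [GeneratorConfig-class].
#' @param path file path.
#' @return `readGeneratorConfig` returns a [GeneratorConfig-class];
#'   `writeGeneratorConfig` returns `path` invisibly.
#' @name generatorIO
NULL

#' @rdname generatorIO
#' @export
writeGeneratorConfig <- function(config, path) {
  obj <- list(n_trajectories = config@nTrajectories,
              frame_rate = config@frameRate, states = config@states,
              activity_graph = config@activityGraph,
              initial_distribution = config@initialDistribution,
              duration_params = list(r = unname(config@durationParams[, 1L]),
                                     p = unname(config@durationParams[, 2L])),
              sensor_spec = lapply(config@sensorSpec,
                                   function(e) lapply(e, unname)),
              ambiguity_pairs = config@ambiguityPairs,
              video_size = config@videoSize,
              drift_range = config@driftRange,
              blob_amplitude = config@blobAmplitude,
              noise_sd = config@noiseSd, illum_sd = config@illumSd,
              terminal_activity = config@terminalActivity,
              min_initial_run = config@minInitialRun,
              max_frames = config@maxFrames, seed = config@seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname generatorIO
#' @export
readGeneratorConfig <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = FALSE)
  S <- length(o$states)
  generatorConfig(
    nTrajectories = o$n_trajectories, frameRate = o$frame_rate,
    states = unlist(o$states),
    activityGraph = matrix(as.numeric(unlist(o$activity_graph)), S, S,
                           byrow = TRUE),
    initialDistribution = as.numeric(unlist(o$initial_distribution)),
    durationParams = cbind(r = as.numeric(unlist(o$duration_params$r)),
                           p = as.numeric(unlist(o$duration_params$p))),
    sensorSpec = lapply(o$sensor_spec, function(e)
      lapply(e, function(tab) as.numeric(unlist(tab)))),
    ambiguityPairs = lapply(o$ambiguity_pairs, unlist),
    videoSize = o$video_size,
    driftRange = as.numeric(unlist(o$drift_range)),
    blobAmplitude = o$blob_amplitude, noiseSd = o$noise_sd,
    illumSd = o$illum_sd,
    terminalActivity = o$terminal_activity,
    minInitialRun = o$min_initial_run, maxFrames = o$max_frames,
    seed = o$seed)
}

#' Write a synthetic trajectory's streams as CSV
#'
#' Writes the sensor stream (columns `frame`, `channel_0` ...) and the
#' activity labels (columns `frame`, `activity`), 0-based frame indices.
#'
#' @param trajectory a [SyntheticTrajectory-class].
#' @param sensorPath,activityPath file paths (either may be `NULL` to skip).
#' @return Invisibly, a character vector of the written paths.
#' @export
writeTrajectoryCSV <- function(trajectory, sensorPath = NULL,
                               activityPath = NULL) {
  written <- character(0)
  tau <- length(trajectory@activities)
  if (!is.null(sensorPath)) {
    df <- data.frame(frame = seq_len(tau) - 1L, trajectory@sensors)
    names(df)[-1L] <- paste0("channel_", seq_len(ncol(trajectory@sensors)) - 1L)
    write.csv(df, sensorPath, row.names = FALSE)
    written <- c(written, sensorPath)
  }
  if (!is.null(activityPath)) {
    write.csv(data.frame(frame = seq_len(tau) - 1L,
                         activity = trajectory@activities),
              activityPath, row.names = FALSE)
    written <- c(written, activityPath)
  }
  invisible(written)
}
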