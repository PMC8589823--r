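#' Rank trace units by event-locked mean shift
#'
#' Scores every unit (column) of a set of representation traces by the
#' standardized mean shift of its values across a known event frame,
#' averaged over trajectories: `|mean(after) - mean(before)| / pooled sd`
#' computed inside a window of `halfWidth` frames on either side of the
#' event. Units are returned sorted by descending score (ties broken by unit
#' index). The signed mean shift (averaged over trajectories) is reported
#' alongside so downstream code can orient the unit's response.
#'
#' Trajectories whose event frame lies at the sequence boundary (no frames
#' on one side) are skipped with a warning; if all are skipped, an error is
#' raised.
#'
#' @param traces list of [RepresentationTrace-class] objects (same source,
#'   same width), one per trajectory.
#' @param eventFrames integer vector of 0-based event frames, one per trace.
#' @param halfWidth window half-width in frames (default 10).
#' @param eventName label stored in the result (default `"diagnosis_end"`).
#' @return data.frame with columns unit, event, score, signed_shift, rank,
#'   sorted by rank.
#' @export
rankComponents <- function(traces, eventFrames, halfWidth = 10L,
                           eventName = "diagnosis_end") {
  if (length(traces) != length(eventFrames))
    stop("one event frame per trace is required")
  width <- ncol(traces[[1L]]@values)
  scores <- matrix(NA_real_, length(traces), width)
  shifts <- matrix(NA_real_, length(traces), width)
  used <- 0L
  for (i in seq_along(traces)) {
    x <- traces[[i]]@values
    tau <- nrow(x)
    e <- eventFrames[i]            # 0-based: first frame after the event
    if (is.na(e) || e <= 0L || e >= tau) {
      warning(sprintf("trace %d skipped: event frame %s at sequence boundary",
                      i, e))
      next
    }
    before <- max(1L, e - halfWidth + 1L):e           # 1-based rows
    after <- (e + 1L):min(tau, e + halfWidth)
    mb <- colMeans(x[before, , drop = FALSE])
    ma <- colMeans(x[after, , drop = FALSE])
    vb <- apply(x[before, , drop = FALSE], 2L, stats::var)
    va <- apply(x[after, , drop = FALSE], 2L, stats::var)
    nb <- length(before); na_ <- length(after)
    pooled <- sqrt(((nb - 1L) * vb + (na_ - 1L) * va) /
                     max(1L, nb + na_ - 2L))
    pooled[!is.finite(pooled) | pooled == 0] <- NA
    d <- (ma - mb) / pooled
    d[is.na(d)] <- 0               # constant on both sides: no shift signal
    scores[i, ] <- abs(d)
    shifts[i, ] <- ma - mb
    used <- used + 1L
  }
  if (used == 0L) stop("all trajectories skipped: no usable event frames")
  score <- colMeans(scores, na.rm = TRUE)
  shift <- colMeans(shifts, na.rm = TRUE)
  ord <- order(-score, seq_len(width))
  data.frame(unit = ord, event = eventName, score = score[ord],
             signed_shift = shift[ord], rank = seq_len(width))
}

#' Detection rule for event-indicator construction
#'
#' Two onset detectors are available. `"jump"` (the default) is
#' trend-robust: it locates the largest local mean shift between `m` frames
#' after and `m` frames before each candidate frame and accepts it if it
#' exceeds the median local shift by `k` median absolute deviations. This is
#' the appropriate detector for activation traces of a progress-regression
#' network, whose units carry a slow progress trend by construction on top
#' of which event responses appear as sustained jumps. `"threshold"` is the
#' plain baseline rule: onset at the first frame where the (smoothed) trace
#' exceeds `baseline mean + k * baseline sd` for at least `m` consecutive
#' frames, with the baseline taken from the first `b` frames; it suits
#' traces that are stationary before the event.
#'
#' @param method `"jump"` or `"threshold"`.
#' @param k detection stringency: MAD multiplier (`jump`) or baseline-sd
#'   multiplier (`threshold`); default 3.
#' @param m local window / persistence length in frames (default 3).
#' @param b number of initial baseline frames for `"threshold"` (default 10).
#' @param smoothWindow centered moving-average window applied before
#'   detection (default 1 = no smoothing).
#' @param minSd lower bound on the baseline sd / MAD, guarding against
#'   saturated (near-constant) traces (default 1e-4 and 1e-6 respectively).
#' @return A named list.
#' @export
indicatorRule <- function(method = c("jump", "threshold"), k = 3, m = 3L,
                          b = 10L, smoothWindow = 1L, minSd = NULL) {
  method <- match.arg(method)
  if (is.null(minSd)) minSd <- if (method == "jump") 1e-6 else 1e-4
  list(method = method, k = k, m = as.integer(m), b = as.integer(b),
       smoothWindow = as.integer(smoothWindow), minSd = minSd)
}

#' Build a latched binary event indicator from one trace unit
#'
#' Detects the onset of a sustained activation increase in one unit of a
#' representation trace and returns the latched 0/1 indicator (0 before the
#' onset, 1 from the onset onward). The detector is selected by the rule's
#' `method` (see [indicatorRule()]): the default `"jump"` rule places the
#' onset at the largest local mean shift of the trace, provided it stands
#' out from the trace's typical local variation; the `"threshold"` rule
#' scans for the first sustained exceedance of a baseline threshold. A trace
#' without a detectable event yields an all-zero indicator with `NA` onset.
#'
#' @param trace a [RepresentationTrace-class] or numeric matrix/vector.
#' @param unit 1-based column index of the unit to use.
#' @param rule an [indicatorRule()] list.
#' @param negate use the negated trace (for units whose event response is a
#'   decrease).
#' @return An [EventIndicator-class].
#' @export
buildEventIndicator <- function(trace, unit = 1L, rule = indicatorRule(),
                                negate = FALSE) {
  x <- traceMatrix(trace)
  if (unit < 1L || unit > ncol(x))
    stop(sprintf("unit %d does not exist (trace has %d units)", unit, ncol(x)))
  v <- x[, unit]
  if (negate) v <- -v
  tau <- length(v)
  if (rule$smoothWindow > 1L) {
    w <- rule$smoothWindow
    sm <- as.vector(stats::filter(v, rep(1 / w, w), sides = 2L))
    nav <- is.na(sm)                # window truncation at the edges
    sm[nav] <- v[nav]
    v <- sm
  }
  onsetFrame <- if (rule$method == "jump") jumpOnset(v, rule)
  else thresholdOnset(v, rule)
  values <- integer(tau)
  if (!is.na(onsetFrame)) values[onsetFrame:tau] <- 1L
  new("EventIndicator", values = values,
      onset = if (is.na(onsetFrame)) NA_integer_ else onsetFrame - 1L)
}

## Largest local mean shift: J_t = mean(v[t .. t+m-1]) - mean(v[t-m .. t-1]),
## accepted if it exceeds median(J) + k * MAD(J). Returns the 1-based onset
## frame or NA. Robust to slow trends, which contribute a constant offset to
## every J_t.
jumpOnset <- function(v, rule) {
  tau <- length(v); m <- rule$m
  if (tau < 2L * m + 1L)
    stop(sprintf("trace length %d is too short for a local window of %d frames",
                 tau, m))
  J <- rep(NA_real_, tau)
  cs <- c(0, cumsum(v))
  for (t in (m + 1L):(tau - m + 1L))
    J[t] <- (cs[t + m] - cs[t]) / m - (cs[t] - cs[t - m]) / m
  Jv <- J[!is.na(J)]
  thr <- median(Jv) + rule$k * max(stats::mad(Jv), rule$minSd)
  tstar <- which.max(J)
  if (length(tstar) && !is.na(J[tstar]) && J[tstar] > thr) tstar else NA_integer_
}

## First sustained exceedance of baseline mean + k * baseline sd, baseline =
## first b frames. Returns the 1-based first frame of the sustained run.
thresholdOnset <- function(v, rule) {
  tau <- length(v)
  if (tau <= rule$b)
    stop(sprintf("trace length %d leaves no frames beyond the %d baseline frames",
                 tau, rule$b))
  base <- v[seq_len(rule$b)]
  thr <- mean(base) + rule$k * max(sd(base), rule$minSd)
  runLen <- 0L
  for (t in seq_len(tau)) {
    if (v[t] > thr) {
      runLen <- runLen + 1L
      if (runLen >= rule$m) return(t - runLen + 1L)
    } else runLen <- 0L
  }
  NA_integer_
}

#' Select the event-encoding unit among top-ranked candidates
#'
#' Automates the verification step that follows component ranking: among the
#' `topN` units with the largest event-locked effect sizes (from
#' [rankComponents()]), build indicators on the supplied trajectories and
#' select the unit whose detected onsets agree most often (within `tol`
#' frames) with the known event frames. Ties are broken by rank. Selection
#' must only ever see training trajectories; held-out data stay untouched.
#'
#' @param traces list of [RepresentationTrace-class] (training trajectories).
#' @param events 0-based event frames, one per trace.
#' @param rule an [indicatorRule()] list.
#' @param topN number of top-ranked candidate units to try (default 5).
#' @param tol agreement tolerance in frames (default 3).
#' @param halfWidth ranking window half-width (see [rankComponents()]).
#' @return List with `unit`, `negate`, `hits` (agreement count of the chosen
#'   unit), and `ranking` (the full ranking table).
#' @export
selectEventUnit <- function(traces, events, rule = indicatorRule(),
                            topN = 5L, tol = 3L, halfWidth = 10L) {
  ranking <- suppressWarnings(
    rankComponents(traces, events, halfWidth = halfWidth))
  topN <- min(topN, nrow(ranking))
  best <- list(unit = ranking$unit[1L], negate = ranking$signed_shift[1L] < 0,
               hits = -1L)
  for (j in seq_len(topN)) {
    u <- ranking$unit[j]
    neg <- ranking$signed_shift[j] < 0
    onsets <- vapply(traces, function(tr) {
      ind <- tryCatch(buildEventIndicator(tr, unit = u, rule = rule,
                                          negate = neg),
                      error = function(e) NULL)
      if (is.null(ind)) NA_integer_ else onset(ind)
    }, integer(1L))
    hits <- sum(abs(onsets - events) <= tol, na.rm = TRUE)
    if (hits > best$hits) best <- list(unit = u, negate = neg, hits = hits)
  }
  c(best, list(ranking = ranking))
}

#' Indicator planted from known event times
#'
#' Constructs the idealized latched indicator directly from a known event
#' frame (used to wire ground-truth event channels into benchmark models
#' independently of representation learning).
#'
#' @param tau trajectory length in frames.
#' @param eventFrame 0-based frame of the event (`NA` for never).
#' @return An [EventIndicator-class].
#' @export
plantedIndicator <- function(tau, eventFrame) {
  values <- integer(tau)
  if (!is.na(eventFrame) && eventFrame < tau && eventFrame >= 0L)
    values[(eventFrame + 1L):tau] <- 1L
  else eventFrame <- NA_integer_
  new("EventIndicator", values = values, onset = as.integer(eventFrame))
}

#' Append an event-indicator channel to a sensor stream
#'
#' Returns the stream with one extra binary categorical channel (symbols 1 =
#' event not yet observed, 2 = observed); the original channels are
#' unchanged. The indicator must align frame-for-frame with the stream.
#'
#' @param sensors integer matrix, frames x channels.
#' @param indicator an [EventIndicator-class] (or 0/1 vector).
#' @return Integer matrix with one additional column.
#' @export
attachFeature <- function(sensors, indicator) {
  v <- if (is(indicator, "EventIndicator")) indicator@values else
    as.integer(indicator)
  sensors <- as.matrix(sensors)
  if (nrow(sensors) != length(v))
    stop(sprintf("stream has %d frames but the indicator has %d",
                 nrow(sensors), length(v)))
  cbind(sensors, v + 1L)
}
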