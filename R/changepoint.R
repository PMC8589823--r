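#' Change-point configuration constructor
#'
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param bandwidth RBF bandwidth; `NA` (default) requests the median
#'   heuristic (median pairwise Euclidean distance over the trace).
#' @param penalty nonnegative per-change-point penalty.
#' @param minSegment minimum segment length in frames (default 2, i.e. one
#'   second at the default 2 fps frame rate).
#' @param standardize standardize each channel over the trajectory before
#'   costing (default `TRUE`; activation scales are heterogeneous).
#' @return A [CPConfig-class] object.
#' @export
cpConfig <- function(kernel = c("linear", "rbf"), bandwidth = NA_real_,
                     penalty = 1, minSegment = 2L, standardize = TRUE) {
  kernel <- match.arg(kernel)
  new("CPConfig", kernel = kernel, bandwidth = as.numeric(bandwidth),
      penalty = as.numeric(penalty), minSegment = as.integer(minSegment),
      standardize = standardize)
}

traceMatrix <- function(trace) {
  if (is(trace, "RepresentationTrace")) trace@values
  else as.matrix(trace)
}

#' Standardize a trace channel-wise
#'
#' Centers and scales every channel to zero mean and unit variance over the
#' trajectory. Constant channels are centered only.
#'
#' @param x numeric matrix (frames x channels) or
#'   [RepresentationTrace-class].
#' @return A numeric matrix of the same shape.
#' @export
standardizeTrace <- function(x) {
  x <- traceMatrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  s[!is.finite(s) | s == 0] <- 1
  sweep(sweep(x, 2L, mu), 2L, s, "/")
}

medianHeuristicBandwidth <- function(x, maxPoints = 400L) {
  n <- nrow(x)
  idx <- if (n > maxPoints) round(seq(1L, n, length.out = maxPoints)) else seq_len(n)
  d <- dist(x[idx, , drop = FALSE])
  h <- median(d[d > 0])
  if (!is.finite(h) || h <= 0) 1 else h
}

## Closure returning cost(s, e) for a 0-based half-open segment [s, e) plus
## the resolved bandwidth. Kernelized mean-change cost:
##   sum_t k(x_t, x_t) - (1/(e-s)) * sum_{t,u} k(x_t, x_u).
segmentCostFunction <- function(x, config) {
  tau <- nrow(x)
  if (config@kernel == "linear") {
    cs <- rbind(0, apply(x, 2L, cumsum))
    cq <- c(0, cumsum(rowSums(x^2)))
    list(cost = function(s, e) {
      m <- cs[e + 1L, ] - cs[s + 1L, ]
      (cq[e + 1L] - cq[s + 1L]) - sum(m * m) / (e - s)
    }, bandwidth = NA_real_)
  } else {
    h <- if (is.na(config@bandwidth)) medianHeuristicBandwidth(x) else config@bandwidth
    sq <- rowSums(x^2)
    D2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
    D2[D2 < 0] <- 0
    G <- exp(-D2 / (2 * h^2))
    CG <- matrix(0, tau + 1L, tau + 1L)
    CG[-1L, -1L] <- apply(apply(G, 2L, cumsum), 1L, cumsum)
    list(cost = function(s, e) {
      len <- e - s
      block <- CG[e + 1L, e + 1L] - CG[s + 1L, e + 1L] -
        CG[e + 1L, s + 1L] + CG[s + 1L, s + 1L]
      len - block / len
    }, bandwidth = h)
  }
}

#' Kernelized mean-change cost of one segment
#'
#' Cost of the half-open segment `[start, end)` of a representation trace:
#' `sum_t k(x_t, x_t) - (1/(end-start)) * sum_{t,u} k(x_t, x_u)`. With the
#' linear kernel this is the within-segment sum of squared deviations from
#' the segment mean; with the RBF kernel it is the kernel least-squares
#' deviation from the segment's kernel mean embedding. No standardization is
#' applied here; [pelt()] standardizes the full trajectory first when its
#' configuration requests it.
#'
#' @param trace matrix (frames x channels) or [RepresentationTrace-class].
#' @param start 0-based inclusive segment start.
#' @param end exclusive segment end.
#' @param config a [CPConfig-class].
#' @return The scalar segment cost.
#' @examples
#' segmentCost(cbind(c(0, 2)), 0, 2, cpConfig())  # 2 * 1^2 = 2
#' @export
segmentCost <- function(trace, start, end, config = cpConfig()) {
  x <- traceMatrix(trace)
  if (start < 0 || end > nrow(x) || start >= end)
    stop("segment must satisfy 0 <= start < end <= number of frames")
  segmentCostFunction(x, config)$cost(as.integer(start), as.integer(end))
}

#' Exact penalized change-point detection (PELT)
#'
#' Minimizes the penalized objective
#' `sum of segment costs + penalty * (number of change points)` exactly with
#' the PELT dynamic program. Candidate pruning uses the standard domination
#' test, with removal deferred by `minSegment` frames so that the minimum
#' segment length never invalidates the domination argument; the result is
#' identical to unpruned optimal partitioning. Change points are reported as
#' the 0-based first index of each new segment.
#'
#' @param trace matrix (frames x channels) or [RepresentationTrace-class].
#' @param config a [CPConfig-class]; `config@penalty` is the penalty.
#' @return A [CPResult-class].
#' @examples
#' x <- cbind(c(rep(0, 25), rep(10, 25)))
#' changepoints(pelt(x, cpConfig(penalty = 1, standardize = FALSE)))  # 25
#' @export
pelt <- function(trace, config = cpConfig()) {
  x <- traceMatrix(trace)
  tau <- nrow(x)
  minSeg <- config@minSegment
  if (tau < minSeg)
    stop(sprintf("trace length %d is below the minimum segment length %d",
                 tau, minSeg))
  if (config@standardize) x <- standardizeTrace(x)
  costFn <- segmentCostFunction(x, config)$cost
  beta <- config@penalty

  F <- rep(Inf, tau + 1L)
  F[1L] <- -beta
  prev <- rep(NA_integer_, tau + 1L)
  prunedAt <- rep(NA_integer_, tau + 1L)   # time at which s failed domination
  cand <- integer(0)

  for (t in minSeg:tau) {
    enter <- t - minSeg
    cand <- c(cand, enter)
    ## drop candidates whose domination became binding minSegment frames ago
    keepMask <- is.na(prunedAt[cand + 1L]) | prunedAt[cand + 1L] + minSeg > t
    cand <- cand[keepMask]
    usable <- cand[is.finite(F[cand + 1L])]
    if (!length(usable)) next
    costs <- vapply(usable, function(s) costFn(s, t), numeric(1L))
    scores <- F[usable + 1L] + costs + beta
    j <- which.min(scores)
    F[t + 1L] <- scores[j]
    prev[t + 1L] <- usable[j]
    newly <- usable[F[usable + 1L] + costs > F[t + 1L]]
    prunedAt[newly + 1L] <- ifelse(is.na(prunedAt[newly + 1L]), t,
                                   prunedAt[newly + 1L])
  }
  if (!is.finite(F[tau + 1L]))
    stop("no admissible segmentation under the minimum segment length")

  cps <- integer(0)
  t <- tau
  while (t > 0L) {
    s <- prev[t + 1L]
    if (s > 0L) cps <- c(s, cps)
    t <- s
  }
  ## F[0] = -beta and each segment adds its cost plus beta, so F[tau] equals
  ## sum of segment costs + beta * (number of change points).
  new("CPResult", changepoints = as.integer(cps), totalCost = F[tau + 1L])
}

#' Calibrate the PELT penalty to a target mean change-point count
#'
#' Searches for a penalty whose mean detected change-point count across the
#' supplied traces is within 0.5 of `targetMean`, exploiting that the count
#' is non-increasing in the penalty (bracketing plus bisection). If the
#' target exceeds the maximum achievable count (at penalty 0) the function
#' returns penalty 0 with a warning status.
#'
#' @param traces list of matrices or [RepresentationTrace-class] objects.
#' @param targetMean desired mean number of change points (>= 0).
#' @param config a [CPConfig-class] (its penalty entry is ignored).
#' @param maxIter bisection iterations.
#' @return List with `penalty`, `achievedMean` and `status` (`"ok"` or
#'   `"unreachable"`).
#' @export
calibratePenalty <- function(traces, targetMean, config = cpConfig(),
                             maxIter = 60L) {
  if (!length(traces)) stop("at least one trace is required")
  if (targetMean < 0) stop("targetMean must be >= 0")
  countAt <- function(beta) {
    cfg <- config
    cfg@penalty <- beta
    mean(vapply(traces, function(tr) length(changepoints(pelt(tr, cfg))),
                numeric(1L)))
  }
  cMax <- countAt(0)
  if (targetMean > cMax + 0.5)
    return(list(penalty = 0, achievedMean = cMax, status = "unreachable"))
  lo <- 0; cLo <- cMax
  hi <- 1; cHi <- countAt(hi)
  while (cHi > targetMean && hi < 1e12) {
    hi <- hi * 4
    cHi <- countAt(hi)
  }
  if (abs(cHi - targetMean) <= 0.5)
    return(list(penalty = hi, achievedMean = cHi, status = "ok"))
  best <- if (abs(cLo - targetMean) <= abs(cHi - targetMean))
    list(penalty = lo, achievedMean = cLo) else list(penalty = hi, achievedMean = cHi)
  for (i in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    cMid <- countAt(mid)
    if (abs(cMid - targetMean) < abs(best$achievedMean - targetMean))
      best <- list(penalty = mid, achievedMean = cMid)
    if (abs(cMid - targetMean) <= 0.5) break
    if (cMid > targetMean) lo <- mid else hi <- mid
  }
  c(best, list(status = "ok"))
}

#' Write a change-point result as JSON
#'
#' @param result a [CPResult-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeCPResultJSON <- function(result, path) {
  jsonlite::write_json(list(changepoints = result@changepoints,
                            total_cost = result@totalCost),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
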