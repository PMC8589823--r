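# Independent oracles used to validate the dynamic programs.
#
# The HSMM oracle enumerates every admissible segmentation of tau frames
# (run lengths <= dMax, consecutive states distinct) and scores each one
# directly from the model definition; the change-point oracle is the plain
# O(n^2) optimal-partitioning recursion without pruning. Both are kept free
# of any code path they are meant to check.

## all compositions of tau into parts of size 1..dMax
allCompositions <- function(tau, dMax) {
  if (tau == 0L) return(list(integer(0)))
  out <- list()
  for (d in seq_len(min(tau, dMax))) {
    for (rest in allCompositions(tau - d, dMax))
      out[[length(out) + 1L]] <- c(d, rest)
  }
  out
}

## all state labelings of k runs over S states with no immediate repeats
allLabelings <- function(k, S) {
  if (k == 1L) return(as.list(seq_len(S)))
  out <- list()
  for (rest in allLabelings(k - 1L, S)) {
    for (s in seq_len(S)) {
      if (s != rest[1L]) out[[length(out) + 1L]] <- c(s, rest)
    }
  }
  out
}

## score one segmentation directly from the definition
scoreSegmentationOracle <- function(spec, obs, statesIdx, durs) {
  r <- spec@durations[, 1L]; p <- spec@durations[, 2L]
  norm <- pnbinom(spec@dMax - 1L, size = r, prob = p)
  score <- log(spec@initial[statesIdx[1L]])
  t <- 0L
  for (j in seq_along(statesIdx)) {
    s <- statesIdx[j]; d <- durs[j]
    if (j > 1L) score <- score + log(spec@transitions[statesIdx[j - 1L], s])
    score <- score + dnbinom(d - 1L, size = r[s], prob = p[s], log = TRUE) -
      log(norm[s])
    for (tt in (t + 1L):(t + d)) {
      for (c in seq_len(ncol(obs)))
        score <- score + log(spec@emissions[[s]][[c]][obs[tt, c]])
    }
    t <- t + d
  }
  score
}

## exhaustive max and sum over all segmentations; with discrete symbols the
## maximum is often attained by several segmentations (exact ties), so the
## number of optima is reported alongside the first one found
exhaustiveHSMM <- function(spec, obs) {
  tau <- nrow(obs)
  S <- length(spec@states)
  best <- -Inf; bestPath <- NULL; nOptima <- 0L
  all <- -Inf
  for (durs in allCompositions(tau, spec@dMax)) {
    k <- length(durs)
    for (lab in allLabelings(k, S)) {
      sc <- scoreSegmentationOracle(spec, obs, lab, durs)
      if (sc > best + 1e-12) {
        best <- sc
        nOptima <- 1L
        ends <- cumsum(durs)
        bestPath <- data.frame(state = spec@states[lab],
                               start = c(0L, ends[-k]), end = ends)
      } else if (abs(sc - best) <= 1e-12) {
        nOptima <- nOptima + 1L
      }
      m <- max(all, sc)
      all <- if (is.finite(m)) m + log(exp(all - m) + exp(sc - m)) else m
    }
  }
  list(logProb = best, path = bestPath, logLik = all, nOptima = nOptima)
}

## score a decoded Segmentation under the oracle's arithmetic
oracleScoreOf <- function(spec, obs, seg) {
  df <- intervals(seg)
  scoreSegmentationOracle(spec, obs, match(df$state, spec@states),
                          df$end - df$start)
}

## random small HSMM instance for the oracle sweep
randomSmallSpec <- function(S = sample(1:3, 1), nch = sample(1:2, 1),
                            dMax = sample(2:4, 1)) {
  rdir <- function(K) { x <- rexp(K) + 0.05; x / sum(x) }
  A <- matrix(0, S, S)
  if (S > 1L) {
    for (s in seq_len(S)) {
      row <- rep(0, S)
      row[-s] <- rdir(S - 1L)
      A[s, ] <- row
    }
  }
  nsym <- sample(2:3, nch, replace = TRUE)
  emissions <- lapply(seq_len(S), function(s)
    lapply(seq_len(nch), function(c) rdir(nsym[c])))
  hsmmSpec(states = paste0("s", seq_len(S)), initial = rdir(S),
           transitions = A,
           durations = cbind(r = runif(S, 0.5, 3), p = runif(S, 0.2, 0.8)),
           emissions = emissions, dMax = dMax)
}

randomObs <- function(spec, tau) {
  nch <- length(spec@emissions[[1L]])
  vapply(seq_len(nch), function(c)
    sample.int(length(spec@emissions[[1L]][[c]]), tau, replace = TRUE),
    integer(tau)) |> matrix(nrow = tau)
}

## unpruned optimal partitioning for the change-point oracle
optimalPartitionOracle <- function(x, config) {
  x <- if (is(x, "RepresentationTrace")) traceValues(x) else as.matrix(x)
  if (config@standardize) x <- standardizeTrace(x)
  cfgRaw <- config
  cfgRaw@standardize <- FALSE
  tau <- nrow(x)
  minSeg <- config@minSegment
  beta <- config@penalty
  F <- rep(Inf, tau + 1L)
  F[1L] <- -beta
  prev <- rep(NA_integer_, tau + 1L)
  for (t in minSeg:tau) {
    for (s in 0:(t - minSeg)) {
      if (!is.finite(F[s + 1L])) next
      val <- F[s + 1L] + segmentCost(x, s, t, cfgRaw) + beta
      if (val < F[t + 1L]) {
        F[t + 1L] <- val
        prev[t + 1L] <- s
      }
    }
  }
  cps <- integer(0)
  t <- tau
  while (t > 0L) {
    s <- prev[t + 1L]
    if (s > 0L) cps <- c(s, cps)
    t <- s
  }
  list(changepoints = cps, totalCost = F[tau + 1L])
}

## trace with strong planted mean shifts shared by all channels (independent
## level walks, common segment boundaries); each channel's shifts are >= ~5
## within-segment standard deviations, which survives channel-wise
## standardization because every channel carries the structure
plantedShiftTrace <- function(nSegments = 11L, segLen = 20L, shiftSd = 5,
                              width = 3L) {
  vals <- vapply(seq_len(width), function(j) {
    levels <- cumsum(c(0, sample(c(-1, 1), nSegments - 1L, TRUE) *
                         rnorm(nSegments - 1L, shiftSd, 0.5)))
    rep(levels, each = segLen) + rnorm(nSegments * segLen)
  }, numeric(nSegments * segLen))
  new("RepresentationTrace", source = "synthetic", values = vals,
      trajectoryId = "planted")
}
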