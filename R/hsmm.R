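#' Construct an explicit-duration HSMM specification
#'
#' Builds and validates an [HSMMSpec-class]. Dwell times in state `s` follow
#' a negative binomial with parameters `(r_s, p_s)` shifted to support
#' `{1, 2, ...}` (an activity occupies at least one frame) and renormalized
#' over `{1, ..., dMax}`. Emissions are per-channel categorical distributions
#' that are conditionally independent given the state.
#'
#' @param states character vector of state names; defaults to
#'   [activityStates()].
#' @param initial initial state distribution.
#' @param transitions zero-diagonal row-stochastic transition matrix.
#' @param durations states x 2 matrix (or data.frame) with columns `r`, `p`.
#' @param emissions list: per state, a list of per-channel probability
#'   vectors over 1-based integer symbols.
#' @param dMax duration truncation bound in frames. The default is the
#'   smallest `d` whose cumulative untruncated negative-binomial mass reaches
#'   0.999, maximized over states.
#' @return A validated [HSMMSpec-class] object.
#' @examples
#' spec <- hsmmSpec(
#'   states = c("a", "b"),
#'   initial = c(1, 0),
#'   transitions = matrix(c(0, 1, 1, 0), 2, 2),
#'   durations = cbind(r = c(1, 1), p = c(0.5, 0.5)),
#'   emissions = list(list(c(0.9, 0.1)), list(c(0.1, 0.9))))
#' spec
#' @export
hsmmSpec <- function(states = activityStates(), initial, transitions,
                     durations, emissions, dMax = NULL) {
  durations <- as.matrix(durations)
  colnames(durations) <- c("r", "p")
  if (is.null(dMax)) {
    dMax <- max(qnbinom(0.999, size = durations[, "r"],
                        prob = durations[, "p"])) + 1L
  }
  new("HSMMSpec", states = states, initial = as.numeric(initial),
      transitions = as.matrix(transitions), durations = durations,
      emissions = emissions, dMax = as.integer(dMax))
}

#' Negative-binomial dwell-time probability
#'
#' Probability that a state is occupied for exactly `d` frames: the negative
#' binomial pmf evaluated at `k = d - 1` with the state's `(r, p)`,
#' renormalized over the truncated support `{1, ..., dMax}`.
#'
#' @param spec an [HSMMSpec-class].
#' @param state state name or index.
#' @param d integer vector of durations in frames, each in `[1, dMax]`.
#' @return Numeric vector of probabilities.
#' @examples
#' spec <- hsmmSpec(states = "a", initial = 1,
#'                  transitions = matrix(0, 1, 1),
#'                  durations = cbind(r = 1, p = 0.5),
#'                  emissions = list(list(c(1))), dMax = 50)
#' durationPMF(spec, "a", 1:3)   # shifted geometric: ~0.5, 0.25, 0.125
#' @export
durationPMF <- function(spec, state, d) {
  s <- if (is.character(state)) match(state, spec@states) else as.integer(state)
  if (is.na(s) || s < 1L || s > length(spec@states))
    stop("unknown state: ", state)
  if (any(d < 1L | d > spec@dMax))
    stop(sprintf("d must lie in [1, dMax = %d]", spec@dMax))
  r <- spec@durations[s, "r"]; p <- spec@durations[s, "p"]
  norm <- pnbinom(spec@dMax - 1L, size = r, prob = p)
  dnbinom(d - 1L, size = r, prob = p) / norm
}

## S x dMax matrix of log dwell-time probabilities (renormalized).
logDurationMatrix <- function(spec) {
  S <- length(spec@states)
  out <- matrix(-Inf, S, spec@dMax)
  for (s in seq_len(S)) {
    r <- spec@durations[s, "r"]; p <- spec@durations[s, "p"]
    lnorm <- pnbinom(spec@dMax - 1L, size = r, prob = p, log.p = TRUE)
    out[s, ] <- dnbinom(seq_len(spec@dMax) - 1L, size = r, prob = p,
                        log = TRUE) - lnorm
  }
  out
}

## S x dMax matrix of log survival P(D >= d | D <= dMax) for the optional
## censored scoring of the final segment.
logSurvivalMatrix <- function(spec) {
  ld <- logDurationMatrix(spec)
  t(apply(ld, 1L, function(row) {
    log(rev(cumsum(rev(exp(row)))))
  }))
}

## Per-frame log emission probabilities: tau x S matrix, channels summed.
## Errors if a symbol is outside a channel's support or has zero probability
## under every state (unless eps-smoothing is enabled).
emissionLogMatrix <- function(spec, obs, smooth = 0) {
  obs <- as.matrix(obs)
  storage.mode(obs) <- "integer"
  tau <- nrow(obs)
  if (tau == 0L) stop("observation stream must contain at least one frame")
  S <- length(spec@states)
  nch <- length(spec@emissions[[1L]])
  if (ncol(obs) != nch)
    stop(sprintf("observation stream has %d channel(s); the model defines %d",
                 ncol(obs), nch))
  out <- matrix(0, tau, S)
  for (c in seq_len(nch)) {
    K <- length(spec@emissions[[1L]][[c]])
    v <- obs[, c]
    bad <- which(v < 1L | v > K)
    if (length(bad))
      stop(sprintf("frame %d, channel %d: symbol %d outside table support (1..%d)",
                   bad[1L] - 1L, c, v[bad[1L]], K))
    tab <- vapply(spec@emissions, function(e) e[[c]], numeric(K))
    tab <- matrix(tab, K, S)
    if (smooth > 0) tab <- tab * (1 - smooth) + smooth / K
    dead <- which(rowSums(tab[v, , drop = FALSE]) == 0)
    if (length(dead))
      stop(sprintf(
        "frame %d, channel %d: symbol %d has zero probability under every state",
        dead[1L] - 1L, c, v[dead[1L]]))
    out <- out + log(tab[v, , drop = FALSE])
  }
  out
}

#' Most probable activity sequence (explicit-duration Viterbi)
#'
#' Decodes the single most probable segmentation of an observation stream
#' under an explicit-duration HSMM. The dynamic program maximizes, for every
#' frame and state, over the segment duration and the predecessor state,
#' scoring each segment as entry log-probability (initial distribution or
#' transition) plus the log dwell-time probability plus the per-frame log
#' emission probabilities (channels summed in log space). All computation is
#' in log space; ties are broken toward the lower state index, then the
#' shorter duration. By default the final segment is scored with its full
#' (renormalized) dwell-time pmf; `finalSurvival = TRUE` switches to the
#' censored survival term `P(D >= d)`.
#'
#' @param spec an [HSMMSpec-class].
#' @param obs integer matrix, frames x channels, of 1-based symbols.
#' @param finalSurvival score the last segment with a survival term.
#' @param smooth optional emission smoothing mass in `[0, 1)` redistributed
#'   uniformly over symbols (0 = strict tables; unseen symbols then error).
#' @return A list with elements `segmentation` ([Segmentation-class]) and
#'   `logProb` (the joint log-probability of the decoded segmentation).
#' @examples
#' spec <- hsmmSpec(states = c("a", "b"), initial = c(1, 0),
#'                  transitions = matrix(c(0, 1, 1, 0), 2, 2),
#'                  durations = cbind(r = c(2, 2), p = c(0.5, 0.5)),
#'                  emissions = list(list(c(0.95, 0.05)),
#'                                   list(c(0.05, 0.95))), dMax = 10)
#' viterbiDecode(spec, cbind(c(1, 1, 2, 2)))$segmentation
#' @export
viterbiDecode <- function(spec, obs, finalSurvival = FALSE, smooth = 0) {
  logB <- emissionLogMatrix(spec, obs, smooth)
  tau <- nrow(logB)
  S <- ncol(logB)
  dMax <- spec@dMax
  logDur <- logDurationMatrix(spec)
  logFinal <- if (finalSurvival) logSurvivalMatrix(spec) else logDur
  logA <- suppressWarnings(log(spec@transitions))
  logPi <- suppressWarnings(log(spec@initial))
  ## -Inf frames (zero-probability symbols) are tracked separately so that
  ## cumulative sums stay finite and exact for admissible segments
  dead <- !is.finite(logB)
  logBf <- logB
  logBf[dead] <- 0
  cumB <- rbind(0, apply(logBf, 2L, cumsum))      # (tau+1) x S
  cumDead <- rbind(0L, apply(dead, 2L, cumsum))

  V <- matrix(-Inf, tau, S)
  ## entry[u+1, s]: best log-score of any path covering frames [0, u) that is
  ## about to enter state s at frame u (u = 0 uses the initial distribution).
  entry <- matrix(-Inf, tau + 1L, S)
  entryArg <- matrix(0L, tau + 1L, S)             # predecessor state (0 = start)
  entry[1L, ] <- logPi
  bpd <- matrix(0L, tau, S)
  bprev <- matrix(0L, tau, S)

  for (t in seq_len(tau)) {
    dlim <- min(dMax, t)
    durMat <- if (t == tau) logFinal else logDur
    for (s in seq_len(S)) {
      ds <- seq_len(dlim)
      scores <- entry[t - ds + 1L, s] + durMat[s, ds] +
        (cumB[t + 1L, s] - cumB[t - ds + 1L, s])
      scores[cumDead[t + 1L, s] - cumDead[t - ds + 1L, s] > 0L] <- -Inf
      best <- which.max(scores)
      if (length(best)) {
        V[t, s] <- scores[best]
        bpd[t, s] <- best
        bprev[t, s] <- entryArg[t - best + 1L, s]
      }
    }
    if (t < tau) {
      for (s in seq_len(S)) {
        cand <- V[t, ] + logA[, s]
        j <- which.max(cand)
        entry[t + 1L, s] <- cand[j]
        entryArg[t + 1L, s] <- j
      }
    }
  }

  sStar <- which.max(V[tau, ])
  if (!is.finite(V[tau, sStar]))
    stop("no segmentation with positive probability explains the observations")

  stateIdx <- integer(0); startIdx <- integer(0); endIdx <- integer(0)
  t <- tau; s <- sStar
  while (t > 0L) {
    d <- bpd[t, s]
    stateIdx <- c(s, stateIdx)
    startIdx <- c(t - d, startIdx)
    endIdx <- c(t, endIdx)
    sPrev <- bprev[t, s]
    t <- t - d
    s <- sPrev
  }
  list(segmentation = segmentation(spec@states[stateIdx], startIdx, endIdx),
       logProb = V[tau, sStar])
}

#' Marginal log-likelihood of an observation stream (forward algorithm)
#'
#' Computes `log P(obs)` under an explicit-duration HSMM by summing over all
#' segmentations with the forward recursion, using log-sum-exp arithmetic.
#' Conventions (duration shift/truncation, final-segment scoring, emission
#' smoothing) match [viterbiDecode()], so the returned value is always an
#' upper bound on the Viterbi log-probability.
#'
#' @inheritParams viterbiDecode
#' @return The scalar log-likelihood.
#' @export
sequenceLogLik <- function(spec, obs, finalSurvival = FALSE, smooth = 0) {
  logB <- emissionLogMatrix(spec, obs, smooth)
  tau <- nrow(logB)
  S <- ncol(logB)
  dMax <- spec@dMax
  logDur <- logDurationMatrix(spec)
  logFinal <- if (finalSurvival) logSurvivalMatrix(spec) else logDur
  logA <- suppressWarnings(log(spec@transitions))
  logPi <- suppressWarnings(log(spec@initial))
  dead <- !is.finite(logB)
  logBf <- logB
  logBf[dead] <- 0
  cumB <- rbind(0, apply(logBf, 2L, cumsum))
  cumDead <- rbind(0L, apply(dead, 2L, cumsum))

  alpha <- matrix(-Inf, tau, S)
  entry <- matrix(-Inf, tau + 1L, S)
  entry[1L, ] <- logPi
  for (t in seq_len(tau)) {
    dlim <- min(dMax, t)
    durMat <- if (t == tau) logFinal else logDur
    for (s in seq_len(S)) {
      ds <- seq_len(dlim)
      scores <- entry[t - ds + 1L, s] + durMat[s, ds] +
        (cumB[t + 1L, s] - cumB[t - ds + 1L, s])
      scores[cumDead[t + 1L, s] - cumDead[t - ds + 1L, s] > 0L] <- -Inf
      alpha[t, s] <- logSumExp(scores)
    }
    if (t < tau) {
      for (s in seq_len(S))
        entry[t + 1L, s] <- logSumExp(alpha[t, ] + logA[, s])
    }
  }
  logSumExp(alpha[tau, ])
}

#' Sample a trajectory from an explicit-duration HSMM
#'
#' Generative draw: initial state from the initial distribution, dwell times
#' from the truncated shifted negative binomial, per-frame per-channel
#' categorical emissions, successors from the transition rows. Generation
#' stops when `maxFrames` frames have been emitted; a final segment running
#' past the horizon is truncated.
#'
#' @param spec an [HSMMSpec-class].
#' @param maxFrames horizon in frames (>= 1).
#' @param seed optional integer seed.
#' @return List with `segmentation` and `sensors` (frames x channels matrix).
#' @export
sampleHSMM <- function(spec, maxFrames, seed = NULL) {
  if (maxFrames < 1L) stop("maxFrames must be >= 1")
  withSeed(seed, {
    S <- length(spec@states)
    nch <- length(spec@emissions[[1L]])
    durP <- exp(logDurationMatrix(spec))
    states <- integer(0); durs <- integer(0)
    t <- 0L
    s <- sample.int(S, 1L, prob = spec@initial)
    while (t < maxFrames) {
      d <- sample.int(spec@dMax, 1L, prob = durP[s, ])
      d <- min(d, maxFrames - t)
      states <- c(states, s); durs <- c(durs, d)
      t <- t + d
      if (t >= maxFrames) break
      if (S == 1L) stop("single-state model cannot fill the horizon by transitions")
      s <- sample.int(S, 1L, prob = spec@transitions[s, ])
    }
    labels <- rep(states, durs)
    sensors <- matrix(0L, length(labels), nch)
    for (c in seq_len(nch)) {
      K <- length(spec@emissions[[1L]][[c]])
      for (s2 in unique(states)) {
        idx <- which(labels == s2)
        sensors[idx, c] <- sample.int(K, length(idx), replace = TRUE,
                                      prob = spec@emissions[[s2]][[c]])
      }
    }
    ends <- cumsum(durs)
    list(segmentation = segmentation(spec@states[states],
                                     c(0L, ends[-length(ends)]), ends),
         sensors = sensors)
  })
}

#' Maximum-a-posteriori initialization of categorical emission tables
#'
#' Estimates per-state per-channel categorical emission tables from a single
#' annotated sequence with a conjugate Dirichlet prior: the MAP estimate of
#' symbol `v` for state `s` and channel `c` is
#' `(n_scv + alpha_v - 1) / (N_sc + sum(alpha) - K)`, where `n_scv` are the
#' annotated co-occurrence counts, `N_sc` their sum and `K` the symbol count.
#' With a uniform prior (`alpha = 1`) this reduces to empirical frequencies;
#' `alpha > 1` acts as a regularizer that keeps unseen symbols at small but
#' positive probability. States absent from the annotation fall back to the
#' prior mode, which requires a strictly regularizing prior (`alpha > 1`).
#'
#' @param activities character vector of per-frame annotated labels.
#' @param obs integer matrix, frames x channels, of 1-based symbols.
#' @param states character vector of all states to estimate (defaults to the
#'   distinct annotated labels in order of appearance).
#' @param nSymbols integer vector of symbols per channel (defaults to the
#'   per-channel maximum observed symbol).
#' @param alpha Dirichlet concentration: a scalar (shared by all symbols) or
#'   a list of per-channel vectors. All entries must be >= 1; the MAP mode is
#'   undefined below that.
#' @return List of per-state lists of per-channel probability vectors,
#'   suitable as the `emissions` argument of [hsmmSpec()].
#' @examples
#' a <- rep(c("x", "y"), c(3, 2))
#' o <- cbind(c(1, 1, 2, 2, 2))
#' mapInitEmissions(a, o, alpha = 1)[["x"]][[1]]  # empirical: 2/3, 1/3
#' @export
mapInitEmissions <- function(activities, obs, states = unique(activities),
                             nSymbols = NULL, alpha = 2) {
  obs <- as.matrix(obs)
  storage.mode(obs) <- "integer"
  if (length(activities) != nrow(obs))
    stop("activities and observations must have equal length")
  nch <- ncol(obs)
  if (is.null(nSymbols)) nSymbols <- apply(obs, 2L, max)
  if (!is.list(alpha))
    alpha <- lapply(seq_len(nch), function(c) rep(alpha, nSymbols[c]))
  for (c in seq_len(nch)) {
    if (length(alpha[[c]]) != nSymbols[c])
      stop(sprintf("alpha for channel %d must have %d entries", c, nSymbols[c]))
    if (any(alpha[[c]] < 1))
      stop("all alpha entries must be >= 1 (the MAP mode is undefined below 1)")
  }
  out <- vector("list", length(states))
  names(out) <- states
  for (s in states) {
    idx <- which(activities == s)
    chans <- vector("list", nch)
    for (c in seq_len(nch)) {
      K <- nSymbols[c]
      a <- alpha[[c]]
      n <- tabulate(obs[idx, c], nbins = K)
      denom <- length(idx) + sum(a) - K
      if (denom <= 0)
        stop(sprintf(
          "state '%s' has no annotated frames and the prior is not strictly regularizing (alpha > 1 required)",
          s))
      chans[[c]] <- (n + a - 1) / denom
    }
    out[[s]] <- chans
  }
  out
}

#' Serialize / deserialize an HSMM specification as JSON
#'
#' @param spec an [HSMMSpec-class].
#' @param path file path of the JSON document.
#' @return `readHSMMSpec` returns an [HSMMSpec-class]; `writeHSMMSpec`
#'   returns `path` invisibly.
#' @name hsmmIO
NULL

#' @rdname hsmmIO
#' @export
writeHSMMSpec <- function(spec, path) {
  obj <- list(states = spec@states, initial = spec@initial,
              transitions = spec@transitions,
              durations = list(r = unname(spec@durations[, "r"]),
                               p = unname(spec@durations[, "p"])),
              emissions = lapply(spec@emissions, function(e) lapply(e, unname)),
              d_max = spec@dMax)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname hsmmIO
#' @export
readHSMMSpec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  S <- length(obj$states)
  emissions <- lapply(obj$emissions, function(e)
    lapply(e, function(tab) as.numeric(unlist(tab))))
  hsmmSpec(states = unlist(obj$states),
           initial = as.numeric(unlist(obj$initial)),
           transitions = matrix(as.numeric(unlist(obj$transitions)),
                                S, S, byrow = TRUE),
           durations = cbind(r = as.numeric(unlist(obj$durations$r)),
                             p = as.numeric(unlist(obj$durations$p))),
           emissions = emissions, dMax = obj$d_max)
}
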