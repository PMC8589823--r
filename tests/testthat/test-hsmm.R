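twoStateSpec <- function(e1 = c(0.95, 0.05), e2 = c(0.05, 0.95),
                         dMax = 10L, r = c(2, 2), p = c(0.5, 0.5)) {
  hsmmSpec(states = c("a", "b"), initial = c(1, 0),
           transitions = matrix(c(0, 1, 1, 0), 2, 2),
           durations = cbind(r = r, p = p),
           emissions = list(list(e1), list(e2)), dMax = dMax)
}

test_that("dwell-time pmf is the shifted, renormalized negative binomial", {
  geo <- hsmmSpec(states = "a", initial = 1, transitions = matrix(0, 1, 1),
                  durations = cbind(r = 1, p = 0.5),
                  emissions = list(list(1)), dMax = 10000L)
  # r = 1 reduces to a shifted geometric: pmf(d) = 0.5^d
  expect_equal(durationPMF(geo, "a", 1:4), 0.5^(1:4), tolerance = 1e-9)

  nb <- hsmmSpec(states = "a", initial = 1, transitions = matrix(0, 1, 1),
                 durations = cbind(r = 2, p = 0.5),
                 emissions = list(list(1)), dMax = 10000L)
  # k = d - 1 = 2: C(3,1) * 0.5^2 * 0.5^2 = 0.1875
  expect_equal(durationPMF(nb, "a", 3), 0.1875, tolerance = 1e-9)

  for (dm in c(3L, 7L, 25L)) {
    tr <- hsmmSpec(states = "a", initial = 1, transitions = matrix(0, 1, 1),
                   durations = cbind(r = 1.7, p = 0.35),
                   emissions = list(list(1)), dMax = dm)
    expect_equal(sum(durationPMF(tr, "a", seq_len(dm))), 1, tolerance = 1e-12)
  }
  expect_error(durationPMF(nb, "a", 0), "dMax")
  expect_error(durationPMF(nb, "a", 10001), "dMax")
})

test_that("MAP emission initialization matches the closed form", {
  acts <- rep(c("x", "y"), c(3, 2))
  obs <- cbind(c(1, 1, 2, 1, 1))
  # state x counts (2, 0, 1) over symbols 1..3 after remap
  acts2 <- rep("x", 3)
  obs2 <- cbind(c(1, 1, 3))
  em <- mapInitEmissions(acts2, obs2, states = "x", nSymbols = 3L, alpha = 1)
  expect_equal(em[["x"]][[1L]], c(2 / 3, 0, 1 / 3))
  em2 <- mapInitEmissions(acts2, obs2, states = "x", nSymbols = 3L, alpha = 2)
  expect_equal(em2[["x"]][[1L]], c(3 / 6, 1 / 6, 2 / 6))
  # state with no annotated frames falls back to the prior mode
  em3 <- mapInitEmissions(acts, obs, states = c("x", "y", "z"),
                          nSymbols = 2L, alpha = 2)
  expect_equal(em3[["z"]][[1L]], c(0.5, 0.5))
  expect_true(all(vapply(em3, function(e) abs(sum(e[[1L]]) - 1) < 1e-12,
                         logical(1L))))
  expect_error(mapInitEmissions(acts, obs, alpha = 0.5), "alpha")
  expect_error(mapInitEmissions(acts, obs, states = c("x", "y", "z"),
                                nSymbols = 2L, alpha = 1),
               "regularizing")
})

test_that("Viterbi decodes forced and deterministic cases", {
  one <- hsmmSpec(states = "solo", initial = 1, transitions = matrix(0, 1, 1),
                  durations = cbind(r = 2, p = 0.4),
                  emissions = list(list(c(0.5, 0.5))), dMax = 20L)
  dec <- viterbiDecode(one, cbind(c(1, 2, 1, 1)))
  expect_equal(intervals(dec$segmentation),
               data.frame(state = "solo", start = 0L, end = 4L))

  det <- twoStateSpec(e1 = c(1, 0), e2 = c(0, 1))
  dec2 <- viterbiDecode(det, cbind(c(1, 1, 2, 2)))
  expect_equal(intervals(dec2$segmentation),
               data.frame(state = c("a", "b"), start = c(0L, 2L),
                          end = c(2L, 4L)))
  # decoding errors
  expect_error(viterbiDecode(det, cbind(c(1, 3))), "support")
  expect_error(viterbiDecode(det, matrix(integer(0), 0, 1)), "at least one")
})

test_that("single-state log-likelihood matches its closed form", {
  spec <- hsmmSpec(states = "a", initial = 1, transitions = matrix(0, 1, 1),
                   durations = cbind(r = 2, p = 0.4),
                   emissions = list(list(c(0.7, 0.3))), dMax = 12L)
  obs <- cbind(c(1, 2, 1, 1, 2))
  expected <- log(durationPMF(spec, "a", 5)) +
    sum(log(c(0.7, 0.3, 0.7, 0.7, 0.3)))
  expect_equal(sequenceLogLik(spec, obs), expected, tolerance = 1e-12)
})

test_that("Viterbi and forward agree with exhaustive enumeration on random instances", {
  set.seed(401)
  for (i in 1:30) {
    spec <- randomSmallSpec()
    ## a single-state model admits exactly one run, so tau cannot exceed dMax
    tau <- if (length(spec@states) == 1L) sample(seq_len(spec@dMax), 1)
    else sample(1:8, 1)
    obs <- randomObs(spec, tau)
    oracle <- exhaustiveHSMM(spec, obs)
    dec <- viterbiDecode(spec, obs)
    expect_equal(dec$logProb, oracle$logProb, tolerance = 1e-9)
    # the decoded path must attain the optimum; when it is unique it must be
    # the oracle's path (discrete symbols admit exactly tied optima)
    expect_equal(oracleScoreOf(spec, obs, dec$segmentation), oracle$logProb,
                 tolerance = 1e-9)
    if (oracle$nOptima == 1L)
      expect_equal(intervals(dec$segmentation), oracle$path,
                   tolerance = 1e-12)
    expect_equal(sequenceLogLik(spec, obs), oracle$logLik, tolerance = 1e-9)
    expect_gte(sequenceLogLik(spec, obs) + 1e-12, dec$logProb)
  }
})

test_that("decoding is invariant to consistent symbol relabeling", {
  set.seed(402)
  spec <- randomSmallSpec(S = 3, nch = 1)
  K <- length(spec@emissions[[1L]][[1L]])
  obs <- randomObs(spec, 8L)
  perm <- sample(K)
  spec2 <- spec
  for (s in seq_along(spec2@emissions))
    spec2@emissions[[s]][[1L]][perm] <- spec@emissions[[s]][[1L]]
  obs2 <- matrix(perm[obs], ncol = 1L)
  d1 <- viterbiDecode(spec, obs)
  d2 <- viterbiDecode(spec2, obs2)
  expect_equal(intervals(d1$segmentation), intervals(d2$segmentation))
  expect_equal(d1$logProb, d2$logProb, tolerance = 1e-12)
})

test_that("appending a state-constant channel never changes the decoding", {
  set.seed(403)
  for (i in 1:5) {
    spec <- randomSmallSpec(S = 3, nch = 1)
    obs <- randomObs(spec, 8L)
    const <- c(0.3, 0.7)
    spec2 <- spec
    for (s in seq_along(spec2@emissions))
      spec2@emissions[[s]] <- c(spec2@emissions[[s]], list(const))
    obs2 <- cbind(obs, sample.int(2L, nrow(obs), replace = TRUE))
    d1 <- viterbiDecode(spec, obs)
    d2 <- viterbiDecode(spec2, obs2)
    shift <- sum(log(const[obs2[, 2L]]))
    expect_equal(d2$logProb - shift, d1$logProb, tolerance = 1e-9)
    # the decoded paths agree up to exactly tied optima: scored without the
    # uninformative channel, both achieve the same joint probability
    expect_equal(oracleScoreOf(spec, obs, d2$segmentation),
                 oracleScoreOf(spec, obs, d1$segmentation), tolerance = 1e-9)
  }
})

test_that("sampling is seeded, respects dMax and matches the initial law", {
  spec <- twoStateSpec(dMax = 6L)
  s1 <- sampleHSMM(spec, 50L, seed = 7L)
  s2 <- sampleHSMM(spec, 50L, seed = 7L)
  expect_identical(s1, s2)
  durs <- s1$segmentation@end - s1$segmentation@start
  expect_true(all(durs <= 6L))

  # empirical initial-state frequencies vs pi over many draws
  spec3 <- hsmmSpec(states = c("a", "b", "c"), initial = c(0.5, 0.3, 0.2),
                    transitions = matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0),
                                         3, 3, byrow = TRUE),
                    durations = cbind(r = rep(2, 3), p = rep(0.5, 3)),
                    emissions = lapply(1:3, function(s) list(c(0.5, 0.5))),
                    dMax = 10L)
  set.seed(404)
  first <- vapply(1:10000, function(i)
    sampleHSMM(spec3, 1L)$segmentation@state[1L], character(1L))
  for (k in 1:3) {
    phat <- mean(first == c("a", "b", "c")[k])
    p0 <- spec3@initial[k]
    se <- sqrt(p0 * (1 - p0) / 10000)
    expect_lt(abs(phat - p0), 3 * se + 1e-9)
  }
  expect_error(sampleHSMM(spec, 0L), "maxFrames")
})

test_that("final-segment survival scoring is consistent between Viterbi and forward", {
  spec <- twoStateSpec()
  obs <- cbind(c(1, 1, 2, 2, 2))
  v <- viterbiDecode(spec, obs, finalSurvival = TRUE)
  f <- sequenceLogLik(spec, obs, finalSurvival = TRUE)
  expect_gte(f + 1e-12, v$logProb)
  # survival mass >= pmf mass, so the censored score cannot be smaller
  expect_gte(v$logProb, viterbiDecode(spec, obs)$logProb - 1e-12)
})

test_that("unseen symbols error by default and decode under epsilon smoothing", {
  spec <- twoStateSpec(e1 = c(1, 0), e2 = c(1, 0))  # symbol 2 impossible
  obs <- cbind(c(1, 2, 1))
  expect_error(viterbiDecode(spec, obs), "zero probability")
  dec <- viterbiDecode(spec, obs, smooth = 1e-8)
  expect_s4_class(dec$segmentation, "Segmentation")
})

test_that("HSMM specs survive a JSON round trip", {
  spec <- twoStateSpec()
  path <- tempfile(fileext = ".json")
  writeHSMMSpec(spec, path)
  back <- readHSMMSpec(path)
  expect_equal(back@states, spec@states)
  expect_equal(back@initial, spec@initial)
  expect_equal(back@transitions, spec@transitions, ignore_attr = TRUE)
  expect_equal(unname(back@durations), unname(spec@durations))
  expect_equal(back@emissions, lapply(spec@emissions, function(e) lapply(e, unname)),
               ignore_attr = TRUE)
  expect_equal(back@dMax, spec@dMax)
  obs <- cbind(c(1, 1, 2, 2))
  expect_equal(sequenceLogLik(back, obs), sequenceLogLik(spec, obs))
})

test_that("invalid specifications are rejected", {
  expect_error(hsmmSpec(states = c("a", "b"), initial = c(0.6, 0.5),
                        transitions = matrix(c(0, 1, 1, 0), 2, 2),
                        durations = cbind(r = c(1, 1), p = c(.5, .5)),
                        emissions = list(list(c(1)), list(c(1)))),
               "sum to 1")
  expect_error(hsmmSpec(states = c("a", "b"), initial = c(1, 0),
                        transitions = matrix(c(0.5, 0.5, 1, 0), 2, 2,
                                             byrow = TRUE),
                        durations = cbind(r = c(1, 1), p = c(.5, .5)),
                        emissions = list(list(c(1)), list(c(1)))),
               "diagonal")
})
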