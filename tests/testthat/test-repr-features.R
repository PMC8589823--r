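stepTrace <- function(tau = 80L, event = 50L, width = 16L, stepUnit = 7L,
                      step = 1, noiseSd = 0.1, seed = 1L) {
  set.seed(seed)
  vals <- matrix(rnorm(tau * width, sd = noiseSd), tau, width)
  vals[(event + 1L):tau, stepUnit] <- vals[(event + 1L):tau, stepUnit] + step
  new("RepresentationTrace", source = "synthetic", values = vals,
      trajectoryId = "t")
}

test_that("a step unit outranks white-noise units", {
  traces <- lapply(1:6, function(i) stepTrace(seed = i, step = 1.5))
  rk <- rankComponents(traces, rep(50L, 6L))
  expect_identical(rk$unit[1L], 7L)
  expect_identical(rk$rank, 1:16)
  expect_gt(rk$score[1L], 3 * rk$score[2L])
  expect_gt(rk$signed_shift[1L], 0)
})

test_that("constant traces score zero and affine rescaling leaves scores unchanged", {
  flat <- new("RepresentationTrace", source = "s",
              values = matrix(1, 40, 3), trajectoryId = "t")
  rk <- rankComponents(list(flat), 20L)
  expect_true(all(rk$score == 0))

  tr <- stepTrace(seed = 3)
  rk1 <- rankComponents(list(tr), 50L)
  tr2 <- tr
  tr2@values[, 7L] <- 5 + 2 * tr2@values[, 7L]
  rk2 <- rankComponents(list(tr2), 50L)
  expect_equal(rk1$score[rk1$unit == 7L], rk2$score[rk2$unit == 7L],
               tolerance = 1e-12)
})

test_that("boundary events are skipped with a warning, all skipped errors", {
  traces <- lapply(1:2, function(i) stepTrace(seed = i))
  expect_warning(rk <- rankComponents(traces, c(50L, 0L)), "boundary")
  expect_identical(rk$unit[1L], 7L)
  expect_error(suppressWarnings(rankComponents(traces, c(0L, 80L))),
               "no usable")
})

test_that("event indicators latch at a clean step for both detection rules", {
  tau <- 80L
  clean <- matrix(c(rep(0, 50), rep(1, 30)), ncol = 1)
  for (method in c("jump", "threshold")) {
    ind <- buildEventIndicator(clean, 1L, indicatorRule(method = method))
    expect_identical(onset(ind), 50L)
    expect_identical(ind@values, c(rep(0L, 50), rep(1L, 30)))
    expect_true(all(diff(ind@values) >= 0L))
  }
  flat <- matrix(rep(0.3, tau), ncol = 1)
  for (method in c("jump", "threshold")) {
    ind <- buildEventIndicator(flat, 1L, indicatorRule(method = method))
    expect_true(is.na(onset(ind)))
    expect_true(all(ind@values == 0L))
  }
  expect_error(buildEventIndicator(matrix(0, 5, 1), 1L,
                                   indicatorRule(method = "threshold", b = 10L)),
               "baseline")
  expect_error(buildEventIndicator(matrix(0, 5, 1), 1L,
                                   indicatorRule(method = "jump")),
               "too short")
  expect_error(buildEventIndicator(clean, 4L), "does not exist")
})

test_that("noisy-step onsets are located within three frames almost always", {
  set.seed(77)
  for (method in c("jump", "threshold")) {
    hits <- 0L
    for (i in 1:50) {
      event <- sample(30:60, 1)
      tr <- stepTrace(tau = 90L, event = event, stepUnit = 1L, step = 1,
                      noiseSd = 0.2, seed = 1000 + i)  # step = 5 noise sd
      ind <- buildEventIndicator(tr, 1L, indicatorRule(method = method))
      if (!is.na(onset(ind)) && abs(onset(ind) - event) <= 3L)
        hits <- hits + 1L
    }
    expect_gte(hits, 45L)   # >= 90% of trajectories
  }
})

test_that("the jump rule localizes a step riding on a strong trend", {
  set.seed(78)
  tau <- 80L
  v <- 0.01 * seq_len(tau) + rnorm(tau, sd = 0.02)
  v[51:tau] <- v[51:tau] + 0.5
  ind <- buildEventIndicator(matrix(v, ncol = 1), 1L, indicatorRule())
  expect_true(abs(onset(ind) - 50L) <= 1L)
})

test_that("selectEventUnit picks the unit whose onsets match the events", {
  set.seed(79)
  traces <- lapply(1:8, function(i) stepTrace(seed = 200 + i, step = 1.2,
                                              noiseSd = 0.2))
  sel <- selectEventUnit(traces, rep(50L, 8L))
  expect_identical(sel$unit, 7L)
  expect_false(sel$negate)
  expect_gte(sel$hits, 7L)
})

test_that("attaching an indicator channel is reversible and aligned", {
  set.seed(80)
  sensorsM <- matrix(sample.int(3L, 60L, TRUE), ncol = 3L)
  ind <- plantedIndicator(20L, 8L)
  aug <- attachFeature(sensorsM, ind)
  expect_identical(ncol(aug), 4L)
  expect_identical(aug[, 1:3], sensorsM)               # originals unchanged
  expect_identical(sort(unique(aug[, 4L])), c(1L, 2L)) # binary channel
  expect_identical(match(2L, aug[, 4L]) - 1L, onset(ind))
  expect_identical(aug[, -4L], sensorsM)               # round trip
  expect_error(attachFeature(sensorsM, plantedIndicator(19L, 5L)),
               "19")
})

test_that("planted indicators respect boundaries", {
  expect_true(is.na(onset(plantedIndicator(10L, NA_integer_))))
  expect_identical(onset(plantedIndicator(10L, 0L)), 0L)
  expect_identical(plantedIndicator(10L, 0L)@values, rep(1L, 10L))
  expect_true(is.na(onset(plantedIndicator(10L, 10L))))
})
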