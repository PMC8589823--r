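test_that("segment costs match hand computations and kernel bounds", {
  cfg <- cpConfig()
  expect_equal(segmentCost(cbind(rep(3, 10)), 0, 10, cfg), 0, tolerance = 1e-12)
  # two points at 0 and 2: sum of squared deviations from the mean = 2
  expect_equal(segmentCost(cbind(c(0, 2)), 0, 2, cfg), 2, tolerance = 1e-12)
  # multivariate linear cost adds over channels
  x <- cbind(c(0, 2), c(1, 5))
  expect_equal(segmentCost(x, 0, 2, cfg), 2 + 8, tolerance = 1e-12)

  rbf <- cpConfig(kernel = "rbf", bandwidth = 1)
  set.seed(1)
  y <- matrix(rnorm(40), ncol = 2)
  for (se in list(c(0, 20), c(3, 11))) {
    cost <- segmentCost(y, se[1], se[2], rbf)
    len <- se[2] - se[1]
    expect_gte(cost, -1e-12)
    expect_lte(cost, len * (1 - 1 / len) + 1e-12)
  }
  expect_error(segmentCost(y, 5, 5, cfg), "start < end")
})

test_that("pelt recovers planted structure and degenerates correctly", {
  x <- cbind(c(rep(0, 25), rep(10, 25)))
  res <- pelt(x, cpConfig(penalty = 1, standardize = FALSE))
  expect_identical(changepoints(res), 25L)

  const <- cbind(rep(2, 40))
  expect_length(changepoints(pelt(const, cpConfig(penalty = 0.5,
                                                  standardize = FALSE))), 0)
  # overwhelming penalty suppresses all change points
  set.seed(2)
  noisy <- cbind(rnorm(60))
  expect_length(changepoints(pelt(noisy, cpConfig(penalty = 1e6))), 0)
  expect_error(pelt(cbind(1), cpConfig(minSegment = 2L)), "below the minimum")
})

test_that("pelt equals unpruned optimal partitioning on random series", {
  set.seed(403)
  for (i in 1:30) {
    tau <- sample(10:50, 1)
    width <- sample(1:3, 1)
    x <- matrix(rnorm(tau * width), ncol = width)
    if (i %% 2 == 0) {  # plant some structure half the time
      cp <- sort(sample(3:(tau - 3), 2))
      x[cp[1]:cp[2], 1] <- x[cp[1]:cp[2], 1] + 4
    }
    kernel <- if (i %% 3 == 0) "rbf" else "linear"
    cfg <- cpConfig(kernel = kernel, bandwidth = 1.5,
                    penalty = runif(1, 0.5, 10), minSegment = 2L)
    got <- pelt(x, cfg)
    want <- optimalPartitionOracle(x, cfg)
    expect_identical(changepoints(got), as.integer(want$changepoints))
    expect_equal(got@totalCost, want$totalCost, tolerance = 1e-9)
  }
})

test_that("detected count is non-increasing in the penalty", {
  set.seed(404)
  tr <- plantedShiftTrace()
  grid <- c(0, 0.5, 1, 2, 5, 10, 50, 200, 1000)
  counts <- vapply(grid, function(b)
    length(changepoints(pelt(tr, cpConfig(penalty = b)))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("penalty calibration hits a planted target and handles edge cases", {
  set.seed(405)
  traces <- lapply(1:6, function(i) plantedShiftTrace())
  cal <- calibratePenalty(traces, targetMean = 10)
  expect_identical(cal$status, "ok")
  expect_gte(cal$achievedMean, 9)
  expect_lte(cal$achievedMean, 11)
  cfg <- cpConfig(penalty = cal$penalty)
  counts <- vapply(traces, function(tr)
    length(changepoints(pelt(tr, cfg))), numeric(1))
  expect_gte(mean(counts), 9)
  expect_lte(mean(counts), 11)
  # doubling the penalty never increases the mean count
  cfg2 <- cpConfig(penalty = 2 * cal$penalty)
  counts2 <- vapply(traces, function(tr)
    length(changepoints(pelt(tr, cfg2))), numeric(1))
  expect_lte(mean(counts2), mean(counts))

  # target 0 achievable with a large penalty
  cal0 <- calibratePenalty(traces, targetMean = 0)
  cfg0 <- cpConfig(penalty = cal0$penalty)
  expect_equal(mean(vapply(traces, function(tr)
    length(changepoints(pelt(tr, cfg0))), numeric(1))), 0, tolerance = 0.5)

  # unreachable target reports penalty 0
  flat <- list(matrix(rep(0, 50), ncol = 1))
  calU <- calibratePenalty(flat, targetMean = 40)
  expect_identical(calU$status, "unreachable")
  expect_identical(calU$penalty, 0)
})

test_that("results are invariant to channel permutation", {
  set.seed(406)
  x <- matrix(rnorm(200), ncol = 4)
  x[30:50, 2] <- x[30:50, 2] + 6
  for (kernel in c("linear", "rbf")) {
    cfg <- cpConfig(kernel = kernel, penalty = 3)
    a <- pelt(x, cfg)
    b <- pelt(x[, c(3, 1, 4, 2)], cfg)
    expect_identical(changepoints(a), changepoints(b))
    expect_equal(a@totalCost, b@totalCost, tolerance = 1e-9)
  }
})

test_that("strong planted mean shifts are recovered within two frames", {
  set.seed(407)
  for (i in 1:10) {
    segLen <- 15L
    tr <- plantedShiftTrace(nSegments = 5L, segLen = segLen, shiftSd = 6)
    truth <- segLen * (1:4)
    cal <- calibratePenalty(list(tr), targetMean = 4)
    got <- changepoints(pelt(tr, cpConfig(penalty = cal$penalty)))
    for (cp in truth)
      expect_true(any(abs(got - cp) <= 2),
                  label = sprintf("planted change point %d recovered", cp))
  }
})
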