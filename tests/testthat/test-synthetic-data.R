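singleActivityConfig <- function(r = 1, p = 0.5) {
  generatorConfig(nTrajectories = 1L, states = "diagnosis",
                  activityGraph = matrix(0, 1, 1),
                  initialDistribution = 1,
                  durationParams = cbind(r = r, p = p),
                  sensorSpec = list(list(c(0.5, 0.5))),
                  ambiguityPairs = list(), terminalActivity = "diagnosis",
                  minInitialRun = 1L, maxFrames = 10000L)
}

test_that("a degenerate initial distribution forces the starting activity", {
  cfg <- generatorConfig(nTrajectories = 4L, seed = 11L)
  ds <- generateDataset(cfg)
  for (tr in ds$trajectories)
    expect_identical(activities(tr)[1L], "diagnosis")
})

test_that("single-activity dwell times follow the shifted geometric law", {
  cfg <- singleActivityConfig(r = 1, p = 0.5)
  set.seed(21)
  durs <- vapply(1:10000, function(i)
    trajectoryLength(generateTrajectory(cfg, sample.int(1e6, 1))), numeric(1))
  # shifted geometric mean: 1 + (1-p)/p = 2; sd = sqrt(q)/p
  se <- sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - 2), 3 * se)
})

test_that("no two consecutive runs share an activity", {
  cfg <- generatorConfig(nTrajectories = 6L, seed = 12L)
  for (tr in generateDataset(cfg)$trajectories) {
    seg <- segmentationFromLabels(activities(tr))
    st <- seg@state
    if (length(st) > 1L) expect_true(all(st[-1L] != st[-length(st)]))
  }
})

test_that("a dead-end non-terminal activity raises a generation error", {
  A <- matrix(0, 3, 3)
  A[1, 2] <- 1  # "stuck" has no outgoing edges and is not terminal
  cfg <- generatorConfig(nTrajectories = 1L,
                         states = c("diagnosis", "stuck", "handle chips"),
                         activityGraph = A, initialDistribution = c(1, 0, 0),
                         durationParams = cbind(r = rep(1, 3), p = rep(.5, 3)),
                         sensorSpec = list(list(c(1)), list(c(1)), list(c(1))),
                         ambiguityPairs = list(),
                         terminalActivity = "handle chips",
                         minInitialRun = 1L)
  expect_error(sampleActivitySequence(cfg, seed = 5L), "stuck")
})

test_that("deterministic emission tables recode the activity sequence", {
  cfg <- generatorConfig(
    nTrajectories = 1L, states = c("diagnosis", "position hysteroscope"),
    activityGraph = matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE),
    initialDistribution = c(1, 0),
    durationParams = cbind(r = c(2, 2), p = c(.5, .5)),
    sensorSpec = list(list(c(1, 0)), list(c(0, 1))),
    ambiguityPairs = list(), terminalActivity = "position hysteroscope")
  seg <- sampleActivitySequence(cfg, seed = 3L)
  labels <- frameLabels(seg)
  stream <- renderSensorStream(labels, cfg, seed = 4L)
  expect_identical(as.vector(stream),
                   ifelse(labels == "diagnosis", 1L, 2L))
  expect_error(renderSensorStream(character(0), cfg), "non-empty")
})

test_that("ambiguity pairs share emissions exactly and empirically", {
  cfg <- generatorConfig(nTrajectories = 1L)
  iD <- match("diagnosis", cfg@states)
  iP <- match("position hysteroscope", cfg@states)
  iH <- match("handle chips", cfg@states)
  expect_identical(cfg@sensorSpec[[iD]], cfg@sensorSpec[[iP]])
  expect_identical(cfg@sensorSpec[[iD]], cfg@sensorSpec[[iH]])

  # empirical symbol distributions of the two activities converge
  n <- 25000L
  sD <- renderSensorStream(rep("diagnosis", n), cfg, seed = 31L)
  sP <- renderSensorStream(rep("position hysteroscope", n), cfg, seed = 32L)
  for (ch in seq_len(ncol(sD))) {
    K <- length(cfg@sensorSpec[[iD]][[ch]])
    fD <- tabulate(sD[, ch], K) / n
    fP <- tabulate(sP[, ch], K) / n
    expect_lt(sum(abs(fD - fP)) / 2, 0.05)
    expect_lt(sum(abs(fD - cfg@sensorSpec[[iD]][[ch]])) / 2, 0.05)
  }
})

test_that("rendered video has drift, a tool blob at the event, and clipped range", {
  cfg <- generatorConfig(nTrajectories = 1L, noiseSd = 0, illumSd = 0)
  labels <- rep(c("diagnosis", "cutting"), c(10, 10))
  et <- c(diagnosis_end = 10L)
  vid <- renderVideo(labels, et, cfg, seed = 41L)
  means <- apply(vid, 1L, mean)
  expect_true(all(diff(means) >= -1e-12))   # monotone without noise
  expect_true(all(vid >= 0 & vid <= 1))

  # blob region jumps by the configured amplitude when no clipping occurs
  lowCfg <- generatorConfig(nTrajectories = 1L, noiseSd = 0, illumSd = 0,
                            driftRange = c(0.1, 0.2), blobAmplitude = 0.5)
  vid2 <- renderVideo(labels, et, lowCfg, seed = 42L)
  b <- max(4L, round(0.4 * 16))
  region <- (16 - b + 1L):16
  before <- mean(vid2[10, region, region])
  after <- mean(vid2[11, region, region])
  expect_gte(after - before, 0.5 - 0.02)

  noisy <- renderVideo(labels, et, generatorConfig(nTrajectories = 1L),
                       seed = 43L)
  expect_true(all(noisy >= 0 & noisy <= 1))
  expect_error(generatorConfig(videoSize = 6L), "videoSize")
})

test_that("datasets regenerate bit-identically from the same seed", {
  cfg <- generatorConfig(nTrajectories = 3L, seed = 99L)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_identical(d1, d2)
  # per-trajectory regeneration from the manifest seed is also identical
  tr <- generateTrajectory(cfg, d1$manifest$seed[2L])
  expect_identical(tr, d1$trajectories[[2L]])

  empty <- generateDataset(generatorConfig(nTrajectories = 0L))
  expect_length(empty$trajectories, 0)
  expect_identical(nrow(empty$manifest), 0L)
})

test_that("planted event times are consistent with the labels", {
  ds <- generateDataset(generatorConfig(nTrajectories = 8L, seed = 13L))
  for (tr in ds$trajectories) {
    a <- activities(tr)
    de <- eventTimes(tr)[["diagnosis_end"]]
    expect_identical(de, match(TRUE, a != a[1L]) - 1L)
    expect_identical(length(a), nrow(sensors(tr)))
    expect_identical(length(a), dim(video(tr))[1L])
  }
})

test_that("cohort mean length matches the closed-form expectation", {
  cfg <- generatorConfig(nTrajectories = 38L, seed = 14L)
  ds <- generateDataset(cfg)
  taus <- ds$manifest$tau
  se <- sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus) - expectedTrajectoryLength(cfg)), 3 * se)
})

test_that("generator configuration and streams survive file round trips", {
  cfg <- generatorConfig(nTrajectories = 2L, seed = 55L)
  path <- tempfile(fileext = ".json")
  writeGeneratorConfig(cfg, path)
  back <- readGeneratorConfig(path)
  expect_identical(generateDataset(back), generateDataset(cfg))

  tr <- generateDataset(cfg)$trajectories[[1L]]
  sp <- tempfile(fileext = ".csv"); ap <- tempfile(fileext = ".csv")
  writeTrajectoryCSV(tr, sp, ap)
  sdf <- read.csv(sp)
  expect_equal(as.matrix(sdf[, -1L]), sensors(tr), ignore_attr = TRUE)
  adf <- read.csv(ap)
  expect_identical(adf$activity, activities(tr))
})
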