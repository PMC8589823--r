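test_that("remaining-progress labels follow y_t = 1 - t / tau", {
  expect_equal(rspLabels(4), c(0.75, 0.5, 0.25, 0))
  expect_identical(rspLabels(1), 0)
  for (tau in c(2L, 7L, 40L)) {
    y <- rspLabels(tau)
    expect_identical(y[tau], 0)
    expect_true(all(diff(y) < 0))
    expect_true(all(y >= 0 & y < 1))
    expect_equal(diff(y), rep(-1 / tau, tau - 1L))  # linear in t
  }
  expect_error(rspLabels(0), "tau")
})

test_that("predictions are sigmoid-bounded, deterministic and size-checked", {
  model <- rspModel(tinySpec(), seed = 5L)
  vid <- tinyVideo(tau = 6L)
  y1 <- predictRSP(model, vid)
  y2 <- predictRSP(model, vid)
  expect_identical(y1, y2)
  expect_true(all(y1 > 0 & y1 < 1))
  expect_lt(mean(abs(y1 - rspLabels(6L))), 1)  # trivially below the range bound
  expect_error(predictRSP(model, tinyVideo(size = 16L)), "expects 8x8")
  expect_error(predictRSP(model, array(0, c(0, 8, 8))), "at least one frame")
})

test_that("training is seeded, reproducible and rejects degenerate input", {
  set.seed(9)
  videos <- lapply(1:4, function(i) tinyVideo(tau = 8L, seed = 100 + i))
  cfg <- trainConfig(epochs = 2L, seed = 3L)
  m1 <- trainRSP(rspModel(tinySpec(), seed = 5L), videos, cfg)
  m2 <- trainRSP(rspModel(tinySpec(), seed = 5L), videos, cfg)
  expect_identical(m1@history, m2@history)
  expect_identical(m1@params, m2@params)
  expect_identical(nrow(m1@history), 2L)
  expect_error(trainRSP(rspModel(tinySpec(), seed = 1L), videos[1], cfg),
               "at least 2")
  expect_error(trainRSP(rspModel(tinySpec(), seed = 1L), list(), cfg),
               "at least 2")
  # rmsprop path also runs
  m3 <- trainRSP(rspModel(tinySpec(), seed = 5L), videos,
                 trainConfig(optimizer = "rmsprop", epochs = 1L, seed = 3L))
  expect_identical(nrow(m3@history), 1L)
})

test_that("activation extraction is shape-correct, bounded and read-only", {
  for (decoder in c("gru", "lstm")) {
    model <- rspModel(tinySpec(decoder), seed = 7L)
    vid <- tinyVideo(tau = 9L)
    srcs <- availableSources(model)
    expect_true("decoder_l1_hidden" %in% srcs)
    gateSrc <- grep("gate", srcs, value = TRUE)
    expect_gte(length(gateSrc), 2L)

    before <- predictRSP(model, vid)
    traces <- extractActivations(model, vid, c("encoder_output", gateSrc,
                                               "rsp"))
    after <- predictRSP(model, vid)
    expect_identical(before, after)           # extraction is read-only

    for (tr in traces) expect_identical(nrow(traceValues(tr)), 9L)
    for (g in gateSrc) {
      v <- traceValues(traces[[g]])
      expect_true(all(v > 0 & v < 1))         # sigmoid gates
    }
    expect_equal(as.vector(traceValues(traces[["rsp"]])), before)
    t1 <- extractActivations(model, vid, "decoder_l1_hidden")[[1L]]
    t2 <- extractActivations(model, vid, "decoder_l1_hidden")[[1L]]
    expect_identical(traceValues(t1), traceValues(t2))
    expect_error(extractActivations(model, vid, "decoder_l9_hidden"),
                 "available")
  }
})

test_that("pretrained-backbone encoders are config hooks without weights", {
  expect_error(rspModelSpec(encoder = "alexnet_like"), "pretrained")
  expect_error(rspModelSpec(encoder = "resnet18_like"), "pretrained")
})
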