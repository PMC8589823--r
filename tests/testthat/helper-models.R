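# Shared toy-trained RSP model (trained once per test run; used by the
# representation-learning tests and the acceptance suite).

.toyCache <- new.env(parent = emptyenv())

toyRSPSetup <- function() {
  if (!exists("fit", envir = .toyCache)) {
    cfg <- generatorConfig(nTrajectories = 20L, seed = 20260919L)
    dataset <- generateDataset(cfg)
    videos <- lapply(dataset$trajectories, video)
    model <- trainRSP(rspModel(rspModelSpec(), seed = 1L), videos,
                      trainConfig(epochs = 40L, seed = 1L))
    events <- vapply(dataset$trajectories, function(tr)
      eventTimes(tr)[["diagnosis_end"]], integer(1L))
    assign("fit", list(config = cfg, dataset = dataset, videos = videos,
                       model = model, events = events,
                       trainIdx = attr(model, "trainIdx"),
                       valIdx = attr(model, "valIdx")),
           envir = .toyCache)
  }
  get("fit", envir = .toyCache)
}

## tiny architecture for fast structural tests
tinySpec <- function(decoder = "gru") {
  rspModelSpec(inputSize = 8L, convChannels = c(2L, 3L, 2L),
               encoderWidth = 4L, decoder = decoder, decoderWidth = 4L,
               decoderLayers = 2L)
}

tinyVideo <- function(tau = 5L, size = 8L, seed = 1L) {
  set.seed(seed)
  array(runif(tau * size * size), dim = c(tau, size, size))
}
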