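#' Architecture specification of the RSP model
#'
#' Describes the encoder-decoder network that regresses remaining surgery
#' progress from video. The default desk-scale configuration is a three-layer
#' stride-2 convolutional encoder on 16x16 grayscale frames feeding a
#' single-layer GRU decoder and a three-layer MLP head (PReLU activations
#' after the first two layers, a sigmoid after the last, so predictions lie
#' in `(0, 1)`). The `alexnet_like` and `resnet18_like` encoder names are
#' accepted as configuration hooks for externally supplied pretrained
#' backbones; no weights ship with the package, so instantiating them
#' without a weight file is an error.
#'
#' @param encoder `"small_cnn"` (default), `"alexnet_like"` or
#'   `"resnet18_like"`.
#' @param inputSize pixels per side of the (square, grayscale) input frames.
#' @param convChannels integer vector of channel counts of the convolution
#'   stack (one stride-2 convolution per entry).
#' @param encoderWidth width of the encoder output feature vector.
#' @param decoder `"gru"` (default) or `"lstm"`.
#' @param decoderWidth recurrent hidden width.
#' @param decoderLayers number of stacked recurrent layers.
#' @param frameRate frames per second the model expects (metadata).
#' @return A named list (the model spec).
#' @export
rspModelSpec <- function(encoder = c("small_cnn", "alexnet_like",
                                     "resnet18_like"),
                         inputSize = 16L, convChannels = c(8L, 16L, 16L),
                         encoderWidth = 16L,
                         decoder = c("gru", "lstm"), decoderWidth = 16L,
                         decoderLayers = 1L, frameRate = 2) {
  encoder <- match.arg(encoder)
  decoder <- match.arg(decoder)
  if (encoder != "small_cnn")
    stop(sprintf(
      "encoder '%s' is a configuration hook for pretrained backbone weights; none are bundled with the package. Use encoder = \"small_cnn\".",
      encoder))
  if (inputSize < 8L) stop("inputSize must be >= 8")
  list(encoder = encoder, inputSize = as.integer(inputSize),
       convChannels = as.integer(convChannels),
       encoderWidth = as.integer(encoderWidth), decoder = decoder,
       decoderWidth = as.integer(decoderWidth),
       decoderLayers = as.integer(decoderLayers),
       frameRate = as.numeric(frameRate))
}

#' Training configuration for the RSP model
#'
#' Whole sequences are the training batches (no truncation). The loss is the
#' mean absolute error between predicted and true remaining surgery
#' progress. The default learning rate of `1e-3` is the desk-scale setting;
#' `1e-5` is the appropriate order of magnitude when training full-scale
#' pretrained encoders.
#'
#' @param optimizer `"adam"` (default) or `"rmsprop"`.
#' @param learningRate positive learning rate.
#' @param epochs number of passes over the training sequences.
#' @param valFraction fraction of sequences held out for validation (split
#'   by trajectory, never by frame).
#' @param seed integer seed governing initialization, the train/validation
#'   split and epoch shuffling.
#' @return A named list.
#' @export
trainConfig <- function(optimizer = c("adam", "rmsprop"),
                        learningRate = 1e-3, epochs = 40L,
                        valFraction = 0.25, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (learningRate <= 0) stop("learningRate must be positive")
  list(optimizer = optimizer, learningRate = learningRate,
       epochs = as.integer(epochs), valFraction = valFraction,
       seed = as.integer(seed))
}

#' Instantiate an RSP model with random weights
#'
#' @param spec an [rspModelSpec()] list.
#' @param seed integer seed for weight initialization.
#' @return An [RSPModel-class] object (untrained).
#' @export
rspModel <- function(spec = rspModelSpec(), seed = 1L) {
  params <- initRSPParams(spec, seed)
  new("RSPModel", spec = spec, params = params,
      history = data.frame(epoch = integer(0), train_mae = numeric(0),
                           val_mae = numeric(0)))
}

#' Remaining-surgery-progress labels
#'
#' The self-supervised regression target `y_t = 1 - t / tau` for
#' `t = 1, ..., tau`: the fraction of the procedure still remaining at frame
#' `t`. Strictly decreasing, starts at `1 - 1/tau` and ends at exactly 0.
#'
#' @param tau trajectory length in frames (>= 1).
#' @return Numeric vector of length `tau`.
#' @examples
#' rspLabels(4)  # 0.75 0.50 0.25 0.00
#' @export
rspLabels <- function(tau) {
  if (tau < 1L) stop("tau must be >= 1")
  1 - seq_len(tau) / tau
}

checkVideo <- function(vid, spec) {
  d <- dim(vid)
  if (is.null(d) || length(d) != 3L)
    stop("video must be a tau x size x size array")
  if (d[1L] < 1L) stop("video must contain at least one frame")
  if (d[2L] != spec$inputSize || d[3L] != spec$inputSize)
    stop(sprintf("frames are %dx%d but the model expects %dx%d",
                 d[2L], d[3L], spec$inputSize, spec$inputSize))
  invisible(TRUE)
}

#' Train the RSP model on whole video sequences
#'
#' Trains the encoder-decoder to regress remaining surgery progress with a
#' mean-absolute-error loss, one whole sequence per optimizer step. The
#' train/validation split is by trajectory. Training is fully seeded and
#' reproducible.
#'
#' @param model an [RSPModel-class].
#' @param videos list of `tau x size x size` arrays (>= 2 sequences).
#' @param config a [trainConfig()] list.
#' @return The trained [RSPModel-class]; `model@history` holds the per-epoch
#'   train and validation MAE, and attributes `"trainIdx"` / `"valIdx"`
#'   record the trajectory indices of the split.
#' @export
trainRSP <- function(model, videos, config = trainConfig()) {
  if (length(videos) < 2L)
    stop("at least 2 sequences are required (one is held out for validation)")
  spec <- model@spec
  for (v in videos) checkVideo(v, spec)
  labels <- lapply(videos, function(v) rspLabels(dim(v)[1L]))
  n <- length(videos)

  params <- model@params
  history <- data.frame(epoch = integer(0), train_mae = numeric(0),
                        val_mae = numeric(0))
  withSeed(config$seed, {
    nVal <- max(1L, round(config$valFraction * n))
    valIdx <- sort(sample.int(n, nVal))
    trainIdx <- setdiff(seq_len(n), valIdx)
    if (!length(trainIdx)) stop("validation fraction leaves no training data")
    trainable <- c("conv", "fc", "rnn", "head")
    state <- optimizerInit(params[trainable])
    evalMAE <- function(idx) {
      mean(vapply(idx, function(i) {
        fw <- rspForwardPass(params, spec, videos[[i]])
        mean(abs(fw$yhat - labels[[i]]))
      }, numeric(1L)))
    }
    for (epoch in seq_len(config$epochs)) {
      for (i in sample(trainIdx)) {
        fw <- rspForwardPass(params, spec, videos[[i]])
        tau <- length(labels[[i]])
        dY <- sign(fw$yhat - labels[[i]]) / tau
        grads <- rspBackwardPass(params, spec, fw, dY)
        upd <- optimizerStep(params[trainable], grads, state,
                             config$learningRate, config$optimizer)
        params[trainable] <- upd$params
        state <- upd$state
      }
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_mae = evalMAE(trainIdx),
                                  val_mae = evalMAE(valIdx)))
    }
    out <- new("RSPModel", spec = spec, params = params, history = history)
    attr(out, "valIdx") <- valIdx
    attr(out, "trainIdx") <- trainIdx
    out
  })
}

#' Predict remaining surgery progress for a video
#'
#' Deterministic forward pass; predictions lie in `(0, 1)` by construction
#' (sigmoid output).
#'
#' @param model an [RSPModel-class].
#' @param video a `tau x size x size` array.
#' @return Numeric vector of length `tau`.
#' @export
predictRSP <- function(model, video) {
  checkVideo(video, model@spec)
  rspForwardPass(model@params, model@spec, video)$yhat
}

#' Available activation sources of an RSP model
#'
#' @param model an [RSPModel-class].
#' @return Character vector of source identifiers usable with
#'   [extractActivations()].
#' @export
availableSources <- function(model) {
  spec <- model@spec
  gates <- if (spec$decoder == "gru") c("update_gate", "reset_gate",
                                        "candidate")
  else c("input_gate", "forget_gate", "output_gate", "cell")
  rnnSrc <- as.vector(vapply(seq_len(spec$decoderLayers), function(l)
    paste0("decoder_l", l, "_", c("hidden", gates)),
    character(length(gates) + 1L)))
  c("encoder_output", rnnSrc, "head_fc1", "head_fc2", "rsp")
}

#' Extract per-frame internal activations
#'
#' Runs a forward pass and records the requested layer outputs or recurrent
#' gate activations as [RepresentationTrace-class] objects, one per source.
#' Gate traces of sigmoid gates lie in `(0, 1)`. Extraction is read-only: it
#' never alters the model or subsequent predictions. Units are addressed
#' 1-based by column; e.g. update gate 14 of the first GRU layer is column
#' 14 of source `"decoder_l1_update_gate"`.
#'
#' @param model an [RSPModel-class].
#' @param video a `tau x size x size` array.
#' @param sources character vector of source ids (see [availableSources()]).
#' @param trajectoryId identifier stored in the returned traces.
#' @return Named list of [RepresentationTrace-class] objects.
#' @export
extractActivations <- function(model, video,
                               sources = "decoder_l1_update_gate",
                               trajectoryId = "trajectory") {
  checkVideo(video, model@spec)
  avail <- availableSources(model)
  bad <- setdiff(sources, avail)
  if (length(bad))
    stop(sprintf("unknown source(s) %s; available: %s",
                 paste(bad, collapse = ", "), paste(avail, collapse = ", ")))
  fw <- rspForwardPass(model@params, model@spec, video)
  grab <- function(src) {
    if (src == "encoder_output") return(fw$enc$enc)
    if (src == "head_fc1") return(fw$head$A1)
    if (src == "head_fc2") return(fw$head$A2)
    if (src == "rsp") return(matrix(fw$yhat, ncol = 1L))
    m <- regmatches(src, regexec("^decoder_l([0-9]+)_(.+)$", src))[[1L]]
    l <- as.integer(m[2L]); what <- m[3L]
    r <- fw$rnn[[l]]
    switch(what,
           hidden = r$H, update_gate = r$Z, reset_gate = r$R,
           candidate = r$N, input_gate = r$I, forget_gate = r$F,
           output_gate = r$O, cell = r$C)
  }
  out <- lapply(sources, function(src)
    new("RepresentationTrace", source = src, values = grab(src),
        trajectoryId = trajectoryId))
  names(out) <- sources
  out
}
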