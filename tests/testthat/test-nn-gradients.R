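# Finite-difference validation of the analytic gradients that drive RSP
# training. Comparison uses a mixed absolute/relative tolerance because
# near-zero gradients sit at the numerical-differentiation noise floor.

gradCheck <- function(decoder) {
  ns <- asNamespace("surgact")
  spec <- tinySpec(decoder)
  model <- rspModel(spec, seed = 3L)
  params <- model@params
  set.seed(11)
  tau <- 5L
  vid <- array(runif(tau * 8 * 8), dim = c(tau, 8, 8))
  y <- runif(tau)
  loss <- function(p) {
    mean(abs(ns$rspForwardPass(p, spec, vid)$yhat - y))
  }
  fw <- ns$rspForwardPass(params, spec, vid)
  grads <- ns$rspBackwardPass(params, spec, fw, sign(fw$yhat - y) / tau)

  checkEntry <- function(getter, setter, analytic, label) {
    eps <- 1e-6
    up <- loss(setter(params, getter(params) + eps))
    dn <- loss(setter(params, getter(params) - eps))
    numeric <- (up - dn) / (2 * eps)
    expect_lt(abs(analytic - numeric),
              1e-6 + 1e-3 * abs(numeric), label = label)
  }
  checkEntry(function(p) p$conv[[1]]$W[3, 1],
             function(p, v) { p$conv[[1]]$W[3, 1] <- v; p },
             grads$conv[[1]]$W[3, 1], paste(decoder, "conv1 weight"))
  checkEntry(function(p) p$conv[[3]]$b[2],
             function(p, v) { p$conv[[3]]$b[2] <- v; p },
             grads$conv[[3]]$b[2], paste(decoder, "conv3 bias"))
  checkEntry(function(p) p$fc$W[2, 3],
             function(p, v) { p$fc$W[2, 3] <- v; p },
             grads$fc$W[2, 3], paste(decoder, "encoder fc weight"))
  checkEntry(function(p) p$rnn[[1]][[1]][2, 3],
             function(p, v) { p$rnn[[1]][[1]][2, 3] <- v; p },
             grads$rnn[[1]][[1]][2, 3], paste(decoder, "rnn1 input weight"))
  checkEntry(function(p) p$rnn[[2]][[5]][1, 2],
             function(p, v) { p$rnn[[2]][[5]][1, 2] <- v; p },
             grads$rnn[[2]][[5]][1, 2], paste(decoder, "rnn2 recurrent weight"))
  checkEntry(function(p) p$rnn[[1]][[10]][1],
             function(p, v) { p$rnn[[1]][[10]][1] <- v; p },
             grads$rnn[[1]][[10]][1], paste(decoder, "rnn1 bias"))
  checkEntry(function(p) p$head$W1[2, 2],
             function(p, v) { p$head$W1[2, 2] <- v; p },
             grads$head$W1[2, 2], paste(decoder, "head fc1 weight"))
  checkEntry(function(p) p$head$a1,
             function(p, v) { p$head$a1 <- v; p },
             grads$head$a1, paste(decoder, "head PReLU slope"))
  checkEntry(function(p) p$head$W3[4, 1],
             function(p, v) { p$head$W3[4, 1] <- v; p },
             grads$head$W3[4, 1], paste(decoder, "head output weight"))
}

test_that("analytic gradients match finite differences for the GRU decoder", {
  gradCheck("gru")
})

test_that("analytic gradients match finite differences for the LSTM decoder", {
  gradCheck("lstm")
})
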