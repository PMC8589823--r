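## Internal neural-network primitives for the remaining-surgery-progress
## model: a small stride-2 convolution stack (im2col formulation, batched
## over all frames of a sequence), a GRU or LSTM recurrent decoder, and a
## three-layer MLP head with PReLU activations and a sigmoid output. Forward
## and reverse passes are written directly against base-R matrix algebra;
## analytic gradients are validated by finite-difference tests.

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- convolution plumbing -------------------------------------------------

## Geometry of one 3x3 / stride-2 / pad-1 convolution on an H x H frame.
convPlan <- function(H) {
  k <- 3L; stride <- 2L; pad <- 1L
  Hp <- H + 2L * pad
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  ## column-major pixel index within a padded frame: (x-1)*Hp + y
  idx <- matrix(0L, Ho * Ho, k * k)
  pos <- 1L
  for (ox in seq_len(Ho)) {
    for (oy in seq_len(Ho)) {
      cell <- 1L
      for (kx in seq_len(k)) {
        for (ky in seq_len(k)) {
          iy <- (oy - 1L) * stride + ky
          ix <- (ox - 1L) * stride + kx
          idx[pos, cell] <- (ix - 1L) * Hp + iy
          cell <- cell + 1L
        }
      }
      pos <- pos + 1L
    }
  }
  ## padded linear indices of the real (unpadded) pixels, y-fastest to match
  ## the column-major activation layout
  real <- as.vector(outer(pad + seq_len(H), (pad + seq_len(H) - 1L) * Hp,
                          "+"))
  list(H = H, Hp = Hp, Ho = Ho, k = k, idx = idx, real = real)
}

## X: (tau*H^2) x Cin activation matrix, frame-major rows. Returns the
## (tau*Ho^2) x (9*Cin) im2col matrix.
im2col <- function(X, plan, tau) {
  Cin <- ncol(X)
  Pp <- plan$Hp^2
  Xp <- matrix(0, tau * Pp, Cin)
  realRows <- rep((seq_len(tau) - 1L) * Pp, each = plan$H^2) +
    rep(plan$real, tau)
  Xp[realRows, ] <- X
  Po <- plan$Ho^2
  out <- matrix(0, tau * Po, plan$k^2 * Cin)
  for (cell in seq_len(plan$k^2)) {
    g <- rep((seq_len(tau) - 1L) * Pp, each = Po) + rep(plan$idx[, cell], tau)
    out[, (cell - 1L) * Cin + seq_len(Cin)] <- Xp[g, , drop = FALSE]
  }
  out
}

## Scatter the im2col gradient back onto the input activations.
col2im <- function(dCol, plan, tau, Cin) {
  Pp <- plan$Hp^2
  Po <- plan$Ho^2
  dXp <- matrix(0, tau * Pp, Cin)
  for (cell in seq_len(plan$k^2)) {
    g <- rep((seq_len(tau) - 1L) * Pp, each = Po) + rep(plan$idx[, cell], tau)
    dXp[g, ] <- dXp[g, , drop = FALSE] +
      dCol[, (cell - 1L) * Cin + seq_len(Cin), drop = FALSE]
  }
  realRows <- rep((seq_len(tau) - 1L) * Pp, each = plan$H^2) +
    rep(plan$real, tau)
  dXp[realRows, , drop = FALSE]
}

## ---- parameter initialization --------------------------------------------

uinit <- function(nr, nc, fanIn) {
  s <- 1 / sqrt(fanIn)
  matrix(runif(nr * nc, -s, s), nr, nc)
}

initRSPParams <- function(spec, seed) {
  withSeed(seed, {
    V <- spec$inputSize
    ch <- c(1L, spec$convChannels)
    plans <- list()
    H <- V
    conv <- list()
    for (l in seq_along(spec$convChannels)) {
      plans[[l]] <- convPlan(H)
      conv[[l]] <- list(W = uinit(9L * ch[l], ch[l + 1L], 9L * ch[l]),
                        b = numeric(ch[l + 1L]))
      H <- plans[[l]]$Ho
    }
    flatDim <- H * H * ch[length(ch)]
    fc <- list(W = uinit(flatDim, spec$encoderWidth, flatDim),
               b = numeric(spec$encoderWidth))
    Hd <- spec$decoderWidth
    rnn <- list()
    inW <- spec$encoderWidth
    for (l in seq_len(spec$decoderLayers)) {
      if (spec$decoder == "gru") {
        rnn[[l]] <- list(Wz = uinit(inW, Hd, Hd), Wr = uinit(inW, Hd, Hd),
                         Wn = uinit(inW, Hd, Hd), Uz = uinit(Hd, Hd, Hd),
                         Ur = uinit(Hd, Hd, Hd), Un = uinit(Hd, Hd, Hd),
                         bz = numeric(Hd), br = numeric(Hd),
                         bn = numeric(Hd), bu = numeric(Hd))
      } else {
        rnn[[l]] <- list(Wi = uinit(inW, Hd, Hd), Wf = uinit(inW, Hd, Hd),
                         Wg = uinit(inW, Hd, Hd), Wo = uinit(inW, Hd, Hd),
                         Ui = uinit(Hd, Hd, Hd), Uf = uinit(Hd, Hd, Hd),
                         Ug = uinit(Hd, Hd, Hd), Uo = uinit(Hd, Hd, Hd),
                         bi = numeric(Hd), bf = rep(1, Hd),
                         bg = numeric(Hd), bo = numeric(Hd))
      }
      inW <- Hd
    }
    head <- list(W1 = uinit(Hd, Hd, Hd), b1 = numeric(Hd), a1 = 0.25,
                 W2 = uinit(Hd, Hd, Hd), b2 = numeric(Hd), a2 = 0.25,
                 W3 = uinit(Hd, 1L, Hd), b3 = numeric(1L))
    list(conv = conv, fc = fc, rnn = rnn, head = head, plans = plans)
  })
}

## ---- forward passes -------------------------------------------------------

encoderForward <- function(params, spec, vid) {
  tau <- dim(vid)[1L]
  V <- spec$inputSize
  ## frame-major activation matrix: row (t-1)*V^2 + p, column-major pixels
  X <- matrix(aperm(vid, c(2L, 3L, 1L)), nrow = V * V)  # (V^2) x tau
  X <- matrix(as.vector(X), ncol = 1L)                  # stacked frame-major
  caches <- list()
  act <- X
  for (l in seq_along(params$conv)) {
    plan <- params$plans[[l]]
    col <- im2col(act, plan, tau)
    pre <- sweep(col %*% params$conv[[l]]$W, 2L, params$conv[[l]]$b, "+")
    out <- pmax(pre, 0)
    caches[[l]] <- list(col = col, pre = pre, cin = ncol(act))
    act <- out
  }
  Po <- params$plans[[length(params$plans)]]$Ho^2
  Cout <- ncol(act)
  arr <- array(act, dim = c(Po, tau, Cout))
  flat <- matrix(aperm(arr, c(2L, 1L, 3L)), nrow = tau)   # tau x (Po*Cout)
  enc <- sweep(flat %*% params$fc$W, 2L, params$fc$b, "+")
  list(enc = enc, flat = flat, caches = caches, tau = tau, Po = Po,
       Cout = Cout)
}

encoderBackward <- function(params, spec, fw, dEnc) {
  tau <- fw$tau
  grads <- list(fc = list(W = crossprod(fw$flat, dEnc),
                          b = colSums(dEnc)),
                conv = vector("list", length(params$conv)))
  dFlat <- dEnc %*% t(params$fc$W)
  arr <- array(dFlat, dim = c(tau, fw$Po, fw$Cout))
  dAct <- matrix(aperm(arr, c(2L, 1L, 3L)), nrow = fw$Po * tau)
  for (l in rev(seq_along(params$conv))) {
    cache <- fw$caches[[l]]
    dPre <- dAct * (cache$pre > 0)
    grads$conv[[l]] <- list(W = crossprod(cache$col, dPre),
                            b = colSums(dPre))
    dCol <- dPre %*% t(params$conv[[l]]$W)
    dAct <- col2im(dCol, params$plans[[l]], tau, cache$cin)
  }
  grads
}

gruForward <- function(p, X) {
  tau <- nrow(X); H <- length(p$bz)
  XW <- cbind(X %*% p$Wz, X %*% p$Wr, X %*% p$Wn)
  Z <- R <- N <- HU <- Hs <- matrix(0, tau, H)
  h <- matrix(0, 1L, H)
  iz <- seq_len(H); ir <- H + iz; inn <- 2L * H + iz
  for (t in seq_len(tau)) {
    z <- sigmoid(XW[t, iz] + h %*% p$Uz + p$bz)
    r <- sigmoid(XW[t, ir] + h %*% p$Ur + p$br)
    hu <- h %*% p$Un + p$bu
    n <- tanh(XW[t, inn] + p$bn + r * hu)
    hNew <- (1 - z) * n + z * h
    Z[t, ] <- z; R[t, ] <- r; N[t, ] <- n; HU[t, ] <- hu; Hs[t, ] <- hNew
    h <- matrix(hNew, 1L, H)
  }
  list(H = Hs, Z = Z, R = R, N = N, HU = HU, X = X)
}

gruBackward <- function(p, fw, dH) {
  tau <- nrow(fw$H); H <- ncol(fw$H)
  Hprev <- rbind(matrix(0, 1L, H), fw$H[-tau, , drop = FALSE])
  dZp <- dRp <- dNp <- dHUa <- matrix(0, tau, H)
  dh <- numeric(H)
  for (t in rev(seq_len(tau))) {
    dht <- dH[t, ] + dh
    z <- fw$Z[t, ]; r <- fw$R[t, ]; n <- fw$N[t, ]; hu <- fw$HU[t, ]
    hp <- Hprev[t, ]
    dz <- dht * (hp - n) * z * (1 - z)
    dn <- dht * (1 - z) * (1 - n^2)
    dr <- dn * hu * r * (1 - r)
    dhu <- dn * r
    dZp[t, ] <- dz; dRp[t, ] <- dr; dNp[t, ] <- dn; dHUa[t, ] <- dhu
    dh <- dht * z + as.vector(dz %*% t(p$Uz)) + as.vector(dr %*% t(p$Ur)) +
      as.vector(dhu %*% t(p$Un))
  }
  dX <- dZp %*% t(p$Wz) + dRp %*% t(p$Wr) + dNp %*% t(p$Wn)
  grads <- list(Wz = crossprod(fw$X, dZp), Wr = crossprod(fw$X, dRp),
                Wn = crossprod(fw$X, dNp), Uz = crossprod(Hprev, dZp),
                Ur = crossprod(Hprev, dRp), Un = crossprod(Hprev, dHUa),
                bz = colSums(dZp), br = colSums(dRp), bn = colSums(dNp),
                bu = colSums(dHUa))
  list(grads = grads, dX = dX)
}

lstmForward <- function(p, X) {
  tau <- nrow(X); H <- length(p$bi)
  XW <- cbind(X %*% p$Wi, X %*% p$Wf, X %*% p$Wg, X %*% p$Wo)
  I <- F <- G <- O <- C <- Hs <- matrix(0, tau, H)
  h <- matrix(0, 1L, H); cc <- numeric(H)
  ii <- seq_len(H); iff <- H + ii; ig <- 2L * H + ii; io <- 3L * H + ii
  for (t in seq_len(tau)) {
    i <- sigmoid(XW[t, ii] + h %*% p$Ui + p$bi)
    f <- sigmoid(XW[t, iff] + h %*% p$Uf + p$bf)
    g <- tanh(XW[t, ig] + h %*% p$Ug + p$bg)
    o <- sigmoid(XW[t, io] + h %*% p$Uo + p$bo)
    cc <- f * cc + i * g
    hNew <- o * tanh(cc)
    I[t, ] <- i; F[t, ] <- f; G[t, ] <- g; O[t, ] <- o; C[t, ] <- cc
    Hs[t, ] <- hNew
    h <- matrix(hNew, 1L, H)
  }
  list(H = Hs, I = I, F = F, G = G, O = O, C = C, X = X)
}

lstmBackward <- function(p, fw, dH) {
  tau <- nrow(fw$H); H <- ncol(fw$H)
  Hprev <- rbind(matrix(0, 1L, H), fw$H[-tau, , drop = FALSE])
  Cprev <- rbind(matrix(0, 1L, H), fw$C[-tau, , drop = FALSE])
  dIp <- dFp <- dGp <- dOp <- matrix(0, tau, H)
  dh <- numeric(H); dc <- numeric(H)
  for (t in rev(seq_len(tau))) {
    dht <- dH[t, ] + dh
    i <- fw$I[t, ]; f <- fw$F[t, ]; g <- fw$G[t, ]; o <- fw$O[t, ]
    cc <- fw$C[t, ]; tc <- tanh(cc)
    do <- dht * tc * o * (1 - o)
    dct <- dc + dht * o * (1 - tc^2)
    di <- dct * g * i * (1 - i)
    df <- dct * Cprev[t, ] * f * (1 - f)
    dg <- dct * i * (1 - g^2)
    dIp[t, ] <- di; dFp[t, ] <- df; dGp[t, ] <- dg; dOp[t, ] <- do
    dc <- dct * f
    dh <- as.vector(di %*% t(p$Ui)) + as.vector(df %*% t(p$Uf)) +
      as.vector(dg %*% t(p$Ug)) + as.vector(do %*% t(p$Uo))
  }
  dX <- dIp %*% t(p$Wi) + dFp %*% t(p$Wf) + dGp %*% t(p$Wg) +
    dOp %*% t(p$Wo)
  grads <- list(Wi = crossprod(fw$X, dIp), Wf = crossprod(fw$X, dFp),
                Wg = crossprod(fw$X, dGp), Wo = crossprod(fw$X, dOp),
                Ui = crossprod(Hprev, dIp), Uf = crossprod(Hprev, dFp),
                Ug = crossprod(Hprev, dGp), Uo = crossprod(Hprev, dOp),
                bi = colSums(dIp), bf = colSums(dFp), bg = colSums(dGp),
                bo = colSums(dOp))
  list(grads = grads, dX = dX)
}

prelu <- function(x, a) pmax(x, 0) + a * pmin(x, 0)

headForward <- function(p, X) {
  Z1 <- sweep(X %*% p$W1, 2L, p$b1, "+")
  A1 <- prelu(Z1, p$a1)
  Z2 <- sweep(A1 %*% p$W2, 2L, p$b2, "+")
  A2 <- prelu(Z2, p$a2)
  Z3 <- A2 %*% p$W3 + p$b3
  list(yhat = as.vector(sigmoid(Z3)), Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2,
       Z3 = Z3, X = X)
}

headBackward <- function(p, fw, dY) {
  y <- sigmoid(fw$Z3)
  dZ3 <- matrix(dY * y * (1 - y), ncol = 1L)
  dA2 <- dZ3 %*% t(p$W3)
  dZ2 <- dA2 * ifelse(fw$Z2 > 0, 1, p$a2)
  dA1 <- dZ2 %*% t(p$W2)
  dZ1 <- dA1 * ifelse(fw$Z1 > 0, 1, p$a1)
  dX <- dZ1 %*% t(p$W1)
  grads <- list(W1 = crossprod(fw$X, dZ1), b1 = colSums(dZ1),
                a1 = sum(dA1 * pmin(fw$Z1, 0)),
                W2 = crossprod(fw$A1, dZ2), b2 = colSums(dZ2),
                a2 = sum(dA2 * pmin(fw$Z2, 0)),
                W3 = crossprod(fw$A2, dZ3), b3 = colSums(dZ3))
  list(grads = grads, dX = dX)
}

## Full forward pass over one video sequence; returns prediction and caches.
rspForwardPass <- function(params, spec, vid) {
  enc <- encoderForward(params, spec, vid)
  act <- enc$enc
  rnnFw <- vector("list", length(params$rnn))
  for (l in seq_along(params$rnn)) {
    rnnFw[[l]] <- if (spec$decoder == "gru") gruForward(params$rnn[[l]], act)
    else lstmForward(params$rnn[[l]], act)
    act <- rnnFw[[l]]$H
  }
  headFw <- headForward(params$head, act)
  list(yhat = headFw$yhat, enc = enc, rnn = rnnFw, head = headFw)
}

rspBackwardPass <- function(params, spec, fw, dY) {
  hb <- headBackward(params$head, fw$head, dY)
  dH <- hb$dX
  rnnGrads <- vector("list", length(params$rnn))
  for (l in rev(seq_along(params$rnn))) {
    rb <- if (spec$decoder == "gru") gruBackward(params$rnn[[l]], fw$rnn[[l]], dH)
    else lstmBackward(params$rnn[[l]], fw$rnn[[l]], dH)
    rnnGrads[[l]] <- rb$grads
    dH <- rb$dX
  }
  encGrads <- encoderBackward(params, spec, fw$enc, dH)
  list(conv = encGrads$conv, fc = encGrads$fc, rnn = rnnGrads,
       head = hb$grads)
}

## ---- optimizers ------------------------------------------------------------

## Parameters, gradients and optimizer state share one nested-list shape;
## walk them in lockstep.
mapParams <- function(p, g, s1, s2, f) {
  if (is.list(p)) {
    out <- vector("list", length(p))
    names(out) <- names(p)
    for (i in seq_along(p))
      out[[i]] <- mapParams(p[[i]], g[[i]], s1[[i]], s2[[i]], f)
    out
  } else f(p, g, s1, s2)
}

zeroLike <- function(p) {
  if (is.list(p)) lapply(p, zeroLike) else p * 0
}

optimizerInit <- function(params) {
  list(m = zeroLike(params), v = zeroLike(params), t = 0L)
}

optimizerStep <- function(params, grads, state, lr, kind = "adam",
                          beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  if (kind == "adam") {
    state$m <- mapParams(state$m, grads, state$m, state$m,
                         function(m, g, ...) beta1 * m + (1 - beta1) * g)
    state$v <- mapParams(state$v, grads, state$v, state$v,
                         function(v, g, ...) beta2 * v + (1 - beta2) * g^2)
    corr1 <- 1 - beta1^t; corr2 <- 1 - beta2^t
    params <- mapParams(params, grads, state$m, state$v,
                        function(p, g, m, v)
                          p - lr * (m / corr1) / (sqrt(v / corr2) + eps))
  } else {  # rmsprop
    state$v <- mapParams(state$v, grads, state$v, state$v,
                         function(v, g, ...) 0.99 * v + 0.01 * g^2)
    params <- mapParams(params, grads, state$v, state$v,
                        function(p, g, v, ...) p - lr * g / (sqrt(v) + eps))
  }
  list(params = params, state = state)
}
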