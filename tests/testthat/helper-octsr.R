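# Shared fixtures: everything is generated in code at test time.

# small, fast phantom for unit tests
tiny_spec <- function(...) {
  PhantomSpec(heightPx = 32L, widthPx = 32L, nLayers = 3L, layerCurvature = 3,
              framesPerSequence = 3L, ...)
}

# slim generator for unit tests (taps clamp to the shallower depth)
tiny_gen_config <- function(...) {
  GeneratorConfig(nResBlocks = 2L, featChannels = 8L, downsampleStride = 2L,
                  upChannels = 4L, projDim = 16L, ...)
}

tiny_train_config <- function(...) {
  do.call(TrainConfig, utils::modifyList(
    list(batchSize = 1L, epochs = 1L, seqLen = 3L, nPatches = 16L,
         dFilters = 8L, lossFramesPerSeq = 1L, lr = 1e-3), list(...)))
}

# central finite-difference check of an autodiff scalar head
fd_grad_check <- function(fwd, x0, nProbe = 8L, eps = 1e-5, seed = 42L) {
  octsr:::ad_tape_start()
  xn <- octsr:::ad_param(x0)
  L <- fwd(xn)
  octsr:::ad_backward(L)
  ga <- xn$g
  octsr:::ad_tape_stop()
  idx <- withr::with_seed(seed, sample(length(x0), min(nProbe, length(x0))))
  worst <- 0
  for (i in idx) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    num <- (as.numeric(octsr:::vof(fwd(xp))) -
            as.numeric(octsr:::vof(fwd(xm)))) / (2 * eps)
    worst <- max(worst, abs(ga[i] - num))
  }
  worst
}

# a random unit-norm matrix
runit <- function(n, d) {
  m <- matrix(rnorm(n * d), n, d)
  m / sqrt(rowSums(m * m))
}

# straight-from-the-definition GCF reimplementation (explicit loops),
# kept deliberately naive and separate from the package's vectorised path
gcf_oracle <- function(image) {
  k <- (image + 1) / 2 * 255
  total <- 0
  for (i in 1:9) {
    f <- 2^(i - 1)
    Hf <- floor(nrow(k) / f); Wf <- floor(ncol(k) / f)
    if (Hf < 1 || Wf < 1) next
    ki <- matrix(0, Hf, Wf)
    for (r in 1:Hf) for (cc in 1:Wf)
      ki[r, cc] <- mean(k[((r - 1) * f + 1):(r * f), ((cc - 1) * f + 1):(cc * f)])
    l <- (ki / 255)^2.2
    acc <- 0
    for (r in 1:Hf) for (cc in 1:Wf) {
      dif <- c()
      if (r > 1) dif <- c(dif, abs(l[r, cc] - l[r - 1, cc]))
      if (r < Hf) dif <- c(dif, abs(l[r, cc] - l[r + 1, cc]))
      if (cc > 1) dif <- c(dif, abs(l[r, cc] - l[r, cc - 1]))
      if (cc < Wf) dif <- c(dif, abs(l[r, cc] - l[r, cc + 1]))
      acc <- acc + if (length(dif)) mean(dif) else 0
    }
    Ci <- acc / (Hf * Wf)
    wi <- (-0.406385 * i / 9 + 0.334573) * i / 9 + 0.0877526
    total <- total + wi * Ci
  }
  total
}

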