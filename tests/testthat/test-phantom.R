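# The synthetic retina phantom: determinism, the stated degradation law,
# motion recovery, dataset layout and the direction of the domain gap.

test_that("phantom rendering is a pure function of (spec, seed)", {
  spec <- tiny_spec()
  a <- simulateRetinaPhantom(spec, seed = 7)
  b <- simulateRetinaPhantom(spec, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, simulateRetinaPhantom(spec, seed = 8)))
  sa <- simulateLRSequence(a, spec, seed = 3)
  sb <- simulateLRSequence(a, spec, seed = 3)
  expect_identical(sa$lr@frames, sb$lr@frames)
})

test_that("a flat single-layer noise-free phantom has constant bands", {
  spec <- PhantomSpec(heightPx = 40L, widthPx = 40L, nLayers = 1L,
                      layerIntensities = 0.5, layerCurvature = 0,
                      sensorNoiseSd = 0)
  img <- simulateRetinaPhantom(spec, seed = 1)
  # within each column, the middle of the band is flat at 0.5 -> mapped 0
  mid <- img[20:21, ]
  expect_lt(max(abs(mid - 0)), 0.02)
  # every column identical (no curvature, no wiggle beyond amplitude 0 rows)
  expect_lt(max(apply(img[15:25, ], 1, function(r) diff(range(r)))), 0.25)
  expect_identical(gcf(matrix(0.3, 16, 16)), 0)
})

test_that("the no-degradation limit reproduces the clean frame exactly", {
  spec <- tiny_spec(motionAmplitudePx = 0, speckleLooks = Inf,
                    contrastScale = 1, blurSigmaPx = 0, sensorNoiseSd = 0)
  hr <- simulateRetinaPhantom(spec, seed = 2)
  s <- simulateLRSequence(hr, spec, seed = 5)
  for (t in seq_len(nFrames(s$lr))) {
    expect_identical(getFrame(s$lr, t), hr)
    expect_identical(getFrame(s$reference, t), hr)
  }
})

test_that("speckle multiplier has unit mean and variance 1/L", {
  L <- 4
  spec <- PhantomSpec(heightPx = 64L, widthPx = 64L, nLayers = 1L,
                      layerIntensities = 0.2, layerCurvature = 2,
                      speckleLooks = L, contrastScale = 1, blurSigmaPx = 0,
                      motionAmplitudePx = 0, sensorNoiseSd = 0,
                      framesPerSequence = 4L)
  ratios <- c()
  for (i in 1:6) {
    hr <- simulateRetinaPhantom(spec, seed = 100 + i)
    s <- simulateLRSequence(hr, spec, seed = 200 + i)
    clean01 <- (hr + 1) / 2
    sel <- clean01 > 0.12 & clean01 < 0.25      # interior band, clip-safe
    for (t in seq_len(4))
      ratios <- c(ratios, (((getFrame(s$lr, t) + 1) / 2) / clean01)[sel])
  }
  n <- length(ratios)
  expect_gt(n, 5000)
  se_mean <- sd(ratios) / sqrt(n)
  expect_lt(abs(mean(ratios) - 1), 3 * se_mean)
  v <- var(ratios)
  se_var <- sd((ratios - mean(ratios))^2) / sqrt(n)
  expect_lt(abs(v - 1 / L), 3 * se_var)
})

test_that("drawn inter-frame motion is recovered by cross-correlation", {
  spec <- PhantomSpec(motionAmplitudePx = 3, speckleLooks = Inf,
                      contrastScale = 1, blurSigmaPx = 0, sensorNoiseSd = 0)
  hr <- simulateRetinaPhantom(spec, seed = 31)
  s <- simulateLRSequence(hr, spec, seed = 32)
  # phase-correlation oracle (fft-based, parabolic sub-pixel refinement)
  phase_shift <- function(a, b) {
    hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    w <- outer(hann(nrow(a)), hann(ncol(a)))
    a <- (a - mean(a)) * w; b <- (b - mean(b)) * w
    FA <- fft(a); FB <- fft(b)
    R <- FA * Conj(FB)
    R <- R / (Mod(R) + 1e-12)
    r <- Re(fft(R, inverse = TRUE)) / length(a)
    pk <- which(r == max(r), arr.ind = TRUE)[1, ]
    H <- nrow(a); W <- ncol(a)
    refine <- function(v, i, n) {
      im <- v[(i - 2) %% n + 1]; i0 <- v[i]; ip <- v[i %% n + 1]
      den <- im - 2 * i0 + ip
      if (abs(den) < 1e-12) 0 else min(max(0.5 * (im - ip) / den, -0.5), 0.5)
    }
    dy <- pk[1] - 1 + refine(r[, pk[2]], pk[1], H)
    dx <- pk[2] - 1 + refine(r[pk[1], ], pk[2], W)
    if (dy > H / 2) dy <- dy - H
    if (dx > W / 2) dx <- dx - W
    c(dx, dy)
  }
  for (t in 2:nFrames(s$reference)) {
    est <- phase_shift(getFrame(s$reference, t), getFrame(s$reference, t - 1))
    truth <- s$shifts[t, ] - s$shifts[t - 1, ]
    expect_lt(max(abs(est - truth)), 0.5)
  }
})

test_that("built datasets have the promised layout, determinism and unpairedness", {
  spec <- tiny_spec()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  man <- buildPhantomDataset(spec, 4, 4, d1, seed = 9)
  roles <- vapply(man$items, `[[`, "", "role")
  expect_identical(sum(roles == "lr_sequence"), 4L)
  expect_identical(sum(roles == "hr_image"), 4L)
  expect_length(list.files(file.path(d1, "lr"), recursive = TRUE), 4L * 3L)
  expect_length(list.files(file.path(d1, "hr")), 4L)
  expect_length(list.files(file.path(d1, "reference"), recursive = TRUE), 4L * 3L)
  # determinism: identical manifests and identical frame bytes
  buildPhantomDataset(spec, 4, 4, d2, seed = 9)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  f1 <- list.files(d1, recursive = TRUE, full.names = TRUE, pattern = "tif$")
  f2 <- list.files(d2, recursive = TRUE, full.names = TRUE, pattern = "tif$")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # unpairedness: disjoint geometry seeds for the two domains
  lrSeeds <- vapply(Filter(function(i) i$role == "lr_sequence", man$items),
                    `[[`, numeric(1), "seed")
  hrSeeds <- vapply(Filter(function(i) i$role == "hr_image", man$items),
                    `[[`, numeric(1), "seed")
  expect_length(intersect(lrSeeds, hrSeeds), 0L)
  expect_error(buildPhantomDataset(spec, 0, 4, withr::local_tempdir()), ">= 1")
})

test_that("the phantom reproduces the direction of the iOCT-preOCT gap", {
  spec <- PhantomSpec()
  n <- 50
  gHR <- fHR <- gLR <- fLR <- numeric(n)
  for (i in seq_len(n)) {
    hr <- simulateRetinaPhantom(spec, seed = 4000 + 2 * i)
    gHR[i] <- gcf(hr); fHR[i] <- fne(hr)
    lr1 <- getFrame(simulateLRSequence(
      simulateRetinaPhantom(spec, seed = 6000 + 2 * i), spec,
      seed = 6500 + i)$lr, 1)
    gLR[i] <- gcf(lr1); fLR[i] <- fne(lr1)
  }
  expect_gt(mean(fLR), mean(fHR))   # iOCT domain is noisier
  expect_lt(mean(gLR), mean(gHR))   # and lower-contrast
})

test_that("clean phantoms carry only mild sensor noise", {
  fnes <- vapply(1:300, function(i)
    fne(simulateRetinaPhantom(PhantomSpec(), seed = 10000 + i)), numeric(1))
  expect_lte(mean(fnes), 0.01)
})
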