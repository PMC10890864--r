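# The recurrent generator: shape contracts, identity cases, propagation
# causality, the zero-warp switch and the encoder taps.

test_that("embedding divides the spatial size exactly and rejects misfits", {
  gen <- newGenerator(tiny_gen_config(), seed = 1)
  e <- downsampleEmbed(gen, matrix(0.1, 32, 32))
  expect_equal(dim(e), c(16L, 16L, 8L))
  expect_error(downsampleEmbed(gen, matrix(0, 33, 33)), "divisible")
})

test_that("a stride-1 identity-initialised embedding reproduces the input", {
  gen <- newGenerator(GeneratorConfig(nResBlocks = 1L, featChannels = 1L,
                                      downsampleStride = 1L, upChannels = 1L,
                                      projHead = FALSE), seed = 1)
  gen$par$embed_W$v <- matrix(1, 1, 1)
  gen$par$embed_b$v <- 0
  x <- matrix(runif(64, -1, 1), 8, 8)
  out <- downsampleEmbed(gen, x)
  expect_equal(out[, , 1], x, tolerance = 1e-12)
})

test_that("zeroed residual branches make the reconstruction an identity", {
  gen <- newGenerator(tiny_gen_config(), seed = 2)
  for (b in gen$res) { b$W1$v <- b$W1$v * 0; b$W2$v <- b$W2$v * 0
                       b$be1$v <- b$be1$v * 0; b$be2$v <- b$be2$v * 0 }
  emb <- downsampleEmbed(gen, matrix(runif(1024, -1, 1), 32, 32))
  st <- octsr:::zero_state(gen, dim(emb))
  out <- reconstructFeatures(gen, st, emb)
  # equals the post-projection input (conv + relu of the concat)
  ref <- octsr:::ad_conv2d(octsr:::ad_concat_c(st, emb), gen$par$recin_W$v,
                           gen$par$recin_b$v, act = "relu")
  expect_equal(out, ref, tolerance = 1e-12)
})

test_that("generator forward passes are bit-reproducible across builds", {
  cfg <- tiny_gen_config(flowBackend = "zero")
  x <- matrix(runif(1024, -1, 1), 32, 32)
  seqArr <- array(rep(x, 3), c(32, 32, 3))
  y1 <- superResolve(newGenerator(cfg, seed = 5), seqArr)
  y2 <- superResolve(newGenerator(cfg, seed = 5), seqArr)
  expect_identical(y1@frames, y2@frames)
})

test_that("a single-frame sequence reduces to reconstruction from zeros", {
  gen <- newGenerator(tiny_gen_config(), seed = 3)
  x <- matrix(runif(1024, -1, 1), 32, 32)
  for (dir in c("backward", "forward")) {
    st <- propagateFeatures(gen, array(x, c(32, 32, 1)), dir)
    emb <- downsampleEmbed(gen, x)
    direct <- reconstructFeatures(gen, octsr:::zero_state(gen, dim(emb)), emb)
    expect_equal(st[[1]], direct, tolerance = 1e-12)
  }
})

test_that("temporal causality: the two branches see opposite time arrows", {
  gen <- newGenerator(tiny_gen_config(flowBackend = "zero"), seed = 4)
  set.seed(31)
  seqArr <- array(runif(32 * 32 * 4, -1, 1), c(32, 32, 4))
  pert <- seqArr
  pert[, , 4] <- pmin(pmax(pert[, , 4] + 0.3, -1), 1)   # touch the last frame
  hb <- propagateFeatures(gen, seqArr, "backward")
  hbP <- propagateFeatures(gen, pert, "backward")
  hf <- propagateFeatures(gen, seqArr, "forward")
  hfP <- propagateFeatures(gen, pert, "forward")
  expect_gt(max(abs(hbP[[1]] - hb[[1]])), 1e-6)   # backward carries it to t=1
  expect_identical(hf[[1]], hfP[[1]])             # forward cannot
})

test_that("the zero-warp switch severs all temporal information flow", {
  gen <- newGenerator(tiny_gen_config(flowBackend = "zero", zeroWarp = TRUE),
                      seed = 5)
  set.seed(32)
  seqArr <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  pert <- seqArr
  pert[, , c(1, 3)] <- -pert[, , c(1, 3)]
  y <- superResolve(gen, seqArr)
  yP <- superResolve(gen, pert)
  expect_identical(getFrame(y, 2), getFrame(yP, 2))
  # and with warping enabled the same perturbation does reach frame 2
  gen2 <- newGenerator(tiny_gen_config(flowBackend = "zero"), seed = 5)
  expect_gt(max(abs(getFrame(superResolve(gen2, seqArr), 2) -
                    getFrame(superResolve(gen2, pert), 2))), 1e-8)
})

test_that("zero-flow propagation equals an explicit pass-through oracle", {
  gen <- newGenerator(tiny_gen_config(flowBackend = "zero"), seed = 6)
  set.seed(33)
  seqArr <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  got <- propagateFeatures(gen, seqArr, "backward")
  # oracle: the same recurrence with the warp replaced by identity
  embeds <- lapply(1:3, function(t) downsampleEmbed(gen, seqArr[, , t]))
  h <- octsr:::zero_state(gen, dim(embeds[[1]]))
  want <- vector("list", 3)
  for (t in 3:1) {
    h <- reconstructFeatures(gen, h, embeds[[t]])
    want[[t]] <- h
  }
  for (t in 1:3) expect_lt(max(abs(got[[t]] - want[[t]])), 1e-6)
})

test_that("outputs preserve resolution, stay in (-1, 1) and accept T = 2..9", {
  gen <- newGenerator(tiny_gen_config(flowBackend = "zero"), seed = 7)
  set.seed(34)
  for (T in c(2L, 5L, 9L)) {
    seqArr <- array(runif(32 * 32 * T, -1, 1), c(32, 32, T))
    y <- superResolve(gen, seqArr)
    expect_equal(dim(y), c(32L, 32L, T))
    expect_true(all(is.finite(y@frames)))
    expect_true(all(abs(y@frames) < 1))
  }
})

test_that("encoder taps have the documented identities and geometry", {
  gen <- newGenerator(tiny_gen_config(), seed = 8)
  x <- matrix(runif(1024, -1, 1), 32, 32)
  fs <- extractLayerFeatures(gen, x)
  expect_named(fs, c("l0", "l1", "l2", "l3", "l4"))
  expect_equal(fs$l0[, , 1], x)                 # pixel layer is the image
  sizes <- vapply(fs, function(f) dim(octsr:::vof(f))[1], numeric(1))
  expect_true(all(diff(sizes) <= 0))            # non-increasing l0 -> l1
  expect_identical(length(unique(sizes[-1])), 1L)  # constant l1 -> l4
  expect_error(extractLayerFeatures(gen, x, layers = c("l0", "l9")), "unknown")
  # the encoder IS the generator: the same parameter environments are used
  before <- extractLayerFeatures(gen, x, layers = "l1")$l1
  gen$par$embed_W$v <- gen$par$embed_W$v * 2
  after <- extractLayerFeatures(gen, x, layers = "l1")$l1
  expect_equal(after, before * 2, tolerance = 1e-12)
})

test_that("the default architecture matches its printed description", {
  cfg <- GeneratorConfig()
  expect_identical(cfg@nResBlocks, 10L)
  expect_identical(cfg@featChannels, 128L)
  gen <- newGenerator(cfg, seed = 1)
  expect_length(gen$res, 10L)
  expect_true(all(vapply(gen$res, function(b) ncol(b$W1$v) == 128L, logical(1))))
})
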