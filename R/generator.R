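# The bidirectional recurrent generator: strided 1x1 embedding, optical-flow
# warping of propagated features, a residual reconstruction module shared by
# both temporal directions, concatenation-based aggregation and pixel-shuffle
# upsampling back to the input resolution with a tanh output. The same
# encoder layers double as the multilayer feature extractor used by the
# contrastive and evaluation paths.

#' Build a recurrent generator
#'
#' @param config a [GeneratorConfig-class]
#' @param seed weight-initialisation seed
#' @return a list with `par` (named parameter environments), `proj`
#'   (contrastive projection heads) and `config`
#' @export
newGenerator <- function(config = GeneratorConfig(), seed = 1L) {
  validObject(config)
  F <- config@featChannels
  s <- config@downsampleStride
  up <- config@upChannels
  with_seed(seed, {
    par <- list(
      embed_W = ad_param(he_init(1L, F)),
      embed_b = ad_param(numeric(F)),
      recin_W = ad_param(he_init(9L * 2L * F, F)),
      recin_b = ad_param(numeric(F)),
      fuse_W = ad_param(he_init(2L * F, F)),
      fuse_b = ad_param(numeric(F)),
      up1_W = ad_param(he_init(9L * F, s * s * up)),
      up1_b = ad_param(numeric(s * s * up)),
      up2_W = ad_param(he_init(9L * up, 1L, gain = 0.1)),
      up2_b = ad_param(numeric(1L)))
    res <- vector("list", config@nResBlocks)
    for (i in seq_len(config@nResBlocks)) {
      res[[i]] <- list(
        W1 = ad_param(he_init(9L * F, F)), g1 = ad_param(rep(1, F)),
        be1 = ad_param(numeric(F)),
        W2 = ad_param(he_init(9L * F, F)), g2 = ad_param(rep(1, F)),
        be2 = ad_param(numeric(F)))
    }
    proj <- NULL
    if (config@projHead) {
      pd <- config@projDim
      dims <- c(1L, F, F, F, F)       # feature widths at taps l0..l4
      proj <- lapply(dims, function(dl) list(
        W1 = ad_param(he_init(dl, pd)), b1 = ad_param(numeric(pd)),
        W2 = ad_param(he_init(pd, pd)), b2 = ad_param(numeric(pd))))
    }
    list(par = par, res = res, proj = proj, config = config)
  })
}

#' Flat list of a generator's trainable parameters
#' @keywords internal
generator_params <- function(gen, includeProj = TRUE) {
  ps <- unname(gen$par)
  for (b in gen$res) ps <- c(ps, unname(b))
  if (includeProj && !is.null(gen$proj))
    for (h in gen$proj) ps <- c(ps, unname(h))
  ps
}

as_hw1 <- function(frame) {
  fv <- vof(frame)
  if (is.matrix(fv)) {
    d <- dim(fv)
    if (is_ad(frame)) stop("frame nodes must already be (H, W, 1)")
    dim(fv) <- c(d, 1L)
    return(fv)
  }
  frame
}

#' Strided 1x1 embedding of a frame to feature resolution
#'
#' @param gen a generator from [newGenerator()]
#' @param frame `(H, W)` matrix (or `(H, W, 1)` array/node) in [-1, 1]
#' @return `(H/s, W/s, F)` feature array (node while a tape is active)
#' @export
downsampleEmbed <- function(gen, frame) {
  x <- as_hw1(frame)
  d <- dim(vof(x))
  s <- gen$config@downsampleStride
  if (d[1] %% s != 0L || d[2] %% s != 0L)
    stop("frame size must be divisible by the downsampling stride")
  maybe_val(ad_conv2d(x, gen$par$embed_W, gen$par$embed_b, kh = 1L, kw = 1L,
                      stride = s, pad = 0L))
}

#' Bilinear feature warping (exported wrapper over the autodiff op)
#'
#' Zero flow is an exact identity; out-of-range samples clamp to the border.
#'
#' @param feat `(H', W', F)` feature array or node
#' @param flow `(H', W', 2)` displacement field at feature resolution
#' @export
warpFeatures <- function(feat, flow) {
  dv <- dim(vof(feat))
  if (!all(dim(vof(flow))[1:2] == dv[1:2]))
    stop("flow and feature spatial sizes differ")
  maybe_val(ad_warp(feat, flow))
}

#' Reconstruction module: fuse warped state with the frame embedding
#'
#' Concatenates the warped propagated features with the current frame's
#' embedding, projects back to F channels (3x3 convolution + ReLU) and
#' refines through the residual blocks (conv - instance norm - ReLU -
#' conv - instance norm, plus the skip).
#'
#' @param gen generator
#' @param warped `(H', W', F)` warped propagated state (use zeros at the
#'   terminal frame)
#' @param embed `(H', W', F)` current-frame embedding
#' @param collectTaps also return the encoder activations used by the
#'   contrastive loss
#' @return the refined `(H', W', F)` state, or a list `(state, taps)` when
#'   `collectTaps`
#' @export
reconstructFeatures <- function(gen, warped, embed, collectTaps = FALSE) {
  x <- ad_concat_c(warped, embed)
  x <- ad_conv2d(x, gen$par$recin_W, gen$par$recin_b, act = "relu")
  taps <- if (collectTaps) list(l2 = x) else NULL
  n <- length(gen$res)
  t3 <- min(2L, n); t4 <- min(4L, n)
  for (i in seq_len(n)) {
    b <- gen$res[[i]]
    r <- ad_conv_in(x, b$W1, b$g1, b$be1, act = "relu")
    r <- ad_conv_in(r, b$W2, b$g2, b$be2)
    x <- ad_add(x, r)
    if (collectTaps) {
      if (i == t3) taps$l3 <- x
      if (i == t4) taps$l4 <- x
    }
  }
  if (collectTaps) list(state = maybe_val(x), taps = lapply(taps, maybe_val))
  else maybe_val(x)
}

zero_state <- function(gen, d) array(0, dim = c(d[1], d[2], gen$config@featChannels))

compute_flows <- function(gen, seqArr, direction) {
  T <- dim(seqArr)[3]
  s <- gen$config@downsampleStride
  backend <- gen$config@flowBackend
  fl <- vector("list", T)
  if (direction == "backward") {
    for (t in seq_len(T - 1L))
      fl[[t]] <- pool_flow(estimateFlow(seqArr[, , t], seqArr[, , t + 1L],
                                        backend = backend), s)
  } else {
    for (t in 2:max(2L, T)) if (t <= T)
      fl[[t]] <- pool_flow(estimateFlow(seqArr[, , t], seqArr[, , t - 1L],
                                        backend = backend), s)
  }
  fl
}

#' Recurrent propagation over a sequence in one temporal direction
#'
#' The backward pass runs t = T..1 aligning the state from frame t+1 with
#' flow OF(x_t, x_t+1); the forward pass runs t = 1..T aligning from frame
#' t-1. Terminal frames start from a zero state. With the zero-warp ablation
#' the warped state is replaced by zeros, making every per-frame state
#' independent of the other frames.
#'
#' @param gen generator
#' @param seq a [VideoSequence-class] or `(H, W, T)` array
#' @param direction "backward" or "forward"
#' @param embeds optional precomputed per-frame embeddings
#' @param flows optional precomputed per-frame feature-resolution flows
#' @return list of per-frame `(H', W', F)` states, index = frame
#' @export
propagateFeatures <- function(gen, seq, direction = c("backward", "forward"),
                              embeds = NULL, flows = NULL) {
  direction <- match.arg(direction)
  seqArr <- if (is(seq, "VideoSequence")) seq@frames else seq
  T <- dim(seqArr)[3]
  if (is.null(embeds))
    embeds <- lapply(seq_len(T), function(t) downsampleEmbed(gen, seqArr[, , t]))
  dfeat <- dim(vof(embeds[[1L]]))
  zw <- gen$config@zeroWarp
  if (is.null(flows) && !zw && T > 1L)
    flows <- compute_flows(gen, seqArr, direction)
  states <- vector("list", T)
  order_t <- if (direction == "backward") T:1 else 1:T
  h <- NULL
  for (t in order_t) {
    w <- if (is.null(h) || zw) zero_state(gen, dfeat)
         else warpFeatures(h, flows[[t]])
    h <- reconstructFeatures(gen, w, embeds[[t]])
    states[[t]] <- h
  }
  states
}

#' Aggregate the two temporal branches and upsample to the input resolution
#'
#' Per frame: channel concatenation of the forward and backward states, a
#' 1x1 fusion convolution, a 3x3 convolution to s^2 x upChannels, pixel
#' shuffle by the downsampling stride, a final 3x3 convolution to one
#' channel and tanh (optionally adding the input frame first when the
#' residual-skip flag is set).
#'
#' @param gen generator
#' @param hF,hB per-frame state lists from [propagateFeatures()]
#' @param inputFrames optional `(H, W, T)` array, required for residual skip
#' @param frames frame indices to synthesise (default: all)
#' @return list of per-frame `(H, W, 1)` outputs in (-1, 1), indexed by frame
#' @export
fuseUpsample <- function(gen, hF, hB, inputFrames = NULL,
                         frames = seq_along(hF)) {
  s <- gen$config@downsampleStride
  T <- length(hF)
  out <- vector("list", T)
  for (t in frames) {
    x <- ad_concat_c(hF[[t]], hB[[t]])
    x <- ad_conv2d(x, gen$par$fuse_W, gen$par$fuse_b, kh = 1L, kw = 1L,
                   stride = 1L, pad = 0L, act = "relu")
    # ReLU commutes with the pixel-shuffle permutation, so it is fused here
    x <- ad_conv2d(x, gen$par$up1_W, gen$par$up1_b, act = "relu")
    if (s > 1L) x <- ad_pixel_shuffle(x, s)
    x <- ad_conv2d(x, gen$par$up2_W, gen$par$up2_b)
    if (gen$config@residualSkip) {
      if (is.null(inputFrames)) stop("residual skip needs the input frames")
      fr <- inputFrames[, , t]
      dim(fr) <- c(dim(fr), 1L)
      x <- ad_add(x, fr)
    }
    out[[t]] <- maybe_val(ad_tanh(x))
  }
  out
}

#' Super-resolve a video sequence
#'
#' Full pipeline: embedding, backward propagation, forward propagation,
#' aggregation and upsampling. The output has exactly the input resolution
#' and frame count (the task is quality enhancement, not spatial upscaling)
#' and any sequence length T >= 1 is accepted regardless of the training
#' length.
#'
#' @param model an [SRModel-class] or a generator list
#' @param seq a [VideoSequence-class] (or `(H, W, T)` array)
#' @param flows optional precomputed list with elements `backward` and
#'   `forward` (feature-resolution flows), e.g. cached across epochs
#' @return a [VideoSequence-class] of enhanced frames
#' @export
superResolve <- function(model, seq, flows = NULL) {
  gen <- if (is(model, "SRModel")) model@generator else model
  seqArr <- if (is(seq, "VideoSequence")) seq@frames else seq
  if (is.matrix(seqArr)) dim(seqArr) <- c(dim(seqArr), 1L)
  out <- generator_forward(gen, seqArr, flows = flows)
  VideoSequence(lapply(out$yhat, function(y) {
    m <- vof(y)
    dim(m) <- dim(m)[1:2]
    m
  }))
}

#' Core generator forward pass (returns nodes while a tape is active)
#' @keywords internal
generator_forward <- function(gen, seqArr, flows = NULL, frames = NULL) {
  T <- dim(seqArr)[3]
  embeds <- lapply(seq_len(T), function(t) downsampleEmbed(gen, seqArr[, , t]))
  zw <- gen$config@zeroWarp
  if (is.null(flows) && !zw && T > 1L) {
    flows <- list(backward = compute_flows(gen, seqArr, "backward"),
                  forward = compute_flows(gen, seqArr, "forward"))
  }
  hB <- propagateFeatures(gen, seqArr, "backward", embeds = embeds,
                          flows = flows$backward)
  hF <- propagateFeatures(gen, seqArr, "forward", embeds = embeds,
                          flows = flows$forward)
  yhat <- fuseUpsample(gen, hF, hB, inputFrames = seqArr,
                       frames = frames %||% seq_len(T))
  list(yhat = yhat, hF = hF, hB = hB, embeds = embeds)
}

#' Extract the multilayer encoder features of a single frame
#'
#' Layers follow the contrastive-loss taps: `l0` the raw pixels, `l1` the
#' downsampling convolution output, `l2` the first convolution of the
#' reconstruction path, `l3` and `l4` the second and fourth residual blocks
#' (clamped to the configured depth for shallower generators). The encoder
#' weights are the generator's own: extracting from an input frame and from
#' a generated frame uses identical parameters.
#'
#' @param model an [SRModel-class] or generator list
#' @param frame `(H, W)` matrix, `(H, W, 1)` array, or a node
#' @param layers subset of c("l0", "l1", "l2", "l3", "l4")
#' @return named list of feature arrays (nodes while a tape is active)
#' @export
extractLayerFeatures <- function(model, frame,
                                 layers = c("l0", "l1", "l2", "l3", "l4")) {
  gen <- if (is(model, "SRModel")) model@generator else model
  unknown <- setdiff(layers, c("l0", "l1", "l2", "l3", "l4"))
  if (length(unknown)) stop("unknown layer id(s): ", paste(unknown, collapse = ", "))
  x <- as_hw1(frame)
  out <- list()
  if ("l0" %in% layers) out$l0 <- x
  emb <- downsampleEmbed(gen, x)
  if ("l1" %in% layers) out$l1 <- emb
  dfeat <- dim(vof(emb))
  rec <- reconstructFeatures(gen, zero_state(gen, dfeat), emb, collectTaps = TRUE)
  if ("l2" %in% layers) out$l2 <- rec$taps$l2
  if ("l3" %in% layers) out$l3 <- rec$taps$l3
  if ("l4" %in% layers) out$l4 <- rec$taps$l4
  lapply(out[layers], maybe_val)
}
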