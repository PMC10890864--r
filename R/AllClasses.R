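# S4 classes for the phantom simulator, the video container, the model and
# the evaluation report.

#' Retina-phantom simulation settings
#'
#' Describes one simulated OCT cross-section domain: image geometry, the
#' layered-band structure, and the degradations that turn the clean
#' high-resolution rendering into an intra-operative-style low-resolution
#' sequence (multiplicative gamma speckle, contrast compression, blur and
#' inter-frame motion).
#'
#' @slot heightPx,widthPx image size in pixels (> 16)
#' @slot nLayers number of retinal bands between vitreous and choroid
#' @slot layerCurvature peak vertical deflection of the retinal arc, px
#' @slot layerIntensities per-band reflectivities in [0, 1] (recycled)
#' @slot speckleLooks gamma-speckle shape L > 0; the multiplicative noise is
#'   unit-mean with variance 1/L; `Inf` disables speckle
#' @slot contrastScale low-resolution contrast compression factor in (0, 1]
#' @slot motionAmplitudePx maximum inter-frame translation, px
#' @slot framesPerSequence frames T per low-resolution sequence (>= 2)
#' @slot blurSigmaPx Gaussian blur applied to the low-resolution domain, px
#' @slot sensorNoiseSd additive sensor noise on the clean [0, 1] rendering
#' @slot seed base random seed for the geometry draw
#' @export
setClass("PhantomSpec", representation(
  heightPx = "integer", widthPx = "integer", nLayers = "integer",
  layerCurvature = "numeric", layerIntensities = "numeric",
  speckleLooks = "numeric", contrastScale = "numeric",
  motionAmplitudePx = "numeric", framesPerSequence = "integer",
  blurSigmaPx = "numeric", sensorNoiseSd = "numeric", seed = "integer"),
  prototype(heightPx = 64L, widthPx = 64L, nLayers = 6L,
            layerCurvature = 6, layerIntensities = numeric(0),
            speckleLooks = 2, contrastScale = 0.45,
            motionAmplitudePx = 1.5, framesPerSequence = 5L,
            blurSigmaPx = 0.8, sensorNoiseSd = 0.003, seed = 1L))

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (object@heightPx <= 16L || object@widthPx <= 16L)
    msg <- c(msg, "heightPx and widthPx must exceed 16")
  if (object@framesPerSequence < 2L)
    msg <- c(msg, "framesPerSequence must be at least 2")
  if (!(object@speckleLooks > 0)) msg <- c(msg, "speckleLooks must be > 0")
  if (length(object@layerIntensities) &&
      (any(object@layerIntensities < 0) || any(object@layerIntensities > 1)))
    msg <- c(msg, "layerIntensities must lie in [0, 1]")
  if (object@contrastScale <= 0 || object@contrastScale > 1)
    msg <- c(msg, "contrastScale must lie in (0, 1]")
  if (object@nLayers < 1L) msg <- c(msg, "nLayers must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' @param heightPx,widthPx,nLayers,layerCurvature,layerIntensities,speckleLooks
#'   see the class slots
#' @param contrastScale,motionAmplitudePx,framesPerSequence,blurSigmaPx,sensorNoiseSd,seed
#'   see the class slots
#' @return a validated [PhantomSpec-class] object
#' @examples
#' spec <- PhantomSpec(heightPx = 32L, widthPx = 32L)
#' @export
PhantomSpec <- function(heightPx = 64L, widthPx = 64L, nLayers = 6L,
                        layerCurvature = 6, layerIntensities = numeric(0),
                        speckleLooks = 2, contrastScale = 0.45,
                        motionAmplitudePx = 1.5, framesPerSequence = 5L,
                        blurSigmaPx = 0.8, sensorNoiseSd = 0.003, seed = 1L) {
  new("PhantomSpec", heightPx = as.integer(heightPx), widthPx = as.integer(widthPx),
      nLayers = as.integer(nLayers), layerCurvature = layerCurvature,
      layerIntensities = layerIntensities, speckleLooks = speckleLooks,
      contrastScale = contrastScale, motionAmplitudePx = motionAmplitudePx,
      framesPerSequence = as.integer(framesPerSequence),
      blurSigmaPx = blurSigmaPx, sensorNoiseSd = sensorNoiseSd,
      seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %dx%d px, %d layers, curvature %.1f px\n",
              object@heightPx, object@widthPx, object@nLayers, object@layerCurvature))
  cat(sprintf("  LR degradation: speckle L=%.3g, contrast x%.2f, blur %.2f px, motion <=%.2f px, T=%d\n",
              object@speckleLooks, object@contrastScale, object@blurSigmaPx,
              object@motionAmplitudePx, object@framesPerSequence))
})

#' Grayscale video clip with values in [-1, 1]
#'
#' Frames are stored as an `(H, W, T)` array; the class is the common
#' currency between the phantom simulator, the recurrent generator and the
#' quality metrics.
#'
#' @slot frames numeric array of dimension `(H, W, T)`
#' @export
setClass("VideoSequence", representation(frames = "array"))

setValidity("VideoSequence", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be an (H, W, T) array")
  if (d[3] < 1L) return("at least one frame is required")
  rng <- range(object@frames)
  if (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9)
    return("frame values must lie in [-1, 1]")
  TRUE
})

#' Construct a VideoSequence from an array or list of frames
#' @param frames an `(H, W, T)` array, a single `(H, W)` matrix, or a list of
#'   equally-sized matrices, values in [-1, 1]
#' @export
VideoSequence <- function(frames) {
  if (is.list(frames)) frames <- simplify2array(frames)
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  new("VideoSequence", frames = frames)
}

#' @describeIn VideoSequence number of frames
#' @param x a VideoSequence
#' @export
nFrames <- function(x) dim(x@frames)[3]

#' @describeIn VideoSequence extract frame t as an `(H, W)` matrix
#' @param t frame index
#' @export
getFrame <- function(x, t) x@frames[, , t]

setMethod("dim", "VideoSequence", function(x) dim(x@frames))

setMethod("show", "VideoSequence", function(object) {
  d <- dim(object@frames)
  cat(sprintf("VideoSequence: %d frame(s) of %dx%d, range [%.3f, %.3f]\n",
              d[3], d[1], d[2], min(object@frames), max(object@frames)))
})

#' Bidirectional recurrent generator settings
#'
#' @slot nResBlocks residual blocks in the reconstruction module (default 10)
#' @slot featChannels propagated feature channels (default 128)
#' @slot downsampleStride stride of the 1x1 embedding convolution (1, 2 or 4)
#' @slot upChannels channels after pixel-shuffle, before the output conv
#' @slot flowBackend one of "builtin" (coarse-to-fine block correlation) or
#'   "zero" (identity alignment)
#' @slot residualSkip add the input frame to the output before the tanh
#' @slot zeroWarp replace warped propagated features by zeros (temporal
#'   ablation switch)
#' @slot projDim width of the contrastive projection head
#' @slot projHead whether a 2-layer projection head is applied to patches
#' @export
setClass("GeneratorConfig", representation(
  nResBlocks = "integer", featChannels = "integer", downsampleStride = "integer",
  upChannels = "integer", flowBackend = "character", residualSkip = "logical",
  zeroWarp = "logical", projDim = "integer", projHead = "logical"),
  prototype(nResBlocks = 10L, featChannels = 128L, downsampleStride = 2L,
            upChannels = 32L, flowBackend = "builtin", residualSkip = FALSE,
            zeroWarp = FALSE, projDim = 256L, projHead = TRUE))

setValidity("GeneratorConfig", function(object) {
  if (object@nResBlocks < 1L) return("nResBlocks must be >= 1")
  if (!object@downsampleStride %in% c(1L, 2L, 4L))
    return("downsampleStride must be 1, 2 or 4")
  if (!object@flowBackend %in% c("builtin", "zero"))
    return("flowBackend must be 'builtin' or 'zero'")
  TRUE
})

#' Construct a GeneratorConfig
#' @param nResBlocks,featChannels,downsampleStride,upChannels,flowBackend,residualSkip,zeroWarp,projDim,projHead
#'   see the class slots
#' @export
GeneratorConfig <- function(nResBlocks = 10L, featChannels = 128L,
                            downsampleStride = 2L, upChannels = 32L,
                            flowBackend = "builtin", residualSkip = FALSE,
                            zeroWarp = FALSE, projDim = 256L, projHead = TRUE) {
  new("GeneratorConfig", nResBlocks = as.integer(nResBlocks),
      featChannels = as.integer(featChannels),
      downsampleStride = as.integer(downsampleStride),
      upChannels = as.integer(upChannels), flowBackend = flowBackend,
      residualSkip = residualSkip, zeroWarp = zeroWarp,
      projDim = as.integer(projDim), projHead = projHead)
}

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf("GeneratorConfig: %d res blocks x %d channels, stride %d, flow '%s'%s\n",
              object@nResBlocks, object@featChannels, object@downsampleStride,
              object@flowBackend, if (object@zeroWarp) " [zero-warp]" else ""))
})

#' Adversarial training settings
#'
#' @slot lr Adam learning rate (linear decay to zero after `decayAfter`)
#' @slot decayAfter epoch after which the learning rate decays linearly
#' @slot epochs total training epochs
#' @slot batchSize sequences per step
#' @slot seqLen frames per training sequence
#' @slot beta1,beta2 Adam moment coefficients
#' @slot lambdaGAN,lambdaContr,lambdaPerc loss weights (adversarial,
#'   contrastive, perceptual); setting one to zero reproduces the
#'   corresponding loss-removal ablation
#' @slot nPatches contrastive patches sampled per layer
#' @slot tau contrastive temperature
#' @slot dFilters base channel count of the patch discriminator
#' @slot lossFramesPerSeq frames per sequence entering the losses each step
#'   (0 = all frames)
#' @slot percSeed seed of the fixed random perceptual backbone
#' @slot seed global training seed
#' @export
setClass("TrainConfig", representation(
  lr = "numeric", decayAfter = "integer", epochs = "integer",
  batchSize = "integer", seqLen = "integer", beta1 = "numeric", beta2 = "numeric",
  lambdaGAN = "numeric", lambdaContr = "numeric", lambdaPerc = "numeric",
  nPatches = "integer", tau = "numeric", dFilters = "integer",
  lossFramesPerSeq = "integer", percSeed = "integer", seed = "integer"),
  prototype(lr = 1e-4, decayAfter = 50L, epochs = 200L, batchSize = 8L,
            seqLen = 5L, beta1 = 0.5, beta2 = 0.999, lambdaGAN = 1,
            lambdaContr = 20, lambdaPerc = 1, nPatches = 256L, tau = 0.07,
            dFilters = 64L, lossFramesPerSeq = 0L, percSeed = 7L, seed = 1L))

setValidity("TrainConfig", function(object) {
  if (object@lr <= 0) return("lr must be positive")
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@tau <= 0) return("tau must be positive")
  if (any(c(object@lambdaGAN, object@lambdaContr, object@lambdaPerc) < 0))
    return("loss weights must be non-negative")
  TRUE
})

#' Construct a TrainConfig
#' @param lr,decayAfter,epochs,batchSize,seqLen,beta1,beta2 see the class slots
#' @param lambdaGAN,lambdaContr,lambdaPerc,nPatches,tau,dFilters see slots
#' @param lossFramesPerSeq,percSeed,seed see the class slots
#' @export
TrainConfig <- function(lr = 1e-4, decayAfter = 50L, epochs = 200L,
                        batchSize = 8L, seqLen = 5L, beta1 = 0.5, beta2 = 0.999,
                        lambdaGAN = 1, lambdaContr = 20, lambdaPerc = 1,
                        nPatches = 256L, tau = 0.07, dFilters = 64L,
                        lossFramesPerSeq = 0L, percSeed = 7L, seed = 1L) {
  new("TrainConfig", lr = lr, decayAfter = as.integer(decayAfter),
      epochs = as.integer(epochs), batchSize = as.integer(batchSize),
      seqLen = as.integer(seqLen), beta1 = beta1, beta2 = beta2,
      lambdaGAN = lambdaGAN, lambdaContr = lambdaContr, lambdaPerc = lambdaPerc,
      nPatches = as.integer(nPatches), tau = tau, dFilters = as.integer(dFilters),
      lossFramesPerSeq = as.integer(lossFramesPerSeq),
      percSeed = as.integer(percSeed), seed = as.integer(seed))
}

#' Unpaired video super-resolution model
#'
#' Bundles the recurrent generator, the patch discriminator, the fixed
#' perceptual backbone, the contrastive projection heads and the optimiser
#' state. Weights are held in environments so the optimiser updates in place.
#'
#' @slot generator list of generator weights and the [GeneratorConfig-class]
#' @slot discriminator list of discriminator weights
#' @slot percNet fixed random-weight perceptual feature network
#' @slot trainConfig the [TrainConfig-class] used to build it
#' @slot step training steps performed so far
#' @export
setClass("SRModel", representation(
  generator = "list", discriminator = "list", percNet = "list",
  trainConfig = "ANY", step = "integer"))

setMethod("show", "SRModel", function(object) {
  cfg <- object@generator$config
  np <- function(ps) sum(vapply(ps, function(p) length(p$v), numeric(1)))
  cat(sprintf("SRModel (step %d)\n", object@step))
  cat(sprintf("  generator: %d res blocks x %d ch, %s params\n",
              cfg@nResBlocks, cfg@featChannels,
              format(np(generator_params(object@generator)), big.mark = ",")))
  cat(sprintf("  discriminator: %s params\n",
              format(np(object@discriminator$params), big.mark = ",")))
})

#' No-reference quality report for a (real, generated) image-set pair
#'
#' Mirrors the evaluation table of the method: distribution distances (FID,
#' KID), absolute differences of mean global contrast factor and mean fast
#' noise estimate, k-NN manifold precision/recall and density/coverage, and
#' optional full-reference PSNR/SSIM when a clean reference exists.
#'
#' @slot fid,kid distribution distances (lower is better)
#' @slot absDeltaGCF,absDeltaFNE absolute differences of mean GCF / mean FNE
#' @slot precision,recall,density,coverage k-NN manifold metrics
#' @slot psnr,ssim full-reference metrics (NA without a reference set)
#' @slot meta list of backend, k, sample sizes and seed used
#' @export
setClass("MetricReport", representation(
  fid = "numeric", kid = "numeric", absDeltaGCF = "numeric",
  absDeltaFNE = "numeric", precision = "numeric", recall = "numeric",
  density = "numeric", coverage = "numeric", psnr = "numeric",
  ssim = "numeric", meta = "list"),
  prototype(psnr = NA_real_, ssim = NA_real_, meta = list()))

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport\n")
  cat(sprintf("  FID %.4f | KID %.5f | |dGCF| %.5f | |dFNE| %.5f\n",
              object@fid, object@kid, object@absDeltaGCF, object@absDeltaFNE))
  cat(sprintf("  P %.3f / R %.3f | D %.3f / C %.3f\n",
              object@precision, object@recall, object@density, object@coverage))
  if (!is.na(object@psnr))
    cat(sprintf("  PSNR %.2f dB | SSIM %.4f\n", object@psnr, object@ssim))
})

#' Convert a MetricReport to a one-row data.frame
#' @param report a [MetricReport-class]
#' @export
reportAsDataFrame <- function(report) {
  data.frame(fid = report@fid, kid = report@kid,
             abs_delta_gcf = report@absDeltaGCF, abs_delta_fne = report@absDeltaFNE,
             precision = report@precision, recall = report@recall,
             density = report@density, coverage = report@coverage,
             psnr = report@psnr, ssim = report@ssim)
}
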