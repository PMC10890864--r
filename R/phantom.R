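# Synthetic retina-phantom data: a clean, high-contrast layered cross-section
# (the pre-operative high-resolution domain) and its speckle-degraded,
# low-contrast, drifting video counterpart (the intra-operative
# low-resolution domain). The two domains are generated from disjoint seeds,
# so a built dataset is unpaired by construction.

default_layer_intensities <- function(n) {
  base <- c(0.70, 0.30, 0.55, 0.22, 0.90, 0.15)
  rep_len(base, n)
}

#' Simulate one clean high-resolution retina-phantom image
#'
#' Renders stacked horizontal reflectivity bands bounded by smooth curves (a
#' global retinal arc plus small per-boundary undulations), with soft
#' sub-pixel edges, dark vitreous above and a dim choroid-like region below.
#' Mild additive sensor noise (`spec@sensorNoiseSd` on the [0, 1] scale) is
#' applied before mapping to [-1, 1]. Deterministic given `(spec, seed)`.
#'
#' @param spec a [PhantomSpec-class]
#' @param seed integer seed controlling the geometry draw
#' @return an `(H, W)` matrix with values in [-1, 1]
#' @examples
#' img <- simulateRetinaPhantom(PhantomSpec(heightPx = 32L, widthPx = 32L), seed = 1)
#' @export
simulateRetinaPhantom <- function(spec, seed = spec@seed) {
  validObject(spec)
  H <- spec@heightPx; W <- spec@widthPx
  n <- spec@nLayers
  ints <- if (length(spec@layerIntensities)) rep_len(spec@layerIntensities, n)
          else default_layer_intensities(n)
  with_seed(seed, {
    xs <- seq(0, 1, length.out = W)
    # global retinal arc
    phase <- runif(1, 0, 2 * pi)
    freq <- runif(1, 0.4, 0.9)
    curv <- spec@layerCurvature * runif(1, 0.8, 1.2)
    tilt <- runif(1, -0.05, 0.05) * H
    arc <- curv * cos(2 * pi * freq * xs + phase) + tilt * (xs - 0.5)
    # band geometry: retina occupies the middle ~60% of the height
    top <- H * runif(1, 0.18, 0.28)
    depth <- H * runif(1, 0.5, 0.62)
    thick <- runif(n, 0.6, 1.4)
    thick <- thick / sum(thick) * depth
    bounds <- matrix(0, n + 1L, W)      # boundary curves, rows = boundaries
    acc <- top
    for (k in seq_len(n + 1L)) {
      wig <- runif(1, 0, 0.02 * H) *
        sin(2 * pi * runif(1, 1, 2.5) * xs + runif(1, 0, 2 * pi))
      bounds[k, ] <- acc + arc + wig
      if (k <= n) acc <- acc + thick[k]
    }
    ys <- seq_len(H)
    sig <- function(b) 1 / (1 + exp(-(outer(ys, b, "-")) / 0.5))  # H x W
    iTop <- 0.04; iBot <- 0.12
    S <- lapply(seq_len(n + 1L), function(k) sig(bounds[k, ]))
    img <- iTop * (1 - S[[1L]])
    for (k in seq_len(n)) img <- img + ints[k] * (S[[k]] - S[[k + 1L]])
    img <- img + iBot * S[[n + 1L]]
    if (spec@sensorNoiseSd > 0)
      img <- img + matrix(rnorm(H * W, sd = spec@sensorNoiseSd), H, W)
    clamp(img, 0, 1) * 2 - 1
  })
}

#' Degrade a clean phantom into a low-resolution video sequence
#'
#' Each of the T frames applies, in order: a sub-pixel rigid translation
#' drawn as a smooth random walk bounded by `motionAmplitudePx`; contrast
#' compression towards the image mean by `contrastScale`; Gaussian blur of
#' `blurSigmaPx`; and independent multiplicative unit-mean gamma speckle with
#' shape `speckleLooks` (applied on the linear [0, 1] intensity scale). The
#' clean reference sequence shares the geometry and motion but none of the
#' degradations; it exists solely for full-reference validation of synthetic
#' experiments and must never be used for training.
#'
#' @param hrClean `(H, W)` matrix in [-1, 1], as from [simulateRetinaPhantom()]
#' @param spec the [PhantomSpec-class] used to generate it
#' @param seed integer seed for motion and speckle draws
#' @return list with `lr` and `reference` ([VideoSequence-class]) and the
#'   drawn per-frame translations `shifts` (T x 2 matrix, columns dx, dy)
#' @export
simulateLRSequence <- function(hrClean, spec, seed = spec@seed) {
  validObject(spec)
  if (!all(dim(hrClean) == c(spec@heightPx, spec@widthPx)))
    stop("hrClean does not match the spec dimensions")
  T <- spec@framesPerSequence
  a <- spec@motionAmplitudePx
  clean01 <- (hrClean + 1) / 2
  with_seed(seed, {
    if (a > 0) {
      steps <- matrix(rnorm(2 * T, sd = a / 2), T, 2)
      steps[1, ] <- 0
      shifts <- apply(steps, 2, cumsum)
      shifts <- clamp(matrix(shifts, T, 2), -a, a)
    } else shifts <- matrix(0, T, 2)
    lr <- ref <- array(0, dim = c(spec@heightPx, spec@widthPx, T))
    for (t in seq_len(T)) {
      fr <- if (a > 0) translate_bilinear(clean01, shifts[t, 1], shifts[t, 2])
            else clean01
      ref[, , t] <- fr
      g <- fr
      if (spec@contrastScale < 1)
        g <- mean(g) + (g - mean(g)) * spec@contrastScale
      if (spec@blurSigmaPx > 0)
        g <- gaussian_blur(g, spec@blurSigmaPx)
      if (is.finite(spec@speckleLooks)) {
        L <- spec@speckleLooks
        g <- g * matrix(rgamma(length(g), shape = L, rate = L), nrow(g))
      }
      lr[, , t] <- g
    }
    list(lr = VideoSequence(clamp(lr, 0, 1) * 2 - 1),
         reference = VideoSequence(clamp(ref, 0, 1) * 2 - 1),
         shifts = shifts)
  })
}

#' Gaussian blur of a 2-D image (EBImage backend)
#' @keywords internal
gaussian_blur <- function(m, sigma) {
  as.matrix(EBImage::gblur(EBImage::Image(m), sigma = sigma))
}

#' Build an unpaired phantom dataset on disk
#'
#' Writes `nLR` low-resolution sequences (`lr/seq_xxx/frame_xxx.tif`), their
#' hidden clean references (`reference/seq_xxx/...`) and `nHR` clean
#' high-resolution images (`hr/img_xxx.tif`), all 16-bit grayscale TIFF,
#' plus a JSON manifest. Low- and high-resolution items are generated from
#' disjoint phantom seeds (even/odd offsets of `seed`), so no sequence shares
#' geometry with any high-resolution image: the dataset is unpaired by
#' construction.
#'
#' @param spec a [PhantomSpec-class]
#' @param nLR,nHR number of sequences / images (>= 1)
#' @param outDir output directory (created if missing)
#' @param seed base seed; item seeds are derived deterministically
#' @param split label recorded for every item ("train", "val" or "test")
#' @return the manifest, invisibly (a list with one entry per item)
#' @export
buildPhantomDataset <- function(spec, nLR, nHR, outDir, seed = 1L,
                                split = "train") {
  if (nLR < 1L || nHR < 1L) stop("nLR and nHR must be >= 1")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("lr", "hr", "reference"))
    dir.create(file.path(outDir, d), recursive = TRUE, showWarnings = FALSE)
  items <- list()
  for (i in seq_len(nLR)) {
    si <- seed + 2L * i                       # even offsets: LR geometry
    id <- fmt_id("seq", i)
    hr <- simulateRetinaPhantom(spec, seed = si)
    seqs <- simulateLRSequence(hr, spec, seed = si + 100003L)
    saveSequence(seqs$lr, file.path(outDir, "lr", id))
    saveSequence(seqs$reference, file.path(outDir, "reference", id))
    items[[length(items) + 1L]] <- list(
      id = id, role = "lr_sequence", path = file.path("lr", id),
      n_frames = nFrames(seqs$lr), seed = si, split = split)
    items[[length(items) + 1L]] <- list(
      id = paste0(id, "_ref"), role = "reference", path = file.path("reference", id),
      n_frames = nFrames(seqs$reference), seed = si, split = split)
  }
  for (i in seq_len(nHR)) {
    si <- seed + 2L * i + 1L                  # odd offsets: HR geometry
    id <- fmt_id("img", i)
    hr <- simulateRetinaPhantom(spec, seed = si)
    p <- file.path(outDir, "hr", paste0(id, ".tif"))
    writeFrameImage(hr, p)
    items[[length(items) + 1L]] <- list(
      id = id, role = "hr_image", path = file.path("hr", paste0(id, ".tif")),
      n_frames = 1L, seed = si, split = split)
  }
  manifest <- list(spec = phantom_spec_as_list(spec), seed = seed, items = items)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

phantom_spec_as_list <- function(spec) {
  list(heightPx = spec@heightPx, widthPx = spec@widthPx, nLayers = spec@nLayers,
       layerCurvature = spec@layerCurvature,
       layerIntensities = spec@layerIntensities,
       speckleLooks = spec@speckleLooks, contrastScale = spec@contrastScale,
       motionAmplitudePx = spec@motionAmplitudePx,
       framesPerSequence = spec@framesPerSequence,
       blurSigmaPx = spec@blurSigmaPx, sensorNoiseSd = spec@sensorNoiseSd,
       seed = spec@seed)
}

phantom_spec_from_list <- function(x) {
  do.call(PhantomSpec, x[intersect(names(x), names(formals(PhantomSpec)))])
}
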