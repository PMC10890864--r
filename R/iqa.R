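# No-reference image-quality suite: global contrast factor (GCF), fast
# noise estimation (FNE), Frechet and kernel distances between embedded
# image sets, k-NN manifold precision/recall and density/coverage, plus
# full-reference PSNR/SSIM for synthetic experiments where a clean
# reference exists.

#' Global contrast factor of a grayscale image
#'
#' Multi-resolution contrast measure: pixels are mapped from [-1, 1] to
#' 0..255 and to perceptual luminance `l = (k/255)^2.2`; the local contrast
#' at one resolution is the mean over pixels of the average absolute
#' luminance difference to the 4-neighbours; resolutions are obtained by
#' block-averaging the 0..255 image by factors 1, 2, 4, ..., 256 (levels
#' smaller than one pixel are skipped) and combined as
#' `GCF = sum_i w_i C_i` with `w_i = (-0.406385 i/9 + 0.334573) i/9 +
#' 0.0877526`.
#'
#' @param image `(H, W)` matrix in [-1, 1]
#' @return non-negative scalar; exactly 0 for a constant image
#' @export
gcf <- function(image) {
  if (!length(image)) stop("empty image")
  k <- (image + 1) / 2 * 255
  total <- 0
  for (i in 1:9) {
    f <- 2^(i - 1L)
    Hf <- nrow(k) %/% f; Wf <- ncol(k) %/% f
    if (Hf < 1L || Wf < 1L) next
    ki <- if (f == 1L) k else {
      kk <- k[seq_len(Hf * f), seq_len(Wf * f), drop = FALSE]
      dim(kk) <- c(f, Hf, f, Wf)
      apply(kk, c(2, 4), mean)
    }
    l <- (ki / 255)^2.2
    Ci <- local_contrast(l)
    wi <- (-0.406385 * i / 9 + 0.334573) * i / 9 + 0.0877526
    total <- total + wi * Ci
  }
  total
}

local_contrast <- function(l) {
  H <- nrow(l); W <- ncol(l)
  if (H < 2L && W < 2L) return(0)
  s <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  if (H > 1L) {
    d <- abs(l[-1, , drop = FALSE] - l[-H, , drop = FALSE])
    s[-H, ] <- s[-H, ] + d; cnt[-H, ] <- cnt[-H, ] + 1
    s[-1, ] <- s[-1, ] + d; cnt[-1, ] <- cnt[-1, ] + 1
  }
  if (W > 1L) {
    d <- abs(l[, -1, drop = FALSE] - l[, -W, drop = FALSE])
    s[, -W] <- s[, -W] + d; cnt[, -W] <- cnt[, -W] + 1
    s[, -1] <- s[, -1] + d; cnt[, -1] <- cnt[, -1] + 1
  }
  mean(s / pmax(cnt, 1))
}

#' Fast noise estimate of a grayscale image
#'
#' Laplacian-difference noise estimator: the image is convolved with
#' `M = [[1,-2,1],[-2,4,-2],[1,-2,1]]` and the noise standard deviation is
#' `sqrt(pi/2) * sum|I * M| / (6 (W-2) (H-2))`, summed over interior pixels.
#' Exactly zero for constant and affine-ramp images. The estimate is on the
#' scale of the input values.
#'
#' @param image `(H, W)` matrix, at least 3x3
#' @export
fne <- function(image) {
  H <- nrow(image); W <- ncol(image)
  if (H < 3L || W < 3L) stop("image must be at least 3x3")
  M <- matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3)
  x <- image
  dim(x) <- c(H, W, 1L)
  r <- ad_conv2d(x, matrix(as.vector(M), 9L, 1L), kh = 3L, kw = 3L,
                 stride = 1L, pad = 0L)
  sqrt(pi / 2) * sum(abs(r)) / (6 * (W - 2) * (H - 2))
}

# ---------------------------------------------------------------------------
# embeddings and set-level metrics

#' Embed a set of images into a fixed feature space
#'
#' Images are resized to `size` x `size` and passed through a frozen
#' random-weight convolutional network (seed recorded); features are the
#' per-channel spatial means and standard deviations of the last two stages.
#' Deterministic given (backend, seed).
#'
#' @param images list of `(H, W)` matrices in [-1, 1]
#' @param backend currently "random" (self-contained offline default)
#' @param seed weight seed of the embedding network
#' @param size input resolution of the embedding network
#' @return n x d feature matrix, one row per image
#' @export
embedImages <- function(images, backend = "random", seed = 11L, size = 64L) {
  n <- length(images)
  if (n < 1L) stop("empty image set")
  backend <- match.arg(backend, "random")
  net <- newPercNet(seed = seed, channels = c(12L, 24L, 48L))
  rows <- lapply(images, function(m) {
    if (!all(dim(m) == c(size, size)))
      m <- as.matrix(EBImage::resize(EBImage::Image(m), w = size, h = size))
    a <- m; dim(a) <- c(dim(m), 1L)
    fs <- perc_features(net, a)
    unlist(lapply(fs[2:3], function(f) {
      v <- vof(f)
      dim(v) <- c(prod(dim(v)[1:2]), dim(v)[3])
      c(colMeans(v), apply(v, 2, stats::sd))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(images)
  attr(out, "backend") <- backend
  attr(out, "seed") <- seed
  out
}

#' Frechet distance between Gaussian fits of two feature sets
#'
#' `||mu_r - mu_g||^2 + Tr(S_r + S_g - 2 (S_r S_g)^{1/2})`, with a symmetric
#' matrix square root and negative eigenvalues clipped to zero; degenerate
#' covariances are regularised by `1e-6 I` with a warning.
#'
#' @param realFeats,genFeats n x d feature matrices (n >= 2)
#' @export
fid <- function(realFeats, genFeats) {
  stopifnot(nrow(realFeats) >= 2L, nrow(genFeats) >= 2L)
  mu1 <- colMeans(realFeats); mu2 <- colMeans(genFeats)
  S1 <- stats::cov(realFeats); S2 <- stats::cov(genFeats)
  if (rcond_safe(S1) < 1e-12 || rcond_safe(S2) < 1e-12) {
    warning("degenerate covariance; regularising with 1e-6 I")
    S1 <- S1 + diag(1e-6, ncol(S1))
    S2 <- S2 + diag(1e-6, ncol(S2))
  }
  e1 <- eigen(S1, symmetric = TRUE)
  sq1 <- e1$vectors %*% (sqrt(pmax(e1$values, 0)) * t(e1$vectors))
  M <- sq1 %*% S2 %*% sq1
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  trsqrt <- sum(sqrt(pmax(ev, 0)))
  sum((mu1 - mu2)^2) + sum(diag(S1)) + sum(diag(S2)) - 2 * trsqrt
}

rcond_safe <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

poly_kernel <- function(A, B) (tcrossprod(A, B) / ncol(A) + 1)^3

#' Kernel distance (unbiased MMD^2, polynomial kernel) between feature sets
#'
#' Kernel `k(a, b) = (a.b / d + 1)^3`; the unbiased squared maximum mean
#' discrepancy is averaged over `nSubsets` random subsets of `subsetSize`
#' rows from each set.
#'
#' @param realFeats,genFeats n x d feature matrices
#' @param subsetSize rows per subset (>= 2; capped at the set sizes)
#' @param nSubsets number of random subsets
#' @param seed subset-sampling seed
#' @export
kid <- function(realFeats, genFeats, subsetSize = 100L, nSubsets = 10L,
                seed = 1L) {
  m <- min(subsetSize, nrow(realFeats), nrow(genFeats))
  if (m < 2L) stop("subsetSize must be at least 2")
  with_seed(seed, {
    vals <- vapply(seq_len(nSubsets), function(s) {
      X <- realFeats[sample.int(nrow(realFeats), m), , drop = FALSE]
      Y <- genFeats[sample.int(nrow(genFeats), m), , drop = FALSE]
      mmd2_unbiased(X, Y)
    }, numeric(1))
    mean(vals)
  })
}

mmd2_unbiased <- function(X, Y) {
  m <- nrow(X); n <- nrow(Y)
  Kxx <- poly_kernel(X, X); Kyy <- poly_kernel(Y, Y); Kxy <- poly_kernel(X, Y)
  (sum(Kxx) - sum(diag(Kxx))) / (m * (m - 1)) +
    (sum(Kyy) - sum(diag(Kyy))) / (n * (n - 1)) -
    2 * mean(Kxy)
}

pdist2 <- function(A, B) {
  an <- rowSums(A * A); bn <- rowSums(B * B)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

knn_radii <- function(X, k) {
  D <- pdist2(X, X)
  diag(D) <- Inf
  apply(D, 1, function(r) sort(r)[k])
}

#' k-NN manifold precision and recall of a generated set
#'
#' Precision: fraction of generated points inside the union of k-NN balls
#' of the real points; recall: fraction of real points inside the union of
#' k-NN balls of the generated points.
#'
#' @param realFeats,genFeats n x d feature matrices (n >= k + 1)
#' @param k neighbourhood size (default 3)
#' @return named vector `c(precision, recall)`
#' @export
precisionRecall <- function(realFeats, genFeats, k = 3L) {
  if (k >= nrow(realFeats) || k >= nrow(genFeats))
    stop("k must be smaller than both set sizes")
  rr <- knn_radii(realFeats, k)
  rg <- knn_radii(genFeats, k)
  Dgr <- pdist2(genFeats, realFeats)
  prec <- mean(apply(Dgr <= rep(rr, each = nrow(genFeats)), 1, any))
  Drg <- t(Dgr)
  rec <- mean(apply(Drg <= rep(rg, each = nrow(realFeats)), 1, any))
  c(precision = prec, recall = rec)
}

#' k-NN manifold density and coverage of a generated set
#'
#' Density counts, per generated point, how many real k-NN balls contain it
#' (normalised by k); coverage is the fraction of real points whose k-NN
#' ball contains at least one generated point.
#'
#' @param realFeats,genFeats n x d feature matrices (n >= k + 1)
#' @param k neighbourhood size (default 5)
#' @return named vector `c(density, coverage)`
#' @export
densityCoverage <- function(realFeats, genFeats, k = 5L) {
  if (k >= nrow(realFeats)) stop("k must be smaller than the real set size")
  rr <- knn_radii(realFeats, k)
  Dgr <- pdist2(genFeats, realFeats)       # gen x real
  inside <- Dgr <= rep(rr, each = nrow(genFeats))
  dens <- sum(inside) / (k * nrow(genFeats))
  cov <- mean(apply(inside, 2, any))
  c(density = dens, coverage = cov)
}

# ---------------------------------------------------------------------------
# full-reference metrics (synthetic validation only)

#' Peak signal-to-noise ratio between two [-1, 1] frames
#' @param x,y `(H, W)` matrices; `dataRange` defaults to 2 (the [-1,1] span)
#' @export
psnr <- function(x, y, dataRange = 2) {
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(dataRange^2 / mse)
}

#' Structural similarity (SSIM) between two [-1, 1] frames
#'
#' Standard single-scale SSIM with an 11x11 Gaussian window (sigma 1.5),
#' stability constants (0.01 L)^2 and (0.03 L)^2, averaged over the valid
#' (un-padded) region.
#'
#' @param x,y `(H, W)` matrices in [-1, 1]
#' @export
ssim <- function(x, y) {
  stopifnot(all(dim(x) == dim(y)))
  L <- 2
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  g <- outer(stats::dnorm(-5:5, sd = 1.5), stats::dnorm(-5:5, sd = 1.5))
  g <- g / sum(g)
  kmat <- matrix(as.vector(g), 121L, 1L)
  win <- function(m) {
    a <- m; dim(a) <- c(dim(m), 1L)
    r <- ad_conv2d(a, kmat, kh = 11L, kw = 11L, stride = 1L, pad = 0L)
    r[, , 1]
  }
  mx <- win(x); my <- win(y)
  sxx <- win(x * x) - mx * mx
  syy <- win(y * y) - my * my
  sxy <- win(x * y) - mx * my
  s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(s)
}

# ---------------------------------------------------------------------------
# directory-level evaluation

#' Full no-reference evaluation of a generated set against a real set
#'
#' Computes FID, KID, |dGCF| and |dFNE| (absolute differences of the mean
#' global contrast factor and mean noise estimate between the generated and
#' real sets), precision/recall and density/coverage, and - when a clean
#' reference directory is supplied - mean PSNR/SSIM of generated frames
#' against their references (matched by relative path order).
#'
#' @param realDir directory of real high-resolution images
#' @param genDir directory of generated frames (searched recursively)
#' @param referenceDir optional directory of clean reference frames
#' @param kPR,kDC neighbourhood sizes for the manifold metrics
#' @param embedSeed seed of the embedding backend
#' @param kidSubset,kidSubsets KID subset size / count
#' @param out optional path stem; writes `<out>.json` and `<out>.csv`
#' @return a [MetricReport-class]
#' @export
evaluateSets <- function(realDir, genDir, referenceDir = NULL, kPR = 3L,
                         kDC = 5L, embedSeed = 11L, kidSubset = 100L,
                         kidSubsets = 10L, out = NULL) {
  real <- loadImageSet(realDir)
  gen <- loadImageSet(genDir)
  report <- evaluateImageSets(real, gen,
    reference = if (!is.null(referenceDir)) loadImageSet(referenceDir),
    kPR = kPR, kDC = kDC, embedSeed = embedSeed,
    kidSubset = kidSubset, kidSubsets = kidSubsets)
  if (!is.null(out)) {
    df <- reportAsDataFrame(report)
    jsonlite::write_json(c(as.list(df), report@meta), paste0(out, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(data.frame(metric = names(df), value = unlist(df)),
                     paste0(out, ".csv"), row.names = FALSE)
  }
  report
}

#' Evaluate in-memory image sets (list-of-matrices interface)
#' @param real,gen,reference lists of `(H, W)` matrices in [-1, 1]
#' @param kPR,kDC,embedSeed,kidSubset,kidSubsets as in [evaluateSets()]
#' @export
evaluateImageSets <- function(real, gen, reference = NULL, kPR = 3L, kDC = 5L,
                              embedSeed = 11L, kidSubset = 100L,
                              kidSubsets = 10L) {
  fr <- embedImages(real, seed = embedSeed)
  fg <- embedImages(gen, seed = embedSeed)
  # small sets: clamp the neighbourhood sizes (recorded in the metadata)
  kPR <- min(kPR, length(real) - 1L, length(gen) - 1L)
  kDC <- min(kDC, length(real) - 1L)
  pr <- precisionRecall(fr, fg, k = kPR)
  dc <- densityCoverage(fr, fg, k = kDC)
  gcfR <- mean(vapply(real, gcf, numeric(1)))
  gcfG <- mean(vapply(gen, gcf, numeric(1)))
  fneR <- mean(vapply(real, fne, numeric(1)))
  fneG <- mean(vapply(gen, fne, numeric(1)))
  ps <- ss <- NA_real_
  if (!is.null(reference)) {
    if (length(reference) != length(gen))
      stop("generated and reference sets differ in size")
    ps <- mean(mapply(psnr, gen, reference))
    ss <- mean(mapply(ssim, gen, reference))
  }
  new("MetricReport",
      fid = fid(fr, fg),
      kid = kid(fr, fg, subsetSize = kidSubset, nSubsets = kidSubsets),
      absDeltaGCF = abs(gcfG - gcfR), absDeltaFNE = abs(fneG - fneR),
      precision = unname(pr["precision"]), recall = unname(pr["recall"]),
      density = unname(dc["density"]), coverage = unname(dc["coverage"]),
      psnr = ps, ssim = ss,
      meta = list(backend = "random", embed_seed = embedSeed,
                  n_real = length(real), n_gen = length(gen),
                  k_pr = kPR, k_dc = kDC, kid_subset = kidSubset,
                  kid_subsets = kidSubsets))
}
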