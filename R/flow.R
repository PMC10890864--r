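# Optical flow between adjacent frames. The default backend is a
# self-contained coarse-to-fine block-correlation estimator (3-level image
# pyramid, exhaustive integer search with parabolic sub-pixel refinement),
# so the package runs fully offline; a "zero" backend disables alignment.

#' Estimate per-pixel optical flow between two frames
#'
#' Returns the displacement field mapping `xAdj` towards `xT`: warping
#' `xAdj` by the returned flow approximately reproduces `xT`.
#'
#' @param xT,xAdj `(H, W)` matrices in [-1, 1]
#' @param backend "builtin" (pyramidal block correlation) or "zero"
#' @param nLevels pyramid levels (builtin backend)
#' @param radius integer search radius per level
#' @param blockSize block size in pixels at each level
#' @return `(H, W, 2)` array of (dx, dy) displacements in pixels
#' @export
estimateFlow <- function(xT, xAdj, backend = c("builtin", "zero"),
                         nLevels = 3L, radius = 3L, blockSize = 8L) {
  backend <- match.arg(backend)
  if (!all(dim(xT) == dim(xAdj))) stop("frames must share dimensions")
  d <- dim(xT)
  if (backend == "zero") return(array(0, dim = c(d, 2L)))
  flow_pyramidal(xT, xAdj, nLevels, radius, blockSize)
}

flow_pyramidal <- function(f1, f2, nLevels, radius, blockSize) {
  p1 <- list(f1); p2 <- list(f2)
  for (l in seq_len(nLevels - 1L)) {
    if (min(dim(p1[[l]])) < 2L * blockSize) break
    p1[[l + 1L]] <- avgpool2(p1[[l]], 2L)[, , 1]
    p2[[l + 1L]] <- avgpool2(p2[[l]], 2L)[, , 1]
  }
  L <- length(p1)
  fl <- NULL
  for (l in L:1) {
    a <- p1[[l]]; b <- p2[[l]]
    d <- dim(a)
    if (is.null(fl)) {
      fl <- array(0, dim = c(d, 2L))
    } else {
      fl <- upsample_flow(fl, d)
    }
    bw <- warp_plain(b, fl)
    res <- block_match(a, bw, radius, blockSize)
    fl <- fl + res
    fl <- smooth_flow(fl)
  }
  fl
}

warp_plain <- function(m, fl) {
  a <- m; dim(a) <- c(dim(m), 1L)
  out <- ad_warp(a, fl)
  dim(out) <- dim(m)
  out
}

upsample_flow <- function(fl, dout) {
  d <- dim(fl)
  out <- array(0, dim = c(dout, 2L))
  for (k in 1:2) {
    up <- kronecker(fl[, , k], matrix(1, 2, 2)) * 2
    out[, , k] <- up[clamp(seq_len(dout[1]), 1, nrow(up)),
                     clamp(seq_len(dout[2]), 1, ncol(up))]
  }
  out
}

block_sums <- function(m, rb, cb) {
  t(rowsum(t(rowsum(m, rb, reorder = TRUE)), cb, reorder = TRUE))
}

block_match <- function(a, b, radius, blockSize) {
  d <- dim(a)
  H <- d[1]; W <- d[2]
  B <- min(blockSize, H, W)
  rb <- pmin((seq_len(H) - 1L) %/% B + 1L, max(1L, H %/% B))
  cb <- pmin((seq_len(W) - 1L) %/% B + 1L, max(1L, W %/% B))
  nbr <- max(rb); nbc <- max(cb)
  cand <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  ssd <- matrix(0, nbr * nbc, nrow(cand))
  rows <- seq_len(H); cols <- seq_len(W)
  for (ci in seq_len(nrow(cand))) {
    rr <- clamp(rows + cand$dy[ci], 1L, H)
    cc <- clamp(cols + cand$dx[ci], 1L, W)
    dif <- a - b[rr, cc]
    ssd[, ci] <- as.vector(block_sums(dif * dif, rb, cb))
  }
  best <- max.col(-ssd, ties.method = "first")
  n <- 2L * radius + 1L
  bx <- cand$dx[best]; by <- cand$dy[best]
  # parabolic sub-pixel refinement along each axis where the neighbours exist
  ref <- function(delta, stride) {
    lin <- seq_len(nbr * nbc)
    ok <- abs(delta) < radius
    idx0 <- best
    dm <- ssd[cbind(lin, pmax(idx0 - stride, 1L))]
    dp <- ssd[cbind(lin, pmin(idx0 + stride, ncol(ssd)))]
    d0 <- ssd[cbind(lin, idx0)]
    den <- dm - 2 * d0 + dp
    # an (almost) exact block match needs no sub-pixel refinement; the
    # parabola through a zero-SSD minimum is noise-driven
    o <- ifelse(ok & den > 1e-12 & d0 > 1e-10, 0.5 * (dm - dp) / den, 0)
    clamp(o, -0.5, 0.5)
  }
  bx <- bx + ref(cand$dx[best], 1L)
  by <- by + ref(cand$dy[best], n)
  out <- array(0, dim = c(H, W, 2L))
  bxm <- matrix(bx, nbr, nbc); bym <- matrix(by, nbr, nbc)
  out[, , 1] <- bxm[rb, cb]
  out[, , 2] <- bym[rb, cb]
  out
}

smooth_flow <- function(fl) {
  d <- dim(fl)
  k <- matrix(1 / 9, 9, 1)
  ones <- array(1, dim = c(d[1], d[2], 1L))
  norm <- ad_conv2d(ones, k, kh = 3L, kw = 3L, stride = 1L, pad = 1L)
  for (i in 1:2) {
    x <- fl[, , i, drop = FALSE]
    sm <- ad_conv2d(x, k, kh = 3L, kw = 3L, stride = 1L, pad = 1L)
    fl[, , i] <- sm[, , 1] / norm[, , 1]
  }
  fl
}

#' Average-pool a full-resolution flow field to feature resolution
#'
#' Displacements are divided by the stride so they are expressed in feature
#' pixels.
#' @keywords internal
pool_flow <- function(fl, stride) {
  if (stride == 1L) return(fl)
  avgpool2(fl, stride) / stride
}
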