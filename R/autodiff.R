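# Reverse-mode automatic differentiation over dense R arrays.
#
# The training losses backpropagate through convolutions, instance
# normalisation, bilinear warping and the contrastive objective; no installed
# R package provides a differentiable tensor engine, so the package carries a
# small tape-based one. Nodes are environments holding a value `v`, an
# accumulated gradient `g`, the parent nodes `pa` and a pullback `bk` that
# maps the node's gradient to per-parent gradients. Operations record onto a
# tape only while one is active, so inference pays no bookkeeping cost beyond
# node allocation.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL
.ad$k <- 0L

# The tape is an environment used as an O(1) hash of creation-order keys:
# in-place assignment, no list copy-on-write.
#' @keywords internal
ad_tape_start <- function() {
  .ad$tape <- new.env(parent = emptyenv())
  .ad$k <- 0L
  invisible(NULL)
}

#' @keywords internal
ad_tape_stop <- function() {
  .ad$tape <- NULL
  .ad$k <- 0L
  invisible(NULL)
}

ad_record <- function(n) {
  if (!is.null(.ad$tape)) {
    k <- .ad$k + 1L
    assign(as.character(k), n, envir = .ad$tape)
    .ad$k <- k
  }
  n
}

ad_node <- function(v, parents = NULL, backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  n$pa <- parents
  n$bk <- backfn
  class(n) <- "ad"
  ad_record(n)
}

#' Create a trainable parameter (autodiff leaf)
#' @param v numeric array with the initial value
#' @keywords internal
ad_param <- function(v) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  n$pa <- NULL
  n$bk <- NULL
  class(n) <- c("ad_param", "ad")
  n
}

is_ad <- function(x) inherits(x, "ad")

# user-facing results: plain value unless a tape is recording
maybe_val <- function(x) if (is.null(.ad$tape)) vof(x) else x

# value of a node or plain array
vof <- function(x) if (is_ad(x)) x$v else x

acc <- function(p, g) {
  if (is.null(p) || !is_ad(p)) return(invisible(NULL))
  p$g <- if (is.null(p$g)) g else p$g + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node through the active tape
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(is_ad(loss), !is.null(.ad$tape))
  loss$g <- array(1, dim = if (is.null(dim(loss$v))) length(loss$v) else dim(loss$v))
  for (i in rev(seq_len(.ad$k))) {
    n <- get(as.character(i), envir = .ad$tape)
    if (is.null(n$g) || is.null(n$bk)) next
    gs <- n$bk(n$g)
    for (j in seq_along(n$pa)) {
      gj <- gs[[j]]
      if (!is.null(gj)) acc(n$pa[[j]], gj)
    }
    n$g <- NULL   # release memory as we walk back
    n$bk <- NULL  # each pullback fires once per tape
    n$pa <- NULL
  }
  invisible(NULL)
}

#' Zero the gradients of a flat list of parameters
#' @keywords internal
ad_zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# convolution plans: cached gather indices for im2col / col2im

.conv_cache <- new.env(parent = emptyenv())

conv_plan <- function(H, W, kh, kw, stride, pad) {
  key <- paste(H, W, kh, kw, stride, pad, sep = "_")
  pl <- .conv_cache[[key]]
  if (!is.null(pl)) return(pl)
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  stopifnot(Ho >= 1L, Wo >= 1L)
  io <- rep(seq_len(Ho), times = Wo)
  jo <- rep(seq_len(Wo), each = Ho)
  di <- rep(0:(kh - 1L), times = kw)
  dj <- rep(0:(kw - 1L), each = kh)
  r <- outer((io - 1L) * stride + 1L, di, "+")
  cc <- outer((jo - 1L) * stride + 1L, dj, "+")
  idx <- r + (cc - 1L) * Hp
  idxvec <- as.vector(idx)
  uidx <- sort(unique(idxvec))
  pl <- list(H = H, W = W, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo,
             kh = kh, kw = kw, stride = stride, pad = pad,
             idxvec = idxvec, uidx = uidx)
  .conv_cache[[key]] <- pl
  pl
}

pad_hw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

im2col <- function(x, pl) {
  # x: (H, W, C) -> matrix (Ho*Wo) x (kh*kw*C); column order: offset fastest
  C <- dim(x)[3]
  xp <- pad_hw(x, pl$pad)
  dim(xp) <- c(pl$Hp * pl$Wp, C)
  im2col_cpp(xp, pl$idxvec, pl$Ho * pl$Wo, pl$kh * pl$kw)
}

col2im_grad <- function(gcols, pl, C) {
  # gcols: (Ho*Wo) x (kh*kw*C) -> gradient w.r.t. unpadded x: (H, W, C)
  gfull <- col2im_cpp(gcols, pl$idxvec, pl$Hp * pl$Wp, pl$Ho * pl$Wo,
                      pl$kh * pl$kw)
  dim(gfull) <- c(pl$Hp, pl$Wp, C)
  if (pl$pad > 0L)
    gfull <- gfull[pl$pad + seq_len(pl$H), pl$pad + seq_len(pl$W), , drop = FALSE]
  gfull
}

#' 2-D convolution with optional fused activation (autodiff op)
#'
#' @param x input, `(H, W, Cin)` array or node
#' @param W weight matrix `(kh*kw*Cin) x Cout`, kernel-offset index fastest
#' @param b bias vector length `Cout` (or NULL)
#' @param kh,kw kernel size; `stride` and `pad` as usual
#' @param act fused activation: "none", "relu" or "lrelu" (slope 0.2)
#' @keywords internal
ad_conv2d <- function(x, W, b = NULL, kh = 3L, kw = 3L, stride = 1L, pad = 1L,
                      act = "none") {
  xv <- vof(x); Wv <- vof(W)
  d <- dim(xv)
  pl <- conv_plan(d[1], d[2], kh, kw, stride, pad)
  C <- d[3]
  Cout <- ncol(Wv)
  cols <- im2col(xv, pl)
  out <- cols %*% Wv
  if (!is.null(b)) out <- out + rep(vof(b), each = pl$Ho * pl$Wo)
  am <- NULL
  if (act == "relu") { am <- out > 0; out <- out * am }
  else if (act == "lrelu") { am <- 0.2 + 0.8 * (out > 0); out <- out * am }
  dim(out) <- c(pl$Ho, pl$Wo, Cout)
  if (!is_ad(x) && !is_ad(W) && !is_ad(b)) return(out)
  ad_node(out, parents = list(x, W, b), backfn = function(g) {
    dim(g) <- c(pl$Ho * pl$Wo, Cout)
    if (!is.null(am)) g <- g * am
    gx <- gW <- gb <- NULL
    if (is_ad(W)) gW <- crossprod(cols, g)
    if (is_ad(b)) gb <- colSums(g)
    if (is_ad(x)) {
      gcols <- g %*% t(Wv)
      gx <- col2im_grad(gcols, pl, C)
    }
    list(gx, gW, gb)
  })
}

#' Fused convolution + instance normalisation + optional activation
#'
#' One tape node for the common conv-IN-activation motif: convolution
#' (no bias; instance normalisation cancels it), per-channel spatial
#' normalisation with affine (gamma, beta), then "none", "relu" or "lrelu".
#' @keywords internal
ad_conv_in <- function(x, W, gamma, beta, kh = 3L, kw = 3L, stride = 1L,
                       pad = 1L, act = "none", eps = 1e-5) {
  xv <- vof(x); Wv <- vof(W)
  d <- dim(xv)
  pl <- conv_plan(d[1], d[2], kh, kw, stride, pad)
  C <- d[3]
  Cout <- ncol(Wv)
  N <- pl$Ho * pl$Wo
  cols <- im2col(xv, pl)
  z <- cols %*% Wv
  mu <- colMeans(z)
  zc <- z - rep(mu, each = N)
  istd <- 1 / sqrt(colSums(zc * zc) / N + eps)
  xhat <- zc * rep(istd, each = N)
  gv <- vof(gamma); bv <- vof(beta)
  y <- xhat * rep(gv, each = N) + rep(bv, each = N)
  am <- NULL
  if (act == "relu") { am <- y > 0; y <- y * am }
  else if (act == "lrelu") { am <- 0.2 + 0.8 * (y > 0); y <- y * am }
  dim(y) <- c(pl$Ho, pl$Wo, Cout)
  if (!is_ad(x) && !is_ad(W) && !is_ad(gamma) && !is_ad(beta)) return(y)
  ad_node(y, parents = list(x, W, gamma, beta), backfn = function(g) {
    dim(g) <- c(N, Cout)
    if (!is.null(am)) g <- g * am
    gg <- if (is_ad(gamma)) colSums(g * xhat)
    gb <- if (is_ad(beta)) colSums(g)
    dxhat <- g * rep(gv, each = N)
    s1 <- colMeans(dxhat)
    s2 <- colMeans(dxhat * xhat)
    dz <- (dxhat - rep(s1, each = N) - xhat * rep(s2, each = N)) *
      rep(istd, each = N)
    gW <- if (is_ad(W)) crossprod(cols, dz)
    gx <- NULL
    if (is_ad(x)) {
      gcols <- dz %*% t(Wv)
      gx <- col2im_grad(gcols, pl, C)
    }
    list(gx, gW, gg, gb)
  })
}

#' Fully-connected layer (autodiff op); X is n x d
#' @keywords internal
ad_linear <- function(X, W, b = NULL) {
  Xv <- vof(X); Wv <- vof(W)
  out <- Xv %*% Wv
  if (!is.null(b)) out <- out + rep(vof(b), each = nrow(Xv))
  if (!is_ad(X) && !is_ad(W) && !is_ad(b)) return(out)
  ad_node(out, parents = list(X, W, b), backfn = function(g) {
    list(if (is_ad(X)) g %*% t(Wv) else NULL,
         if (is_ad(W)) crossprod(Xv, g) else NULL,
         if (is_ad(b)) colSums(g) else NULL)
  })
}

ad_relu <- function(x) {
  xv <- vof(x)
  out <- xv * (xv > 0)
  if (!is_ad(x)) return(out)
  ad_node(out, list(x), function(g) list(g * (xv > 0)))
}

ad_lrelu <- function(x, slope = 0.2) {
  xv <- vof(x)
  m <- slope + (1 - slope) * (xv > 0)
  out <- xv * m
  if (!is_ad(x)) return(out)
  ad_node(out, list(x), function(g) list(g * m))
}

ad_tanh <- function(x) {
  xv <- vof(x)
  out <- tanh(xv)
  if (!is_ad(x)) return(out)
  ad_node(out, list(x), function(g) list(g * (1 - out^2)))
}

#' Instance normalisation over the spatial axes of an (H, W, C) array
#' @keywords internal
ad_inorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- vof(x)
  d <- dim(xv)
  N <- d[1] * d[2]
  xm <- xv; dim(xm) <- c(N, d[3])
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = N)
  va <- colSums(xc * xc) / N
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * rep(istd, each = N)
  gv <- vof(gamma); bv <- vof(beta)
  out <- xhat * rep(gv, each = N) + rep(bv, each = N)
  dim(out) <- d
  if (!is_ad(x) && !is_ad(gamma) && !is_ad(beta)) return(out)
  ad_node(out, list(x, gamma, beta), function(g) {
    dim(g) <- c(N, d[3])
    gg <- gb <- gx <- NULL
    if (is_ad(gamma)) gg <- colSums(g * xhat)
    if (is_ad(beta)) gb <- colSums(g)
    if (is_ad(x)) {
      dxhat <- g * rep(gv, each = N)
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * xhat)
      gx <- (dxhat - rep(s1 / N, each = N) - xhat * rep(s2 / N, each = N)) *
        rep(istd, each = N)
      dim(gx) <- d
    }
    list(gx, gg, gb)
  })
}

ad_add <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  out <- av + bv
  if (!is_ad(a) && !is_ad(b)) return(out)
  ad_node(out, list(a, b), function(g) list(if (is_ad(a)) g else NULL,
                                            if (is_ad(b)) g else NULL))
}

ad_scale <- function(x, s) {
  xv <- vof(x)
  out <- xv * s
  if (!is_ad(x)) return(out)
  ad_node(out, list(x), function(g) list(g * s))
}

#' Concatenate two (H, W, C) arrays along the channel axis
#' @keywords internal
ad_concat_c <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  da <- dim(av); db <- dim(bv)
  out <- array(c(av, bv), dim = c(da[1], da[2], da[3] + db[3]))
  if (!is_ad(a) && !is_ad(b)) return(out)
  ad_node(out, list(a, b), function(g) {
    na <- da[1] * da[2] * da[3]
    ga <- gb <- NULL
    if (is_ad(a)) { ga <- g[seq_len(na)]; dim(ga) <- da }
    if (is_ad(b)) { gb <- g[na + seq_len(db[1] * db[2] * db[3])]; dim(gb) <- db }
    list(ga, gb)
  })
}

.shuffle_cache <- new.env(parent = emptyenv())

pixel_shuffle_plan <- function(H, W, C, s) {
  key <- paste(H, W, C, s, sep = "_")
  pl <- .shuffle_cache[[key]]
  if (!is.null(pl)) return(pl)
  stopifnot(C %% (s * s) == 0L)
  Cout <- C %/% (s * s)
  Ho <- H * s; Wo <- W * s
  yo <- rep(seq_len(Ho) - 1L, times = Wo * Cout)
  xo <- rep(rep(seq_len(Wo) - 1L, each = Ho), times = Cout)
  fo <- rep(seq_len(Cout) - 1L, each = Ho * Wo)
  ci <- fo * s * s + (yo %% s) * s + (xo %% s)            # 0-based input channel
  src <- (yo %/% s) + (xo %/% s) * H + ci * H * W + 1L    # linear into (H,W,C)
  inv <- integer(length(src)); inv[src] <- seq_along(src)
  pl <- list(src = src, inv = inv, dout = c(Ho, Wo, Cout), din = c(H, W, C))
  .shuffle_cache[[key]] <- pl
  pl
}

#' Sub-pixel (pixel-shuffle) upsampling: (H, W, C*s^2) -> (H*s, W*s, C)
#'
#' Output pixel (y, x, f) (0-based) reads input channel
#' `f*s^2 + (y mod s)*s + (x mod s)` at location (y div s, x div s).
#' @keywords internal
ad_pixel_shuffle <- function(x, s) {
  xv <- vof(x)
  d <- dim(xv)
  pl <- pixel_shuffle_plan(d[1], d[2], d[3], s)
  out <- xv[pl$src]
  dim(out) <- pl$dout
  if (!is_ad(x)) return(out)
  ad_node(out, list(x), function(g) {
    gx <- g[pl$inv]
    dim(gx) <- pl$din
    list(gx)
  })
}

#' Bilinear backward-warp of features by a flow field (autodiff op)
#'
#' `out[i, j, ] = x[i + flow[i,j,2], j + flow[i,j,1], ]` with bilinear
#' interpolation; sample positions are clamped to the image border.
#' Differentiable in the features and (when a node) in the flow.
#' @keywords internal
ad_warp <- function(x, flow) {
  xv <- vof(x); fv <- vof(flow)
  if (any(!is.finite(fv))) stop("non-finite flow field")
  d <- dim(xv)
  H <- d[1]; W <- d[2]; C <- d[3]
  ii <- rep(seq_len(H), times = W)
  jj <- rep(seq_len(W), each = H)
  sy <- pmin(pmax(ii + as.vector(fv[, , 2]), 1), H)
  sx <- pmin(pmax(jj + as.vector(fv[, , 1]), 1), W)
  y0 <- pmin(floor(sy), H - 1L); x0 <- pmin(floor(sx), W - 1L)
  wy <- sy - y0; wx <- sx - x0
  i00 <- y0 + (x0 - 1) * H
  i10 <- i00 + 1
  i01 <- i00 + H
  i11 <- i01 + 1
  xm <- xv; dim(xm) <- c(H * W, C)
  w00 <- (1 - wy) * (1 - wx); w10 <- wy * (1 - wx)
  w01 <- (1 - wy) * wx;       w11 <- wy * wx
  out <- xm[i00, , drop = FALSE] * w00 + xm[i10, , drop = FALSE] * w10 +
         xm[i01, , drop = FALSE] * w01 + xm[i11, , drop = FALSE] * w11
  dim(out) <- d
  if (!is_ad(x) && !is_ad(flow)) return(out)
  ad_node(out, list(x, flow), function(g) {
    dim(g) <- c(H * W, C)
    gx <- gf <- NULL
    if (is_ad(x)) {
      idx <- c(i00, i10, i01, i11)
      gall <- rbind(g * w00, g * w10, g * w01, g * w11)
      gs <- rowsum(gall, group = idx, reorder = TRUE)
      gx <- matrix(0, H * W, C)
      gx[sort(unique(idx)), ] <- gs
      dim(gx) <- d
    }
    if (is_ad(flow)) {
      v00 <- xm[i00, , drop = FALSE]; v10 <- xm[i10, , drop = FALSE]
      v01 <- xm[i01, , drop = FALSE]; v11 <- xm[i11, , drop = FALSE]
      dsx <- rowSums(g * ((1 - wy) * (v01 - v00) + wy * (v11 - v10)))
      dsy <- rowSums(g * ((1 - wx) * (v10 - v00) + wx * (v11 - v01)))
      # clamped samples have zero derivative w.r.t. the flow
      dsx[sx <= 1 | sx >= W] <- 0
      dsy[sy <= 1 | sy >= H] <- 0
      gf <- array(c(dsx, dsy), dim = c(H, W, 2))
    }
    list(gx, gf)
  })
}

#' Mean of the numerically-stable softplus log(1 + exp(x))
#' @keywords internal
ad_mean_softplus <- function(x) {
  xv <- vof(x)
  n <- length(xv)
  sp <- pmax(xv, 0) + log1p(exp(-abs(xv)))
  out <- sum(sp) / n
  if (!is_ad(x)) return(out)
  ad_node(out, list(x), function(g) {
    gx <- as.numeric(g) * (1 / (1 + exp(-xv))) / n
    dim(gx) <- dim(xv)
    list(gx)
  })
}

ad_neg <- function(x) ad_scale(x, -1)

#' Mean squared difference between two arrays (autodiff op)
#' @keywords internal
ad_mse <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  dif <- av - bv
  n <- length(dif)
  out <- sum(dif * dif) / n
  if (!is_ad(a) && !is_ad(b)) return(out)
  ad_node(out, list(a, b), function(g) {
    gg <- as.numeric(g) * 2 * dif / n
    list(if (is_ad(a)) gg else NULL, if (is_ad(b)) -gg else NULL)
  })
}

#' Weighted sum of scalar nodes
#' @keywords internal
ad_wsum <- function(xs, w) {
  vals <- vapply(xs, function(x) as.numeric(vof(x)), numeric(1))
  out <- sum(vals * w)
  if (!any(vapply(xs, is_ad, logical(1)))) return(out)
  ad_node(out, xs, function(g) {
    lapply(seq_along(xs), function(i)
      if (is_ad(xs[[i]])) as.numeric(g) * w[i] else NULL)
  })
}

#' Gather rows of a flattened (H*W) x C feature map
#' @keywords internal
ad_gather_rows <- function(x, idx) {
  xv <- vof(x)
  d <- dim(xv)
  xm <- xv
  if (length(d) == 3L) dim(xm) <- c(d[1] * d[2], d[3])
  out <- xm[idx, , drop = FALSE]
  if (!is_ad(x)) return(out)
  ad_node(out, list(x), function(g) {
    gm <- matrix(0, nrow(xm), ncol(xm))
    gs <- rowsum(g, group = idx, reorder = TRUE)
    gm[sort(unique(idx)), ] <- gs
    if (length(d) == 3L) dim(gm) <- d
    list(gm)
  })
}

#' Row-wise L2 normalisation of an n x d matrix
#' @keywords internal
ad_l2norm_rows <- function(x, eps = 1e-12) {
  xv <- vof(x)
  nr <- sqrt(rowSums(xv * xv)) + eps
  out <- xv / nr
  if (!is_ad(x)) return(out)
  ad_node(out, list(x), function(g) {
    dotg <- rowSums(out * g)
    list((g - out * dotg) / nr)
  })
}

#' Patchwise InfoNCE with internal negatives (autodiff op)
#'
#' Rows of U are unit query vectors from the input's features, rows of V the
#' spatially-corresponding unit vectors from the generated output. For query
#' i the positive logit is u_i.v_i / tau and the negatives are u_i.u_j / tau
#' for all j != i. Returns the mean (or sum) over queries of the (1+K)-way
#' cross-entropy with the positive as the true class.
#' @keywords internal
ad_nce <- function(U, V, tau = 0.07, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  Uv <- vof(U); Vv <- vof(V)
  P <- nrow(Uv)
  if (P == 1L) {  # no negatives: -log(1) = 0
    out <- 0
    if (!is_ad(U) && !is_ad(V)) return(out)
    return(ad_node(out, list(U, V), function(g) list(array(0, dim(Uv)), array(0, dim(Vv)))))
  }
  s <- rowSums(Uv * Vv)
  Q <- tcrossprod(Uv)                 # u_i . u_j
  Z <- Q / tau
  diag(Z) <- s / tau
  zmax <- apply(Z, 1, max)
  E <- exp(Z - zmax)
  rs <- rowSums(E)
  Pm <- E / rs                        # row softmax
  li <- -(diag(Z) - zmax - log(rs))
  out <- if (reduce == "mean") mean(li) else sum(li)
  if (!is_ad(U) && !is_ad(V)) return(out)
  ad_node(out, list(U, V), function(g) {
    scl <- as.numeric(g) * if (reduce == "mean") 1 / P else 1
    G <- Pm
    diag(G) <- diag(G) - 1
    G <- G * scl / tau
    gd <- diag(G)
    Goff <- G
    diag(Goff) <- 0
    gU <- gV <- NULL
    if (is_ad(U)) gU <- gd * Vv + Goff %*% Uv + crossprod(Goff, Uv)
    if (is_ad(V)) gV <- gd * Uv
    list(gU, gV)
  })
}
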