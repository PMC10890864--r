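# Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed, restoring global state
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' He-normal weight initialisation for a conv/linear weight matrix
#' @keywords internal
he_init <- function(nin, nout, gain = 1) {
  matrix(rnorm(nin * nout, sd = gain * sqrt(2 / nin)), nin, nout)
}

#' 2x2-style mean pooling of an (H, W) or (H, W, C) array by integer factor
#' @keywords internal
avgpool2 <- function(x, s) {
  if (s == 1L) return(x)
  d <- dim(x)
  if (length(d) == 2L) { dim(x) <- c(d, 1L); d <- dim(x) }
  Ho <- d[1] %/% s; Wo <- d[2] %/% s
  x <- x[seq_len(Ho * s), seq_len(Wo * s), , drop = FALSE]
  dim(x) <- c(s, Ho, s, Wo, d[3])
  out <- apply(x, c(2, 4, 5), mean)
  out
}

#' Bilinear sub-pixel translation of a 2-D image (border clamp)
#'
#' Positive `dx` moves content rightwards (towards larger column index),
#' positive `dy` downwards.
#' @keywords internal
translate_bilinear <- function(m, dx, dy) {
  d <- dim(m)
  fl <- array(0, dim = c(d[1], d[2], 2))
  fl[, , 1] <- -dx
  fl[, , 2] <- -dy
  a <- m
  dim(a) <- c(d[1], d[2], 1L)
  out <- ad_warp(a, fl)
  dim(out) <- d
  out
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

fmt_id <- function(prefix, i) sprintf("%s_%03d", prefix, i)
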