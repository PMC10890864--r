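# Patch-based discriminator and the adversarial objective. The
# discriminator scores overlapping 70x70 receptive-field patches of a single
# frame; the losses use the logistic (log) form of the objective, with the
# generator trained on the standard non-saturating variant.

#' Build a 70x70-receptive-field patch discriminator
#'
#' Four 4x4 convolutions (strides 2, 2, 2, 1; channels nd, 2nd, 4nd, 8nd;
#' leaky-ReLU 0.2; instance normalisation except on the first layer)
#' followed by a 1-channel 4x4 convolution producing raw patch logits.
#'
#' @param nd base channel count (default 64)
#' @param seed weight-initialisation seed
#' @export
newDiscriminator <- function(nd = 64L, seed = 2L) {
  with_seed(seed, {
    ch <- c(1L, nd, 2L * nd, 4L * nd, 8L * nd)
    params <- list(
      W1 = ad_param(he_init(16L * ch[1], ch[2])), b1 = ad_param(numeric(ch[2])),
      W2 = ad_param(he_init(16L * ch[2], ch[3])),
      g2 = ad_param(rep(1, ch[3])), be2 = ad_param(numeric(ch[3])),
      W3 = ad_param(he_init(16L * ch[3], ch[4])),
      g3 = ad_param(rep(1, ch[4])), be3 = ad_param(numeric(ch[4])),
      W4 = ad_param(he_init(16L * ch[4], ch[5])),
      g4 = ad_param(rep(1, ch[5])), be4 = ad_param(numeric(ch[5])),
      W5 = ad_param(he_init(16L * ch[5], 1L)), b5 = ad_param(numeric(1L)))
    list(params = params, nd = nd)
  })
}

#' Patch logits of a single frame
#'
#' @param disc a discriminator from [newDiscriminator()] or an
#'   [SRModel-class]
#' @param frame `(H, W)` matrix / `(H, W, 1)` array or node in [-1, 1]
#' @return `(h, w, 1)` array (or node) of raw patch realness logits
#' @export
discriminate <- function(disc, frame) {
  if (is(disc, "SRModel")) disc <- disc@discriminator
  x <- as_hw1(frame)
  dv <- dim(vof(x))
  if (dv[3] != 1L) stop("the discriminator expects grayscale frames")
  p <- disc$params
  x <- ad_conv2d(x, p$W1, p$b1, kh = 4L, kw = 4L, stride = 2L, pad = 1L,
                 act = "lrelu")
  x <- ad_conv_in(x, p$W2, p$g2, p$be2, kh = 4L, kw = 4L, stride = 2L,
                  pad = 1L, act = "lrelu")
  x <- ad_conv_in(x, p$W3, p$g3, p$be3, kh = 4L, kw = 4L, stride = 2L,
                  pad = 1L, act = "lrelu")
  x <- ad_conv_in(x, p$W4, p$g4, p$be4, kh = 4L, kw = 4L, stride = 1L,
                  pad = 1L, act = "lrelu")
  maybe_val(ad_conv2d(x, p$W5, p$b5, kh = 4L, kw = 4L, stride = 1L, pad = 1L))
}

#' Discriminator loss (logistic GAN)
#'
#' Mean over patches of `-log sigma(real) - log(1 - sigma(fake))`: the
#' discriminator maximises the log objective by minimising this. Equals
#' `2 log 2` when all logits are zero and approaches 0 only as real logits
#' go to +Inf and fake logits to -Inf.
#'
#' @param realLogits,fakeLogits logit arrays (or nodes) from [discriminate()]
#' @return scalar (node while a tape is active)
#' @export
ganLossD <- function(realLogits, fakeLogits) {
  stopifnot(all(is.finite(vof(realLogits))), all(is.finite(vof(fakeLogits))))
  ad_wsum(list(ad_mean_softplus(ad_neg(realLogits)),
               ad_mean_softplus(fakeLogits)), c(1, 1))
}

#' Generator adversarial loss
#'
#' Non-saturating form by default: mean of `-log sigma(fake)`, which is
#' `log 2` at zero logits, approaches 0 as the discriminator is fooled and
#' has strictly negative gradient in every fake logit. `literal = TRUE`
#' gives the raw `mean log(1 - sigma(fake))` term of the printed minimax
#' objective instead.
#'
#' @param fakeLogits logit array (or node)
#' @param literal use the saturating textbook form
#' @export
ganLossG <- function(fakeLogits, literal = FALSE) {
  stopifnot(all(is.finite(vof(fakeLogits))))
  if (literal) return(ad_scale(ad_mean_softplus(fakeLogits), -1))
  ad_mean_softplus(ad_neg(fakeLogits))
}
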