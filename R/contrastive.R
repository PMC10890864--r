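# Structure preservation: the multilayer patchwise contrastive (InfoNCE)
# loss between input and generated frames, the fixed-backbone perceptual
# loss, and the weighted total objective.

#' Sample corresponding patch features for the contrastive loss
#'
#' For each layer, draws `nPatches` spatial sites uniformly without
#' replacement; queries come from the input features at those sites,
#' positives from the generated-output features at the *same* sites, and
#' each query's negatives are the input features at the other sampled sites
#' (internal negatives, K = nPatches - 1). An optional projection head
#' (2-layer MLP) is applied before unit normalisation.
#'
#' @param featsX,featsY named per-layer lists of `(H, W, C)` feature arrays,
#'   spatially congruent per layer
#' @param nPatches sites per layer; must not exceed any layer's site count
#' @param seed sampling seed
#' @param proj optional projection heads (one per layer, as in a generator's
#'   `$proj`); plain values are used, so the bank is detached from training
#' @param tau temperature stored in the bank
#' @return a patch-feature bank: per layer `u` (P x d), `v` (P x d),
#'   `n` (P x K x d) and the sampled `coords`
#' @export
samplePatchTriplets <- function(featsX, featsY, nPatches, seed = 1L,
                                proj = NULL, tau = 0.07) {
  stopifnot(length(featsX) == length(featsY))
  with_seed(seed, {
    layers <- lapply(seq_along(featsX), function(li) {
      fx <- vof(featsX[[li]]); fy <- vof(featsY[[li]])
      dx <- dim(fx)
      if (!all(dx[1:2] == dim(fy)[1:2]))
        stop("featsX and featsY are not spatially congruent at layer ", li)
      sites <- dx[1] * dx[2]
      if (nPatches > sites)
        stop("nPatches exceeds the ", sites, " spatial sites of layer ", li)
      idx <- sample.int(sites, nPatches)
      dim(fx) <- c(sites, dx[3]); dim(fy) <- c(sites, dim(fy)[3])
      u <- fx[idx, , drop = FALSE]
      v <- fy[idx, , drop = FALSE]
      if (!is.null(proj)) {
        h <- proj[[li]]
        mlp <- function(m) {
          z <- m %*% vof(h$W1) + rep(vof(h$b1), each = nrow(m))
          z <- z * (z > 0)
          z %*% vof(h$W2) + rep(vof(h$b2), each = nrow(m))
        }
        u <- mlp(u); v <- mlp(v)
      }
      nrm <- function(m) m / (sqrt(rowSums(m * m)) + 1e-12)
      u <- nrm(u); v <- nrm(v)
      P <- nrow(u)
      n <- NULL
      if (P > 1L) {
        n <- array(0, dim = c(P, P - 1L, ncol(u)))
        for (i in seq_len(P)) n[i, , ] <- u[-i, , drop = FALSE]
      }
      list(u = u, v = v, n = n, coords = idx)
    })
    names(layers) <- names(featsX)
    list(layers = layers, tau = tau)
  })
}

#' Multilayer patchwise contrastive loss on a sampled bank
#'
#' For query i at layer l the logits are `u_i . v_i / tau` against
#' `u_i . n_k / tau`, and the loss is the negative log-probability of the
#' positive under the (1+K)-way softmax. By default the per-layer values are
#' averaged over queries and summed over layers, so the magnitude is
#' independent of the patch count; `reduce = "sum"` gives the raw double
#' sum over layers and queries.
#'
#' @param bank a bank from [samplePatchTriplets()]
#' @param reduce "layerMean" (default) or "sum"
#' @return scalar loss
#' @export
patchNCELoss <- function(bank, reduce = c("layerMean", "sum")) {
  reduce <- match.arg(reduce)
  tau <- bank$tau
  if (tau <= 0) stop("temperature tau must be positive")
  total <- 0
  for (ly in bank$layers) {
    P <- nrow(ly$u)
    li <- vapply(seq_len(P), function(i) {
      pos <- sum(ly$u[i, ] * ly$v[i, ]) / tau
      if (is.null(ly$n)) return(0)      # K = 0: softmax over one logit
      nm <- ly$n[i, , , drop = FALSE]
      dim(nm) <- dim(ly$n)[2:3]
      negs <- nm %*% ly$u[i, ] / tau
      -(pos - logsumexp(c(pos, negs)))
    }, numeric(1))
    total <- total + if (reduce == "layerMean") mean(li) else sum(li)
  }
  total
}

#' Build the fixed random-weight perceptual backbone
#'
#' A small convolutional feature network with frozen He-initialised weights
#' drawn from a recorded seed; used both by the perceptual loss and, with a
#' different seed, as the embedding for the distribution metrics. A
#' pretrained classification backbone can be substituted where its weights
#' are available, but the package default is self-contained.
#'
#' @param seed weight seed (recorded in checkpoints and reports)
#' @param channels channel widths of the three stride-2 stages
#' @export
newPercNet <- function(seed = 7L, channels = c(8L, 16L, 32L)) {
  with_seed(seed, {
    ch <- c(1L, channels)
    ws <- lapply(seq_len(3L), function(i) he_init(9L * ch[i], ch[i + 1L]))
    list(ws = ws, seed = seed, channels = channels)
  })
}

perc_features <- function(net, x) {
  feats <- list()
  for (i in seq_along(net$ws)) {
    x <- ad_conv2d(x, net$ws[[i]], kh = 3L, kw = 3L, stride = 2L, pad = 1L,
                   act = "relu")
    feats[[i]] <- x
  }
  feats
}

#' Perceptual loss between an input frame and a generated frame
#'
#' Mean squared distance between the deep features of the two frames under
#' the fixed backbone (last two stages, equally weighted). Exactly zero for
#' identical frames and symmetric in its arguments.
#'
#' @param x,y `(H, W)` matrices / `(H, W, 1)` arrays (either may be a node)
#' @param net a backbone from [newPercNet()] (built from its default seed
#'   when omitted)
#' @export
perceptualLoss <- function(x, y, net = NULL) {
  if (is.null(net)) net <- newPercNet()
  fx <- perc_features(net, as_hw1(x))
  fy <- perc_features(net, as_hw1(y))
  k <- length(fx)
  ad_wsum(list(ad_mse(fx[[k - 1L]], fy[[k - 1L]]),
               ad_mse(fx[[k]], fy[[k]])), c(0.5, 0.5))
}

#' Weighted total generator objective
#'
#' `lambdaGAN * gan + lambdaContr * contr + lambdaPerc * perc`. Setting a
#' weight to zero reproduces the corresponding loss-removal ablation.
#'
#' @param gan,contr,perc scalar loss terms (values or nodes)
#' @param weights numeric length-3 vector `(lambdaGAN, lambdaContr,
#'   lambdaPerc)`, all >= 0
#' @export
totalGeneratorLoss <- function(gan, contr, perc, weights = c(1, 20, 1)) {
  if (any(weights < 0)) stop("loss weights must be non-negative")
  stopifnot(length(weights) == 3L)
  ad_wsum(list(gan, contr, perc), weights)
}
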