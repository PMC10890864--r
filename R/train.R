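# Adversarial optimisation: alternating discriminator/generator Adam steps,
# the linear learning-rate decay schedule, checkpointing and the ablation
# harness (loss-term removal and the zero-warp temporal switch).

#' Build a full model (generator, discriminator, perceptual backbone)
#'
#' @param genConfig a [GeneratorConfig-class]
#' @param trainConfig a [TrainConfig-class]
#' @param seed weight-initialisation seed (defaults to the training seed)
#' @return an [SRModel-class]
#' @export
newSRModel <- function(genConfig = GeneratorConfig(),
                       trainConfig = TrainConfig(), seed = trainConfig@seed) {
  validObject(trainConfig)
  gen <- newGenerator(genConfig, seed = seed)
  disc <- newDiscriminator(nd = trainConfig@dFilters, seed = seed + 1L)
  perc <- newPercNet(seed = trainConfig@percSeed)
  m <- new("SRModel", generator = gen, discriminator = disc, percNet = perc,
           trainConfig = trainConfig, step = 0L)
  m
}

# ---------------------------------------------------------------------------
# Adam

adam_new <- function() new.env(parent = emptyenv())

adam_step <- function(params, opt, lr, beta1, beta2, t, eps = 1e-8) {
  b1t <- 1 - beta1^t
  b2t <- 1 - beta2^t
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (is.null(p$g)) next
    key <- as.character(i)
    st <- opt[[key]]
    if (is.null(st)) {
      st <- list(m = 0 * p$v, v = 0 * p$v)
    }
    st$m <- beta1 * st$m + (1 - beta1) * p$g
    st$v <- beta2 * st$v + (1 - beta2) * p$g^2
    opt[[key]] <- st
    p$v <- p$v - lr * (st$m / b1t) / (sqrt(st$v / b2t) + eps)
  }
  invisible(NULL)
}

#' Learning rate at a given epoch under the linear-decay policy
#'
#' Constant at `lr` through `decayAfter` epochs, then decays linearly to
#' zero at the final epoch: `lr * (1 - (e - decayAfter) / (epochs -
#' decayAfter))`.
#'
#' @param epoch 1-based epoch index
#' @param tc a [TrainConfig-class]
#' @export
lrAtEpoch <- function(epoch, tc) {
  if (epoch <= tc@decayAfter) return(tc@lr)
  tc@lr * (1 - (epoch - tc@decayAfter) / (tc@epochs - tc@decayAfter))
}

pick_loss_frames <- function(T, k) {
  if (k <= 0L || k >= T) seq_len(T) else sort(sample.int(T, k))
}

#' One alternating adversarial training step
#'
#' First a discriminator update (real high-resolution frames against
#' detached generated frames), then a generator update on the weighted
#' total objective (adversarial + contrastive + perceptual). Deterministic
#' given the RNG state at entry. Aborts with a diagnostic on non-finite
#' loss.
#'
#' @param model an [SRModel-class]; weights and optimiser state are updated
#'   in place
#' @param lrBatch list of [VideoSequence-class] (or `(H, W, T)` arrays)
#' @param hrBatch list of `(H, W)` matrices from the high-resolution pool
#' @param lr learning rate for this step
#' @param flowsBatch optional list of precomputed per-sequence flows
#'   (elements `backward`/`forward`), e.g. cached across epochs
#' @return the model (weights updated in place); the step's loss components
#'   are attached as attribute `losses`
#' @export
trainStep <- function(model, lrBatch, hrBatch, lr = model@trainConfig@lr,
                      flowsBatch = NULL) {
  tc <- model@trainConfig
  gen <- model@generator
  disc <- model@discriminator
  if (is.null(model@generator$opt_g)) {
    gen$opt_g <- adam_new()
    gen$opt_d <- adam_new()
    model@generator <- gen
  }
  lam <- c(tc@lambdaGAN, tc@lambdaContr, tc@lambdaPerc)
  seqArrs <- lapply(lrBatch, function(s) if (is(s, "VideoSequence")) s@frames else s)
  dparams <- unname(disc$params)
  gparams <- generator_params(gen)
  t_step <- model@step + 1L

  # ---- generate (recorded) and pick the frames entering the losses
  ad_tape_start()
  lossFrames <- lapply(seqArrs, function(sa)
    pick_loss_frames(dim(sa)[3], tc@lossFramesPerSeq))
  fwd <- lapply(seq_along(seqArrs), function(i)
    generator_forward(gen, seqArrs[[i]],
                      flows = if (!is.null(flowsBatch)) flowsBatch[[i]],
                      frames = lossFrames[[i]]))
  fakeFrames <- list()   # nodes, one per (sequence, loss frame)
  inFrames <- list()     # matching plain input frames
  for (i in seq_along(seqArrs)) {
    for (t in lossFrames[[i]]) {
      fakeFrames[[length(fakeFrames) + 1L]] <- fwd[[i]]$yhat[[t]]
      inFrames[[length(inFrames) + 1L]] <- seqArrs[[i]][, , t]
    }
  }

  # ---- discriminator update on detached fakes
  ad_zero_grads(dparams)
  nD <- min(length(hrBatch), length(fakeFrames))
  dReal <- lapply(hrBatch[seq_len(nD)], function(h) discriminate(disc, h))
  dFake <- lapply(fakeFrames[seq_len(nD)], function(f) discriminate(disc, vof(f)))
  dLoss <- ad_wsum(c(lapply(dReal, function(r) ad_mean_softplus(ad_neg(r))),
                     lapply(dFake, ad_mean_softplus)),
                   rep(1 / nD, 2L * nD))
  if (!is.finite(vof(dLoss))) stop("non-finite discriminator loss at step ", t_step)
  ad_backward(dLoss)
  adam_step(dparams, gen$opt_d, lr, tc@beta1, tc@beta2, t_step)

  # ---- generator update
  ad_zero_grads(gparams)
  ad_zero_grads(dparams)
  ganTerms <- lapply(fakeFrames, function(f) ganLossG(discriminate(disc, f)))
  ganG <- ad_wsum(ganTerms, rep(1 / length(ganTerms), length(ganTerms)))
  contr <- 0
  if (lam[2] > 0) {
    contrTerms <- list()
    for (j in seq_along(fakeFrames)) {
      fx <- extractLayerFeatures(gen, inFrames[[j]])
      fy <- extractLayerFeatures(gen, fakeFrames[[j]])
      contrTerms[[j]] <- nce_loss_nodes(gen, fx, fy, tc@nPatches, tc@tau)
    }
    contr <- ad_wsum(contrTerms, rep(1 / length(contrTerms), length(contrTerms)))
  }
  perc <- 0
  if (lam[3] > 0) {
    percTerms <- lapply(seq_along(fakeFrames), function(j)
      perceptualLoss(inFrames[[j]], fakeFrames[[j]], model@percNet))
    perc <- ad_wsum(percTerms, rep(1 / length(percTerms), length(percTerms)))
  }
  total <- totalGeneratorLoss(ganG, contr, perc, lam)
  if (!is.finite(vof(total))) stop("non-finite generator loss at step ", t_step)
  if (any(lam > 0)) {
    ad_backward(total)
    ad_zero_grads(dparams)  # the generator step must not move D
    adam_step(gparams, gen$opt_g, lr, tc@beta1, tc@beta2, t_step)
  }
  ad_tape_stop()
  model@step <- t_step
  losses <- list(step = t_step, lr = lr, d = as.numeric(vof(dLoss)),
                 gan_g = as.numeric(vof(ganG)), contr = as.numeric(vof(contr)),
                 perc = as.numeric(vof(perc)), total = as.numeric(vof(total)))
  attr(model, "losses") <- losses
  model
}

#' Contrastive loss between two frames' encoder features (autodiff path)
#' @keywords internal
nce_loss_nodes <- function(gen, featsX, featsY, nPatches, tau) {
  terms <- list()
  for (li in seq_along(featsX)) {
    fx <- featsX[[li]]; fy <- featsY[[li]]
    dx <- dim(vof(fx))
    sites <- dx[1] * dx[2]
    idx <- sample.int(sites, min(nPatches, sites))
    U <- ad_gather_rows(fx, idx)
    V <- ad_gather_rows(fy, idx)
    if (!is.null(gen$proj)) {
      h <- gen$proj[[li]]
      U <- ad_linear(ad_relu(ad_linear(U, h$W1, h$b1)), h$W2, h$b2)
      V <- ad_linear(ad_relu(ad_linear(V, h$W1, h$b1)), h$W2, h$b2)
    }
    U <- ad_l2norm_rows(U)
    V <- ad_l2norm_rows(V)
    terms[[li]] <- ad_nce(U, V, tau = tau, reduce = "mean")
  }
  ad_wsum(terms, rep(1, length(terms)))
}

#' Fit a model on a phantom (or same-layout) dataset
#'
#' Loads the low-resolution sequences and high-resolution pool named in the
#' dataset manifest, optionally holds out a fraction of each, precomputes
#' and caches optical flow per sequence (the inputs are fixed, so flow
#' never changes across epochs), and runs alternating updates with the
#' linear learning-rate decay. Writes `checkpoint_last.rds` and a JSON loss
#' log when `outDir` is given.
#'
#' @param model an [SRModel-class] from [newSRModel()]
#' @param datasetDir dataset directory with a `manifest.json`
#' @param outDir optional output directory for checkpoint and log
#' @param verbose print a line per epoch
#' @return the trained model; the loss log is attached as attribute `log`
#' @export
fitSRModel <- function(model, datasetDir, outDir = NULL, verbose = FALSE) {
  tc <- model@trainConfig
  man <- readManifest(datasetDir)
  lrItems <- Filter(function(it) it$role == "lr_sequence", man$items)
  hrItems <- Filter(function(it) it$role == "hr_image", man$items)
  if (!length(lrItems) || !length(hrItems)) stop("dataset has no training items")
  seqs <- lapply(lrItems, function(it)
    loadSequence(file.path(datasetDir, it$path))@frames)
  hrs <- lapply(hrItems, function(it)
    readFrameImage(file.path(datasetDir, it$path)))
  gen <- model@generator
  flowCache <- NULL
  if (!gen$config@zeroWarp) {
    flowCache <- lapply(seqs, function(sa) list(
      backward = compute_flows(gen, sa, "backward"),
      forward = compute_flows(gen, sa, "forward")))
  }
  log <- list()
  set.seed(tc@seed)
  nb <- max(1L, length(seqs) %/% tc@batchSize)
  for (e in seq_len(tc@epochs)) {
    lre <- lrAtEpoch(e, tc)
    ord <- sample(length(seqs))
    for (b in seq_len(nb)) {
      take <- ord[((b - 1L) * tc@batchSize + 1L):min(b * tc@batchSize, length(ord))]
      hrTake <- sample(length(hrs), min(length(take) * max(1L, tc@lossFramesPerSeq),
                                        length(hrs)))
      model <- trainStep(model, seqs[take], hrs[hrTake], lr = lre,
                         flowsBatch = flowCache[take])
      log[[length(log) + 1L]] <- attr(model, "losses")
    }
    if (verbose) {
      l <- log[[length(log)]]
      message(sprintf("epoch %d/%d lr %.2e D %.3f G %.3f contr %.3f perc %.4f",
                      e, tc@epochs, lre, l$d, l$gan_g, l$contr, l$perc))
    }
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    saveCheckpoint(model, file.path(outDir, "checkpoint_last.rds"))
    jsonlite::write_json(log, file.path(outDir, "train_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(model, "log") <- log
  model
}

# ---------------------------------------------------------------------------
# checkpointing

params_values <- function(params) lapply(params, function(p) p$v)

restore_params <- function(params, values) {
  for (i in seq_along(params)) params[[i]]$v <- values[[i]]
  invisible(NULL)
}

#' Save a model checkpoint (weights, configs, optimiser state, step)
#' @param model an [SRModel-class]
#' @param path output `.rds` file
#' @export
saveCheckpoint <- function(model, path) {
  gen <- model@generator
  state <- list(
    gen_values = params_values(generator_params(gen)),
    disc_values = params_values(unname(model@discriminator$params)),
    opt_g = if (!is.null(gen$opt_g)) as.list(gen$opt_g),
    opt_d = if (!is.null(gen$opt_d)) as.list(gen$opt_d),
    gen_config = gen$config,
    train_config = model@trainConfig,
    perc_seed = model@percNet$seed,
    nd = model@discriminator$nd,
    step = model@step,
    rng = if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()))
  saveRDS(state, path)
  invisible(path)
}

#' Load a model checkpoint saved by [saveCheckpoint()]
#' @param path checkpoint `.rds` file
#' @return an [SRModel-class] reproducing the saved state bit-exactly
#' @export
loadCheckpoint <- function(path) {
  st <- readRDS(path)
  tc <- st$train_config
  model <- newSRModel(st$gen_config, tc, seed = tc@seed)
  gen <- model@generator
  restore_params(generator_params(gen), st$gen_values)
  restore_params(unname(model@discriminator$params), st$disc_values)
  gen$opt_g <- adam_new(); gen$opt_d <- adam_new()
  for (k in names(st$opt_g)) gen$opt_g[[k]] <- st$opt_g[[k]]
  for (k in names(st$opt_d)) gen$opt_d[[k]] <- st$opt_d[[k]]
  model@generator <- gen
  model@step <- st$step
  if (!is.null(st$rng))
    assign(".Random.seed", st$rng, envir = globalenv())
  model
}

#' Inference-time ablation variants of a trained model
#'
#' `zero_warp` replaces the warped propagated features by zeros, making
#' each output frame independent of its neighbours; the loss-removal
#' variants (`no_gan`, `no_contr`, `no_perc`) zero the corresponding weight
#' in the training configuration (they matter when the returned model is
#' trained further); `none` returns the model unchanged.
#'
#' @param model an [SRModel-class]
#' @param which one of "none", "zero_warp", "no_gan", "no_contr", "no_perc"
#' @export
ablationVariant <- function(model,
                            which = c("none", "zero_warp", "no_gan",
                                      "no_contr", "no_perc")) {
  which <- match.arg(which)
  if (which == "none") return(model)
  if (which == "zero_warp") {
    gen <- model@generator
    gen$config@zeroWarp <- TRUE
    model@generator <- gen
    return(model)
  }
  tc <- model@trainConfig
  slot(tc, switch(which, no_gan = "lambdaGAN", no_contr = "lambdaContr",
                  no_perc = "lambdaPerc")) <- 0
  model@trainConfig <- tc
  model
}
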