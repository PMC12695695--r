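# ---------------------------------------------------------------------------
# Training regimes: MAE autoencoder (also used as generator pre-training),
# Pix2Pix conditional GAN, and CBCT<->CT CycleGAN.
#
# The optimization protocol mirrors the clinical setting: batches of 3 axial
# slices, Adam, generator learning rate 1e-4, discriminator learning rate
# 1e-6, and generator pre-training before adversarial training — the fix for
# the collapse mode where the discriminator loss races to zero while the
# generator loss explodes.
# ---------------------------------------------------------------------------

#' Loss-term weights
#'
#' @param lambdaL1 Weight of the L1 reconstruction term in the Pix2Pix
#'   generator loss (default 100, the standard Pix2Pix weighting).
#' @param lambdaCycle Weight of the cycle-consistency term in the CycleGAN
#'   loss (default 10).
#' @return A validated list.
#' @export
lossWeights <- function(lambdaL1 = 100, lambdaCycle = 10) {
  stopifnot(lambdaL1 >= 0, lambdaCycle >= 0)
  list(lambdaL1 = lambdaL1, lambdaCycle = lambdaCycle)
}

#' Training configuration
#'
#' Defaults reproduce the study protocol at desk scale: batches of 3 slices,
#' Adam with learning rate 1e-4 for the generator and 1e-6 for the
#' discriminator.
#'
#' @param epochs Adversarial (or autoencoder) training epochs; the clinical
#'   protocol uses 100.
#' @param batch Slices per batch (protocol value 3).
#' @param lrGenerator,lrDiscriminator Adam step sizes. When adversarial
#'   training is enabled the discriminator rate must not exceed the
#'   generator rate.
#' @param seed Integer seed controlling init, shuffling and all noise.
#' @param withMri Use the 2-channel CBCT+MRI input?
#' @param pretrainEpochs Generator MAE warm-up epochs before adversarial
#'   training.
#' @param weights A [lossWeights()] list.
#' @param enforceLrOrder Set FALSE to deliberately allow
#'   `lrDiscriminator > lrGenerator` (e.g. to reproduce the collapse mode).
#' @return A validated list.
#' @export
trainConfig <- function(epochs = 5L, batch = 3L, lrGenerator = 1e-4,
                        lrDiscriminator = 1e-6, seed = 1L, withMri = TRUE,
                        pretrainEpochs = 1L, weights = lossWeights(),
                        enforceLrOrder = TRUE) {
  stopifnot(epochs >= 0, batch >= 1, lrGenerator > 0, lrDiscriminator > 0)
  if (enforceLrOrder && lrDiscriminator > lrGenerator)
    stop("lrDiscriminator must not exceed lrGenerator for adversarial training")
  list(epochs = as.integer(epochs), batch = as.integer(batch),
       lrGenerator = lrGenerator, lrDiscriminator = lrDiscriminator,
       seed = as.integer(seed), withMri = isTRUE(withMri),
       pretrainEpochs = as.integer(pretrainEpochs), weights = weights)
}

# ---- numeric (non-tape) loss functions ------------------------------------

.bceLogits <- function(s, target) {
  mean(pmax(s, 0) - s * target + log1p(exp(-abs(s))))
}

#' Mean absolute error loss
#'
#' @param pred,target Numeric arrays of equal shape.
#' @param mask Optional logical/0-1 array restricting the mean.
#' @return Scalar mean absolute difference.
#' @export
lossMae <- function(pred, target, mask = NULL) {
  stopifnot(all(dim(pred) == dim(target)))
  if (is.null(mask)) return(mean(abs(pred - target)))
  if (sum(mask) == 0) stop("empty mask in lossMae")
  sum(abs(pred - target) * mask) / sum(mask)
}

#' Pix2Pix generator loss
#'
#' Adversarial binary cross-entropy of the fake patch scores toward the
#' "real" label, plus `lambdaL1` times the L1 distance to the target.
#'
#' @param dScoresFake Discriminator logit map on (condition, prediction).
#' @param pred,target Predicted and reference slices.
#' @param weights A [lossWeights()] list.
#' @return Scalar loss.
#' @export
lossPix2PixGenerator <- function(dScoresFake, pred, target,
                                 weights = lossWeights()) {
  .bceLogits(dScoresFake, 1) + weights$lambdaL1 * lossMae(pred, target)
}

#' Discriminator loss
#'
#' Mean of BCE(real scores toward 1) and BCE(fake scores toward 0), halved
#' (the standard convention, so that logit-0 scores give loss `ln 2`).
#'
#' @param dScoresReal,dScoresFake Logit maps of equal shape.
#' @return Scalar loss.
#' @export
lossDiscriminator <- function(dScoresReal, dScoresFake) {
  stopifnot(all(dim(dScoresReal) == dim(dScoresFake)))
  0.5 * (.bceLogits(dScoresReal, 1) + .bceLogits(dScoresFake, 0))
}

#' Run a discriminator in inference mode
#' @param model Discriminator handle.
#' @param input `(H, W, C, N)` array of stacked condition/candidate channels.
#' @return Logit map array.
#' @export
runDiscriminator <- function(model, input) {
  nnRecording(FALSE)
  model$forward(model, nnConst(input))$value
}

#' CycleGAN loss components
#'
#' Adversarial terms in both directions plus `lambdaCycle` times the two
#' cycle-consistency L1 terms.
#'
#' @param realA,realB `(H, W, 1, N)` arrays from domains A (CBCT) and B (CT).
#' @param generators `list(ab = , ba = )` generator handles.
#' @param discriminators `list(a = , b = )` critic handles (candidate-only
#'   input).
#' @param weights A [lossWeights()] list.
#' @return Named list with `advAB`, `advBA`, `cycleA`, `cycleB`, `total`.
#' @export
lossCycleGan <- function(realA, realB, generators, discriminators,
                         weights = lossWeights()) {
  fakeB <- runGenerator(generators$ab, realA)
  fakeA <- runGenerator(generators$ba, realB)
  recA <- runGenerator(generators$ba, fakeB)
  recB <- runGenerator(generators$ab, fakeA)
  advAB <- .bceLogits(runDiscriminator(discriminators$b, fakeB), 1)
  advBA <- .bceLogits(runDiscriminator(discriminators$a, fakeA), 1)
  cycleA <- mean(abs(recA - realA))
  cycleB <- mean(abs(recB - realB))
  list(advAB = advAB, advBA = advBA, cycleA = cycleA, cycleB = cycleB,
       total = advAB + advBA + weights$lambdaCycle * (cycleA + cycleB))
}

# ---- batch assembly --------------------------------------------------------

.catC <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# Normalize raw triplets once and keep the slice arrays.
.prepSlices <- function(triplets, withMri) {
  lapply(triplets, function(tr) {
    norm <- prepareTriplet(tr)$triplet
    list(cbct = norm@cbct@data, mri = if (withMri) norm@mri@data else NULL,
         ct = norm@ct@data)
  })
}

# Shuffled (volume, slice) batches for one epoch.
.epochBatches <- function(prepped, batch, seed) {
  pairs <- do.call(rbind, lapply(seq_along(prepped), function(i) {
    cbind(i, seq_len(dim(prepped[[i]]$ct)[3]))
  }))
  ord <- withRng(seed, sample.int(nrow(pairs)))
  pairs <- pairs[ord, , drop = FALSE]
  starts <- seq(1L, nrow(pairs), by = batch)
  lapply(starts, function(s) {
    rows <- pairs[s:min(s + batch - 1L, nrow(pairs)), , drop = FALSE]
    n <- nrow(rows)
    p1 <- prepped[[rows[1, 1]]]
    d <- dim(p1$ct)
    nC <- if (is.null(p1$mri)) 1L else 2L
    x <- array(0, c(d[1], d[2], nC, n))
    y <- array(0, c(d[1], d[2], 1L, n))
    for (m in seq_len(n)) {
      p <- prepped[[rows[m, 1]]]; k <- rows[m, 2]
      x[, , 1L, m] <- p$cbct[, , k]
      if (nC == 2L) x[, , 2L, m] <- p$mri[, , k]
      y[, , 1L, m] <- p$ct[, , k]
    }
    list(input = x, target = y)
  })
}

.valMaskedMae <- function(generator, valTriplets, withMri) {
  if (is.null(valTriplets) || !length(valTriplets)) return(NA_real_)
  mean(vapply(valTriplets, function(tr) {
    sct <- synthesizeVolume(generator, tr, withMri)
    mask <- volData(tripletLabels(tr)) > 0
    lossMae(volData(sct), volData(ctVolume(tr)), mask)
  }, 0))
}

# ---- generator pre-training (MAE autoencoder) ------------------------------

#' Pre-train a generator with the MAE loss
#'
#' This is both the self-autoencoder training regime and the warm-up used to
#' initialize adversarial training.
#'
#' @param model Generator handle.
#' @param data `list(train = <list of GroundTruthTriplet>, val = NULL)` in
#'   native HU/intensity units; normalization is applied internally.
#' @param cfg A [trainConfig()]; `cfg$pretrainEpochs` epochs are run.
#' @return `list(model, log)` where `log` is a per-epoch data.frame.
#' @export
pretrainGenerator <- function(model, data, cfg) {
  stopifnot(cfg$pretrainEpochs >= 1)
  prepped <- .prepSlices(data$train, cfg$withMri)
  opt <- adamInit(model$params)
  log <- data.frame()
  for (epoch in seq_len(cfg$pretrainEpochs)) {
    batches <- .epochBatches(prepped, cfg$batch, cfg$seed + 7L * epoch)
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      nnRecording(TRUE); nnTapeReset()
      nnZeroGrads(model$params)
      pred <- model$forward(model, nnConst(b$input))
      loss <- opMae(pred, b$target)
      if (!is.finite(loss$value))
        stop("pre-training diverged (non-finite MAE) at epoch ", epoch)
      nnBackward(loss)
      nnRecording(FALSE); nnTapeReset()
      opt <- adamStep(opt, model$params, cfg$lrGenerator)
      losses[bi] <- loss$value
    }
    log <- rbind(log, data.frame(epoch = epoch, genLoss = mean(losses),
                                 discLoss = NA_real_,
                                 valMae = .valMaskedMae(model, data$val, cfg$withMri)))
  }
  list(model = model, log = log)
}

# ---- Pix2Pix ---------------------------------------------------------------

#' Train a Pix2Pix conditional GAN
#'
#' Alternating discriminator/generator updates with separate Adam optimizers
#' at `lrDiscriminator` / `lrGenerator`. The generator is expected to be
#' pre-trained ([pretrainGenerator()]); the checkpoint with the best
#' validation masked MAE is retained (last epoch when no validation set is
#' given). Non-finite losses abort with the last good checkpoint restored.
#'
#' @param generator,discriminator Model handles; the discriminator must
#'   accept `inChannels = condition channels + 1`.
#' @param data As in [pretrainGenerator()].
#' @param cfg A [trainConfig()].
#' @return `list(generator, discriminator, log, minDiscLoss, bestEpoch)`.
#' @export
fitPix2Pix <- function(generator, discriminator, data, cfg) {
  nCond <- if (cfg$withMri) 2L else 1L
  if (discriminator$cfg$inChannels != nCond + 1L)
    stop("discriminator inChannels must equal condition channels + 1")
  prepped <- .prepSlices(data$train, cfg$withMri)
  optG <- adamInit(generator$params)
  optD <- adamInit(discriminator$params)
  log <- data.frame()
  best <- list(valMae = Inf, epoch = 0L, gen = paramValues(generator))
  lastGood <- paramValues(generator)
  minDisc <- Inf
  for (epoch in seq_len(cfg$epochs)) {
    batches <- .epochBatches(prepped, cfg$batch, cfg$seed + 31L * epoch)
    gl <- dl <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      # discriminator update on detached fakes
      fake <- runGenerator(generator, b$input)
      nnRecording(TRUE); nnTapeReset()
      nnZeroGrads(discriminator$params)
      dReal <- discriminator$forward(discriminator, nnConst(.catC(b$input, b$target)))
      dFake <- discriminator$forward(discriminator, nnConst(.catC(b$input, fake)))
      dLoss <- opScale(opAdd(opBceLogits(dReal, 1), opBceLogits(dFake, 0)), 0.5)
      nnBackward(dLoss)
      nnRecording(FALSE); nnTapeReset()
      optD <- adamStep(optD, discriminator$params, cfg$lrDiscriminator)
      # generator update through the discriminator
      nnRecording(TRUE); nnTapeReset()
      nnZeroGrads(generator$params); nnZeroGrads(discriminator$params)
      predT <- generator$forward(generator, nnConst(b$input))
      dFake2 <- discriminator$forward(discriminator,
                                      opConcatC(nnConst(b$input), predT))
      gLoss <- opAdd(opBceLogits(dFake2, 1),
                     opScale(opMae(predT, b$target), cfg$weights$lambdaL1))
      if (!is.finite(gLoss$value) || !is.finite(dLoss$value)) {
        nnRecording(FALSE); nnTapeReset()
        setParamValues(generator, lastGood)
        warning("adversarial training diverged; restored last good checkpoint")
        return(list(generator = generator, discriminator = discriminator,
                    log = log, minDiscLoss = minDisc, bestEpoch = best$epoch,
                    aborted = TRUE))
      }
      nnBackward(gLoss)
      nnRecording(FALSE); nnTapeReset()
      optG <- adamStep(optG, generator$params, cfg$lrGenerator)
      gl[bi] <- gLoss$value; dl[bi] <- dLoss$value
    }
    minDisc <- min(minDisc, dl)
    lastGood <- paramValues(generator)
    valMae <- .valMaskedMae(generator, data$val, cfg$withMri)
    log <- rbind(log, data.frame(epoch = epoch, genLoss = mean(gl),
                                 discLoss = mean(dl), valMae = valMae))
    score <- if (is.na(valMae)) -epoch else valMae  # no val: prefer last epoch
    if (score <= best$valMae) {
      best <- list(valMae = score, epoch = epoch, gen = paramValues(generator))
    }
  }
  if (cfg$epochs > 0) setParamValues(generator, best$gen)
  list(generator = generator, discriminator = discriminator, log = log,
       minDiscLoss = minDisc, bestEpoch = best$epoch, aborted = FALSE)
}

# ---- CycleGAN --------------------------------------------------------------

#' Train a CBCT-to-CT CycleGAN (unpaired, no MRI)
#'
#' Two generators (A = CBCT to B = CT and back) and two candidate-only patch
#' critics, trained on independently shuffled batches with adversarial plus
#' cycle-consistency losses.
#'
#' @param generators `list(ab = , ba = )` 1-channel generator handles.
#' @param discriminators `list(a = , b = )` 1-channel critic handles.
#' @param data As in [pretrainGenerator()] (the paired structure is ignored;
#'   slices are shuffled independently per domain).
#' @param cfg A [trainConfig()] (`withMri` is ignored; CycleGAN is CBCT-only).
#' @return `list(generators, discriminators, log)`.
#' @export
fitCycleGan <- function(generators, discriminators, data, cfg) {
  prepped <- .prepSlices(data$train, withMri = FALSE)
  optGab <- adamInit(generators$ab$params)
  optGba <- adamInit(generators$ba$params)
  optDa <- adamInit(discriminators$a$params)
  optDb <- adamInit(discriminators$b$params)
  log <- data.frame()
  for (epoch in seq_len(cfg$epochs)) {
    batchesA <- .epochBatches(prepped, cfg$batch, cfg$seed + 13L * epoch)
    batchesB <- .epochBatches(prepped, cfg$batch, cfg$seed + 17L * epoch + 1L)
    nb <- min(length(batchesA), length(batchesB))
    gl <- dl <- numeric(nb)
    for (bi in seq_len(nb)) {
      a <- batchesA[[bi]]$input   # CBCT slices
      bdom <- batchesB[[bi]]$target  # CT slices, independently shuffled
      if (dim(a)[4] != dim(bdom)[4]) next
      fakeB <- runGenerator(generators$ab, a)
      fakeA <- runGenerator(generators$ba, bdom)
      # critics
      for (side in list(list(d = discriminators$b, o = "optDb", real = bdom, fake = fakeB),
                        list(d = discriminators$a, o = "optDa", real = a, fake = fakeA))) {
        nnRecording(TRUE); nnTapeReset()
        nnZeroGrads(side$d$params)
        dr <- side$d$forward(side$d, nnConst(side$real))
        df <- side$d$forward(side$d, nnConst(side$fake))
        dL <- opScale(opAdd(opBceLogits(dr, 1), opBceLogits(df, 0)), 0.5)
        nnBackward(dL)
        nnRecording(FALSE); nnTapeReset()
        assign(side$o, adamStep(get(side$o), side$d$params, cfg$lrDiscriminator))
        dl[bi] <- dl[bi] + dL$value / 2
      }
      # generators
      nnRecording(TRUE); nnTapeReset()
      nnZeroGrads(generators$ab$params); nnZeroGrads(generators$ba$params)
      nnZeroGrads(discriminators$a$params); nnZeroGrads(discriminators$b$params)
      fb <- generators$ab$forward(generators$ab, nnConst(a))
      ra <- generators$ba$forward(generators$ba, fb)
      fa <- generators$ba$forward(generators$ba, nnConst(bdom))
      rb <- generators$ab$forward(generators$ab, fa)
      adv <- opAdd(opBceLogits(discriminators$b$forward(discriminators$b, fb), 1),
                   opBceLogits(discriminators$a$forward(discriminators$a, fa), 1))
      cyc <- opAdd(opMae(ra, a), opMae(rb, bdom))
      gL <- opAdd(adv, opScale(cyc, cfg$weights$lambdaCycle))
      if (!is.finite(gL$value)) {
        nnRecording(FALSE); nnTapeReset()
        warning("CycleGAN training diverged; stopping early")
        return(list(generators = generators, discriminators = discriminators,
                    log = log))
      }
      nnBackward(gL)
      nnRecording(FALSE); nnTapeReset()
      optGab <- adamStep(optGab, generators$ab$params, cfg$lrGenerator)
      optGba <- adamStep(optGba, generators$ba$params, cfg$lrGenerator)
      gl[bi] <- gL$value
    }
    log <- rbind(log, data.frame(epoch = epoch, genLoss = mean(gl),
                                 discLoss = mean(dl), valMae = NA_real_))
  }
  list(generators = generators, discriminators = discriminators, log = log)
}

# ---- volume synthesis ------------------------------------------------------

#' Synthesize a CT volume from a triplet with a trained generator
#'
#' Runs per-slice inference over the axial stack, reassembles the volume,
#' maps back from [-1, 1] to HU, clips to [-1024, 3072], and copies the CT
#' grid metadata.
#'
#' @param generator Trained generator handle.
#' @param triplet A [GroundTruthTriplet-class] in native units.
#' @param withMri Use the MRI channel (must match the generator's
#'   `inChannels`).
#' @param batch Slices per inference batch.
#' @return The synthetic CT as a [VolumeGrid-class] in HU.
#' @export
synthesizeVolume <- function(generator, triplet, withMri = TRUE, batch = 8L) {
  ctg <- triplet@ct
  sct <- synthesizeFromVolumes(generator, triplet@cbct,
                               if (withMri) triplet@mri else NULL, batch)
  VolumeGrid(sct@data, ctg@spacing, ctg@origin, ctg@orientation)
}

#' Synthesize a CT from raw CBCT (and optional MRI) volumes
#'
#' Like [synthesizeVolume()] but without a full triplet: the CBCT (and MRI)
#' are normalized internally and the output carries the CBCT grid metadata.
#'
#' @inheritParams synthesizeVolume
#' @param cbct CBCT [VolumeGrid-class] in HU.
#' @param mri Optional MRI [VolumeGrid-class]; required iff the generator
#'   has 2 input channels.
#' @return Synthetic CT [VolumeGrid-class] in HU.
#' @export
synthesizeFromVolumes <- function(generator, cbct, mri = NULL, batch = 8L) {
  b <- huBounds()
  cb <- normalizeMinMax(clipHU(cbct, b), b)@data
  d <- dim(cb)
  nC <- if (is.null(mri)) 1L else 2L
  if (nC != generator$cfg$inChannels)
    stop("generator expects ", generator$cfg$inChannels,
         " input channels; got ", nC)
  if (!is.null(mri)) {
    mb <- range(mri@data)
    if (mb[2] <= mb[1]) mb <- c(mb[1], mb[1] + 1)
    mr <- normalizeMinMax(mri, mb)@data
  }
  out <- array(0, d)
  for (s in seq(1L, d[3], by = batch)) {
    ks <- s:min(s + batch - 1L, d[3])
    x <- array(0, c(d[1], d[2], nC, length(ks)))
    x[, , 1L, ] <- cb[, , ks]
    if (nC == 2L) x[, , 2L, ] <- mr[, , ks]
    pred <- runGenerator(generator, x)
    out[, , ks] <- pred[, , 1L, ]
  }
  clipHU(denormalizeMinMax(VolumeGrid(out, cbct@spacing, cbct@origin,
                                      cbct@orientation)))
}
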