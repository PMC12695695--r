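# ---------------------------------------------------------------------------
# Synthetic multimodal head phantom.
#
# The phantom emulates the acquisition setting of a head proton-therapy
# course: an aligned CT/CBCT/T1-MRI triplet with ground-truth organ labels.
# Organ geometry is a jittered arrangement of ellipsoids and capsules (head,
# skull shell, brain, paired ventricles, eyes with lenses, optic nerves, a
# nasal air cavity) chosen to cover exactly the structures whose recovery the
# evaluation metrics probe. All intensity tables are configurable defaults of
# this package, not measured values.
# ---------------------------------------------------------------------------

# Base organ geometry for a spec, jittered deterministically from its seed.
.organParams <- function(spec) {
  a <- spec@headAxesMm
  base <- list(
    head = list(center = c(0, 0, 0), axes = a),
    skullInnerScale = 0.86,
    brain = list(center = c(0, 0, 0.12 * a[3]), axes = 0.74 * a),
    ventricles = list(centers = rbind(c(-12, 5, 0.12 * a[3]),
                                      c(12, 5, 0.12 * a[3])),
                      axes = c(9, 22, 9)),
    eyes = list(centers = rbind(c(-28, -0.72 * a[2], 0),
                                c(28, -0.72 * a[2], 0)), radius = 11),
    lenses = list(offset = c(0, -7, 0), radius = 5),
    opticNerves = list(radius = 3, innerEnd = rbind(c(-10, -0.35 * a[2], 5),
                                                    c(10, -0.35 * a[2], 5))),
    nasal = list(center = c(0, -0.62 * a[2], -0.45 * a[3]),
                 axes = c(14, 18, 16)))
  jitterOrganParams(base, spec@jitterFrac, spec@seed)
}

# Multiplicative size jitter and additive center jitter (sd = frac * scale).
# `interPatient` additionally boosts ventricular variability: ventricle size
# and position are by far the most variable features across subjects. The
# boost is off for the small per-triplet (weekly) jitter so the planning MRI
# stays anatomically faithful within a patient.
jitterOrganParams <- function(params, frac, seed, interPatient = TRUE) {
  if (frac <= 0) return(params)
  withRng(seed, {
    jsize <- function(v, k = 1) v * (1 + k * frac * pmax(pmin(stats::rnorm(length(v)), 2), -2))
    jpos <- function(v, mm = 20) v + frac * mm * pmax(pmin(stats::rnorm(length(v)), 2), -2)
    vk <- if (interPatient) 3 else 1
    vmm <- if (interPatient) 100 else 20
    params$brain$axes <- jsize(params$brain$axes)
    params$ventricles$axes <- jsize(params$ventricles$axes, k = vk)
    params$ventricles$centers <- t(apply(params$ventricles$centers, 1, jpos,
                                         mm = vmm))
    params$eyes$radius <- jsize(params$eyes$radius)
    params$eyes$centers <- t(apply(params$eyes$centers, 1, jpos))
    params$lenses$radius <- jsize(params$lenses$radius)
    params$nasal$axes <- jsize(params$nasal$axes)
    params$nasal$center <- jpos(params$nasal$center)
    params
  })
}

.inEllipsoid <- function(co, center, axes) {
  ((co$x - center[1]) / axes[1])^2 + ((co$y - center[2]) / axes[2])^2 +
    ((co$z - center[3]) / axes[3])^2 <= 1
}

.inSphere <- function(co, center, r) {
  (co$x - center[1])^2 + (co$y - center[2])^2 + (co$z - center[3])^2 <= r^2
}

.inCapsule <- function(co, p0, p1, r) {
  v <- p1 - p0
  L2 <- sum(v^2)
  t <- ((co$x - p0[1]) * v[1] + (co$y - p0[2]) * v[2] + (co$z - p0[3]) * v[3]) / L2
  t <- pmin(pmax(t, 0), 1)
  (co$x - (p0[1] + t * v[1]))^2 + (co$y - (p0[2] + t * v[2]))^2 +
    (co$z - (p0[3] + t * v[3]))^2 <= r^2
}

# Error unless the 6 axis-extreme points of an ellipsoid/sphere sit inside
# the head ellipsoid.
.checkInsideHead <- function(center, axes, head, organ) {
  pts <- rbind(center + c(axes[1], 0, 0), center - c(axes[1], 0, 0),
               center + c(0, axes[2], 0), center - c(0, axes[2], 0),
               center + c(0, 0, axes[3]), center - c(0, 0, axes[3]))
  q <- rowSums(sweep(sweep(pts, 2, head$center), 2, head$axes, `/`)^2)
  if (any(q > 1))
    stop("invalid phantom spec: ", organ, " geometry exceeds head bounds",
         call. = FALSE)
}

#' Generate the ground-truth organ label volume of a head phantom
#'
#' Paints the head ellipsoid and the toggled organs onto a centered grid.
#' Ventricles are painted only inside the brain, lenses only inside the eyes,
#' so the nesting invariants hold by construction. Deterministic given the
#' spec (including its seed).
#'
#' @param spec A [PhantomSpec-class].
#' @param params Optional pre-computed organ geometry (used by
#'   [makeDataset()] to share patient-level anatomy across triplets).
#' @return A [LabelVolume-class].
#' @export
generateLabelVolume <- function(spec, params = NULL) {
  stopifnot(validObject(spec))
  if (is.null(params)) params <- .organParams(spec)
  d <- spec@gridShape
  co <- coordArrays(gridCoords(d, spec@spacingMm), d)
  lab <- array(0L, d)
  head <- .inEllipsoid(co, params$head$center, params$head$axes)
  lab[head] <- 1L
  codes <- labelCodes()
  if ("skull" %in% spec@organs) {
    inner <- .inEllipsoid(co, params$head$center,
                          params$skullInnerScale * params$head$axes)
    lab[head & !inner] <- codes[["skull"]]
  }
  if ("brain" %in% spec@organs) {
    br <- .inEllipsoid(co, params$brain$center, params$brain$axes)
    lab[head & br] <- codes[["brain"]]
  }
  if ("ventricles" %in% spec@organs) {
    if (!"brain" %in% spec@organs)
      stop("invalid phantom spec: ventricles require the brain toggle")
    for (i in 1:2) {
      .checkInsideHead(params$ventricles$centers[i, ], params$ventricles$axes,
                       params$head, "ventricle")
      vm <- .inEllipsoid(co, params$ventricles$centers[i, ], params$ventricles$axes)
      lab[vm & lab == codes[["brain"]]] <- codes[["ventricle"]]
    }
  }
  if ("eyes" %in% spec@organs) {
    for (i in 1:2) {
      .checkInsideHead(params$eyes$centers[i, ], rep(params$eyes$radius, 3),
                       params$head, "eye")
      em <- .inSphere(co, params$eyes$centers[i, ], params$eyes$radius)
      lab[em & head] <- codes[["eye"]]
    }
  }
  if ("lenses" %in% spec@organs) {
    if (!"eyes" %in% spec@organs)
      stop("invalid phantom spec: lenses require the eyes toggle")
    for (i in 1:2) {
      lc <- params$eyes$centers[i, ] + params$lenses$offset
      .checkInsideHead(lc, rep(params$lenses$radius, 3), params$head, "lens")
      lm <- .inSphere(co, lc, params$lenses$radius)
      lab[lm & lab == codes[["eye"]]] <- codes[["lens"]]
    }
  }
  if ("optic_nerves" %in% spec@organs) {
    if (!"eyes" %in% spec@organs)
      stop("invalid phantom spec: optic nerves require the eyes toggle")
    for (i in 1:2) {
      p0 <- params$eyes$centers[i, ]
      p1 <- params$opticNerves$innerEnd[i, ]
      .checkInsideHead(p1, rep(params$opticNerves$radius, 3), params$head,
                       "optic nerve")
      nm <- .inCapsule(co, p0, p1, params$opticNerves$radius)
      lab[nm & (lab %in% c(1L, codes[["skull"]], codes[["brain"]]))] <-
        codes[["optic_nerve"]]
    }
  }
  if ("nasal_cavities" %in% spec@organs) {
    nm <- .inEllipsoid(co, params$nasal$center, params$nasal$axes)
    lab[nm & head & lab != codes[["eye"]] & lab != codes[["lens"]]] <-
      codes[["nasal_cavity"]]
  }
  LabelVolume(VolumeGrid(lab, spec@spacingMm,
                         origin = -(d - 1) / 2 * spec@spacingMm))
}

#' Default HU table for CT rendering
#'
#' Mean HU per organ code; package defaults for the phantom, not measured
#' calibration values.
#' @return Named numeric vector (names as in [labelCodes()]).
#' @export
defaultHuTable <- function() {
  c(background = -1000, soft_tissue = 40, skull = 1000, brain = 35,
    ventricle = 10, eye = 30, lens = 80, optic_nerve = 40,
    nasal_cavity = -1000)
}

.tableByCode <- function(tab, labels, what) {
  codes <- labelCodes()
  present <- sort(unique(as.vector(labels)))
  names(present) <- names(codes)[match(present, codes)]
  missing <- setdiff(names(present), names(tab))
  if (length(missing))
    stop(what, " table missing entries for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  lut <- rep(NA_real_, max(codes) + 1)
  lut[codes[names(tab)] + 1] <- tab
  lut
}

#' Render a CT volume from organ labels
#'
#' Each voxel takes the table mean for its label plus Gaussian noise, then
#' is clipped to the HU range [-1024, 3072].
#'
#' @param labels A [LabelVolume-class].
#' @param huTable Named mean HU per organ (see [defaultHuTable()]); must cover
#'   every code present.
#' @param noiseSd Gaussian noise standard deviation in HU.
#' @param seed RNG seed.
#' @return A [VolumeGrid-class] in HU.
#' @export
renderCT <- function(labels, huTable = defaultHuTable(), noiseSd = 5,
                     seed = 1L) {
  lab <- volData(labels)
  lut <- .tableByCode(huTable, lab, "HU")
  v <- array(lut[lab + 1L], dim(lab))
  if (noiseSd > 0)
    v <- v + withRng(seed, array(stats::rnorm(length(v), 0, noiseSd), dim(v)))
  clipHU(VolumeGrid(v, labels@grid@spacing, labels@grid@origin,
                    labels@grid@orientation))
}

#' Default CBCT degradation settings
#'
#' Per-tissue affine HU corruption (scale/offset), a radial cupping field,
#' Gaussian blur, noise, and a cylindrical field-of-view truncation. The
#' defaults collapse the brain/ventricle contrast (both near 20 HU) and
#' depress bone, reproducing at desk scale the HU inaccuracy that makes raw
#' CBCT unreliable for dose calculation.
#'
#' @param huScale Named per-tissue multiplicative HU factor.
#' @param huOffset Named per-tissue additive HU shift.
#' @param cuppingAmplitudeHu Additive HU at the lateral edge of the grid.
#' @param blurSigmaMm Isotropic Gaussian blur sigma in mm.
#' @param noiseSd Gaussian noise sd in HU.
#' @param fovDiameterMm Cylindrical field-of-view diameter; voxels at larger
#'   lateral radius are set to -1024.
#' @return A named list of degradation settings.
#' @export
cbctDegradation <- function(huScale = NULL, huOffset = NULL,
                            cuppingAmplitudeHu = 40, blurSigmaMm = 1.2,
                            noiseSd = 15, fovDiameterMm = 200) {
  if (fovDiameterMm <= 0) stop("fovDiameterMm must be positive")
  nm <- names(labelCodes())
  scale <- stats::setNames(rep(1, length(nm)), nm)
  offset <- stats::setNames(rep(0, length(nm)), nm)
  offset[c("soft_tissue", "skull", "brain", "ventricle", "eye", "lens",
           "optic_nerve")] <- c(20, -20, -15, 10, -5, -30, -15)
  if (!is.null(huScale)) scale[names(huScale)] <- huScale
  if (!is.null(huOffset)) offset[names(huOffset)] <- huOffset
  list(huScale = scale, huOffset = offset,
       cuppingAmplitudeHu = cuppingAmplitudeHu, blurSigmaMm = blurSigmaMm,
       noiseSd = noiseSd, fovDiameterMm = fovDiameterMm)
}

#' Simulate a CBCT from a CT and its labels
#'
#' Applies, in order: per-tissue affine HU corruption, a radially increasing
#' additive cupping field, Gaussian blur, Gaussian noise, cylindrical FOV
#' truncation to -1024, and clipping to [-1024, 3072].
#'
#' @param ct CT [VolumeGrid-class] in HU.
#' @param labels Aligned [LabelVolume-class].
#' @param degradation Settings from [cbctDegradation()].
#' @param seed RNG seed for the noise.
#' @return A CBCT [VolumeGrid-class] in HU.
#' @export
simulateCBCT <- function(ct, labels, degradation = cbctDegradation(),
                         seed = 1L) {
  if (degradation$fovDiameterMm <= 0) stop("fovDiameterMm must be positive")
  lab <- volData(labels)
  stopifnot(all(dim(lab) == dim(ct@data)))
  sc <- .tableByCode(degradation$huScale, lab, "huScale")
  of <- .tableByCode(degradation$huOffset, lab, "huOffset")
  v <- ct@data * array(sc[lab + 1L], dim(lab)) + array(of[lab + 1L], dim(lab))
  d <- dim(v)
  co <- coordArrays(gridCoords(d, ct@spacing), d)
  if (degradation$cuppingAmplitudeHu != 0) {
    rmax <- max(abs(gridCoords(d, ct@spacing)[[1]]), abs(gridCoords(d, ct@spacing)[[2]]))
    r2 <- (co$x^2 + co$y^2) / rmax^2
    v <- v + degradation$cuppingAmplitudeHu * r2
  }
  if (degradation$noiseSd > 0)
    v <- v + withRng(seed, array(stats::rnorm(length(v), 0, degradation$noiseSd), d))
  # noise sits under the resolution kernel: CBCT texture is blurrier than CT
  if (degradation$blurSigmaMm > 0)
    v <- .cpp_gauss_blur3d(v, degradation$blurSigmaMm / ct@spacing)
  outside <- (co$x^2 + co$y^2) > (degradation$fovDiameterMm / 2)^2
  v[outside] <- -1024
  clipHU(VolumeGrid(v, ct@spacing, ct@origin, ct@orientation))
}

#' Default T1 contrast table for the simulated MRI
#'
#' T1 convention: bone and air near zero signal, CSF (ventricles) darker than
#' brain parenchyma — the soft-tissue contrast the CBCT lacks.
#' @return Named non-negative intensity means per organ code.
#' @export
defaultMriContrast <- function() {
  c(background = 0, soft_tissue = 60, skull = 5, brain = 100, ventricle = 25,
    eye = 40, lens = 70, optic_nerve = 90, nasal_cavity = 0)
}

#' Simulate a T1-weighted MRI from organ labels
#'
#' Voxel intensity is the table mean times a smooth multiplicative bias field
#' (max/min ratio bounded by `(1+a)/(1-a)`), plus Gaussian noise, floored
#' at 0.
#'
#' @param labels A [LabelVolume-class].
#' @param contrastTable Named non-negative mean intensity per organ.
#' @param biasFieldAmplitude Relative amplitude `a` of the bias field.
#' @param noiseSd Gaussian noise sd in intensity units.
#' @param seed RNG seed.
#' @return An MRI [VolumeGrid-class] in arbitrary intensity units.
#' @export
simulateT1Mri <- function(labels, contrastTable = defaultMriContrast(),
                          biasFieldAmplitude = 0.2, noiseSd = 3, seed = 1L) {
  if (any(contrastTable < 0)) stop("negative MRI contrast table entries")
  lab <- volData(labels)
  lut <- .tableByCode(contrastTable, lab, "MRI contrast")
  v <- array(lut[lab + 1L], dim(lab))
  d <- dim(lab)
  if (biasFieldAmplitude > 0) {
    field <- withRng(seed + 1L, {
      cs <- gridCoords(d, labels@grid@spacing)
      ext <- vapply(cs, function(c) max(abs(c)) + 1e-9, 0)
      g <- array(0, d)
      co <- coordArrays(cs, d)
      for (k in 1:3) {
        w <- stats::rnorm(3, 0, 1)
        ph <- stats::runif(3, 0, 2 * pi)
        g <- g + w[1] * cos(pi * co$x / ext[1] + ph[1]) +
          w[2] * cos(pi * co$y / ext[2] + ph[2]) +
          w[3] * cos(pi * co$z / ext[3] + ph[3])
      }
      1 + biasFieldAmplitude * g / max(abs(g))
    })
    v <- v * field
  }
  if (noiseSd > 0)
    v <- v + withRng(seed, array(stats::rnorm(length(v), 0, noiseSd), d))
  VolumeGrid(pmax(v, 0), labels@grid@spacing, labels@grid@origin,
             labels@grid@orientation)
}

#' Simulate one aligned CT/CBCT/MRI triplet
#'
#' Convenience wrapper chaining [generateLabelVolume()], [renderCT()],
#' [simulateCBCT()] and [simulateT1Mri()] with seeds derived from the spec
#' seed, so the whole triplet is a pure function of the spec.
#'
#' @param spec A [PhantomSpec-class].
#' @param huTable,ctNoiseSd Passed to [renderCT()].
#' @param degradation Passed to [simulateCBCT()].
#' @param mriContrast,biasFieldAmplitude,mriNoiseSd Passed to [simulateT1Mri()].
#' @param params Optional pre-computed organ geometry.
#' @param mri Optional pre-rendered MRI volume (the per-patient planning MRI
#'   reused across that patient's triplets).
#' @return A [GroundTruthTriplet-class].
#' @export
simulateTriplet <- function(spec, huTable = defaultHuTable(), ctNoiseSd = 5,
                            degradation = cbctDegradation(),
                            mriContrast = defaultMriContrast(),
                            biasFieldAmplitude = 0.2, mriNoiseSd = 3,
                            params = NULL, mri = NULL) {
  labels <- generateLabelVolume(spec, params)
  ct <- renderCT(labels, huTable, ctNoiseSd, seed = spec@seed + 1L)
  cbct <- simulateCBCT(ct, labels, degradation, seed = spec@seed + 2L)
  if (is.null(mri))
    mri <- simulateT1Mri(labels, mriContrast, biasFieldAmplitude, mriNoiseSd,
                         seed = spec@seed + 3L)
  GroundTruthTriplet(ct = ct, cbct = cbct, mri = mri, labels = labels)
}

#' Simulate a cohort of phantom patients in memory
#'
#' Emulates a fractionated course: each patient has one planning MRI
#' (rendered once from the patient's base anatomy) reused across all of that
#' patient's triplets, while CT/CBCT receive fresh small anatomical jitter
#' per triplet (weekly acquisitions).
#'
#' @param nPatients,tripletsPerPatient Counts (>= 1).
#' @param specTemplate A [PhantomSpec-class]; each patient derives its
#'   anatomy from `specTemplate@seed` plus the patient index.
#' @param tripletJitterFrac Relative per-triplet jitter applied on top of the
#'   patient anatomy.
#' @return A data-frame-free list with elements `triplets` (list of
#'   [GroundTruthTriplet-class]), `patientId`, `tripletId`, `seed`.
#' @export
simulateCohort <- function(nPatients, tripletsPerPatient,
                           specTemplate = phantomSpec(),
                           tripletJitterFrac = 0.02) {
  stopifnot(nPatients >= 1, tripletsPerPatient >= 1)
  triplets <- list(); patientId <- character(); tripletId <- integer()
  seeds <- integer()
  for (p in seq_len(nPatients)) {
    pseed <- specTemplate@seed + 7919L * p
    pspec <- phantomSpec(specTemplate@gridShape, specTemplate@spacingMm,
                         specTemplate@headAxesMm, specTemplate@organs,
                         seed = pseed, jitterFrac = specTemplate@jitterFrac)
    baseParams <- .organParams(pspec)
    baseLabels <- generateLabelVolume(pspec, baseParams)
    mri <- simulateT1Mri(baseLabels, seed = pseed + 3L)
    for (t in seq_len(tripletsPerPatient)) {
      tseed <- pseed + 104729L * t
      tspec <- phantomSpec(pspec@gridShape, pspec@spacingMm, pspec@headAxesMm,
                           pspec@organs, seed = tseed,
                           jitterFrac = pspec@jitterFrac)
      tparams <- jitterOrganParams(baseParams, tripletJitterFrac, tseed,
                                   interPatient = FALSE)
      triplets[[length(triplets) + 1L]] <-
        simulateTriplet(tspec, params = tparams, mri = mri)
      patientId <- c(patientId, sprintf("patient%03d", p))
      tripletId <- c(tripletId, t)
      seeds <- c(seeds, tseed)
    }
  }
  list(triplets = triplets, patientId = patientId, tripletId = tripletId,
       seed = seeds)
}

#' Write a phantom dataset to disk as NIfTI plus a manifest
#'
#' One MRI file per patient is shared across that patient's triplets; CT,
#' CBCT and labels are written per triplet. The manifest CSV lists patient
#' id, triplet id, file paths and the seed of each triplet.
#'
#' @inheritParams simulateCohort
#' @param outDir Output directory (created if needed).
#' @return The manifest as a data.frame (also written to
#'   `file.path(outDir, "manifest.csv")`).
#' @export
makeDataset <- function(nPatients, tripletsPerPatient,
                        specTemplate = phantomSpec(), outDir,
                        tripletJitterFrac = 0.02) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  probe <- file.path(outDir, ".write_probe")
  ok <- tryCatch({ file.create(probe) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory not writable: ", outDir)
  unlink(probe)
  cohort <- simulateCohort(nPatients, tripletsPerPatient, specTemplate,
                           tripletJitterFrac)
  rows <- list()
  writtenMri <- character()
  for (i in seq_along(cohort$triplets)) {
    pid <- cohort$patientId[i]; tid <- cohort$tripletId[i]
    tr <- cohort$triplets[[i]]
    stem <- file.path(outDir, sprintf("%s_t%02d", pid, tid))
    mriPath <- file.path(outDir, sprintf("%s_mri.nii.gz", pid))
    if (!pid %in% writtenMri) {
      writeVolume(tr@mri, mriPath)
      writtenMri <- c(writtenMri, pid)
    }
    writeVolume(tr@ct, paste0(stem, "_ct.nii.gz"))
    writeVolume(tr@cbct, paste0(stem, "_cbct.nii.gz"))
    writeVolume(tr@labels, paste0(stem, "_labels.nii.gz"))
    rows[[i]] <- data.frame(patient_id = pid, triplet_id = tid,
                            ct = paste0(stem, "_ct.nii.gz"),
                            cbct = paste0(stem, "_cbct.nii.gz"),
                            mri = mriPath,
                            labels = paste0(stem, "_labels.nii.gz"),
                            seed = cohort$seed[i])
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
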