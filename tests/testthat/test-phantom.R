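test_that("all-toggles-off spec yields only background and soft tissue", {
  labs <- generateLabelVolume(tinySpec(organs = character(0)))
  expect_setequal(unique(as.vector(volData(labs))), c(0L, 1L))
})

test_that("label generation is deterministic and organs form nested regions", {
  spec <- tinySpec(seed = 5L)
  labs1 <- generateLabelVolume(spec)
  labs2 <- generateLabelVolume(tinySpec(seed = 5L))
  expect_identical(volData(labs1), volData(labs2))
  lab <- volData(labs1)
  codes <- labelCodes()
  for (organ in c("ventricle", "eye", "lens", "optic_nerve"))
    expect_gt(sum(lab == codes[[organ]]), 0)
  # every ventricle voxel lies inside the brain region dilated by one voxel:
  # scan each for a code-3 neighbor (or itself being enclosed by ventricle
  # voxels that touch brain)
  vent <- which(lab == codes[["ventricle"]], arr.ind = TRUE)
  brain <- lab == codes[["brain"]]
  d <- dim(lab)
  for (r in seq_len(nrow(vent))) {
    i <- vent[r, ]
    nb <- as.matrix(expand.grid(i[1] + -1:1, i[2] + -1:1, i[3] + -1:1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
             nb[, 3] >= 1 & nb[, 3] <= d[3], , drop = FALSE]
    expect_true(any(brain[nb]))
  }
})

test_that("organ geometry exceeding the head raises an invalid-spec error", {
  spec <- tinySpec()
  params <- dualsct:::.organParams(spec)
  params$eyes$centers[1, ] <- c(-95, -90, 0)
  expect_error(generateLabelVolume(spec, params), "exceeds head bounds")
})

test_that("CT rendering honors the HU table, noise statistics and clip range", {
  labs <- generateLabelVolume(tinySpec())
  ct0 <- renderCT(labs, noiseSd = 0)
  lab <- volData(labs)
  expect_true(all(volData(ct0)[lab == labelCodes()[["ventricle"]]] == 10))
  expect_true(all(volData(ct0)[lab == labelCodes()[["skull"]]] == 1000))
  # missing code in the table is a configuration error
  expect_error(renderCT(labs, huTable = c(background = -1000)), "missing")
  # CLT bound: sample mean of a large uniform region within 3 sd / sqrt(n)
  plain <- generateLabelVolume(tinySpec(organs = character(0)))
  ct20 <- renderCT(plain, noiseSd = 20, seed = 9)
  soft <- volData(ct20)[volData(plain) == 1]
  expect_gt(length(soft), 1000)
  expect_lt(abs(mean(soft) - 40), 3 * 20 / sqrt(length(soft)))
  # hard clip bounds
  tabHot <- defaultHuTable()
  tabHot[c("soft_tissue", "skull")] <- 5000
  hot <- renderCT(labs, huTable = tabHot, noiseSd = 500, seed = 2)
  expect_gte(min(volData(hot)), -1024)
  expect_lte(max(volData(hot)), 3072)
})

test_that("identity degradation reproduces the CT exactly", {
  tr <- cachedTriplet()
  ident <- cbctDegradation(huScale = setNames(rep(1, 9), names(labelCodes())),
                           huOffset = setNames(rep(0, 9), names(labelCodes())),
                           cuppingAmplitudeHu = 0, blurSigmaMm = 0,
                           noiseSd = 0, fovDiameterMm = 1e4)
  cbct <- simulateCBCT(ctVolume(tr), tripletLabels(tr), ident)
  expect_equal(volData(cbct), volData(ctVolume(tr)))
})

test_that("CBCT FOV truncation and per-tissue offsets behave as configured", {
  tr <- cachedTriplet()
  deg <- cbctDegradation(cuppingAmplitudeHu = 0, blurSigmaMm = 0, noiseSd = 0,
                         fovDiameterMm = 150)
  cbct <- simulateCBCT(ctVolume(tr), tripletLabels(tr), deg)
  d <- dim(volData(cbct))
  cs <- dualsct:::gridCoords(d, voxelSpacing(ctVolume(tr)))
  co <- dualsct:::coordArrays(cs, d)
  outside <- (co$x^2 + co$y^2) > 75^2
  expect_true(all(volData(cbct)[outside] == -1024))
  # +80 HU soft-tissue-only offset shows up as the masked mean difference
  deg80 <- cbctDegradation(huOffset = c(soft_tissue = 80, skull = 0, brain = 0,
                                        ventricle = 0, eye = 0, lens = 0,
                                        optic_nerve = 0),
                           cuppingAmplitudeHu = 0, blurSigmaMm = 0,
                           noiseSd = 0, fovDiameterMm = 1e4)
  cb80 <- simulateCBCT(ctVolume(tr), tripletLabels(tr), deg80)
  soft <- volData(tripletLabels(tr)) == 1L
  expect_equal(mean((volData(cb80) - volData(ctVolume(tr)))[soft]), 80,
               tolerance = 1e-9)
  expect_error(simulateCBCT(ctVolume(tr), tripletLabels(tr),
                            cbctDegradation(fovDiameterMm = -1)))
})

test_that("simulated MRI has T1 contrast, bounded bias field and CSF < brain", {
  labs <- generateLabelVolume(tinySpec())
  flat <- simulateT1Mri(labs, biasFieldAmplitude = 0, noiseSd = 0)
  lab <- volData(labs)
  expect_true(all(volData(flat)[lab == 3] == 100))
  expect_true(all(volData(flat)[lab == 4] == 25))
  expect_error(simulateT1Mri(labs, contrastTable = c(defaultMriContrast()[-2],
                                                     soft_tissue = -5)),
               "negative")
  # bias amplitude 0.2 keeps the in-head intensity ratio of a uniform class
  biased <- simulateT1Mri(labs, biasFieldAmplitude = 0.2, noiseSd = 0, seed = 3)
  brain <- volData(biased)[lab == 3]
  expect_lte(max(brain) / min(brain), 1.5 + 1e-9)
})

test_that("MRI carries the ventricle/brain contrast the CBCT lacks", {
  tr <- cachedTriplet()
  lab <- volData(tripletLabels(tr))
  gapOverNoise <- function(v) {
    abs(mean(v[lab == 3]) - mean(v[lab == 4])) /
      (stats::sd(v[lab == 3]) + 1e-12)
  }
  expect_gt(gapOverNoise(volData(mriVolume(tr))),
            gapOverNoise(volData(cbctVolume(tr))))
})

test_that("masked CBCT error is non-decreasing in each degradation amplitude", {
  tr <- cachedTriplet()
  head <- volData(tripletLabels(tr)) > 0
  # sweep one degradation at a time with the per-tissue corruption disabled
  # (a tissue offset can partially cancel a cupping shift)
  nm <- names(labelCodes())
  noAffine <- list(huScale = setNames(rep(1, 9), nm),
                   huOffset = setNames(rep(0, 9), nm))
  mk <- function(...) do.call(cbctDegradation,
                              c(noAffine, list(...), fovDiameterMm = 1e4))
  sweep1 <- list(
    cupping = lapply(c(0, 40, 120), function(a)
      mk(cuppingAmplitudeHu = a, blurSigmaMm = 0, noiseSd = 0)),
    noise = lapply(c(0, 15, 60), function(a)
      mk(cuppingAmplitudeHu = 0, blurSigmaMm = 0, noiseSd = a)),
    blur = lapply(c(0, 2, 6), function(a)
      mk(cuppingAmplitudeHu = 0, blurSigmaMm = a, noiseSd = 0)))
  for (sweep in sweep1) {
    maes <- vapply(sweep, function(deg) {
      cb <- simulateCBCT(ctVolume(tr), tripletLabels(tr), deg, seed = 4)
      maskedMAE(cb, ctVolume(tr), head)
    }, 0)
    expect_true(all(diff(maes) >= -1e-9))
  }
})

test_that("makeDataset writes a consistent manifest with shared per-patient MRI", {
  outDir <- file.path(tempdir(), "dsct_ds")
  unlink(outDir, recursive = TRUE)
  man <- makeDataset(2, 3, tinySpec(), outDir)
  expect_equal(nrow(man), 6)
  expect_equal(length(unique(man$mri)), 2)
  expect_true(all(file.exists(man$ct, man$cbct, man$mri, man$labels)))
  # determinism: byte-identical payloads on re-run
  v1 <- readVolume(man$ct[1])
  outDir2 <- file.path(tempdir(), "dsct_ds2")
  unlink(outDir2, recursive = TRUE)
  man2 <- makeDataset(2, 3, tinySpec(), outDir2)
  v2 <- readVolume(man2$ct[1])
  expect_identical(volData(v1), volData(v2))
  unlink(c(outDir, outDir2), recursive = TRUE)
})

test_that("a 27-patient cohort at tiny grids runs with unique patient ids", {
  spec <- phantomSpec(gridShape = c(8L, 8L, 8L), spacingMm = c(24, 24, 16),
                      headAxesMm = c(80, 90, 55), seed = 2L, jitterFrac = 0.02)
  cohort <- simulateCohort(27, 1, spec)
  expect_equal(length(unique(cohort$patientId)), 27)
})
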