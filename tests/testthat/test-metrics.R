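test_that("masked MAE/PSNR agree with brute-force oracles on random volumes", {
  for (s in 1:6) {
    set.seed(s)
    d <- c(9, 9, 9)
    a <- array(runif(prod(d), -1000, 2000), d)
    b <- a + array(rnorm(prod(d), 0, 50), d)
    m <- array(runif(prod(d)) > 0.4, d)
    expect_equal(maskedMAE(a, b, m), bruteMae(a, b, m), tolerance = 1e-6)
    expect_equal(maskedPSNR(a, b, m), brutePsnr(a, b, m), tolerance = 1e-6)
  }
  a <- array(runif(27), c(3, 3, 3)); m <- array(TRUE, c(3, 3, 3))
  expect_equal(maskedMAE(a, a, m), 0)
  expect_equal(maskedMAE(a, a + 10, m), 10)
  expect_identical(maskedPSNR(a, a, m), Inf)
  # masked MSE equal to dataRange^2 gives 0 dB
  z <- array(0, c(3, 3, 3))
  expect_equal(maskedPSNR(z, z + 4096, m), 0)
  expect_error(maskedPSNR(a, a, array(FALSE, c(3, 3, 3))), "empty")
})

test_that("masked SSIM matches a sliding-window reference and its limits", {
  set.seed(7)
  d <- c(9, 9, 9)
  a <- array(runif(prod(d), 0, 2000), d)
  b <- a + array(rnorm(prod(d), 0, 100), d)
  m <- array(TRUE, d)
  expect_equal(maskedSSIM(a, b, m), bruteSsim(a, b, m), tolerance = 1e-6)
  expect_equal(maskedSSIM(a, a, m), 1)
  # anticorrelation on a zero-mean patch drives local SSIM <= 0
  p <- array(rnorm(343, 0, 800), c(7, 7, 7))
  p <- p - mean(p)
  expect_lte(maskedSSIM(p, -p, array(TRUE, c(7, 7, 7)), dataRange = 100), 0)
  expect_error(maskedSSIM(a[1:5, 1:5, 1:5], b[1:5, 1:5, 1:5],
                          m[1:5, 1:5, 1:5]), "window")
})

test_that("metrics are computed strictly inside the mask", {
  tr <- cachedTriplet()
  ct <- volData(ctVolume(tr))
  sct <- ct + array(rnorm(length(ct), 0, 30), dim(ct))
  mask <- array(volData(tripletLabels(tr)) %in% c(3L, 4L),
                dim(volData(tripletLabels(tr))))
  before <- c(maskedMAE(sct, ct, mask), maskedPSNR(sct, ct, mask),
              maskedSSIM(sct, ct, mask))
  # corrupt background voxels beyond the reach of any mask-centered SSIM
  # window (9 six-neighbor dilations cover the 7^3 window corners)
  far <- mask
  for (rep in 1:9) {
    d <- dim(far); g <- far
    g[2:d[1], , ] <- g[2:d[1], , ] | far[1:(d[1] - 1), , ]
    g[1:(d[1] - 1), , ] <- g[1:(d[1] - 1), , ] | far[2:d[1], , ]
    g[, 2:d[2], ] <- g[, 2:d[2], ] | far[, 1:(d[2] - 1), ]
    g[, 1:(d[2] - 1), ] <- g[, 1:(d[2] - 1), ] | far[, 2:d[2], ]
    g[, , 2:d[3]] <- g[, , 2:d[3]] | far[, , 1:(d[3] - 1)]
    g[, , 1:(d[3] - 1)] <- g[, , 1:(d[3] - 1)] | far[, , 2:d[3]]
    far <- g
  }
  corrupted <- sct
  corrupted[!far & volData(tripletLabels(tr)) == 0L] <- 3000
  after <- c(maskedMAE(corrupted, ct, mask), maskedPSNR(corrupted, ct, mask),
             maskedSSIM(corrupted, ct, mask))
  expect_equal(before, after, tolerance = 1e-12)
})

test_that("HU error maps and difference histograms conserve mask counts", {
  tr <- cachedTriplet()
  ct <- ctVolume(tr)
  expect_true(all(volData(huErrorMap(ct, ct)) == 0))
  mask <- volData(tripletLabels(tr)) > 0
  h0 <- huDifferenceHistogram(ct, ct, mask)
  expect_equal(sum(h0$counts), sum(mask))
  zeroBin <- findInterval(0, h0$edges)
  expect_equal(h0$counts[zeroBin], sum(mask))
  # mid-bin shift (a shift on a bin edge splits on float rounding)
  shifted <- VolumeGrid(volData(ct) + 75, voxelSpacing(ct))
  h75 <- huDifferenceHistogram(shifted, ct, mask)
  expect_equal(h75$counts[findInterval(75, h75$edges)], sum(mask))
  set.seed(8)
  noisy <- VolumeGrid(volData(ct) + rnorm(length(volData(ct)), 0, 300),
                      voxelSpacing(ct))
  expect_equal(sum(huDifferenceHistogram(noisy, ct, mask)$counts), sum(mask))
})

test_that("Dice handles identity, disjoint, partial overlap and empty masks", {
  d <- c(6, 6, 6)
  a <- array(FALSE, d); a[1:3, 1:2, 1] <- TRUE
  expect_equal(diceCoefficient(a, a), 1)
  b <- array(FALSE, d); b[4:6, 5:6, 6] <- TRUE
  expect_equal(diceCoefficient(a, b), 0)
  a4 <- array(FALSE, d); a4[1:4, 1, 1] <- TRUE
  b4 <- array(FALSE, d); b4[3:6, 1, 1] <- TRUE
  expect_equal(diceCoefficient(a4, b4), 0.5)  # 2*2/(4+4)
  expect_equal(diceCoefficient(array(FALSE, d), array(FALSE, d)), 1)
})

test_that("Hausdorff distance matches the all-pairs brute-force oracle", {
  d <- c(8, 8, 8)
  a <- array(FALSE, d); a[2, 2, 2] <- TRUE
  b <- array(FALSE, d); b[7, 2, 2] <- TRUE
  expect_equal(hausdorffDistance(a, b, spacing = c(2, 2, 2)), 10)  # 5 voxels * 2 mm
  expect_equal(hausdorffDistance(a, a, spacing = c(1, 1, 1)), 0)
  for (s in 1:5) {
    set.seed(s)
    ra <- array(runif(prod(d)) > 0.8, d)
    rb <- array(runif(prod(d)) > 0.8, d)
    sp <- c(1, 1.5, 2)
    expect_equal(hausdorffDistance(ra, rb, sp), bruteHausdorff(ra, rb, sp),
                 tolerance = 1e-9)
  }
  expect_error(hausdorffDistance(a, array(FALSE, d)), "empty")
})

test_that("DSC and HD respond oppositely to progressive dilation", {
  tr <- cachedTriplet()
  base <- volData(tripletLabels(tr)) == 3L
  dilate <- function(m) {
    d <- dim(m); out <- m
    out[2:d[1], , ] <- out[2:d[1], , ] | m[1:(d[1] - 1), , ]
    out[1:(d[1] - 1), , ] <- out[1:(d[1] - 1), , ] | m[2:d[1], , ]
    out
  }
  dscs <- hds <- numeric(3)
  cur <- base
  for (i in 1:3) {
    cur <- dilate(cur)
    dscs[i] <- diceCoefficient(cur, base)
    hds[i] <- hausdorffDistance(cur, base, voxelSpacing(ctVolume(tr)))
  }
  expect_true(all(diff(dscs) < 0))
  # coarse jagged surfaces can keep HD flat for one step, never decreasing
  expect_true(all(diff(hds) >= 0))
  expect_gt(hds[3], hds[1])
})

test_that("delineation report scores organs and flags missing ones", {
  tr <- cachedTriplet()
  labs <- tripletLabels(tr)
  rep0 <- delineationReport(labs, labs)
  scored <- rep0[!rep0$flagged, ]
  expect_true(all(scored$dsc == 1))
  expect_true(all(scored$hdMm == 0))
  # dilate one organ by a voxel along x: DSC < 1, HD = x spacing
  lab2 <- volData(labs)
  vent <- lab2 == 4L
  d <- dim(lab2)
  grown <- vent
  grown[2:d[1], , ] <- grown[2:d[1], , ] | vent[1:(d[1] - 1), , ]
  lab2[grown & lab2 == 3L] <- 4L
  rep1 <- delineationReport(LabelVolume(VolumeGrid(lab2, voxelSpacing(labs),
                                                   labelGrid(labs)@origin)),
                            labs, organs = "ventricle")
  expect_lt(rep1$dsc, 1)
  expect_equal(rep1$hdMm, voxelSpacing(labs)[1])
  # missing organ: flagged, not silently scored
  lab3 <- volData(labs); lab3[lab3 == 6L] <- 5L
  rep2 <- delineationReport(LabelVolume(VolumeGrid(lab3, voxelSpacing(labs),
                                                   labelGrid(labs)@origin)),
                            labs, organs = c("ventricle", "lens"))
  expect_true(rep2$flagged[rep2$organ == "lens"])
  expect_false(rep2$flagged[rep2$organ == "ventricle"])
})

test_that("paired signed-rank test matches the exact enumerated tail", {
  x <- c(5.1, 6.2, 4.8, 5.9, 6.6, 5.2, 4.9, 6.1, 5.7, 5.4)
  y <- x + 1  # constant positive shift, n = 10
  res <- pairedModelComparison(y, x)
  # enumerate all 2^10 sign assignments of ranks to get the exact two-sided p
  n <- 10
  ranks <- 1:n
  vmax <- sum(ranks)
  counts <- integer(vmax + 1)
  for (bits in 0:(2^n - 1)) {
    v <- sum(ranks[bitwAnd(bits, 2^(0:(n - 1))) > 0])
    counts[v + 1] <- counts[v + 1] + 1
  }
  pExact <- 2 * sum(counts[(vmax + 1)]) / 2^n  # all-positive => V = 55
  expect_equal(res$pValue, pExact, tolerance = 1e-12)
  expect_equal(res$statistic, vmax)
  # antisymmetry: swapped inputs give the same p, mirrored statistic
  swapped <- pairedModelComparison(x, y)
  expect_equal(swapped$pValue, res$pValue, tolerance = 1e-12)
  expect_equal(swapped$statistic, 0)
  # degenerate: all differences zero
  degen <- pairedModelComparison(x, x)
  expect_true(degen$degenerate)
  expect_error(pairedModelComparison(1:3, 2:4), "n >= 5")
})

test_that("cohort summary is the unweighted mean of per-volume values", {
  df <- data.frame(maeHu = c(10, 20, 30), ssim = c(0.9, 0.8, 1.0))
  cs <- cohortSummary(df)
  expect_equal(cs$mean[cs$metric == "maeHu"], 20)
  expect_equal(cs$sd[cs$metric == "ssim"], sd(c(0.9, 0.8, 1.0)))
})
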