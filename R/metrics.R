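# ---------------------------------------------------------------------------
# Masked image-quality metrics, HU error maps/histograms, delineation
# overlap metrics, and the paired signed-rank model comparison.
#
# All metrics are computed strictly inside the supplied mask — background is
# never scored.
# ---------------------------------------------------------------------------

.asArr <- function(x) {
  if (is(x, "VolumeGrid")) return(x@data)
  if (is(x, "LabelVolume")) return(x@grid@data)
  x
}

.asMask <- function(x) {
  m <- .asArr(x)
  if (is.list(m) && !is.null(m$mask)) m <- m$mask
  storage.mode(m) <- "logical"
  m
}

#' Build a named region mask from a label volume
#'
#' Supported names: `whole_head`, `brain_tissue` (brain + ventricles),
#' `skull`, `nasal_cavities`, `ventricles`, `eyes` (incl. lenses), `lenses`,
#' `optic_nerves`, `soft_tissue`.
#'
#' @param labels A [LabelVolume-class].
#' @param name Region name.
#' @return `list(mask = <logical array>, name = name)`.
#' @export
regionMask <- function(labels, name) {
  lab <- .asArr(labels)
  codes <- labelCodes()
  sel <- switch(name,
    whole_head = lab > 0,
    brain_tissue = lab %in% codes[c("brain", "ventricle")],
    skull = lab == codes[["skull"]],
    nasal_cavities = lab == codes[["nasal_cavity"]],
    ventricles = lab == codes[["ventricle"]],
    eyes = lab %in% codes[c("eye", "lens")],
    lenses = lab == codes[["lens"]],
    optic_nerves = lab == codes[["optic_nerve"]],
    soft_tissue = lab == codes[["soft_tissue"]],
    stop("unknown region name: ", name))
  sel <- array(sel, dim(lab))
  list(mask = sel, name = name)
}

#' Brain-tissue mask from HU values
#'
#' When no labels exist, "brain tissue" defaults to head voxels above a HU
#' threshold (excluding air); configurable.
#'
#' @param ct CT [VolumeGrid-class].
#' @param thresholdHu HU floor (default -200).
#' @return `list(mask, name)`.
#' @export
huBrainMask <- function(ct, thresholdHu = -200) {
  list(mask = .asArr(ct) > thresholdHu, name = "brain_tissue")
}

#' Masked mean absolute error (HU)
#' @param a,b Volumes or arrays in HU.
#' @param mask Region mask (logical array or [regionMask()] result).
#' @return MAE in HU over the mask.
#' @export
maskedMAE <- function(a, b, mask) {
  lossMae(.asArr(a), .asArr(b), .asMask(mask))
}

#' Masked peak signal-to-noise ratio (dB)
#'
#' `10 log10(dataRange^2 / MSE)` over the mask; identical inputs return
#' `Inf`.
#'
#' @inheritParams maskedMAE
#' @param dataRange Dynamic range; default 4096 HU (the clipped CT range).
#' @return PSNR in dB.
#' @export
maskedPSNR <- function(a, b, mask, dataRange = 4096) {
  stopifnot(dataRange > 0)
  m <- .asMask(mask)
  if (sum(m) == 0) stop("empty mask in maskedPSNR")
  mse <- sum(((.asArr(a) - .asArr(b))^2) * m) / sum(m)
  if (mse == 0) return(Inf)
  10 * log10(dataRange^2 / mse)
}

# 3D box sums via cumulative sums (summed-area table).
.boxSum <- function(x, w) {
  for (axis in 1:3) {
    cs <- apply(x, setdiff(1:3, axis), cumsum)
    cs <- aperm(cs, order(c(axis, setdiff(1:3, axis))))
    d <- dim(x)[axis]
    n <- d - w + 1
    idx <- function(i) switch(axis,
      cs[i, , , drop = FALSE], cs[, i, , drop = FALSE], cs[, , i, drop = FALSE])
    hi <- idx(w:d)
    x <- if (w < d + 1 && n > 1) hi - abind0(idx(1:(n - 1)), axis) else hi
  }
  x
}

# prepend a zero slab along `axis` (helper for .boxSum differences)
abind0 <- function(x, axis) {
  p <- c(axis, setdiff(1:3, axis))
  xz <- aperm(x, p)
  dd <- dim(xz); dd[1] <- dd[1] + 1
  comb <- array(0, dd)
  comb[-1, , ] <- xz
  aperm(comb, order(p))
}

#' Masked structural similarity index (3D)
#'
#' Mean local SSIM over cubic windows whose centers lie inside the mask
#' (windows fully inside the volume). Uniform window, standard constants.
#'
#' @inheritParams maskedPSNR
#' @param window Odd cubic window side (default 7).
#' @param k1,k2 SSIM stability constants (defaults 0.01 / 0.03).
#' @return Scalar in [-1, 1].
#' @export
maskedSSIM <- function(a, b, mask, window = 7L, k1 = 0.01, k2 = 0.03,
                       dataRange = 4096) {
  a <- .asArr(a); b <- .asArr(b); m <- .asMask(mask)
  d <- dim(a)
  if (any(d < window)) stop("volume smaller than SSIM window")
  w3 <- window^3
  mu_a <- .boxSum(a, window) / w3
  mu_b <- .boxSum(b, window) / w3
  saa <- .boxSum(a * a, window) / w3
  sbb <- .boxSum(b * b, window) / w3
  sab <- .boxSum(a * b, window) / w3
  va <- saa - mu_a^2; vb <- sbb - mu_b^2; cab <- sab - mu_a * mu_b
  c1 <- (k1 * dataRange)^2; c2 <- (k2 * dataRange)^2
  ssim <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  # window centers: offset (window-1)/2 from each face
  r <- (window - 1L) %/% 2L
  centerMask <- m[(r + 1):(d[1] - r), (r + 1):(d[2] - r), (r + 1):(d[3] - r),
                  drop = FALSE]
  if (sum(centerMask) == 0) stop("mask has no valid SSIM window centers")
  mean(ssim[centerMask])
}

#' Signed HU error map
#' @param sct,ct Aligned volumes in HU.
#' @return A [VolumeGrid-class] of `sct - ct`.
#' @export
huErrorMap <- function(sct, ct) {
  stopifnot(all(dim(.asArr(sct)) == dim(.asArr(ct))))
  g <- if (is(ct, "VolumeGrid")) ct else VolumeGrid(.asArr(ct))
  VolumeGrid(.asArr(sct) - .asArr(ct), g@spacing, g@origin, g@orientation)
}

#' Histogram of HU differences over a mask
#'
#' Differences are clamped into the outer bins so the total count equals the
#' mask voxel count.
#'
#' @inheritParams huErrorMap
#' @param mask Region mask.
#' @param binEdges Bin edges; default 50-HU bins spanning -1000..1000.
#' @return `list(counts, edges, mids)`.
#' @export
huDifferenceHistogram <- function(sct, ct, mask,
                                  binEdges = seq(-1000, 1000, by = 50)) {
  m <- .asMask(mask)
  d <- (.asArr(sct) - .asArr(ct))[m]
  eps <- diff(range(binEdges)) * 1e-12
  d <- pmin(pmax(d, binEdges[1] + eps), binEdges[length(binEdges)] - eps)
  idx <- findInterval(d, binEdges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(binEdges) - 1)
  list(counts = counts, edges = binEdges,
       mids = (binEdges[-1] + binEdges[-length(binEdges)]) / 2)
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks are defined as DSC 1.
#'
#' @param segA,segB Boolean masks on the same grid.
#' @return Scalar in [0, 1].
#' @export
diceCoefficient <- function(segA, segB) {
  a <- .asMask(segA); b <- .asMask(segB)
  stopifnot(all(dim(a) == dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Surface voxels: mask voxels with a 6-neighbor outside the mask (volume
# boundary counts as outside).
.surfaceVoxels <- function(m) {
  d <- dim(m)
  p <- array(FALSE, d + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- p[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
        p[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
        p[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
        p[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
        p[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
        p[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  which(core & !nb, arr.ind = TRUE)
}

#' Hausdorff distance between two segmentations (mm)
#'
#' Symmetric maximum (or percentile, e.g. HD95) of directed
#' surface-to-surface distances, in mm via the voxel spacing.
#'
#' @param segA,segB Nonempty boolean masks on the same grid.
#' @param spacing Voxel spacing in mm (numeric(3)).
#' @param percentile Percentile of directed distances in (0, 100];
#'   100 = exact Hausdorff.
#' @return Distance in mm.
#' @export
hausdorffDistance <- function(segA, segB, spacing = c(1, 1, 1),
                              percentile = 100) {
  a <- .asMask(segA); b <- .asMask(segB)
  stopifnot(all(dim(a) == dim(b)))
  if (sum(a) == 0 || sum(b) == 0) stop("empty mask in hausdorffDistance")
  if (percentile <= 0 || percentile > 100) stop("percentile must be in (0, 100]")
  pa <- sweep(.surfaceVoxels(a), 2, spacing, `*`)
  pb <- sweep(.surfaceVoxels(b), 2, spacing, `*`)
  dab <- .cpp_min_dists(pa, pb)
  dba <- .cpp_min_dists(pb, pa)
  dir <- function(dv) if (percentile == 100) max(dv)
         else unname(stats::quantile(dv, percentile / 100, type = 7))
  max(dir(dab), dir(dba))
}

#' Per-organ delineation report (DSC / Hausdorff)
#'
#' The CT-derived labels are the ground truth; organs absent from either
#' volume are flagged, never silently scored.
#'
#' @param sctLabels,ctLabels [LabelVolume-class] objects on the same grid.
#' @param organs Character vector of organ names (see [labelCodes()]).
#' @param percentile Hausdorff percentile.
#' @return data.frame with organ, presence flags, dsc, hdMm.
#' @export
delineationReport <- function(sctLabels, ctLabels,
                              organs = c("brain", "ventricle", "eye", "lens",
                                         "optic_nerve", "skull"),
                              percentile = 100) {
  codes <- labelCodes()
  sp <- voxelSpacing(ctLabels)
  sl <- .asArr(sctLabels); cl <- .asArr(ctLabels)
  rows <- lapply(organs, function(o) {
    code <- codes[[o]]
    a <- sl == code; b <- cl == code
    inS <- sum(a) > 0; inC <- sum(b) > 0
    if (!inS || !inC)
      return(data.frame(organ = o, inSct = inS, inCt = inC,
                        dsc = NA_real_, hdMm = NA_real_, flagged = TRUE))
    data.frame(organ = o, inSct = TRUE, inCt = TRUE,
               dsc = diceCoefficient(a, b),
               hdMm = hausdorffDistance(a, b, sp, percentile), flagged = FALSE)
  })
  do.call(rbind, rows)
}

#' Paired Wilcoxon signed-rank comparison of two models
#'
#' Two-sided paired signed-rank test on per-subject metric values. For
#' n <= 25 nonzero differences the exact permutation distribution of the
#' signed-rank statistic is computed (midranks for tied magnitudes, zeros
#' discarded); larger samples fall back to the normal approximation.
#'
#' @param metricValuesModel1,metricValuesModel2 Paired numeric vectors
#'   (n >= 5).
#' @return `list(statistic, pValue, n, degenerate, method)`; when every
#'   paired difference is zero a degenerate-case report is returned
#'   (`pValue = NA`).
#' @export
pairedModelComparison <- function(metricValuesModel1, metricValuesModel2) {
  x <- metricValuesModel1; y <- metricValuesModel2
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 5) stop("paired comparison requires n >= 5")
  d <- x - y
  if (all(d == 0))
    return(list(statistic = NA_real_, pValue = NA_real_, n = n,
                degenerate = TRUE, method = "all paired differences zero"))
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (m <= 25) {
    # exact distribution of 2V by dynamic programming over doubled midranks
    w <- round(2 * r)
    total <- sum(w)
    probs <- numeric(total + 1)
    probs[1] <- 1
    for (wi in w) {
      shifted <- c(rep(0, wi), probs[seq_len(total + 1 - wi)])
      probs <- (probs + shifted) / 2
    }
    v2 <- round(2 * V)
    pLow <- sum(probs[seq_len(v2 + 1)])
    pHigh <- sum(probs[(v2 + 1):(total + 1)])
    p <- min(1, 2 * min(pLow, pHigh))
    method <- "exact Wilcoxon signed rank (permutation)"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = FALSE))
    p <- wt$p.value
    method <- wt$method
  }
  list(statistic = V, pValue = p, n = n, degenerate = FALSE, method = method)
}

#' Cohort summary of per-volume metrics
#'
#' Unweighted mean and standard deviation of each numeric metric column over
#' volumes (the cohort mean is the mean of per-volume values).
#'
#' @param perVolume data.frame of per-volume metric values.
#' @return data.frame with metric, mean, sd, n.
#' @export
cohortSummary <- function(perVolume) {
  num <- vapply(perVolume, is.numeric, TRUE)
  cols <- names(perVolume)[num]
  do.call(rbind, lapply(cols, function(cn) {
    v <- perVolume[[cn]]
    data.frame(metric = cn, mean = mean(v), sd = stats::sd(v), n = length(v))
  }))
}

#' Mean absolute discrete Laplacian of a volume
#'
#' A sharpness surrogate: the 6-neighbor Laplacian magnitude averaged over
#' interior voxels of the mask.
#'
#' @param vol Volume or array.
#' @param mask Optional mask; default all interior voxels.
#' @return Scalar sharpness value (HU per voxel^2 for HU input).
#' @export
meanAbsLaplacian <- function(vol, mask = NULL) {
  v <- .asArr(vol)
  d <- dim(v)
  i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
  lap <- v[i - 1, j, k] + v[i + 1, j, k] + v[i, j - 1, k] + v[i, j + 1, k] +
    v[i, j, k - 1] + v[i, j, k + 1] - 6 * v[i, j, k]
  if (is.null(mask)) return(mean(abs(lap)))
  m <- .asMask(mask)[i, j, k]
  if (sum(m) == 0) stop("empty interior mask in meanAbsLaplacian")
  mean(abs(lap)[m])
}
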