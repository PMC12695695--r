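# ---------------------------------------------------------------------------
# HU -> stopping-power-ratio conversion, SPR relative error, and a
# simplified straight-ray proton range engine.
#
# The engine replaces a clinical treatment-planning dose calculation with an
# analytic Bragg curve evaluated at the water-equivalent path length (WEPL)
# of each depth sample: no scatter, no lateral spread, no nuclear halo.
# Distal-R80 geometry is faithful under these assumptions; absolute dose is
# not.
# ---------------------------------------------------------------------------

#' Default HU-to-SPR calibration curve
#'
#' A small piecewise-linear table anchored at air (-1024 -> 0.001), water
#' (0 -> 1.0) and dense bone (1500 -> 1.6), shipped with the package as a
#' configurable synthetic stand-in for a clinical calibration.
#'
#' @return An [SprCurve-class].
#' @export
defaultSprCurve <- function() {
  readSprCurve(system.file("extdata", "spr_default.csv", package = "dualsct",
                           mustWork = TRUE), provenance = "package default")
}

#' Read an SPR calibration from a two-column CSV
#'
#' @param path CSV with header columns `hu` and `spr`.
#' @param provenance Text tag stored on the curve.
#' @return An [SprCurve-class].
#' @export
readSprCurve <- function(path, provenance = path) {
  tab <- utils::read.csv(path)
  if (!all(c("hu", "spr") %in% names(tab)))
    stop("SPR curve file must have header columns 'hu' and 'spr'")
  sprCurve(tab$hu, tab$spr, provenance = provenance)
}

#' Convert a HU volume to stopping-power ratios
#'
#' Piecewise-linear interpolation between calibration nodes; HU outside the
#' node range clamp to the end SPR values.
#'
#' @param vol HU [VolumeGrid-class] (or array).
#' @param curve An [SprCurve-class].
#' @return SPR volume (same type as input).
#' @export
huToSpr <- function(vol, curve = defaultSprCurve()) {
  stopifnot(validObject(curve))
  arr <- .asArr(vol)
  spr <- array(stats::approx(curve@hu, curve@spr, xout = as.vector(arr),
                             rule = 2)$y, dim(arr))
  if (is(vol, "VolumeGrid"))
    VolumeGrid(spr, vol@spacing, vol@origin, vol@orientation)
  else spr
}

#' Mean SPR relative error between a synthetic and a reference CT
#'
#' `mean(|SPR(sct) - SPR(ct)| / SPR(ct)) * 100` over mask voxels whose
#' reference SPR is at least `floor` (keeps the ratio defined in air).
#'
#' @param sct,ct Aligned HU volumes.
#' @param curve An [SprCurve-class].
#' @param mask Region mask.
#' @param floor Reference-SPR floor (default 0.1).
#' @return `list(percent = scalar, map = relative-error array in percent)`.
#' @export
sprRelativeError <- function(sct, ct, curve = defaultSprCurve(), mask,
                             floor = 0.1) {
  ss <- huToSpr(.asArr(sct), curve)
  sc <- huToSpr(.asArr(ct), curve)
  m <- .asMask(mask) & sc >= floor
  if (sum(m) == 0) stop("empty mask after SPR floor in sprRelativeError")
  remap <- abs(ss - sc) / sc * 100
  list(percent = mean(remap[m]), map = remap, mask = m)
}

# Ray entry: first in-volume sample parameter for a world ray p + t*d, in mm.
.rayBoxRange <- function(vol, point, dir) {
  # transform to continuous voxel coordinates (orientation orthonormal)
  d <- dim(vol@data)
  toVox <- function(p) as.vector(t(vol@orientation) %*% (p - vol@origin)) / vol@spacing
  p0 <- toVox(point)
  dv <- as.vector(t(vol@orientation) %*% dir) / vol@spacing
  tmin <- -Inf; tmax <- Inf
  for (a in 1:3) {
    if (abs(dv[a]) < 1e-12) {
      if (p0[a] < 0 || p0[a] > d[a] - 1) return(NULL)
    } else {
      t1 <- (0 - p0[a]) / dv[a]; t2 <- (d[a] - 1 - p0[a]) / dv[a]
      tmin <- max(tmin, min(t1, t2)); tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin > tmax) return(NULL)
  c(tmin, tmax)
}

#' Cumulative water-equivalent path length along a ray
#'
#' `WEPL(d) = integral of SPR` along the ray, by midpoint-sampled
#' accumulation with trilinear (or nearest) lookup.
#'
#' @param sprVol SPR [VolumeGrid-class].
#' @param entryMm World coordinate where the ray enters (must be inside the
#'   volume).
#' @param directionMm Unit direction vector.
#' @param stepMm Sampling step; must not exceed the smallest voxel size.
#' @param maxDepthMm Optional maximum geometric depth (defaults to the exit
#'   of the volume).
#' @param interpolation `"linear"` or `"nearest"`.
#' @return `list(depths, wepl)`: geometric depths (mm) and cumulative WEPL.
#' @export
weplProfile <- function(sprVol, entryMm, directionMm,
                        stepMm = min(voxelSpacing(sprVol)),
                        maxDepthMm = NULL,
                        interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (stepMm > min(sprVol@spacing) + 1e-9)
    stop("stepMm must not exceed the smallest voxel size")
  dir <- directionMm / sqrt(sum(directionMm^2))
  rng <- .rayBoxRange(sprVol, entryMm, dir)
  if (is.null(rng) || rng[1] > 1e-6 || rng[2] < 0)
    stop("entry point outside the volume support")
  L <- if (is.null(maxDepthMm)) rng[2] else min(maxDepthMm, rng[2])
  n <- max(1L, floor(L / stepMm))
  mids <- (seq_len(n) - 0.5) * stepMm
  pts <- outer(mids, dir)
  pts <- sweep(pts, 2, entryMm, `+`)
  vox <- sweep(sweep(pts %*% sprVol@orientation, 2,
                     as.vector(t(sprVol@orientation) %*% sprVol@origin), `-`),
               2, sprVol@spacing, `/`)
  spr <- .cpp_sample_trilinear(sprVol@data, vox, 0,
                               interpolation == "nearest")
  list(depths = seq_len(n) * stepMm, wepl = cumsum(spr) * stepMm)
}

#' Analytic normalized Bragg curve on a WEPL axis
#'
#' An asymmetric-Gaussian depth-dose model: a low entrance plateau rising to
#' a single Bragg peak with a sharp distal falloff whose 80% crossing sits
#' exactly at `r80WaterMm`. All widths scale with `r80WaterMm`, so doubling
#' the energy (expressed as water range) exactly doubles the distal
#' crossing.
#'
#' @param weplAxis Water-equivalent depths (mm) at which to evaluate.
#' @param r80WaterMm Distal R80 in water for the nominal energy.
#' @return Dose values normalized to peak 1.
#' @export
braggCurve <- function(weplAxis, r80WaterMm) {
  stopifnot(r80WaterMm > 0)
  sigmaD <- 0.015 * r80WaterMm
  sigmaP <- 7 * sigmaD
  peak <- r80WaterMm - sigmaD * sqrt(2 * log(0.7 / 0.5))
  sigma <- ifelse(weplAxis < peak, sigmaP, sigmaD)
  0.3 + 0.7 * exp(-((weplAxis - peak)^2) / (2 * sigma^2))
}

#' Compute one 1x1 mm dose line through the volume
#'
#' Samples geometric depth on the beam's dose grid, converts to WEPL,
#' evaluates the analytic Bragg curve, and normalizes the line to its own
#' maximum (the Bragg-peak sample). Lines whose peak or distal falloff is
#' not contained in the volume are flagged invalid.
#'
#' @param sprVol SPR [VolumeGrid-class].
#' @param entryMm World entry point of the beamlet ray (inside the volume).
#' @param beam A [BeamSpec-class].
#' @return A [DoseLine-class].
#' @export
computeDoseLine <- function(sprVol, entryMm, beam) {
  wp <- weplProfile(sprVol, entryMm, beam@direction, stepMm = beam@doseGridMm,
                    interpolation = "linear")
  dose <- braggCurve(wp$wepl, beam@r80WaterMm)
  pk <- which.max(dose)
  valid <- pk > 1 && pk < length(dose) && any(dose[pk:length(dose)] < 0.8 * dose[pk])
  dose <- dose / max(dose)
  new("DoseLine", depths = wp$depths, dose = dose, valid = valid)
}

#' Extract the distal R80 depth of a dose line (mm)
#'
#' Depth of the last downward crossing of 80% of the peak beyond the peak
#' sample, located by linear interpolation between bracketing samples.
#'
#' @param line A [DoseLine-class].
#' @return Depth in mm.
#' @export
extractDistalR80 <- function(line) {
  dose <- line@dose; depths <- line@depths
  pk <- which.max(dose)
  thr <- 0.8 * dose[pk]
  if (pk >= length(dose) || all(dose[(pk + 1):length(dose)] >= thr))
    stop("invalid dose line: no distal crossing below 80% of peak")
  after <- pk:length(dose)
  cross <- after[which(dose[after] >= thr &
                       c(dose[after][-1], Inf) < thr)]
  i <- cross[length(cross)]
  frac <- (dose[i] - thr) / (dose[i] - dose[i + 1])
  depths[i] + frac * (depths[i + 1] - depths[i])
}

# Orthonormal lateral basis perpendicular to the beam direction.
.lateralBasis <- function(dir) {
  ref <- if (abs(dir[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  u <- ref - sum(ref * dir) * dir
  u <- u / sqrt(sum(u^2))
  v <- c(u[2] * dir[3] - u[3] * dir[2],
         u[3] * dir[1] - u[1] * dir[3],
         u[1] * dir[2] - u[2] * dir[1])
  list(u = u, v = v)
}

#' Compute the 2D distal-R80 map of a beam
#'
#' One dose line per 1x1 mm beamlet across the square field centered on the
#' isocenter; beamlets whose line never shows a distal falloff inside the
#' volume are masked invalid.
#'
#' @param sprVol SPR [VolumeGrid-class].
#' @param beam A [BeamSpec-class].
#' @return An [R80Map-class].
#' @export
computeR80Map <- function(sprVol, beam) {
  basis <- .lateralBasis(beam@direction)
  n <- round(beam@fieldSizeMm / beam@beamletGridMm)
  offsets <- (seq_len(n) - (n + 1) / 2) * beam@beamletGridMm
  values <- matrix(NA_real_, n, n)
  valid <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      center <- beam@isocenterMm + offsets[i] * basis$u + offsets[j] * basis$v
      rng <- .rayBoxRange(sprVol, center, beam@direction)
      if (is.null(rng)) next
      entry <- center + (rng[1] + 1e-6) * beam@direction
      line <- tryCatch(computeDoseLine(sprVol, entry, beam),
                       error = function(e) NULL)
      if (is.null(line) || !line@valid) next
      r80 <- tryCatch(extractDistalR80(line), error = function(e) NA_real_)
      if (is.finite(r80)) { values[i, j] <- r80; valid[i, j] <- TRUE }
    }
  }
  if (!any(valid)) stop("no valid beamlets in field")
  new("R80Map", values = values, valid = valid,
      beamletGridMm = beam@beamletGridMm)
}

#' Histogram and summary of R80 differences, normalized to the water range
#'
#' Per-beamlet error `(R80_sct - R80_ct) / r80WaterMm * 100` over the common
#' valid mask, with a fixed-bin histogram (default 0.1%-wide bins spanning
#' +/-5%) and a summary (mean, sd, fraction within +/-1%).
#'
#' @param mapSct,mapCt [R80Map-class] objects on the same beamlet grid.
#' @param r80WaterMm Water range of the beam energy.
#' @param binWidthPct,rangePct Histogram geometry in percent.
#' @return `list(errorsPct, counts, edges, meanPct, sdPct, fracWithin1Pct)`.
#' @export
r80DifferenceHistogram <- function(mapSct, mapCt, r80WaterMm,
                                   binWidthPct = 0.1, rangePct = 5) {
  stopifnot(all(dim(mapSct@values) == dim(mapCt@values)))
  common <- mapSct@valid & mapCt@valid
  if (!any(common)) stop("disjoint valid beamlet masks")
  err <- (mapSct@values[common] - mapCt@values[common]) / r80WaterMm * 100
  edges <- seq(-rangePct, rangePct, by = binWidthPct)
  eps <- rangePct * 1e-9
  clamped <- pmin(pmax(err, -rangePct + eps), rangePct - eps)
  counts <- tabulate(findInterval(clamped, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  list(errorsPct = err, counts = counts, edges = edges,
       meanPct = mean(err), sdPct = stats::sd(err),
       fracWithin1Pct = mean(abs(err) <= 1))
}

#' Dose volume for an axis-aligned beam
#'
#' For beams along a grid axis, accumulates WEPL down every voxel column,
#' evaluates the analytic Bragg curve, normalizes each in-field line to its
#' own maximum, and zeroes dose outside the square field. Used to drive
#' DVH-style analyses; not a clinical dose calculation.
#'
#' @param sprVol SPR [VolumeGrid-class].
#' @param beam A [BeamSpec-class] whose direction is (+/-) a grid axis.
#' @return Dose [VolumeGrid-class] (per-line normalized).
#' @export
doseVolumeFromBeam <- function(sprVol, beam) {
  dloc <- as.vector(t(sprVol@orientation) %*% beam@direction)
  axis <- which(abs(abs(dloc) - 1) < 1e-6)
  if (length(axis) != 1)
    stop("doseVolumeFromBeam requires an axis-aligned beam direction")
  sgn <- sign(dloc[axis])
  v <- sprVol@data
  d <- dim(v)
  perm <- c(axis, setdiff(1:3, axis))
  vp <- aperm(v, perm)
  if (sgn < 0) vp <- vp[rev(seq_len(dim(vp)[1])), , , drop = FALSE]
  step <- sprVol@spacing[axis]
  wepl <- apply(vp, c(2, 3), cumsum) * step
  dose <- braggCurve(wepl, beam@r80WaterMm)
  dim(dose) <- dim(vp)
  # per-line normalization to the Bragg peak sample
  mx <- apply(dose, c(2, 3), max)
  dose <- sweep(dose, c(2, 3), mx, `/`)
  # lateral field mask around the isocenter
  co <- coordArrays(gridCoords(d, sprVol@spacing), d)
  basis <- .lateralBasis(beam@direction)
  ctr <- beam@isocenterMm
  uoff <- (co$x - ctr[1]) * basis$u[1] + (co$y - ctr[2]) * basis$u[2] +
    (co$z - ctr[3]) * basis$u[3]
  voff <- (co$x - ctr[1]) * basis$v[1] + (co$y - ctr[2]) * basis$v[2] +
    (co$z - ctr[3]) * basis$v[3]
  half <- beam@fieldSizeMm / 2
  infield <- abs(uoff) <= half & abs(voff) <= half
  if (sgn < 0) dose <- dose[rev(seq_len(dim(dose)[1])), , , drop = FALSE]
  dose <- aperm(dose, order(perm))
  dose[!infield] <- 0
  VolumeGrid(dose, sprVol@spacing, sprVol@origin, sprVol@orientation)
}

#' Cumulative dose-volume histogram of a structure
#'
#' `V(>= D)`: the fraction of the structure receiving at least each dose
#' level; starts at 1 and reaches 0 beyond the maximum structure dose.
#'
#' @param doseVol Dose [VolumeGrid-class] or array (non-negative).
#' @param structure Region mask (nonempty).
#' @param doseBins Increasing dose axis starting at 0; default 200 levels up
#'   to 5% above the maximum structure dose.
#' @param structureName Name stored on the curve.
#' @return A [DvhCurve-class].
#' @export
computeDvh <- function(doseVol, structure, doseBins = NULL,
                       structureName = "structure") {
  dv <- .asArr(doseVol)
  if (any(dv < 0)) stop("dose must be non-negative")
  m <- .asMask(structure)
  if (sum(m) == 0) stop("empty structure in computeDvh")
  vals <- dv[m]
  if (is.null(doseBins))
    doseBins <- seq(0, max(vals) * 1.05 + 1e-9, length.out = 200)
  vol <- vapply(doseBins, function(b) mean(vals >= b), 0)
  new("DvhCurve", dose = doseBins, volume = vol, structure = structureName)
}

#' Write an R80 map as CSV
#' @param map An [R80Map-class].
#' @param path Output CSV path (values; invalid beamlets as NA).
#' @return Invisibly, `path`.
#' @export
writeR80Map <- function(map, path) {
  vals <- map@values
  vals[!map@valid] <- NA
  utils::write.csv(vals, path, row.names = FALSE)
  invisible(path)
}
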