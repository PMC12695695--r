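#' Default HU bounds used for CT/CBCT clipping and normalization
#' @return numeric(2): c(-1024, 3072).
#' @export
huBounds <- function() c(-1024, 3072)

#' Read a NIfTI-1 volume from disk
#'
#' Geometry (spacing, origin, orientation) is decoded from the sform affine.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [VolumeGrid-class].
#' @export
readVolume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("not a readable NIfTI file: ",
                                           path, " (", conditionMessage(e), ")",
                                           call. = FALSE))
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  M <- unclass(aff)[1:3, 1:3]
  spacing <- sqrt(colSums(M^2))
  if (any(spacing <= 0)) stop("malformed NIfTI header: non-positive spacing")
  orientation <- sweep(M, 2, spacing, `/`)
  data <- as.array(img)
  if (length(dim(data)) != 3L)
    stop("malformed NIfTI volume: expected 3 dimensions, got ",
         length(dim(data)))
  VolumeGrid(array(as.double(data), dim(data)), spacing = spacing,
             origin = unclass(aff)[1:3, 4], orientation = orientation)
}

#' Write a VolumeGrid as NIfTI-1
#'
#' Images are stored as float32, label volumes as uint8; the geometry is
#' carried in the sform (code 2).
#'
#' @param vol A [VolumeGrid-class] or [LabelVolume-class].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
writeVolume <- function(vol, path) {
  labels <- is(vol, "LabelVolume")
  if (labels) vol <- labelGrid(vol)
  aff <- rbind(cbind(vol@orientation %*% diag(vol@spacing), vol@origin),
               c(0, 0, 0, 1))
  img <- RNifti::asNifti(vol@data,
                         datatype = if (labels) "uint8" else "float")
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                 error = function(e) stop("cannot write NIfTI to ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Clip voxel values to bounds
#'
#' Every voxel `v` is replaced by `min(max(v, lo), hi)`; idempotent.
#'
#' @param vol A [VolumeGrid-class].
#' @param bounds numeric(2), `c(lo, hi)` with `hi > lo`; default the CT HU
#'   range `c(-1024, 3072)`.
#' @return The clipped [VolumeGrid-class].
#' @export
clipHU <- function(vol, bounds = huBounds()) {
  stopifnot(length(bounds) == 2L, bounds[2] > bounds[1])
  VolumeGrid(pmin(pmax(vol@data, bounds[1]), bounds[2]),
             vol@spacing, vol@origin, vol@orientation)
}

#' Min-max normalize a volume to [-1, 1]
#'
#' `v' = 2 (v - lo) / (hi - lo) - 1`. For CT/CBCT the fixed HU bounds are
#' used (clip first); for MRI pass the per-volume `range()` as bounds.
#'
#' @param vol A [VolumeGrid-class].
#' @param bounds numeric(2) normalization bounds, `hi > lo`.
#' @return Normalized [VolumeGrid-class] with values in [-1, 1].
#' @export
normalizeMinMax <- function(vol, bounds = huBounds()) {
  if (bounds[2] <= bounds[1]) stop("degenerate normalization range")
  VolumeGrid(2 * (vol@data - bounds[1]) / (bounds[2] - bounds[1]) - 1,
             vol@spacing, vol@origin, vol@orientation)
}

#' @rdname normalizeMinMax
#' @export
denormalizeMinMax <- function(vol, bounds = huBounds()) {
  if (bounds[2] <= bounds[1]) stop("degenerate normalization range")
  VolumeGrid((vol@data + 1) / 2 * (bounds[2] - bounds[1]) + bounds[1],
             vol@spacing, vol@origin, vol@orientation)
}

#' Invert a rigid transform
#' @param t A [RigidTransform-class].
#' @return The inverse [RigidTransform-class].
#' @export
invertTransform <- function(t) {
  Rt <- t(t@rotation)
  RigidTransform(Rt, -as.vector(Rt %*% t@translation))
}

#' Resample a volume onto a reference grid through a rigid transform
#'
#' The output carries the reference grid metadata; the voxel at reference
#' world position `x` takes the value of `moving` at world position
#' `t(x) = R x + translation` (the registration matrix mapping reference space
#' into moving space). Out-of-support voxels take `fill` (-1024 for HU images,
#' 0 for MRI/normalized data).
#'
#' @param moving [VolumeGrid-class] to resample.
#' @param reference [VolumeGrid-class] providing the output grid.
#' @param transform A [RigidTransform-class]; identity by default.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill Fill value outside the support of `moving`.
#' @return A [VolumeGrid-class] on the reference grid.
#' @export
resampleRigid <- function(moving, reference, transform = RigidTransform(),
                          interpolation = c("linear", "nearest"),
                          fill = -1024) {
  interpolation <- match.arg(interpolation)
  d <- dim(reference@data)
  idx <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
  world <- sweep(idx, 2, reference@spacing, `*`) %*% t(reference@orientation)
  world <- sweep(world, 2, reference@origin, `+`)
  mapped <- world %*% t(transform@rotation)
  mapped <- sweep(mapped, 2, transform@translation, `+`)
  local <- sweep(mapped, 2, moving@origin, `-`) %*% moving@orientation
  vox <- sweep(local, 2, moving@spacing, `/`)
  vals <- .cpp_sample_trilinear(moving@data, vox, fill,
                                interpolation == "nearest")
  VolumeGrid(array(vals, d), reference@spacing, reference@origin,
             reference@orientation)
}

#' Patient-level train/validation/test split
#'
#' Partitions patient ids (never slices or triplets) into three disjoint sets.
#' Validation and test sizes are floored; leftover patients go to training.
#'
#' @param patientIds Vector of unique patient identifiers.
#' @param fractions numeric(3) `(train, val, test)` summing to 1.
#' @param seed Integer seed making the shuffle deterministic.
#' @return Named list with elements `train`, `val`, `test`.
#' @examples
#' splitPatients(sprintf("p%02d", 1:27), seed = 1)
#' @export
splitPatients <- function(patientIds, fractions = c(0.75, 0.10, 0.15),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (anyDuplicated(patientIds)) stop("patient ids must be unique")
  n <- length(patientIds)
  nVal <- floor(fractions[2] * n)
  nTest <- floor(fractions[3] * n)
  nTrain <- n - nVal - nTest
  if (n < sum(fractions > 0)) stop("fewer patients than nonzero partitions")
  perm <- withRng(seed, sample.int(n))
  shuffled <- patientIds[perm]
  list(train = shuffled[seq_len(nTrain)],
       val = if (nVal) shuffled[nTrain + seq_len(nVal)] else patientIds[0],
       test = if (nTest) shuffled[nTrain + nVal + seq_len(nTest)] else patientIds[0])
}

#' Preprocess a triplet for training
#'
#' CT and CBCT are clipped to the HU bounds and min-max normalized to [-1, 1]
#' against those fixed bounds; the MRI is normalized against its own
#' per-volume min/max (no fixed window exists for T1 intensities).
#'
#' @param triplet A [GroundTruthTriplet-class] in native units.
#' @return A list with the normalized triplet (`triplet`) and the MRI bounds
#'   used (`mriBounds`), needed to undo the MRI scaling.
#' @export
prepareTriplet <- function(triplet) {
  b <- huBounds()
  mb <- range(triplet@mri@data)
  if (mb[2] <= mb[1]) mb <- c(mb[1], mb[1] + 1)
  norm <- GroundTruthTriplet(
    ct = normalizeMinMax(clipHU(triplet@ct, b), b),
    cbct = normalizeMinMax(clipHU(triplet@cbct, b), b),
    mri = normalizeMinMax(triplet@mri, mb),
    labels = triplet@labels,
    misalignment = triplet@misalignment)
  list(triplet = norm, mriBounds = mb)
}

#' Axial slice batches for 2D training
#'
#' Yields axial slices of a preprocessed triplet in batches. The input stack
#' is the CBCT slice alone (1 channel) or CBCT + MRI (2 channels, CBCT always
#' first); the target is the CT slice. The final partial batch is returned
#' as-is.
#'
#' @param triplet A normalized [GroundTruthTriplet-class].
#' @param batch Batch size (number of slices); the training default is 3.
#' @param withMri Include the MRI channel?
#' @return List of batches, each `list(input = H x W x C x n, target = H x W x 1 x n,
#'   slices = slice indices)`.
#' @export
axialSliceBatches <- function(triplet, batch = 3L, withMri = TRUE) {
  d <- dim(triplet@ct@data)
  nC <- if (withMri) 2L else 1L
  starts <- seq(1L, d[3], by = batch)
  lapply(starts, function(s) {
    ks <- s:min(s + batch - 1L, d[3])
    n <- length(ks)
    input <- array(0, c(d[1], d[2], nC, n))
    target <- array(0, c(d[1], d[2], 1L, n))
    for (m in seq_along(ks)) {
      input[, , 1L, m] <- triplet@cbct@data[, , ks[m]]
      if (withMri) input[, , 2L, m] <- triplet@mri@data[, , ks[m]]
      target[, , 1L, m] <- triplet@ct@data[, , ks[m]]
    }
    list(input = input, target = target, slices = ks)
  })
}
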