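#' Accessors for volume objects
#'
#' `volData` returns the raw 3D array, `voxelSpacing` the per-axis voxel size
#' in mm, `volOrigin` the world position of voxel (0,0,0), and `volOrientation`
#' the axis-direction matrix. `labelGrid` extracts the underlying
#' [VolumeGrid-class] of a [LabelVolume-class].
#'
#' @param x A [VolumeGrid-class], [LabelVolume-class] or
#'   [GroundTruthTriplet-class] object.
#' @return The requested component.
#' @examples
#' v <- VolumeGrid(array(1, c(2, 2, 2)), spacing = c(2, 2, 4))
#' voxelSpacing(v)
#' @name volume-accessors
NULL

#' @rdname volume-accessors
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @rdname volume-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname volume-accessors
#' @export
setGeneric("volOrigin", function(x) standardGeneric("volOrigin"))
#' @rdname volume-accessors
#' @export
setGeneric("volOrientation", function(x) standardGeneric("volOrientation"))
#' @rdname volume-accessors
#' @export
setGeneric("labelGrid", function(x) standardGeneric("labelGrid"))

#' @rdname volume-accessors
#' @export
setMethod("volData", "VolumeGrid", function(x) x@data)
#' @rdname volume-accessors
#' @export
setMethod("voxelSpacing", "VolumeGrid", function(x) x@spacing)
#' @rdname volume-accessors
#' @export
setMethod("volOrigin", "VolumeGrid", function(x) x@origin)
#' @rdname volume-accessors
#' @export
setMethod("volOrientation", "VolumeGrid", function(x) x@orientation)
#' @rdname volume-accessors
#' @export
setMethod("volData", "LabelVolume", function(x) x@grid@data)
#' @rdname volume-accessors
#' @export
setMethod("labelGrid", "LabelVolume", function(x) x@grid)
#' @rdname volume-accessors
#' @export
setMethod("voxelSpacing", "LabelVolume", function(x) x@grid@spacing)

#' Triplet component accessors
#'
#' @param x A [GroundTruthTriplet-class].
#' @return The requested member volume.
#' @name triplet-accessors
NULL

#' @rdname triplet-accessors
#' @export
setGeneric("ctVolume", function(x) standardGeneric("ctVolume"))
#' @rdname triplet-accessors
#' @export
setGeneric("cbctVolume", function(x) standardGeneric("cbctVolume"))
#' @rdname triplet-accessors
#' @export
setGeneric("mriVolume", function(x) standardGeneric("mriVolume"))
#' @rdname triplet-accessors
#' @export
setGeneric("tripletLabels", function(x) standardGeneric("tripletLabels"))

#' @rdname triplet-accessors
#' @export
setMethod("ctVolume", "GroundTruthTriplet", function(x) x@ct)
#' @rdname triplet-accessors
#' @export
setMethod("cbctVolume", "GroundTruthTriplet", function(x) x@cbct)
#' @rdname triplet-accessors
#' @export
setMethod("mriVolume", "GroundTruthTriplet", function(x) x@mri)
#' @rdname triplet-accessors
#' @export
setMethod("tripletLabels", "GroundTruthTriplet", function(x) x@labels)

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeGrid %dx%dx%d voxels, spacing %s mm, range [%.6g, %.6g]\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 4), collapse = "x"),
              min(object@data), max(object@data)))
})

setMethod("show", "LabelVolume", function(object) {
  tab <- table(factor(object@grid@data, levels = labelCodes(),
                      labels = names(labelCodes())))
  cat("LabelVolume with voxel counts:\n")
  print(tab[tab > 0])
})

setMethod("show", "GroundTruthTriplet", function(object) {
  d <- dim(object@ct@data)
  cat(sprintf("GroundTruthTriplet %dx%dx%d voxels @ %s mm (CT/CBCT/MRI + labels)\n",
              d[1], d[2], d[3],
              paste(format(object@ct@spacing, digits = 4), collapse = "x")))
})

setMethod("show", "SprCurve", function(object) {
  cat(sprintf("SprCurve with %d nodes, HU in [%g, %g], SPR in [%g, %g] (%s)\n",
              length(object@hu), min(object@hu), max(object@hu),
              min(object@spr), max(object@spr), object@provenance))
})

setMethod("show", "R80Map", function(object) {
  cat(sprintf("R80Map %dx%d beamlets (%.0f%% valid), R80 in [%.1f, %.1f] mm\n",
              nrow(object@values), ncol(object@values),
              100 * mean(object@valid),
              min(object@values[object@valid]), max(object@values[object@valid])))
})

setMethod("show", "DoseLine", function(object) {
  cat(sprintf("DoseLine: %d samples over [%.1f, %.1f] mm, %s\n",
              length(object@depths), min(object@depths), max(object@depths),
              if (object@valid) "valid" else "invalid (no distal falloff in volume)"))
})

setMethod("show", "DvhCurve", function(object) {
  cat(sprintf("DvhCurve for '%s': %d dose levels up to %.3g\n",
              object@structure, length(object@dose), max(object@dose)))
})
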