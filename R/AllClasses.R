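#' VolumeGrid: a 3D scalar volume with geometry metadata
#'
#' The common currency of the package: a 3D array of voxel values together
#' with voxel spacing (mm), the world coordinate of voxel (0,0,0) and an
#' axis-direction matrix. World coordinates follow the RAS convention and the
#' mapping `world = origin + orientation %*% (index0 * spacing)` with 0-based
#' voxel indices.
#'
#' @slot data 3D numeric array of voxel values.
#' @slot spacing numeric(3), voxel size in mm per axis; strictly positive.
#' @slot origin numeric(3), world coordinate (mm) of voxel (0,0,0).
#' @slot orientation 3x3 orthonormal axis-direction matrix.
#' @export
setClass("VolumeGrid",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 orientation = "matrix"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), orientation = diag(3)))

setValidity("VolumeGrid", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  o <- object@orientation
  if (!all(dim(o) == c(3, 3)) || max(abs(crossprod(o) - diag(3))) > 1e-6)
    msg <- c(msg, "orientation must be a 3x3 orthonormal matrix")
  if (length(msg)) msg else TRUE
})

#' Construct a VolumeGrid
#'
#' @param data 3D numeric array.
#' @param spacing voxel size in mm per axis.
#' @param origin world coordinate (mm) of voxel (0,0,0).
#' @param orientation 3x3 orthonormal direction matrix (default identity, RAS).
#' @return A [VolumeGrid-class] object.
#' @examples
#' v <- VolumeGrid(array(0, c(4, 4, 2)), spacing = c(0.625, 0.625, 1.25))
#' voxelSpacing(v)
#' @export
VolumeGrid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       orientation = diag(3)) {
  new("VolumeGrid", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation)
}

#' LabelVolume: integer organ labels on a VolumeGrid
#'
#' Voxel codes: 0 background/air, 1 soft tissue, 2 skull bone, 3 brain,
#' 4 ventricle (CSF), 5 eye, 6 lens, 7 optic nerve, 8 nasal air cavity.
#'
#' @slot grid A [VolumeGrid-class] whose data are integer-valued codes.
#' @export
setClass("LabelVolume", representation(grid = "VolumeGrid"))

#' Organ label codes used by the head phantom
#' @return Named integer vector of label codes.
#' @examples labelCodes()["ventricle"]
#' @export
labelCodes <- function() {
  c(background = 0L, soft_tissue = 1L, skull = 2L, brain = 3L,
    ventricle = 4L, eye = 5L, lens = 6L, optic_nerve = 7L, nasal_cavity = 8L)
}

setValidity("LabelVolume", function(object) {
  v <- object@grid@data
  if (any(v != round(v))) return("label values must be integers")
  if (!all(unique(as.vector(v)) %in% labelCodes()))
    return("label codes outside the supported enumeration")
  TRUE
})

#' @rdname LabelVolume-class
#' @param grid A [VolumeGrid-class] of integer codes.
#' @export
LabelVolume <- function(grid) new("LabelVolume", grid = grid)

#' RigidTransform: rotation plus translation in world (mm) coordinates
#'
#' @slot rotation 3x3 rotation matrix with det +1.
#' @slot translation numeric(3) translation in mm.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3, 3)) || max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation must be orthonormal")
  if (abs(det(R) - 1) > 1e-6) return("rotation must have determinant +1")
  if (length(object@translation) != 3L) return("translation must have length 3")
  TRUE
})

#' @rdname RigidTransform-class
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric(3) mm.
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation, translation = as.numeric(translation))
}

#' GroundTruthTriplet: aligned CT/CBCT/MRI volumes with organ labels
#'
#' @slot ct CT volume in HU.
#' @slot cbct CBCT volume in HU.
#' @slot mri T1-weighted MRI volume in arbitrary intensity units.
#' @slot labels Ground-truth [LabelVolume-class].
#' @slot misalignment The [RigidTransform-class] applied to CBCT/MRI before
#'   any re-registration (identity when the triplet is generated aligned).
#' @export
setClass("GroundTruthTriplet",
  representation(ct = "VolumeGrid", cbct = "VolumeGrid", mri = "VolumeGrid",
                 labels = "LabelVolume", misalignment = "RigidTransform"))

setValidity("GroundTruthTriplet", function(object) {
  d <- dim(object@ct@data)
  same <- function(v) all(dim(v@data) == d) &&
    max(abs(v@spacing - object@ct@spacing)) < 1e-9
  if (!same(object@cbct) || !same(object@mri) || !same(object@labels@grid))
    return("ct, cbct, mri and labels must share grid shape and spacing")
  r <- range(object@ct@data)
  if (r[1] < -1024 - 1e-9 || r[2] > 3072 + 1e-9)
    return("ct HU values must lie within [-1024, 3072]")
  TRUE
})

#' @rdname GroundTruthTriplet-class
#' @param ct,cbct,mri Aligned [VolumeGrid-class] volumes.
#' @param labels A [LabelVolume-class] on the same grid.
#' @param misalignment Optional [RigidTransform-class].
#' @export
GroundTruthTriplet <- function(ct, cbct, mri, labels,
                               misalignment = RigidTransform()) {
  new("GroundTruthTriplet", ct = ct, cbct = cbct, mri = mri, labels = labels,
      misalignment = misalignment)
}

#' PhantomSpec: parameters of the synthetic multimodal head phantom
#'
#' @slot gridShape integer(3), voxels per axis.
#' @slot spacingMm numeric(3), voxel size in mm.
#' @slot headAxesMm numeric(3), semi-axes of the head ellipsoid in mm.
#' @slot organs character vector of organ toggles; any subset of
#'   `c("skull","brain","ventricles","eyes","lenses","optic_nerves","nasal_cavities")`.
#' @slot seed integer RNG seed; identical specs give bit-identical phantoms.
#' @slot jitterFrac relative random perturbation of organ sizes and positions.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", spacingMm = "numeric",
                 headAxesMm = "numeric", organs = "character",
                 seed = "integer", jitterFrac = "numeric"))

.phantomOrgans <- c("skull", "brain", "ventricles", "eyes", "lenses",
                    "optic_nerves", "nasal_cavities")

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape <= 0L))
    return("gridShape must be 3 strictly positive integers")
  if (length(object@spacingMm) != 3L || any(object@spacingMm <= 0))
    return("spacingMm must be 3 strictly positive values")
  if (length(object@headAxesMm) != 3L || any(object@headAxesMm <= 0))
    return("headAxesMm must be 3 strictly positive values")
  if (!all(object@organs %in% .phantomOrgans))
    return(paste("unknown organ toggle; supported:",
                 paste(.phantomOrgans, collapse = ", ")))
  if (object@jitterFrac < 0 || object@jitterFrac > 0.5)
    return("jitterFrac must be in [0, 0.5]")
  TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults describe a desk-scale head: 64x64x32 voxels at 4 mm spacing with
#' every organ enabled. Clinical-geometry grids (e.g. CT 0.625 mm pixels /
#' 1.25 mm slices) are available by passing the corresponding `gridShape` and
#' `spacingMm`.
#'
#' @param gridShape voxels per axis.
#' @param spacingMm voxel size in mm per axis.
#' @param headAxesMm semi-axes of the head ellipsoid in mm.
#' @param organs organ toggles; default all.
#' @param seed integer RNG seed.
#' @param jitterFrac relative jitter of organ sizes/positions.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(seed = 1)
#' labs <- generateLabelVolume(spec)
#' table(volData(labelGrid(labs)))
#' @export
phantomSpec <- function(gridShape = c(64L, 64L, 32L), spacingMm = c(4, 4, 4),
                        headAxesMm = c(80, 95, 58), organs = .phantomOrgans,
                        seed = 1L, jitterFrac = 0.05) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacingMm = as.numeric(spacingMm), headAxesMm = as.numeric(headAxesMm),
      organs = organs, seed = as.integer(seed), jitterFrac = jitterFrac)
}

#' SprCurve: piecewise-linear HU to stopping-power-ratio calibration
#'
#' @slot hu strictly increasing HU node positions.
#' @slot spr non-negative, non-decreasing SPR values at the nodes; the curve
#'   must pass within 1e-3 of SPR = 1 at HU = 0 (water anchor).
#' @slot provenance free-text tag describing where the calibration came from.
#' @export
setClass("SprCurve",
  representation(hu = "numeric", spr = "numeric", provenance = "character"))

setValidity("SprCurve", function(object) {
  if (length(object@hu) < 2L) return("at least two nodes required")
  if (any(diff(object@hu) <= 0)) return("HU nodes must be strictly increasing")
  if (any(object@spr < 0)) return("SPR values must be non-negative")
  if (any(diff(object@spr) < 0)) return("SPR must be non-decreasing")
  at0 <- stats::approx(object@hu, object@spr, xout = 0, rule = 2)$y
  if (abs(at0 - 1) > 1e-3) return("curve must pass through SPR = 1 at HU = 0")
  TRUE
})

#' @rdname SprCurve-class
#' @param hu,spr Calibration nodes.
#' @param provenance Text tag.
#' @export
sprCurve <- function(hu, spr, provenance = "user") {
  new("SprCurve", hu = as.numeric(hu), spr = as.numeric(spr),
      provenance = provenance)
}

#' BeamSpec: geometry of the monoenergetic lateral probing beam
#'
#' The beam is described by its direction, the isocenter it shares with the
#' plan, a square field of 80-100 mm sampled by 1x1 mm beamlets on a 1 mm dose
#' grid, and the nominal energy expressed directly as the R80 depth in water.
#'
#' @slot direction unit vector of beam travel (world axes).
#' @slot isocenterMm beam isocenter in world mm.
#' @slot fieldSizeMm square field side in mm; must lie in [80, 100].
#' @slot spotSpacingMm delivery spot spacing (2.5 mm default).
#' @slot beamletGridMm lateral spacing of dose lines (1 mm default).
#' @slot doseGridMm depth sampling of dose lines (1 mm default).
#' @slot r80WaterMm distal R80 of the nominal energy in water, mm.
#' @export
setClass("BeamSpec",
  representation(direction = "numeric", isocenterMm = "numeric",
                 fieldSizeMm = "numeric", spotSpacingMm = "numeric",
                 beamletGridMm = "numeric", doseGridMm = "numeric",
                 r80WaterMm = "numeric"))

setValidity("BeamSpec", function(object) {
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-6)
    return("direction must be a unit vector")
  if (object@fieldSizeMm < 80 || object@fieldSizeMm > 100)
    return("fieldSizeMm must lie in [80, 100]")
  if (object@spotSpacingMm <= 0 || object@beamletGridMm <= 0 ||
      object@doseGridMm <= 0)
    return("all spacings must be positive")
  if (object@r80WaterMm <= 0) return("r80WaterMm must be positive")
  TRUE
})

#' @rdname BeamSpec-class
#' @param direction,isocenterMm,fieldSizeMm,spotSpacingMm,beamletGridMm,doseGridMm,r80WaterMm
#'   See slots.
#' @export
beamSpec <- function(direction = c(1, 0, 0), isocenterMm = c(0, 0, 0),
                     fieldSizeMm = 80, spotSpacingMm = 2.5,
                     beamletGridMm = 1, doseGridMm = 1, r80WaterMm = 100) {
  d <- direction / sqrt(sum(direction^2))
  new("BeamSpec", direction = d, isocenterMm = as.numeric(isocenterMm),
      fieldSizeMm = fieldSizeMm, spotSpacingMm = spotSpacingMm,
      beamletGridMm = beamletGridMm, doseGridMm = doseGridMm,
      r80WaterMm = r80WaterMm)
}

#' DoseLine: a normalized depth-dose line through the patient
#'
#' @slot depths strictly increasing geometric depths in mm.
#' @slot dose dose samples normalized so the Bragg-peak sample equals 1
#'   (for valid lines).
#' @slot valid whether the line reached its peak and distal falloff inside
#'   the volume.
#' @export
setClass("DoseLine",
  representation(depths = "numeric", dose = "numeric", valid = "logical"))

setValidity("DoseLine", function(object) {
  if (length(object@depths) != length(object@dose))
    return("depths and dose must have equal length")
  if (any(diff(object@depths) <= 0)) return("depths must be strictly increasing")
  if (isTRUE(object@valid) && abs(max(object@dose) - 1) > 1e-9)
    return("valid lines must be normalized to max dose 1")
  TRUE
})

#' R80Map: lateral grid of distal-R80 depths for one beam
#'
#' @slot values matrix of R80 depths in mm, one per 1x1 mm beamlet.
#' @slot valid logical matrix; beamlets whose distal falloff left the volume
#'   are masked, never silently zero.
#' @slot beamletGridMm lateral beamlet spacing in mm.
#' @export
setClass("R80Map",
  representation(values = "matrix", valid = "matrix", beamletGridMm = "numeric"))

setValidity("R80Map", function(object) {
  if (!all(dim(object@values) == dim(object@valid)))
    return("values and valid mask must share shape")
  if (any(!is.finite(object@values[object@valid])))
    return("valid beamlets must carry finite R80 values")
  TRUE
})

#' DvhCurve: cumulative dose-volume histogram of one structure
#'
#' @slot dose dose axis (non-negative, increasing).
#' @slot volume fraction of the structure receiving at least each dose;
#'   starts at 1, monotone non-increasing, reaches 0 beyond the maximum dose.
#' @slot structure structure name.
#' @export
setClass("DvhCurve",
  representation(dose = "numeric", volume = "numeric", structure = "character"))

setValidity("DvhCurve", function(object) {
  if (length(object@dose) != length(object@volume))
    return("dose and volume must have equal length")
  if (any(diff(object@dose) <= 0)) return("dose axis must be increasing")
  if (any(diff(object@volume) > 1e-12)) return("volume must be non-increasing")
  if (abs(object@volume[1] - 1) > 1e-12) return("curve must start at V(0) = 1")
  TRUE
})
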