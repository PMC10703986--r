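#' @rdname CTVolume-class
#' @param x a CTVolume, DoseGrid or OrganMaskSet.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname CTVolume-class
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' @rdname CTVolume-class
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname OrganMaskSet-class
#' @param x an OrganMaskSet.
#' @param name structure name (body, bone, bladder, rectum, prostate, or
#'   softTissue for body minus the four organs).
#' @export
setGeneric("organMask", function(x, name) standardGeneric("organMask"))

#' @rdname OrganMaskSet-class
#' @export
setGeneric("structureNames", function(x) standardGeneric("structureNames"))

#' Isocentre dose
#'
#' The scalar model output: absorbed dose (Gy) at the plan isocentre.
#' Applied to a [CTVolume-class] it evaluates the beam model directly at
#' the isocentre point; applied to a [DoseGrid-class] it interpolates the
#' grid trilinearly at the isocentre.
#'
#' @param x a CTVolume or DoseGrid.
#' @param plan a calibrated [BeamPlan-class].
#' @return dose in Gy (scalar).
#' @export
setGeneric("isocentreDose", function(x, plan) standardGeneric("isocentreDose"))
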