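#' @rdname CTVolume-class
#' @aliases voxels,CTVolume-method
setMethod("voxels", "CTVolume", function(x) x@voxels)

#' @rdname CTVolume-class
setMethod("voxels", "DoseGrid", function(x) x@voxels)

#' @rdname CTVolume-class
setMethod("voxelSpacing", "CTVolume", function(x) x@spacing)

#' @rdname CTVolume-class
setMethod("voxelSpacing", "DoseGrid", function(x) x@spacing)

#' @rdname CTVolume-class
setMethod("gridOrigin", "CTVolume", function(x) x@origin)

#' @rdname CTVolume-class
setMethod("gridOrigin", "DoseGrid", function(x) x@origin)

#' @rdname CTVolume-class
setMethod("dim", "CTVolume", function(x) dim(x@voxels))

#' @rdname OrganMaskSet-class
setMethod("dim", "OrganMaskSet", function(x) dim(x@masks$body))

#' @rdname OrganMaskSet-class
setMethod("organMask", "OrganMaskSet", function(x, name) {
  if (identical(name, "softTissue")) return(softTissueMask(x))
  if (!name %in% names(x@masks))
    stop("unknown structure '", name, "'; expected one of ",
         paste(c(names(x@masks), "softTissue"), collapse = ", "))
  x@masks[[name]]
})

#' @rdname OrganMaskSet-class
setMethod("structureNames", "OrganMaskSet", function(x) names(x@masks))

#' Remaining soft tissue mask
#'
#' Body minus bone, bladder, rectum and prostate.
#'
#' @param masks an [OrganMaskSet-class].
#' @return logical 3-D array.
#' @export
softTissueMask <- function(masks) {
  m <- masks@masks
  m$body & !(m$bone | m$bladder | m$rectum | m$prostate)
}

setMethod("show", "CTVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("CTVolume: %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  HU range [%.0f, %.0f], origin (%.1f, %.1f, %.1f) mm [LPS]\n",
              min(object@voxels), max(object@voxels),
              object@origin[1], object@origin[2], object@origin[3]))
})

setMethod("show", "OrganMaskSet", function(object) {
  d <- dim(object)
  cat(sprintf("OrganMaskSet on %d x %d x %d grid\n", d[1], d[2], d[3]))
  for (nm in names(object@masks))
    cat(sprintf("  %-9s %d voxels\n", nm, sum(object@masks[[nm]])))
})

setMethod("show", "DoseGrid", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("DoseGrid: %d x %d x %d nodes @ %.3g mm, max %.2f Gy\n",
              d[1], d[2], d[3], object@spacing[1], max(object@voxels)))
})

setMethod("show", "BeamPlan", function(object) {
  cat(sprintf("BeamPlan: %d beams (gantry %s deg), SAD %.0f mm\n",
              length(object@gantryAngles),
              paste(round(object@gantryAngles, 1), collapse = ", "),
              object@sad))
  cat(sprintf("  prescription %.1f Gy in %d fractions; mu_w %.4f /mm; aperture %.0f mm\n",
              object@prescriptionGy, object@fractions, object@muWater,
              object@aperture))
  cat(sprintf("  isocentre (%.1f, %.1f, %.1f) mm; normalisation %s\n",
              object@isocentre[1], object@isocentre[2], object@isocentre[3],
              if (is.na(object@normalisation)) "uncalibrated"
              else sprintf("%.4g", object@normalisation)))
})

setMethod("show", "MorrisDesign", function(object) {
  K <- nrow(object@factors)
  cat(sprintf("MorrisDesign: K=%d factors, R=%d trajectories, p=%d levels, delta=%.4g\n",
              K, object@repetitions, object@levels, object@delta))
  cat(sprintf("  %d rows; factors: %s\n", nrow(object@design),
              paste(object@factors$name, collapse = ", ")))
})

setMethod("show", "ExperimentResult", function(object) {
  np <- length(unique(object@summary$patient))
  cat(sprintf("ExperimentResult: %d patients, %d factors, %d evaluations\n",
              np, nrow(object@cohort), nrow(object@evaluations)))
  print(object@cohort, digits = 4)
})
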