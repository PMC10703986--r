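#' Construct perturbation specifications
#'
#' `artefactSpec()` describes a localized spherical additive HU error;
#' `organShiftSpec()` describes organ-wise mean HU shifts. Both are pure
#' descriptions validated against the study factor ranges.
#'
#' @param deltaHU additive HU offset, \[-250, 250\].
#' @param diameter artefact diameter in mm, \[2, 50\].
#' @param distance displacement from the isocentre in mm, \[0, 100\].
#' @param beamIndex 1-based beam whose source-to-isocentre axis carries
#'   the displacement (default the first beam).
#' @return an [ArtefactSpec-class] / [OrganShiftSpec-class].
#' @export
artefactSpec <- function(deltaHU = 0, diameter = 50, distance = 0,
                         beamIndex = 1L) {
  new("ArtefactSpec", deltaHU = as.double(deltaHU),
      diameter = as.double(diameter), distance = as.double(distance),
      beamIndex = as.integer(beamIndex))
}

#' @rdname artefactSpec
#' @param bladder,prostate,softTissue HU offsets in \[-100, 100\].
#' @param rectum HU offset in \[-1000, 200\] (rectal gas uncertainty).
#' @param bone HU offset in \[-500, 500\].
#' @export
organShiftSpec <- function(bladder = 0, rectum = 0, bone = 0, prostate = 0,
                           softTissue = 0) {
  new("OrganShiftSpec", bladder = as.double(bladder),
      rectum = as.double(rectum), bone = as.double(bone),
      prostate = as.double(prostate), softTissue = as.double(softTissue))
}

#' Insert a spherical HU artefact into a CT volume
#'
#' Adds `deltaHU` to every voxel whose centre lies within `diameter/2` of
#' the artefact centre, then clamps at -1000 HU (air). The artefact centre
#' is the plan isocentre displaced by `distance` mm along the unit
#' source-to-isocentre direction of beam `beamIndex`. The input volume is
#' never modified; a zero offset returns a voxel-identical copy.
#'
#' @param ct a [CTVolume-class].
#' @param masks the matching [OrganMaskSet-class] (used to reject
#'   artefacts that lie entirely outside the body).
#' @param plan a [BeamPlan-class] providing isocentre and beam axes.
#' @param artefact an [ArtefactSpec-class].
#' @return a new [CTVolume-class].
#' @export
insertArtefact <- function(ct, masks, plan, artefact) {
  validObject(artefact)
  if (artefact@beamIndex > length(plan@gantryAngles))
    stop("beamIndex exceeds the number of beams in the plan")
  dir <- .beamDirections(plan)[artefact@beamIndex, ]
  centre <- plan@isocentre + artefact@distance * dir
  coords <- .axisCoords(dim(ct), ct@spacing, ct@origin)
  r2 <- (artefact@diameter / 2)^2
  dx2 <- (coords[[1]] - centre[1])^2
  dy2 <- (coords[[2]] - centre[2])^2
  dz2 <- (coords[[3]] - centre[3])^2
  sphere <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r2

  body <- organMask(masks, "body")
  if (any(sphere)) {
    if (!any(sphere & body))
      stop("artefact sphere lies entirely outside the body; ",
           "such a perturbation cannot affect tissue")
  } else {
    nearest <- pmin(pmax(round((centre - ct@origin) / ct@spacing) + 1, 1), dim(ct))
    if (!body[nearest[1], nearest[2], nearest[3]])
      stop("artefact centre lies outside the body")
  }

  v <- ct@voxels
  if (artefact@deltaHU != 0 && any(sphere))
    v[sphere] <- pmax(v[sphere] + artefact@deltaHU, -1000)
  new("CTVolume", voxels = v, spacing = ct@spacing, origin = ct@origin)
}

#' Apply organ-wise mean HU shifts
#'
#' Adds each structure's offset to the voxels of its mask; the
#' `softTissue` offset applies to the body minus the four delineated
#' organs. Air outside the body is untouched and values are clamped at
#' -1000 HU. The input volume is never modified.
#'
#' @param ct a [CTVolume-class].
#' @param masks an [OrganMaskSet-class].
#' @param shifts an [OrganShiftSpec-class].
#' @return a new [CTVolume-class].
#' @export
applyOrganShifts <- function(ct, masks, shifts) {
  validObject(shifts)
  v <- ct@voxels
  off <- c(bladder = shifts@bladder, rectum = shifts@rectum,
           bone = shifts@bone, prostate = shifts@prostate)
  for (nm in names(off)) {
    if (off[[nm]] != 0) {
      m <- organMask(masks, nm)
      v[m] <- pmax(v[m] + off[[nm]], -1000)
    }
  }
  if (shifts@softTissue != 0) {
    m <- softTissueMask(masks)
    v[m] <- pmax(v[m] + shifts@softTissue, -1000)
  }
  new("CTVolume", voxels = v, spacing = ct@spacing, origin = ct@origin)
}
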