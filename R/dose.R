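#' HU to relative electron density calibration
#'
#' `densityCurve()` builds a [DensityCurve-class] from control points;
#' the defaults are a standard bilinear-style CT calibration anchored at
#' air (-1000 HU, density 0) and water (0 HU, density 1) with a reduced
#' slope above water for bone. `huToDensity()` evaluates the curve by
#' piecewise-linear interpolation, clamped at the endpoints.
#'
#' @param hu numeric, strictly increasing HU control points.
#' @param density numeric, matching non-decreasing densities.
#' @return a [DensityCurve-class] / numeric densities.
#' @examples
#' huToDensity(c(-1000, 0, 500), densityCurve())
#' @export
densityCurve <- function(hu = c(-1000, 0, 1000, 3000),
                         density = c(0, 1, 1.6, 2.1)) {
  new("DensityCurve", hu = hu, density = density)
}

#' @rdname densityCurve
#' @param x numeric HU values.
#' @param curve a [DensityCurve-class].
#' @export
huToDensity <- function(x, curve = densityCurve()) {
  validObject(curve)
  .curveEval(curve@hu, curve@density, x)
}

#' Water-equivalent path length along a ray
#'
#' Line integral of relative electron density from `source` to `target`
#' (mm), evaluated by uniform sampling at a step no larger than half the
#' smallest voxel dimension. Regions outside the volume are air and
#' contribute zero.
#'
#' @param ct a [CTVolume-class].
#' @param source numeric(3) mm, ray origin (the beam source).
#' @param target numeric(3) mm; must lie inside the volume grid.
#' @param curve a [DensityCurve-class].
#' @param step sampling step in mm; capped at half the smallest voxel size.
#' @return water-equivalent path length in mm.
#' @export
radiologicalDepth <- function(ct, source, target, curve = densityCurve(),
                              step = NULL) {
  lo <- ct@origin
  hi <- ct@origin + (dim(ct) - 1) * ct@spacing
  if (any(target < lo) || any(target > hi))
    stop("target lies outside the volume bounds")
  cap <- min(ct@spacing) / 2
  step <- if (is.null(step)) cap else min(step, cap)
  .weplRaysCpp(ct@voxels, dim(ct), ct@spacing, ct@origin,
               as.double(source), matrix(as.double(target), 1L, 3L),
               step, curve@hu, curve@density)[1]
}

#' Build a simplified coplanar photon beam plan
#'
#' Default geometry mirrors a 7-beam coplanar 6 MV prostate plan: beams
#' equally spaced over \[0, 360) degrees and offset by half the beam
#' spacing (25.7, 77.1, ..., 334.3 degrees), source-axis distance
#' 1000 mm, equal weights, a 40 mm field-aperture radius around each beam
#' axis, and a prescription of 39 fractions of 2 Gy (78 Gy total). The
#' half-spacing offset places one field directly posterior, so every
#' delineated pelvic structure is traversed by at least one central ray
#' on its upstream side -- a requirement for organ factors to register in
#' a primary-fluence engine. The attenuation coefficient defaults to the
#' broad-beam 6 MV value for water, 0.0049 per mm.
#'
#' @param isocentre numeric(3) mm; for `planForPhantom` this is the
#'   prostate-mask centroid.
#' @param nBeams number of equally spaced coplanar beams.
#' @param gantryAngles beam angles in degrees (overrides `nBeams`).
#' @param sad source-axis distance in mm.
#' @param muWater linear attenuation coefficient of water, per mm.
#' @param aperture field radius around the beam axis, mm.
#' @param weights per-beam weights (default equal).
#' @param prescriptionGy total prescription in Gy.
#' @param fractions number of fractions.
#' @param gridSpacing dose-grid spacing, mm (isotropic).
#' @param curve a [DensityCurve-class].
#' @param rayStep WEPL sampling step in mm.
#' @return a [BeamPlan-class] (uncalibrated; see [calibratePlan()]).
#' @export
makeBeamPlan <- function(isocentre, nBeams = 7L,
                         gantryAngles = 180 / nBeams + seq(0, nBeams - 1L) * 360 / nBeams,
                         sad = 1000, muWater = 0.0049, aperture = 40,
                         weights = rep(1, length(gantryAngles)),
                         prescriptionGy = 78, fractions = 39L,
                         gridSpacing = 3, curve = densityCurve(),
                         rayStep = 1) {
  new("BeamPlan", isocentre = as.double(isocentre),
      gantryAngles = as.double(gantryAngles), sad = sad, muWater = muWater,
      aperture = aperture, weights = as.double(weights),
      prescriptionGy = prescriptionGy, fractions = as.integer(fractions),
      gridSpacing = gridSpacing, densityCurve = curve, rayStep = rayStep,
      normalisation = NA_real_)
}

#' @rdname makeBeamPlan
#' @param ct a [CTVolume-class].
#' @param masks the matching [OrganMaskSet-class]; the isocentre is placed
#'   at the centre of the prostate.
#' @param ... further arguments to `makeBeamPlan`.
#' @export
planForPhantom <- function(ct, masks, ...) {
  iso <- maskCentroid(organMask(masks, "prostate"), ct@spacing, ct@origin)
  makeBeamPlan(isocentre = iso, ...)
}

#' Beam source positions
#'
#' Source of beam b sits at SAD from the isocentre in the transverse
#' plane: gantry 0 anterior (-y in LPS), angles increasing towards +x.
#'
#' @param plan a [BeamPlan-class].
#' @return numeric matrix, one row (x, y, z in mm) per beam.
#' @export
beamSources <- function(plan) {
  g <- plan@gantryAngles * pi / 180
  t(vapply(g, function(a) plan@isocentre + plan@sad * c(sin(a), -cos(a), 0),
           numeric(3)))
}

# unit source-to-isocentre direction of each beam (rows)
.beamDirections <- function(plan) {
  g <- plan@gantryAngles * pi / 180
  t(vapply(g, function(a) c(-sin(a), cos(a), 0), numeric(3)))
}

# raw (unnormalised) model output at arbitrary points: per beam,
# weight * exp(-mu_w * WEPL) * (SAD / source-distance)^2, summed over the
# beams whose aperture cylinder contains the point
.rawDose <- function(ct, plan, points) {
  src <- beamSources(plan)
  dirs <- .beamDirections(plan)
  step <- min(plan@rayStep, min(ct@spacing) / 2)
  total <- numeric(nrow(points))
  for (b in seq_along(plan@gantryAngles)) {
    rel <- sweep(points, 2, src[b, ])
    along <- as.vector(rel %*% dirs[b, ])
    rad2 <- rowSums(rel^2) - along^2
    sel <- which(along > 0 & rad2 <= plan@aperture^2 + 1e-9)
    if (!length(sel)) next
    wepl <- .weplRaysCpp(ct@voxels, dim(ct), ct@spacing, ct@origin,
                         src[b, ], points[sel, , drop = FALSE], step,
                         plan@densityCurve@hu, plan@densityCurve@density)
    dist2 <- rowSums(rel[sel, , drop = FALSE]^2)
    total[sel] <- total[sel] +
      plan@weights[b] * exp(-plan@muWater * wepl) * plan@sad^2 / dist2
  }
  total
}

.checkIsoInBody <- function(ct, plan) {
  lo <- ct@origin
  hi <- ct@origin + (dim(ct) - 1) * ct@spacing
  if (any(plan@isocentre < lo) || any(plan@isocentre > hi))
    stop("isocentre lies outside the volume grid")
  huIso <- .trilinear(ct@voxels, (plan@isocentre - ct@origin) / ct@spacing)
  if (huIso <= -900)
    stop("isocentre lies in air, outside the body")
}

#' Fix the plan's global dose normalisation on a reference volume
#'
#' Sets the single scaling factor so the model's isocentre dose on this
#' (unperturbed) volume equals the prescription exactly. The calibrated
#' plan is then reused unchanged for every perturbed copy of the same
#' patient, mirroring how planned beam parameters are copied onto
#' modified CTs.
#'
#' @param plan a [BeamPlan-class].
#' @param ct the patient's unperturbed [CTVolume-class].
#' @return the plan with its `normalisation` slot set.
#' @export
calibratePlan <- function(plan, ct) {
  .checkIsoInBody(ct, plan)
  raw <- .rawDose(ct, plan, matrix(plan@isocentre, 1L, 3L))
  if (raw <= 0) stop("zero model output at the isocentre; cannot calibrate")
  plan@normalisation <- plan@prescriptionGy / raw
  plan
}

#' @rdname isocentreDose
setMethod("isocentreDose", "CTVolume", function(x, plan) {
  .checkIsoInBody(x, plan)
  norm <- plan@normalisation
  raw <- .rawDose(x, plan, matrix(plan@isocentre, 1L, 3L))
  if (is.na(norm)) norm <- plan@prescriptionGy / raw
  as.double(raw * norm)
})

#' @rdname isocentreDose
setMethod("isocentreDose", "DoseGrid", function(x, plan) {
  p <- (plan@isocentre - x@origin) / x@spacing
  .trilinear(x@voxels, p)
})

#' Compute the 3-D dose distribution
#'
#' Evaluates the simplified beam model on a dose grid (default 3 mm
#' isotropic) aligned so that the isocentre falls exactly on a grid node
#' and covering the CT volume. If the plan is uncalibrated the
#' normalisation is fixed on this volume, making its isocentre dose equal
#' the prescription by construction.
#'
#' @param ct a [CTVolume-class].
#' @param plan a [BeamPlan-class].
#' @return a [DoseGrid-class] in Gy.
#' @export
computeDose <- function(ct, plan) {
  .checkIsoInBody(ct, plan)
  gs <- plan@gridSpacing
  lo <- ct@origin
  hi <- ct@origin + (dim(ct) - 1) * ct@spacing
  ax <- lapply(1:3, function(a) {
    k <- seq(ceiling((lo[a] - plan@isocentre[a]) / gs - 1e-9),
             floor((hi[a] - plan@isocentre[a]) / gs + 1e-9))
    plan@isocentre[a] + k * gs
  })
  nd <- vapply(ax, length, integer(1))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]], KEEP.OUT.ATTRS = FALSE))
  dimnames(pts) <- NULL
  raw <- .rawDose(ct, plan, pts)
  norm <- plan@normalisation
  if (is.na(norm)) {
    rawIso <- .rawDose(ct, plan, matrix(plan@isocentre, 1L, 3L))
    norm <- plan@prescriptionGy / rawIso
  }
  new("DoseGrid", voxels = array(raw * norm, nd),
      spacing = rep(gs, 3), origin = vapply(ax, `[`, numeric(1), 1L))
}

#' Write a dose grid as NIfTI or MetaImage
#'
#' @param dose a [DoseGrid-class].
#' @param path output path (.nii, .nii.gz, .mha or .mhd); values in Gy.
#' @export
writeDose <- function(dose, path) {
  .writeImage(dose@voxels, dose@spacing, dose@origin, path)
  invisible(path)
}
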