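#' @useDynLib ctDoseSens, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

STRUCTURES <- c("body", "bone", "bladder", "rectum", "prostate")
ORGANS <- c("bone", "bladder", "rectum", "prostate")

#' CTVolume: a 3-D CT image in Hounsfield units
#'
#' Container for a 3-D grid of Hounsfield units (HU) together with its
#' physical geometry. World coordinates are in mm using the LPS convention
#' (+x left, +y posterior, +z superior); `origin` is the world coordinate of
#' the centre of voxel `[1, 1, 1]`.
#'
#' @slot voxels 3-D numeric array of HU, column-major (x fastest).
#' @slot spacing numeric(3), per-axis voxel size in mm, strictly positive.
#' @slot origin numeric(3), world position (mm) of the first voxel centre.
#' @export
setClass("CTVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    v <- object@voxels
    if (length(dim(v)) != 3L) return("voxels must be a 3-D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 strictly positive values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("origin must be 3 finite values (mm)")
    if (any(!is.finite(v))) return("voxels must be finite")
    r <- range(v)
    if (r[1] < -1024 || r[2] > 3100)
      return(sprintf("HU outside [-1024, 3100]: range %.1f..%.1f", r[1], r[2]))
    TRUE
  })

#' OrganMaskSet: boolean organ masks on a CT grid
#'
#' One logical mask per structure in body, bone, bladder, rectum, prostate,
#' all defined on the same voxel grid as the paired [CTVolume]. The four
#' organ masks are pairwise disjoint subsets of the body; the "remaining
#' soft tissue" is body minus the four organs.
#'
#' @slot masks named list of logical 3-D arrays (body, bone, bladder,
#'   rectum, prostate), identical dimensions.
#' @export
setClass("OrganMaskSet",
  representation(masks = "list"),
  validity = function(object) {
    m <- object@masks
    if (!identical(sort(names(m)), sort(STRUCTURES)))
      return(paste("masks must be named:", paste(STRUCTURES, collapse = ", ")))
    dims <- lapply(m, dim)
    if (!all(vapply(dims, identical, logical(1), dims[[1]])))
      return("all masks must share the same dimensions")
    if (!all(vapply(m, is.logical, logical(1))))
      return("masks must be logical arrays")
    body <- m$body
    for (o in ORGANS) {
      if (any(m[[o]] & !body)) return(sprintf("'%s' extends outside the body", o))
    }
    for (i in seq_along(ORGANS)) for (j in seq_len(i - 1L)) {
      if (any(m[[ORGANS[i]]] & m[[ORGANS[j]]]))
        return(sprintf("masks '%s' and '%s' overlap", ORGANS[i], ORGANS[j]))
    }
    if (!any(m$prostate)) return("prostate mask is empty")
    soft <- body & !(m$bone | m$bladder | m$rectum | m$prostate)
    if (!any(soft)) return("remaining soft tissue (body minus organs) is empty")
    TRUE
  })

#' PhantomSpec: parameters of the synthetic pelvic phantom
#'
#' Parametric description of one pelvic CT phantom: grid, organ geometry
#' (ellipsoids/cylinders, mm, world coordinates centred on the grid) and
#' per-tissue baseline HU distributions. See [phantomSpec()] for defaults.
#'
#' @slot shape integer(3) grid dimensions.
#' @slot spacing numeric(3) voxel size in mm.
#' @slot geometry named list of organ geometry parameters (mm).
#' @slot hu named list of c(mean, sd) HU per tissue class.
#' @slot gasProbability probability in [0, 1] of a rectal gas pocket.
#' @slot seed integer random seed.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric", geometry = "list",
                 hu = "list", gasProbability = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@shape) != 3L || any(object@shape < 8L))
      return("shape must be 3 integers >= 8")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values (mm)")
    if (object@gasProbability < 0 || object@gasProbability > 1)
      return("gasProbability must be in [0, 1]")
    need <- c("soft", "bone", "bladder", "rectum", "prostate")
    if (!all(need %in% names(object@hu)))
      return(paste("hu must contain:", paste(need, collapse = ", ")))
    mh <- vapply(object@hu[need], `[`, numeric(1), 1L)
    # air < soft tissue < bone ordering of the baseline means
    if (!(-1000 < min(mh) && mh[["soft"]] < mh[["bone"]]))
      return("baseline HU means must satisfy air < soft tissue < bone")
    TRUE
  })

#' DensityCurve: HU to relative electron density calibration
#'
#' Ordered control points mapping HU to relative electron density, applied
#' by piecewise-linear interpolation with clamping outside the range. Must
#' anchor air (-1000 HU -> 0) and water (0 HU -> 1).
#'
#' @slot hu numeric, strictly increasing HU control points.
#' @slot density numeric, non-decreasing relative electron densities.
#' @export
setClass("DensityCurve",
  representation(hu = "numeric", density = "numeric"),
  validity = function(object) {
    if (length(object@hu) < 2L) return("need at least two control points")
    if (length(object@hu) != length(object@density))
      return("hu and density lengths differ")
    if (any(diff(object@hu) <= 0)) return("hu must be strictly increasing")
    if (any(diff(object@density) < 0)) return("density must be non-decreasing")
    if (abs(.curveEval(object@hu, object@density, -1000)) > 1e-9)
      return("density at -1000 HU (air) must be 0")
    if (abs(.curveEval(object@hu, object@density, 0) - 1) > 1e-9)
      return("density at 0 HU (water) must be 1")
    TRUE
  })

#' BeamPlan: simplified coplanar photon plan
#'
#' Geometry and physics of the simplified multi-beam 6 MV photon model: a
#' set of coplanar gantry angles at fixed source-axis distance, a single
#' broad-beam attenuation coefficient, a cylindrical field aperture per
#' beam, and a total prescription delivered in equal fractions. The slot
#' `normalisation` is the single global factor, fixed on the unperturbed
#' volume via [calibratePlan()], that maps the raw model output to Gy so
#' the baseline isocentre dose equals the prescription; it is then reused
#' unchanged on every perturbed volume of that patient.
#'
#' @slot isocentre numeric(3) mm, beam intersection point (prostate centroid).
#' @slot gantryAngles numeric, coplanar gantry angles in degrees.
#' @slot sad numeric, source-axis distance in mm.
#' @slot muWater numeric, linear attenuation coefficient of water (per mm).
#' @slot aperture numeric, field radius around each beam axis in mm.
#' @slot weights numeric, non-negative per-beam weights.
#' @slot prescriptionGy numeric, total prescribed dose in Gy.
#' @slot fractions integer, number of fractions.
#' @slot gridSpacing numeric, dose-grid spacing in mm (isotropic).
#' @slot densityCurve a [DensityCurve-class].
#' @slot rayStep numeric, WEPL sampling step in mm.
#' @slot normalisation numeric, global Gy scaling; NA before calibration.
#' @export
setClass("BeamPlan",
  representation(isocentre = "numeric", gantryAngles = "numeric",
                 sad = "numeric", muWater = "numeric", aperture = "numeric",
                 weights = "numeric", prescriptionGy = "numeric",
                 fractions = "integer", gridSpacing = "numeric",
                 densityCurve = "DensityCurve", rayStep = "numeric",
                 normalisation = "numeric"),
  validity = function(object) {
    nb <- length(object@gantryAngles)
    if (nb < 1L) return("need at least one beam")
    if (length(object@weights) != nb) return("one weight per beam required")
    if (any(object@weights < 0) || sum(object@weights) <= 0)
      return("weights must be non-negative with positive sum")
    if (object@sad <= 0) return("sad must be positive (mm)")
    if (object@muWater <= 0) return("muWater must be positive (per mm)")
    if (object@aperture <= 0) return("aperture must be positive (mm)")
    if (object@prescriptionGy <= 0) return("prescriptionGy must be positive")
    if (object@fractions < 1L) return("fractions must be >= 1")
    dpf <- object@prescriptionGy / object@fractions
    if (!is.finite(dpf) || dpf <= 0)
      return("prescription must equal fractions x dose-per-fraction > 0")
    if (length(object@isocentre) != 3L) return("isocentre must be length 3 (mm)")
    if (object@rayStep <= 0) return("rayStep must be positive (mm)")
    TRUE
  })

#' ArtefactSpec: a localized spherical HU artefact
#'
#' A spherical additive HU error of given diameter, displaced from the
#' isocentre along the source-to-isocentre axis of one beam.
#'
#' @slot deltaHU additive HU offset in [-250, 250].
#' @slot diameter sphere diameter in mm, in [2, 50].
#' @slot distance displacement from the isocentre in mm, in [0, 100].
#' @slot beamIndex 1-based index of the beam whose axis carries the
#'   displacement.
#' @export
setClass("ArtefactSpec",
  representation(deltaHU = "numeric", diameter = "numeric",
                 distance = "numeric", beamIndex = "integer"),
  validity = function(object) {
    if (object@deltaHU < -250 || object@deltaHU > 250)
      return("deltaHU must be in [-250, 250]")
    if (object@diameter < 2 || object@diameter > 50)
      return("diameter must be in [2, 50] mm")
    if (object@distance < 0 || object@distance > 100)
      return("distance must be in [0, 100] mm")
    if (object@beamIndex < 1L) return("beamIndex must be >= 1")
    TRUE
  })

#' OrganShiftSpec: organ-wise mean HU shifts
#'
#' Additive HU offsets applied per structure; `softTissue` applies to the
#' body minus the four delineated organs.
#'
#' @slot bladder HU offset in [-100, 100].
#' @slot rectum HU offset in [-1000, 200].
#' @slot bone HU offset in [-500, 500].
#' @slot prostate HU offset in [-100, 100].
#' @slot softTissue HU offset in [-100, 100].
#' @export
setClass("OrganShiftSpec",
  representation(bladder = "numeric", rectum = "numeric", bone = "numeric",
                 prostate = "numeric", softTissue = "numeric"),
  validity = function(object) {
    chk <- function(x, lo, hi, nm)
      if (x < lo || x > hi) sprintf("%s offset must be in [%g, %g] HU", nm, lo, hi) else NULL
    msg <- c(chk(object@bladder, -100, 100, "bladder"),
             chk(object@rectum, -1000, 200, "rectum"),
             chk(object@bone, -500, 500, "bone"),
             chk(object@prostate, -100, 100, "prostate"),
             chk(object@softTissue, -100, 100, "softTissue"))
    if (length(msg)) msg[[1]] else TRUE
  })

#' DoseGrid: a 3-D dose distribution in Gy
#'
#' @slot voxels 3-D numeric array of dose (Gy), non-negative and finite.
#' @slot spacing numeric(3) mm.
#' @slot origin numeric(3) mm, world position of the first node.
#' @export
setClass("DoseGrid",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L) return("voxels must be a 3-D array")
    if (any(!is.finite(object@voxels))) return("dose must be finite")
    if (any(object@voxels < 0)) return("dose must be non-negative")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("spacing must be 3 positive values (mm)")
    TRUE
  })

#' MorrisDesign: one-at-a-time trajectory design
#'
#' R trajectories of K+1 points each on a p-level grid in normalised
#' [0,1]^K factor space. Within a trajectory consecutive rows differ in
#' exactly one factor by +/- delta, and every factor moves exactly once.
#'
#' @slot design numeric matrix, N = R*(K+1) rows by K columns, normalised.
#' @slot factors data.frame with columns name, lower, upper (physical units).
#' @slot repetitions integer R.
#' @slot levels integer p.
#' @slot delta numeric unit step in normalised space, p/(2(p-1)).
#' @slot steps data.frame (trajectory, step, factor, signedDelta) recording
#'   which factor moved at each within-trajectory transition.
#' @slot seed integer seed the design was drawn from.
#' @export
setClass("MorrisDesign",
  representation(design = "matrix", factors = "data.frame",
                 repetitions = "integer", levels = "integer",
                 delta = "numeric", steps = "data.frame", seed = "integer"),
  validity = function(object) {
    K <- nrow(object@factors)
    R <- object@repetitions
    if (!all(c("name", "lower", "upper") %in% names(object@factors)))
      return("factors must have columns name, lower, upper")
    if (any(object@factors$lower >= object@factors$upper))
      return("each factor needs lower < upper")
    if (ncol(object@design) != K) return("design must have K columns")
    if (nrow(object@design) != R * (K + 1L))
      return("design must have R*(K+1) rows")
    if (min(object@design) < -1e-9 || max(object@design) > 1 + 1e-9)
      return("design must lie in [0,1]^K")
    if (nrow(object@steps) != R * K)
      return("steps must record R*K transitions")
    TRUE
  })

#' ExperimentResult: one full sensitivity experiment over a cohort
#'
#' @slot summary data.frame of per-patient Morris summaries (patient,
#'   factor, mu, sigma, mu_star, distance).
#' @slot cohort data.frame of cohort aggregates per factor (means and sds
#'   of mu_star and sigma across patients, mean distance, rank, label).
#' @slot ee data.frame of raw elementary effects (patient, factor,
#'   repetition, ee).
#' @slot scc data.frame of Spearman correlations (patient, factor, scc);
#'   zero rows for experiments without sweeps.
#' @slot designs list of per-patient [MorrisDesign-class] objects.
#' @slot evaluations data.frame of all model evaluations (patient, row,
#'   isocentre dose and physical factor values).
#' @slot provenance list of seeds and configuration for reproduction.
#' @export
setClass("ExperimentResult",
  representation(summary = "data.frame", cohort = "data.frame",
                 ee = "data.frame", scc = "data.frame", designs = "list",
                 evaluations = "data.frame", provenance = "list"))
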