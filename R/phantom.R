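#' Default synthetic pelvic phantom specification
#'
#' Builds a [PhantomSpec-class] describing a parametric pelvic CT phantom:
#' an elliptic-cylinder body of soft tissue containing femoral heads,
#' sacrum and pubic bones, a bladder anterior--superior to a prostate
#' spheroid, and a rectum (vertical cylinder, optionally holding a gas
#' pocket) posterior to the prostate. All geometry is in mm, in world
#' coordinates centred on the grid (LPS axes: +x left, +y posterior,
#' +z superior). Baseline tissue HU follow standard CT literature values.
#'
#' The prostate centre sits 15 mm anterior of the body axis, which leaves
#' more than 100 mm of tissue posterior to the isocentre so that artefact
#' displacement sweeps along a beam axis remain inside the body.
#'
#' @param shape integer(3) grid dimensions (default 128 x 128 x 64).
#' @param spacing numeric(3) voxel size in mm (default 2 x 2 x 2.5).
#' @param geometry named list of organ geometry; see Details in the source.
#'   Defaults place all organs inside the body with jitter-proof margins.
#' @param hu named list of c(mean, sd) per tissue class
#'   (soft, bone, bladder, rectum, prostate).
#' @param gasProbability probability of a rectal gas pocket (default 0.3).
#' @param seed integer seed for the voxel noise and gas draw.
#' @return a validated [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(shape = c(64L, 64L, 32L), spacing = c(4, 4, 5))
#' @export
phantomSpec <- function(shape = c(128L, 128L, 64L),
                        spacing = c(2, 2, 2.5),
                        geometry = defaultGeometry(),
                        hu = defaultTissueHU(),
                        gasProbability = 0.3,
                        seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      geometry = geometry, hu = hu,
      gasProbability = gasProbability, seed = as.integer(seed))
}

#' @rdname phantomSpec
#' @export
defaultGeometry <- function() {
  list(
    body = c(rx = 110, ry = 95),
    prostate = list(centre = c(0, -15, 0), radii = c(20, 18, 18)),
    bladder  = list(centre = c(0, -62, 10), radii = c(28, 24, 22)),
    rectum   = list(centre = c(0, 45), radius = 14, halfLength = 65),
    gasRadius = 8,
    bones = list(
      femoralL = list(centre = c( 72, -5, -10), radii = c(20, 20, 20)),
      femoralR = list(centre = c(-72, -5, -10), radii = c(20, 20, 20)),
      sacrum   = list(centre = c(0, 78, 0),     radii = c(20, 12, 38)),
      pubicL   = list(centre = c( 25, -72, -25), radii = c(12, 8, 18)),
      pubicR   = list(centre = c(-25, -72, -25), radii = c(12, 8, 18))))
}

#' @rdname phantomSpec
#' @export
defaultTissueHU <- function() {
  list(soft = c(35, 10), bone = c(700, 150), bladder = c(10, 8),
       rectum = c(-20, 15), prostate = c(40, 5))
}

# logical mask of voxel centres inside an axis-aligned ellipsoid
.ellipsoidMask <- function(coords, centre, radii) {
  ex <- ((coords[[1]] - centre[1]) / radii[1])^2
  ey <- ((coords[[2]] - centre[2]) / radii[2])^2
  ez <- ((coords[[3]] - centre[3]) / radii[3])^2
  outer(outer(ex, ey, `+`), ez, `+`) <= 1
}

# per-tissue HU draw, truncated at mean +/- 4 sd so tissue histograms
# stay inside their configured band
.tissueDraw <- function(n, ms) {
  x <- stats::rnorm(n, ms[1], ms[2])
  pmin(pmax(x, ms[1] - 4 * ms[2]), ms[1] + 4 * ms[2])
}

#' Generate one synthetic pelvic phantom
#'
#' Renders the parametric phantom described by a [PhantomSpec-class] into a
#' [CTVolume-class] (HU) and a matching [OrganMaskSet-class]. Voxels outside
#' the body are air (-1000 HU). The same spec (including its seed) always
#' reproduces a bit-identical phantom.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with elements `ct` ([CTVolume-class]) and
#'   `masks` ([OrganMaskSet-class]).
#' @examples
#' ph <- generatePhantom(phantomSpec(shape = c(48L, 48L, 24L),
#'                                   spacing = c(5, 5, 6)))
#' ph$ct
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  g <- spec@geometry
  shape <- spec@shape
  sp <- spec@spacing
  origin <- -(shape - 1) * sp / 2   # grid centred on the world origin
  coords <- .axisCoords(shape, sp, origin)

  ex <- (coords[[1]] / g$body[["rx"]])^2
  ey <- (coords[[2]] / g$body[["ry"]])^2
  body <- outer(outer(ex, ey, `+`), rep(0, shape[3]), `+`) <= 1

  bone <- array(FALSE, shape)
  for (b in g$bones) bone <- bone | .ellipsoidMask(coords, b$centre, b$radii)
  bladder <- .ellipsoidMask(coords, g$bladder$centre, g$bladder$radii)
  prostate <- .ellipsoidMask(coords, g$prostate$centre, g$prostate$radii)
  rc <- g$rectum
  rxy <- outer((coords[[1]] - rc$centre[1])^2, (coords[[2]] - rc$centre[2])^2,
               `+`) <= rc$radius^2
  rz <- abs(coords[[3]]) <= rc$halfLength
  rectum <- outer(rxy, rz, `&`)

  organs <- list(bone = bone, bladder = bladder, rectum = rectum,
                 prostate = prostate)
  for (nm in names(organs)) {
    if (!any(organs[[nm]])) stop("structure '", nm, "' contains no voxel")
    if (any(organs[[nm]] & !body))
      stop("invalid phantom spec: '", nm, "' exits the body contour")
  }
  nms <- names(organs)
  for (i in seq_along(nms)) for (j in seq_len(i - 1L)) {
    if (any(organs[[nms[i]]] & organs[[nms[j]]]))
      stop("invalid phantom spec: '", nms[i], "' and '", nms[j], "' overlap")
  }

  vol <- withSeed(spec@seed, {
    v <- array(-1000, shape)
    soft <- body
    v[soft] <- .tissueDraw(sum(soft), spec@hu$soft)
    v[bone] <- .tissueDraw(sum(bone), spec@hu$bone)
    v[bladder] <- .tissueDraw(sum(bladder), spec@hu$bladder)
    v[rectum] <- .tissueDraw(sum(rectum), spec@hu$rectum)
    v[prostate] <- .tissueDraw(sum(prostate), spec@hu$prostate)
    if (stats::runif(1) < spec@gasProbability) {
      gz <- stats::runif(1, -0.6, 0.6) * rc$halfLength / 2
      gas <- .ellipsoidMask(coords, c(rc$centre[1], rc$centre[2], gz),
                            rep(g$gasRadius, 3)) & rectum
      v[gas] <- -1000
    }
    v
  })
  vol <- pmin(pmax(vol, -1000), 3100)

  ct <- new("CTVolume", voxels = vol, spacing = sp, origin = origin)
  masks <- new("OrganMaskSet",
               masks = list(body = body, bone = bone, bladder = bladder,
                            rectum = rectum, prostate = prostate))
  list(ct = ct, masks = masks)
}

#' Generate a cohort of phantoms with inter-patient variability
#'
#' Draws `n` phantoms from a template spec, applying per-patient
#' multiplicative jitter (+/-10%) to every organ radius and additive jitter
#' to the tissue baseline means (+/-10 HU for soft tissues, +/-100 HU for
#' bone), emulating anatomical and density variability across a patient
#' population. The body outline is kept fixed so jittered organs always
#' stay inside it.
#'
#' @param spec template [PhantomSpec-class] (defaults to [phantomSpec()]).
#' @param n number of patients (the study cohort size, default 39).
#' @param seed master seed; patient i's phantom noise uses `seed + i`.
#' @return list of length `n`; each element a list with `ct`, `masks` and
#'   the jittered `spec`.
#' @export
phantomCohort <- function(spec = phantomSpec(), n = 39L, seed = 1L) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  specs <- withSeed(seed, lapply(seq_len(n), function(i) jitterSpec(spec, i)))
  for (i in seq_len(n)) specs[[i]]@seed <- as.integer(seed + i)
  lapply(specs, function(s) c(generatePhantom(s), list(spec = s)))
}

#' @rdname phantomCohort
#' @param patient patient index (only used to label errors).
#' @details `jitterSpec` draws one patient's jittered spec from the current
#'   RNG stream; exported so a single jittered patient can be reproduced.
#' @export
jitterSpec <- function(spec, patient = 1L) {
  g <- spec@geometry
  jit <- function(r) r * stats::runif(length(r), 0.9, 1.1)
  g$prostate$radii <- jit(g$prostate$radii)
  g$bladder$radii <- jit(g$bladder$radii)
  g$rectum$radius <- jit(g$rectum$radius)
  g$rectum$halfLength <- jit(g$rectum$halfLength)
  g$bones <- lapply(g$bones, function(b) { b$radii <- jit(b$radii); b })
  hu <- spec@hu
  for (t in c("soft", "bladder", "rectum", "prostate"))
    hu[[t]][1] <- hu[[t]][1] + stats::runif(1, -10, 10)
  hu$bone[1] <- hu$bone[1] + stats::runif(1, -100, 100)
  out <- spec
  out@geometry <- g
  out@hu <- hu
  out
}
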