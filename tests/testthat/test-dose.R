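test_that("density curve anchors air and water and interpolates linearly", {
  cv <- densityCurve()
  expect_equal(huToDensity(-1000, cv), 0)
  expect_equal(huToDensity(0, cv), 1)
  expect_equal(huToDensity(500, cv), 1.3)  # midway between (0,1) and (1000,1.6)
  expect_equal(huToDensity(-500, cv), 0.5)
  expect_equal(huToDensity(-2000, cv), 0)   # clamped below
  expect_equal(huToDensity(5000, cv), 2.1)  # clamped above
  expect_error(densityCurve(hu = c(-1000, 0), density = c(0.2, 1)), "air")
})

test_that("radiological depth reproduces closed-form path integrals", {
  air <- waterTank(hu = -1000)
  expect_equal(radiologicalDepth(air, c(0, -2000, 0), c(0, 0, 0)), 0)

  water <- waterTank(hu = 0)
  expect_equal(radiologicalDepth(water, c(0, -2000, 0), c(0, 0, 0)), 100,
               tolerance = 1e-9)

  # 20 mm slab of density 1.5 (833.33 HU) across the beam: 80 + 20*1.5 = 110
  slab <- waterTank(hu = 0)
  v <- voxels(slab)
  iy <- which(abs(seq(-100, 100, by = 5) - (-52.5)) <= 7.5)  # centres -60..-45
  v[, iy, ] <- 2500 / 3
  slab@voxels <- v
  expect_equal(radiologicalDepth(slab, c(0, -2000, 0), c(0, 0, 0)), 110,
               tolerance = 1e-6)

  expect_error(radiologicalDepth(water, c(0, -2000, 0), c(0, 500, 0)),
               "outside the volume bounds")
})

test_that("baseline isocentre dose equals the 78 Gy prescription by construction", {
  ph <- miniPhantom()
  plan <- miniPlan()
  expect_equal(plan@prescriptionGy, plan@fractions * 2)
  expect_equal(isocentreDose(ph$ct, plan), 78, tolerance = 1e-12)
  # the same normalisation is reused unchanged on perturbed volumes
  shifted <- applyOrganShifts(ph$ct, ph$masks, organShiftSpec(softTissue = 100))
  expect_lt(isocentreDose(shifted, plan), 78)
})

test_that("uniform HU overestimation inside the body reduces the isocentre dose", {
  ph <- miniPhantom()
  plan <- miniPlan()
  v <- voxels(ph$ct)
  v[ph$masks@masks$body] <- v[ph$masks@masks$body] + 100
  up <- new("CTVolume", voxels = v, spacing = voxelSpacing(ph$ct),
            origin = gridOrigin(ph$ct))
  expect_lt(isocentreDose(up, plan), 78)
})

test_that("single-beam dose on a water tank matches the one-ray closed form", {
  water <- waterTank(hu = 0)
  plan <- makeBeamPlan(isocentre = c(0, 0, 0), nBeams = 1L, gantryAngles = 0,
                       gridSpacing = 10, aperture = 25)
  plan <- calibratePlan(plan, water)
  dg <- computeDose(water, plan)
  # node on the beam axis, 30 mm upstream of the isocentre
  atNode <- isocentreDose(dg, makeBeamPlan(isocentre = c(0, -30, 0),
                                           nBeams = 1L, gantryAngles = 0))
  expected <- 78 * exp(plan@muWater * 30) * (1000 / 970)^2
  expect_equal(atNode, expected, tolerance = 1e-6)
  expect_equal(isocentreDose(dg, plan), 78, tolerance = 1e-9)
  expect_true(all(voxels(dg) >= 0) && all(is.finite(voxels(dg))))
})

test_that("dose grids align the isocentre on a node and interpolate trilinearly", {
  dg <- new("DoseGrid", voxels = array(2, c(4, 4, 4)), spacing = c(3, 3, 3),
            origin = c(0, 0, 0))
  anyPoint <- makeBeamPlan(isocentre = c(4.1, 2.7, 6.2))
  expect_equal(isocentreDose(dg, anyPoint), 2)

  v <- array(0, c(3, 3, 3)); v[1, 2, 2] <- 1; v[2, 2, 2] <- 3
  dg2 <- new("DoseGrid", voxels = v, spacing = c(2, 2, 2),
             origin = c(0, 0, 0))
  onNode <- makeBeamPlan(isocentre = c(2, 2, 2))
  expect_equal(isocentreDose(dg2, onNode), 3)
  midway <- makeBeamPlan(isocentre = c(1, 2, 2))
  expect_equal(isocentreDose(dg2, midway), 2)  # mean of 1 and 3
  expect_error(isocentreDose(dg2, makeBeamPlan(isocentre = c(40, 0, 0))),
               "outside the grid")

  ph <- miniPhantom()
  plan <- miniPlan()
  plan@gridSpacing <- 6
  dg3 <- computeDose(ph$ct, plan)
  expect_equal(isocentreDose(dg3, plan), 78, tolerance = 1e-9)
})

test_that("isocentre dose responds monotonically to artefact factors", {
  ph <- miniPhantom()
  plan <- miniPlan()
  doseFor <- function(...) isocentreDose(
    insertArtefact(ph$ct, ph$masks, plan, artefactSpec(...)), plan)
  byDelta <- sapply(c(-200, -100, 0, 100, 200),
                    function(d) doseFor(deltaHU = d, diameter = 50))
  expect_true(all(diff(byDelta) < 0))
  bySize <- sapply(c(10, 30, 50),
                   function(s) doseFor(deltaHU = 200, diameter = s))
  expect_true(all(diff(bySize) <= 0))
  byDist <- sapply(c(0, 50, 100),
                   function(r) doseFor(deltaHU = 200, diameter = 50,
                                       distance = r))
  expect_true(all(diff(byDist) >= 0))
})

test_that("halving the ray-sampling step changes the isocentre dose by < 0.1%", {
  ph <- miniPhantom()
  plan <- calibratePlan(planForPhantom(ph$ct, ph$masks, rayStep = 1), ph$ct)
  art <- insertArtefact(ph$ct, ph$masks, plan,
                        artefactSpec(deltaHU = 200, diameter = 50))
  d1 <- isocentreDose(art, plan)
  planFine <- calibratePlan(planForPhantom(ph$ct, ph$masks, rayStep = 0.5),
                            ph$ct)
  d2 <- isocentreDose(art, planFine)
  expect_lt(abs(d1 - d2) / d2, 0.001)
})

test_that("degenerate plans are rejected", {
  ph <- miniPhantom()
  expect_error(calibratePlan(makeBeamPlan(isocentre = c(0, 0, 500)), ph$ct),
               "outside the volume grid")
  expect_error(calibratePlan(makeBeamPlan(isocentre = c(-120, -120, 0)),
                             ph$ct),
               "in air")
  expect_error(makeBeamPlan(isocentre = c(0, 0, 0), weights = rep(0, 7)),
               "weights")
})
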