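test_that("zero-offset artefact is a bit-exact identity and inputs are never mutated", {
  ph <- miniPhantom()
  plan <- miniPlan()
  before <- voxels(ph$ct)
  out <- insertArtefact(ph$ct, ph$masks, plan, artefactSpec(deltaHU = 0))
  expect_identical(voxels(out), before)
  out2 <- insertArtefact(ph$ct, ph$masks, plan,
                         artefactSpec(deltaHU = 150, diameter = 30))
  expect_identical(voxels(ph$ct), before)  # purity
  # repeated application to the same input gives identical output
  out3 <- insertArtefact(ph$ct, ph$masks, plan,
                         artefactSpec(deltaHU = 150, diameter = 30))
  expect_identical(voxels(out2), voxels(out3))
})

test_that("artefact modifies exactly the voxel centres inside the sphere", {
  ph <- miniPhantom()
  plan <- miniPlan()
  art <- artefactSpec(deltaHU = 200, diameter = 10, distance = 20)
  out <- insertArtefact(ph$ct, ph$masks, plan, art)
  changed <- which(voxels(out) != voxels(ph$ct))

  # independent brute-force scan over every voxel centre
  g <- plan@gantryAngles[1] * pi / 180
  centre <- plan@isocentre + 20 * c(-sin(g), cos(g), 0)
  d <- dim(ph$ct); sp <- voxelSpacing(ph$ct); or <- gridOrigin(ph$ct)
  inside <- integer()
  for (k in seq_len(d[3])) for (jj in seq_len(d[2])) for (ii in seq_len(d[1])) {
    p <- or + (c(ii, jj, k) - 1) * sp
    if (sum((p - centre)^2) <= 25)
      inside <- c(inside, ii + (jj - 1) * d[1] + (k - 1) * d[1] * d[2])
  }
  expect_setequal(changed, inside)
  expect_equal(voxels(out)[changed] - voxels(ph$ct)[changed],
               rep(200, length(changed)))
})

test_that("artefact values are clamped at air and spheres outside the body are rejected", {
  ph <- miniPhantom()
  plan <- miniPlan()
  gasSpec <- miniSpec(seed = 3L, gasProbability = 1)
  gph <- generatePhantom(gasSpec)
  out <- insertArtefact(gph$ct, gph$masks, plan,
                        artefactSpec(deltaHU = -250, diameter = 50, distance = 30))
  expect_gte(min(voxels(out)), -1000)
  # a 100 mm displacement along the first (oblique anterior) beam axis
  # stays inside the default body; shrink the body to force a rejection
  empty <- array(FALSE, dim(ph$ct))
  body <- empty; body[30:34, 30:34, 14:18] <- TRUE
  prostate <- empty; prostate[32, 32, 16] <- TRUE
  tiny <- new("OrganMaskSet", masks = list(body = body, bone = empty,
                                           bladder = empty, rectum = empty,
                                           prostate = prostate))
  expect_error(
    insertArtefact(ph$ct, tiny, plan,
                   artefactSpec(deltaHU = 100, diameter = 10, distance = 100)),
    "outside the body")
})

test_that("organ shifts change exactly the masked voxels by the offset", {
  ph <- miniPhantom()
  out <- applyOrganShifts(ph$ct, ph$masks, organShiftSpec(bladder = 100))
  m <- ph$masks@masks
  expect_equal(mean(voxels(out)[m$bladder]) - mean(voxels(ph$ct)[m$bladder]),
               100)
  expect_identical(voxels(out)[!m$bladder], voxels(ph$ct)[!m$bladder])
  # all-zero shift is a bit-exact identity
  expect_identical(voxels(applyOrganShifts(ph$ct, ph$masks, organShiftSpec())),
                   voxels(ph$ct))
})

test_that("the illustrated five-organ shift moves each per-mask mean by its offset", {
  ph <- generatePhantom(miniSpec(gasProbability = 0))
  sh <- organShiftSpec(bladder = 100, rectum = 66.6, prostate = 55.5,
                       softTissue = 78, bone = -146.5)
  out <- applyOrganShifts(ph$ct, ph$masks, sh)
  m <- ph$masks@masks
  dmean <- function(mask) mean(voxels(out)[mask]) - mean(voxels(ph$ct)[mask])
  expect_equal(dmean(m$bladder), 100)
  expect_equal(dmean(m$rectum), 66.6)
  expect_equal(dmean(m$prostate), 55.5)
  expect_equal(dmean(softTissueMask(ph$masks)), 78)
  expect_equal(dmean(m$bone), -146.5)
  expect_identical(voxels(out)[!m$body], voxels(ph$ct)[!m$body])
})

test_that("rectal shifts clamp at -1000 HU and disjoint shifts commute", {
  gph <- generatePhantom(miniSpec(seed = 3L, gasProbability = 1))
  out <- applyOrganShifts(gph$ct, gph$masks, organShiftSpec(rectum = -1000))
  expect_gte(min(voxels(out)), -1000)
  base <- voxels(gph$ct)[gph$masks@masks$rectum]
  expect_equal(voxels(out)[gph$masks@masks$rectum], pmax(base - 1000, -1000))
  expect_true(any(voxels(out)[gph$masks@masks$rectum] == -1000))
  a <- applyOrganShifts(
    applyOrganShifts(gph$ct, gph$masks, organShiftSpec(bone = 200)),
    gph$masks, organShiftSpec(bladder = -50))
  b <- applyOrganShifts(
    applyOrganShifts(gph$ct, gph$masks, organShiftSpec(bladder = -50)),
    gph$masks, organShiftSpec(bone = 200))
  expect_identical(voxels(a), voxels(b))
})

test_that("perturbation specs enforce the study factor ranges", {
  expect_error(artefactSpec(deltaHU = 300), "deltaHU")
  expect_error(artefactSpec(diameter = 1), "diameter")
  expect_error(artefactSpec(distance = 150), "distance")
  expect_error(organShiftSpec(rectum = -1500), "rectum")
  expect_error(organShiftSpec(bone = 600), "bone")
})
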