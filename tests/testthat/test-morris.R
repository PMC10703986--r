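threeFactors <- data.frame(name = c("a", "b", "c"),
                           lower = c(-250, 0, 2), upper = c(250, 100, 50))

test_that("design arithmetic: R trajectories of K+1 points on the level grid", {
  d1 <- buildMorrisDesign(threeFactors, repetitions = 50, seed = 1)
  expect_equal(nrow(d1@design), 200)       # R=50, K=3
  five <- data.frame(name = letters[1:5], lower = rep(0, 5), upper = rep(1, 5))
  d2 <- buildMorrisDesign(five, repetitions = 40, seed = 1)
  expect_equal(nrow(d2@design), 240)       # R=40, K=5
  expect_equal(d1@delta, 2 / 3)            # p = 4 levels

  # every coordinate sits on the p-level grid
  expect_true(all(abs(d1@design * 3 - round(d1@design * 3)) < 1e-12))

  # OAT structure: consecutive rows differ in exactly one factor by delta,
  # and each factor moves exactly once per trajectory
  for (r in seq_len(d1@repetitions)) {
    rows <- d1@design[(r - 1) * 4 + 1:4, ]
    movedFactors <- integer()
    for (s in 1:3) {
      df <- rows[s + 1, ] - rows[s, ]
      moved <- which(df != 0)
      expect_length(moved, 1L)
      expect_equal(unname(abs(df[moved])), 2 / 3, tolerance = 1e-12)
      movedFactors <- c(movedFactors, moved)
    }
    expect_setequal(movedFactors, 1:3)
  }

  # reproducibility and seed sensitivity
  expect_identical(d1@design,
                   buildMorrisDesign(threeFactors, 50, seed = 1)@design)
  expect_false(identical(d1@design,
                         buildMorrisDesign(threeFactors, 50, seed = 2)@design))
})

test_that("denormalisation maps the unit cube onto physical ranges", {
  d <- buildMorrisDesign(threeFactors, repetitions = 10, seed = 3)
  phys <- denormaliseDesign(d)
  expect_true(all(phys[, "a"] >= -250 & phys[, "a"] <= 250))
  expect_true(all(phys[, "b"] >= 0 & phys[, "b"] <= 100))
  expect_true(all(phys[, "c"] >= 2 & phys[, "c"] <= 50))
  m <- matrix(c(0, 1, 0.5), 3, 3)
  pm <- denormaliseDesign(m, threeFactors)
  expect_equal(pm[, 1], c(-250, 250, 0))     # midpoint of [-250,250] is 0 HU
  expect_equal(pm[, 2], c(0, 100, 50))
  expect_equal(normaliseDesign(pm, threeFactors), m)  # round trip
})

test_that("elementary effects recover constant, linear and interacting models", {
  d <- buildMorrisDesign(threeFactors, repetitions = 20, seed = 5)
  X <- d@design

  eeConst <- elementaryEffects(d, rep(3.14, nrow(X)))
  expect_true(all(eeConst == 0))

  eeLin <- elementaryEffects(d, 3 * X[, 1])
  expect_equal(unname(eeLin[, 1]), rep(3, 20), tolerance = 1e-12)
  expect_true(all(abs(eeLin[, 2:3]) < 1e-12))

  yInt <- X[, 1] * X[, 2]
  eeInt <- elementaryEffects(d, yInt)
  ref <- naiveEffects(X, 3, 20, yInt)
  expect_equal(unname(eeInt), ref, tolerance = 1e-12)

  expect_error(elementaryEffects(d, c(NaN, rep(1, nrow(X) - 1))),
               "non-finite model output at design row")
  expect_error(elementaryEffects(d, 1:5), "one value per design row")
})

test_that("summaries on f = sum(a_i x_i) give mu = a, mu* = |a|, sigma = 0", {
  a <- c(3, -1, 0)
  for (seed in c(2, 17, 99)) {
    d <- buildMorrisDesign(threeFactors, repetitions = 12, seed = seed)
    y <- as.vector(d@design %*% a)
    s <- morrisSummary(elementaryEffects(d, y))
    expect_equal(s$mu, a, tolerance = 1e-10)
    expect_equal(s$mu_star, abs(a), tolerance = 1e-10)
    expect_equal(s$sigma, rep(0, 3), tolerance = 1e-10)
  }
})

test_that("summaries match an independent reference on shared design and outputs", {
  fac <- data.frame(name = c("u", "v", "w", "x"),
                    lower = c(-1, 0, 2, -5), upper = c(1, 10, 4, 5))
  d <- buildMorrisDesign(fac, repetitions = 25, seed = 8)
  X <- d@design
  y <- sin(3 * X[, 1]) + X[, 2]^2 * X[, 3] - exp(-X[, 4])
  s <- morrisSummary(elementaryEffects(d, y))
  refEE <- naiveEffects(X, 4, 25, y)
  expect_equal(s$mu, colMeans(refEE), tolerance = 1e-10)
  expect_equal(s$mu_star, colMeans(abs(refEE)), tolerance = 1e-10)
  expect_equal(s$sigma, apply(refEE, 2, sd), tolerance = 1e-10)
  expect_equal(s$distance, sqrt(colMeans(abs(refEE))^2 + apply(refEE, 2, sd)^2),
               tolerance = 1e-10)
})

test_that("hand-worked micro-examples for the EE summaries", {
  s1 <- morrisSummary(cbind(e = c(2, 2, 2)))
  expect_equal(s1$mu, 2); expect_equal(s1$mu_star, 2)
  expect_equal(s1$sigma, 0); expect_equal(s1$distance, 2)

  s2 <- morrisSummary(cbind(e = c(-2, 2)))
  expect_equal(s2$mu, 0)
  expect_equal(s2$mu_star, 2)  # |EE| mean resolves opposite signs

  s3 <- morrisSummary(cbind(e = c(1, 3)))
  expect_equal(s3$mu, 2)
  expect_equal(s3$sigma, sqrt(2))     # sample standard deviation
  expect_equal(s3$distance, sqrt(6))  # sqrt(mu*^2 + sigma^2)

  expect_error(morrisSummary(cbind(e = 1)), "at least 2")
})

test_that("mu* dominates |mu| and D dominates both mu* and sigma", {
  set.seed(42)
  for (k in 1:20) {
    ee <- matrix(rnorm(30, sd = runif(1, 0.1, 5)), 10, 3)
    s <- morrisSummary(ee)
    expect_true(all(s$mu_star >= abs(s$mu) - 1e-12))
    expect_true(all(s$distance >= s$mu_star - 1e-12))
    expect_true(all(s$distance >= s$sigma - 1e-12))
  }
})

test_that("factor classification follows the mu*-sigma quadrants and D ranking", {
  s <- data.frame(factor = c("big", "inter", "none"),
                  mu_star = c(5, 2, 0), sigma = c(1, 4, 0))
  cl <- classifyFactors(s)
  expect_equal(cl$label, c("linear/additive", "nonlinear-or-interacting",
                           "negligible"))
  expect_equal(cl$rank[cl$factor == "big"], 1L)
  d <- sqrt(s$mu_star^2 + s$sigma^2)
  expect_equal(cl$rank, rank(-d, ties.method = "first"))
  expect_error(classifyFactors(s[0, ]), "empty")
})
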