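# Shared fixtures: a miniature phantom grid (same world extent as the
# default, coarser voxels) keeps the whole suite fast while preserving
# the organ geometry in mm.

miniSpec <- function(seed = 1L, gasProbability = 0.3, ...) {
  phantomSpec(shape = c(64L, 64L, 32L), spacing = c(4, 4, 5),
              gasProbability = gasProbability, seed = seed, ...)
}

miniPhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generatePhantom(miniSpec())
    cache
  }
})

miniPlan <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- miniPhantom()
      cache <<- calibratePlan(planForPhantom(ph$ct, ph$masks), ph$ct)
    }
    cache
  }
})

miniCohort <- function(n = 2, seed = 11) {
  phantomCohort(miniSpec(), n = n, seed = seed)
}

# uniform block of given HU embedded in an air grid: a water tank when hu = 0
waterTank <- function(hu = 0, shape = c(41L, 41L, 21L), spacing = c(5, 5, 5)) {
  origin <- -(shape - 1) * spacing / 2
  new("CTVolume", voxels = array(hu, shape), spacing = spacing,
      origin = origin)
}

# Independent reference for elementary effects: re-scan the design matrix
# itself for the factor that moved between consecutive rows (no use of the
# design's step bookkeeping), then summarise with plain mean/sd.
naiveEffects <- function(designMat, K, R, outputs) {
  ee <- matrix(NA_real_, R, K)
  for (r in seq_len(R)) {
    for (s in seq_len(K)) {
      i1 <- (r - 1) * (K + 1) + s
      i2 <- i1 + 1
      moved <- which(designMat[i2, ] != designMat[i1, ])
      step <- designMat[i2, moved] - designMat[i1, moved]
      ee[r, moved] <- (outputs[i2] - outputs[i1]) / step
    }
  }
  ee
}
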