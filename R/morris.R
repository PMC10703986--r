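#' Build a Morris one-at-a-time trajectory design
#'
#' Draws R trajectories in normalised [0,1]^K factor space on a p-level
#' grid. Each trajectory starts at a random grid point and then moves one
#' factor at a time, in random order, by the unit step
#' delta = p / (2 (p - 1)); when a move would leave \[0, 1\] its sign is
#' flipped (always feasible on the level grid). The model is evaluated
#' once per design row, N = R (K + 1) times per patient.
#'
#' @param factors data.frame with columns `name`, `lower`, `upper`
#'   (physical units, e.g. HU or mm).
#' @param repetitions R, the number of trajectories (= elementary effects
#'   per factor).
#' @param levels p, the number of grid levels (even, default 4).
#' @param seed integer seed; the same seed reproduces the design exactly.
#' @return a [MorrisDesign-class].
#' @examples
#' fac <- data.frame(name = c("a", "b", "c"),
#'                   lower = c(-250, 0, 2), upper = c(250, 100, 50))
#' buildMorrisDesign(fac, repetitions = 50, seed = 1)
#' @export
buildMorrisDesign <- function(factors, repetitions, levels = 4L, seed = 1L) {
  stopifnot(is.data.frame(factors),
            all(c("name", "lower", "upper") %in% names(factors)))
  K <- nrow(factors)
  R <- as.integer(repetitions)
  p <- as.integer(levels)
  if (K < 1L) stop("need at least one factor")
  if (R < 2L) stop("repetitions must be >= 2")
  if (p < 2L || p %% 2L != 0L) stop("levels must be an even integer >= 2")
  delta <- p / (2 * (p - 1))
  grid <- seq(0, 1, length.out = p)

  rows <- matrix(NA_real_, R * (K + 1L), K)
  steps <- vector("list", R)
  withSeed(seed, {
    for (r in seq_len(R)) {
      x <- grid[sample.int(p, K, replace = TRUE)]
      sgn <- sample(c(-1, 1), K, replace = TRUE)
      infeasible <- x + sgn * delta < -1e-9 | x + sgn * delta > 1 + 1e-9
      sgn[infeasible] <- -sgn[infeasible]
      ord <- sample.int(K)
      base <- (r - 1L) * (K + 1L)
      rows[base + 1L, ] <- x
      for (s in seq_len(K)) {
        i <- ord[s]
        x[i] <- round((x[i] + sgn[i] * delta) * (p - 1)) / (p - 1)
        rows[base + s + 1L, ] <- x
      }
      steps[[r]] <- data.frame(trajectory = r, step = seq_len(K),
                               factor = ord, signedDelta = sgn[ord] * delta)
    }
  })
  colnames(rows) <- factors$name
  new("MorrisDesign", design = rows, factors = factors, repetitions = R,
      levels = p, delta = delta, steps = do.call(rbind, steps),
      seed = as.integer(seed))
}

#' Map a normalised design onto physical factor ranges
#'
#' Affine map of each normalised \[0, 1\] column onto its factor's
#' \[lower, upper\] interval, and back.
#'
#' @param design a [MorrisDesign-class] or a numeric matrix in \[0,1\]^K.
#' @param factors data.frame (`name`, `lower`, `upper`); taken from the
#'   design when omitted.
#' @return numeric matrix with one column per factor.
#' @export
denormaliseDesign <- function(design, factors = NULL) {
  if (is(design, "MorrisDesign")) {
    if (is.null(factors)) factors <- design@factors
    design <- design@design
  }
  out <- design
  for (k in seq_len(ncol(design)))
    out[, k] <- factors$lower[k] + design[, k] * (factors$upper[k] - factors$lower[k])
  out
}

#' @rdname denormaliseDesign
#' @export
normaliseDesign <- function(design, factors) {
  out <- design
  for (k in seq_len(ncol(design)))
    out[, k] <- (design[, k] - factors$lower[k]) / (factors$upper[k] - factors$lower[k])
  out
}

#' Elementary effects of one patient's model evaluations
#'
#' For each within-trajectory transition, the elementary effect of the
#' factor that moved is the finite difference of the model output divided
#' by the signed step, in normalised factor space:
#' EE = (f(x + delta e_i) - f(x)) / delta. A forward and a backward move
#' across the same pair of points give the same effect.
#'
#' @param design a [MorrisDesign-class].
#' @param outputs numeric vector of model outputs, aligned row-for-row
#'   with the design matrix.
#' @return numeric matrix with R rows (one per trajectory) and K columns
#'   (one per factor), column names the factor names.
#' @export
elementaryEffects <- function(design, outputs) {
  K <- nrow(design@factors)
  R <- design@repetitions
  if (length(outputs) != nrow(design@design))
    stop("outputs must have one value per design row (expected ",
         nrow(design@design), ", got ", length(outputs), ")")
  bad <- which(!is.finite(outputs))
  if (length(bad))
    stop("non-finite model output at design row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  ee <- matrix(NA_real_, R, K, dimnames = list(NULL, design@factors$name))
  st <- design@steps
  for (idx in seq_len(nrow(st))) {
    r <- st$trajectory[idx]
    s <- st$step[idx]
    i <- st$factor[idx]
    base <- (r - 1L) * (K + 1L)
    ee[r, i] <- (outputs[base + s + 1L] - outputs[base + s]) / st$signedDelta[idx]
  }
  ee
}

#' Summarise elementary effects per factor
#'
#' For each factor: mu = mean of the R elementary effects, sigma = their
#' sample standard deviation, mu_star = mean of absolute effects (guards
#' against sign cancellation in non-monotonic responses), and the
#' Euclidean distance D = sqrt(mu_star^2 + sigma^2) of the (mu_star,
#' sigma) point to the origin, used to rank factor importance.
#'
#' @param ee elementary-effects matrix from [elementaryEffects()]
#'   (R rows, K columns), or any numeric matrix with >= 2 rows.
#' @return data.frame with columns `factor`, `mu`, `sigma`, `mu_star`,
#'   `distance`.
#' @examples
#' morrisSummary(cbind(f1 = c(-2, 2), f2 = c(1, 3)))
#' @export
morrisSummary <- function(ee) {
  ee <- as.matrix(ee)
  if (nrow(ee) < 2L) stop("need at least 2 elementary effects per factor")
  if (any(!is.finite(ee))) stop("elementary effects must be finite")
  mu <- colMeans(ee)
  sigma <- apply(ee, 2, stats::sd)
  mu_star <- colMeans(abs(ee))
  data.frame(factor = colnames(ee) %||% paste0("x", seq_len(ncol(ee))),
             mu = unname(mu), sigma = unname(sigma),
             mu_star = unname(mu_star),
             distance = unname(sqrt(mu_star^2 + sigma^2)),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Aggregate Morris summaries across a patient cohort
#'
#' Unweighted mean and standard deviation of mu_star and sigma over
#' patients per factor; the cohort Euclidean distance is computed from the
#' mean (mu_star, sigma) point and used to rank factors in descending
#' order of importance.
#'
#' @param summary data.frame of per-patient summaries with columns
#'   `patient`, `factor`, `mu`, `sigma`, `mu_star`, `distance`.
#' @return data.frame per factor: `mu_star`, `mu_star_sd`, `sigma`,
#'   `sigma_sd`, `distance`, `rank`.
#' @export
cohortSummary <- function(summary) {
  sp <- split(summary, summary$factor)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(factor = d$factor[1],
               mu_star = mean(d$mu_star),
               mu_star_sd = stats::sd(d$mu_star),
               sigma = mean(d$sigma),
               sigma_sd = stats::sd(d$sigma),
               row.names = NULL)
  }))
  out$distance <- sqrt(out$mu_star^2 + out$sigma^2)
  out$rank <- rank(-out$distance, ties.method = "first")
  out[order(out$rank), , drop = FALSE]
}

#' Classify factors from their Morris summary
#'
#' A factor is `negligible` when both mu_star and sigma fall below a
#' threshold (by default 5% of the largest distance D across factors);
#' `nonlinear-or-interacting` when sigma exceeds mu_star (dispersion of
#' the effects dominates their magnitude); otherwise `linear/additive`.
#'
#' @param summary data.frame with columns `factor`, `mu_star`, `sigma`
#'   (e.g. from [morrisSummary()] or [cohortSummary()]).
#' @param negligibleFrac threshold as a fraction of the maximum D.
#' @return the input with added `label` column and `rank` by descending D.
#' @export
classifyFactors <- function(summary, negligibleFrac = 0.05) {
  if (nrow(summary) == 0L) stop("empty factor summary")
  d <- sqrt(summary$mu_star^2 + summary$sigma^2)
  thr <- negligibleFrac * max(d)
  summary$label <- ifelse(summary$mu_star <= thr & summary$sigma <= thr,
                          "negligible",
                          ifelse(summary$sigma > summary$mu_star,
                                 "nonlinear-or-interacting", "linear/additive"))
  summary$rank <- rank(-d, ties.method = "first")
  summary
}
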