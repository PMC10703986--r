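#' Factor definitions for the two experiments
#'
#' Experiment 1 screens a localized spherical artefact by its intensity
#' (-250..250 HU), distance to the isocentre (0..100 mm) and diameter
#' (2..50 mm). Experiment 2 screens organ-wise mean HU shifts: bladder,
#' prostate and remaining soft tissue within +/-100 HU, bone within
#' +/-500 HU and rectum within -1000..+200 HU (wider bounds reflect how
#' hard those tissues are to predict in synthetic CT, rectal gas in
#' particular).
#'
#' @return data.frame with columns `name`, `lower`, `upper`.
#' @export
experiment1Factors <- function() {
  data.frame(name = c("intensity", "distance", "size"),
             lower = c(-250, 0, 2), upper = c(250, 100, 50))
}

#' @rdname experiment1Factors
#' @export
experiment2Factors <- function() {
  data.frame(name = c("bladder", "rectum", "bone", "prostate", "softTissue"),
             lower = c(-100, -1000, -500, -100, -100),
             upper = c(100, 200, 500, 100, 100))
}

# memoising isocentre-dose evaluator for one patient; keyed on the
# perturbation parameters so sweeps and trajectories sharing a case
# (e.g. the unperturbed point) are computed once
.doseEvaluator <- function(ct, masks, plan, kind = c("artefact", "organs"),
                           beamIndex = 1L) {
  kind <- match.arg(kind)
  cache <- new.env(parent = emptyenv())
  function(params) {
    key <- rlang::hash(list(kind, params))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    pct <- if (kind == "artefact") {
      insertArtefact(ct, masks, plan,
                     artefactSpec(deltaHU = params[["intensity"]],
                                  diameter = params[["size"]],
                                  distance = params[["distance"]],
                                  beamIndex = beamIndex))
    } else {
      applyOrganShifts(ct, masks,
                       organShiftSpec(bladder = params[["bladder"]],
                                      rectum = params[["rectum"]],
                                      bone = params[["bone"]],
                                      prostate = params[["prostate"]],
                                      softTissue = params[["softTissue"]]))
    }
    dose <- isocentreDose(pct, plan)
    cache[[key]] <- dose
    dose
  }
}

# shared experiment driver: Morris screening of `factors` over a cohort
.runExperiment <- function(cohort, factors, kind, repetitions, levels, seed,
                           beamIndex = 1L, planArgs = list(),
                           verbose = FALSE) {
  if (length(cohort) == 0L) stop("cohort is empty")
  sumL <- list(); eeL <- list(); evalL <- list(); designs <- list()
  evaluators <- list()
  for (j in seq_along(cohort)) {
    pat <- cohort[[j]]
    if (kind == "organs") {
      for (nm in c("body", STRUCTURES[-1])) {
        if (!nm %in% structureNames(pat$masks))
          stop("patient ", j, " is missing the '", nm, "' structure mask")
      }
    }
    t0 <- proc.time()[3]
    plan <- do.call(planForPhantom, c(list(pat$ct, pat$masks), planArgs))
    plan <- calibratePlan(plan, pat$ct)
    design <- buildMorrisDesign(factors, repetitions, levels,
                                seed = seed + j)
    phys <- denormaliseDesign(design)
    evalFun <- .doseEvaluator(pat$ct, pat$masks, plan, kind, beamIndex)
    doses <- vapply(seq_len(nrow(phys)),
                    function(r) evalFun(phys[r, ]), numeric(1))
    ee <- elementaryEffects(design, doses)
    s <- morrisSummary(ee)
    s <- cbind(patient = j, s)
    sumL[[j]] <- s
    eeL[[j]] <- data.frame(patient = j,
                           repetition = rep(seq_len(nrow(ee)), ncol(ee)),
                           factor = rep(colnames(ee), each = nrow(ee)),
                           ee = as.vector(ee))
    evalL[[j]] <- data.frame(patient = j, row = seq_len(nrow(phys)),
                             phys, dose = doses, check.names = FALSE)
    designs[[j]] <- design
    evaluators[[j]] <- list(evalFun = evalFun, plan = plan, patient = pat)
    if (verbose)
      message(sprintf("patient %d/%d: %d evaluations in %.1f s", j,
                      length(cohort), nrow(phys), proc.time()[3] - t0))
  }
  summary <- do.call(rbind, sumL)
  cohortAgg <- classifyFactors(cohortSummary(summary))
  list(summary = summary, cohort = cohortAgg, ee = do.call(rbind, eeL),
       evaluations = do.call(rbind, evalL), designs = designs,
       evaluators = evaluators)
}

#' Run Experiment 1: artefact screening plus Spearman sweeps
#'
#' For every patient, builds a K = 3 Morris design over the artefact
#' factors (intensity, distance, size), inserts the corresponding
#' spherical artefact for each design row, evaluates the isocentre dose
#' with the patient's calibrated plan, and summarises the elementary
#' effects. Optionally runs the one-factor-at-a-time Spearman sweeps:
#' intensity in 25 HU steps with a 50 mm artefact centred on the
#' isocentre; distance in 10 mm steps at +200 HU and 50 mm; size at
#' +200 HU placed 30 mm from the isocentre.
#'
#' @param cohort list of patients as returned by [phantomCohort()].
#' @param repetitions R, trajectories per patient (default 50; with K = 3
#'   this is 200 evaluations per patient, 7800 for a 39-patient cohort).
#' @param levels Morris grid levels p.
#' @param seed master seed; patient j uses `seed + j` for its design.
#' @param beamIndex beam axis carrying the artefact displacement.
#' @param planArgs named list of overrides passed to [makeBeamPlan()].
#' @param sweeps logical, also compute the Spearman sweeps.
#' @param sweepStep named list of grid steps (`intensity` in HU,
#'   `distance` and `size` in mm).
#' @param verbose print per-patient timing.
#' @return an [ExperimentResult-class].
#' @export
runExperiment1 <- function(cohort, repetitions = 50L, levels = 4L, seed = 1L,
                           beamIndex = 1L, planArgs = list(), sweeps = TRUE,
                           sweepStep = list(intensity = 25, distance = 10,
                                            size = 2),
                           verbose = FALSE) {
  res <- .runExperiment(cohort, experiment1Factors(), "artefact",
                        repetitions, levels, seed, beamIndex, planArgs,
                        verbose)
  scc <- data.frame(patient = integer(), factor = character(),
                    scc = numeric())
  if (sweeps) {
    sccL <- lapply(seq_along(cohort), function(j) {
      ev <- res$evaluators[[j]]
      one <- function(fac, grid, fixed) {
        sw <- sweepAndCorrelate(ev$patient$ct, ev$patient$masks, ev$plan,
                                factor = fac, grid = grid, fixed = fixed,
                                beamIndex = beamIndex,
                                evalFun = ev$evalFun)
        data.frame(patient = j, factor = fac, scc = sw$scc)
      }
      rbind(
        one("intensity", seq(-250, 250, by = sweepStep$intensity),
            list(distance = 0, size = 50)),
        one("distance", seq(0, 100, by = sweepStep$distance),
            list(intensity = 200, size = 50)),
        one("size", seq(2, 50, by = sweepStep$size),
            list(intensity = 200, distance = 30)))
    })
    scc <- do.call(rbind, sccL)
  }
  new("ExperimentResult", summary = res$summary, cohort = res$cohort,
      ee = res$ee, scc = scc, designs = res$designs,
      evaluations = res$evaluations,
      provenance = list(experiment = 1L, seed = as.integer(seed),
                        repetitions = as.integer(repetitions),
                        levels = as.integer(levels),
                        nPatients = length(cohort),
                        beamIndex = as.integer(beamIndex),
                        factors = experiment1Factors(),
                        sweepStep = if (sweeps) sweepStep else NULL,
                        package = as.character(utils::packageVersion("ctDoseSens"))))
}

#' Run Experiment 2: organ-wise mean HU shift screening
#'
#' K = 5 Morris screening over additive mean shifts in bladder, rectum,
#' bone, prostate and remaining soft tissue (body minus the four organs).
#' Each design row applies the five shifts and evaluates the isocentre
#' dose with the patient's calibrated plan.
#'
#' @inheritParams runExperiment1
#' @param repetitions R (default 40; with K = 5 this is 240 evaluations
#'   per patient, 9360 for a 39-patient cohort).
#' @return an [ExperimentResult-class].
#' @export
runExperiment2 <- function(cohort, repetitions = 40L, levels = 4L, seed = 1L,
                           planArgs = list(), verbose = FALSE) {
  res <- .runExperiment(cohort, experiment2Factors(), "organs",
                        repetitions, levels, seed, planArgs = planArgs,
                        verbose = verbose)
  new("ExperimentResult", summary = res$summary, cohort = res$cohort,
      ee = res$ee,
      scc = data.frame(patient = integer(), factor = character(),
                       scc = numeric()),
      designs = res$designs, evaluations = res$evaluations,
      provenance = list(experiment = 2L, seed = as.integer(seed),
                        repetitions = as.integer(repetitions),
                        levels = as.integer(levels),
                        nPatients = length(cohort),
                        factors = experiment2Factors(),
                        package = as.character(utils::packageVersion("ctDoseSens"))))
}

#' One-factor dose sweep and Spearman rank correlation
#'
#' Evaluates the isocentre dose over an ordered grid of one artefact
#' factor while holding the other two fixed, and computes the Spearman
#' correlation coefficient (Pearson correlation of average ranks) between
#' factor value and dose. A constant dose across the grid leaves the
#' correlation undefined and is reported as NA, not 0.
#'
#' @param ct a [CTVolume-class].
#' @param masks the matching [OrganMaskSet-class].
#' @param plan a calibrated [BeamPlan-class].
#' @param factor one of `"intensity"`, `"distance"`, `"size"`.
#' @param grid strictly increasing factor values (>= 3).
#' @param fixed named list giving the two held-fixed factors (defaults:
#'   intensity 200 HU, distance 0 mm, size 50 mm for whichever are absent).
#' @param beamIndex beam axis carrying the displacement.
#' @param evalFun optional memoised evaluator (internal reuse).
#' @return list with `sweep` (data.frame `value`, `dose`) and `scc`.
#' @export
sweepAndCorrelate <- function(ct, masks, plan,
                              factor = c("intensity", "distance", "size"),
                              grid, fixed = list(), beamIndex = 1L,
                              evalFun = NULL) {
  factor <- match.arg(factor)
  if (length(grid) < 3L) stop("sweep grid needs at least 3 points")
  if (any(diff(grid) <= 0)) stop("sweep grid must be strictly increasing")
  defaults <- list(intensity = 200, distance = 0, size = 50)
  fixed <- utils::modifyList(defaults[setdiff(names(defaults), factor)],
                             fixed[setdiff(names(fixed), factor)])
  if (is.null(evalFun))
    evalFun <- .doseEvaluator(ct, masks, plan, "artefact", beamIndex)
  doses <- vapply(grid, function(v) {
    params <- c(fixed, stats::setNames(list(v), factor))
    evalFun(unlist(params)[c("intensity", "distance", "size")])
  }, numeric(1))
  scc <- spearmanCC(grid, doses)
  list(sweep = data.frame(value = grid, dose = doses), scc = scc)
}

#' Spearman rank correlation with explicit undefined case
#'
#' @param x,y numeric vectors.
#' @return correlation in \[-1, 1\], or NA when either variable is
#'   constant (undefined ranks dispersion).
#' @export
spearmanCC <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Write result tables, figures and a reproduction manifest
#'
#' Emits `summary.csv` (per-patient Morris summaries), `cohort.csv`
#' (cohort aggregates with labels and ranking), `ee.csv`, `scc.csv` (if
#' sweeps were run), `design.csv`, `manifest.json` (seeds and
#' configuration sufficient to reproduce the run bit-identically), a
#' mu*-sigma scatter with cohort error bars and a bar chart of the
#' Euclidean distances in descending order of importance.
#'
#' @param result an [ExperimentResult-class].
#' @param outdir output directory (created if needed).
#' @param figures logical; write PNG figures.
#' @return invisibly, the paths written.
#' @export
report <- function(result, outdir, figures = TRUE) {
  if (nrow(result@cohort) == 0L) stop("result contains no factors to report")
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create directory ", outdir)
  }
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(result@summary, "summary.csv")
  wr(result@cohort, "cohort.csv")
  wr(result@ee, "ee.csv")
  if (nrow(result@scc)) wr(result@scc, "scc.csv")
  designs <- do.call(rbind, lapply(seq_along(result@designs), function(j) {
    data.frame(patient = j, result@designs[[j]]@design, check.names = FALSE)
  }))
  wr(designs, "design.csv")
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(result@provenance, mp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  paths <- c(paths, mp)

  if (figures) {
    co <- result@cohort
    g1 <- ggplot2::ggplot(co, ggplot2::aes(x = mu_star, y = sigma,
                                           colour = factor)) +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(sigma - sigma_sd, 0),
                                          ymax = sigma + sigma_sd),
                             width = 0, na.rm = TRUE) +
      ggplot2::geom_errorbarh(ggplot2::aes(xmin = pmax(mu_star - mu_star_sd, 0),
                                           xmax = mu_star + mu_star_sd),
                              height = 0, na.rm = TRUE) +
      ggplot2::geom_point(size = 3) +
      ggplot2::labs(x = "μ* (mean |EE|, Gy per unit factor)",
                    y = "σ (sd of EE)",
                    title = "Morris screening: factor effects at the isocentre") +
      ggplot2::theme_minimal()
    p1 <- file.path(outdir, "mu_star_sigma.png")
    ggplot2::ggsave(p1, g1, width = 6, height = 5, dpi = 120)
    co$factor <- stats::reorder(co$factor, -co$distance)
    g2 <- ggplot2::ggplot(co, ggplot2::aes(x = factor, y = distance)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = NULL, y = "D = √(μ*² + σ²)",
                    title = "Factor importance (descending)") +
      ggplot2::theme_minimal()
    p2 <- file.path(outdir, "distance_ranking.png")
    ggplot2::ggsave(p2, g2, width = 6, height = 4, dpi = 120)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
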