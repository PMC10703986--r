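# ctDoseSens

**Sensitivity of the radiotherapy isocentre dose to Hounsfield-unit
errors in CT and synthetic-CT images.**

MRI-only radiotherapy replaces the planning CT with a synthetic CT
(sCT) generated from MRI. Errors in the synthetic Hounsfield units (HU)
propagate through the dose calculation to the dose actually delivered to
the target. `ctDoseSens` is for medical-physics researchers who want to
quantify that propagation for a prostate geometry: which HU errors —
by intensity, size, location, or by organ — move the dose at the
isocentre (the centre of the prostate), and by how much, ranked with a
global sensitivity analysis.

The package provides, end to end:

* a **synthetic pelvic phantom cohort** (body, bone, bladder, rectum
  with optional gas, prostate) with per-patient anatomical and density
  variability, so the whole pipeline runs without patient data
  (NIfTI/MetaImage I/O included);
* **controlled HU error injection**: spherical additive artefacts
  (intensity × diameter × distance along a beam axis) and organ-wise
  mean shifts;
* a **simplified 7-beam 6 MV photon dose model** — primary fluence with
  exponential attenuation over the water-equivalent path length (WEPL,
  traced in C++) and inverse-square falloff, normalised per patient so
  the unperturbed isocentre dose equals the 78 Gy prescription
  (39 × 2 Gy);
* **Spearman correlation sweeps** per error factor, and
* **Morris elementary-effects screening**: for factor *i* of patient
  *j*, elementary effects
  EE<sub>i,j</sub> = [f<sub>j</sub>(X₁,…,X<sub>i</sub>+Δ<sub>i</sub>,…,X<sub>K</sub>) − f<sub>j</sub>(X)] / Δ<sub>i</sub>
  over R random one-at-a-time trajectories, summarised per factor as
  μ (mean), μ\* (mean absolute), σ (sample sd) and the importance score
  D = √(μ\*² + σ²), with factor classification
  (negligible / linear-additive / nonlinear-or-interacting) and cohort
  aggregation.

## Worked example

```r
library(ctDoseSens)

## one synthetic patient and a calibrated 7-beam plan
ph   <- generatePhantom(phantomSpec(seed = 1))
plan <- calibratePlan(planForPhantom(ph$ct, ph$masks), ph$ct)
isocentreDose(ph$ct, plan)
#> [1] 78            # baseline = prescription, by construction

## a +200 HU spherical artefact, 30 mm diameter, centred on the isocentre
art <- insertArtefact(ph$ct, ph$masks, plan,
                      artefactSpec(deltaHU = 200, diameter = 30))
isocentreDose(art, plan)
#> [1] 77.322        # overestimated HU attenuate the beams -> less dose

## screen a 5-patient cohort (R = 10 trajectories each)
co <- phantomCohort(n = 5, seed = 1)
r1 <- runExperiment1(co, repetitions = 10, seed = 1)
aggregate(scc ~ factor, data = r1@scc, FUN = mean)
#>      factor        scc
#> 1  distance  0.9770084
#> 2 intensity -1.0000000
#> 3      size -0.9677492

r2 <- runExperiment2(co, repetitions = 10, seed = 1)
r2@cohort[, c("factor", "mu_star", "sigma", "distance", "rank", "label")]
#>                factor   mu_star      sigma  distance rank           label
#> softTissue softTissue 3.7074517 0.53266232 3.7455210    1 linear/additive
#> rectum         rectum 1.5186651 0.10259277 1.5221265    2 linear/additive
#> prostate     prostate 0.9753612 0.13011743 0.9840020    3 linear/additive
#> bone             bone 0.7224459 0.07767907 0.7266100    4 linear/additive
#> bladder       bladder 0.3643438 0.05293320 0.3681689    5 linear/additive

report(r2, "results/exp2")   # CSV tables, manifest, mu*-sigma + D figures
```

Reading the output: the Spearman sweeps show the expected monotonic
structure — raising HU in an artefact that covers the target *lowers*
the isocentre dose (SCC < 0), larger +200 HU artefacts lower it more
(SCC < 0), and displacing the artefact away from the isocentre along a
beam axis restores it (SCC > 0). The organ screening ranks mean HU
errors in the remaining soft tissue as most influential (every beam
crosses it) and bladder errors as least influential. Units of μ\*, σ and
D are Gy per unit normalised factor range.

The mechanics of the model, all tunable parameters and the reasoning
behind the defaults are in the methods vignette,
`vignettes/hu-error-dose-sensitivity.Rmd`.

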