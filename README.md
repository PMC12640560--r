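# dbscompare

Comparative evaluation of deep brain stimulation (DBS) activation models,
at desk scale and fully seeded.

Image-guided DBS programming leans on computational models that predict
which axonal pathways a stimulation setting activates, but published
pipelines differ in three consequential ways: the **biophysical method**
(a binary *volume of tissue activated*, VTA — a fixed 0.2 V/mm E-field
isosurface used as an activation proxy — versus a *driving-force*, DF,
predictor that thresholds each fiber from the second spatial difference of
the extracellular potential at its nodes of Ranvier), the **imaging
space** (patient-native versus a normative template reached by nonlinear
warping), and the **anatomical representation** (pathway streamlines
versus volumetric structures). Crossing these axes gives six admissible
model variants — DF is pathway-only — and practitioners need to know which
axes actually matter.

`dbscompare` implements all six variants end to end and evaluates them the
way such comparisons are done against intraoperative evoked-potential
recordings: per-subject coefficients of determination
R² = corr(prediction, EP amplitude)², paired Wilcoxon signed-rank tests on
R² across subjects for every single-factor contrast, and presence/absence
F-scores for the far (side-effect) pathway where zeros dominate. Because
in-vivo recordings cannot ship with a package, the cohort is synthetic and
the truth is designated: a seeded generator builds 11-subject cohorts
(lead mix and setting counts mirroring a published 11-patient STN-DBS
table: 8 standard / 3 steerable leads, 15–49 settings each, 1–5 mA at
60 µs) with an STN-like ellipsoid, a thin-fiber near bundle (hyperdirect
pathway analog, read out by EP1) and a large-fiber far bundle
(corticospinal tract analog, read out by the zero-inflated EP0), and EP
amplitudes generated from a known truth variant. The evaluation question
becomes well-posed ranking recovery; the circularity is deliberate and
documented.

The machinery underneath is a finite-difference quasi-static volume
conductor (compiled SOR; harmonic face conductances; radiation outer
boundary transparent to 1/r fields; exact floating-potential handling of
passive contacts via a contact conductance matrix), a parametric lead
catalog (Medtronic 3387/3389, Boston Vercise 2201/2202, Abbott 6172,
segmented 1-3-3-1 layouts with roll), a synthetic normative space (smooth
random deformation fields plus global scaling, with total-least-squares
lead re-straightening and field recomputation around the idealized
straight lead), and NIfTI / TCK / TRK / CSV I/O.

## Worked example

Generate one 11-subject cohort, run all six variants, and compare:

```r
library(dbscompare)

spec  <- cohort_spec(n_subjects = 11, seed = 3)
co    <- generate_cohort(spec)             # anatomy, settings, truth, EPs
act   <- run_cohort(co, all_variants())    # per-setting % activation
rep   <- compare_variants(act, co)         # R^2, medians, paired tests
rep$summary
```

```
                   variant target  n   q25 median   q75
1        DF-Native-Pathway   CSBT 11 0.942  0.974 0.981
2        DF-Native-Pathway    HDP 11 0.934  0.956 0.972
3     DF-Normative-Pathway   CSBT 11 0.841  0.891 0.912
4     DF-Normative-Pathway    HDP 11 0.868  0.927 0.948
5       VTA-Native-Pathway   CSBT  2 0.138  0.146 0.155
6       VTA-Native-Pathway    HDP 11 0.796  0.812 0.875
7     VTA-Native-Structure   CSBT 11 0.702  0.723 0.784
8     VTA-Native-Structure    HDP 11 0.304  0.351 0.383
9    VTA-Normative-Pathway   CSBT  3 0.166  0.203 0.348
10   VTA-Normative-Pathway    HDP 11 0.733  0.786 0.847
11 VTA-Normative-Structure   CSBT 11 0.410  0.449 0.668
12 VTA-Normative-Structure    HDP 11 0.268  0.331 0.381
```

Read: the designated-truth variant (`DF-Native-Pathway`) tops both
pathways; every native variant beats its normative counterpart (the warp
is applied to anatomy but the field is recomputed around a re-straightened
ideal lead, which is exactly how template-space error arises); and the VTA
pathway metrics collapse for the far bundle — `n` drops from 11 to 2–3
because most subjects' VTA never reaches it, so their prediction series
are identically zero and R² is undefined (those exclusions are reported,
not hidden). The paired contrasts come out as, e.g., p = 0.000977
(= 2/2¹¹, every subject in the same direction) for native vs normative DF,
and `rep$fscore` carries the presence/absence F-scores for the far
pathway with all-zero subjects excluded. `autoplot(rep)` draws the
per-variant box plots; `tidy(rep)` and `glance(rep)` return the tidy
per-subject and summary tables.

A YAML-driven pipeline (`pipeline_generate()` / `pipeline_run()` /
`pipeline_evaluate()`, also exposed as the `inst/cli/dbscompare` script
with `generate` / `run` / `evaluate` / `fixtures` subcommands) writes the
cohort, per-subject-per-variant activation tables (resumable; `--force`
recomputes) and the report to disk with full provenance.

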