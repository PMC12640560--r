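---
title: "Methods: comparing DBS activation-model variants at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing DBS activation-model variants at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question the package answers

Computational models of deep brain stimulation (DBS) predict which axonal
pathways a given stimulation setting activates. Practice varies along three
largely independent axes:

* **biophysical method** — a binary *volume of tissue activated* (VTA,
  a fixed E-field-magnitude isosurface used as a proxy for activation)
  versus a *driving-force* (DF) predictor that evaluates the second spatial
  difference of the extracellular potential at nodes of Ranvier along
  realistic fiber trajectories and assigns each fiber an activation
  threshold;
* **imaging space** — the patient's own (native) frame versus a population
  template (normative) frame reached by nonlinear warping;
* **anatomical representation** — pathway streamlines versus volumetric
  structures.

Crossing the axes yields six admissible variants (the DF method is
intrinsically pathway-based), from `DF-Native-Pathway` to
`VTA-Normative-Structure`. `dbscompare` implements all six against a fully
synthetic, seeded cohort whose ground-truth activation is known, and
reproduces the statistical machinery used to rank them: per-subject
$R^2$ between per-setting predictions and evoked-potential amplitudes,
paired Wilcoxon signed-rank tests on $R^2$ across subjects, and
presence/absence F-scores for the far (side-effect) pathway.

The synthetic cohort's two bundles play the roles of the clinically
relevant pathways near the subthalamic nucleus (STN): a thin-fiber (4 µm)
near bundle standing in for the cortico-subthalamic hyperdirect pathway
(HDP), indexed by the short-latency evoked potential EP1, and a
large-fiber (12 µm) far bundle standing in for the corticospinal/bulbar
tract (CSBT), indexed by the very-short-latency EP0.

# Volume conductor

The quasi-static potential solves $\nabla\!\cdot\!(\sigma\nabla\varphi)=0$
on a regular isotropic lattice (finite differences, harmonic face
conductances, SOR iteration in compiled code). With currents in mA,
lengths in mm and conductivities in S/m, potentials come out in volts
without unit conversions.

Two conductivity conventions mirror the two modelling branches:

* **VTA branch** — tissue classes: 0.33 S/m inside the supplied
  gray-matter mask, 0.14 S/m elsewhere, with the electrode shaft removed
  from the conduction domain.
* **DF branch** — homogeneous 0.2 S/m bulk with a 0.5 mm encapsulation
  scar layer at 0.07 S/m wrapped around the lead; the lattice spacing must
  not exceed the scar thickness.

**Boundary handling.** The outer boundary is the monopolar return
("case"). A hard 0 V box at desk-scale domain sizes would truncate the
$1/r$ tail and corrupt mid-range potentials by tens of percent, so the
default boundary is an inverse-distance radiation condition — face
conductance $\sigma h^2\,|d_n|/r^2$ toward the source centroid — which is
transparent to a point-source field ("ground at infinity"). A hard
grounded box remains available (`solver_options(boundary = "ground")`).
With this boundary a single-voxel source reproduces
$I/(4\pi\sigma r)$ to better than 2% for $r \in [2, 8]$ mm at 0.5 mm
spacing, and the error falls under refinement; this analytic oracle is a
standing test.

**Active, passive and floating contacts.** Each contact is voxelized as a
Dirichlet surface. One unit-voltage basis problem is solved per contact,
and the contact conductance matrix $G$ ($G_{jk}$ = current into tissue
through contact $j$ when contact $k$ is at 1 V) is assembled from discrete
face fluxes. A stimulation setting prescribes injected currents $b$
(cathodic current negative, split equally over multiple cathodes, zero at
passive contacts); solving $Gv=b$ gives the contact voltages and the field
follows by superposition. This enforces the floating-potential conditions
— equipotential surface, zero net current — exactly, and makes every
per-setting field a cheap linear combination of cached basis fields. It
replaces an equivalent iterative projection scheme (solve, equalize,
correct, repeat) whose fixed point is the same solution.

An observation worth recording: at fixed injected current the resistive
scar *raises* the potential just outside itself in the contact plane
(about +10% at 1.5 mm for the standard lead). The concentric-shell
intuition that a series layer leaves the exterior unchanged does not apply
to a cylindrical lead — the sleeve suppresses axial current spreading
along the insulating shaft and collimates current radially at the contact
level. The suite asserts this directional effect.

**Temporal structure.** The stimulation waveform is asymmetric biphasic
(60 µs cathodic phase, 70 µs inter-phase gap as metadata); the field model
is linear and uses the cathodic amplitude. Temporal variation is separable:
the spatial field at $t=0$ times the voltage drop of a one-dimensional
equivalent circuit, implemented as $\exp(-\mathrm{PW}/R_aC_{dl})$ with
defaults $R_a = 100\ \Omega$, $C_{dl}=3.3\ \mu\mathrm{F}$ (a scale of
0.83 at 60 µs). The circuit values are package defaults — typical DBS
electrode-interface magnitudes — exposed in the configuration; no
published component values were available to inherit.

# Activation predictors

**VTA.** The binary VTA thresholds the E-field magnitude at 0.2 V/mm
(central differences; one-sided at the lattice edge) and keeps only the
26-connected suprathreshold component attached to the active contacts, so
disconnected suprathreshold islands never count. The VTA deliberately
ignores pulse width and frequency — it is a static construct. Three
activation metrics consume it: percent of pathway streamlines with any
resampled point inside the mask (any-point inclusion; the resampling step
never exceeds the grid spacing); percent of structure voxels covered
(normative-space convention); percent of structure surface vertices inside
(native-space convention; the surface is the exposed-voxel-face mesh at
the 0.5 level, and a vertex on a voxel boundary belongs to the upper voxel
by the floor convention).

**Driving force.** Nodes of Ranvier are placed along each streamline's arc
length at the internodal spacing $L = 100d$ (0.4 mm for 4 µm fibers,
1.2 mm for 12 µm). The driving force at an interior node is the second
difference $V_{i-1}-2V_i+V_{i+1}$ of the trilinearly interpolated
potential; with cathodic currents negative, depolarization is positive.
The per-fiber threshold is

$$ I_{th} = \frac{k_0\,(1 + \tau_c/\mathrm{PW})}{\max_i \Delta^2 V^{(1\,\mathrm{mA})}_i}, $$

with the node placement phase chosen to maximize the peak drive
(worst-case alignment over 5 phases per internodal length; a fixed-phase
mode exists). This surrogate **stands in** for a full multicompartment
cable threshold search, which the package deliberately does not contain;
it preserves the three properties the comparison relies on — reciprocity
in peak drive, chronaxie-form strength–duration behaviour, and the
diameter effect through node spacing. Calibration is anchored to the VTA's
own operating point: $k_0$ is chosen so a 3.5 µm fiber at 60 µs reaches
threshold exactly at the 0.2 V/mm radius of a 3 mA point source in
0.2 S/m ($k_0 \approx 0.0047$ V), with $\tau_c = 65$ µs, a typical
myelinated-axon chronaxie. Anchoring both predictors to one excitability
scale makes their divergence at distance a geometric consequence, not a
calibration artifact: 12 µm fibers activate well beyond the fixed VTA
boundary, which is what produces the far-bundle distance effect the
evaluation looks for. The DF pulse-width dependence is carried entirely by
the chronaxie factor; the equivalent-circuit scaling remains available as
an explicit field operation.

# Native and normative spaces

The package cannot ship a population template, so "normative" is defined
operationally: a smooth synthetic displacement field (sum of random
vector-valued Gaussian bumps, rescaled to a target mean magnitude, default
1.0 mm) composed with a global scaling of 1.05 about the domain centre
(population templates are slightly larger than the average brain). All
geometry — structures, streamlines, contact centres — is warped forward;
masks are pulled back through the numerically inverted field with
nearest-neighbour sampling so they stay binary; then the lead is
**re-straightened**: a total-least-squares line is fitted to the warped
tip and contact centres, the rigid contact spacing of the lead model is
restored along the fitted axis, the roll angle is recovered from a warped
roll marker, and the electric field is recomputed around this idealized
straight lead. That last step is the crux: it reproduces the real
mechanism of template-space error, in which anatomy is warped but the
field computation never sees the warp. The default 1.0 mm mean
displacement is a package choice (no published value exists for typical
native-to-template warp magnitude near the STN); it is a configuration
knob and the evaluation sweeps it 0 → 2 mm.

# The synthetic cohort

Geometry is primitive-based, not atlas-realistic, and entirely
parameterized: per subject, a jittered lead placement (tilt ~3°, random
roll for segmented leads), an STN-like ellipsoid (semi-axes 3 × 2 × 4 mm)
adjacent to the distal contacts (also the gray-matter map), a 4 µm near
bundle arcing past the lead at ~2 mm and terminating in the ellipsoid, a
12 µm far bundle at ~7 mm inside a capsule-like tube of radius 3.8 mm, and
100 streamlines per bundle. The far-bundle offset was chosen so that its
driving-force thresholds fall in the 2.5–6 mA range — reached only by the
stronger settings — while the 0.2 V/mm VTA (maximum reach ≈ 3.8 mm at
5 mA in 0.14 S/m) rarely or never reaches it; this is the geometric regime
the in-vivo construct occupies (EP0 appears mainly at high stimulation
intensity) and is fixed once here, not tuned per analysis.

Lead models carry vendor-nominal dimensions (e.g. 1.5 mm contacts, 0.5 mm
gaps, 1.27 mm shaft for the standard 4-contact lead; 1-3-3-1 layouts with
three 90° sectors per segmented level for the directional leads) in an
overridable catalog file. The per-subject lead mix and monopolar/bipolar
setting counts mirror the shipped 11-patient in-vivo summary table
(8 standard / 3 steerable leads; 15–49 settings per subject, 360 total);
amplitudes are drawn from 1–5 mA at 60 µs / 10 Hz. A setting is
*directional* when some level's active segments are a proper subset of
that level's segments; driving all segments of a level together (a
"pseudo ring") is non-directional.

**Ground truth and evoked potentials.** Ground truth is a designated
variant (default `DF-Native-Pathway` on the true geometry) — an explicit,
documented circularity: the evaluation's job is *ranking recovery*, which
is well-posed only when the truth is a known member of the family. EP1
tracks near-bundle truth, EP0 far-bundle truth, as
$\mathrm{EP} = \max(g\,A + \varepsilon, 0)$ with gain $g = 1$ µV/% and
noise SD 5 µV (5% of the activation scale — declared arbitrary; the study
this emulates reports no amplitude noise model). Settings with zero true
activation read exactly 0 (no response, no amplitude), EP0 additionally
has a 1 µV detection floor and near-threshold dropout (probability 0.4
below 3 µV), producing the zero-inflated EP0 structure: per-subject
zero-fractions in the 0.1–0.7 range at defaults, tunable upward with the
dropout probability. Amplitude units are arbitrary; only
correlation-based statistics consume them.

All randomness is seeded hierarchically (cohort seed → subject seeds →
separate streams for anatomy, settings, noise, warp), so regenerating a
cohort is byte-identical, and changing only the warp magnitude leaves the
native-space anatomy, settings and EP tables untouched — which is what
lets the warp sweep hold everything else fixed.

**What passing tests do and do not show.** The generator emulates the
*statistical shape* of the in-vivo construct — relative pathway
geometry, setting menus, zero inflation, warp error — not real anatomy:
no anisotropy or tissue heterogeneity beyond the two-class map, no
atlas-shaped structures, no electrode localization error, no
physiological EP latency structure. Recovery of the qualitative findings
here demonstrates that the pipeline's machinery behaves as designed under
known truth; it cannot certify accuracy on real patients.

# Evaluation harness

Per subject, variant and pathway the harness computes $R^2$ — the square
of the Pearson correlation between per-setting predictions and EP
amplitudes (at least 3 paired settings; a constant series is undefined and
the subject is excluded from that contrast, reported, never silently
dropped). Variant summaries are medians and IQRs with linear-interpolation
(type-7) quantiles, so printed tables reproduce across implementations.
Contrasts are paired two-sided Wilcoxon signed-rank tests at
$\alpha = 0.05$ with zero differences dropped — exact distribution up to
n = 25 when the absolute differences are tie-free, normal approximation
with continuity correction otherwise (the method used is reported).
No multiple-testing correction is applied, matching the reporting
convention of the comparison this machinery reproduces. The default
contrast set is the 7 single-factor pairs (3 space, 2 method,
2 representation) plus the conventional pair `DF-Native-Pathway` vs
`VTA-Normative-Structure`. For the far pathway an F-score on
presence/absence (binarization strictly above 0, configurable)
complements $R^2$; subjects whose observed EP0 is zero throughout carry no
signal and are excluded. Directional and non-directional settings can be
analysed separately.

# Numerical choices and problem sizes

Solver lattices: 0.5 mm spacing for the DF branch (two cells across the
scar would require 0.25 mm; one cell at 0.5 mm is the coarsest admissible
and is what the desk-scale runs use), 0.6 mm for the VTA branch, domains
extending 7 mm beyond the contact span, SOR tolerance $2\times10^{-6}$
with the model-problem optimal relaxation factor. DF basis fields are
solved once per lead model in the canonical lead frame (the scar
conductivity is lead-frame-defined, hence anatomy-independent) and reused
across subjects and cohorts; VTA basis fields are per subject and space
(the gray-matter mask breaks the symmetry). The stand-alone
`solver_options()` default (0.25 mm, 40 mm cube) is finer and suits
single-field studies rather than cohort sweeps. Evaluation problem sizes:
cohorts of 11 subjects; ranking recovery over 10 seeded cohorts; the warp
sweep at 0, 1, 2 mm mean displacement. A full cohort (generation plus all
six variants) runs in roughly a minute on one core.

One statistic deserves a caution: for the far bundle under VTA pathway
metrics, most subjects' prediction series are identically zero and are
excluded, so the surviving "median R²" rests on two or three subjects
whose identity shifts with any perturbation (e.g. the warp magnitude).
The package reports such cells with their `n` and treats them as
non-estimable in sweep-style assertions; this mirrors the in-vivo
situation in which some far-pathway activation measures were all zero and
limited the statistics.

Degenerate inputs are handled explicitly: empty VTAs are valid (zero
activation), fibers shorter than three nodes are unevaluable and get
infinite thresholds with a flag, constant prediction series are excluded
and logged, a deformation field is validated for positive Jacobian
determinant, and a lead whose contact array comes within 5 mm of the
domain edge is rejected rather than silently truncated.

# Known limitations

Isotropic conductivity only (no tensors), no frequency-domain dispersion,
no multicompartment cable models, no probabilistic VTAs or fiber-filtering
sweet-spot mapping, no raw-signal EP extraction, and no real registration:
the normative emulation reproduces the *mechanism* of template-space
error, not any specific template. The DF threshold surrogate is a
documented stand-in whose absolute thresholds should not be read as
physiological predictions; only their relative structure is load-bearing
here.
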