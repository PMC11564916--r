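---
title: "Deformable dose accumulation for adaptive prostate radiotherapy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformable dose accumulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A fractionated prostate radiotherapy course delivers its prescription over
many sessions (here 20 fractions of 3 Gy). Between sessions the anatomy
moves: the bladder fills and empties, the rectum changes volume, and the
prostate drifts, typically posteriorly. Conventional image-guided
radiotherapy (conv-IGRT) compensates with a translation-only couch
correction against a daily image; online-adaptive MR-guided radiotherapy
(OA-MRgRT) re-contours and re-optimizes the plan on each day's MRI. The
dose actually absorbed by each tissue element over the course therefore
differs from the single planned distribution, and comparing treatment
strategies requires *deformable dose accumulation* (DDA): register every
fraction's anatomy to a common frame (the first fraction), map each
fraction dose along the resulting displacement field, and sum.

`ddacc` implements this comparison pipeline end to end — spatial
containers and NIfTI I/O, rigid and deformable registration, direct dose
mapping and accumulation, DVH/dose-volume-parameter extraction, LKB NTCP
radiobiology, and paired nonparametric statistics — together with a seeded
synthetic pelvis cohort that provides ground-truth deformations, so every
stage can be validated against a known answer.

# Coordinate and field conventions

All geometry is in world millimetres with a voxel-centre convention and
0-based indices; grids carry spacing, origin and an orthonormal direction
matrix (identity for all synthetic data, honoured on input otherwise).
Displacement fields use the *pull-back* convention: a field `u` on a fixed
grid warps a moving volume via `warped(x) = moving(x + u(x))`. This is the
convention in which dose warping needs no field inversion: the field
produced by registering fraction k (moving) to fraction 1 (fixed) is
exactly the field that maps fraction-k dose into the fraction-1 frame.

Dose mapping is *direct dose mapping* (DDM): trilinear interpolation of
the fraction dose at the displaced sample point, with no energy or mass
rescaling. DDM preserves pointwise dose values (no new maxima) but not
integral dose under volume-changing deformations; that is a property of
the method, not a defect, and the companion energy/mass-transfer approach
is out of scope here because the two have been reported to yield
comparable results for this application.

# The synthetic pelvis cohort

No public dataset underlies this workflow (the clinical images are not
deposited), so the package generates a synthetic cohort whose *statistical
structure* matches what the analysis assumes. It is first-class, tested
code, not a fixture.

## Anatomy

A 160 mm cube at 2 mm isotropic spacing (80^3 voxels) holds smooth
parametric organs: an ellipsoidal prostate CTV with semi-axes
(23, 20, 22) mm (about 42 cm^3), a 3 mm-radius urethra along the CTV
axis, a tubular rectum (radius 13.5 mm) directly dorsal and abutting the
prostate, and an ellipsoidal bladder (about 130 cm^3) anterior-superior,
overlapping the PTV dome as real bladders do. The PTV is the CTV dilated
5 mm, 3 mm dorsally — the printed margin recipe. Overlaps after daily
warping are resolved by contouring priority (CTV wins; the urethra stays
inside the CTV), mirroring how abutting structures are contoured. The
single 2 mm grid is a deliberate compromise between the clinical image
grids (0.83–3 mm); heterogeneous-grid input is supported through
`resample_to_grid()`.

The T2-weighted appearance is emulated only so far as registration needs:
piecewise organ intensities plus smooth seeded texture and mild daily
noise. Realistic MR contrast is a non-goal.

## The analytic plan model

The reference "plan" is an analytic conformal dose:

* a plateau (about 61.8 Gy before constraint carving) inside the PTV,
  falling off through a logistic penumbra of width 2 mm whose 50% point
  sits 4 mm outside the PTV surface;
* two dorso-lateral hotspot lobes (+1.5 Gy, sigma 6 mm) anchored to the
  CTV centroid, giving the within-PTV heterogeneity real IMRT plans have
  (maximum near 103–104% of prescription);
* a low-dose bath of 8 Gy;
* *constraint carving*: whenever an organ at risk comes near the printed
  maximum-dose limit (any OAR voxel above 58 Gy), dose inside that organ
  plus a 3 mm safety margin is clamped to 60.5 Gy, and a V56Gy carve
  analogously protects the printed rectum/bladder volume constraints.
  This stands in for the optimizer's hard OAR constraints; the 3 mm
  margin plays the role of a planning-risk-volume margin and keeps daily
  plans robust to sub-voxel mapping error during accumulation.

A small tuner nudges the plateau and penumbra offset until the complete
printed objective set passes (CTV D50% >= 60 Gy, D98% >= 57 Gy; OAR
Dmax <= 61 Gy; rectum V56Gy < 13.5%; bladder V56Gy < 18%); generation
fails loudly if it cannot. The same plan model evaluated on a fraction's
own anatomy is the daily re-optimization surrogate for the OA arm; the
conv-IGRT arm instead translates the *reference* dose by the translation
found by the rigid registration of the reference image to the fraction
image — precisely the couch-correction simulation.

## Per-fraction variation

Each fraction's anatomy is the reference warped by one smooth pull-back
field composed of three parts:

* a prostate shift: a per-patient systematic posterior drift with
  amplitude drawn once per patient from U(2, 9) mm, plus an isotropic
  N(0, 1.5 mm) daily residual. The motion weight is 1 on the CTV and its
  6 mm vicinity and decays over ~18 mm; inside the rectum it is
  attenuated towards a coupling of 0.3, so the anterior rectal wall
  partially follows the prostate while the rectal lumen stays put (the
  prostate slides along the rectum);
* bladder volume change: a radial scaling about the bladder *base* (the
  bladder neck is anatomically fixed) towards a daily volume drawn from
  U(90, 180) cm^3; the scale factor is calibrated by secant iteration so
  the voxelised warped volume matches the draw to better than 1%;
* rectum volume change: a cross-sectional scaling about the rectal axis
  towards U(45, 75) cm^3, calibrated the same way.

Both organ scalings vanish on a protected region around the target so
the CTV moves rigidly. The composed field is checked for invertibility
(Jacobian determinant > 0.05 everywhere; resampled on failure), and is
stored as the fraction's ground truth. Warping the reference structures
by it *is* how the fraction structures are built, which makes the field
an exact recovery oracle for the registration module.

Magnitudes deserve a note. The variation defaults are generator
configuration, chosen once to be clinically plausible (posterior prostate
drifts of a few mm to ~1 cm and two-fold bladder volume changes are well
documented) *and* to reproduce the qualitative clinical contrast the
analysis is about: with translation-only correction, some patients'
accumulated doses violate at least one OAR objective — the dominant
mechanism being organs drifting out of their carved constraint pockets
into plateau dose — while daily re-planning, which re-carves on the day's
anatomy, meets all OAR objectives, and both strategies maintain CTV
coverage (D98% >= 57 Gy) because translations do track the target. What
passing these checks on the phantom does *not* show is quantitative
agreement with any clinical cohort: real anatomy deforms less smoothly,
real plans are less conformal in complicated ways, and real image
registration faces contrast and artefact challenges absent here.

# Registration

The conv-IGRT simulation is a translation-only rigid registration:
exhaustive coarse search on a +/-15 mm, 3 mm lattice of the mean squared
intensity difference inside the CTV bounding box dilated 10 mm, followed
by per-axis golden-section refinement; rotations are excluded by
contract, and ties break towards the smallest translation so identical
images return exactly zero.

The deformable registration is a multi-resolution demons surrogate with
structure guidance: the update force sums an intensity channel and one
channel per guidance structure (CTV, bladder, rectum), each the demons
force of clamped, scaled signed-distance transforms of the corresponding
masks, weighted by `structure_weight` (default 2; 0 disables guidance).
Updates are capped at 2 mm per iteration, fluid-smoothed (sigma 1 mm),
added, and the field diffusion-smoothed (sigma 1.5 mm) per iteration over
a 3-level pyramid. The vendor algorithm used clinically is proprietary;
this surrogate deliberately exposes its whole configuration and is held
to a *recovery contract* on the phantom's ground truth instead: warped
structure Dice >= 0.95 and mean target-registration error <= one voxel
inside the CTV. The conclusions of the comparison depend on the workflow
contract, not on any particular optimizer.

# Analysis

DVHs are cumulative with a 0.01 Gy bin width; Dq% interpolates linearly
between bins (boundary-inclusive, matching the printed ">=" objectives),
and Dmax is always the single hottest voxel, never read off the
histogram. The accumulated arms are evaluated in the fraction-1 frame on
fraction-1 structures; the reference plan is evaluated in its own frame
with no mapping.

NTCP uses the Lyman-Kutcher-Burman chain: voxelwise EQD2 under the
linear-quadratic model with uniform fractionation (`d = D / n` per
voxel), gEUD reduction `(mean EQD2^(1/n))^n`, then the logistic
`NTCP = 1 / (1 + exp(-(gEUD - TD50) / (m TD50)))`, with the published
endpoint parameters: bladder incontinence G2+ (alpha/beta 1.5 Gy, TD50
108.9 Gy, m 0.24, n 0.02) and rectum late toxicity G2+ (alpha/beta
3.0 Gy, TD50 80.8 Gy, m 0.15, n 0.12). Because the printed logistic takes
a scalar EQD2 while a volume parameter n is published per endpoint, the
standard ordering — EQD2 first, then gEUD, then the logistic — is adopted
and documented as an assumption.

Statistics are paired and nonparametric: a two-sided Wilcoxon signed-rank
test, exact by full enumeration of the 2^n sign assignments for n <= 15
(zero differences dropped, ties mid-ranked; exactness under ties is
preserved by enumerating the actual rank vector) and a continuity- and
tie-corrected normal approximation above; Bonferroni correction with
k = 3 for the three arm pairs; and the paired Cohen's d
(`mean(diff) / sd(diff)`) — the paired form is documented prominently
since the pooled-SD variant differs. Reports give median (range) per arm,
the three pairwise comparisons per parameter, NTCP summaries, and
objective-attainment percentages.

# Numerical choices and degenerate inputs

* Out-of-field samples fill with 0 Gy for dose (conservative under
  accumulation) and with the background intensity for images; mask
  warping and resampling are nearest-neighbour and stay binary.
* Field inversion uses the fixed-point iteration
  `v <- -u(x + v(x))`; on the phantom's smooth fields the residual of
  `compose(invert(u), u)` is well under a voxel in the interior. The
  ground-truth fraction-1-to-fraction-k field is
  `compose(invert(u_k), u_1)`.
* The exact Euclidean distance transform is the separable
  lower-envelope-of-parabolas algorithm; Gaussian smoothing is separable
  with border renormalisation; both live in compiled code, as do
  trilinear/nearest sampling and mask dilation.
* All-zero paired differences give p = 1 with a warning; a zero SD of
  differences reports Cohen's d as missing rather than infinite.
* Empty masks, non-overlapping grids, missing guidance structures,
  non-finite fields and 4-D NIfTI inputs raise typed errors early.

# Problem sizes

The full study conditions (10 patients x 20 fractions at 2 mm) are
exercised in the end-to-end validation using the phantom's ground-truth
fields for the accumulation step — the package's oracle path, which
isolates the accumulation arithmetic from registration error; the
deformable registration's recovery contract is validated separately on
dedicated fractions at the same 2 mm resolution. Unit tests run the same
generator on a 4 mm grid, which preserves every contract while keeping
the suite quick.

# Known limitations

* Patients share one baseline anatomy: inter-patient variation enters
  through the per-patient drift amplitude and the daily draws, not
  through organ geometry. Reference-plan dose-volume parameters are
  therefore identical across the synthetic cohort (real cohorts spread);
  the paired statistics are unaffected because every comparison is
  within-patient.
* The OA arm always re-plans (an adapt-to-shape surrogate); the
  adapt-to-position variant is a rigid special case already covered by
  the conv-IGRT machinery and is not modelled separately.
* No intrafraction motion, no seminal-vesicle target, no DICOM-RT
  import, no rotational registration, no uncertainty propagation on the
  accumulated dose — each either a stated non-goal or an acknowledged
  limitation of the workflow itself.
* NTCP endpoints are limited to the two published parameter sets; no
  tumour-control modelling.
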