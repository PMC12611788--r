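---
title: "Models and methods behind cardionuc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cardionuc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cardionuc` packages the quantitative machinery of a cardiomyocyte nuclear
mechanobiology study: an assay that measures how much of the sarcomere's
contractile strain reaches the nucleus, a finite-element model of the
cytoskeletal pre-stress that shapes and stresses the resting nucleus, image
quantifications for nuclear damage readouts, and a biphasic regression for
aspect-ratio-versus-enrichment relations. This vignette explains each
model, its assumptions, and the numerical and design choices; every figure
of merit quoted here is computed by the test suite or the analysis scripts,
not transcribed from elsewhere.

## Sarcomere-nuclear strain coupling

During a stimulated twitch, sarcomere shortening compresses the nucleus
along the contractile axis. The assay takes per-cell recordings of
sarcomere length (250 Hz in the synthetic cohorts) and nuclear length and
width (91 Hz), averages five steady-state beats anchored at the
stimulation timestamps (window = median inter-stimulus interval), linearly
interpolates onto the common 91-Hz grid, and converts lengths to strains
against the mean length over a 200-ms window ending at the first stimulus.
Strains are stored signed (compression negative); all coupling-map
quantities use compression magnitudes, matching the convention of plotting
compression as positive.

Cells enter the analysis when the baseline sarcomere length exceeds
1.7 um and the peak sarcomere strain exceeds 10 % (`qc_filter()`); the
failing criterion is named in the output. In the synthetic cohorts the
cell-to-cell spread implies roughly a fifth of cells sit below the strain
gate; in the source assay this gate was applied during cell selection, so
the reported cohort statistics refer to the full recorded cohort here.

The coupling curve plots nuclear against sarcomere compression in time
order. The systolic branch runs to the sample of maximum sarcomere
compression (earliest on ties), the diastolic branch after it. Two areas
summarize the transfer loss, both integrated against sarcomere compression
(trapezoidal; the areas live in the strain-strain plane, not in time):

* **Systolic dampening** `D_sys`: area between the lossless 1:1 line and
  the observed curve over the systolic branch. Zero for identity coupling;
  a rigid nucleus at 10 % peak sarcomere strain gives the full triangle
  0.005 strain^2.
* **Diastolic dampening** `D_dia`: area between the observed
  re-lengthening path and a unit-slope reference line through the
  end-systolic point. The slope is fixed at 1 because only the intercept
  of the reference is pinned by the end-systolic state; a lossless elastic
  retrace then accrues zero area, and a nucleus that lags the sarcomere
  accrues positive area. The slope choice is configurable in principle but
  is the only one that makes the elastic retrace exactly neutral.

**Integrated nuclear strain** `S_int` is the time integral of the absolute
nuclear length strain over one cycle; absolute length strain is used (the
width channel does not contribute) so that compression and the slow return
both count as load on the nucleus.

### The synthetic trace generator

The generator is the study-conditions module: its defaults are the
conditions everything else is tested under. A beat is a raised-cosine
upstroke (150 ms) with exponential relaxation (tau = 120 ms), preceded by
a 20-ms electromechanical delay. The nuclear strain is the sarcomere
strain passed through a first-order lag and rescaled so that its peak is
`coupling_gain` times the sarcomere peak; the lag creates the diastolic
hysteresis, the rescaling keeps the per-cell peak-compression gain an
exact, reportable ground truth. Nuclear width moves anti-phase at 0.35 of
the length gain. Gaussian noise (0.2 % of baseline length) is added to the
reconstructed lengths.

Condition presets store the effect sizes in one place: WT draws peak
sarcomere compression from N(11.4 %, 1.8 %) and the gain from
N(0.579, 0.074) - the dispersions are chosen so that a 20-cell cohort
reproduces the reported standard errors (0.4 % and 0.3 %), since only
means and standard errors are known; the mutant preset (gain 0.66, lag
70 ms) was calibrated once so that integrated nuclear strain exceeds WT by
~30 %; the microtubule-depolymerization preset accelerates sarcomere
relaxation (tau = 70 ms) at unchanged nuclear lag, producing the increased
diastolic hysteresis; LINC disruption leaves coupling unchanged. The
generator does not emulate drift, photobleaching, segmentation jitter
correlated in time, or arrhythmic beats - passing round-trip tests shows
the pipeline's arithmetic is right under the stated noise model, not that
it is robust to all instrument pathology.

## The axisymmetric chemo-mechanical pre-stress model

The model asks where cytoskeletal forces concentrate on the nucleus of a
*resting* cardiomyocyte. A cylindrical cell (radius 35 um, length 100 um)
contains a round nucleus (radius 4 um) wrapped in a 0.2-um envelope plus
lamina, surrounded by an ellipsoidal microtubule cage; exploiting symmetry
only a quarter of the (r, z) section is meshed. The stated cage axis
lengths 8 and 4.4 um are read as **semi-axes**: full lengths would put the
cage boundary inside the nuclear surface along the long axis, leaving no
pole-enriched shell to speak of.

Four materials:

* **Cytoplasm (myofibrils)**: linear elasticity (E = 1.2 kPa, nu = 0.3)
  coupled to a stress-regulated contractility field. Eliminating the
  contractility yields effective ("barred") moduli and an isotropic active
  eigenstress: `3*Kbar = (3*K*beta - 1)/(beta - alpha_v)`,
  `2*mubar = (2*mu*beta - 1)/(beta - alpha_v)`,
  `rhobar0 = beta*rho0/(beta - alpha_v)`, with chemical stiffness
  beta = 2.77 kPa^-1 and volumetric feedback alpha_v = 2.3 kPa^-1
  (`effective_moduli()`). At the physiological rho0 = 1.2 kPa the
  eigenstress is 7.07 kPa. The contractility tensor itself is recovered in
  post-processing from the same closure.
* **Microtubule cage**: passive cytoplasm-like elasticity plus an
  isotropic compressive eigenstress `sigma_MT` ramped to 0.5 kPa.
* **Nucleoplasm (chromatin)**: linear elastic, E = 150 Pa, nu = 0.49,
  displacement-only.
* **Envelope + lamina**: fully incompressible (nu = 0.5) layer at
  E = 15 kPa, handled by a mixed displacement-pressure (Taylor-Hood
  P2-P1) formulation to avoid volumetric locking in the thin shell.

Boundary conditions: `u_r = 0` on the axis, `u_z = 0` on the mid-cell
symmetry plane and on the cell end - the myocardium and titin restoring
forces hold the cell length, so raising the contractility drives a purely
radial contraction whose mismatch with the stiff inclusions creates the
pre-stress field.

### Kinematic regime

All compartments use linearized kinematics with the active terms as
eigenstresses. The constitutive relations are small-strain forms, and one
consistent kinematic regime keeps the model well-posed: the radial
contraction reaches ~60 %, where a Saint-Venant-Kirchhoff finite-strain
variant loses ellipticity (compressive stretch ~0.38) and cannot be relied
on to converge. The envelope is therefore an incompressible *linear* layer
rather than a finite-strain neo-Hookean one; strain stiffening of the
lamina is not represented. Consequences, measured not assumed:

* The far-field cytoplasm axial tension is 2.04 kPa, inside the 2-3 kPa
  band expected of diastolic myofibril tension.
* The cage is axially compressed everywhere, most at the nuclear long
  tips (1.2 kPa) and least at the short sides (0.62 kPa). The tip/side
  ratio (~1.9) matches the expected field structure, but magnitudes run
  ~35 % low against the 1-1.8 kPa band - the price of the small-strain
  convention at these deformations.
* Nuclear shape: the WT nucleus elongates to aspect ratio ~2.3.

### Conditions and the cage parameterization

Lamin mutation is modelled as softening the envelope to 10 kPa. LINC
disruption decreases cage stress and stiffness; the two must be scaled
separately. Scaling both by 0.1 makes the cage a soft pocket around which
the contracting cytoplasm arches, *widening* and swelling the nucleus -
the opposite of the observed phenotype. The stress channel dominates the
real effect: with cage stress x0.1 and stiffness x0.5 the nucleus becomes
thinner and longer at nearly conserved volume. This parameterization was
fixed once, from the qualitative phenotype (not from any numeric target),
and gives the ordering AR(WT) < AR(LMNA) < AR(LINC) < AR(LMNA+LINC) with
a maximum nuclear volume change of ~7 % across conditions.

The enrichment sweep maps an imaging enrichment ratio e to a cage scale
e/2 on both stress and stiffness (2.0 taken as the physiological
enrichment); the map is a stand-in, exposed in the API, because no
quantitative imaging-to-stress map is known. Below e ~ 0.75 the
stiffness-collapse arching effect dominates and the aspect-ratio trend
inverts; the monotone negative enrichment-aspect-ratio relation holds
above it.

### Tip instability proxy

A true tip instability is a post-buckling phenomenon outside a linear
model's vocabulary. The implemented criterion is the location switch of
the maximum principal envelope stress: mid-section at the physiological
state, jumping to the tip region (beyond 70 % of the deformed half-length)
above a critical cage stress found by grid scan plus bisection
(`detect_instability()`; ~1.2 kPa at the WT envelope). Newton failure
would also be recorded as a detection signal, but cannot occur in the
linear model. Two limitations are documented rather than patched: the
location classification is re-entrant at extreme cage stresses (the
argmax migrates back toward the equator), and the softer 10-kPa envelope
switches at a *higher* critical stress than the 15-kPa one - capturing
the expected "fragile nuclei destabilize earlier" ordering would require
the nonlinear shell.

### Numerics

Quadratic triangles on a polar-structured mesh (36 angular rays by
default; radial bands of 5/2/5/14 layers for nucleoplasm, envelope, cage
and cytoplasm, the last geometrically graded) so every material interface
lies on element edges; the 0.2-um envelope always carries >= 2 element
layers. Six-point quadrature; the incompressibility constraint is
regularized by a large penalty bulk modulus (1000 x E_ne), which bounds
envelope volumetric strain below ~0.5 % element-averaged. Loads ramp
proportionally in 5 steps with a relative residual check of 1e-8 per step
(one correction suffices for a linear model, but the interface and checks
are ramp-based). The default model has ~1800 elements and solves in a few
seconds; mesh refinement changes the aspect ratio by < 1 %, and subdomain
areas are conserved to < 0.1 % under refinement. Zero load reproduces
zero fields to machine precision, the homogeneous-cytoplasm far field
matches the one-unknown closed form to < 1 %, and the net axial reaction
balances across the constrained planes to < 1e-6.

Nuclear volume is computed two independent ways - a revolution integral
over the deformed envelope boundary and a deformed-element quadrature sum
- which agree to < 0.5 % and guard the shape metrics.

## Image quantification

Standard steps go through EBImage (Otsu thresholds, 2-D labelling,
morphological dilation, distance-map watershed, Gaussian blur); 3-D
connected components (26-connectivity) are labelled slice-wise and merged
with a union-find, since no installed labeller is 3-D. Pixel indexing is
0-based at the physical-coordinate level (voxel centres at (i - 0.5) x
voxel size); all user-facing geometry is in micrometres.

* Nuclear morphology comes from principal axes of the voxel-coordinate
  covariance (a solid ellipsoid of semi-axis a has variance a^2/5, so the
  full axis is `2*sqrt(5*var)`); minimum object sizes of 20 um^2 / 50 um^3
  reject debris.
* The perinuclear ring is a 0.5-um dilation minus the nucleus; the
  cytoplasmic ring a further 3-um dilation minus both. Enrichment is the
  ratio of mean intensities (scale-invariant; threshold-based readouts
  below are not).
* Pole enrichment automates what was a manual tracing: 2-um caps where
  the principal axes meet the boundary, normalized to the cytoplasmic
  mean; the output flags itself as automated, and near-round nuclei are
  flagged degenerate with image-axis tie-breaks.
* Rupture-reporter foci (2-D MIP): fixed intensity threshold (600 a.u.,
  or 200 a.u. for the mutant reporter line - the generator emits
  intensities on the same arbitrary-unit scale, which is what makes fixed
  thresholds meaningful), area > 0.8 um^2, 8-connected contact with the
  nucleus, and overlap with a 1-um perinuclear ring. The ring is
  implemented as a 1-um-wide dilation ring (the source description
  alternates between "perimeter" and "diameter" phrasing; width is the
  reading that makes the contact gate non-trivial).
* DNA-damage foci (3-D): intranuclear components above 2000 a.u. within
  0.02-1000 um^3; summaries are count, mean focus volume and focus
  fraction of nuclear volume. Outlier rows (> mean + 3 s.d. on count or
  mean volume, each criterion independently) are excluded before
  normalization to the control-group mean.
* Tissue coverage: membrane-channel Otsu plus watershed of the interior
  distance map (cell segments); marker coverage: 0.3-um Gaussian blur,
  MIP, fixed threshold, percent area.

Chromatin-protrusion scoring is deliberately not automated (it was a
blinded human readout); the generator can plant protrusion-like
distortions for visual checks only.

The image generator renders hard-edged objects (uniform ellipsoids,
spheres, grids) plus optional Poisson-Gaussian detector noise - no PSF,
no anisotropic blur, no intensity gradients. Recovery tests on these
stacks validate geometry and bookkeeping of the quantifiers, not their
robustness to optical artefacts.

## Biphasic regression

The aspect-ratio-versus-enrichment relation is summarized by LOESS
(degree-1 local fits, tricube weights, span 0.6 by default - the span is
a choice, reported with the output, as no value is prescribed) evaluated
on a uniform grid, and by a continuity-constrained piecewise linear
("hinge") regression `y = a + b_low*x + (b_high - b_low)*max(x - c, 0)`.
Continuity is enforced because a deflection point is a change of slope,
not a jump; no free-discontinuity variant is offered. The breakpoint is
profiled over a 100-point grid spanning the central 80 % of x, refined
once, then polished by 1-D minimization inside the bracketing interval,
with ties broken to the smaller SSE then the smaller breakpoint; fits
with fewer than 5 points on a side are rejected. Slope standard errors
and p-values come from the conditional linear model at the selected
breakpoint under homoscedastic normal errors (the breakpoint-search
uncertainty is not propagated - the p-values answer "is this segment's
slope zero", the question asked of them). Degenerate single-line data is
flagged unidentifiable. The deflection locator uses slope changes over
windows of fixed physical width (15 % of the x-range), which keeps the
estimate stable under grid refinement; hinge SSE can never exceed the
single-line SSE, and this nesting is tested.

The scatter generator draws x uniformly over [0.8, 3.5] and adds
N(0, 0.3) noise to a hinge with deflection 1.9, lower slope -2.1, flat
upper segment and aspect ratio 2.0 at the deflection - the noise level is
chosen to make the lower slope overwhelmingly significant and the upper
one non-significant in ~90 % of 300-point cohorts, mirroring the pooled
relation it emulates.

## Problem sizes

The defaults used by the tests and the acceptance script: 20-cell trace
cohorts at 250/91 Hz for ~5.6 s; a ~1800-element default mesh (refinement
checks at 4x); image fields of 24 x 18 x 8 to 246 x 246 x 2 um at 0.1-0.2
um lateral voxels; 20 x 300-point biphasic scatters. These sizes keep a
full run in minutes on one core while leaving every estimator's error well
inside its test tolerance.

## Known limitations

Linearized kinematics under ~60 % strain (stress magnitudes at the cage
run low; no strain stiffening of the lamina; instability only by proxy);
the enrichment-to-cage-stress map is an assumed linear stand-in; pole
enrichment approximates a manual protocol; the generators emulate effect
sizes and noise levels, not full biological or optical variability; and
animal-cohort readouts (survival, ejection fraction, in-vivo foci counts)
are outside the package's scope.
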