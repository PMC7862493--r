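---
title: "Predicting dose-volume histograms from prior plans: models and methods"
author: "kbdvh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting dose-volume histograms from prior plans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbdvh)
```

## The problem

In radiotherapy planning, the cumulative dose-volume histogram (DVH) of an
organ at risk (OAR) or planning target volume (PTV) summarises what a
treatment plan achieves: for each dose level $d$, the percentage of the
structure's volume receiving at least $d$. Knowledge-based planning (KBP)
asks whether the DVH that a skilled planner would achieve for a *new*
patient can be predicted from a database of prior plans, before any
optimization is run. A reliable prediction gives planners a
patient-specific quality benchmark and usable optimization objectives.

`kbdvh` implements two complementary feature sets for this prediction:

* **IDVHs** — the *individual-field DVHs*. Nine uniform-intensity conformal
  fields are placed at the site's gantry angles, each fitted to the
  outermost target, and the structure's DVH is computed for every field
  *separately* (no inter-field dose superposition). Each of the nine curves
  is sampled at 50 equally spaced points on a normalized dose axis, giving
  a 450-dimensional input that encodes direction-dependent dosimetric
  information: which beam directions traverse the structure and at what
  depth.
* **DTH + CPDVH** — a geometric descriptor plus a superimposed dosimetric
  one. The *distance-to-target histogram* (DTH) is the cumulative fraction
  of OAR volume within a given signed Euclidean distance of the target
  surface; the *conformal-plan DVH* (CPDVH) is the structure's DVH under
  the equal-weight sum of the nine fields. Fifty samples of each give a
  100-dimensional input.

OARs can use either method; PTVs use only IDVHs, because a target's own
geometry-to-target distance carries no information while its per-field
dose distribution does.

## The prediction model

The regressor is a generalized regression neural network (GRNN), i.e.
Gaussian-kernel Nadaraya–Watson regression over stored exemplars. Given
training pairs $(x_i, Y_i)$ with $Y_i$ the 50-point clinical DVH:

$$\hat Y(x) = \frac{\sum_i w_i Y_i}{\sum_i w_i},
  \qquad w_i = \exp\!\left(-\frac{\lVert x - x_i\rVert^2}{2\sigma^2}\right).$$

The prediction is a convex combination of training curves, so it is
bounded by the componentwise range of the exemplars; as $\sigma \to 0$ it
approaches the nearest exemplar and as $\sigma \to \infty$ the exemplar
mean. If every weight underflows, the nearest exemplar is returned. OAR
and PTV models are trained separately, one model per structure *type*
(bilateral organs contribute two instances to one shared model — the left
and right organ are treated as exchangeable draws of the same organ type,
which doubles the training set for paired structures). Predicted curves
are post-processed into valid cumulative DVHs: clipped to $[0, 100]$ and
made monotone by a running minimum from the low-dose end.

The kernel width $\sigma$ is not reported in the KBP literature we follow,
so it is selected by leave-one-out cross-validation minimizing the mean
absolute curve error, with ties broken towards the smaller width. The
candidate grid is 25 log-spaced values spanning 0.01–10 *times the median
pairwise exemplar distance*. A fixed absolute grid would be fragile here:
feature-space distances scale with $\sqrt{d}$ and with curve variability,
so anchoring the grid to the observed distance scale keeps the search
meaningful for both the 450- and the 100-dimensional inputs. Toolbox
conventions that parameterise the kernel by a "spread" with bias
$0.8326/\mathrm{spread}$ translate as
$\sigma = \mathrm{spread}/(0.8326\sqrt 2)$.

## Cohort-level normalizations

Four axis normalizations are fitted on training patients only and carried
as `NormConstants` with a provenance hash (the pipeline verifies that test
patients never contributed):

* IDVH dose axis: maximum dose of all individual fields;
* DTH distance axis: maximum OAR-to-target distance (the sampling span's
  lower end is likewise fixed from the training cohort's minimum
  normalized signed distance, so all patients share abscissae — kernel
  distances require aligned coordinates);
* CPDVH dose axis: maximum PTV dose of all conformal plans;
* clinical DVH dose axis: maximum PTV dose of all clinical plans.

Curve sampling uses 50 equally spaced points *including both endpoints*
($k/49$, $k = 0\ldots49$), which preserves the $V(0) = 100\%$ anchor of
every cumulative DVH. Test-time abscissae beyond a training constant are
clipped to the normalized value 1 with a warning, carrying the ordinate
interpolated at the clip point.

## Evaluation

Prediction accuracy uses the determination coefficient and the mean
absolute error over the 50 sampled volume values,

$$R^2 = 1 - \frac{\sum_{i=1}^{50}(V_{i,\mathrm{ref}} - V_{i,\mathrm{pred}})^2}
                 {\sum_{i=1}^{50}(V_{i,\mathrm{ref}} - \bar V_{\mathrm{ref}})^2},
  \qquad
  \mathrm{MAE} = \frac{1}{50}\sum_{i=1}^{50}
   \lvert V_{i,\mathrm{ref}} - V_{i,\mathrm{pred}}\rvert,$$

computed on the normalized-axis curves (both are defined by 50-point sums,
so they are evaluated on exactly those samples, not on raw internal bins).
Dose-volume endpoints ($D_y$: the minimum dose to the hottest $y\%$;
$V_x$: the volume receiving at least $x$ Gy) are read off the curves with
linear interpolation; the uniformity index is $UI = D_5/D_{95}$, with 1
indicating a perfectly homogeneous target dose. Paired comparisons use the
two-sided Wilcoxon signed-rank test: zero differences are dropped, the
null distribution is computed exactly (by convolution over rank
contributions, equivalent to enumerating all $2^n$ sign assignments, with
midranks for ties) for up to 25 nonzero pairs, and by normal approximation
with tie and continuity corrections beyond. Both modes are exposed because
reports rarely state which was used. $D_y$ requests outside a curve's
ordinate range return the boundary dose with a warning rather than
extrapolating. A site-specific catalogue of protocol constraints
(brainstem $D_0 \le 60$ Gy, parotid $V_{30} \le 50\%$, bladder
$V_{50} \le 50\%$, ... with inclusive bounds) supports plan-quality
checks.

## The synthetic cohort and dose engine

Clinical planning databases are not publicly deposited, so the package
ships a first-class synthetic stand-in with two parts.

**Phantoms.** Seeded cohorts for two sites on a default
$96 \times 96 \times 48$ grid at $(0.2, 0.2, 0.3)$ cm (axial slices along
z, 0.3 cm slice thickness, voxel-centre coordinates, gantry rotation in
the axial plane). The head-and-neck-like site has three nested targets
(PTV70/PTV60/PTV54, built from ellipsoidal CTVs expanded by a 0.3 cm
margin), a posterior cord-like cylinder, paired lateral parotid-like
ellipsoids and small anterior lens-like spheres; prescription 70 Gy. The
pelvis-like site has PTV50/PTV45 (0.5 cm margin), an anterior bladder-like
shell, paired femoral-head-like spheres and a superior bowel-like blob;
prescription 50 Gy. Structure geometry is drawn uniformly from documented
ranges (`hnGeometry()`, `pelvisGeometry()`); these ranges are the
package's own choices of plausible inter-patient variability, not values
derived from any clinical dataset. Margins are implemented by thresholding
an exact anisotropic Euclidean distance transform (not a structuring
element), with a $10^{-9}$ cm tolerance at the threshold so voxels at
exactly the margin distance are kept despite floating-point rounding.
Per-patient seeds are a fixed multiplicative mix of the master seed and
the patient index, so a cohort can be extended without reshuffling
existing patients.

**Dose engine.** A deliberately simple, fully testable parallel-beam
model — what the feature construction needs is monotone depth dose and
direction-dependent geometry, not a clinical algorithm. For gantry angle
$\theta$ the beam travels along $(\sin\theta, \cos\theta, 0)$; the
aperture is the beam's-eye-view projection of the fit target represented
per axial slice as a lateral interval (per-slice conformal leaf fitting),
expanded by an aperture margin (default 0.5 cm) and edge-softened by a
Gaussian penumbra of width 0.3 cm applied as
$T = \Phi((\text{margin} - s)/\sigma_p)$ with $s$ the signed distance to
the projection — the exact blurred-half-plane edge profile. Depth from the
body surface is an exact 2-D voxel traversal along the ray, and
$\mathrm{dose} = D_0\,T\,e^{-\mu\,\mathrm{depth}}$ with
$\mu = 0.05\,\mathrm{cm}^{-1}$, zero outside the body, $D_0$ set so the
maximum dose in the fit target is 1 before plan-level scaling. The
interval-based aperture and the exact traversal make the engine
mirror- and rotation-consistent to floating-point precision, which the
test suite exploits. The conformal plan is the equal-weight field sum
scaled so the median dose of the highest PTV equals the prescription
(exact by construction). The HN preset uses the fixed nine angles
160/120/80/40/0/200/240/280/320 with apertures fitted to PTV54; the
pelvis preset approximates an arc with nine equally spaced fields fitted
to PTV45.

**Pseudo-clinical plans.** The learnable ground truth that clinical
optimized plans would provide. Starting from the conformal plan, dose
outside the PTV union is multiplied by
$g(v) = 1 - s\,(1 - e^{-\mathrm{dist}(v)/\lambda})$ with a per-patient
sparing strength $s \sim U(0.2, 0.5)$ and fall-off $\lambda = 2$ cm;
inside each PTV the dose is set to that PTV's level (70/60/54 or 50/45 Gy,
innermost winning) times $1 + \varepsilon(v)$, where $\varepsilon$ is
white noise blurred at 1 cm and rescaled to a 2% standard deviation;
finally the in-target dose is rescaled so the $D_1$ of the highest PTV is
1.06 times the prescription. The construction is smooth in the patient
geometry, so a kernel regressor can learn it; it is a stand-in, and its
parameters are not presented as clinically calibrated.

The DTH is computed against the *union* of the nested PTVs (equal to the
outermost PTV), the same region that drives the sparing model — the
distance that governs achievable OAR dose. The signed convention puts
negative distances inside the target; the KBP literature does not state a
convention, so this is a package decision, recorded here. The surface is
defined on the voxel lattice via two distance transforms (outside:
distance to the target; inside: minus the distance to its complement),
which is reproducible without mesh extraction.

## Numerical choices

* Cumulative DVHs use "$\ge$" at bin edges on an equal-interval grid from
  0 to the maximum in-structure dose, 1000 internal bins by default —
  interpolation error well below the metric tolerances; a structure
  receiving no dose yields the degenerate single-point curve $(0, 100)$.
* $D_y$ tie-breaking on flat curve segments: the largest dose at
  $y = 100$, the smallest at $y = 0$, so $D_0$ is the maximum voxel dose.
* The per-patient sparing strength $s$ is *not* visible to the features,
  so part of the OAR dose scale is irreducibly random; the regressor can
  only predict its conditional mean. This is intentional — clinical
  plans likewise vary between planners for identical geometry.
* Train/test splits are seeded uniform draws without replacement; all
  pipeline randomness flows from one master seed through fixed substreams
  (cohort, per-patient plan noise, split), making every run exactly
  reproducible.

## What the synthetic tests do and do not show

The phantom cohort exercises every contract of the pipeline — histogram
exactness, feature dimensionalities (450/100), normalization hygiene,
learnability of a smooth geometry-to-DVH mapping, endpoint extraction and
the statistical comparisons — at desk scale (a full HN run of 90 patients
on the default grid takes on the order of a minute). Passing them shows
the machinery is correct and that the two feature sets recover a smooth
planning function on anatomically plausible geometry variation. It does
*not* show clinical accuracy: real anatomies vary in ways ellipsoids do
not, real optimizers trade off competing objectives non-smoothly, and
real dose engines model scatter, build-up and heterogeneity that the
exponential parallel-beam model omits. Accuracy numbers obtained on the
synthetic cohort therefore characterise the method under the generator's
assumptions, nothing more.

## Known limitations

* PTV targets in the pseudo-clinical model have little inter-patient DVH
  variability (by construction their dose is prescription plus smooth
  noise), so PTV prediction on synthetic data is an easier task than on
  clinical plans.
* VMAT delivery is approximated by nine static equally spaced fields; no
  MLC, build-up or heterogeneity modelling.
* DICOM-RT import/export is out of scope; volumetric I/O uses NIfTI.

## A minimal run

```{r tiny-run, eval = FALSE}
cfg <- runConfig("HN", nTrain = 10, nTest = 4, seed = 1,
                 grid = gridSpec(c(48, 48, 24), c(0.4, 0.4, 0.6)))
res <- runPipeline(cfg)
res$report$oar_accuracy
```

The full-size study configuration (70/20 patients, default grid) is what
`scripts/acceptance.R` runs; see the README for how to reproduce its
numbers.
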