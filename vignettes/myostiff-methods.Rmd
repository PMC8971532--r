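---
title: "Estimating passive myocardial stiffness from the EDPVR: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating passive myocardial stiffness from the EDPVR: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The end-diastolic pressure-volume relationship (EDPVR) is the organ-level
signature of passive ventricular filling. It confounds three things: the
intrinsic stiffness of the myocardium, the anatomy of the chamber, and the
fiber architecture of the wall. `myostiff` implements an inverse-modelling
pipeline that deconvolutes them: a feed-forward neural network is trained on
a large synthetic corpus of (geometry, fiber, EDPVR) → (stiffness) examples
and then predicts the two fiber-stiffness constants of a reduced
Holzapfel–Ogden (H–O) constitutive model directly from measurements that are
available in vivo.

## Constitutive model

The myocardium is modelled as an incompressible, transversely isotropic
hyperelastic solid with energy

$$\Psi = \frac{a}{2b} e^{b(I_1 - 3)}
      + \frac{a_f}{2 b_f}\left[e^{b_f (I_{4f}-1)^2} - 1\right],$$

where $I_1$ is the first invariant of the right Cauchy–Green tensor and
$I_{4f}$ the squared fiber stretch. The four constants are strictly
positive; $a$, $a_f$ carry stress units (kPa). The ground-matrix pair is
fixed at healthy reference values $a = 0.22$ kPa, $b = 1.62$ and only
$(a_f, b_f)$ — overall fiber stiffness and exponential stiffening rate —
are estimated. Two deliberate conventions:

* **No tension-compression switch.** The fiber term applies for
  $I_{4f} < 1$ too, matching the stress expression as written. Under the
  inflation loading used everywhere in this package $I_{4f} \ge 1$, so the
  choice is inert in practice.
* **Energy offset.** The matrix term is nonzero at the reference state, so
  `strain_energy()` also returns the energy measured from the reference,
  which vanishes at identity deformation and is the quantity used in
  zero-point tests.

Incompressibility is enforced exactly ($\lambda_r = 1/\lambda_\theta
\lambda_z$), never by penalty: the semi-analytic solver depends on exact
volume conservation.

## Synthetic anatomy

The generator emulates a library of rodent biventricular "parent" hearts
with truncated semi-ellipsoids of revolution: an epicardial surface
(equatorial radius 3.9–4.3 mm, base-to-apex length 10.5–11.5 mm), an LV
endocardial cavity (equatorial radius 1.99–2.04 mm, apex depth 8.5–8.9 mm)
and an RV crescent (a 1.2–2.2 rad sector of the band between the
LV-concentric mid-wall surface and the epicardium, radial fraction
0.30–0.50). Chamber resizing scales the LV endocardium in the short-axis
plane only and the RV band thickness, with the epicardium held fixed.

The LV cavity band is deliberately narrow: combined with the resize factor
range $f_{LV} \in (0.7, 1.6)$, whose square scales cavity volume, the
unloaded LV volume spans roughly 35 µl up to about five times that across
the library — the stated span of the study conditions. The resulting wall
volume (about 250 µl against a 70 µl cavity) is on the thin side of
rat-like, which makes the chambers, if anything, more compliant than real
rodent hearts.

Twelve geometric features are extracted per heart: LV cavity volume and
endocardial area, RV cavity volume and area, six short-axis
epicardium-enclosed slice areas (base plane through 5/6 of the apex
distance; the apex point itself has zero area and carries no information),
and epicardial interior volume and surface area. Two ambiguities in the
feature definitions were resolved as follows: slice areas are whole
epicardium-enclosed cross sections (robust to chamber resizing), and all
surface areas are lateral (open-base) areas of the surfaces of revolution.

Fiber architecture follows the standard rule: the helix angle turns
linearly with transmural depth from $\theta_{endo} \in (0, \pi/2)$ to
$\theta_{epi} \in (-\pi/2, 0)$, discretized into four equal-thickness
layers that carry their midpoint-depth angle.

## Reduced-order inflation solver

Forward pressurization is solved on an equivalent thick-walled cylinder:
length equal to the epicardial long axis, inner radius preserving the LV
cavity volume, outer radius preserving the LV wall volume
(epicardial − LV − RV). With the base fixed axially ($\lambda_z = 1$, no
torsion), incompressibility gives $r(R)^2 = r_i^2 + R^2 - R_i^2$ and the
luminal pressure is the transmural integral of
$(\sigma_{\theta\theta} - \sigma_{rr})/r$ against the reference measure.
The integral is evaluated with 8-point Gauss–Legendre quadrature per fiber
layer; the deformed inner radius is found by bracketed root finding,
warm-started along the 100-step pressure grid (0.3–30 mmHg, fixed
increments), with the bracket capped at $10 R_i$. Doubling the quadrature
order and halving the pressure step changes volumes by well under 0.1%.

The RV is *not* pressurized: the cylinder has no septal coupling, so the
RV enters only through its geometric features (which the feature-importance
analysis finds unimportant). This is a documented systematic difference
from a full biventricular finite-element stage, along with the absence of
long-axis stretch and torsion.

Units: kPa and mm/µl internally; pressures cross the interface in mmHg at
1 mmHg = 0.133322 kPa.

## Inverse fitting and identifiability

`inverse_fit()` is a Levenberg–Marquardt least-squares fit of selected
constants to a target EDPVR, log-transformed for positivity (convergence:
relative step < 1e-8 or relative residual change < 1e-10, 200 iterations).
It is deliberately single-start: `identifiability_report()` uses repeated
fits from spread initializations to probe uniqueness, and auto-restarting
would mask exactly the structure it measures.

Two landscape facts matter when reading its output:

* With $b = b_f$ fixed and equal, the matrix and fiber scale constants
  $(a, a_f)$ trade off almost perfectly: fits from distant starts reach
  equally small residuals with grossly different estimates. This
  non-identifiability is why the pipeline fixes $(a, b)$ and estimates
  only the fiber pair, for which multi-start fits collapse onto a single
  estimate.
* The $b_f \to 0$ subspace is flat (the exponent loses all leverage on the
  curve), and a trajectory started from a far-too-stiff $a_f$ can stall
  there with a *large* residual. Such runs are optimizer failures, not
  evidence about identifiability; the report therefore assesses uniqueness
  over the fits that actually reach the residual tolerance (0.5% volume
  RMS by default) and merely records the failures.

## Sampling and the training corpus

The six design dimensions $(f_{LV}, f_{RV}, \theta_{endo}, \theta_{epi},
a_f, b_f)$ are sampled by plain Latin hypercube (one point per
equal-probability interval per dimension, uniform jitter, no maximin
optimization) over the stated ranges, with $a_f \in (0.01, 100)$ kPa and
$b_f \in (0.01, 20)$. Parents are assigned round-robin so each of the 25
parents anchors an equal share of the corpus; the pairing of design rows
with parents is not dictated by the study conditions, and round-robin
preserves the "25 parents × resizing" structure. Each example pairs the
114-element input (12 geometry + 2 fiber + 100 EDPVR volumes) with its
$(a_f, b_f)$ targets; 100 examples are held out for testing.

## Surrogate

The surrogate is a multilayer feed-forward network, 114 inputs → two
hidden rectifier layers → 2 outputs, trained with minibatch Adam
(learning rate 1e-4, batch 32) on an MAE loss over normalized targets.
Inputs are standardized per column; targets are normalized by their
maximum absolute value. Early stopping is implemented as best-checkpoint
selection: the weights with the lowest validation loss (a seeded 10%
holdout of the training pool) are returned. The default structure is
2×1024, the best performer in the cross-validated structure scan; the
network-structure scan itself uses ten folds at a 2,000-epoch budget.

The implementation is in compiled code with a single seeded RNG stream for
weight initialization and epoch shuffling, so a fixed seed reproduces a
training run bit-for-bit on the same machine.

Prediction quality is reported with three metrics per target: MAE in
physical units, NMAE (MAE as a percentage of the observed target range),
and the coefficient of determination $R^2$.

## Feature importance

Permutation importance shuffles one input column at a time (K = 10 seeded
repetitions by default, computed on the training/validation data) and
measures the rise in the model's MAE score. Importance is reported as
*degradation* — mean corrupted score minus reference score — so features
the model relies on come out positive; the alternative sign convention
(reference minus corrupted) merely flips the bars. The feature-reduction
workflow retrains with identical hyperparameters on a reduced input (LV
volume and area plus fibers and the EDPVR block, which is always kept).

## Klotz-style single-point reconstruction

A universal EDPVR is fitted by pooled log-log regression of pressure on
normalized volume $V_n = (V - V_0)/(V_{30} - V_0)$ (floor $V_n > 0.01$),
giving $P = A_n V_n^{B_n}$. Note that the normalization pins
$V_n(30\,\mathrm{mmHg}) = 1$, so a family that is exactly a power law
always yields $A_n = 30$; on heterogeneous corpora $A_n$ is free.

From a single measured point $(P_{ED}, V_{ED})$, the unloaded volume is
estimated as $V_0 = V_{ED}(k_0 - k_1 P_{ED})$ (defaults $k_0 = 0.6$,
$k_1 = 0.006$/mmHg, exposed as arguments), $V_{30}$ follows from the
universal curve, and the reconstructed relation is the single-beat power
law $P = \alpha V^\beta$ through $(P_{ED}, V_{ED})$ and $(30, V_{30})$,
inverted onto the standard grid. Two caveats are inherent to the method
and documented rather than patched: the low-pressure limb of the
reconstruction falls below the $V_0$ estimate (which is therefore kept as
metadata), and the empirical constants were calibrated on human data — on
this rodent-scale synthetic corpus the reconstruction envelope against the
true curves is substantially wider than the anchor-point accuracy, which
is exact by construction. The reconstruction error is reported by the
workflow, not asserted.

## Problem sizes and numerical budgets

The package's own studies use three tiers, chosen once as a balance of
statistical resolution against single-CPU runtime:

* module tests: a 300-example corpus, 2×128 network, 1,500 epochs;
* acceptance tests: a 1,000-example corpus, 2×512, 2,000 epochs;
* the acceptance script: the full 2,500-example corpus, 2×512, 1,200
  epochs for both the full-feature and reduced-feature models.

The full-scale reference protocol (2×1024, 10,000 epochs) is available
through the same configuration objects.

## Known limitations

* **$b_f$ is intrinsically hard in this reduced-order world.** The
  exponent acts through $(I_{4f}-1)^2$, which is second order in fiber
  strain. With the base fixed axially the cylinder develops no long-axis
  stretch, fibers at steep helix angles barely stretch, and the uniform
  thick wall develops no strain concentrations; in addition, most of the
  sampled $a_f$ range (uniform up to 100 kPa, against a 4 kPa maximal
  load) produces chambers that stay close to their unloaded volume, where
  curvature information about $b_f$ is minute. Held-out recovery of
  $b_f$ is therefore markedly worse than $a_f$ here — the gap between the
  two targets has the same sign as in full 3-D finite-element corpora but
  is much larger. A gradient-boosted-tree baseline does no better on the
  same corpus, indicating the limit sits in the data-generating physics,
  not the network. Fiber stress curves, by contrast, are robustly
  reproduced even from the worst parameter predictions, because
  $(a_f, b_f)$ errors compensate along the stress manifold.
* The RV is mechanically inert; its features exist to mirror the input
  contract and are expected (and verified) to carry near-zero importance.
* Passing tests on this synthetic corpus demonstrate correctness of the
  pipeline and recoverability under the generator's assumptions —
  axisymmetric anatomy, rule-based fibers, noise-free curves. They do not
  certify accuracy on imaging-derived anatomies or catheter data, which
  add segmentation error, measurement noise, and shape modes the
  equivalent cylinder cannot represent.
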