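---
title: "Template-based mapping of white-matter tract damage: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based mapping of white-matter tract damage: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tractem)
```

# The problem

Diffuse axonal injury lowers fractional anisotropy (FA) and raises mean
diffusivity (MD) in white matter.  The natural way to quantify damage in a
specific tract -- run probabilistic tractography in the patient and sample
FA/MD inside the reconstructed tract -- is circular: the same damage that is
being measured also disrupts the tracking, so the reconstructed tract
preferentially avoids the most damaged tissue and the damage estimate is
biased low, increasingly so as damage grows.

`tractem` implements the alternative this package is built around: delineate
the tract once, in healthy controls, as a binary *mean tract template*
(average of streamline-count-normalized connectivity maps, thresholded at the
95th percentile of the averaged values and binarized), then sample every
subject -- however damaged -- through that fixed template.  Damage per tract
is the percentage of sampled voxels whose metric is a Z-score outlier against
the control cohort (Z > 3 for MD, Z < -3 for FA).  Masking the template to a
TBSS-style white-matter skeleton, minus CSF and grey-matter regions, confines
sampling to tract centers where partial-volume and residual-registration
errors are smallest.

Because no suitable diffusion data ships with the package, a synthetic
phantom module generates entire cohorts with known geometry, noise and
injury, and every claim the package makes about the method is expressed as a
property of that stated world and verified in the test suite.

# Models

## Forward signal model

Voxels follow the ball-and-stick mixture with a shared diffusivity $d$:

$$S(b, g) = S_0\Big[(1 - \textstyle\sum_j f_j)\,e^{-bd} +
  \textstyle\sum_j f_j\,e^{-b d (g^\top v_j)^2}\Big],$$

with up to two stick compartments $(f_j, v_j)$.  Rician noise is applied as
the magnitude of a complex Gaussian perturbation with standard deviation
$\sigma$ expressed in $S_0$ units; SNR is defined as $S_0/\sigma$.

The ground-truth tensor of a voxel is the compartment mixture
$D = d\,[(1 - \sum f_j) I + \sum_j f_j v_j v_j^\top]$, from which true FA/MD
are evaluated in closed form.  One subtlety is deliberate: the log-linear
tensor fit inverts a *mono-exponential* signal exactly, but the
ball-and-stick mixture is not mono-exponential, so exact FA/MD recovery can
only be demonstrated on signal generated from $D$ itself.
`simulate_dwi(model = "tensor")` exists for exactly that purpose; the
mixture model remains the default everywhere else, and the model-recovery
acceptance test uses the tensor forward model while the noisy-recovery bound
(median |FA error| < 0.05 at SNR 20) runs on the mixture.

## Model fitting

The tensor is fitted by log-linear least squares (signals clamped at
$10^{-6} S_0$ before the log), eigenvalues sorted descending, negatives
clamped to zero and flagged.  The two-fiber ball-and-stick fit is nonlinear
least squares with the compartment amplitudes profiled out by a small
non-negative least squares (variable projection): Nelder-Mead over
$(\log d, \theta_1, \phi_1, \theta_2, \phi_2)$ from two starts -- the tensor
eigenvector pair and their bisectors, where the sticks of a symmetric
crossing actually lie -- followed by a Levenberg-Marquardt polish.

Orientation uncertainty -- the tracking PDF -- uses a *residual bootstrap*
instead of the Bayesian MCMC of the original FDT tooling: the fit is
repeated on fitted-signal-plus-resampled-residuals, each refit
warm-started from the point estimate and run to convergence with
Levenberg-Marquardt.  This yields an equivalent sampling distribution with
far less machinery and is exactly reproducible from one integer seed.  On
noiseless data the residuals vanish and the PDF degenerates to the point
estimate, which the tests assert.

The second fiber participates in tracking only when its point-estimate
fraction reaches 0.05 (the conventional support threshold; the source
tooling's value is not published).  *Dispersion* is $1 - \mu_1$ with
$\mu_1$ the principal eigenvalue of the mean dyadic tensor
$\tfrac1N \sum_s v_s v_s^\top$ of the orientation samples: 0 when all
samples agree, $2/3$ for a uniform sphere.  The original tool's internal
dispersion formula is not published; this dyadic definition is the
documented substitute, so published dispersion percentages are not
reproduction targets.

## Tracking

From each seed voxel center, streamlines propagate bidirectionally (two
legs with opposite initial signs -- without this, half the walks from a
seed at a tract end would immediately exit and the success rate could never
reach 1 even on a perfect phantom).  Per step, one orientation sample is
drawn for the current voxel (nearest-voxel lookup; interpolating between
per-voxel sample *sets* is ill-defined); between two supported populations
the one most aligned with the previous direction (absolute cosine) is
taken, sign-flipped so the cosine is positive.  A cosine at or below the
curvature threshold 0.2 terminates the leg, as does grid exit, entering a
voxel without samples (the brain-mask analogue), target entry, or the step
cap.  Streamlines entering the exclusion mask are discarded entirely;
visited voxels of target-reaching streamlines are counted once per
streamline and normalized by the total number of generated streamlines.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| b-value | 1000 | s/mm^2 | single-shell acquisition this emulates |
| directions | 32 + 4 b=0 | -- | desk-scale knob, scaled down from 64 + 4 |
| stick diffusivity $d$ | 1.7e-3 | mm^2/s | deep-white-matter axial diffusivity |
| peak fiber fraction | 0.7 | -- | tract FA ~ 0.66 at tube center |
| $S_0$, noise $\sigma$ | 100, 5 | signal units | SNR 20, the stated test condition |
| grid | 40^3 | voxels | desk-scale common space |
| tube radius | 3 | voxels | thalamo-cortical-bundle caliber at this scale |
| jitter bound | 1 | voxels | residual post-registration misalignment |
| curvature threshold | 0.2 | cosine | tracking contract (cosine, the FSL convention) |
| streamlines/seed voxel | 500 | -- | desk default; 5000 available by config |
| step, step cap | 0.5, 2000 | voxels, steps | tracking contract, configurable |
| bootstrap samples | 50 | -- | orientation PDF resolution |
| template percentile | 95 | -- | template contract |
| skeleton FA floor | 0.2 | -- | TBSS convention |
| Z threshold | 3 | SD | outlier contract |

# The synthetic world, and what a green test establishes

Each cohort shares one base geometry: two mirrored quarter-circle arcs
("left/right" bundles) in a cubic grid, an exclusion slab between them (the
interhemispheric analogue), spherical seed/target regions at the arc ends
(doubling as the grey-matter masks), and a one-voxel CSF rim hugging each
tube.  The anisotropic fraction decays parabolically toward the tube
surface, giving tracts a partial-volume edge; the isotropic background (and
CSF rim) has the same $d$, hence CSF-like high MD and zero FA.  Per
subject, the whole field is warped by a smooth band-limited random
displacement bounded in max-norm; no registration is ever estimated --
the recoverable part of the warp is known and inverted, and the rest
persists as residual misregistration (see below).

Injury does three things inside a lesion, each scaling with severity $s$:

1. *compartment mixing* -- stick fractions scale by $(1-s)$, the isotropic
   diffusivity by the fixed factor $(1+s)$, so true FA falls and true MD
   rises monotonically (evaluated in closed form from the mixture tensor);
2. *orientation incoherence* -- each damaged voxel's stick directions are
   blended with an independent random unit vector with weight $s$ and
   renormalized.  Per-voxel rotations leave true FA/MD exactly unchanged
   (they are rotation invariant), preserving the analytic control, but the
   loss of voxel-to-voxel coherence is what actually breaks streamline
   propagation: axonal injury misaligns fibers rather than merely diluting
   them.  Calibration runs showed that compartment mixing alone leaves the
   stick direction identifiable at SNR 20 even at stick fraction 0.07, so
   tractography would barely fail and the method's motivating phenomenon
   would never appear in the phantom;
3. *extent growth* -- in the default focal mode the lesion is a ball
   anchored on the tube surface at the arc midpoint with radius
   $r_\mathrm{damage}(1+s)$.  Extent scaling matters because the clinical
   quantity, percent abnormal voxels, varies across patients mainly
   through damage extent: a fixed-extent lesion saturates the Z > 3 rule
   for any severity above roughly 0.1.  Anchoring the ball on the surface
   guarantees an intact corridor on the far side of the tube (reached only
   at $s = 1$); with target-filtered streamline counting on a single-route
   phantom this corridor is essential, because a full-cross-section lesion
   forces every *surviving* streamline through the damage and the
   individual tract would paradoxically oversample it.

A whole-tract diffuse mode is also provided.  The per-subject warp is
split into a recoverable component (whose known inverse is the
subject-to-common warp) and a residual component (default half the jitter
bound) that persists in common space -- the residual misregistration that
skeleton and CSF/GM masking exist to absorb; with an exactly-invertible
warp the masking-benefit property would be unmeasurable.

What the phantom does *not* emulate: real axonal geometry (undulation,
fanning, crossing anatomy beyond an optional second population), eddy
currents, susceptibility distortion, motion, estimated registration, tissue
segmentation, or clinical heterogeneity.  A green suite therefore
establishes that the *pipeline machinery* reproduces the method's
qualitative behaviour in a controlled world -- not that it reproduces any
clinical number.  The published patient percentages and correlation
(rho = 0.89 on real data) are explicitly out of reach and are replaced by
sign/ordering properties with seeded significance tests.

# Numerical choices

* **Percentile threshold** -- linear interpolation between order statistics
  (R's type 7), computed over voxels with positive mean connectivity;
  including the ~97% zero background would make the 95th percentile
  degenerate on a mostly-empty grid.  A flag restores the all-voxel
  distribution.  Retention is strict (`mean > threshold`).
* **Volume-matched binarization** -- ties at the cut break by (value
  descending, linear voxel index ascending); fewer nonzero voxels than the
  template volume yields all of them plus a shortfall flag, never a silent
  pad.
* **Skeleton** -- local FA maxima along the FA gradient, compared against
  trilinear samples one voxel to each side; where the gradient vanishes
  (ridge interiors) the most concave Hessian eigendirection is used.  Only
  the skeleton-as-mask role is implemented; TBSS's projection step is out
  of scope because the method uses the skeleton purely as a mask.
* **Z directionality** -- MD abnormal iff Z > +3, FA abnormal iff Z < -3:
  axonal injury elevates diffusivity and lowers anisotropy, and the
  published figure captions define abnormality as elevated MD.  A
  `two_sided` flag restores |Z| > 3.  Voxels with zero control SD are
  flagged invalid and excluded from denominators, with a warning.
* **Absent individual tracts** -- a severely damaged subject's tractography
  can produce a tract reconstructed away from the template's location, so
  that it covers few or no voxels of the sampling mask; estimating a
  percentage from a handful of voxels is meaningless (observed estimates
  swing between 0 and 100%).  Entries whose coverage falls below a quarter
  of the template's sampled voxel count are therefore flagged absent
  (never silently skipped) -- the synthetic analogue of tracts that "fail
  almost completely" in patients -- and the method comparison enters them
  as 0% abnormal by default ("failed tractography detects no damage", the
  limiting case of the underestimation being measured).
* **Group statistics** -- Spearman significance by exact enumeration
  (n <= 7) or seeded permutation, with the t-approximation reported
  alongside; rank-sum p exact by full enumeration up to n = 10 per group
  (ties handled by enumeration), normal approximation with tie and
  continuity corrections beyond.  Boundary convention: outcomes exactly as
  extreme as observed are included, so identical samples give p = 1.  The
  published ANOVA main effect is replaced by a paired Wilcoxon signed-rank
  test across subject-tract pairs -- distribution-free and consistent with
  the other tests; the F statistic is not reproduced.  Per-tract
  correlations are reported with raw and Holm-adjusted p side by side (the
  original analysis does not state a correction).
* **Z > 3 calibration test** -- the false-positive rate of the plug-in Z
  statistic converges to pnorm(-3) = 0.00135 only as the control cohort
  grows (at n = 20 controls the t-tail inflation roughly triples it); the
  calibration test therefore uses 500 Gaussian controls so the plug-in
  bias is negligible relative to the 3-binomial-SE acceptance band.
* **Determinism** -- every stochastic stage takes one integer seed;
  per-voxel and per-streamline RNG streams are derived by fixed integer
  mixing, so results are independent of processing order.  C++ fitting and
  tracking use their own `mt19937` streams, leaving R's RNG state
  untouched (library code saves and restores `.Random.seed`).

# Known limitations

* The jitter warp's nearest-neighbour inverse is exact only to first order
  in the displacement; at the default 1-voxel bound the residual error is
  well under half a voxel, which is precisely the regime the skeleton
  masking is designed to absorb.
* The residual bootstrap underestimates orientation uncertainty in voxels
  where the model is badly misspecified (it resamples residuals around a
  fitted model); in heavily damaged voxels the fit itself is unstable,
  which in practice *raises* sampled dispersion, and only the ordinal
  dispersion properties are asserted.
* Per-voxel dispersion is *not* monotone in damage severity here: raising
  the isotropic diffusivity sharpens the orientation kernel at b = 1000
  (signal falls off faster with angle), which offsets the stick-fraction
  loss until the fraction is small (severity above roughly 0.7).  Damaged
  voxels are reliably separable at the cohort level (percentage of
  dispersion outliers per subject), but a matched-voxel median comparison
  at moderate severities is not -- an inherent property of the
  compartment-mixing damage model, documented rather than patched.
* With 50 bootstrap samples the dispersion floor is coarse
  (resolution ~ 1/50 in the dyadic eigenvalue); absolute dispersion values
  are not comparable across different sample counts.
* The skeleton of a noisy mean-FA map can be patchy at tract ends where
  the grey-matter caps begin; the skeleton+GM+CSF configuration excludes
  those voxels anyway.
* Desk-scale defaults (32 directions, 500 streamlines/seed voxel, 40^3
  grid) are size knobs, not statements about the emulated acquisition; the
  acquisition-scale values (64 directions, 5000 samples) are a config away
  but slow.
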