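---
title: "Parametric response mapping and spirometry prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric response mapping and spirometry prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prmct)
```

## The measurement problem

Spirometry (FEV1/FVC and FEV1% predicted) is the reference standard for
diagnosing chronic obstructive pulmonary disease (COPD), but it is
insensitive to the earliest, still-reversible stage of the disease:
functional small-airways disease (fSAD), in which peripheral airways trap
air at expiration before any parenchymal destruction is visible. Parametric
response mapping (PRM) detects this stage on paired breath-hold CT. After
the expiratory scan is deformably aligned onto the inspiratory grid, each
lung voxel is classified by joint thresholding of its two HU values:

| class | inspiratory HU | expiratory HU | interpretation |
|---|---|---|---|
| emphysema | ≤ −950 | ≤ −856 | low density in both phases |
| fSAD | > −950 | ≤ −856 | air trapping without destruction |
| normal | > −950 | > −856 | normal parenchyma |
| uncategorized | ≤ −950 | > −856 | low inspiration, normal expiration |

The verbal category definitions are mutually inconsistent exactly at
−950/−856 (one category claims each boundary with "≤", its neighbour with
"<"). `classify_prm()` therefore uses the half-plane partition
*insp ≤ −950* versus *> −950* and *exp ≤ −856* versus *> −856*, which
reproduces every off-boundary case and is total; boundary voxels are
measure-zero in real data.

Class voxel counts are converted to volumes (mL, voxel count × voxel
volume) and percentages of the regional lung volume, over eight regions —
whole lung, left lung (lobes 4–5), right lung (lobes 1–3), and the five
lobes — giving 9 quantities × 8 regions = 72 PRM parameters
(`prm_parameter_names()`). This enumeration is adopted because the regional
quantity set (LV, four class volumes, four class percentages) and the eight
regions are the only combination that yields exactly 72.

Two regressors map the 72 PRM parameters plus age, sex, height and weight
(76 features) to FEV1/FVC and FEV1%; predicted spirometry is then staged by
the same deterministic rules used for measured spirometry, which is how a
screening CT can triage subjects without a spirometer.

## Staging rules

In fraction units: COPD iff FEV1/FVC < 0.7, with GOLD stage I (FEV1% ≥
0.80), II ([0.50, 0.80)), III ([0.30, 0.50)), IV (< 0.30). Among
non-obstructed subjects, normal iff FEV1% ≥ 0.95, otherwise high-risk. Two
gaps in the verbal definitions are closed deterministically: FEV1/FVC
exactly 0.7 is non-COPD (the obstruction criterion is a strict `<`), and
non-COPD subjects with FEV1% below the nominal 0.80 band edge are
high-risk — predicted spirometry does land there, and published discordant
cases treat such predictions as high-risk. CSV ingestion rescales
percent-scale spirometry columns (median > 2) to fractions, because both
unit conventions are in circulation.

## The phantom generator

The image stages are validated on a digital phantom whose ground truth is
known by construction:

* **Geometry.** Five disjoint axis-aligned ellipsoidal lobes (three right,
  two left) inside a cuboid grid (default 64³ voxels at 1 mm); the lung
  mask is exactly their union. This is deliberately schematic — it
  reproduces the region structure of a segmented lung, not its anatomy.
* **Classes.** Each in-mask voxel draws its PRM class from the configured
  per-lobe fractions, so regional class counts are exact ground truth.
* **HU values.** Paired HU are drawn uniformly from class-specific
  intervals that leave a 1-HU guard band around the −950/−856 thresholds
  (inspiratory emphysema/uncategorized: [−1000, −951], fSAD/normal:
  [−949, −700]; expiratory emphysema/fSAD: [−1000, −857],
  normal/uncategorized: [−855, −600]). The guard band makes the zero-noise
  phantom classifiable *exactly*, which turns round-trip tests into
  equality checks. Gaussian HU noise (default 0) then produces controlled
  threshold-crossing rates.
* **Warp.** The expiration can be warped by a smooth random displacement
  field (Gaussian-smoothed white noise, default smoothness 8 voxels),
  tapered to zero at the lung boundary and scaled to a configured peak
  amplitude; the generator stores the alignment field (the numerical
  inverse of the applied warp).

What the phantom does **not** emulate: vessels, airways and fissures; the
spatially correlated texture of real parenchyma; scanner physics. Its two
breath-hold volumes are drawn *independently* within each class, which has
one important consequence: a real inspiratory/expiratory pair shares
anatomical texture across phases, the phantom pair does not. Registration
fidelity is therefore assessed as *self-consistency* — recovering a known
warp of a volume against its own unwarped copy — and passing phantom tests
demonstrates the machinery is correct, not that any particular accuracy
will be reached on clinical data.

## Registration

No published algorithm is attached to the original workstation step, so
the package implements a conventional multi-scale demons-style scheme
under a masked mean-squared-difference metric: at each scale (image
smoothing 5, 2.5, 1.2 voxels; 40/40/30 iterations) the accumulated field
warps the moving volume, the classical normalized update
$\,du = -(M-F)\,\nabla F / (|\nabla F|^2 + (M-F)^2)$ is capped at 1
voxel, smoothed (fluid σ = 1), added, and the field re-smoothed
(diffusion σ = 1). The DC intensity offset between phases is removed
inside the (2-voxel-dilated) mask before the metric is evaluated. The best
iterate by masked MSE is kept, so the result never degrades the metric
relative to identity; on identical inputs every update is exactly zero.

Registering two volumes that share *no* texture signal is ill-posed under
an MSD metric: the optimizer will still reduce MSE by hallucinating warps
(partly mere interpolation smoothing). A correspondence gate protects
against this: the masked correlation of the two volumes after normalized
(mask-aware) smoothing at σ = 4 is computed over the eroded mask interior,
and below 0.4 the identity field is returned with a warning. Plain
smoothing would not work here — background bleeding across the lung
boundary makes any two masked volumes correlate through the shared
boundary alone, which is why the gate uses normalized convolution. On
phantom self-consistency problems a 2-voxel peak warp is recovered to
about 0.3 voxel mean residual in roughly 40 s at 64³; individual field
realizations of larger amplitude can decorrelate the voxel-scale texture
enough to trip the gate, which is then reported honestly (identity field,
`converged = FALSE`) rather than returning an unreliable warp.

Resampling is trilinear with boundary clamping; out-of-volume samples of a
user-supplied field are marked invalid and removed from the lung mask. One
consequence of the phantom's i.i.d. per-voxel texture is worth stating:
applying even the *exact* alignment field to a warped phantom leaves HU
residuals on the order of the within-class spread, because double
interpolation of white texture is lossy regardless of geometric accuracy.
Field-application correctness is therefore tested on smooth content, and
geometric accuracy via the recovered field itself.

## The cohort generator

The model stages are validated on a synthetic screening cohort with an
explicit generative model. Per-subject severities are drawn as
fSAD% ~ Gamma(1.8, scale 7) (mean ≈ 12.6), Emph% = 0.12·fSAD% +
Gamma(0.8, scale 1.5), uncategorized% ~ Gamma(1.5, scale 1.2); per-lobe
values jitter log-normally (σ = 0.25) around the subject level, lobe
volumes follow a Dirichlet split of a Normal(4400, 900) mL total, and all
72 regional parameters are aggregated exactly the way the image pipeline
aggregates them (so conservation identities hold by construction).
Spirometry is linear in the whole-lung percentages:

$$\mathrm{FEV1/FVC} = 0.87 - 0.0045\,\mathrm{fSAD\%} - 0.012\,\mathrm{Emph\%} + \varepsilon,\quad \sigma = 0.03$$
$$\mathrm{FEV1\%} = 1.14 - 0.0123\,\mathrm{fSAD\%} - 0.010\,\mathrm{Emph\%} + \varepsilon,\quad \sigma = 0.06$$

The coefficients were fixed once so that staging the noiseless spirometry
yields roughly 60% normal / 30% high-risk / 10% COPD — the class balance
of a community screening population — with plausible group medians
(normal FEV1/FVC ≈ 0.82, COPD ≈ 0.66). The slopes are *effective* marginal
associations chosen for that prevalence, not literature estimates of lung
physiology; likewise the per-lobe heterogeneity (the log-normal jitter) is
a free parameter, since no distributional information about lobar PRM
variation was available to estimate it. The generator's ground-truth group
label is the staging rule applied to the *noiseless* spirometry; the
emitted measured columns add the Gaussian noise and are clipped to the
physiologic domains (0, 1.2] and (0, 1.6].

## Models and evaluation

The 4:1 split is a seeded shuffle (validation size `round(n/5)`, or
explicit sizes for designs such as 494/121 that are not an exact ratio).
The random forest uses 500 trees, `mtry = ceiling(76/3)`, node size 5 —
conventional regression defaults, exposed for override. The perceptron
baseline is a single hidden layer of 32 units with weight decay 10⁻³ on
standardized inputs; a single hidden layer is the configuration the
underlying fitter supports, and the baseline's role here is comparative
only. Predictions are clipped to (0, 1.6].

Evaluation reports R² = 1 − SS_res/SS_tot (negative when a model
underperforms the mean predictor), MAE, MSE, RMSE and Spearman's ρ with
average ranks on ties. Confusion reports store integer counts and derive
sensitivity, specificity, PPV, NPV and accuracy as exact fractions,
with zero-denominator metrics reported as not-applicable rather than 0;
rounded percentages are always recomputed from the stored counts. The
prediction-based staging cascade evaluates three tasks: COPD vs non-COPD
from predicted FEV1/FVC over the whole validation set (positive class
COPD); normal vs high-risk from predicted FEV1% among subjects predicted
non-COPD whose measured-spirometry label is normal or high-risk (positive
class high-risk — this restriction is why that task's denominator is
smaller than the validation set); and GOLD stage agreement among
measured-spirometry COPD subjects. The discordant-subject list of the
second task equals FP + FN of its confusion matrix by construction, an
identity the tests verify.

One evaluation subtlety is documented rather than hidden: with a
noiseless, near-deterministic feature→target link, a *single* permuted-
target control can retain a chance correlation with the true target
(standard deviation ≈ 1/√n) that a flexible learner amplifies out of
sample. The permutation control is therefore summarized as the mean
held-out R² over five independent permutations, which concentrates near
zero.

## Problem sizes and numerical choices

Phantom validation uses 64³ grids (≈ 30 mL of lung at 1 mm voxels; the
geometry scales, the conclusions do not depend on physical lung volume);
unit tests use 40³–48³ and cohorts of 300, the acceptance checks 64³ and
500. Tolerances: class fractions under 5 HU noise are recovered within 2
percentage points (and within 0.5 points of the brute-force
threshold-crossing oracle); warp recovery below 0.5 voxel mean residual;
percentage sums to 100 within 10⁻⁶; volume conservation within one voxel
volume (integer counts make these exact up to float summation). Ties and
degenerate inputs: constant regression targets yield R² = NA with a
warning; empty regions report zero percentages and are flagged; lung
voxels without a lobe label count toward whole lung only, with a warning.

## Known limitations

* The phantom's missing cross-phase texture correspondence means the
  registration default on phantom *pairs* is the gated identity; on real
  pairs, which do share texture, the gate passes. No claim about clinical
  registration accuracy is made or testable here.
* The cohort generator's linear spirometry model makes the regression
  task easier than reality; its purpose is recoverability testing
  (a learner that fails on it is wrong), not difficulty calibration.
* GOLD stage agreement is evaluated only among measured-spirometry COPD
  subjects, which are few in a screening-prevalence cohort; its variance
  is correspondingly large.
* Symptom- or exposure-based risk definitions, post-bronchodilator
  spirometry, airway/vessel exclusion from the mask, and image-input deep
  learning are out of scope.
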