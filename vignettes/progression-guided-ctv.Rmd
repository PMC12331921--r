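---
title: "Progression-guided CTV definition: models, losses and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progression-guided CTV definition: models, losses and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Standard-of-care radiotherapy for glioblastoma irradiates a clinical
target volume (CTV) built geometrically from the visible tumor: the
combined contrast-enhancing lesion (CEL) and T2-FLAIR lesion (T2L) plus
a uniform 2 cm margin (the RTOG recipe), or the enhancing tumor and
resection cavity plus 1.5 cm excluding edema (the EORTC recipe). Both
ignore where the tumor is actually going to grow: infiltration is
spatially heterogeneous and anisotropic, so geometric CTVs simultaneously
overtreat normal brain and undertreat infiltrative disease.

`gliomctv` implements an alternative: predict the region of future
progression from pre-radiotherapy multi-parametric MRI — anatomic
(post-contrast T1, T2-FLAIR), diffusion (ADC, FA) and metabolic MR
spectroscopic index maps (choline-to-NAA index CNI, choline-to-creatine
index CCrI) — and derive the CTV from that prediction. The package
covers the full pipeline: voxel transition labelling between timepoints,
per-patient median statistics, voxel-wise random-forest classifiers, a
3D U-Net trained with size-adaptive overlap losses, geometric comparison
CTVs, and a six-metric evaluation suite.

Because no public dataset accompanies the method, the package ships a
seeded synthetic cohort generator that reproduces the statistical
structure the method relies on; every claim the test suite makes is a
claim about recovery of effects planted by that generator.

## Voxel transitions and the analysis band

Each case carries region masks at two timepoints. Derived compartments
are defined by exact set identities: the non-enhancing lesion
`NEL = T2L \ CEL`, and normal-appearing voxels
`NAV = brain \ (cavity | ventricles | T2L)`. Between pre-RT and
progression, every brain voxel gets exactly one label: `NAV_to_CEL`,
`NAV_to_NEL`, `NEL_to_CEL`, `STABLE_NAV`, `OTHER` (e.g. voxels already
enhancing at baseline), or `OUTSIDE_BAND`. The analysis is restricted to
a 40 mm isotropic expansion of the pre-RT lesion: progression beyond
that distance is not observed, and an unrestricted stable class would
swamp the progressed classes.

Per-patient medians of each (min-max normalized) channel are computed
per transition class, requiring at least 5 voxels per class; metabolic
channels additionally require the voxels to lie inside the MRSI coverage
box (the PRESS excitation volume), and the covered count must itself
reach the 5-voxel minimum so that out-of-box fill values never
contaminate a median. Classes below threshold are absent from the table,
not zero.

Group differences are tested with a paired Wilcoxon signed-rank test
across patients on the per-patient medians. The source literature names
a "Mann–Whitney signed-rank test", which conflates the paired and
unpaired tests; since the compared quantities are two within-patient
summaries, the paired test is the defensible reading and is the default
(`paired = FALSE` gives the rank-sum variant). P-values are reported
with the usual clinical banding (<0.05, <0.01, <0.001, <0.0001).

## The size-adaptive Tversky loss (PCC)

The Tversky index generalizes Dice by weighting false positives and
false negatives asymmetrically:

$$T_{\alpha,\beta} = \frac{TP}{TP + \alpha\,FP + \beta\,FN},$$

with $\alpha=\beta=0.5$ recovering Dice exactly. For CTV prediction the
two error types are not symmetric: a false negative is untreated tumor,
a false positive is irradiated normal brain. The Progression Coverage
Coefficient (PCC) sets the weights per patient from the lesion-to-brain
voxel fraction $f = n_{lesion}/n_{brain}$:

$$\beta = \frac{1}{f+1}, \qquad \alpha = 1 - \beta,$$

which is algebraically identical to
$\beta = n_{brain}/(n_{brain}+n_{lesion})$ (the package asserts the two
forms agree exactly for all $f \ge 0$). Small lesions — the strongest
class imbalance — get the largest $\beta$, punishing misses hardest. At
the typical clinical lesion fraction $f \approx 0.02$, $(\alpha, \beta)$
round to $(0.02, 0.98)$.

Choices worth making explicit:

* **Lesion reference for `f`.** During training and evaluation, `f` is
  computed from the ground-truth composite target of the case; at pure
  inference, when no truth exists, the pre-RT lesion is the documented
  fallback.
* **Soft vs hard counts.** Training losses use soft (probabilistic)
  confusion sums for differentiability; all reported evaluation metrics
  binarize at 0.5 first.
* **Smoothing.** All ratio losses add a `1e-6` smoothing constant to
  numerator and denominator, guarding empty-mask limits without visibly
  biasing scores.
* **Specificity inside the brain.** True negatives are counted within
  the brain mask only; air voxels would inflate specificity
  meaninglessly.
* **HD95 convention.** The 95th percentile is taken over the pooled
  bidirectional surface-distance set (6-connectivity surfaces, distances
  in physical mm); the max-of-directions convention is available behind
  a flag. Quantiles use R's default type-7 interpolation, matched by the
  brute-force oracle in the tests.

## Geometry in physical millimetres

All margin growing uses an anisotropy-aware Euclidean distance transform
over voxel centres (Felzenszwalb–Huttenlocher, per-axis squared spacing),
with inclusion at `distance <= margin`. Margins are always specified in
mm, never voxels, and every CTV is clipped to the brain mask — dose
targets outside the skull-stripped brain are meaningless. Expansions are
computed fully in 3D. The working resolution is 3 mm isotropic
throughout; the synthetic generator emits 3 mm grids directly.

## The segmentation model

The network is a 3D U-Net: four encoder stages of two 3×3×3
convolution + ReLU blocks with 2× max-pooling between stages and feature
counts doubling from `base_features`; a symmetric decoder with
nearest-neighbour upsampling and concatenation skips; a final 1×1×1
projection with a logistic output. Inputs are the per-case min-max
normalized channels (default nT1c, nFLAIR, nADC, nFA, CNI, CCrI); when
metabolic channels are used, the MRSI coverage mask is concatenated as an
auxiliary input channel so the model can discount uncovered voxels — a
direct response to the observed instability of predictions outside the
PRESS box. The training target is the composite lesion: CEL ∪ NEL from
*both* timepoints, predicted from pre-RT images alone.

There is no deep-learning framework in the package's dependency
footprint: forward and backward passes (direct 3D convolution, pooling,
upsampling) are compiled kernels in the package's own `src/`, with
gradients verified against finite differences in the test suite, and a
standard adaptive-moment (Adam) optimizer. The original optimizer
(Ranger) is treated as an implementation detail of the optimizer
contract, not part of the method. Shapes not divisible by
`2^(stages-1)` are symmetrically zero-padded and cropped back after the
forward pass.

Augmentation applies seeded axis flips and 90°-multiple rotations
identically to channels and target (90° multiples avoid interpolating
masks), Gaussian noise to channels only, and optional channel shuffling
and dropping. Model selection maximizes the validation Tversky
coefficient at fixed (0.02, 0.98), the imbalance-sensitive metric; the
best-epoch weights are kept. Case splits are 67/16/18
train/validation/test, stratified by treatment cohort with
largest-remainder allocation, and a leakage guard asserts that no case
id appears in more than one split (the analogous guard runs in every
cross-validation fold of the random forests). The two-phase
hyperparameter search (coarse grid, then random draws around the best
grid point, ranked by validation Tversky) defaults to 5 random trials at
desk scale; the reference profile `net_config_paper()` records the
original printed optimum (learning rate 5e-5, 48 base features,
mini-batch 1).

The reference "five-fold CV with a 70/30 train/test ratio" is
internally inconsistent as stated; grouped k-fold assignment is primary
here and the ratio treated as descriptive.

## The synthetic cohort: what it emulates and what it does not

`cohort_spec()` defaults *are* the study conditions:

* **Grid**: 48³ voxels at 3 mm (brain ellipsoid ≈ 700–800 cm³ with
  embedded ventricles and a resection cavity adjacent to the lesion).
* **Lesion volume law**: log-normal with median 26.4 cm³ and
  `sdlog = 0.73` (chosen so the mean ≈ 34 cm³, matching the reported
  mean/median pair); the resulting mean lesion-to-brain fraction sits
  near the canonical `f ≈ 0.02–0.05`.
* **Cohort mix**: SOC/ATT/ENZA at 44/27/30 out of 101, allocated by
  largest remainder so realized counts match to within one case.
* **Progression time**: log-normal with median 7 months; cases at or
  past 7 months count as late progressors and get effect sizes
  attenuated by 0.4, mirroring the reported drop in late-progression
  predictability.
* **Growth model**: the progression T2L grows from the pre-RT lesion
  with an isotropic 4 mm base plus a per-case directional extent drawn
  uniformly from 8–26 mm along a random preferred direction (cosine
  falloff). A minority of cases therefore progress beyond a 2 cm margin
  of the pre-RT lesion but none beyond 4 cm, consistent with reported
  recurrence-pattern proportions. Anti-angiogenic cohorts (ATT/ENZA) get
  proportionally less enhancing growth, biasing them toward
  non-enhancing progression.
* **Channels**: tissue baseline + per-class planted shifts + spatially
  correlated Gaussian noise (sd 0.15 after smoothing at a ~2-voxel
  correlation length — index maps are spatially smooth). The shift
  ordering encodes the reported significance ordering:
  CNI = CCrI = nFLAIR (+0.25) > nADC (+0.12) > |nFA| (−0.06), lipid
  (+0.12) only in the to-CEL classes, lactate 0. The literature is
  internally ambiguous about the FA direction (its results table lists
  an elevation while its discussion describes infiltration lowering FA);
  the generator follows the infiltration physiology with a small
  negative shift. No quantitative effect sizes are reported anywhere, so
  the magnitudes are package defaults chosen to be recoverable but not
  trivial against the noise floor; they are tunable via `effect_table`
  and `effect_scale`.
* **MRSI coverage**: an axis-aligned PRESS box centred on the lesion
  spanning 60% of the brain bounding box per axis; metabolic channels
  outside it carry a constant baseline fill and the coverage flag is 0.

What the generator does **not** emulate: reaction–diffusion growth
dynamics, registration error and tissue shift, pulse-sequence physics,
field inhomogeneity, pseudoprogression. Passing tests therefore show
that the pipeline recovers the planted structure under the stated noise
model — they do not certify clinical performance on patient data.

## Problem sizes, runtimes and numerical choices

The package's own test and acceptance runs use desk-scale sizes chosen
as the smallest cohorts at which the respective effects are reliably
expressed: 40 default cases for the statistics and random forests
(stable-NAV rows capped at 1500 per case by seeded down-sampling; the
cap is provenance-recorded and optional), 10–14 case cohorts for network
training with `base_features = 4`, three stages and 15–40 epochs, and a
single 32³ case for the overfit capacity check with `base_features = 8`
and four stages. Training samples are cropped to the bounding box of
the 4 cm analysis band by default (`crop_to_band`): no progression
occurs outside the band, so voxels beyond it carry no training signal,
and the fully convolutional network still predicts whole volumes at
inference. On 32³ smoke-test grids the lesion-volume law is scaled
down with the brain (median divided by 3, or 6 for the deliberately
small-lesion cohort) so the lesion-to-brain fraction stays in the
clinically realistic range — at full lesion size a 32³ brain would make
the all-positive prediction a near-optimum of any high-β Tversky loss.
For the CTV-ordering experiment the models are trained with the
PCC + 0.5·BCE compound loss: it is reported as the best-performing
variant in the source, and its occasional non-contiguous segmentations —
the reason the source preferred pure PCC for its final model — are
handled here by the anchored connected-component filter in `dl_ctv()`
(components must touch the pre-RT T2L or cavity; internal holes are
filled). Pure PCC remains the default training loss. `dl_ctv()` also
unions the pre-RT lesion into the CTV by default
(`include_pre_lesion`): a target volume must always cover visible
disease, with the prediction supplying the anticipated growth around
it. For that experiment the binarization threshold is chosen by
`tune_dl_threshold()`, which maximizes the mean per-case PCC on the
*validation* cases only — the test split never informs the choice.

Other numerical conventions: probability clipping at `1e-7` before BCE
logarithms; DL CTV threshold fixed at 0.5 (threshold tuning exists but
is off by default, and when enabled uses validation cases only); EORTC
edema exclusion applied after the 1.5 cm expansion (both orders
available); vasogenic edema operationalized as the pre-RT NEL — the only
T2-hyperintense non-enhancing compartment the mask model defines —
behind an explicit toggle, since clinical edema and NEL are not strictly
identical; early/late split boundary is inclusive on the late side
(time ≥ 7 months is late). Empty-mask distance metrics raise errors
distinct from geometry mismatches. The random forests use 150–200
probability trees with impurity importances and balanced class weights;
forests and fold assignments are seeded and single-threaded for exact
reproducibility.

## Known limitations

* The generator's blob lesions are smoother and more convex than real
  infiltrative margins; boundary metrics (HD95) on synthetic cases are
  optimistic.
* Voxel noise is Gaussian and stationary; real index maps have
  spatially varying noise and registration artefacts.
* The training engine is CPU-bound and desk-scale; the reference
  configuration (48 base features) is provided but is not exercised by
  the test suite.
* Specificity comparisons are brain-restricted by design; values are not
  comparable to whole-volume specificities reported elsewhere.
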