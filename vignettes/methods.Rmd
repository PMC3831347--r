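---
title: "Joint tissue classification, bias correction and registration: the model and its choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint tissue classification, bias correction and registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Brain MR intensities are not quantitative: the same tissue scans to
different values across vendors, field strengths and coils, and every
volume carries a smooth multiplicative inhomogeneity (bias) field from the
receive/transmit hardware.  Automated tissue classification of large,
heterogeneous, multi-site collections therefore cannot rely on fixed
intensity thresholds.  `emtseg` implements the classic joint strategy:
atlas-prior-driven Gaussian-mixture classification by
expectation-maximization (EM), interleaved with bias-field estimation and
registration refinement, so that each sub-problem benefits from the
current solution of the others.

## The model

Let $y_i \in \mathbb{R}^M$ be the (fused) intensity vector of voxel $i$
across $M$ modalities, and $\Gamma_i \in \{1,\dots,K\}$ its tissue class.
The likelihood per class is multivariate normal with full inter-modality
covariance, $y_i \mid \Gamma_i = l \sim N(\mu_l, \Sigma_l)$, evaluated on
bias-corrected intensities.  Class membership probabilities come entirely
from spatial priors; there are no free global mixing weights:

$$p(\Gamma_i = l) \;=\; \frac{w_l\, \psi(t_{il})\, \mathbb{1}_{\beta_l}(y_i)}
   {\sum_j w_j\, \psi(t_{ij})\, \mathbb{1}_{\beta_j}(y_i)},$$

where $t_{il}$ is the atlas prior probability of class $l$ at voxel $i$,
$\psi$ the registration warp carrying the atlas into subject space, $w_l$
a per-class weight from the tissue configuration, and
$\mathbb{1}_{\beta_l}$ the *intensity-context indicator*: 1 iff, for
every modality $m$, $y_i^m$ lies strictly inside the class's quantile
interval $(q^m_{\mathrm{lower}}, q^m_{\mathrm{upper}})$ of the masked
image histogram.  The E-step computes per-voxel posteriors from density
times prior (in log space); the M-step re-estimates $(\mu_l, \Sigma_l)$
from posterior-weighted data.

Because quantiles are equivariant under monotone intensity maps, the
context constraint is invariant to global rescaling — exactly the
robustness needed across scanners.  The bounds shipped with the package
(17 extended classes: six GM subdivisions, cerebral and cerebellar WM,
CSF, two deep-gray WM&GM classes, venous blood, and five background
"Not-tissue"/Air nuisance classes) are deliberately conservative: they
should never exclude true members of a class, only prune impossible ones.

### Bias field

Scanner bias is multiplicative; the mixture wants an additive residual.
The package works in log-intensity space,
$w = \log(\max(y,0) + \varepsilon)$ with
$\varepsilon = 10^{-3}\times$ the masked median (non-positive intensities,
possible after noise, are clamped — the only deviation from an exact
round trip).  Per modality, the field is a polynomial of total degree 4
(35 terms in $[-1,1]^3$-scaled coordinates) fitted by weighted least
squares to the residual $w_i - \sum_l p_{il}\mu_l$ with precision weights
$\sum_{l\,\text{eligible}} p_{il} / \sigma^2_{l}$, where eligibility is
the per-class `use_in_bias` flag (pure, well-modelled tissues such as WM
and CSF; never the background classes).  The fitted field's mask-mean is
removed: a constant offset is unidentifiable and belongs to the class
means.  One independent field per modality, since different sequences see
different coil profiles.

### Outer loop

1. rigid intra-session alignment to the first scan, then voxel-wise
   fusion of repeats (averaging $k$ repeats cuts independent noise by
   $\sqrt{k}$);
2. atlas-to-subject registration (affine, or an external deformable
   engine through the plug-in contract; a missing plug-in degrades to
   affine with a warning, never a failure);
3. repeat until the relative EM log-likelihood change falls below
   `outer_tol` (default $10^{-4}$) or `max_outer_iter` (default 5):
   recompute quantile bounds on current corrected images → constrain the
   warped priors → EM → fit and accumulate the bias field → optionally
   re-register the atlas to the corrected reference image.

A note on monitoring: the outer-loop log-likelihood is **not comparable
across iterations** — each bias update changes the data the likelihood is
evaluated on — so no monotonicity is claimed (or observed) for it.
Monotonicity holds, and is tested to $10^{-9}$ slack, for the EM trace
with priors and bias fixed.  End-to-end progress is instead checked as
segmentation accuracy: the converged posteriors must beat the arg-max of
the raw degraded priors.

## The synthetic phantom

Real brain anatomy and gold-standard labels cannot ship with a package,
so every stage is exercised against an analytic phantom: nested
ellipsoids (air background, CSF shell, GM shell, WM core, optional
subcortical blobs) on a default $64^3$ grid, piecewise-constant class
means per modality (T1w: WM 140 > GM 100 > CSF 40; T2w: CSF 180 > GM 110
> WM 70, arbitrary units), a seeded multiplicative bias field
(low-order cosine components, zero-mean over the head, rescaled so its
peak deviation is exactly `rf`%), and additive Gaussian noise with SD =
`pn`% of the WM mean (the BrainWeb convention; the noise menu
{0,1,3,5,7,9}% follows the standard BrainWeb levels).  Imperfect atlases
are emulated by blurring (default 1.5 voxels ≈ population averaging) and
translating (misregistration) the one-hot ground-truth priors.

What a green phantom test does **not** establish: realistic cortical
folding and partial-volume effects, Rician noise statistics, and
anatomy-dependent registration difficulty are all outside the generator's
world.  The evaluation-grid orderings (context prior helps; aligned
priors beat offset priors) are structural claims reproduced at phantom
scale, not clinical accuracy figures.

## Numerical and design choices

* **Prior weights** enter multiplicatively before normalization — the
  only reading under which the configured weight 1.5 of cerebellar WM is
  operative.
* **Quantile-histogram mask**: voxels whose summed non-Air warped prior
  exceeds 0.5.  A permissive cutoff (e.g. 0.01) lets the air tail of any
  soft atlas dominate the histogram and pushes every configured quantile
  into the wrong intensity regime; 0.5 realizes the intent — "the
  atlas-supported head region" — for any atlas sharpness.
* **Degenerate voxels**: zero spatial support for every class ⇒ assigned
  Air (outside the head, by construction).  All-zero context products ⇒
  fall back to the unconstrained prior (constraints are conservative,
  never fatal) and are counted in the log.
* **Quantiles** use the linear-interpolation (type-7) estimator;
  interval membership is strict.  Configured fractions of 0 and 1 act as
  *unbounded* sentinels (no lower / upper constraint): an interval meant
  to include its tissue completely must not exclude voxels merely for
  lying outside the masked histogram's range — the background classes
  live below the head minimum by construction, and the maximal voxel of
  a `q_upper = 1` tissue would otherwise fail its own strict bound.
* **Background classes are exempt from the context constraint** in the
  pipeline.  Their role is to absorb non-tissue voxels; if their spatial
  prior were removed from the denominator wherever their (noise-straddled)
  interval fails, renormalization would hand air voxels wholesale to
  whichever tissue interval reaches lowest.  With the exemption, the
  context prior delivers its intended rescue under prior misregistration
  (three-tissue Dice near 1 on a 3-voxel-offset phantom versus ~0.77
  without the constraint); without it, the effect inverts.
* **Bias extrapolation is clamped** outside the mask to the field's
  on-mask range: the polynomial is unconstrained off-mask and its
  far-corner values would otherwise dwarf the data scale.
* **Phantom bounds are conservative in the phantom's own world**: the
  phantom's WM row uses a T2 lower fraction of 0 (sentinel) because WM
  is the darkest T2 tissue there and fills the bottom of the head
  histogram; real heads have darker non-brain content (captured by the
  "Not-tissue" classes), which is why the shipped 17-class table can
  afford a 0.05 lower fraction.
* **Bounds timing**: recomputed at the start of every outer iteration on
  current corrected images; iteration 0 uses raw intensities (no
  correction exists yet).
* **Covariance regularization**: $10^{-6}\times$ the mean per-modality
  variance added to the diagonal; collapsed classes (vanishing posterior
  mass) keep their previous parameters so the class vector shape is
  stable.
* **Ties** in the hard segmentation break to the lowest class index.
* **Three-tissue evaluation mapping**: GM ← {GM block, Thalamus,
  Globus}, WM ← {Wm, Crbl Wm}, CSF ← {Csf}; VB and background classes are
  pooled into an `Other` column (conserving probability) and excluded
  from Dice/Hausdorff.  Deep gray counts as GM, following the BrainWeb
  convention.
* **Registration**: similarity is histogram mutual information evaluated
  on a 0.37-voxel-jittered grid (off-grid sampling removes the
  interpolation artifact that makes grid-aligned transforms spuriously
  sharp), optimized by restarted Nelder-Mead in scaled units with a
  coarse exhaustive translation search for capture range.  Rigid uses a
  multi-resolution pyramid; affine runs at full resolution (coarse
  levels bias the 12-parameter scale estimate) and is initialized from
  rigid.  Joint-histogram bins scale with the level's voxel count.
* **Modified Hausdorff** follows Dubuisson: the larger of the two
  directed mean nearest-boundary distances between face-adjacency
  boundary voxels, in physical mm; the mean-of-means variant is
  available behind `variant = "mean"`.  Both-masks-empty Dice is 1
  (agreement on absence), with a message.

## Known limitations

* The deformable (SyN-class) registration is a plug-in contract only;
  the built-in fallback is affine.
* Repeats are fused by averaging, not modelled jointly; Rician noise,
  partial-volume mixels and MRF spatial smoothing are out of scope.
* NIfTI support is deliberately minimal (spacing and origin pass-through,
  no orientation gymnastics); volumes are float32 on disk, float64 in
  memory.
* The outer loop has no global objective; convergence is declared on the
  relative change of the EM log-likelihood within an iteration's fixed
  priors.
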