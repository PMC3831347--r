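# emtseg

Joint iterative tissue classification, bias-field correction and
registration for multi-modal brain MRI, in pure R.

## Who this is for

Brain MR intensities are not quantitative: tissue appearance drifts
across scanner vendors, field strengths and coils, and every volume
carries a smooth multiplicative inhomogeneity (bias) field.  `emtseg`
targets the automated processing of such heterogeneous data: it
classifies each voxel into tissue classes (gray matter, white matter,
CSF, deep-gray, venous blood, background) while simultaneously estimating
and removing the bias field and refining the atlas-to-subject
registration — the three problems are solved jointly because each one's
solution improves the others.

## The model

Voxel intensity vectors `y_i` (one component per modality, repeats fused
by averaging) follow a Gaussian mixture with full inter-modality
covariance, `y_i | Γ_i = l ~ N(μ_l, Σ_l)`, fitted by
expectation-maximization.  Class membership probabilities come from
warped atlas priors `t_il`, per-class weights `w_l`, and a *multi-modal
intensity-context indicator* `1_β`:

    p(Γ_i = l) = w_l ψ(t_il) 1_β(y_i; l) / Σ_j w_j ψ(t_ij) 1_β(y_i; j)

where `1_β(y_i; l) = 1` iff, for every modality `m`, `y_i^m` lies
strictly inside class `l`'s interval between the `q_lower^m` and
`q_upper^m` quantiles of the masked image histogram.  Quantile-anchored
bounds are invariant to global intensity rescaling — the property that
makes one configuration work across scanners.  The bias field `Φ^m` is a
degree-4 3-D polynomial per modality, additive in log-intensity space
(where multiplicative scanner bias becomes additive), fitted by
precision-weighted least squares to the residual `y - Σ_l p_il μ_l` over
the bias-eligible tissues, zero-meaned over the head mask.  The shipped
tissue configuration is a 17-class extended scheme (12 biological + 5
background "Not-tissue" classes) with per-class weights, bias
eligibility, and T1/T2 quantile bounds.

Agreement with ground truth is scored by the Dice index
`2|A∩B|/(|A|+|B|)` and the modified (average) Hausdorff distance — the
larger of the two directed mean nearest-boundary distances, in mm.

## Worked example

```r
library(emtseg)

# synthetic two-modality session: 20% peak bias, 3% noise,
# priors blurred by 1.5 voxels to emulate an imperfect atlas
spec <- phantom_spec(n = 32, pn = 3, rf = 20, prior_blur = 1.5, seed = 7)
ph   <- generate_phantom_session(spec)

cfg <- run_config(max_outer_iter = 4L, em_max_iter = 15L,
                  registration = "none", seed = 7)
res <- run_pipeline(ph$session, ph$atlas, cfg)

score_three_tissue(res$posteriors, ph$config, ph$labels)
#>   tissue dice mhd n_seg n_truth
#> 1     GM    1   0  3632    3632
#> 2     WM    1   0  1704    1704
#> 3    CSF    1   0  3496    3496

round(class_means(res$corrected, res$posteriors), 1)
#>        T1    T2
#> Air  10.9  10.5
#> Csf  40.2 182.1
#> Gm   99.4 109.6
#> Wm  137.4  68.1

cor(res$bias$fields$T1[ph$labels$data > 0],
    log(ph$fields$T1$data[ph$labels$data > 0]))
#> [1] 0.9901426
```

The segmentation recovers the ground-truth labels exactly (Dice 1.0 per
tissue, modified Hausdorff 0 mm); the posterior-weighted class means of
the bias-corrected images sit within ~2% of the generating values (T1:
CSF 40, GM 100, WM 140; T2: CSF 180, GM 110, WM 70), and the estimated
log-space bias field correlates 0.99 with the true simulated field.

## Command line

```sh
emtseg phantom --out demo/ --seed 1 --n 32 --pn 3 --rf 20
emtseg run --scan T1=demo/T1_rep1.nii.gz --scan T2=demo/T2_rep1.nii.gz \
           --atlas-dir demo/ --out result/ --seed 1
emtseg evaluate --seg result/labels.nii.gz --truth demo/labels.nii.gz \
                --out eval.csv
```

(the `emtseg` wrapper lives at `system.file("cli", "emtseg",
package = "emtseg")`; every run writes a manifest with seed,
configuration and output checksums).

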