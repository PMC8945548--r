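# braintensor

Group-level identification of brain networks — in particular the default
mode network (DMN) and its subcortical extent — from multi-subject
resting-state BOLD data sampled on a grayordinate-style space (cortical
vertices plus subcortical voxels on a 3-D grid).

Resting-state fMRI is not directly comparable across subjects because
spontaneous activity is not temporally synchronized. `braintensor`
implements the two-stage group analysis built around that problem:

1. **Temporal synchronization.** Each subject's space × time matrix `X_s`
   (rows normalized to zero mean and unit norm) is aligned on the time axis
   by an orthogonal transform `O_s`. The pairwise problem
   `min_O ||X_ref − X_s O||_F` over orthogonal `O` has the closed-form
   orthogonal-Procrustes solution `O = U Vᵀ` from the SVD of `X_sᵀ X_ref`.
   The group version alternates between aligning all subjects to a
   "virtual reference subject" and updating that reference as the
   row-renormalized mean of the aligned subjects, avoiding the bias of
   choosing any real subject as the reference. Because the transforms are
   orthogonal, full-window connectivity (inner products between normalized
   rows) is exactly preserved.

2. **Low-rank tensor decomposition.** The synchronized subjects are stacked
   into a space × time × subject tensor `X ∈ ℝ^{V×T×S}` and modeled as a
   sum of `R` rank-1 networks (canonical polyadic model):

   `X ≈ Σ_{r=1..R} λ_r · a_r ∘ b_r ∘ c_r`

   where `a_r` is the spatial map, `b_r` the temporal dynamics, `c_r` the
   per-subject participation level, and `λ_r` the network magnitude. The
   solver minimizes the squared reconstruction error with rank-incremental
   warm starts (the rank-`(r−1)` solution initializes the rank-`r` problem;
   only the fresh component is random, seeded, and refined by a few power
   iterations against the residual) and full-gradient Nadam updates. The
   global "physiological" signal is captured as the strongest component,
   which decouples it from the DMN — typically the second-strongest —
   without global signal regression.

Downstream tools select the target network by correlation with a cortical
template, split its spatial map into cortical and subcortical parts,
normalize the subcortical map by the 95% quantile of the cortical map
(making values interpretable as fractions of cortical network strength),
upsample it trilinearly, and quantify each subcortical nucleus against its
containing region (one-sided Welch t-test with random-field-theory resel
correction, `resels = volume / FWHM³`). Seed-based correlation maps with
and without global signal regression are provided for comparison, along
with a split-half reproducibility experiment. A synthetic-data generator
(`generate_dataset()`) emulates the assumed statistical structure — shared
low-rank networks, a dominant global component, anti-correlated regions,
per-subject temporal misalignment, additive noise — with full ground truth
and a toy spherical ROI atlas, so the entire pipeline is testable end to
end.

## Worked example

```r
library(braintensor)

cfg <- synth_config(n_cortical_vertices = 400, subcortical_grid = c(10, 10, 4),
                    n_timepoints = 120, n_subjects = 8, snr = 2, seed = 42)
sim <- generate_dataset(cfg)
sim$dataset
#> grayordinate_dataset: 8 subjects, V = 800 (400 cortical + 400 subcortical), T = 120

template <- sim$ground_truth$spatial_maps[sim$dataset$cortical_index, 2]
cfg_run <- pipeline_config(rank = 6, seed = 42,
                           seed_vertex = sim$ground_truth$seed_vertex)
res <- run_pipeline(sim$dataset, sim$ground_truth$atlas, template, cfg_run)

res$decomposition
#> cp_decomposition: 6 components, lambda = 54.5, 18.2, 16.2, 14.9, 10, 3.43, final relative error = 0.6251
```

The dominant component is the global physiological signal; the DMN-like
network is found as the second strongest, exactly as expected:

```r
cat(sprintf("selected component: %d (template correlation %.3f)\n",
            res$selection$index, res$selection$correlation))
#> selected component: 2 (template correlation 0.960)

print(res$roi_table[, c("roi", "region", "n_voxels", "median", "t_statistic",
                        "p_corrected", "significant_at_0.05")], digits = 3)
#>   roi    region n_voxels median t_statistic p_corrected significant_at_0.05
#> 1  CL  thalamus       41  0.293        6.33    4.21e-07                TRUE
#> 2 VTA brainstem       75  0.210        3.74    2.47e-03                TRUE
```

The normalized medians say the toy "CL" and "VTA" nuclei carry roughly
20–30% of the cortical network strength, and both are significantly more
coupled to the network than their containing regions (thalamus, brainstem)
after random-field correction — the sign structure and significance pattern
the generator embedded. Comparing with a raw (no GSR) seed-correlation map:

```r
cat(sprintf("tensor vs seed-map agreement: r = %.2f, sign agreement = %.2f\n",
            res$comparison$pearson, res$comparison$sign_agreement))
#> tensor vs seed-map agreement: r = 0.88, sign agreement = 0.21
```

The relative contrast agrees (r = 0.88) but the raw seed map is inflated to
almost all-positive values by the global component, so the signs disagree
wherever the tensor map is negative — the ambiguity that modeling the
global signal as its own component avoids.

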