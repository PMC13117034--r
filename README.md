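# attnmil

Weakly-supervised classification of 3D medical volumes with a
dual-attention, adaptively-sized bag embedding — plus the multimodal
tabular pipeline (univariate screening, LASSO selection, concatenation
fusion, MLP prediction) that typically surrounds it in imaging studies of
treatment complications such as radiation pneumonitis.

## The problem

In many imaging cohorts only *patient-level* outcomes are available: we
know whether a patient developed the complication, but not which CT slices
carry the predictive signal. Multiple-instance learning (MIL) treats each
patient's volume as a *bag* of slice-level *instances* with the MIL
constraint

```
Y = 0   iff every instance in the bag is negative,
Y = 1   otherwise.
```

A compact 3D convolutional backbone `f` maps a normalized volume
`X ∈ R^{H×W×S}` to instance feature vectors `H = {h_1, …, h_k}`, one per
depth position of its final feature map. Two attention layers then build a
bag representation:

1. **Attention MIL pooling.** Each instance is scored
   `a_k = softmax_k( wᵀ tanh(V h_kᵀ) )` and pooled, `Z = Σ_k a_k h_k`.
2. **Adaptive bag embedding.** The top-M instances by `a` form the
   *critical set* `{c_1,…,c_M}`; M itself is adapted as
   `M' = clamp(round(σ(MLP(softmax(top scores))) · k), 1, k)`.
   Every instance is projected to a query and value,
   `q_k = W_q h_k`, `v_k = W_v h_k`, and calibrated by its inner-product
   softmax distance to the critical set,

   ```
   D_k = (1/k) Σ_{m=1..M}  exp(⟨q_k, q_cm⟩) / Σ_n exp(⟨q_n, q_cm⟩)
   ```

   (so `Σ_k D_k = M/k`; a `1/M` normalizer is available by option). The bag
   embedding is `B = Σ_k D_k v_k`, and its flattened form is the patient's
   deep-feature vector.

The deep block is fused with a clinical/dosimetric block (t-test /
chi-square screening at `p < α`, then LASSO with a cross-validated λ on the
`(1/2M)·RSS + λ‖β‖₁` objective) and a radiomics-style block (LASSO), by
plain concatenation, and a sigmoid MLP produces the patient-level risk.

Because real cohorts of this kind are rarely shareable, the package ships a
seeded synthetic cohort generator: volumes with bright ellipsoid lesions
planted on known key slices, a Table-1-style clinical table (six null
categorical features, five mean-shifted dosimetric features), and a
high-dimensional sparse-signal radiomics table — so the whole pipeline,
including instance-level recovery of the planted slices, is testable end to
end.

## Worked example

```r
library(attnmil)

cohort <- generate_cohort(cohort_config(n_patients = 120, seed = 1))
model  <- train_stage1(cohort$volumes[1:96],
                       cohort$ground_truth$bag_labels[1:96],
                       backbone_config(seed = 1),
                       stage1_config(lr = 1e-3, max_epochs = 25,
                                     patience = 8, seed = 1))

rec <- instance_recovery_auc(model, cohort)
rec$auc
#> [1] 0.9724379

instance_attention(model, cohort$volumes[["P0004"]])
#>   instance slice_from slice_to            a            D selected
#> 1        1          1        4 6.044458e-08 6.872662e-64    FALSE
#> 2        2          5        8 9.999129e-01 5.000000e-01     TRUE
#> 3        3          9       12 4.757758e-05 3.290336e-73     TRUE
#> 4        4         13       16 3.942225e-05 6.726037e-71    FALSE
```

Patient `P0004`'s planted key slices are 6 and 7; the first attention layer
puts essentially all its weight (`a ≈ 1`) on instance 2, whose provenance
is slices 5–8, that instance is in the selected critical set, and the
second layer's distance calibration concentrates `D` on it (the weights sum
to `M/k = 0.5` here). The `instance_recovery_auc` of 0.97 says that, pooled
over all positive patients, attention ranks lesion-bearing instances far
above background — learned from patient-level labels alone.

The six-variant ablation (clinical only, radiomics only, mean-pooling MIL
CT, dual-attention CT, and the two fused models) runs on one shared
patient-level split:

```r
abl <- run_ablation(cohort, seed = 1)
abl[, c("variant", "accuracy", "auc")]
#>       variant  accuracy       auc
#> 1          cd 0.7083333 0.5378151
#> 2          rf 0.9166667 0.9831933
#> 3      ct-mil 1.0000000 1.0000000
#> 4     ct-daae 1.0000000 1.0000000
#> 5  fusion-mil 1.0000000 1.0000000
#> 6 fusion-daae 1.0000000 1.0000000
```

At this desk scale the planted lesion is deliberately strong, so every
deep/fused variant saturates; the discriminating observable is the
instance-level localization above, which only the attention model provides.
`run_pipeline(run_config(...))` executes the same chain end to end and
writes every intermediate table, checkpoints, the cross-validated
evaluation report and a content-hash manifest.

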