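# layercal

Layer-embedding analysis and probability calibration for 3D fully
convolutional segmentation networks.

## The problem

Voxel-wise lesion classifiers are usually *overconfident*: the softmax
score attached to "anomaly" overstates the empirical probability that the
voxel is anomalous, even when the ranking (AUC) is good. `layercal`
calibrates the output by probing the network's own hidden layers. Every
layer `l` is decomposed into **spatial information aggregation** (each
voxel's feature vector becomes the concatenation of its 27 dilated-neighbor
vectors — the *pre-convolution representation*) and **information
synthesis** (`ReLU(BN(conv))` — the *post-convolution representation*). A
20-tree random forest fitted on training-set representations at one slot
turns each voxel's representation into an *embedding output*
`sigma_l` — that layer's own anomaly probability. Calibration is the
voxel-wise product

```
sigma' = a * sigma_l * sigma + b        (a = 1, b = 0)
```

which down-weights scores the probed layer does not support; the only
learned hyper-parameter is the slot `(l, pre/post)`, chosen on the
validation split by minimum calibrated ACE. Platt scaling, Monte Carlo
dropout, and deep ensembles are included as baselines; metrics are
reliability diagrams, average calibration error (ACE), AUC, and Dice.
Experiments run on a built-in synthetic multi-channel liver phantom
(background / parenchyma / viable tumor / necrosis).

## Worked example

The canonical desk-scale study: 10 synthetic subjects, a narrow 10-layer
dilated FCN, one fold of a subject-level 60/20/20 split, probes on all 20
layer/stage slots, layer selection on validation, evaluation on held-out
test subjects.

```r
library(layercal)

res <- run_experiment(experiment_config(
  methods = c("raw", "embedding"), seed = 42))
print(res)
#> <experiment_result> 10 subjects, fold(s) 1
#>  fold 1: selected slot l3_post
#>  fold    method       ace       auc       dsc n_voxels
#>     1       raw 0.4705044 0.8587840 0.1504834    27648
#>     1 embedding 0.1651369 0.9190247 0.0000000    27648
```

The raw FCN is heavily miscalibrated (ACE 0.47); weighting it by the
layer-3 post-convolution embedding output cuts ACE to 0.17 while AUC
*improves* (0.859 to 0.919). The selected slot sits in the early layers, as
expected: early representations are generic enough not to have inherited
the output's overconfidence, yet informative enough to know where lesions
cannot be. (The embedding-calibrated DSC at threshold 0.5 is 0 here —
down-weighted scores rarely exceed 0.5; rankings, and hence AUC, are what
the product calibration preserves.)

Lower-level pieces compose directly:

```r
vol <- generate_phantom(phantom_config(seed = 7))
net <- build_fcn(fcn_spec(channels = c(8, 8, 12, 12, 16, 16, 12, 12, 8, 8)))
param_count(fcn_spec())$total
#> [1] 320276

fr  <- forward_with_representations(net, vol)   # 20 slots: l1_pre ... l10_post
dim(fr$reps$l1_pre$values)
#> [1] 13824    81
```

See the vignette (`vignettes/layer-embedding-calibration.Rmd`) for the
method in full, the phantom's scope, and the reasoning behind the
under-specified choices.

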