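# octlan

Lesion-aware attention networks for volumetric retinal OCT classification in
R.

`octlan` is for researchers who want to screen diabetic patients at risk of
diabetic nephropathy (DN) from macular OCT volumes, and for anyone studying
attention mechanisms guided by weak localization. Distinguishing DN from
plain diabetic retinopathy (DR) in OCT is hard for ordinary CNNs because the
discriminative lesions occupy a small part of the scan. The package
implements a two-stage remedy:

1. **Stage 1** trains a plain 3D residual network on preprocessed
   100 × 100 × 70 volumes.
2. Its **Grad-CAM** localization maps,

   α<sub>k</sub><sup>c</sup> = (1/Z) Σ<sub>i</sub> ∂y<sup>c</sup>/∂A<sub>i</sub><sup>k</sup>,  L<sup>c</sup> = ReLU(Σ<sub>k</sub> α<sub>k</sub><sup>c</sup> A<sup>k</sup>),

   are min-max normalized, upsampled, and binarized at threshold T = 50 into
   coarse lesion masks B ∈ {0,1}.
3. **Stage 2** inserts a mask-guided self-attention module into the backbone,

   X<sub>L</sub> = X ⊙ X<sub>B</sub>,  A<sub>L</sub> = softmax(X<sub>LC</sub> X<sub>LC</sub><sup>T</sup>) X<sub>C</sub> + X<sub>C</sub>,

   where X<sub>LC</sub> and X<sub>C</sub> are 1×1×1-convolution projections of
   the gated and original features, and trains the attention network with the
   masks fixed.

Around that core the package provides the full B-scan preprocessing chain
(macular slice selection → interval sampling → center crop → binarization →
dilation → largest-contour foreground extraction → resize → volume
assembly), patient-level k-fold cross-validation with
accuracy/sensitivity/specificity and ROC/AUC, a synthetic OCT phantom
generator so everything is testable without clinical data, and a CLI.

The network engine (3D convolution, instance normalization, pooling,
attention, Adam) is implemented in vectorized base R and validated against
finite-difference oracles in the test suite; image plumbing goes through
EBImage and png.

## Worked example

```r
library(octlan)
options(octlan.verbose = FALSE)

# a 20-patient synthetic study, preprocessed to 48 x 48 x 16 volumes
vols <- study_phantom_volumes(n_patients = 20, dn_fraction = 0.5, seed = 1)
dim(vols[[1]]$data)
#> [1] 48 48 16

# two-stage attention network vs its baseline on a held-out patient split
res <- two_stage_comparison(vols, seeds = c(1, 2, 3))
res
#>   seed baseline_acc lam_acc
#> 1    1         0.75    0.75
#> 2    2         1.00    0.75
#> 3    3         1.00    1.00
median(res$lam_acc - res$baseline_acc)
#> [1] 0
```

Each row holds one seed's held-out accuracy for the stage-1 baseline and the
two-stage attention network; at this miniature scale the attention model
matches the baseline in the median. Inspecting a mask:

```r
tc <- train_config(epochs = 15, lr = 1e-3, step_size = 10, seed = 7)
s1 <- train_stage1(vols, NULL, tiny_backbone_config(), tc)
s1$final_train_acc
#> [1] 1
cam <- gradcam(s1$model, vols[[1]], class_label = 1)
mask <- cam_to_mask(cam, dim(vols[[1]]$data), T = 50)
mean(mask$values)        # fraction of the volume flagged as lesion-relevant
```

The command-line interface mirrors the same pipeline
(`system.file("cli", "octlan", package = "octlan")`):

```sh
octlan phantom --n 20 --seed 1 --out data/raw
octlan preprocess --data data/raw --out data/vols --config cfg.yaml
octlan train --stage all --data data/vols/manifest.tsv --out runs/exp1 --config cfg.yaml
octlan evaluate --data data/vols/manifest.tsv --out runs/eval --config cfg.yaml
```

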