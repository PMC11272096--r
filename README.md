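# apunet

Artifact removal and depth-profile restoration for ultrasound-guided
diffuse optical tomography (DOT) of the breast.

Frequency-domain DOT reconstructs the tissue absorption perturbation
`δμa(r)` (cm⁻¹) under a hand-held probe — 9 source fibers, 14 detector
fibers, 140.02 MHz modulation — from the scattered photon-density wave
`Usc`. The linear (Born) inverse problem

```
Usc = W δμa ,      W[i,j] = -(v/D) · G(r_src, r_j) · G(r_j, r_det) · V_j
δμa = argmin ‖Usc − W δμa‖² + λ²‖δμa − δμa0‖²
```

is solved by conjugate gradient on a dual mesh (0.25 × 0.25 × 0.5 cm fine
voxels around the ultrasound-localized lesion, 1.5 × 1.5 × 0.5 cm coarse
background blocks, 9 × 9 × 3.5 cm grid, 7 depth layers). Reconstructions
of this kind carry well-known artifacts: source hot spots over shallow
lesions, clutter from optode-coupling errors and tissue heterogeneity, and
the *shadowing effect* — progressive loss of reconstructed amplitude in
deeper lesion layers.

The package implements, end to end and with no external data:

* the semi-infinite frequency-domain diffusion Green's function
  (extrapolated boundary), Born weight matrix, and measurement synthesis;
* the dual-mesh Tikhonov-regularized conjugate-gradient reconstruction
  (volume-weighted, sensitivity-compensated penalty);
* a seeded synthetic phantom generator (spheres, ellipsoids, cubes,
  two-hemisphere balls, extruded glyphs; coupling/heterogeneity/noise
  degradation modes; surface hot spots for shallow targets);
* **APU-Net**: an attention-based physically informed U-Net whose encoder
  predicts the measurement vector in its bottleneck (a learned forward
  solver) and whose decoder returns the enhanced absorption map, built on
  contextual-transformer (CoT) attention blocks, trained with the
  composite loss `α·L_p + β·L_i + γ·L_f` (perturbation MSE, lesion-weighted
  image MSE, perceptual feature loss; α=5, β=1, γ=0.01, a=0.98, b=0.02);
* the image-quality metrics used to judge enhancement: artifact contrast
  `C_arti` (max over artifact region / max over lesion region, lower is
  better) and depth contrasts `C12`, `C13` (deeper lesion layer max /
  first lesion layer max, 1 is ideal), plus a paired evaluation harness
  and an attention-ablation study.

The neural network, backpropagation and Adam optimizer are implemented
natively in R (im2col + BLAS, with a small compiled gather kernel);
gradient correctness is verified against finite differences in the test
suite.

## Worked example

```r
library(apunet)

# 1. simulate a training corpus (seeded, self-contained)
ds <- generate_dataset(375, splits = c(train = 0.8, val = 0.04, test = 0.16),
                       config = list(seed = 42))

# 2. train a small APU-Net for a desk-scale demonstration
model <- build_apunet(apunet_config_small(), seed = 1)
fit <- train_apunet(model, ds,
                    train_config(learning_rate = 1e-3, epochs = 30,
                                 batch_size = 16, seed = 11))

# 3. paired evaluation on the held-out split
rep <- evaluate_dataset(ds, fit$model, split = "test")
print(rep)
```

On the 60 held-out samples this prints:

```
Metrics report over 60 samples:
          arm metric      mean        sd  n n_excluded
 ground_truth c_arti 0.0000000 0.0000000 60          0
 ground_truth    c12 1.0754432 0.2344841 59          1
 ground_truth    c13 1.2872923 0.5970467 45         15
        input c_arti 0.8039999 1.0886227 60          0
        input    c12 0.8987279 0.4000210 59          1
        input    c13 0.8351521 0.6268802 45         15
       output c_arti 0.6190807 0.2579190 60          0
       output    c12 1.1703511 0.1873972 53          7
       output    c13 1.2137857 0.2319562 40         20
```

Reading the table: the `input` rows are the degraded conjugate-gradient
reconstructions — depth contrasts scattered well away from 1 (mean
|C12−1| = 0.34, |C13−1| = 0.56 per sample) and high artifact contrast.
The `output` rows show the network pulling the depth profile toward 1
(mean |C12−1| = 0.18, |C13−1| = 0.23) with much smaller spread, and
suppressing the artifact contrast on the corrupted subset (0.90 → 0.64).
`ground_truth` rows are the reference; their depth contrasts deviate from
1 only on multi-target samples whose inclusions have different
absorptions. `n_excluded` counts samples whose lesion does not span the
required layers or falls under the low-signal exclusion rule.

A command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/apunet.R simulate --n 100 --seed 1 --out data.rds
Rscript inst/cli/apunet.R train --data data.rds --out model.rds
Rscript inst/cli/apunet.R evaluate --data data.rds --model model.rds --out report.json
Rscript inst/cli/apunet.R ablate --data data.rds --out ablation.json
```

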