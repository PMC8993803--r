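# mammowave

Multiclass abnormality classification for digital mammograms built around a
**wavelet-activated convolutional network (wCNN)**, for researchers in
computer-aided detection who want the full method — preprocessing,
augmentation, training, evaluation — runnable and testable end to end on a
laptop without clinical data.

Mammographic abnormalities (masses, calcifications, architectural
distortion, asymmetry) are low-contrast, small, and class-imbalanced. The
pipeline addresses each point:

* **CLAHE** (contrast-limited adaptive histogram equalization) spreads the
  compressed intensity histograms of mammograms.
* **Seam carving** removes the 8-connected pixel path of minimal cumulative
  gradient energy, `g(i,j) = |∂I/∂x| + |∂I/∂y|`, shrinking images while
  preserving informative structure.
* **2D Haar wavelet decomposition** (orthonormal, perfect reconstruction,
  Parseval-exact) splits images into LL/LH/HL/HH subbands; the deepest
  low-pass band LL feeds the classifier.
* The **wCNN** replaces ReLU with the cosine-Gaussian wavelet activation

  ψ(x) = cos(βx)·e^(−x²/2),  ψ′(x) = −β·sin(βx)·e^(−x²/2) − x·cos(βx)·e^(−x²/2)

  (default β = 0.5), in an otherwise conventional architecture: six blocks
  of three 3×3 convolutions + pooling, L2 2e−4, dropout 0.5, softmax head,
  299×299 grayscale input. A matched ReLU CNN with identical topology and
  parameter count is the baseline.
* A **DCGAN** (100-dim noise, stride-2 fractionally strided 5×5
  convolution ladder, tanh output; mirrored sigmoid discriminator)
  synthesizes under-represented classes.
* **Metrics**: accuracy, specificity, sensitivity, precision, F1 and recall
  over per-class one-vs-rest confusion counts, with explicit micro/macro
  averaging.
* A **seeded synthetic mammogram generator** produces labeled images with
  class-specific structure (blobs for masses, speckle clusters for
  calcifications, radial lines for architectural distortion, lateral ramps
  for asymmetry) so every stage is testable reproducibly.

The neural-network engine is the package's own compact CPU implementation
(C++ im2col/BLAS convolution kernels, R layers and optimizers); seeded runs
are bit-reproducible.

## Worked example

Train a compact wCNN on the synthetic two-class task (normals vs masses,
200 training / 100 validation images at 64×64):

```r
library(mammowave)

psi(0)    # 1
psi(pi)   # 4.403758e-19  (cos(pi/2) = 0 at beta = 0.5)
psi(1)    # 0.5322807     (cos(0.5) * exp(-0.5))

train <- generate_dataset(synthetic_spec(image_size = 64,
           class_counts = c(N = 100, M = 100), seed = 11))
val   <- generate_dataset(synthetic_spec(image_size = 64,
           class_counts = c(N = 50, M = 50), seed = 12))
val$split <- "val"
train$class_set <- val$class_set <- c("N", "M")

# preprocessing chain on one sample: CLAHE -> carve 5% -> depth-2 low pass
ll <- wavelet_features(preprocess_image(train$samples[[1]]$image), depth = 2)
dim(ll)   # 16 16

spec <- network_spec(input_size = 64, n_blocks = 2, convs_per_block = 1,
                     filters_per_block = c(16L, 32L), activation = "wavelet",
                     n_classes = 2, pooling = "avg")
set.seed(42)
model <- build_wcnn(spec)
history <- train_model(model, train, val,
                       train_config(learning_rate = 3e-4, batch_size = 8,
                                    epochs = 5, seed = 42))
history
#>   epoch      loss   acc   val_loss val_acc
#> 1     1 0.8322366 0.595 0.30389618    0.99
#> 2     2 0.3202686 0.890 0.14612682    1.00
#> 3     3 0.1871715 0.945 0.16466428    0.95
#> 4     4 0.1403064 0.985 0.07164077    1.00
#> 5     5 0.1087943 0.980 0.06161925    1.00

pred <- predict_classes(model, val)
metrics_report(vapply(val$samples, `[[`, "", "label"), pred$labels,
               val$class_set)
#> <metrics_report> (micro averaging)
#>   accuracy     1.0000
#>   specificity  1.0000
#>   precision    1.0000
#>   f1           1.0000
#>   recall       1.0000
#>   sensitivity  1.0000
```

The training loss falls monotonically while validation accuracy reaches
1.00 — the separable synthetic task is learned through the wavelet
activation. `run_pipeline(pipeline_config(...))` chains every stage
(synthesis → optional GAN augmentation → CLAHE → carving → wavelet features
→ training → evaluation) and writes a JSON manifest, history and metrics
CSVs; `inst/cli/mammowave` exposes the same stages as shell subcommands
(`synth`, `preprocess`, `decompose`, `train`, `gan-train`, `gan-sample`,
`pipeline`, `compare`).

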