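# adffnet

Binary segmentation of skin lesions in dermoscopy images with an
attention-based dual-path feature-fusion network, implemented natively in R
(compiled C++ tensor kernels, no external deep-learning framework). The
package is aimed at medical-image-analysis researchers who want a fully
inspectable, CPU-scale reference implementation of this family of
segmentation models: every block, the loss, the optimiser and the data
generator are ordinary R objects that can be probed, ablated and tested.

## The model

A VGG16-style five-block encoder (3x3 convolutions + ReLU, 2x2 max
pooling; channels `base, 2b, 4b, 8b, 8b` at scales S/2 .. S/32) feeds two
paths:

* **Spatial path — boundary refinement (BR).** With C2' the upsampled
  second-block map,

  X₁ = Conv_{k×1}(Conv_{1×k}(C2')), X₂ = Conv_{1×k}(Conv_{k×1}(C2')),
  A = σ(X₁ + X₂), X = A · C1,

  a single-channel strip-convolution spatial attention (k = 3) that gates
  the shallow, boundary-rich features.
* **Context path — multi-scale context extraction + feature selection.**
  Blocks 3–5 each pass through parallel 1×1 and 3×3 dilated convolutions
  (rates 3/5/7, each C/4 channels, concatenated). The aligned branch maps
  U', U'', U''' are summed to Ū; GAP and two fully connected layers feed a
  per-channel three-way softmax giving convex weights with
  αᵢ + βᵢ + γᵢ = 1, and Vᵢ = αᵢU' + βᵢU'' + γᵢU'''.
* **Dual-path fusion.** x = ReLU(BN(Conv(Concat(H, L)))),
  a = σ(ReLU(GAP(x))), M = a·L + H, followed by a 1×1 conv + sigmoid head
  upsampled to input resolution.

Training minimises the multivariate loss

L = λ₁·L_E + λ₂·L_BCE + λ₃·L_Dice,  (λ = 0.2, 1, 1)

where L_E is a boundary-oriented cross-entropy on Laplacian edge maps
(3×3 kernel, centre 8; E = ReLU(tanh(∇T))) weighted by
W = ΣE_t / ΣT ∈ [0,1], L_BCE is mean binary cross-entropy, and L_Dice is a
two-sided smoothed Dice loss (ε = 1). Optimisation is Adam (lr 1e-4,
β₁ 0.9, β₂ 0.999, decay 1e-4), batch 8, up to 60 epochs with early
stopping at patience 10. Evaluation reports accuracy, sensitivity,
specificity, precision, F1 and Jaccard similarity (the primary criterion)
plus ROC/AUC, all at pixel level.

A seeded procedural generator produces dermoscopy-like images (star-convex
lesions, blurred boundaries, uneven colour, low contrast, hair and bubble
artefacts) so the whole pipeline builds and tests without any external
dataset or download.

## Worked example

Train a reduced-width model on synthetic easy images and evaluate:

```r
library(adffnet)
samples <- generateSamples(40, 64, "easy", seed = 7)
data <- list(train = samples[1:28], val = samples[29:32],
             test = samples[33:40])
model <- assembleADFFNet(modelConfig(input_size = 64, base_channels = 8,
                                     seed = 1))
fit <- trainModel(model, data,
                  trainConfig(batch_size = 8, max_epochs = 12,
                              patience = 5, seed = 1))
tail(fit$history[, c("epoch", "train_total", "val_loss", "val_dice")], 3)
#>    epoch train_total  val_loss  val_dice
#> 10    10   0.3672318 0.3147188 0.7031845
#> 11    11   0.3158176 0.2794798 0.7278836
#> 12    12   0.2958051 0.2622375 0.7490270

ev <- evaluateModel(fit$model, data$test)
round(ev$metrics, 3)
#>    ac    se    sp    pc    f1    js
#> 0.938 0.745 0.970 0.804 0.774 0.631
round(ev$auc, 3)
#> [1] 0.978
```

Twelve epochs on 28 tiny images already reach JS 0.63 / AUC 0.98 on held-out
synthetic data: the multivariate loss falls epoch over epoch, the
validation Dice rises, and the pooled test metrics show the usual pattern
of high specificity with sensitivity still climbing. Longer training (see
`trainConfig()` defaults) takes these numbers well above 0.85 JS on easy
synthetic data.

`runAblation()` trains one model per module combination (BR / MCIE / FS /
DFF subsets, bypassing the rest) and reports test JS per row;
`generateDataset()` + the CLI (`inst/cli/adffnet.R synthesize|train|
predict|evaluate|ablate --config run.yaml`) drive the same pipeline from
the shell with a reproducibility manifest per run.

## Layout

- `R/` — autodiff tape, compiled-kernel wrappers, blocks, model assembly,
  losses, metrics, generator, training loop, IO, CLI dispatch
- `src/` — conv2d/maxpool/bilinear kernels with adjoints (Rcpp +
  RcppArmadillo)
- `tests/testthat/` — oracle-driven unit and acceptance tests
- `vignettes/adffnet-methods.Rmd` — the methods vignette: model,
  assumptions, numerical choices, limitations
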