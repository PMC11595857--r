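# esaresnet

Crop pest and disease recognition from leaf photographs is a 61-class
image-classification problem where the models accurate enough to be useful
(deep residual networks) are usually too heavy for the mobile and edge
devices used in the field. `esaresnet` implements **ESA-ResNet34**, a
lightweight classifier that keeps the ResNet34 skeleton but

1. inserts an **effective spatial attention (ESA)** gate into every
   residual block — a global pooling to a `1×1×C` descriptor, a tiny
   cross-channel 1-d convolution, and a sigmoid, producing a per-channel
   gate `g ∈ (0,1)^C` that rescales the block output without any channel
   dimensionality reduction (despite the name, the mechanism gates
   channels); and
2. replaces every stage `3×3` convolution with a **depthwise separable
   pair** (`3×3` depthwise carrying the stride, then `1×1` pointwise),
   cutting a `k×k` convolution's parameters and multiply–accumulates by a
   factor of roughly `1/C_out + 1/k²`.

Training uses softmax cross-entropy
`L = −(1/N) Σᵢ Σ_c y_{ic} log p_{ic}`, Adam (lr `0.001`, weight decay
`1e-4`), batch size 128, a reduce-on-plateau schedule (factor `0.5`),
early stopping after 50 stagnant epochs, and seed 2022 — all explicit
fields of `training_config()`.

Because no deep-learning framework exists for R in the target
environment, the package ships its own small tensor engine: im2col
convolutions in C++ (Rcpp/RcppArmadillo), hand-derived backward passes
for every layer (verified against central differences to ~1e-9), batch
norm, max/global pooling, dropout, and Adam. Architectures are described
as declarative layer graphs, so the complexity profiler
(`count_parameters()`, `count_macs()`, `complexity_report()`) audits the
proposed model and the reference zoo (AlexNet, VGG16, DenseNet121,
ResNet-18/34/50/101/152, MobileNetV2) without instantiating weights.

## Worked example: the complexity audit

```r
library(esaresnet)
cmd_profile("ours", num_classes = 61)
#> Complexity report for 'esa_resnet34' at input (1, 3, 224, 224)
#>   parameters: 2,636,669 (2.64 M)
#>   MACs:       569,510,592 (0.57 G, printed as GFlops in the published table)
```

2.64 M parameters and 0.57 G MACs, against 21.32 M / 3.68 G for the
standard ResNet34 it replaces. The side-by-side audit of the full model
zoo (the published table is reproduced to two decimals in every row;
the proposed-model row corresponds to the 1000-class default head — see
the vignette):

```r
cmd_profile(paper_table = TRUE)
#>        model params_m params_m_published gflops gflops_published status
#>        vgg16   134.51             134.51  15.48            15.48   PASS
#>      alexnet    57.25              57.25   0.71             0.71   PASS
#>  densenet121     7.02               7.02   2.90             2.90   PASS
#>     resnet18    11.21              11.21   1.82             1.82   PASS
#>     resnet34    21.32              21.32   3.68             3.68   PASS
#>     resnet50    23.63              23.63   4.13             4.13   PASS
#>    resnet101    42.63              42.63   7.86             7.86   PASS
#>    resnet152    58.27              58.27  11.60            11.60   PASS
#>         ours     3.12               3.12   0.57             0.57   PASS

reduction_percent(21.32, 3.12)  #> 85.37   (parameters)
reduction_percent(3.68, 0.57)   #> 84.51   (MACs)
```

## Worked example: training on synthetic data

Real data (the 50,000-image crop disease set, read via
`read_annotations()` / `load_image_dataset()`) is never required: the
seeded generator fabricates class-separable lesion images so the whole
pipeline runs at desk scale.

```r
ds  <- generate_synthetic_dataset(synthetic_dataset_spec(
         num_classes = 5, samples_per_class = 40, image_size = 32))
val <- seq(1, 200, by = 5)
arch <- architecture_spec(stage_block_counts = c(1, 1, 1, 1),
                          stage_widths = c(8, 16, 32, 64),
                          num_classes = 5, dropout_rate = 0)
cfg <- training_config(batch_size = 32, max_epochs = 15,
                       early_stop_patience = 10, seed = 2022)
fit <- train_model(build_esa_resnet34(arch),
                   list(x = ds$x[-val, , , ], y = ds$y[-val]),
                   list(x = ds$x[ val, , , ], y = ds$y[ val]), cfg)
tail(fit$history, 3)
#>  epoch train_loss train_accuracy validation_accuracy
#>     13  0.5013815        0.96875               0.825
#>     14  0.3987375        0.98750               0.825
#>     15  0.3407641        0.98750               0.850

ev <- evaluate_model(fit$model, list(x = ds$x[val, , , ], y = ds$y[val]))
classification_metrics(confusion_matrix(ds$y[val], ev$predictions, 5))
#> Evaluation report (macro averaging, n = 40)
#>   accuracy  0.8500
#>   precision 0.8457
#>   recall    0.8500
#>   F1        0.8444
```

The train accuracy (98.8%) versus held-out accuracy (85.0%) gap is the
expected overfit on 160 tiny training images; the run is deterministic —
repeating it with the same seed reproduces the history bit for bit.

## Command line

A thin wrapper is installed at `inst/cli/esaresnet`:

```sh
Rscript inst/cli/esaresnet synth   --out data/demo --classes 5 --per-class 40
Rscript inst/cli/esaresnet train   --config run.json --out runs/demo
Rscript inst/cli/esaresnet profile --model ours --classes 61 --out reports/ours
Rscript inst/cli/esaresnet profile --paper-table
```

Run configs are JSON; every run directory receives the echoed config,
per-epoch history (CSV + JSON), the best checkpoint with a JSON
architecture sidecar, the evaluation report, and a log.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

rebuilds the proposed architecture under the frozen calibration,
recounts its parameters (both by enumerating the instantiated arrays and
from the per-layer closed forms, which must agree) and its
multiply–accumulates at input `(1, 3, 224, 224)`, and writes the two
figures (millions of parameters; billions of MACs) as JSON.
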