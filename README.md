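# dhcnn — dilated heterogeneous convolutions for cell detection and segmentation

`dhcnn` is an R package for building and analysing **DHConv** (dilation
heterogeneous convolution) layers and the cell instance-segmentation networks
assembled from them. It targets quantitative microscopy: detecting and
segmenting individual cells in phase-contrast or fluorescence images, under
tight compute budgets where a full-width Mask R-CNN is too expensive.

## The operator

A standard convolution layer applies `N` filters of shape `K × K × M` to an
`M`-channel feature map. A DHConv filter keeps only a fraction `P` of its `M`
per-channel kernels at the full size — and dilates those by rate `r` — while
the remaining `(1 − P)·M` kernels shrink to pointwise `1 × 1`:

* Effective kernel extent: `K_D = (K − 1)·r + 1` per side, so `r` widens the
  receptive field with no extra weights.
* Cost of the layer (multiply–accumulates, `D_w × D_h` output):
  `FL_hc = (D_w·D_h·N·K²·C)·P + (D_w·D_h·C)·(N − N·P)`
* Cost ratio against standard convolution: `R_hc = P + (1 − P)/K²`.
  At `P = 1/4, K = 3` the ratio is exactly **1/3** — a two-thirds saving —
  while the dilated survivors (`r = 2`) see a `5 × 5` footprint instead of
  `3 × 3`.

The package implements this operator with an exact dense masked-kernel oracle
(used to verify both the numerics and the FLOPs accounting), the analytic
cost model, conversion of ResNet-style backbones (all sixteen 3×3 bottleneck
convolutions of ResNet-50 under the default policy), a compact trainable
cell detector built from DHConv layers, the instance-segmentation metric
suite (precision, recall, Dice, AP, and panoptic quality `PQ = DQ × SQ`),
COCO-style annotation I/O with exact polygon↔mask round-trips, and a seeded
synthetic microscopy scene generator so everything runs fully offline.

## Worked example

```r
library(dhcnn)

flops_ratio(1/4, 3)
#> [1] 0.3333333

flops_het(4, 4, 2, 3, 8, 1/4)
#> Heterogeneous convolution layer cost (multiply-accumulates)
#>   standard     : 2,304
#>   large-kernel : 576
#>   pointwise    : 192
#>   heterogeneous: 768  (ratio 0.333333)

cv <- convert_backbone(resnet50_backbone(), conversion_policy())
nrow(cv$report)                                     # 16 layers converted
backbone_param_count(resnet50_backbone())           # 23481472
backbone_param_count(cv$backbone)                   # 15936640
count_model_flops(cv$backbone, c(224L, 224L))$total /
  count_model_flops(resnet50_backbone(), c(224L, 224L))$total
#> [1] 0.7046422   (whole backbone; each replaced 3x3 conv costs exactly 1/3)
```

The 768 multiply–accumulates above are also what the dense oracle counts when
it materializes the masked kernels and convolves them — the analytic model
and the empirical count agree on every tested configuration.

End to end, on seeded synthetic scenes (bright, well-separated cells,
128×128 px):

```r
easy <- function(seed) scene_params(image_size = 128L, count_range = c(4L, 7L),
  radius_range = c(8, 16), deform = 0.05, overlap = 0, fg_intensity = 200,
  bg_intensity = 30, noise_sd = 5, blur_sigma = 1, seed = seed)
cfg   <- train_config(initial_lr = 0.1, max_epochs = 3L, seed = 1L)
model <- build_mask_rdhcnn(policy = conversion_policy(), config = cfg)
model <- train(model, scenes_to_dataset(lapply(1:12, function(s)
                 generate_scene(easy(s)))), cfg)
round(model$loss_history, 4)
#> [1] 1.1995 0.6545 0.3473

test_scene <- generate_scene(easy(101))
evaluate_detections(predict(model, test_scene$image), test_scene$instances)
#> Instance segmentation metrics (IoU threshold 0.50)
#>   TP 4  FP 0  FN 0
#>   precision 1.0000
#>   recall    1.0000
#>   dice      1.0000
#>   ap        1.0000
#>   dq        1.0000
#>   sq        0.8942
#>   pq        0.8942
```

All four cells on the held-out scene are found (detection quality 1); the
segmentation quality 0.894 is the mean IoU of the matched masks, giving
panoptic quality 0.894.

A command-line wrapper with `cost`, `synth`, `train`, `eval` and `predict`
subcommands is shipped as `inst/cli/dhcnn.R`; see `?dhcnn_cli`.

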