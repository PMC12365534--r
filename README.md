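# milgrade

Weakly supervised ordinal grading of H&E-stained gastric biopsy
whole-slide images (WSIs) with attention-based multiple-instance
learning (MIL).

Histological assessment of chronic gastritis grades four features of a
biopsy — inflammation, activity, glandular atrophy and intestinal
metaplasia — on the updated Sydney system's ordinal scale
(normal/mild/moderate/severe; the ternary tasks drop "normal"). The
grade is a slide-level property driven by the fraction of tissue
showing the alteration, while the slide itself is gigapixel-sized and
pixel-level annotation is impractical at scale. `milgrade` implements
the weakly supervised route for pathologists' workflows: slide-level
labels only, patch-level interpretation for free via attention.

The package covers the full pipeline: tissue segmentation and
non-overlapping 256×256 tiling, Macenko stain normalization, a
pluggable patch-feature backbone contract (1,024-d ResNet50-style
features), the gated attention-MIL network, an imbalance-aware
(gradient-rebalanced) training objective for long-tailed grade
distributions, stratified 5-fold cross-validation, antrum→corpus
fine-tuning, whole-slide attention heatmaps over *all* foreground
patches, and the evaluation stack of ordinal grading studies
(macro-AUC, clinical utility index, quadratic weighted kappa,
McNemar's, DeLong's and χ² tests). A synthetic cohort generator with
instance-level ground truth makes every stage testable offline.

## The model

For a slide represented as a bag of patch features
$x_1,\dots,x_M \in \mathbb{R}^{1024}$:

$$h_i = \mathrm{ReLU}(W_1^\top P^\top x_i + b_1), \qquad
  a_i = \mathrm{softmax}_i\!\left(w^\top\!\left[\tanh(V^\top h_i)
  \odot \sigma(U^\top h_i)\right] + c\right),$$

$$z = \sum_{i=1}^M a_i h_i, \qquad
  \hat{p} = \mathrm{softmax}(W_2^\top \mathrm{ReLU}(W_c^\top z) + b_2),$$

with $P$ a frozen data-driven compression onto the leading principal
axes of the pooled training instances (see the methods vignette for why
this matters at cohort scale). Training minimizes a rebalanced
cross-entropy in which each slide is weighted by the inverse
exponential moving average of its grade's gradient magnitude,
renormalized to mean 1 per batch — equal to plain cross-entropy when
classes are equally hard, and up-weighting rare "severe" grades when
they are not. The attention weights $a_i$ are rendered back onto the
slide as a pale-blue→dark-red heatmap.

## Worked example

Simulate a small graded cohort (bags of patch-feature vectors whose
grade is determined by the fraction of lesion instances), train, and
inspect:

```r
library(milgrade)

scheme <- grading_scheme(3)                  # task 3: atrophy, K = 4
spec   <- cohort_spec(n_features = 256, bag_size = c(48, 96))
coh    <- generate_cohort(spec, 240, seed = 1)

fit <- mil_grader(coh$bags, coh$labels$grade, scheme,
                  config = mil_config(input_dim = 256, n_classes = 4,
                                      seed = 1),
                  train  = train_config(epochs = 10, seed = 1))
fit
#> Attention-MIL grader: task 3 (atrophy), 4 classes
#>   256 -> 512 -> (attn 256, gated) -> 128 -> 4, dropout 0.25
#>   trained on 240 bags, 10 epochs, loss 'rebalanced', final loss 0.5890

test <- generate_cohort(spec, 80, seed = 2)
pred <- predict(fit, test$bags)
head(pred, 3)
#>      slide_id   p_0    p_1      p_2      p_3 rank  class
#> 1 synth_00001 0.456 0.5068 0.032347 5.26e-03    1   mild
#> 2 synth_00002 0.918 0.0813 0.000347 7.17e-05    0 normal
#> 3 synth_00003 0.855 0.1432 0.001122 2.10e-04    0 normal

report <- compute_report(test$labels$grade,
                         predict(fit, test$bags, type = "prob"), scheme)
report
#> Evaluation report: task 3 (atrophy), n = 80
#>   ACC 0.650 | macro-AUC 0.893 | macro-F1 0.670 | QWK 0.737
#>   macro precision 0.672 | recall 0.535 | NPV 0.883 | CUI+ 0.468 (poor) | CUI- 0.768 (good)
#>   confusion (rows = truth):
#>           predicted
#> truth      normal mild moderate severe
#>   normal       23    0        0      0
#>   mild         16   18        0      0
#>   moderate      0    7       11      0
#>   severe        0    1        4      0
```

The first line of the report is the accuracy, macro one-vs-rest AUC,
macro F1 and the quadratic weighted kappa of predicted against true
grades; the clinical utility indices are banded on the standard
excellent/good/satisfactory/poor cut points. This desk-sized demo
(240 training slides, 256-d features, small bags) runs in about a
minute; at the package's reference experiment scale — 800 slides,
1,024-d features, bags of 64-256 instances, 5-fold cross-validation
(`label_recovery_experiment()`) — the same model reaches a fold-mean
macro-AUC around 0.96 and accuracy around 0.80, close to the analytic
ceiling of the generator (see the methods vignette). Attention maps
come from the same fitted object:

```r
pa <- predict(fit, test$bags[[1]], type = "attention")
pa$attention[[1]]
#> attention_map 'synth_00001': 51 instances, sum 1.000000, max 0.0328
```

For slide images, the preprocessing front end feeds the same model:

```r
toy   <- generate_toy_wsi(1024, 768, coverage = 0.5, lesion_ratio = 0.2)
slide <- slide_image(toy$image, slide_id = "toy", magnification = 40)
mask  <- segment_tissue(slide)
grid  <- tile_foreground(slide, mask, magnification = 40)
bag   <- extract_features(grid, slide, synthetic_backbone(1024))
```

A thin command-line front end (`inst/exec/milgrade`) wires the stages
(`simulate`, `tile`, `extract`, `train`, `infer`, `heatmap`,
`evaluate`, `compare`) with run manifests; see `?mil_cli`.

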