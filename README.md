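# ktopmil

Top-K attention multiple-instance learning (MIL) for whole-slide-image
(WSI) subtype classification, with a deterministic synthetic multi-center
cohort generator so the entire pipeline runs and is tested without any
pathology dataset.

## The problem and who this is for

Ovarian carcinoma is diagnosed from gigapixel H&E whole-slide images into
five histotypes — CC, MC, LGSC, HGSC, EC — but the diagnosis is attached
to the *slide*, not to any region of it. The standard computational
treatment is MIL: tile the slide, keep a bag of N tiles sharing the
slide label, embed each tile, and learn a permutation-invariant
aggregator plus classifier on bag level. This package is for researchers
who want a complete, tested, CPU-scale implementation of that pipeline —
the tiling arithmetic, the filtering and resampling, the aggregation
operators, the training recipe, the evaluation metrics, and the
leave-one-domain-out generalization protocol — with every stage
verifiable on synthetic multi-center cohorts.

## The model

For bag $i$ with instance features $F_{i,j} = M(X_{i,j};\Theta) \in
\mathbb{R}^d$, the bag representation is $B_i = A(\{F_{i,j}\}_{j=1}^n)$
and the prediction is $\hat y_i = \mathrm{softmax}_\tau(W B_i + b)$,
trained with mean bag-level cross-entropy. Four aggregators $A$ are
implemented:

| aggregator | definition |
|---|---|
| mean | $B = \frac1n\sum_j F_j$ |
| max | $B_k = \max_j F_{jk}$ (element-wise) |
| attention | $B = \sum_j \alpha_j F_j$, $\alpha = \mathrm{softmax}(s/\tau_a)$, $s_j = w^\top\tanh(VF_j + b_1) + b_2$ |
| **top-K attention** | rank by $s_j$, aggregate the top $K$ with renormalized softmax weights (or uniformly) |

plus a prediction-level max baseline (per-class maximum over instance
logits). $\mathrm{softmax}_\tau(z)_i = e^{z_i/\tau}/\sum_j e^{z_j/\tau}$
is the temperature-scaled softmax used for calibration sweeps. At
$K = n$, top-K pooling reduces exactly to attention pooling
(renormalized) or mean pooling (uniform) — asserted in the tests.

The rationale for top-K: in histopathology only a few tiles of a bag may
contain tumor, so averaging over all instances dilutes the signal while a
learned scorer can concentrate the bag representation on the informative
few. The package's headline experiment plants exactly this structure in
synthetic slides and checks that top-K pooling recovers it at least as
well as mean pooling.

## Worked example

Tiling arithmetic for a 16,000 × 16,000 slide into non-overlapping
512-px tiles:

```r
library(ktopmil)
tile_grid(16000, 16000, 512)
#> tile_grid: 16000x16000 image, 512x512 tiles, stride (512, 512): 31 x 31 = 961 tiles
```

A complete synthetic run — generate a 30-slide two-domain cohort, tile,
filter, downscale, extract frozen features, train a top-K attention probe
and evaluate:

```r
cfb <- cohort_feature_bags(n_per_class = 6, n_domains = 2, size_range = 512,
                           tile_size = 128, downscale = 64, bag_size = 16,
                           seed = 42, informative_fraction = 0.15,
                           artifact_fraction = 0.05, cell = 128,
                           informative_cell = 128)
split <- make_split(cfb$manifest, ratio = c(0.7, 0.3), stratify = TRUE, seed = 1)
bags  <- standardize_bags(cfb$bags, train_ids = split$train)$bags

model <- mil_model(d = 64, aggregator = aggregator_config("ktop", k = 3),
                   m = 32, seed = 1)
fit <- train_mil(bags, model,
                 train_config(learning_rate = 0.03, epochs = 12, batch_size = 4,
                              schedule = "constant", warmup_epochs = 3, seed = 2),
                 train_ids = split$train)

ids <- vapply(bags, `[[`, character(1), "wsi_id")
evaluate_mil(fit$model, bags[ids %in% split$test])$report
#> MIL evaluation report (averaging: weighted )
#>          accuracy         precision            recall                f1
#>            0.7778            0.8148            0.7778            0.7704
#> balanced_accuracy      cohens_kappa             auroc             auprc
#>            0.8000            0.7188            0.9857            0.9667
```

Accuracy here is the fraction of held-out slides assigned the correct
histotype (0.78 on 9 test slides vs. a 0.2 chance floor); AUROC/AUPRC are
macro one-vs-rest areas from the calibrated probabilities. The trained
model is interpretable at instance level — `forward_bag()` returns which
tiles the scorer selected:

```r
fb <- forward_bag(fit$model, bags[[1]]$features)
fb$pred       # "CC"
fb$selected   # e.g. 6 7 14 — the three top-scored tiles of the bag
```

Domain-generalization bookkeeping from per-domain accuracies (in %):

```r
res <- data.frame(domain_id = 1:4, accuracy = c(85.2, 83.9, 84.6, 85.1))
domain_gaps(res)$max_gap                          # 1.3
delta_table(res, source_domain = 1, best_accuracy = 95.72)
#>   domain_id accuracy delta1 delta2    consistency
#> 1         1     85.2     NA  10.52    (-, medium)
#> 2         2     83.9    1.3  11.82 (high, medium)
#> 3         3     84.6    0.6  11.12 (high, medium)
#> 4         4     85.1    0.1  10.62 (high, medium)
```

A thin CLI wraps the same functions
(`inst/cli/ktopmil synth|tile|domain-table ...`).

See `vignettes/ktopmil-methods.Rmd` for the model assumptions, the
synthetic-generator design, the top-K cold-start pathology and its
warm-up remedy, and all numerical choices.

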