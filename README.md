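# bmkfo

Episodic meta-learning for few-shot binary image segmentation in R:
a **bidirectional meta-Kronecker factored optimizer (BM-KFO)** that learns a
gradient-preconditioning optimizer alongside the model, and an
**average-Hausdorff-distance (AHD) loss** that scores and trains
segmentations by boundary-aware set distance. The package is aimed at
researchers studying optimization-based meta-learning (MAML-family methods)
and shape-aware segmentation losses, and ships a seeded generator of
organ-like synthetic episodes so every experiment is reproducible on one
CPU.

## The method in brief

A 1-way 1-shot episode is a labeled support pair and a query image of the
same class. MAML adapts parameters on the support loss,
`θ' = θ − α ∇L_s(θ)`, and updates the initialization with the query-loss
gradient, `θ ← θ − β ∇_θ L_q(θ')` (second-order, through the inner step).

BM-KFO augments this with a learned optimizer `U_ξ` applied to gradients
before they are used. For an `m × n` gradient matrix `G`, `U_ξ(G) = L G R`
with square factors `L (m×m)`, `R (n×n)` — the action of the Kronecker
matrix `Rᵀ ⊗ L` on `vec(G)` at `m² + n²` parameters instead of `(mn)²`.
The identity factors recover plain gradient descent exactly. One step runs

1. meta-train phase (support): `θ' ← θ − β ∂L_s/∂θ`, `ξ' ← ξ − β ∂L_s/∂ξ`;
2. meta-test phase (support): `θ* ← θ' − α U_ξ'(∇L_s(θ'))`;
3. outer update (query): `L_q(θ*)` differentiated w.r.t. the outer `(θ, ξ)`.

The AHD between point sets X, Y is
`(mean_x min_y d(x,y) + mean_y min_x d(x,y)) / 2` under Manhattan,
Euclidean, or Chebyshev (default) grid metrics — robust to outliers, unlike
the classical max–min Hausdorff distance, and exactly computed here along
with exact distance transforms. Training uses a differentiable surrogate
built on those transforms that coincides with the exact AHD on binary
predictions; the full objective is cross-entropy plus AHD.

See the methods vignette (`vignettes/bmkfo-methods.Rmd`) for the design
decisions, numerical choices, and what the synthetic benchmark does and
does not demonstrate.

## Worked example

```r
library(bmkfo)

plan <- split_plan(train_classes = c(1, 2, 3), test_classes = 4,
                   mode = "setting2")           # test class never seen in training
ds <- make_dataset(plan, n_train = 200, n_test = 50, seed = 42)

spec <- seg_model_spec()                        # tiny conditioned CNN (954 params)
hy <- hyper_config(alpha = 0.1, beta = 0.05, inner_steps = 1,
                   second_order = FALSE)

st <- train_meta(spec, ds$train, hyper = hy, method = "bmkfo", seed = 42)
print(st)
#> <meta_state> iter 200 | 954 model params | 11361 optimizer params |
#>   alpha 0.1 beta 0.05 | xi deviation from identity 0.2582

report <- evaluate_meta(st, ds$test, inner_steps = 5)
format_metric_table(report)
#> # A tibble: 1 x 5
#>   `Dice score` Precision Recall Mean  `AHD (px)`
#> 1 98.17        99.05     97.34  98.19 0.02
```

After 200 meta-iterations, five adaptation steps on a single labeled
example of the *held-out* class segment its queries at Dice 98.2 and mean
exact AHD 0.02 px; the same five steps from a random initialization score
Dice 0 (the network predicts background everywhere) — the fast-adaptation
gap the meta-optimizer exists to produce. The `xi deviation` line shows the
learned optimizer has moved off its identity (gradient-descent)
initialization.

A shell entry point wrapping the same functions is installed at
`inst/cli/bmkfo.R`:

```sh
Rscript inst/cli/bmkfo.R simulate --seed 1 --out runs/data
Rscript inst/cli/bmkfo.R train    --seed 1 --data runs/data --out runs/fit
Rscript inst/cli/bmkfo.R evaluate --checkpoint runs/fit/checkpoint.rds --out runs/eval
Rscript inst/cli/bmkfo.R verify
```

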