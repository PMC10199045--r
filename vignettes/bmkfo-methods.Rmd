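---
title: "Methods: bidirectional meta-Kronecker factored optimization and Hausdorff losses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidirectional meta-Kronecker factored optimization and Hausdorff losses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmkfo)
```

# The problem

In few-shot binary segmentation, a model must segment a new structure class
from a single labeled example (the *support*) and generalize to an unlabeled
image of the same class (the *query*). One support/query pair is an
*episode*. Optimization-based meta-learning treats each episode as a task:
an inner loop adapts the model to the support set, and an outer loop updates
the shared initialization so that a few inner steps suffice on unseen
classes.

This package implements two intertwined ideas at desk scale:

1. a **bidirectional meta-Kronecker factored optimizer (BM-KFO)** that
   learns, alongside the model parameters $\theta$, the parameters $\xi$ of
   a gradient-preconditioning optimizer $U_\xi$, and
2. an **average-Hausdorff-distance (AHD) loss** that scores predicted masks
   by boundary-aware set distance rather than pixelwise overlap alone.

Everything is exercised on a seeded generator of organ-like synthetic
episodes rather than on clinical images; the closing section spells out what
that does and does not demonstrate.

# The meta-optimizer

## MAML baseline

For a task with support loss $L_s$ and query loss $L_q$, one MAML iteration
computes the adapted parameters
$\theta' = \theta - \alpha \nabla L_s(\theta)$ (possibly several such steps)
and updates the initialization with
$\theta \leftarrow \theta - \beta \nabla_\theta L_q(\theta')$, where $\beta$
is the meta step size. The outer gradient is second-order: by the chain
rule, $\nabla_\theta L_q(\theta') = (I - \alpha H_s(\theta))\,
\nabla_{\theta'} L_q(\theta')$ with $H_s$ the support-loss Hessian.
`maml_outer_step()` implements this exactly (see *Numerical choices*), with
a first-order flag that drops the Hessian term.

## The learned optimizer $U_\xi$

The meta-optimizer transforms gradients before they are applied:
$\theta \mapsto \theta - \alpha\, U_\xi(\nabla L(\theta))$. Parameterizing a
dense linear map on $\mathrm{vec}(G)$ for an $m \times n$ gradient matrix
$G$ would cost $(mn)^2$ parameters; the Kronecker factorization
$W = R^\top \otimes L$ with $L \in \mathbb{R}^{m\times m}$,
$R \in \mathbb{R}^{n\times n}$ reduces this to $m^2 + n^2$ while keeping
three properties that matter here: the cost of applying it is one pair of
small matrix products ($U_\xi(G) = L\,G\,R$, never materializing $W$); it is
full-rank whenever $L$ and $R$ are; and the identity lies in its span, so
initializing $L = I_m$, $R = I_n$ recovers plain gradient descent exactly —
the optimizer can only improve on gradient descent by moving away from the
identity, and the package tests this recovery property to $10^{-10}$.

One factor pair is allocated per parameter tensor (a per-layer choice;
sharing across layers is also conceivable, but per-layer factors keep every
map square and small). Convolution kernels of shape
$(\mathrm{out}, \mathrm{in}, k, k)$ are stored flattened to
$(\mathrm{out}, \mathrm{in}\cdot k^2)$ matrices, biases as $m \times 1$
matrices, so every tensor is a matrix; tensors with fewer than 4 elements
get scalar ($1\times1$) factors acting as a single learned multiplier.
`vec` is column-major throughout, matching the identity
$(A \otimes B)\,\mathrm{vec}(X) = \mathrm{vec}(B X A^\top)$ used by the
test oracle.

## The bidirectional step

`bmkfo_step()` runs two phases per task before the outer update:

* **Meta-train phase** (support set): a gradient step on the model,
  $\theta' \leftarrow \theta - \beta\, \partial L_s/\partial\theta$, and a
  gradient step on the optimizer,
  $\xi' \leftarrow \xi - \beta\, \partial L_s/\partial\xi$.
* **Meta-test phase** (support set):
  $\theta^\star \leftarrow \theta' - \alpha\, U_{\xi'}(\nabla_{\theta'}
  L_s(\theta'))$ — the freshly updated optimizer is immediately exercised.
* **Outer update** (query set): $L_q(\theta^\star)$ is differentiated with
  respect to the outer $(\theta, \xi)$ and both are stepped with $\beta$,
  averaged over the task batch.

Three gaps in this recipe required decisions:

* **Which data feeds which phase.** Both inner phases consume the support
  set and only the outer update consumes the query set. In the one-shot
  setting there is no way to split the support set into inner train/test
  halves, which is precisely the motivation for running a second,
  test-like phase inside the inner loop; putting the query anywhere inside
  the inner loop would leak the labels the outer objective is supposed to
  hold out.
* **What $\partial L_s/\partial\xi$ means.** The raw support loss does not
  depend on $\xi$. The only well-defined dependence passes through a
  $U_\xi$-driven update, so the package differentiates the *probe*
  objective $L_s(\theta - \alpha\, U_\xi(\nabla L_s(\theta)))$ with respect
  to $\xi$. For $\theta^\star_t = \theta_t - \alpha L G R$ per tensor, the
  factor gradients have the closed forms
  $\partial L/\partial L = -\alpha\, \hat G (G R)^\top$ and
  $\partial L/\partial R = -\alpha\, (L G)^\top \hat G$, with $\hat G$ the
  loss gradient at the displaced point.
* **The step size of the meta-test arrow.** The update is taken as
  $\alpha\, U_{\xi'}(\cdot)$, so that with identity factors the meta-test
  phase is one standard gradient-descent step (the identity-span property
  would otherwise hold only at $\alpha = 1$).

The outer gradient in second-order mode backpropagates exactly through both
phases of the $\theta$ path (two Hessian-vector products) and through
$\xi'$ inside the meta-test update; the Jacobian of the meta-train $\xi$
update itself is truncated to the identity. The truncated terms are second
derivatives of the probe objective multiplied by an extra factor of
$\beta$ — with the reference schedule ($\beta \le 10^{-3}$, decaying) they
are an order of magnitude below everything retained. With $\xi$ frozen at
the identity the truncation is exactly zero, which is why the package can
test that a frozen-$\xi$ bidirectional trajectory coincides with a
two-inner-step MAML trajectory to $10^{-8}$.

With a single scalar parameter and quadratic task losses of curvature $c$,
the optimal preconditioned step is $\alpha\,\xi_{\mathrm{eff}} = 1/c$; the
test suite checks that 300 bidirectional steps move
$\xi_{\mathrm{eff}} = l\cdot r$ decisively toward $1/(\alpha c)$ from its
identity start, i.e. the optimizer actually learns step-size structure that
plain MAML cannot represent.

## Hyperparameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.01 | inner/adaptation step size |
| `beta` | 0.001 | meta step size (reference schedule) |
| `lr_decay`, `decay_every` | 0.98, 1000 | stepping decay of `beta` |
| `inner_steps` | 1 | adaptation steps per phase |
| `tasks_per_meta_batch` | 1 | tasks averaged per outer update |
| `second_order` | `TRUE` | exact outer gradients vs first-order |
| `clip` | `Inf` | global-norm bound on outer gradients |

The 0.001 / 0.98-per-1000-iterations schedule is the reference
configuration for long runs (it anneals meaningfully only over tens of
thousands of iterations). The desk-scale experiments in the tests and the
acceptance script run 200 outer iterations on a tiny CNN and instead use
`alpha = 0.1`, `beta = 0.05` with first-order outer gradients — ordinary
SGD rates for a small network on unit-scaled inputs, chosen once for the
200-iteration budget. First-order mode is also the right match for a ReLU
network, whose Hessian-vector products are only piecewise smooth.

# The Hausdorff machinery

## Exact set distances

For point sets $X, Y$ on the pixel grid, the directed Hausdorff distance is
$\max_{x\in X}\min_{y\in Y} d(x,y)$; the symmetric form takes the maximum
of both directions; and the average Hausdorff distance is

$$\mathrm{AHD}(X,Y) = \tfrac12\Big(\tfrac{1}{|X|}\sum_{x\in X}\min_{y\in Y}
d(x,y) + \tfrac{1}{|Y|}\sum_{y\in Y}\min_{x\in X} d(x,y)\Big),$$

with $1/|X|$, $1/|Y|$ the set cardinalities. One outlier among $n$ points
moves the symmetric Hausdorff distance to its full distance $d$ but the
average form by only about $d/(2n)$ — the robustness that makes the average
form usable as a training signal. Three grid metrics are supported —
Manhattan ($L_1$), Euclidean ($L_2$), Chebyshev ($L_\infty$) — with
Chebyshev the default, since it measures king-move distance uniformly in
all grid directions; the pointwise ordering
$d_{\mathrm{cheb}} \le d_{\mathrm{eucl}} \le d_{\mathrm{manh}}$ carries
over to all derived quantities. Pixel spacing is unit and isotropic; all
distances are in pixels.

Masks can be reduced to point sets either as all foreground pixels
(default) or as the 4-neighbor boundary. Foreground mode is the default
because it makes the degenerate full-image mask (empty boundary) a
non-issue; both modes are available because either reading is consistent
with computing set distance "from both perspectives" between prediction
and truth.

## The differentiable surrogate

The exact AHD of a thresholded probability map is piecewise constant in the
probabilities, so it cannot train a network. The package's surrogate
replaces the two directed means with distance-transform inner products:

$$\mathcal{L}_{\mathrm{AHD}}(p, g) = \tfrac12\Big(
\frac{\langle p, D_g\rangle}{\Sigma p} +
\frac{\langle g, D_{\hat p}\rangle}{\Sigma g}\Big),$$

where $D_g$ is the exact distance transform of the ground truth, $\hat p$
the prediction thresholded at 0.5, and $D_{\hat p}$ its distance transform.
On exactly binary predictions this *equals* the exact foreground-mode AHD
(tested to $10^{-9}$), so the surrogate is a genuine continuous extension.
The gradient flows through $p$ in the first term only; the thresholded
second term is treated as constant.

Two consequences of this construction matter in practice:

* **Scale sensitivity.** The first term is a probability-weighted mean
  whose gradient carries a factor $1/\Sigma p$: for a diffuse, shrinking
  prediction the gradient grows without bound, and the all-zero prediction
  is an absorbing degenerate state (the implementation returns a configured
  large constant — the grid diameter — with zero gradient and a warning).
  Training therefore applies the AHD term only after a cross-entropy
  warm-up (`ahd_warmup` outer iterations), putting the network into the
  confident regime the shape term is designed for — the same reason
  boundary-aware losses are conventionally applied on top of a pretrained
  backbone rather than from scratch.
* **One-sided pressure.** Only the prediction-to-truth direction is
  differentiable, which adds precision-like pressure (suppress stray
  foreground mass) but cannot by itself reward covering the object;
  cross-entropy supplies the recall pressure. The default placement keeps
  the combined objective in the outer (query) loss and adapts with
  cross-entropy only (`support_weights`), confining the strongly scaled
  shape gradient to the meta-update instead of the few-step inner loop —
  which is also exactly how episodes are adapted at evaluation time.

The combined objective is the unweighted sum
$L = L_{\mathrm{CE}} + \mathcal{L}_{\mathrm{AHD}}$ by default, with
weights exposed. Cross-entropy uses a probability floor
$\varepsilon = 10^{-7}$ (the loss is undefined at zero predicted
probability); ground-truth slices with empty foreground contribute
cross-entropy only, and such skips are counted
(`ahd_skipped_count()`) rather than silently ignored.

## Exact distance transforms

Distance transforms are exact, not chamfer approximations in the usual
sense: Manhattan and Chebyshev distances are realized by monotone grid
paths, so one forward and one backward raster scan over the 4- or
8-neighborhood yields the exact transform; the Euclidean transform uses the
lower-envelope-of-parabolas algorithm on squared distances, separably along
columns then rows. All three agree exactly with an
$O(\mathrm{pixels}\times|S|)$ brute force in the tests.

# Evaluation metrics

Pixelwise confusion counts give precision $TP/(TP+FP)$, recall
$TP/(TP+FN)$ and Dice $2TP/(2TP+FP+FN)$, the harmonic mean of precision
and recall whenever the sum is positive. Degenerate conventions: if
prediction and truth are both empty, all three are 1; if exactly one is
empty, all are 0 (the standard benchmark convention). Reports also carry
the exact set AHD per episode; an empty prediction against a non-empty
truth is scored with the grid diameter. Aggregates are arithmetic means
over episodes; `format_metric_table()` prints percentages with two
decimals and a Mean column in the conventional benchmark style.

# The synthetic episode generator

Each shape class fixes a geometry family — an ellipse with random center,
radii, orientation, and a radial-harmonic boundary perturbation
$r(\varphi) = 1 + \sum_j a_j \cos(j\varphi + \phi_j)$ — plus foreground and
background intensity means. Masks are rejection-sampled until they are a
single 4-connected component with foreground fraction in a configured band
(default 2–40% of the grid). Images add Gaussian noise (default
$\sigma = 0.05$), an optional smooth multiplicative bias field (a low-order
random polynomial within $\pm15\%$, mimicking MRI coil inhomogeneity), and
optional *distractor* blobs painted at foreground intensity but labeled
background — the confusable regime in which nearby organs share brightness.
The default grid is $64 \times 64$; support and query of an episode are
independent draws from the same class.

Superpixel-style pseudo-labels for self-supervised episodes come from
seeded multi-source shortest-path label propagation with step cost
$1 + \lambda\,|I(p) - I(\mathrm{seed})|$; on a constant image this reduces
provably to Manhattan-metric Voronoi cells of the seeds (ties to the lower
seed index), which is how it is tested. It mirrors the spirit of
superpixel over-segmentation without reproducing any specific algorithm.

Class splits: under **setting 1** the held-out test class may appear in the
*background* of training imagery (as distractors); under **setting 2** the
id sets are disjoint and the training distractor pool excludes test
classes. Setting-2 hygiene is machine-audited over every generated training
episode (`audit_split()`), not assumed.

Everything is a pure function of (configuration, seed): same seed, byte-
identical datasets, checkpoints and CSV logs, which the tests check
literally at the file level.

**What the generator does not emulate:** real anatomy and its spatial
context, 3-D structure, partial-volume effects, scanner-specific noise
correlations, and annotation noise. A method that meta-learns these
episodes has demonstrated fast adaptation to *intensity-and-shape-defined
blob classes under nuisance variation* — a necessary sanity property, not
clinical performance.

# The segmentation network

A deliberately small conditioned CNN satisfies the model-agnostic contract:
input channels are (target image, support image, support mask), output is
per-pixel 2-class logits; 2–3 stride-1 conv layers (default widths 8, 8,
kernel 3, ~1k parameters, cap 50k) with ReLU, implemented as im2col
gathers plus matrix products so every trainable tensor is a matrix ready
for Kronecker factoring. No pooling stages are used: for
intensity-defined blobs at $64\times64$ a small receptive field suffices,
and the all-matrix structure keeps the hand-derived backward pass (checked
against central finite differences at relative error $<10^{-3}$) short.
In the one-shot support loss the support example serves as both exemplar
and target, so the conditioning mask is trivially informative there; the
outer objective is what penalizes shortcut solutions, since the query
target is never an input channel.

# Numerical choices

* **Hessian-vector products** use central finite differences of the
  analytic gradient, $\mathrm{Hv} \approx (g(\theta+\epsilon v) -
  g(\theta-\epsilon v))/2\epsilon$ with
  $\epsilon = 10^{-5}(1+\|\theta\|)/\|v\|$: exact (to rounding) for the
  quadratic losses used by the closed-form oracle tests, $O(\epsilon^2)$
  for smooth losses.
* **Ties** in the pseudo-label propagation go to the lower seed index;
  thresholding uses $\ge$; the prediction threshold default is 0.5.
* **Degenerate inputs**: empty point sets raise a typed error at the
  distance layer (callers decide policy); an all-zero probability map in
  the surrogate returns the grid diameter with zero gradient and a
  warning; 0/0 metric conventions as above.
* **Problem sizes.** The test-suite experiments use 200 training episodes,
  50 test episodes, $64\times64$ grids and a ~1k-parameter CNN; the oracle
  sweeps use 200 random mask pairs up to $32\times32$ — sizes chosen so
  the full suite runs on one CPU in minutes while every property is still
  exercised at non-toy scale.

# The loss-ablation experiment

The package's acceptance experiment compares meta-training with
cross-entropy only against cross-entropy plus the AHD surrogate (100
warm-up iterations, shape term in the outer loss, outer updates clipped at
global norm 1). Choosing the regime for this comparison is itself a design
question:

* in the clean high-contrast regime the cross-entropy model is already at
  ceiling (mean exact AHD of a few hundredths of a pixel), leaving the
  shape term nothing to fix, so any added gradient noise reads as harm;
* with *fully* confusable distractors (identical foreground intensity) the
  tiny CNN cannot solve the task at all (Dice around 0.36), and refining an
  incompetent model with a shape term is meaningless;
* the informative regime is in between: one distractor blob per image at
  intermediate intensity (0.6 against foreground 0.75 / background 0.3),
  where the base model is competent (Dice around 0.76) yet still commits
  distant false positives — exactly the error mode a distance-weighted
  loss penalizes more strongly than pixel-counting cross-entropy.

The tests require the combined objective to achieve mean exact-set AHD no
worse than cross-entropy alone there at matched Dice (within 10 points).
Clipping matters for this experiment: the outer loss is evaluated at a
lightly adapted point whose predicted mass can be small, which inflates the
surrogate gradient by orders of magnitude; without bounded updates the
meta-initialization is catapulted between all-foreground and
all-background solutions.

Two caveats on interpreting this comparison. First, the mean exact AHD of
a trained model is a noisy functional of the training seed — a single rare
degenerate prediction contributes the full grid diameter to the mean — so
a one-seed comparison of two means should be read alongside the per-episode
distributions that the evaluation report carries. Second, the combined
objective's characteristic effect is a recall/precision shift (it
suppresses distant false-positive mass and tolerates slight dilation); its
larger masks can cost a fraction of a pixel of mean AHD on routine episodes
even while it prevents catastrophic empty predictions on hard ones. The
test suite asserts the directional mean comparison at its fixed seed and
the acceptance script reports both means for whatever seed it is given.

# Known limitations

* Second-order outer gradients truncate the Jacobian of the meta-train
  $\xi$ update (an $O(\beta)$ correction), and finite-difference
  Hessian-vector products on ReLU networks are only piecewise reliable —
  first-order mode is recommended for such models.
* The AHD surrogate's gradient is one-sided (prediction-to-truth); it
  must be paired with an overlap loss and a warm-up.
* The generator's episodes are far easier than clinical data; absolute
  Dice values here say nothing about performance on real images.
* Training is single-process and deterministic by design; there is no
  parallel episode evaluation unless order-independence is guaranteed by
  the caller.
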