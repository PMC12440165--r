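---
title: "ASGBC: methods, design choices and desk-scale study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ASGBC: methods, design choices and desk-scale study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gallbladder cancer is routinely screened with B-mode ultrasound, where
malignant lesions are notoriously hard to call: speckle noise degrades
boundaries, and malignancy often presents as an ill-defined, heterogeneous
mass rather than a clean focal finding. Supervised deep classifiers need
expert labels for every image; `asgbc` implements a three-phase pipeline that
spends the labeling budget where it matters and learns its representation
without labels:

1. **Active selection** — a variational-adversarial game chooses which
   images are worth annotating.
2. **Self-supervised pretraining** — a residual convolutional extractor with
   a multi-scale high-order pooling (MsHop) block is trained on the selected
   images with a dual-branch objective (no labels).
3. **Linear probe** — the backbone is frozen and a single affine layer is
   fitted on the selected images' labels to produce the 3-class model
   (normal / benign / malignant).

## Phase 1: variational-adversarial selection

A beta-VAE encoder–decoder learns a latent representation of *all* images
while a discriminator is trained to distinguish latents of already-selected
images (labeled pool) from the rest. The VAE's objective adds, to its
reconstruction + KL terms over both pools,

$$L_{\mathrm{VAE}} = \lambda_1 L_{\mathrm{trd}} + \lambda_2 L_{\mathrm{adv}},$$

where the adversarial part $-\mathbb{E}\log D(z_S) - \mathbb{E}\log D(z_U)$
pushes the discriminator to call every latent "selected", and the
discriminator itself minimizes
$-\mathbb{E}\log D(z_S) - \mathbb{E}\log(1 - D(z_U))$. After training, the
unselected samples with the *lowest* discriminator scores — those whose
latents look least like anything already selected — are acquired, round by
round, up to each budget fraction (default schedule 15/25/35%, starting from
a 5% random seed set). Selection scores are computed on posterior means, so
acquisition is deterministic given the trained weights; ties break by
ascending index. The phase never reads the label column, and the test suite
verifies bit-identical output when labels are deleted.

Defaults follow the printed configuration where one exists
($\beta = 1$, $\lambda_1 = \lambda_2 = 1$, 5% initialization). Architecture
is unspecified in the source method, so the package uses a deliberately
small fully connected VAE (images resized to 32 px and flattened, hidden
width 256, latent 32) and a 3-layer discriminator: the selection game is
architecture-agnostic, and at a few hundred images a convolutional VAE adds
cost without changing which samples look under-covered. The task-learner
slot of the selection loop is a no-op: the phase is defined to be label-free,
and any supervised auxiliary task would contradict that.

## The MsHop block

A feature map $F \in \mathbb{R}^{H \times W \times D}$ first passes a
hierarchical multi-scale stage: channels split into four groups
$F_1, \dots, F_4$, with

$$S_i = \mathrm{Conv}_{3\times3}^i(F_i \oplus S_{i-1}), \qquad S_1 =
\mathrm{Conv}_{3\times3}^1(F_1),$$

and $F' = \mathrm{Conv}_{1\times1}([S_1, S_2, S_3, S_4])$. Three $1\times1$
reductions then shrink one axis each ($D \to D'$, $W \to W'$, $H \to H'$),
and the *sample covariance* of the reduced features is computed along each
axis — every spatial position is one observation of the $D'$ channel
variables, every height–channel coordinate one observation of the $W'$
width variables, and so on. Covariances are mean-centered with divisor
$m - 1$ and computed strictly per sample; batch statistics never mix. A
1-D kernel convolved along each covariance row, a learned affine map from
the covariance side length to the matching feature-map axis length, and a
sigmoid produce three statistical weight vectors
$\lambda_W, \lambda_H, \lambda_D \in (0,1)^\cdot$, and the block output is

$$\hat F = \mathrm{Conv}_{1\times1}\big((\lambda_W \otimes F') \oplus
(\lambda_D \otimes F') \oplus (\lambda_H \otimes F')\big) \oplus F,$$

with $\otimes$ broadcasting along the vector's own axis and $\oplus$
element-wise addition.

Open details are fixed as follows, each exposed in `mshop_config()`:

* **Attention length bridge.** The weight vector derived from a
  $W' \times W'$ covariance must rescale an axis of length $W$; a learned
  affine map $W' \to W$ before the sigmoid is the minimal learnable bridge
  (mirroring global second-order pooling practice).
* **Reduction ratios.** $W' = \lceil W/2 \rceil$, $H' = \lceil H/2 \rceil$,
  $D' = \lceil D/4 \rceil$; only the strict inequality is prescribed.
* **Insertion points.** After residual stages 2 and 3, where covariance
  pooling sees mid-level texture; configurable via `mshop_stages`.
* **Row-conv kernel.** Length 3.

Setting the final fusion convolution to zero makes the block an exact
identity; the suite uses this residual degeneracy, plus a literal
straight-line oracle of the full composition, as correctness anchors.

## Phase 2: the dual-branch objective

Two augmented views of each batch are encoded to features $Y_1, Y_2$ and
expanded by a three-layer MLP to $Z_1, Z_2$. The contrastive branch is the
variance-invariance-covariance loss

$$L_{\mathrm{con}} = \lambda\, s(Z_1, Z_2) + \mu\,[v(Z_1) + v(Z_2)] +
\nu\,[c(Z_1) + c(Z_2)]$$

with $s$ the mean squared pair distance, $v$ the hinge
$\tfrac1d \sum_j \max(0, \gamma - \sqrt{\mathrm{Var}(z_j) + \epsilon})$ and
$c$ the mean squared off-diagonal covariance. The source text defines the
regularizer as $\mathrm{Var} + \epsilon$ while calling it a "regularized
standard deviation"; the package follows the standard-deviation reading
(`sqrt_variance = TRUE`), with the literal reading available as a flag.
$\lambda = \mu = 25$ and $\gamma = 1$ are the printed values; $\nu = 1$ and
$\epsilon = 10^{-4}$ follow the convention of this loss family.

The clustering branch assigns features to $K$ learnable prototypes by
entropically regularized optimal transport: Sinkhorn–Knopp iterations push
$\exp(\mathrm{scores}/\varepsilon)$ toward uniform marginals (rows $1/n$,
columns $1/K$; three sweeps, finishing on the rows so row marginals are
exact). Each view must then predict the *other* view's codes through a
temperature softmax over cosine similarities
($p_i(k) \propto \exp(\hat y_i \cdot \hat c_k / \tau)$, $\tau = 0.1$),
giving $L_{\mathrm{clu}} = \ell(Y_1, Q_2) + \ell(Y_2, Q_1)$. Codes are
computed without gradient tracking; prototypes are parameters, re-normalized
to unit norm after each step. $\varepsilon = 10^{-4}$ is the printed value
and produces near-hard assignments; a smoother alternative is a config
field. $K = 30$ at desk scale. The total objective is
$L_{\mathrm{total}} = L_{\mathrm{con}} + \alpha L_{\mathrm{clu}}$ with
$\alpha = 0.1$; $\alpha = 0$ with MsHop disabled reproduces the
contrastive-only baseline configuration of the ablation.

**Stability without normalization layers.** The networks here use no batch
normalization in the backbone; to keep activations bounded every residual
branch's final convolution starts near zero (the block opens as an
identity), and the expander's hidden layers are batch-standardized
(parameter-free) before their ReLUs during pretraining. The second point is
load-bearing: without it the variance hinge has a stable constant-embedding
fixed point (zero gradient at exact collapse) and small-batch training falls
into it.

## Phase 3 and prediction

The frozen extractor embeds the selected images; embeddings are
standardized per dimension, and a single affine layer ($d \to 3$) is fitted
by softmax cross-entropy with Adam under an L2 ridge
(`probe_wd = 0.01`, 300 steps). The ridge is what keeps the probe
sample-efficient at small label budgets — without it the 35%-budget probe
visibly overfits its ~170 labels. Backbone parameters are untouched, which
the suite checks by comparing the full parameter vector before and after.

## Training defaults

Published settings are the defaults of `train_config()`: Adam with
$\beta_1 = 0.9$ (the optimizer's "momentum"), batch 64, initial learning
rate 0.003, weight decay $10^{-6}$, cosine decay, 800 steps ("iterations"
are optimizer steps; batches are shuffled epochs without replacement).
Augmentation (`augmentation_policy()`): random resized crop (scale 0.6–1),
horizontal flip $p = 0.5$, brightness/contrast jitter ±20%, Gaussian blur
$\sigma \in [0.1, 1]$, multiplicative speckle jitter — grayscale-safe
choices consistent with B-mode physics.

**Desk scale.** The benchmark harnesses run the `micro` backbone (64 px,
four conv stages, MsHop after stages 2 and 3, 64-d embeddings, pooled
features from stages 2 and 3) with the published optimizer settings
(batch 64, lr 0.003, cosine), and with the step count scaled to 7 passes
over the selected pool — so the 35% and 100% label budgets receive equal
optimization pressure rather than equal step counts. The label-efficiency
harness runs the selection VAE with an 8-dimensional latent: at a few
hundred images a higher-capacity latent memorizes patient identity, and
bottom-score acquisition then hoards every image of a few unusual patients
instead of diversifying over appearance.

## The phantom generator

`generate_dataset()` emulates the statistical structure of a B-mode
gallbladder cohort, not its acoustics: a smooth tissue background with
multiplicative speckle (smoothed exponential field, the standard
log-compressed approximation), a dark elliptical lumen with an echogenic
wall, and class-dependent lesions — benign: a compact bright focus with a
smooth sharp margin; malignant: a larger mid-echogenic mass with a
harmonically perturbed (irregular) margin, heterogeneous internal texture
and a suppressed wall sector. Each synthetic patient owns one anatomy and
one class; all of a patient's images perturb that anatomy slightly, which
is what makes patient-grouped splitting meaningful. Class proportions
default to 34.4/44.5/21.1% (the balance of the public gallbladder
ultrasound cohort this emulates). Lesion-parameter ranges were chosen once
so that the generator satisfies its own validity properties — a hand-coded
margin-irregularity score separates malignant phantoms with AUC > 0.9, and
the micro pipeline learns the task to ~0.8+ accuracy on a few hundred
images — and are not revisited per experiment.

What the phantoms do **not** model: acquisition physics (no beam profile,
no attenuation or shadowing), scanner/vendor variation, anatomy other than
the gallbladder, comorbid findings, or the full difficulty of real
malignancy (where margins can be subtle at any resolution). Passing the
synthetic benchmarks therefore demonstrates that the pipeline's machinery —
selection, representation learning, probing, evaluation — behaves as
designed, not that it reaches clinical accuracy on real images.

The noise operator used by the robustness protocol adds zero-mean Gaussian
noise whose field is smoothed by a spatial Gaussian kernel
($\sigma = 5$ px) and rescaled so its standard deviation equals the level
times the dynamic range. The reported "kernel sigma" is read as this
spatial smoothing — the construction that makes noise spatially correlated,
as ultrasound artifacts are; level and sigma are both config fields since
the printed description is ambiguous.

## Evaluation protocol

`confusion_and_metrics()` computes 3-class accuracy (trace over total),
sensitivity as malignant recall, specificity as pooled non-malignant recall,
malignant F1, and macro-F1 (mean per-class F1; 0/0 defined as 0).
`grouped_cross_validation()` partitions patients, never images. Paired
t-tests are two-sided at 0.05, with zero-variance differences flagged
degenerate ($p = 1$). Confidence intervals use
$\bar x \pm 1.96\, s/\sqrt{k}$. `relative_change()` is
$100\,|new - old| / old$ with the direction reported separately — the
arithmetic behind the reported ablation and noise percentages.

`kappa_bounds()` addresses agreement with raters known only through
marginal summaries (sensitivity, specificity, prevalence): within each true
class, the probability that both raters are correct is only constrained to
its Fréchet interval, so observed agreement $P_o$ is interval-valued while
chance agreement $P_e$ is fixed by the marginal positive rates; the bounds
on $\kappa = (P_o - P_e)/(1 - P_e)$ are sharp and verified against a
brute-force grid search. The package does not attempt to reproduce any
specific published kappa table whose sample-size and marginal assumptions
are not stated; the estimator is general.

## Desk-scale study conditions (what the tests run)

* **Label efficiency**: 5 cohorts of ~600 images (150 patients, 3–5 images
  each), patient-stratified 80/20 split; arms = active 35%, random 35%,
  full; equal epochs per arm. Checked: mean accuracy (active) ≥ mean
  accuracy (random), and within 0.02 of the full-data run.
* **Ablation**: 5 cohorts of ~240 images; contrastive-only baseline versus
  MsHop enabled and clustering branch enabled; checked on macro-F1 at a
  −0.01 tolerance. The clustering branch's gradient contribution is small
  (near-hard transport codes at $\varepsilon = 10^{-4}$), so its effect at
  this scale is modest and batch-size dependent — the property checked is
  "does not hurt", not a specific effect size.
* **Noise robustness**: 5 cohorts, model trained clean, evaluated at
  0/1/5/10% correlated noise; checked for monotone non-increasing mean
  accuracy.

All randomness flows from explicit seeds; runs are bit-reproducible on a
fixed machine and BLAS.

## Known limitations

* The in-package autodiff/conv stack is single-threaded CPU code sized for
  64-px micro models; `resnet18`/`resnet50` profiles are provided and
  functional but not practical to train here.
* ImageNet-pretrained initialization is intentionally unsupported
  (`pretrained_init = TRUE` raises an error): no download is ever needed.
* At desk scale the self-supervised gains over a well-initialized random
  backbone are modest (the phantom task is learnable from generic conv
  features); the benchmarks therefore check directional properties rather
  than effect sizes.
* Sinkhorn at $\varepsilon = 10^{-4}$ yields near-one-hot codes; the
  clustering branch is correspondingly weak at small batch sizes.
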