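---
title: "Methods: paired cell/gene VAEs with static gene-embedding priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired cell/gene VAEs with static gene-embedding priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

scPairVAE couples two variational autoencoders. The **cell VAE** encodes a
cell's scaled log-normalized expression profile $c_i \in \mathbb{R}^M$ into
a diagonal Gaussian posterior over a $K$-dimensional latent; the **gene
VAE** encodes a gene's static embedding $g_j \in \mathbb{R}^D$ (a fixed
vector exported from some pretrained model and consumed here purely as
numbers) into the *same* $K$-dimensional latent space. Latents are sampled
with the reparameterization trick,
$z = \mu + \epsilon \odot \exp(0.5 \log \sigma^2)$, and each decoder maps
its latent to a last-hidden vector of width $l$ — deliberately *without* a
final linear projection. Expression is reconstructed bilinearly:
$\hat c_{ij} = \langle h_i^{cell}, h_j^{gene}\rangle + b_j$ with one
trained bias per gene.

The modeling assumptions are therefore: (1) expression is approximately a
low-rank bilinear function of cell state and gene identity on the scaled
scale, plus per-gene offsets; (2) the static embeddings carry enough
information about genes that a smooth map from embedding space can place
each gene correctly in the shared latent space; (3) a standard-normal
prior with a small KL weight is an adequate regularizer — we use a
Gaussian reconstruction likelihood (squared error), not a count
likelihood, so inputs must already be normalized and standardized.

## Decoder output convention

"Last-hidden output" is implemented as: the nonlinearity (softplus by
default) is applied to every decoder layer *except* the final width-$l$
layer, which stays affine. A nonnegative final activation would force
$\langle h^{cell}, h^{gene}\rangle \ge 0$, so reconstructions could never
fall below the per-gene bias — a real restriction for z-scored expression,
which is signed. The affine convention keeps the bilinear decoder
expressive and makes the single-layer identity-activation configuration an
exactly linear autoencoder, which is what the truncated-SVD equivalence
check exploits.

# Three-step optimization

* **Step 1 — cell VAE pretraining.** The cell VAE reconstructs $c_i$
  through a linear head ($W^{cell} \in \mathbb{R}^{l\times M}$, bias
  $b^{head}$): loss $\frac1{N_b}\sum_i \lVert c_i - \hat c_i\rVert^2 +
  \beta\,\frac1{N_b}\sum_i KL_i$.
* **Step 2 — gene VAE pretraining.** The entire cell side (encoder,
  decoder, head) is frozen; `fit()` stores a snapshot and the test suite
  asserts bit-identity after the step. The gene VAE learns to reconstruct
  the expression batch through the inner-product decoder. The frozen cell
  pass uses the posterior *means*: since no gradient reaches the cell
  side, sampling there would only inject noise into the regression
  targets. The gene side is sampled, as its ELBO requires.
* **Step 3 — joint optimization.** All parameters (except the retired
  step-1 head) train together. The loss adds the alignment term
  $\gamma\,\frac1{N_b}\sum_i \lVert c_i - (z_i^{cell\top} z^{gene} +
  b)\rVert^2$, a reconstruction on the *latents* themselves that forces
  the coordinates of the two latent spaces to correspond dimension by
  dimension — this is what makes a gene latent interpretable alongside
  cell latents.

Scaling conventions: all per-cell sums are divided by the minibatch size,
so losses are batch-size invariant; the gene KL runs over all $M$ genes
once per optimization step (the reconstruction of any cell needs every
gene, so minibatching is over cells only) and is divided by $M$. The
per-gene bias $b_j$ is shared between the hidden-path and alignment-path
reconstructions by default (they model the same offset; a
`shared_bias = FALSE` switch separates them). It receives gradients in
both steps 2 and 3.

# Tunable parameters

| parameter | default | role |
|---|---|---|
| `K` | 32 | shared latent dimensionality (both VAEs; required equal by the alignment term) |
| `l` | 64 | last-hidden width of both decoders (required equal by the inner product) |
| `cell_hidden`, `gene_hidden` | 128 | hidden widths of encoders/decoders |
| `beta_max` | 0.01 | KL weight ceiling; kept small so reconstruction dominates |
| `beta_warmup_epochs` | 10 | linear ramp of $\beta$ from 0; restarts at each step, since each step optimizes a fresh objective |
| `gamma` | 0.05 | alignment weight; small so the term guides rather than dominates |
| `epochs_per_step` | 100, 100, 200 | step lengths; joint refinement gets the longest run |
| `batch_size` | 128 | cells per minibatch |
| `learning_rate` | 1e-3 | Adam step size |
| `grad_clip` | 5 | global-norm clip; stabilizes the bilinear decoder early on |
| `target_sum` | 1e4 | per-cell library-size normalization target in `preprocess()` |
| `clip` | 10 | symmetric bound on scaled expression |

All values are unitless (expression enters pre-standardized). Widths and
`K`/`l` were chosen as conventional round numbers for datasets of a few
hundred to a few thousand cells; everything is overridable.

# Numerical choices

* Log-variances are clamped to $[-15, 15]$; the clamp passes no gradient
  at its boundaries.
* Per-gene standardization uses the population denominator ($1/N$), so a
  standardized gene satisfies $\frac1N\sum_i x_i^2 = 1$ exactly.
  Zero-variance genes become all-zero columns and are reported.
* Optimizer: Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$), fresh state per
  step.
* Weight init: seeded Gaussian with $1/\sqrt{\text{fan-in}}$ scale,
  zero biases; all randomness flows through R's RNG seeded from the model
  and training configs, so identical configs reproduce identical logs,
  parameters and embeddings bit-for-bit.
* Divergence (non-finite loss) aborts training with a warning and returns
  the last finite-loss checkpoint.
* Gradients of all three objectives are hand-derived; the test suite
  verifies them against central finite differences to $10^{-5}$.

# Inference conventions

Downstream embeddings default to posterior **means**. The generative view
samples latents, but deterministic embeddings are required for
reproducible clustering and metric computation; sampling stays available
behind `mode = "sampled"` with an explicit seed.

**Leave-one-gene-out imputation**: a gene absent from training is encoded
from its static vector, decoded to $h^{gene}$, and combined with every
cell's $h^{cell}$. Its per-gene bias was never trained, so the default
prediction uses zero bias (the least-assumption choice for standardized
expression, whose per-gene mean is 0); `bias = "mean_bias"` substitutes
the mean trained bias. The faithful protocol retrains per held-out gene;
batched evaluation trains once on all-but-the-target-set and imputes each
target from that one model.

# Metrics

ARI/NMI are computed on Leiden communities of a 15-nearest-neighbor graph
(Euclidean), scanning resolutions 0.1–2.0 in steps of 0.1 and reporting
the best score per metric (scan recorded in the metadata) — the
benchmark-style convention when no single resolution is canonical.
Silhouettes are rescaled $(s+1)/2$; batch-ASW averages $1-|s|$ of the
batch labeling within each cell type, skipping types confined to one
batch. Graph LISI uses the same k-NN neighborhoods (self included):
integration flavor $(\text{LISI}-1)/(B-1)$, cell-type flavor
$(C-\text{LISI})/(C-1)$. For the Jensen–Shannon divergence between signed
expression vectors, each vector is shifted by its minimum and normalized
to sum to one; base-2 logs bound the result in $[0,1]$. Gene modules come
from the same graph-clustering machinery on contextual gene embeddings;
singleton communities are labelled $-1$ and excluded from module
summaries.

# The synthetic generator

`generate()` plants: cell loadings drawn around cell-type-specific means
and gene loadings around module-specific means (group means
$\mathcal{N}(0,1)$ per coordinate, within-group sd 0.3 — strongly
separated groups) in a rank-8 latent space; expression as the bilinear
product plus per-gene intercepts, per-batch per-gene offsets (sd 0.5) and
entry-wise Gaussian noise (sd 0.5); and a static embedding table that is a
noisy random affine image of the true gene loadings (`informative`), a
row-permutation of it (`shuffled`), or pure noise (`random`). Defaults:
500 cells, 200 genes, 4 cell types, 2 batches, 5 modules, $D = 32$,
embedding noise sd 0.1 — sizes chosen so a full three-step fit runs in
well under a minute on one CPU while leaving room for all planted
structure.

Because the default generator produces *continuous* signed values
(matching the bilinear decoder's natural scale), only the standardization
and clipping stages of the preprocessing contract apply to it; the
optional count mode (Poisson draws from a softplus rate) exercises the
full normalize–log1p–scale path instead.

What the generator does **not** emulate: dropout and zero inflation,
overdispersed counts, library-size gradients correlated with cell state,
nonlinear (non-bilinear) expression programs, and embeddings whose
informativeness varies across gene families. Passing tests on this data
therefore demonstrates that the machinery is correct and that the
informative-versus-shuffled ordering holds when the prior genuinely
encodes module structure — not that any particular external embedding
source is informative for real tissues.

# Problem sizes used by the checks

The SVD-equivalence check runs a 50-cell × 30-gene matrix with
$K = l = 5$ linear networks for 3000 full-batch epochs; loss-oracle
comparisons use 4 cells × 3 genes; module-recovery runs three full
default-size studies; the imputation comparison holds out 10 genes in
each of five paired studies (informative vs shuffled), training one model
per study arm with epochs 60/60/120. These are the package's documented
evaluation conditions.

# Known limitations

* Gaussian likelihood only — raw counts must be preprocessed; there is no
  negative-binomial/ZINB decoder.
* No batch covariate enters the network; batch mixing is emergent (and
  measured), not enforced.
* The gene encoder processes all genes every optimization step, so very
  large gene panels (tens of thousands) make steps 2–3 expensive.
* Networks are plain dense MLPs; no attention, no normalization layers.
* Hyperparameters are not searched automatically.
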