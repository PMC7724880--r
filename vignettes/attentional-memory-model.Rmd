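---
title: "A hybrid attentional memory model for drug repositioning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hybrid attentional memory model for drug repositioning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amnet)
```

## The problem and the model

Drug repositioning data is implicit feedback: a binary matrix $R$ of
verified drug–disease associations in which a 0 means *unverified*, not
*false*. The data is extremely sparse (around $10^{-2}$), and many drugs
have a single known indication, so any useful model must exploit side
information and must not treat zeros as trustworthy negatives.

`amnet` scores a pair $(i, j)$ by fusing two views.

The **neighborhood view** looks at $N(j)$, the drugs already associated
with disease $j$. Each drug carries two learned vectors: a latent factor
$\mathrm{drug}_i \in \mathbb{R}^d$ (from the autoencoder below) and an
external memory row $c_i \in \mathbb{R}^{\ell}$ holding its
*neighbor-role* information. Preferences
$p_{ijn} = \mathrm{drug}_i^\top \mathrm{drug}_n$ are softmax-normalized
into attention weights $q_{ij}$, and the neighborhood representation is
the attention-pooled memory $o_{ij} = \sum_{n \in N(j)} q_{ijn} c_n$.
Attention lets the few strongly similar neighbors dominate; the memory
dimension $\ell$ is decoupled from $d$ so the capacity of this pathway can
be tuned independently.

The **global view** extracts latent factors with one denoising autoencoder
per side. The drug encoder consumes the association row and the drug–drug
similarity row, both corrupted by random masking, and two decoder heads
reconstruct the *clean* profiles:
$$\mathrm{drug}_i = g(W_1 \tilde{s}_i + V_1 \widetilde{\mathrm{DrugSim}}_{i\cdot} + b),$$
with reconstruction loss
$\alpha \lVert s_i - \hat{s}_i \rVert^2 + (1-\alpha) \lVert \mathrm{DrugSim}_{i\cdot} - \widehat{\mathrm{DrugSim}}_{i\cdot} \rVert^2$
plus an $L_2$ penalty $\lambda$ on the four weight matrices of the side
(biases unpenalized). The disease side mirrors this with columns of $R$,
the disease–disease similarity, and weights $\beta, \delta$. Because the
similarity row alone can drive the encoding, a drug with an empty
association row still receives a meaningful factor — this is what the
cold-start protocol exercises.

The **fusion layer** combines the views,
$$\hat{r}_{ij} = F_{out}\!\left(\eta\, h^\top(\mathrm{drug}_i \odot \mathrm{disease}_j) + (1-\eta)\, W^\top o_{ij} + b\right),$$
and the joint objective is
$\mathcal{L} = \mathcal{L}_r + \varphi \mathcal{L}_d + \psi \mathcal{L}_p$,
with $\mathcal{L}_r$ the binary cross-entropy over known positives and
sampled negatives. One reading note on conventions: the prediction loss is
implemented as the *negated* log-likelihood so that "loss" is minimized,
and the attention denominator is the standard softmax normalization over
$n \in N(j)$ — the only reading under which the weights form a probability
vector.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `latent_dim` ($d$) | latent factor size | 64 | middle of the conventional 16–256 search range |
| `memory_dim` ($\ell$) | memory row size | 64 | the neighborhood pathway saturates and then overfits as $\ell$ grows |
| `eta` ($\eta$) | latent vs neighborhood weight | 0.7 | the global pathway carries most of the signal; the neighborhood corrects a minority of pairs |
| `alpha`, `beta` | association vs similarity reconstruction | 0.5 | no prior reason to favor either input |
| `lambda`, `delta` | weight penalty | 0.001 | smallest value of the conventional {0.1, 0.01, 0.001} range; the denoising corruption already regularizes |
| `phi`, `psi` ($\varphi,\psi$) | reconstruction weight in the joint loss | 0.1 | keeps the prediction loss dominant while anchoring the factors |
| `mask_rate` ($\rho$) | input corruption rate | 0.3 | standard denoising rate for sparse binary rows; $\rho = 0$ recovers a plain autoencoder |
| `neg_ratio` | negatives per positive, per epoch | 1 | standard implicit-feedback practice; resampling each epoch sweeps many zero cells over training |
| `learning_rate` | Adam step size | 0.01 | within the conventional grid; converges within 100 epochs at the problem sizes below |
| `epochs` | training passes | 100 | loss and held-out AUC plateau well before this on the synthetic conditions |

`default_grid()` exposes the full conventional search ranges and
`grid_search_amnet()` evaluates them (the grid's enumeration is 112,500
configurations; use `max_configs` to subsample).

## Design decisions where the design was open

**Noise model.** "Random noise" on the inputs is implemented as masking
(each entry independently zeroed with probability $\rho$). Masking is the
natural corruption for sparse binary association rows — additive Gaussian
noise would make binary reconstruction targets incoherent — and it makes
the denoising ablation exact at $\rho = 0$.

**Activations.** Encoder $g$ is ReLU; both decoders and $F_{out}$ are
logistic, because every reconstruction target (binary associations,
$[0,1]$ similarities) and the predicted score live in $(0,1)$. All are
configurable.

**Reconstruction targets are the clean inputs** (denoising convention):
corruption enters only the encoder.

**Self-exclusion.** When scoring pair $(i,j)$, drug $i$ is removed from
$N(j)$; otherwise a training positive attends to its own label and the
neighborhood pathway degenerates into a label detector. At inference,
$N(j)$ comes from the training matrix only. A disease with no training
associations yields $o_{ij} = 0$, so the predictor degrades gracefully to
the latent pathway.

**No cap on $|N(j)|$.** Nothing restricts the neighbor set size; capping
is a property of the methods this model is meant to improve on.

**Training regime.** One joint objective trains both autoencoders, the
memory and the fusion layer end to end; an optional pretraining phase on
the reconstruction losses alone (`pretrain_epochs`) is provided but off by
default. The optimizer is minibatch Adam on hand-derived gradients; the
prediction term is computed per minibatch while $\mathcal{L}_d$ and
$\mathcal{L}_p$ (which sum over all drugs/diseases, not over pairs) are
evaluated in full at every step — an optimizer detail, not a change of
objective. Early stopping on validation AUC (patience `patience`) is
available by passing a validation split to `train_amnet()`; it is off by
default so fixed-epoch runs are exactly reproducible.

**Training-time forward pass.** The latent factors fed into the prediction
pathway during training are the encodings of the *corrupted* inputs — the
corruption defines the training-time encoder — while inference always uses
clean inputs.

**Test negatives.** Following the implicit-feedback protocol, *all*
unverified cells serve as test negatives in every fold, and training
negatives are sampled from those same zero cells; a pair can therefore be
a sampled training negative in one epoch and a test negative. This overlap
is unavoidable under the protocol and is shared by every method evaluated
this way.

**Metric conventions.** AUC uses midranks for ties. AUPR is the step-wise
sum $\sum_k (R_k - R_{k-1}) P_k$ over descending thresholds with tied
scores grouped. HR@k ranks each held-out positive among *all* diseases
without a training association to its drug (full ranking, deterministic,
stricter than sampled-candidate variants), breaking score ties by
ascending disease index.

## Numerical choices

* Softmax with max-subtraction: exact up to rounding, immune to overflow;
  components more than ~745 nats below the maximum underflow to zero,
  which is the correct double-precision answer.
* Scores are clipped to $[10^{-12}, 1-10^{-12}]$ inside the cross-entropy
  to guard $\log 0$; gradients use the unclipped $\hat{r} - r$ form.
* Gaussian initialization, sd 0.1, for all weights and the memory table;
  biases start at zero.
* Every random draw (initialization, fold shuffles, negative samples,
  corruption masks, minibatch order) flows from one user seed through a
  collision-free derivation, so any run is bit-reproducible
  single-threaded.
* Similarity CSVs are written with 12 significant digits; asymmetry up to
  $10^{-6}$ on reading is repaired by averaging (floating-point dumps of
  symmetric matrices commonly drift), larger asymmetry is an error.
* TSV edge lists carry ids only on edges, so entities with no associations
  are dropped and id order on re-reading is first-appearance order; the
  MatrixMarket format with an id sidecar round-trips exactly and is what
  the CLI and model archives use.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` plants nonnegative rank-$r$ factors, marks the top
$q = \mathrm{round}(\text{sparsity} \cdot mn)$ true-score pairs as
associations (deterministic thresholding, so realized sparsity is exact),
and derives both similarity matrices as noisy cosine similarities of the
planted factors. "Similar drugs treat similar diseases" is thus literally
true, similarities are honestly informative about associations, and
ranking by the true scores attains AUC 1 by construction — an explicit
ceiling.

Real data differs in ways the generator does not attempt: chemical and
phenotype similarities are only imperfectly predictive of shared
indications; association matrices have heavy-tailed degree distributions
and curation biases; and zeros include false negatives by design.
Passing the synthetic-recovery tests therefore shows the estimator and
protocols are implemented correctly and can recover structure they are
matched to — it does not certify benchmark performance on curated
datasets, which additionally depends on the quality of the supplied
similarities.

The cold-start generator plants an exact number of single-association
drugs (keeping each chosen drug's highest-propensity association, and
topping up chance singletons elsewhere so the count is exact, except at
`n_singletons = 0`, which leaves the data untouched).

## Problem sizes used in the shipped checks

The test suite and the acceptance script run ten-fold cross-validation on
a $200 \times 100$ generated dataset (rank 8, sparsity 0.05) with
$d = \ell = 16$, $\eta = 0.7$ and 100 epochs — sizes at which the planted
structure is comfortably recoverable and a full run trains thirty-odd
models in a few minutes on one core. Oracle-equivalence checks use 100
random micro-instances per operation; the gradient check uses a
$3 \times 3$ instance with $d = \ell = 2$, where central finite
differences are trustworthy (the fixture is verified to sit away from the
ReLU kink).

## Known limitations

* Single-layer encoders with two decoder heads; no stacked/deep variant.
* Memory is defined over drugs in the neighbor role only; there is no
  disease-side memory.
* Training is single-threaded by design (reproducibility first); the cost
  is roughly linear in epochs × (positives + sampled negatives) plus the
  dense autoencoder passes, so very large matrices will be slow.
* Similarities are consumed as given; computing them from structures or
  text, and downloading published benchmark datasets, are out of scope.
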