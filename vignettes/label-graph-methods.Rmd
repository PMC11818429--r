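---
title: "Methods: label-graph attention for multifunctional peptide prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-graph attention for multifunctional peptide prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Bioactive peptides are short (roughly 5–50 residue) sequences with
therapeutic activities; a single peptide may carry two of the five
activities modelled here (antimicrobial AMP, anticancer ACP,
antidiabetic ADP, antihypertensive AHP, anti-inflammatory AIP — in
benchmark data never more than two). Predicting the *set* of activities
is a multi-label problem, and the activities are not independent:
certain pairs co-occur far more often than chance. `mfpep` encodes this
by building a graph with one node per label and letting attention learn
which label dependencies matter.

The forward computation, for a peptide embedding $p \in \mathbb{R}^d$:

1. **Node encoder.** $h_i = \mathrm{dropout}(W_i\,p)$ with one
   projection $W_i \in \mathbb{R}^{d' \times d}$ per label; $d' = 128$
   by default, standardising node features regardless of the embedding
   backend's dimension. Dropout acts only in training mode (inverted
   dropout, kept entries rescaled by $1/(1-\text{rate})$).
2. **Graph attention.** Per head, with a shared transform $W$ and
   attention vector $a$: scores
   $e_{ij} = \mathrm{LeakyReLU}(a^\top [W h_i \,\|\, W h_j])$,
   weights $\alpha_{ij} = \exp(e_{ij}) / \sum_{k \in N(i)} \exp(e_{ik})$,
   update $h_i' = \sigma\!\big(\sum_{j \in N(i)} \alpha_{ij} W h_j\big)$.
   Heads are concatenated in hidden layers and averaged in the final
   layer (the usual GAT convention for an output layer); $\sigma$ is the
   ELU and the LeakyReLU slope is 0.2.
3. **Node classifier.** $\mathrm{result}_i = \mathrm{sigmoid}(W_r \cdot h_i')$,
   one probability per label. No layer carries a bias term; the model is
   exactly the weight-only composition above.

The label graph is **fully connected with self-loops**: no prior
adjacency is imposed, so the attention weights themselves express the
learned label dependencies. This is the natural null topology when no
biological adjacency is given; with only $M = 5$ nodes the cost of full
attention is negligible.

Label order is fixed everywhere: (AMP, ACP, ADP, AHP, AIP), so a peptide
that is antimicrobial and anticancer has label vector $[1,1,0,0,0]$.

## Adversarial training

Training minimises the multi-label binary cross-entropy
$L_\text{init}$ (full two-term form $-[y\log p + (1-y)\log(1-p)]$,
summed over the five labels, averaged over the batch; probabilities
clamped at $10^{-7}$) plus an adversarial loss $L_\text{adv}$ computed
on perturbed embeddings. The fast gradient method (FGM) takes the
gradient $g$ of the log-likelihood with respect to the input embedding
and perturbs the embedding by
$r_\text{adv} = -\varepsilon\, g / \lVert g \rVert_2$ — an
$L_2$-normalised step of radius $\varepsilon$ up the loss surface. One
optimisation step computes $L_\text{init}$ and its gradients, builds
$e_\text{adv} = e + r_\text{adv}$ per sample, recomputes loss and
gradients there (reusing the same dropout masks, so the perturbation
attacks the same stochastic network realisation), and applies a single
Adam update on the summed gradients. Zero or non-finite gradients skip
the perturbation for the affected samples with a logged warning.

Two exactness conventions worth noting:

* **$\varepsilon = 0$ or FGM disabled take the identical plain-BCE code
  path** (one update on $L_\text{init}$, with $L_\text{adv}$ reported
  equal to $L_\text{init}$). With $\varepsilon = 0$ the combined
  objective would be $2L_\text{init}$, whose minimiser is the same but
  whose Adam trajectory differs microscopically from plain training;
  collapsing both to one path makes "FGM off" and "$\varepsilon = 0$"
  reproduce plain training bit for bit.
* The perturbation is applied to the pooled sequence embedding (the
  model input); token-level embeddings live inside external language
  models and are out of scope.

All gradients — through the classifier, head averaging/concatenation,
ELU, the attention softmax, LeakyReLU scoring, the head transforms, the
node encoder and down to the input embedding — are derived analytically
and implemented as dense matrix algebra vectorised over the batch. The
test suite verifies every parameter leaf and the input gradient against
central differences at tolerance $10^{-6}$.

## Embedding backends

The model consumes any fixed-length per-sequence vector. Adapters for
pretrained protein language models (ESM-2, ProtT5, RoBERTa) are
interface stubs: the checkpoints are multi-gigabyte external artifacts,
so these backends raise an informative error naming the alternatives.
Two backends are fully functional everywhere:

* **`kmer-test`** — concatenated, per-block-normalised 1-mer and 2-mer
  frequency vectors ($d = 20 + 400 = 420$). Deterministic, dependency
  free, and sufficient to make motif-bearing synthetic data learnable.
* **`precomputed`** — delimited tables of externally computed vectors
  (one id column plus $d$ numeric columns), e.g. embeddings exported
  from a language model elsewhere.

Per-residue representations can be reduced by mean (default), CLS or
max pooling; mean pooling is the default because no pooling convention
is canonical for these models and the mean is invariant to sequence
length in expectation.

## Ensembling

Member probabilities are combined by an element-wise weighted mean with
weights normalised to sum one (probability-level fusion followed by a
single thresholding step — combining decisions instead would discard
calibration). Weight fitting searches the simplex discretised at
`grid_step` (default 0.1; the exact uniform weighting is always added
as a candidate), maximising validation absolute true, with ties broken
toward uniform. Fitting on the evaluation set is deliberately not
supported: weights are fitted on validation data only.

# The evaluation metrics

For true set $Y$ and predicted set $Y^*$ per sample, averaged over
samples: precision (aiming) $|Y \cap Y^*|/|Y^*|$, coverage
$|Y \cap Y^*|/|Y|$, accuracy $|Y \cap Y^*|/|Y \cup Y^*|$, absolute true
$\mathbb{1}[Y = Y^*]$, absolute false $(|Y \cup Y^*| - |Y \cap Y^*|)/M$.
Degenerate sets: a ratio with an empty denominator set contributes 0,
except when both sets are empty (a perfect match, contributing 1).
These conventions imply the invariants
absolute true $\le$ accuracy $\le$ min(precision, coverage) and
(absolute false $= 0 \iff$ absolute true $= 1$), which the test suite
checks on 10,000 random instances alongside a brute-force
set-arithmetic oracle.

Per-label binary metrics use strict thresholding (probability exactly
at the threshold maps to 0), the determinant MCC with the 0/0
convention MCC $= 0$, and the rank-sum (Mann–Whitney) AUC with
mid-ranks for ties; single-class truth yields AUC NA with a warning.
The decision rule is threshold 0.5 with an optional "min-one" fallback
that sets the arg-max label when nothing clears the threshold —
appropriate for benchmark-like data where every peptide carries at
least one activity.

# Synthetic data: what it emulates and what it does not

The generator plants one short distinctive motif per activity (3-mers
by default: KWK, CYC, DED, HPH, IQI) at a random non-overlapping
position in a uniform random background, with label sets following
requested per-combination counts; `default_benchmark_like()` mirrors
the benchmark's class imbalance at one-tenth scale (AMP dominant at
226 of 591, four dual-activity pairs, never more than two labels) and
`motif_fixture()` is a balanced 200-peptide variant used in the
recovery study below.

Two rejection-sampling guards keep the noise-free task *separable per
label*, which is the property the fixture exists to provide: a
background is redrawn (a) if it contains an off-label motif by chance
(expected ~3 such collisions per 200 uniform sequences, each of which
would mislabel a record), and (b) if it contains **all constituent
dimers** of an off-label motif — under the $k \le 2$ embedder a motif
is visible only through its dimers, so such a background is provably
indistinguishable from a planted motif.

What passing tests on this fixture shows: the full pipeline — I/O,
embedding, the graph model, analytic gradients, FGM, checkpointing,
metrics — is correct and can recover a planted signal from data.
What it does not show: performance on real peptides. Real bioactivity
is not governed by three-residue motifs in uniform backgrounds, real
class structure is far noisier, and real embeddings come from language
models; benchmark-scale accuracy claims require the real data and
embeddings, which are outside this package.

# The parameter-recovery study

The study trains on the 200-peptide motif fixture (motif noise 0,
`kmer-test` embeddings, 80/20 group-stratified split) and asks for
held-out absolute true $\ge 0.9$ within 100 epochs. Its configuration
differs from the package defaults in four places, each forced by the
desk scale of the study:

* **Learning rate 5e-3** (default 1e-3): 161 training records at batch
  size 64 give only ~300 Adam steps in 100 epochs; the default rate
  demonstrably under-converges here (loss still falling at epoch 100).
* **$\varepsilon = 0.05$** (default 0.5): k-mer embeddings have
  $L_2$ norms of 0.3–0.7, so the default radius — sized for
  language-model embeddings with norms an order of magnitude larger —
  would replace the input outright. 0.05 is ~10% of the median
  embedding norm, the usual FGM operating point.
* **Checkpoint selection by validation loss** (default: best validation
  absolute true): the 10% validation carve-out holds ~16 records, so
  absolute true is quantised at 1/16 and tends to select a lucky early
  epoch; validation BCE is continuous and selects stably. Ties resolve
  to the later, better-converged epoch.
* **Min-one decision fallback on**: every fixture peptide carries at
  least one activity.

With these settings the run reaches held-out absolute true 0.92 at the
fixture's fixed seed, and 0.90–0.97 (median 0.94) across arbitrary
seeds; each held-out record is worth 1/39 ≈ 0.026 of absolute true, so
seed-to-seed variation of one or two records is expected. FGM is doing
real work in this regime: the same run without the adversarial term
plateaus around 0.62 under the default rate and does not exceed ~0.7
when converged.

Problem sizes throughout the test suite (200-peptide fixture, tiny
gradient-check models, 25-epoch smoke pipelines) were chosen so the
whole suite completes in about a minute while still exercising every
code path at full depth.

# Numerical choices and degenerate inputs

* Attention softmax subtracts the row maximum before exponentiation.
* Loss probabilities are clamped at $10^{-7}$ from both ends.
* Glorot-uniform initialisation, seeded; the saved RNG state is
  restored after every seeded operation so library calls do not disturb
  the caller's stream.
* Duplicate sequences are merged by bitwise label union (no annotation
  discarded), with every merge logged; deduplication is idempotent.
* The group-stratified split rounds each label-combination group's test
  share to the nearest integer, with at least one record on each side
  for groups of two or more; fractions outside (0,1) are rejected.
* An empty attention neighbourhood, an all-zero ensemble weight vector,
  mismatched embedding dimensions, ragged or non-numeric embedding
  tables, and non-standard residues all raise immediate, named errors.

# Known limitations

* No trainable language-model backends: embeddings beyond the k-mer
  test backend must be precomputed externally.
* The label graph is fixed and fully connected; no structure inference
  from label co-occurrence is attempted.
* Single-step FGM only; no multi-step (PGD-style) adversarial variants.
* Exact-sequence deduplication only — no similarity-threshold
  clustering.
* Saturation mutagenesis is single-position only; combinatorial
  mutation scans are out of scope.
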