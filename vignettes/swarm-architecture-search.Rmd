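---
title: "Swarm-intelligence architecture search for fundus severity grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swarm-intelligence architecture search for fundus severity grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmnas)
```

## The problem

Grading diabetic retinopathy (DR) from fundus photographs is a five-class
ordinal classification problem (0 = no DR through 4 = proliferative DR).
Convolutional networks pretrained on generic image collections often
transfer poorly to fundus data, which motivates searching for a *tailored*
deep ConvNet (TDCN): a layer sequence selected for the dataset at hand
rather than fixed in advance. `swarmnas` implements two swarm-intelligence
searches over a constrained space of layer sequences — an ant-colony-system
(ACS) search and a discrete particle-swarm (PSO) search — together with the
combinatorial calculus of that space, a lightweight CNN trainer that
supplies the fitness signal, the evaluation metrics used in this field
(accuracy, one-vs-rest AUC, Cohen's kappa), and a synthetic fundus-like
image generator so the complete pipeline is testable without any external
download.

## The search space

A candidate is an ordered sequence of typed layers drawn from the
vocabulary `C2D` (2-D convolution), `BN` (batch normalization), `DO`
(dropout), `MP`/`AP` (max / average pooling), `DE` (dense), `F` (flatten),
written in a pipe notation:

```{r}
arch <- tdcn_pso_architecture()
format_architecture(arch)
```

With a vocabulary of $t_l$ layer kinds and sequence lengths bounded by
$B_l \le b \le B_u$, the number of kind-sequences is

$$t_s = \sum_{b=B_l}^{B_u} t_l^{\,b},$$

computed exactly in arbitrary-precision integer arithmetic because the
values overflow doubles quickly:

```{r}
format(count_search_space(4, 3, 20))
```

Each kind additionally carries a grid of parameter permutations
($P_i$ choices for kind $i$; for the ACO grid
$P = (9, 2, 1, 4)$ for `C2D`, `MP`, `BN`, `DE`). Two readings of the
permutation calculus over layer multiplicities $n_i$ are provided by
`count_parameterized_space()`: the literal sum of powers
$\sum_i P_i^{n_i}$ and the combinatorial product $\prod_i P_i^{n_i}$,
which counts the distinct parameterizations of one fixed sequence. The two
readings disagree, and neither reproduces every value quoted for this
calculus in the literature this package follows; for the stack of 12
`C2D`, 1 `MP`, 15 `BN`, 3 `DE` layers the sum of powers is
`r format(count_parameterized_space(c(9,2,1,4), c(12,1,15,3)))`. Both modes
are exposed rather than silently resolving the ambiguity.

Three structural rules restrict the space: at least one `DE` layer, an `F`
before the first `DE`, and no `C2D` after `F`. `validate_architecture()`
reports violations as values; `repair_architecture()` enforces the rules
with minimal edits (append a default `DE` if none, insert `F` immediately
before the first `DE`, drop convolutions after `F`). Every candidate any
search evaluates has passed repair, so feasibility is an invariant, not an
error path.

## Ant-colony-system search

The ACO search grows a layer-choice graph from a bare input node. When an
ant reaches an unexpanded node, all layer choices legal at that position
(each kind paired with each of its parameter permutations; after a `DE`
only `DE`-block layers may follow) are attached once as children, each edge
starting at pheromone $\tau_0$. Ants advance one layer per depth level
under the ACS pseudo-random proportional rule: with probability $q_0$ the
maximal-pheromone edge, otherwise sampling proportional to pheromone. Each
traversed edge receives the local update
$\tau' = (1-\rho)\tau + \rho\tau_0$, which decays well-trodden edges back
toward $\tau_0$ and keeps exploration alive. After every depth level each
ant's path is repaired into a network and evaluated, and the level's best
ant deposits the global update $\tau' = (1-\rho)\tau + \rho f$ along its
path, $f$ being its fitness. The training budget is therefore exactly
`ants * depth` models (`count_models_aco()`).

The source material names the ACS rules but not their constants, so the
canonical ant-colony-system forms are used with defaults $q_0 = 0.5$,
$\rho = 0.1$, $\tau_0 = 1$, all configurable; no heuristic desirability
term is used because selection is described as pheromone-driven only. The
global update is triggered by the per-depth-level best ant. Identical
candidates are deliberately re-evaluated rather than cached so the budget
identity holds exactly.

## Particle-swarm search

A particle *is* an architecture; the swarm remembers each particle's best
(`pbest`) and the global best (`gbest`). The classical continuous velocity
update does not apply to a discrete layer sequence, so movement is a
per-slot block-copy plan: aligning particle, `pbest` and `gbest` from the
input end, a slot already agreeing with both sources is kept; a differing
slot is copied from `gbest` with probability $C_g$ (default 0.5) and from
`pbest` otherwise; slots beyond the particle's length are append decisions
drawn the same way, capped at $B_u$. The continuous coefficients
($w$, $c_1$, $r_{t1}$, $r_{t2}$) are retained in `pso_config()` as
documented, unused fields to record the correspondence. After every move
the repair pass restores feasibility. Each particle update counts as one
trained model, so `r` runs of `i` iterations over `p` particles cost
exactly `r * i * p` evaluations (`count_models_pso()`; the published
profile `5 * 12 * 20 = 1200`).

Fitness ties for `gbest` are broken toward the smaller trainable-parameter
count, then the earlier discovery — lightweight models are the point of a
tailored search.

## Fitness: the lightweight CNN trainer

No deep-learning framework is required: the package ships its own
vectorized CNN engine (im2col convolution with same-padding and stride 1,
strided max/average pooling, batch normalization, inverted dropout, dense
layers, a softmax head, Adam optimization, cross-entropy loss). Gradients
were verified against central finite differences to relative error
$\sim 10^{-9}$ for every layer type. Fitness of a candidate is its
validation accuracy on a fixed stratified 80/20 split after
`epochs_particle` epochs (1 in the published profile); candidates that
cannot be instantiated (e.g. pooling below $1 \times 1$) or diverge score
0 and the search continues. The final `gbest` is retrained longer
(`epochs_gbest`). Initialization is He-scaled and seeded, so a seeded
search with this trainer replays bit-identically.

`count_parameters()` follows the usual conventions — convolution
$k^2 C_{in} F + F$, dense $D U + U$, batch normalization two trainable
terms per channel — counting exactly the listed layers (the classification
head appended at instantiation is reported separately by
`network_parameters()`).

## Metrics and cross-validation

* **Accuracy** is the confusion-matrix trace over the grand total.
* **AUC** is one-vs-rest per class via the rank (Mann–Whitney) statistic
  with ties at 0.5, macro-averaged over classes present; this matches the
  per-class ROC reading standard in DR grading papers.
* **Cohen's kappa** defaults to the unweighted $(p_o - p_e)/(1 - p_e)$
  form; a quadratic-weighted variant is also reported because the APTOS
  competition metric is quadratic-weighted.
* **Cross-validation** is stratified k-fold (default 10) with per-class
  fold counts within one of the ideal, seeded and deterministic.

All three metrics are property-tested against independent brute-force
oracles (exhaustive pair concordance for AUC, direct $p_o/p_e$ evaluation
for kappa) to $10^{-12}$.

## The synthetic data generator

Real fundus datasets are large, external and partly unlabelled, so the
generator emulates the *structure* of the grading problem: a reddish
retina disc on a dark background, one bright optic-disc ellipse at a
random position, and — the ground truth — exactly $k$ small bright lesion
blobs for severity class $k$, rejection-sampled to avoid the optic disc
and each other, plus additive Gaussian pixel noise. Severity-as-lesion-count
is a deliberately simple monotone analogue of DR grading that gives an
analytic ground truth: at zero noise the dataset is perfectly separable by
a mean-intensity feature, and raising the noise can only make that oracle
worse (both are tested). Class proportions default to the published APTOS
training distribution 1805:370:999:193:295; `"uniform"` is available, and
counts are apportioned by largest remainder so totals are conserved
exactly.

The lesion radius (`0.08` of the image side, floor 1.2 px) was chosen so
lesions stay salient after two pooling stages at $32 \times 32$, the size
the desk-scale experiments use; with the original smaller radius a small
CNN could not reliably separate the classes within a few epochs, which
would have made the generator useless as a search-quality oracle.

What passing tests on this generator do **not** show: robustness to the
photometric variability, resolution range, acquisition artifacts and label
noise of real fundus photographs. The generator validates the *search and
evaluation machinery*, not clinical performance.

## Study sizes and profiles

Two search-space profiles are built in. `pso_space("paper")` carries the
published initialization ranges (conv outputs 3–256, kernels 3/5/7, dense
1–300, $B_l = 3$, $B_u = 20$) and is what the cardinality calculus and a
GPU-scale user would use. `pso_space("desk")` is the package's scaled-down
study space — filters {4, 8, 16}, kernel 3, dense units {8, 16, 32, 64},
$B_u = 8$ — sized so that a complete search-plus-retraining experiment runs
in minutes on one CPU core with the built-in trainer. The desk-scale study
conditions used throughout the tests and the acceptance script are: the
easy generator profile (`synth_easy_spec()`: 600 images, 5 balanced
classes, $32 \times 32$, noise 0.02), PSO with $r = 1$, $i = 3$, $p = 5$,
1-epoch fitness evaluations, 5-epoch retraining of the global best, Adam
at learning rate $2 \times 10^{-3}$ with batch size 8. The balanced easy
profile isolates learnability from class imbalance; the APTOS-proportioned
default profile adds the realistic skew back.

$B_l$ and $B_u$ bound the *sampled trunk* of a candidate (conv / pool /
dense draws); batch-normalization and dropout attachments and the repair
pass may push the final layer count past $B_u$. This keeps the published
layer-probability semantics (0.7 conv / 0.15 pool / 0.15 dense over trunk
draws, with `BN` attached after every conv/dense draw — the published
initialization setting — and `DO` attached with probability 0.3 at rate
0.5)
while guaranteeing feasibility.

## Numerical choices and degenerate inputs

* Counting never touches floating point: an exact base-$10^7$ digit-vector
  integer is used (`bigint()`), with double carriers that stay below
  $2^{53}$.
* ACS argmax ties go to the lowest edge index; `gbest` fitness ties to the
  smaller model, then the incumbent.
* Pooling uses stride = pool side over full blocks; trailing rows/columns
  that do not fill a block are ignored, and pooling below $1 \times 1$ is
  an instantiation error naming the layer.
* Batch normalization uses biased batch variance, $\epsilon = 10^{-5}$,
  running-statistic momentum 0.9; evaluation mode uses running statistics.
* A non-finite training loss marks the candidate diverged (fitness 0 with
  a warning) instead of propagating.
* Kappa is `NA` with a warning when the expected agreement is 1;
  degenerate AUC classes (no positives or no negatives) are skipped with a
  warning and excluded from the macro average.
* The goal criterion records success as `metric + epsilon >= G` per
  configured metric (accuracy on the percent scale), with the published
  comparison bounds as defaults.

## Known limitations

* Sequential (chain) architectures only; no branching topologies.
* The trainer is CPU-bound R; it is honest but slow, intended for
  desk-scale studies and correctness, not for training at
  $128 \times 128$ with hundreds of filters.
* One search-quality acceptance check is inherently stochastic: the
  desk-scale PSO search is asserted to reach retrained validation accuracy
  $\ge 0.80$ on at least two of three fixed seeds, not on every seed.
* The published APTOS benchmark numbers require the external Kaggle
  dataset and GPU-scale training and are out of scope; the package
  reproduces the combinatorial quantities exactly and the search behavior
  qualitatively at toy scale.
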