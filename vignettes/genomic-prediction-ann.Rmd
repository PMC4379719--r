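---
title: "Genome-enabled prediction with single-hidden-layer neural networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-enabled prediction with single-hidden-layer neural networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpnet)
```

## The prediction problem

Genome-enabled prediction estimates the yet-to-be-observed phenotype of an
individual from its SNP genotypes, using a reference population in which
both genotypes and phenotypes are recorded. Linear mixed-model methods such
as GBLUP assume purely additive gene action; when interactions between loci
(epistasis) contribute, a model that is non-linear in its inputs can in
principle capture signal that linear methods ignore. gpnet implements one
such model: a single-hidden-layer feed-forward neural network trained by
regularized back-propagation, together with the linear benchmark it is
traditionally compared against and the cross-validation machinery used to
measure predictive ability.

## The network

For an individual with covariate vector $x \in \mathbb{R}^m$ (its genomic
data in one of the three encodings below), hidden neuron $t = 1, \dots, s$
computes

$$ z^{[t]} = f\!\left(a_t + \sum_{j=1}^{m} w^{[t]}_{1j}\, x_j\right), $$

with $f$ either $\tanh$ (non-linear mode) or the identity. The output
neuron combines the hidden basis functions linearly:

$$ \hat y = b + \sum_{t=1}^{s} w_{2t}\, z^{[t]}. $$

With identity activations throughout, the network collapses to an affine
map — `linear_coefficients()` constructs its slope $w_1^\top w_2$ and
intercept $b + w_2^\top a$ explicitly — so the one-neuron identity network
fed the genomic relationship matrix performs a multiple linear regression
on relationship covariates. That configuration
(`quasi_gblup_config()`) approximates GBLUP and is the benchmark arm of
every experiment; `ridge_oracle()` provides the closed-form penalized
least-squares solution used to verify the equivalence numerically.

## Training

Training minimizes the averaged mean squared error (aMSE) between network
output and the normalized phenotype, plus an L2 weight-decay penalty
$\lambda(\lVert w_1 \rVert^2 + \lVert w_2 \rVert^2)$ on the connection
weights; biases are not penalized so that the all-zero network keeps an
interpretable constant output. Gradients are computed exactly by
back-propagation (reverse-mode chain rule) and verified against central
finite differences in the test suite. The optimizer is full-batch gradient
descent with momentum. Two rules stop training: an iteration cap of 1000,
and a training-aMSE threshold of $10^{-3}$ on the normalized phenotype
scale; whichever fires first ends the run, and a tie is reported as the
threshold. Weights start at i.i.d. uniform values on $[-0.1, 0.1]$, drawn
from a per-run seed, so repeated cross-validation runs use genuinely
different initializations.

Defaults are learning rate 0.01, momentum 0.9, decay 0.01. These are
deliberately conservative: the appropriate learning rate depends strongly
on the input encoding, and the intended workflow — used by the package's
own evaluation scripts — is a one-off pre-processing adjustment per data
set with `grid_search_lr()`. With `validation_frac > 0` the grid scores
candidate rates on a held-out fraction rather than on the training error,
which is the right criterion when the rate is tuned for prediction. Two
behaviours observed on the package's synthetic data sets are worth
recording: raw-marker inputs (`X`) tolerate and need larger rates (around
0.1) than relationship inputs, and noiseless traits on G benefit from
heavier momentum (0.95) because the relationship columns make the
least-squares problem ill-conditioned and plain gradient descent converges
slowly along its weak directions. Divergence (non-finite aMSE) raises an
error naming the iteration rather than returning garbage.

## The three genomic encodings

Genotypes enter as allele counts 0/1/2, pass the QC filter (sample minor
allele frequency below 0.05 removed; missing-call fraction above 0.95
removed — the latter threshold is unusually permissive, is kept
configurable, and is flagged in the QC log), and are coded $-1/0/1$ with
the minor-allele homozygote at $-1$. Missing calls are mean-imputed per
marker. Three input structures are then available:

* **X** — the coded marker matrix itself ($n \times m$); the coding is its
  feature scaling.
* **G** — the standardized genomic relationship matrix
  $G = WW^\top / \left(2\sum_j q_j(1 - q_j)\right)$, where $W$ centers each
  column of $X$ by its expectation $2q_j - 1$ under Hardy–Weinberg
  proportions ($q_j$ = frequency of the $+1$-coded allele). This is the
  VanRaden construction expressed on the $-1/0/1$ scale; its average
  diagonal tends to 1 under Hardy–Weinberg genotypes, which the tests
  assert.
* **UD** — principal-component scores from the SVD $X = UDV^\top$, i.e.
  $XV$: an $n$-column re-expression that preserves the Gram matrix
  $(UD)(UD)^\top = XX^\top$ exactly, so G built from X and the Gram matrix
  of UD agree up to the G denominator. Singular-vector signs are pinned
  (largest-magnitude element of each right-singular vector positive) for
  reproducibility; all $n$ columns are kept.

G and UD are min–max scaled to $[-1, 1]$ before training. The scaling is
applied with the **whole-matrix** minimum and maximum by default, not per
column. This was a genuinely open design choice; the whole-matrix form was
adopted for two reasons. First, it is what the brnn-style normalization
function actually does when handed a matrix (a single affine map from the
global range). Second, and decisively for UD: a per-column map stretches
every principal component to full range, erasing the singular-value
weighting that makes the leading components informative — empirically the
UD input then carries almost no predictive signal, while whole-matrix
scaling (a single affine transformation, which preserves all relative
scale information) leaves it on par with G. Per-column scaling remains
available via `minmax_scale(per_column = TRUE)`.

## Phenotype normalization

Phenotypes are normalized to the network's working scale as
$y^* = (y - \mu_y)/\max_y$ with $\mu_y$ the sample mean and $\max_y$ the
sample **maximum** — the literal convention, which puts typical yield
deviations approximately (not exactly) into $[-1, 1]$. A trait whose large
negative deviations exceed its maximum in magnitude will leave that range;
`strict = TRUE` divides by $\max|y - \mu_y|$ instead and guarantees it. A
non-positive maximum is refused rather than silently sign-flipping the
scale. The transform stores $(\mu_y, \max_y)$ and inverts exactly, and
Pearson correlations are invariant under it, so reported predictive
ability does not depend on the scale. Inside cross-validation the
normalization statistics are recomputed from the training folds only;
genomic inputs, by contrast, are built once from the full genotype panel —
genotypes carry no phenotype information, so this mirrors feeding one
fixed G into the validation loop without leaking held-out phenotypes
(asserted bitwise in the tests).

## Cross-validation protocol

`make_folds()` cuts a fresh uniform permutation into $k$ near-equal folds
(remainder spread one-per-fold from the first fold) for each of `repeats`
randomizations; the canonical design, 5 folds repeated 20 times, yields
100 train/test evaluations. Each run trains from its own derived seed and
is scored by the Pearson correlation between observed and predicted
phenotypes on the held-out fold; `run_cv()` reports the per-run values,
their mean, and their population variance (the "variance over
cross-validation runs" convention of predictive-ability tables). Runs
that fail (divergence, undefined correlation) are recorded; more than 10%
failures aborts with a diagnostic. `run_experiment()` wraps the whole
pipeline over a grid of hidden-layer sizes (default 1–20) and always adds
the quasi-GBLUP benchmark arm.

## The synthetic data generator

No usable public genotype–phenotype data accompany the class of dairy-
cattle analyses this machinery targets, so the package ships a simulator
that is itself first-class, tested code. `simulate_genotypes()` draws each
marker's allele frequency uniformly from `maf_range` (default
$[0.05, 0.5]$) and genotypes from Hardy–Weinberg proportions,
independently across loci by default — independence keeps every
per-marker expectation exactly computable, which the binomial-CI oracle
tests exploit. Real SNP panels have linkage disequilibrium, which is
exactly why dense panels predict well when markers far outnumber
individuals; the optional `ld_blocks` mode (markers within a block share
latent gametes, giving strong within-block correlation) emulates that
structure and is used for the high-dimensional ($m \gg n$) evaluations,
where an LD-free panel of 3000 independent markers and 120 training
individuals would leave even the closed-form ridge oracle near zero
predictive ability — nothing for the input encodings to differ on.

`simulate_phenotype()` builds genetic values that are additive
($\sum_k \beta_k\, \tilde x_k$ on centered counts at sampled QTL), purely
epistatic (effects on pairwise products of centered counts — a trait with
no marginal additive signal in expectation, the regime motivating
non-linear prediction), or mixed. QTL effects are i.i.d. standard normal,
a standard choice where no architecture is prescribed. Gaussian noise is
projected orthogonal to the genetic values and rescaled against the
*realized* genetic variance, so the realized heritability equals the
target exactly and the phenotypic variance decomposes exactly — tight,
assertable behaviour even at small $n$. The defaults (sample sizes in the
low hundreds, 20 QTL, heritabilities 0.5–0.9 in the evaluation scripts)
are modest desk-scale stand-ins chosen to make each qualitative contrast
detectable at the 5×5-fold cross-validation size the evaluations use;
they emulate the statistical *structure* of dairy data (HWE genotypes,
quantitative traits with controlled $h^2$), not its scale, LD decay,
allele-frequency spectrum or pedigree structure. Passing tests therefore
demonstrate correctness of the machinery and the direction of the
qualitative contrasts, not cattle-scale accuracy values.

## Numerical choices and degenerate inputs

* Constant columns min–max scale to 0; the inverse restores the constant.
* A monomorphic-only panel (G denominator $2\sum q(1-q) = 0$) errors.
* Rank-deficient X is allowed in the SVD; trailing zero singular values
  are kept so UD is always $n \times n$.
* `pearson_r()` on a constant vector raises an explicit undefined-
  correlation error, never a silent 0.
* At allele frequency exactly 0.5 there is no minor allele; coding keeps
  the counted orientation (no flip).
* Both stopping rules firing on the same iteration reports the aMSE
  threshold.
* The finite-difference gradient checks use central differences with step
  $10^{-6}$ and a $10^{-4}$ relative floor.

## Problem sizes used by the evaluation suite

The packaged evaluations run at desk scale: benchmark-equivalence at
$n = 200, m = 500, h^2 = 0.5$; noiseless-trait recovery at
$n = 300, m = 100$; the epistatic contrast at $n = 400, m = 100$ with 4
QTL pairs at $h^2 = 0.9$ (a strong-signal setting fixed a priori); the
high-dimensional contrast at $n = 150, m = 3000, h^2 = 0.6$ with 20-marker
LD blocks; all with 5-fold cross-validation repeated 5 times. These sizes
were chosen as the smallest at which each effect is comfortably resolved
by 25 paired cross-validation runs.

## Known limitations

* Plain full-batch gradient descent is sensitive to the learning rate;
  the grid helper mitigates but does not remove this.
* The simulator has no pedigree, no multi-trait correlations, no
  sequence-level structure, and its LD model is a coarse block device.
* "Early stopping" here means the iteration cap, not validation-based
  stopping; a validation-split variant is not currently exposed.
* The mean/maximum normalization can leave $[-1, 1]$ for traits with
  heavy negative tails; use `strict = TRUE` for such traits.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_individuals = 200, n_markers = 300, h2 = 0.6,
                  n_qtl = 20, seed = 1)
ds  <- simulate_phenotype(simulate_genotypes(cfg), cfg)

coded <- code_genotypes(qc_filter(ds$genotypes))
g_in  <- build_input(coded, "G")

cv <- run_cv(g_in$values, ds$phenotype,
             ann_architecture(ncol(g_in$values), n_hidden = 4, "tanh"),
             training_config(seed = 1), k = 5, repeats = 5)
glance(cv)
autoplot(cv)
```
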