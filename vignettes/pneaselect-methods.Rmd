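---
title: "Active selection of non-experimentally annotated proteins: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active selection of non-experimentally annotated proteins: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pneaselect)
```

## The problem

Multi-label subcellular-localization predictors are conventionally trained
only on proteins whose location annotations are experimentally proven
(PEAs).  Those are a small and slowly growing minority of curated entries.
Entries whose `SUBCELLULAR LOCATION` comments carry one of the three
non-experimental evidence qualifiers — *Probable* (indirect experimental
evidence), *Potential* (computational or logical inference) and *By
similarity* (transfer from a close family member) — are several times more
numerous (PNEAs), but a fraction of their labels is simply wrong.  Adding
all of them to the training set imports label noise; adding none wastes
most of the available signal.  `pneaselect` implements an active
sample-selection strategy that scores every PNEA candidate by the
worst-case classification risk its addition would cause, keeps the
candidates whose worst case is still benign, and discards the rest.

## The risk model

Let $D_L = \{(x_i, y_i)\}_{i=1}^{n}$ be the trusted training set with
$y_i \in \{-1,+1\}^Q$ over $Q$ locations, and let $\tilde{x}$ be a
candidate with annotation statuses per location.  Certain coordinates
(experimental positives and unannotated negatives) pin the corresponding
entries of the candidate's actual label vector $\tilde{y}$; each
non-experimental positive may truly be $+1$ or $-1$, so with $m$ such
coordinates the feasible set of $\tilde{y}$ has $2^m$ elements.

For one hypothesized $\tilde{y}$, the risk of adding the candidate is the
minimized objective of a weighted, regularized kernel least-squares
problem over the augmented set:

$$
R(\tilde{x}, \tilde{y}) \;=\; \min_{f_1..f_Q \in \mathcal{H}}
\frac{1}{n+1}\sum_{i}\sum_{j=1}^{Q} \omega_{ij}\,(f_j(x_i) - y_{ij})^2
\;+\; \gamma \sum_{j=1}^{Q} \lVert f_j \rVert_{\mathcal{H}}^2 ,
$$

where $\mathcal{H}$ is the RKHS of the Gaussian kernel
$k(x, x') = \exp(-\lVert x - x'\rVert^2 / 2\sigma^2)$ and the sum over $i$
runs over $D_L$ plus the candidate.  By the representer theorem each
$f_j$ is a kernel expansion over the augmented points, and the expansion
coefficients solve, per label,

$$
(W_j K + N\gamma I)\,\alpha_j = W_j\, y_{\cdot j},
$$

with $K$ the Gram matrix, $W_j$ the diagonal weight matrix of label $j$
and $N$ the augmented size; the stacked $Q$-label system is block
diagonal (the Kronecker product of the label identity with $K$).  We
solve the equivalent symmetric system
$(\,\mathrm{diag}(\sqrt{w})\,K\,\mathrm{diag}(\sqrt{w}) + N\gamma I\,)$ by
Cholesky factorization, with a $10^{-10}$ jitter retry on near-singular
input (near-duplicate proteins); a system that remains singular raises an
error suggesting a larger $\gamma$.  The closed form is verified in the
test suite against direct numerical minimization (BFGS with analytic
gradient) of the written-out objective to $10^{-6}$.

The risk is reported per-sample-averaged (the $1/(n{+}1)$ above) so that
evaluation values remain comparable as the training set grows.

### Label confidence weights

The weight $\omega_{ij}$ expresses how much a loss term can be trusted.
Certain statuses get weight 1.  A non-experimental positive gets the
posterior probability that its annotation is the actual label, combining
an evidence-type prior $p$ with Parzen-window class-conditional densities
estimated on the certain set:

$$
\Pr(\text{label correct} \mid x) =
\frac{p\,\hat{d}_{\mathrm{own}}(x)}
     {p\,\hat{d}_{\mathrm{own}}(x) + (1-p)\,\hat{d}_{\mathrm{opp}}(x)},
$$

where $\hat{d}_{\mathrm{own}}$ averages the Gaussian kernel over certain
samples positive for the label and $\hat{d}_{\mathrm{opp}}$ over certain
negatives.  The construction has the limits one wants: exactly symmetric
evidence returns the bare prior, a vanishing opposing density returns 1,
the posterior is monotone in the prior, and an infinite bandwidth (all
points look alike) recovers the prior.  When a label has no certain
positives or no certain negatives the bare prior is used with a warning
(configurable to an error).

Default priors follow the relative strength of the qualifiers: 0.85
(*Probable*), 0.80 (*Potential*), 0.75 (*By similarity*).

### Worst-case evaluation and ranking

The candidate's evaluation value is its worst case over the feasible set,
$J(\tilde{x}) = \max_{\tilde{y}} R(\tilde{x}, \tilde{y})$, enumerated
exhaustively (the default cap of $m \le 12$ non-experimental coordinates,
4096 assignments, is far beyond what real annotations carry; there is no
approximate fallback).  Ties take the lexicographically smallest
assignment, $-1$ before $+1$, so results are order-independent.  A low
$J$ means that *no matter which way* the uncertain labels resolve, the
candidate fits the current model cheaply — it is safe to adopt.  A
candidate whose pinned or uncertain labels conflict with its neighborhood
is expensive under every assignment and ranks last.

`rank_pool()` sorts the pool ascending by $J$ (ties by candidate id).
The default `single_pass` mode scores all candidates against the fixed
training set, which directly produces the full ranking the proportion
rule needs; `sequential` mode instead accepts the current minimizer,
commits it to the training set (weights retained) and re-scores the
remainder, which matches a strictly incremental reading of the procedure
at $O(n_U^2)$ evaluations.  Both are exposed; the mode is recorded in the
ranking object.

### The preferred proportion

How much of the ranked pool to keep is decided from the stabilization of
the evaluation-value change rates
$r_i = (J_{i+1} - J_i)/J_i$ (a zero denominator is guarded with
$10^{-12}$).  The ranking is split into $T$ contiguous intervals of
proportion $s$ each ($s = 10\%$, $T = 10$ by default, so
$\theta^\* \in \{10\%, \dots, 100\%\}$).  With $R_t$ the mean change rate
inside interval $t$ and $\bar{R}$ the overall mean rate, the preferred
proportion is $\theta^\* = s\,t^\*$ where $t^\*$ is the longest prefix of
intervals with $R_t \le \bar{R}$: while evaluation values grow slowly the
ranked candidates are comparably useful, and the first interval whose
growth exceeds the overall level marks the point past which additions
stop helping.  If no interval exceeds $\bar{R}$ (e.g. a flat curve) the
whole pool is kept; $\theta^\*$ is never below $s$.  The rule is
parameter-free given $(s, T)$; pools smaller than $T$ leave some
intervals empty, which are treated as stable, with a warning.  Selected
candidates are committed with their non-experimental positives as $+1$,
carrying their posterior weight for weight-aware retraining
(weight-unaware classifiers receive the hard labels).

## Features

Sequences are embedded with the amphiphilic (series-correlation) pseudo
amino acid composition: 20 residue frequencies plus, for each of $m$
physicochemical property scales and each lag $j = 1..\lambda$, the mean
lagged product of standardized property values, weighted by $w$ and
jointly normalized so the $20 + m\lambda$ components sum to 1.  Defaults
follow the study settings: $\lambda = 5$, $w = 0.4$, and the three
classical scales hydrophobicity, hydrophilicity and side-chain mass
($d = 35$); the scales ship as auditable TSV files and are standardized
to zero mean and unit population SD over the 20 residues.  The $m$ used
is configuration: with a different property list the dimension changes
accordingly.  Since correlation terms can be negative, the normalizer
$1 + w\sum\tau$ is guarded ($\le 10^{-9}$ raises an error rather than
returning unstable features).  Non-canonical residues (B/J/O/U/X/Z) are
rejected by default; a `drop_ambiguous` flag removes them from the
composition counts instead.

## Shared numerical choices

* **Bandwidth.** One Gaussian $\sigma$ serves both the Parzen posterior
  and the risk model.  The default is the median pairwise distance of the
  certain set (median heuristic), overridable with any positive number.
* **Regularization.** $\gamma = 0.1$ by default; the solver is stable for
  $\gamma \ge 10^{-8}$ on non-duplicate data.
* **Rounding.** The selected count is
  $\lfloor \theta^\* n_U + 0.5 \rfloor$ (at least 1); selections are
  nested across the $\theta$ grid by construction.
* **Rank ties.** All score-to-rank conversions (metrics, prediction sets)
  break ties toward the lower label index, making every reported number
  deterministic.

## Evaluation metrics

Six metrics are computed from predictions on a test set.  Accuracy, MCC
and F1 are pooled over all $n \times Q$ (sample, label) decisions — the
pooling that matches locative-protein counting, where a protein in $N$
locations contributes $N$ decisions.  Average precision, ranking loss and
coverage are the standard multi-label ranking definitions over per-label
confidence scores; an MCC denominator of zero returns 0 with a warning;
a sample with empty truth is an error (ranking loss undefined).  All six
are verified against brute-force pair/prefix enumeration in the tests.

## Baseline classifiers

The selection strategy is classifier-agnostic, so the retrain-and-compare
loop is exercised with two transparent baselines rather than
re-derivations of published models: a multi-label k-NN (Laplace-smoothed
neighbour vote, scores in $(0,1)$, threshold 0.5) and a weight-aware
kernel ridge one-vs-rest scorer reusing the risk model's solver
(threshold 0).  Predictions are never empty: when no label clears the
threshold the top-ranked label is emitted.  For corruption-sensitivity
comparisons the k-NN baseline is the informative one — it consumes hard
labels, so wrong supplement labels genuinely hurt it, whereas the
weight-aware scorer largely neutralizes them through the posterior
weights.

## The synthetic generator

`generate_study()` emulates the data situation the method addresses,
with the selection math isolated from sequence handling: $Q$ class
centers at separation `class_separation` (default 3) along orthogonal
axes, unit isotropic Gaussian noise, a second true label with probability
`multilabel_rate` (default 0.2, about the locative inflation seen in
curated localization datasets; a two-label sample sits between its two
centers), and a pool whose true positives are displayed as
non-experimental positives of a random evidence type and *moved to a
wrong location* with that type's corruption probability (defaults
$1 - \text{prior}$: 0.15 / 0.20 / 0.25).  Corruption relocates rather
than deletes a positive because wrong positives, not missing ones, are
what the worst-case risk is designed to catch.  Hidden truth lives in
separate fields that never enter the pool's statuses.  Default sizes
(train 60, pool 200, test 100, $Q = 4$, $d = 10$) keep a full ranking of
the pool in the low seconds on one core.

What the generator does **not** emulate: sequence homology and redundancy
structure, class imbalance of real compartments, non-Gaussian feature
geometry, and annotation biases that correlate corruption with feature
position.  Passing tests therefore demonstrate the machinery and its
statistical direction (enrichment of correct labels, improvement over
no-supplement training), not performance figures transferable to real
proteomes.  For real data, the package reads FASTA plus a per-(protein,
location) evidence TSV (or a minimal UniProt flat-file subset), applies
the fragment/length-50 quality filters, and an external identity-culling
keep-list can be applied by subsetting the labeled set (`set[idx]`)
before selection.

## Protocol

`run_cv_experiment()` reproduces the select–retrain–evaluate comparison
under repeated k-fold cross-validation (defaults 10 randomizations × 10
folds): per fold the held-in portion is augmented per arm — `none`,
`top_theta` (selection recomputed against that portion only, so the
held-out fold never informs the ranking), `all` — and the six metrics of
the held-out fold are recorded.  Metrics are averaged over folds within a
randomization; reported mean ± SD is over randomizations.  Pool samples
are never scored.  `run_independent_test()` is the single train/test
variant.  Per-fold re-selection is the default (a global precomputed
selection would leak fold-test information into the ranking); both
entry points are deterministic given their seed.

## Known limitations

* The preferred-proportion rule is a heuristic; there is no optimality
  guarantee for $\theta^\*$, and on pools whose risk curve rises smoothly
  the chosen cut can sit anywhere on the grid.
* Worst-case enumeration is exponential in the number of
  non-experimental labels of a single candidate (capped at 12).
* `sequential` ranking costs $O(n_U^2)$ candidate evaluations and is
  impractical for pools beyond a few hundred.
* Posterior estimates inherit the usual Parzen-window small-sample
  variance; with very few certain samples per label the weights revert
  toward the priors.
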