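---
title: "Hybrid oversampling for imbalanced activity recognition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid oversampling for imbalanced activity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harsmote)
```

## The problem

Wearable-sensor activity datasets are almost always imbalanced: people walk
far more than they jump, and short gestures yield few labelled windows.
A classifier trained on such data learns the majority activities well and
largely ignores the rare ones, which are often exactly the activities of
clinical interest (falls, stair use, hand-to-mouth gestures). `harsmote`
addresses this at the data level: it synthesises new minority-class feature
vectors so that the *training* split — and only the training split — is
rebalanced before a classifier sees it.

## Samplers

All six constituent methods and the three hybrids operate per minority
class. With majority count $n_{maj}$ and class count $n_c$, a sampling
percentage $\alpha$ requests $\mathrm{round}(\alpha\,(n_{maj}-n_c))$
synthetic rows for class $c$; $\alpha = 1$ (the package default and the
setting used throughout the evaluation harness) brings every class to
parity.

**SMOTE.** A seed $x$ is drawn uniformly from the minority class, a partner
$x_k$ uniformly from the seed's $k$ nearest same-class neighbours
(Euclidean metric, $k = 5$ by default), and the synthetic point is
$x_{new} = x + u\,(x_k - x)$, $u \sim U[0,1)$. Some presentations write the
update with a scalar distance $\lVert x - x_k\rVert$ multiplying the random
draw; that form is dimensionally inconsistent with a vector-valued
$x_{new}$, and the accompanying prose always requires the synthetic point
to *lie on the line between* the two samples, so this package implements
componentwise interpolation. This reading is load-bearing for every method
below and is asserted by the geometric test suite (synthetics must lie on
their recorded seed–neighbour segments).

**Random-SMOTE.** Two further minority rows $x_1, x_2$ (both distinct from
the seed $x$) are drawn; a temporary point $x_{tmp} = x_1 + u_1(x_2 - x_1)$
is placed between them and the synthetic point $x + u_2(x_{tmp} - x)$
between it and the seed — i.e. inside the closed triangle $(x, x_1, x_2)$,
opening a 2-D synthesis region where SMOTE only offers 1-D segments. With
fewer than three minority rows the method falls back to 1-NN SMOTE (the
provenance records the fallback).

**SMOTE + Tomek links.** After SMOTE brings the classes to parity, every
cross-class mutual-nearest-neighbour pair (Tomek link) in the *augmented*
set is located and **both endpoints** are removed, whether original or
synthetic. The link definition is applied verbatim: $(x_a, x_b)$ is a link
iff no $z$ has $d(x_a,z) < d(x_a,x_b)$ or $d(x_b,z) < d(x_a,x_b)$. Removing
both endpoints (rather than only the majority one) follows the convention
of the classic SMOTE+Tomek pipeline; the documented consequence is that the
output may sit slightly off perfect parity, by exactly the number of logged
removals per class.

**MSMOTE.** Each minority row is first typed by its $k$ nearest neighbours
in the full training set: *safe* if all $k$ share its class, *noise* if
none do, *border* otherwise. Safe seeds interpolate toward one of their $k$
nearest minority neighbours; border seeds only toward their single nearest
one; noise rows are disregarded — in this implementation they are excluded
both as seeds and from the neighbour candidate pool, so no synthetic point
is ever pulled toward suspected label noise. When every row is safe the
procedure reduces to SMOTE exactly (bit-identically under a shared seed —
both routes share one interpolation core with the same RNG call sequence).

**CBSO.** Minority rows are clustered by average-linkage agglomeration, cut
at height $T = c_{th} \times$ (mean nearest-minority-neighbour distance),
$c_{th} = 3$. Seeds are drawn with probability proportional to a border
weight — the fraction of other-class points among the seed's $k$ all-class
nearest neighbours — and partners uniformly from the seed's own cluster, so
synthesis concentrates near the class boundary and never bridges separate
minority clusters (a singleton cluster duplicates its seed). The linkage,
threshold form and weighting are declared package defaults: the method
description in the literature defers these details to its reference
implementation.

**ProWSyn.** Minority rows are peeled into proximity levels: level 1
collects every minority row appearing among the $k$ nearest remaining
minority neighbours of any majority row, the peel repeats on the remainder,
and after `max_levels − 1` (default 4) passes everything left gets the last
level. Level weights decay exponentially, $w(l) \propto e^{-\theta(l-1)}$
with $\theta = 1$, and the per-level synthetic allocation is proportional
to total row weight, rounded by largest remainder so allocations sum
exactly to the request. Generation is SMOTE-style within each level. The
exponential weight form and defaults (`max_levels = 5`, $\theta = 1$,
$k = 5$) follow the method's reference implementation; the qualitative
requirement — boundary-near levels dominate — is what the tests pin down
(weights strictly decrease; $\theta \to \infty$ sends all synthesis to
level 1).

## The hybrid combinators

DBM (distance-based) concatenates SMOTE + Random-SMOTE; NDBM
(noise-detection-based) concatenates SMOTE-with-Tomek-cleaning + MSMOTE;
CBM (cluster-based) concatenates ProWSyn + CBSO. Both constituents run
independently on the *same* training split with the same $\alpha$ but
independent RNG substreams, and their synthetic batches are concatenated
over a **single** copy of the original rows. Two design points are worth
making explicit:

* *One copy of the originals.* The combination is described as
  concatenating *synthesised* data; duplicating the original rows would
  silently double-weight every real sample. Consequently, at $\alpha = 1$
  hybrid minority classes overshoot the majority count — counts
  `{A: 20, B: 5}` yield `B = 5 + 15 + 15 = 35` under DBM. This follows the
  combination rule taken literally and is deliberately not rebalanced.
* *Cleaning.* Only the Tomek step deletes rows. For NDBM, originals deleted
  by it are removed from the shared copy; MSMOTE's noise rows are merely
  unused, never deleted. DBM and CBM never remove anything, so the exact
  counting identity `|augmented| = |train| − |removed| + |batch A| +
  |batch B|` holds on every run and is asserted on every run.

## Preprocessing

Raw tri-axial records are collapsed to the orientation-invariant magnitude
$\sqrt{x^2+y^2+z^2}$, segmented into non-overlapping windows of
`window_seconds` (the trailing partial window is discarded), and summarised
by six time-domain features: mean, standard deviation, minimum, maximum,
median and range. Numerical conventions, chosen once for
bit-reproducibility where the convention is otherwise unstated:

* standard deviation uses the population form (divide by $n$);
* an even-length median averages the two central order statistics;
* a mixed-label window keeps its modal label, ties broken toward the
  earlier class in `class_names` — modal labelling is the least destructive
  deterministic rule for boundary windows;
* windows whose modal label is the null/background class are dropped before
  any sampling or classification.

## Leakage-safe evaluation

Oversampling before splitting leaks synthetic copies of test information
into training data and inflates scores. The harness therefore folds first
(stratified, because with 20:1 imbalance an unstratified 3-fold split can
lose a class entirely), oversamples each training fold only, and scores on
the untouched test fold. `leakage_guard()` audits every oversampled fold:
every provenance index must point inside the training split and no test row
may appear in the augmented data (an exact duplicate that also equals a
training row is reported as a coincidence, not a failure). A guard failure
aborts the experiment rather than producing a contaminated score.

Scores are weighted F1 / recall / precision with weights $w_i = n_i/N$ from
the true labels; a class never predicted gets precision 0, and a class term
with $P_i + R_i = 0$ contributes 0. Under these weights the weighted recall
equals plain accuracy, which the tests assert numerically. Per-cell scores
are the mean over folds, then mean ± sd over repetitions (the nesting order
is a documented package choice).

Classifiers are pluggable behind a `fit`/`predict` contract; the roster is
KNN, multinomial logistic regression, an RBF SVM, a random forest (library
defaults), and a multilayer perceptron with one hidden layer of 100 ReLU
units trained by minibatch Adam on softmax cross-entropy (learning rate
0.001, L2 penalty $10^{-4}$, up to 200 epochs, batch `min(200, n)`, early
stop after 10 epochs without a $10^{-4}$ loss improvement). No installed R
package offers that architecture/optimiser pairing, so the training loop is
implemented in compiled code inside the package; weight initialisation and
epoch shuffles are drawn from the package's explicit RNG handle, making
fits bit-reproducible. Features enter classifiers unscaled; the samplers
likewise use the raw Euclidean metric.

## Statistical comparison

A classifiers × sampling-methods score matrix is screened with the
Anderson–Darling normality test on its flattened cells (for the canonical
5 × 9 roster that is 45 values); if normality is not rejected at
$\alpha = 0.05$ the methods are compared by one-way ANOVA (between-methods
df $= k - 1$), otherwise by the Friedman rank test. Friedman ranks each
classifier row 1 (worst) to $k$ (best), ties averaged, and refers
$\chi^2 = \frac{12}{nk(k+1)}\sum_j R_j^2 - 3n(k+1)$ to $\chi^2_{k-1}$ (no
exact small-sample tables; the $\chi^2$ approximation matches the df/p
presentation of the published comparison this package reproduces). The
Anderson–Darling statistic uses estimated mean and variance, the
small-sample correction $A^{*2} = A^2(1 + 4/n - 25/n^2)$, and the standard
piecewise-exponential p-value map; the uncorrected $A^2$ is cross-checked
against an independent reference implementation in the tests. Worked
examples: the two shipped 5 × 9 rank tables (`example_rank_matrices()`)
reproduce $\chi^2 = 21.8133$ and $24.2133$ with df 8, and their column sums
reproduce the published sum-of-ranks rows.

## The synthetic-data generator

Two tiers. The raw tier emits labelled tri-axial recordings — per-activity
sinusoids with activity-specific amplitude and frequency, Gaussian noise, a
gravity offset on one axis, and random phases — and exists to exercise the
full preprocessing chain (durations, window counts, null-label handling,
orientation invariance). The feature tier emits 6-D Gaussian class clouds
directly and exists to give precise geometric control for the sampler
oracles and the evaluation experiments.

The default feature scenario is five classes with counts
200/30/20/15/10 (majority : smallest = 20 : 1), class means at distance 1.2
along distinct coordinate axes, and within-class spreads falling from 1.3
(majority) to 0.5 (rarest). The descending spreads mirror how activity
window features behave in practice — common locomotion is diffuse and
heterogeneous, rare dynamic activities form tight distinctive clusters —
and they matter methodologically: they keep minority rows locally dense
enough that MSMOTE's typing finds same-class neighbours, while the heavy
overlap with the broad majority still makes the baseline classifier miss
minority windows, which is precisely the regime oversampling is for. With
equal spherical variances no single separation achieves both at once.

What the generator does **not** emulate: subject-level variability,
autocorrelation between adjacent windows, non-Gaussian feature marginals,
and concurrent/transitional activities. Passing tests therefore demonstrate
the samplers' contracts and the harness's integrity, not absolute
performance on any real benchmark; reproducing published absolute scores
requires the corresponding public datasets, which this package deliberately
reads only through its generic CSV interface.

## Problem sizes and runtime choices

The repeated experiment used by the test suite and the acceptance script is
the default scenario (275 windows) × 3 stratified folds × 30 repetitions ×
all nine samplers plus baseline, scored with the MLP — the classifier for
which sampling matters most. Property suites use 50 random imbalanced
datasets for the balance rule and 1000 synthetics per geometric audit.
These sizes were chosen to estimate every reported quantity stably (30
repetitions match the repeated-evaluation design the harness implements)
while remaining desk-scale.

## Known limitations

* Sampling percentages are per-class fractions of the gap to the majority;
  schemes that target a global class distribution are out of scope.
* No undersampling, no ENN-style cleaning beyond Tomek links, no
  cross-family hybrids (e.g. distance + cluster).
* Frequency-domain features and multi-sensor fusion are out of scope for
  the preprocessing chain.
* The Friedman test stops at the omnibus statistic and rank sums; post-hoc
  pairwise procedures are not provided.
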