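---
title: "Structured logistic regression for protein sequence classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured logistic regression for protein sequence classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqslr)
```

## The model

seqslr classifies protein sequences with *structured logistic regression*:
an ordinary logistic regression whose features are occurrence indicators of
contiguous subsequences ("predictors") of unrestricted length. For a
sequence $x$ the decision function is

$$f(x) = b + \sum_{j=1}^{k} w_j\, I(s_j \sqsubseteq x),$$

where $s_j$ is the $j$-th selected predictor, $I(s_j \sqsubseteq x)$ is 1
exactly when $s_j$ is a contiguous substring of $x$ (anywhere, any number of
times), and $P(y = +1 \mid x) = \sigma(f(x)) = 1/(1+e^{-f(x)})$. Features
are binary indicators, not counts, and there is no intercept by default
($b = 0$); a bias slot exists for completeness and is persisted with the
model. Sequences are treated as plain strings over the 20 amino-acid
letters plus B/X/Z/U/O — a predictor containing `X` matches only a literal
`X`. No assumption is made about residue composition, alignment, or motif
grammar: the data alone drive predictor selection, and the fitted model is
directly interpretable as a list of positively and negatively weighted
subsequences.

## Training: coordinate-wise ascent with a branch-and-bound search

Given labeled sequences $\{x_i, y_i\}$, $y_i \in \{+1, -1\}$, training
maximizes $L = \sum_i \log \sigma(y_i f(x_i))$ one coordinate at a time.
Each iteration:

1. **Search** the space of *all* substrings of the training corpus for the
   coordinate with the largest absolute gradient
   $\partial L / \partial w_s = \sum_i y_i\, I(s \sqsubseteq x_i)\,
   \sigma(-y_i f(x_i))$.
2. **Line-search** the selected coordinate: the 1-D restriction of $L$ is
   concave, so the maximizer is bracketed by doubling steps and located by
   bisection on the derivative sign.
3. **Update** the cached decision scores of the affected sequences.

The search is exact, not heuristic. Substrings form a lattice under
right-extension: every substring of length $\ell+1$ extends a corpus
substring of length $\ell$, and its occurrence set is a subset of its
prefix's. Consequently

$$\mu(s) = \max\Big(\sum_{i:\, s \sqsubseteq x_i,\, y_i = +1}
\sigma(-f(x_i)),\ \sum_{i:\, s \sqsubseteq x_i,\, y_i = -1}
\sigma(f(x_i))\Big)$$

bounds $|\partial L / \partial w_t|$ for *every* superstring $t$ of $s$,
so a breadth-first expansion from single characters can prune any node
whose bound cannot beat the best gradient already seen. This is what makes
predictors of unrestricted length tractable; the test suite verifies on
hundreds of random corpora that the pruned search returns exactly the
brute-force maximum. Ties are broken deterministically (shortest predictor
first, then lexicographic order), which the breadth-first,
alphabet-ordered traversal yields for free. Occurrence lists never change
during a training run, so the first three lattice levels are computed once
and reused by every iteration; only the per-sequence sigmoid weights are
recomputed.

### Stopping, separation, and numerical choices

Iteration stops when the best absolute gradient falls below `grad_tol`
(default $10^{-4}$), when the relative log-likelihood gain falls below
`loglik_rel_tol` (default $10^{-9}$), or at `max_iters` (default 1000).
Re-selecting an already chosen predictor updates its weight in place, so
models stay compact. Each accepted step provably does not decrease $L$:
the line search returns the bracket endpoint approached from the current
weight through a region of positive directional improvement, so monotone
ascent holds exactly rather than to tolerance (asserted at $10^{-12}$ in
every training run of the test suite).

The unregularized likelihood has no finite maximizer when a predictor
perfectly separates the classes — common here, since a subfamily motif may
occur in every positive and no negative. Such weights are clamped at
$\pm$`w_max` (default 50, where $\sigma$ saturates far below double
precision) and the model flags `separation`. No penalty is applied by
default; the model-file header records the full training configuration so
a persisted model documents how it was fit. Probabilities and
log-likelihoods use stable log-sigmoid forms and cannot overflow at any
score magnitude. Cached scores are refreshed from scratch every
`refresh_every` (default 25) iterations to guard against incremental
drift. Training is deterministic: identical data and configuration give
identical models, bit for bit.

`min_support` (default 1) excludes candidates occurring in fewer training
sequences; it exists because support is anti-monotone, so raising it
shrinks the search dramatically on large corpora. `min_len`/`max_len`
bound predictor length (defaults 1/unbounded); restricting predictors to a
minimum length is occasionally useful when single-residue predictors are
suspected of driving misclassification.

## Multiclass classification with rejection, and self-training

The 11 P-type ATPase subfamilies (IA-VB) are handled one-vs-all: one
binary model per class, trained with that class's members as positives and
everything else as negatives. All 11 probabilities are stored for every
sequence. A sequence is assigned to the maximum-probability class, ties
broken by class-list order; if every probability is below 0.5 it is
rejected into class "0" with an assigned score of 0.5. The stored
probabilities preserve how far a rejected sequence was from any class.

Unregularized likelihood training on separable data leaves margins
arbitrary: once every training sequence is classified, the weights of
rarely-informative features are unconstrained, so near-ubiquitous one- and
two-residue predictors can accumulate into a deep surrogate intercept and
a predictor memorizing a single training sequence can ride to the
separation clamp. For one-vs-all models trained on a few dozen positives
this hurts generalization measurably. The recommended cascade
configuration therefore sets `fit_bias = TRUE` (the intercept absorbs the
class prior, removing the gradient that otherwise drags ubiquitous short
predictors down), `min_support = 5` (a subfamily signature must recur
across sequences; smaller support memorizes individuals) and
`min_len = 3` (one- and two-residue predictors are exactly the degenerate
"motifs" known to drive misclassification in this setting). An L2 penalty
(`l2 > 0`) is available as an alternative guard against separation; it is
not used for the cascade because a penalty applied uniformly lets the
hundreds of negatives out-pull the handful of positives that carry only
one of a class's motifs. Even so, margins for evidence patterns absent
from a training split remain partly arbitrary — a structural property of
the estimator, not a tuning failure — and class members whose only motif
was never forced into their class model can still be rejected.

Because curated seed labels are typically scarce relative to the sequences
to be classified, `retrain_until_stable()` implements self-training: round
0 trains on the seed set and labels the test set; each later round
retrains on the seed set plus the test sequences under their current
labels and relabels the whole test set, until the label vector reaches a
fixed point. Three design points the procedure leaves open were resolved
as follows. Class-0 sequences are excluded from retraining (they carry no
class to train on); seed labels are never overwritten; and two guard rails
were added because self-training can in principle oscillate — a
`max_rounds` cap (flagged "not converged") and detection of a label vector
repeating a non-adjacent earlier round (flagged "cycle"). Stopping at a
fixed point makes the final labeling idempotent by construction, which the
tests verify by running one extra round.

## Evaluation

`kfold_split()` stratifies by label, dealing shuffled members round-robin
so per-fold counts differ by at most one. Stratification is the default
because the motivating regime is a needle-in-a-haystack: a few hundred
positives among tens of thousands of negatives, where unstratified folds
can easily contain no positive. `roc_auc()` is the Mann-Whitney
probability with half-credit ties, identical to the trapezoidal area under
the ROC curve; the tests check it against an $O(n^2)$ pairwise oracle and
against an independent reference implementation at $10^{-12}$.
`cross_validate()` reports per-fold and pooled metrics and exports both
the fold assignment and every held-out score, so the same folds can be
reused by another method and every number recomputed independently. TP/FP
rates use the inclusive probability cut-off 0.5, the same midpoint rule as
screening.

## Curation and topology decomposition

Curation emits *flags*, never deletions: length outliers (outside
600-2000 residues; under 50 residues additionally marked as removal
candidates) and phosphorylation-motif status. `scan_motif()` reports every
window at Hamming distance at most `max_mismatch` from DKTGT
(substitutions only — the variants of interest are single point
mutations), so sequences carrying a mutated motif are distinguishable from
those lacking it entirely; variant sites are marked as needing external
homology review, which is out of scope here. Because flags never mutate
sequences, classification results are identical with curation on or off.

The membrane topology of a P-type ATPase decomposes into a 6-helix core
(M1-M6) flanked by optional N- and C-terminal helix elements. The anchor
is the DKTGT motif, which sits in the cytosolic loop after core helix M4:
with $m$ helices ending before the motif, the core is helices $m-3 \dots
m+2$, giving $n = m - 4$ N-element and $c = \text{total} - (m+2)$
C-element helices, and one of six categories (`core_only`, `N_core`,
`core_C`, `N_core_C`, `core_1TM`, `broken_core`). Edge rules chosen here:
a helix *containing* the motif position counts as before it (with a
warning — in real pumps the motif is cytosolic, so this indicates a noisy
prediction); when several DKTGT sites exist the first anchors the
decomposition and the extras are listed; `core_1TM` is applied
structurally ($n=0, c=1$) to any class rather than being reserved for the
one subfamily where it is typically observed; and sequences with no
anchor at all get the bookkeeping category `unanchored`, which is excluded
from the six-category summary table and counted separately. Helix-count
conservation $n + 6 + c = \text{total}$ holds for every intact-core
record, and the decomposition is invariant under shifting all coordinates.

## What the synthetic generator emulates — and what it does not

All tests and the acceptance script run on synthetic data with known
ground truth. `synthetic_spec()` describes i.i.d. background residues
(uniform by default) with class motifs planted at uniform random
positions, extreme class imbalance, uniform length variation (400-1200
residues, the typical span of the target family), truncation of a
configurable fraction of sequences to 10-50% fragments (default 0.05),
and post-planting substitution noise (default 0.005 per residue, always
changing the residue). Negatives and decoys are rejection-sampled to be
provably motif-free. The defaults are the study conditions; they were
chosen once and are not adjusted per test. For the multiclass benchmark
each class carries two independent 8-mer motifs at 95% presence each,
mirroring real subfamilies with several independently conserved signature
segments and leaving only $\sim 0.25\%$ of members with no class signal.

Two consequences of the generator design are worth stating plainly.
First, a class member that carries none of its motifs is *exactly* a
background sequence: no classifier can score it above a decoy. With
single-motif presence $p$, expected held-out AUC is therefore capped near
$1 - (1-p)/2$ (about 0.975 at $p = 0.95$), and fragmentation lowers it
slightly further; the benchmark suite measures ~0.974. This ceiling is a
property of the generating process, not of the fitting algorithm — on
fully separable data (presence 1, no fragments) held-out AUC is
indistinguishable from 1 and the held-out false-positive rate is 0 at
$\geq 95\%$ recall. Second, uniform background makes the planted motif
the *only* signal, which real proteomes are not: compositional bias,
homology between training and test sequences, and phylogenetic
correlation are all absent. Passing these benchmarks therefore
demonstrates the correctness and the imbalance behaviour of the
machinery, not field performance on real databases. The same arithmetic
bounds the 11-class benchmark: with two motifs per class at presence
0.95 and 5% fragmentation, roughly 2.5-3% of members end up with no
intact class motif, so held-out assignment accuracy is capped near 97%,
and the margin arbitrariness discussed above costs a further few percent
on unlucky splits — the benchmark suite measures 92-95% across seeds
with the recommended cascade configuration.

Problem sizes used by the test suite were chosen to exercise the
documented regimes: 200/2,000 sequences for the identification benchmark
(100 independent seeds), 100/10,000 for the false-positive-control
benchmark (10 seeds), 550 members + 100 decoys for the 11-class cascade,
and exhaustive-enumeration oracles on corpora small enough to enumerate
(up to 50 sequences of length 30).

## Known limitations

* Matching is exact and contiguous: no gapped, position-specific, or
  mismatch-tolerant predictors inside the model (mismatch scanning exists
  only in curation).
* No probability recalibration across the 11 one-vs-all classifiers; the
  0.5 rejection rule treats the raw outputs as comparable.
* The unregularized fit clamps rather than penalizes separated weights; an
  L2 path would change reported weights (not rankings) and is deliberately
  not enabled by default.
* Scores are not normalized by sequence length; long sequences containing
  a positively weighted predictor by chance score the same as short ones.
* TM-helix prediction and homology (BLAST-style) validation are consumed
  as inputs, never computed.
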