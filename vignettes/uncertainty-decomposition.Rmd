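---
title: "Site-of-metabolism prediction with deep-ensemble uncertainty decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-of-metabolism prediction with deep-ensemble uncertainty decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A site of metabolism (SOM) is the atom of a xenobiotic at which a metabolic
reaction is initiated. Predicting SOMs is an atom-level binary
classification task on molecular graphs: each heavy atom carries a label
$y_i \in \{0, 1\}$, and a model must output a per-atom probability that the
atom is metabolically labile. Because experimental SOM annotation is noisy,
incomplete and expensive, a useful predictor must report not only a
probability but also *why* that probability should or should not be
trusted. `uqsom` does this by training a deep ensemble and decomposing each
atom's predictive entropy into an aleatoric component (label noise) and an
epistemic component (insufficient training coverage).

## The model

Each ensemble member is an edge-aware message-passing network:

* **Convolutional module** — $L$ GINE-style layers (default $L = 4$, width
  500). Layer $l$ computes, for atom $i$ with neighbours $j$,
  $$m_{ij} = \mathrm{ReLU}(h_j + W_e\, e_{ij}), \qquad
    h_i' = \phi\Big(W \big(h_i + \sum_j m_{ij}\big)\Big),$$
  where $e_{ij}$ are bond features and $\phi$ is batch normalization
  followed by a LeakyReLU (slope 0.01). Bond features are projected to the
  node width by a learned linear map per layer, since the convolution
  operator itself does not fix the edge dimension. The GIN self-weight
  $\varepsilon$ is fixed at 0; the batch-norm shift subsumes it together
  with the (omitted, mathematically redundant) pre-normalization biases.
* **Molecular context pooling** — the final node representations are
  sum-pooled into one graph vector, which is concatenated onto every node
  representation, doubling its width ($500 \to 1000$ by default). Pooling
  uses the *final* convolution layer's output; the alternative (pooling an
  earlier layer) was rejected to keep the pooled context on the same
  representational level as the node states it augments.
* **Classification module** — two fully connected hidden layers of width
  888 with batch normalization, LeakyReLU and dropout (rate 0.2), then a
  linear map to one logit and a sigmoid. Dropout appears only in this
  module.

Training minimises a weighted binary cross-entropy
$-[\,2.1\, y \log p + (1-y) \log(1-p)\,]$ with AdamW (decoupled weight
decay 0.01), batch size 32 molecules. The positive-class weight 2.1
compensates the roughly 1:10 SOM:non-SOM imbalance, which is what allows a
0.5 decision threshold on the ensemble mean. Probabilities are clamped at
$10^{-7}$ before logarithms. Learning rate ($10^{-4}$) and epoch count
(100) are exposed in `train_config()`; the reduced-scale configurations
used by the test suite (below) raise the rate to $10^{-3}$, chosen once by
inspecting training-loss convergence at width 64, not by optimising any
downstream test statistic.

The ensemble consists of $M$ members (default 10) trained on *identical*
data; member $m$ is seeded with `base_seed + m`, which controls both its
Glorot initialisation and its batch shuffling, making every training run
bitwise reproducible.

## Uncertainty decomposition

For one atom, let $p_m$ be member $m$'s predicted probability and
$\bar p = \frac1M \sum_m p_m$ the Bayesian model average (BMA), which is
also the reported prediction. With $H_2$ the binary entropy *in bits*,

$$u_{tot} = H_2(\bar p), \qquad
  u_{ale} = \frac1M \sum_m H_2(p_m), \qquad
  u_{epi} = u_{tot} - u_{ale}.$$

$u_{epi}$ is the mutual information between the member parameters and the
label; it is nonnegative by concavity of $H_2$ and vanishes exactly when
all members agree. Base-2 entropy places all three quantities in $[0, 1]$
for a binary label; the package's analytic reference points for
logit-uniform member disagreement (`theoretical_epistemic_max()`: 0.06,
0.54 and 0.76 bits at logit half-ranges 1, 5 and 10) only reproduce in
base 2, which is why bits are used throughout and documented on every
output.

The interpretation framework (`interpret_uncertainty()`) triages epistemic
uncertainty first: $u_{epi} \ge 0.10$ marks an atom *out-of-coverage*
(too few similar training examples — collect data before trusting any
score); otherwise $u_{ale} \ge 0.70$ marks the *noisy-label-regime*
(similar training atoms carry inconsistent labels); atoms below both
thresholds are *reliable*. Both thresholds are configurable; the defaults
are working values for data of the curated-database regime, not universal
constants.

## The baseline

`train_rf()` reimplements a circular-fingerprint random forest: each atom
is described by a radius-5, atom-centered binary fingerprint (per-depth
multisets of typed atom environments hashed onto 1024 bits, with the depth
salted into the hash) concatenated with 14 electronic/topological
descriptors. The descriptor set — PEOE partial charge, electronegativity,
polarizability, degree, valence, attached hydrogens, formal charge,
aromatic and ring indicators, smallest ring size, distances to the nearest
heteroatom and ring atom, heteroatom-neighbour count, eccentricity — is a
documented stand-in of the two descriptor families such baselines use; the
historical models' exact list is not public in a reimplementable form.
Undefined topological distances use the sentinel *molecule diameter + 1*,
finite and monotone with "far away". The forest (250 trees, decision
threshold 0.3) is an explicit bagging loop over `rpart` trees because the
defining detail — observation weights inversely proportional to class
frequencies *within each tree's bootstrap sample* — is not expressible in
any packaged random forest; each tree additionally draws a $p/3$-column
feature subspace. The subspace is drawn per tree rather than per split
(the tree learner does not expose per-split sampling), so it is kept much
wider than the classic per-split $\sqrt p$ heuristic, which would starve
most trees of the few informative fingerprint bits.

## Synthetic data: what it emulates and what it does not

Curated SOM databases are license-restricted, so the package generates its
own benchmark. `generate_library()` assembles 2–5 drug-like fragments
(aryl/heteroaryl rings, amide/ester/ether/amine/sulfonyl linkers, alkyl
chains) by SMILES concatenation at free valences — every product is a
valid molecule of 5–50 heavy atoms — and attaches a halogen substituent to
30% of molecules, mirroring the ~30% halogenated substrates of curated
data. `apply_label_rules()` labels atoms with deterministic structural
heuristics (benzylic carbons, carbons alpha to N, acyclic carbons alpha to
O), purely as label-generating machinery; halogens are forced non-SOM,
matching their consistent annotation in real data. The realised imbalance
is about 1:9 (target 1:10). With ~15 heavy atoms per molecule this yields
~1.5 SOMs per molecule rather than the ~2.4 of real substrates, whose
molecules are larger; the imbalance ratio was preferred when the two
could not be matched simultaneously at this molecule size. Label noise is
independent per-atom Bernoulli (`flip_noise()`), matching the statistical
notion of aleatoric noise.

Passing tests on this benchmark demonstrate that the architecture learns
local structural rules, that the decomposition reacts correctly to
engineered noise and coverage gaps, and that the evaluation machinery is
exact. They do *not* demonstrate chemical accuracy on real metabolism
data: the rules are far simpler than enzymatic regioselectivity, there is
no inter-laboratory annotation inconsistency, and the chemical space is
narrow.

## Controlled experiments

`run_ablation()` reproduces the two designed perturbations at property
level: training with all halogen-containing molecules removed must raise
epistemic uncertainty on test-set halogens (the members' halogen-input
weights are never trained, so members disagree), while training with
duplicated, halogen-mislabeled molecules must raise aleatoric uncertainty
(members converge to a common intermediate probability). The test set is
checksummed before and after every experiment. `ensemble_size_sweep()`
shares trained members across sizes (smaller ensembles are prefixes of the
largest), and `learning_curve()` uses nested molecule subsamples — both
choices remove sampling variance from comparisons along the grid. All
scenarios share one hyperparameter configuration; per-scenario re-tuning
is deliberately out of scope.

## Numerical choices

* Entropies: base 2; $0 \log 0 \equiv 0$; decomposition additivity holds
  to $10^{-9}$ and is tested, not assumed.
* `theoretical_epistemic_max()` uses a 100,001-point trapezoid rule; the
  test suite checks it against a $10^6$-sample Monte-Carlo oracle to
  within 0.005 bits.
* Batch norm: biased variance, $\varepsilon = 10^{-5}$, running-statistic
  momentum 0.1; inference always uses running statistics and disables
  dropout, so predictions are deterministic and independent of batch
  composition (both properties are tested).
* Ranking ties in TOP-2 break by ascending atom index; retention-curve
  ties by stable original order. Molecules without any annotated SOM are
  excluded from TOP-2 (real curated sets contain no non-metabolised
  compounds; the case arises only synthetically).
* Bootstrap resamples molecules, never atoms; cross-validation folds
  partition molecules.
* Atom indices are 1-based everywhere — internally and in files — the
  natural convention in R; no index translation layer exists.

## Problem sizes used by the shipped checks

The test suite exercises the full study design at a reduced scale chosen
as the smallest at which the qualitative effects are stable: 1000
molecules (800/200 molecule-level split, generator seed 0), convolution
and MLP width 64, 30 epochs, learning rate $10^{-3}$, ensembles of 5–10
members. The analytic and oracle-equivalence checks run at full precision.

## Known limitations

* Hybridization, conjugation and implicit-hydrogen counts are derived
  from the kekulized connection table by documented deterministic rules;
  exotic valence states (beyond common organic and hypervalent S/P
  patterns) may be typed coarsely.
* The fingerprint hashes typed-atom shells only (no bond-path
  information); collisions are possible at 1024 bits, though the
  per-depth salting keeps them rare in drug-like space.
* Aleatoric/epistemic separation inherits the usual caveat that a
  distribution shift mixes model uncertainty into both components; the
  epistemic values observed under engineered coverage gaps are well below
  the theoretical maximum, consistent with the logit-uniform analysis
  exposed by `theoretical_epistemic_max()`.
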