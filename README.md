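# uqsom

Atom-level **site-of-metabolism (SOM) prediction** with **deep-ensemble
uncertainty decomposition**, for computational chemists who need to know not
just *where* a xenobiotic is likely to be metabolised, but *whether that
prediction can be trusted* — and if not, why.

## The method

SOM prediction is binary node classification on the heavy-atom graph of a
molecule. `uqsom` trains an ensemble of M edge-aware message-passing
networks (GINE-style convolutions with molecular context pooling and an MLP
head) that differ only in their random initialisation. For each atom, with
member probabilities `p_m` and the Bayesian model average
`p̄ = (1/M) Σ p_m` as the reported prediction, the predictive entropy
decomposes as

```
u_tot = H₂(p̄)            total uncertainty        (bits)
u_ale = (1/M) Σ H₂(p_m)   aleatoric (label noise)  (bits)
u_epi = u_tot − u_ale     epistemic (coverage)     (bits)
```

`u_epi` is the mutual information between model parameters and label: zero
when members agree, positive when they disagree. The interpretation
framework triages `u_epi ≥ 0.10` as *out-of-coverage* (the training data
lacks similar atoms), then `u_ale ≥ 0.70` as *noisy-label-regime*, else
*reliable*.

The package also provides a circular-fingerprint random-forest baseline
(radius-5 atom-centered fingerprints + 14 electronic/topological
descriptors, per-bootstrap inverse-frequency class weights, decision
threshold 0.3), a molecule-level evaluation battery (ROC-AUC, PR-AUC, F1,
MCC, precision, recall, TOP-2 success, Brier retention curves, bootstrap,
10-fold CV), a rule-labeled synthetic molecule generator, and controlled
perturbation experiments (halogen-agnostic ablation, label-noise injection,
ensemble-size sweeps, learning curves). See the vignette
`vignettes/uncertainty-decomposition.Rmd` for the full model description
and design rationale.

## Worked example

```r
library(uqsom)

# a rule-labeled synthetic library: ~1:10 SOM imbalance, 30% halogenated
cfg <- synth_config(n_molecules = 300, seed = 0)
lib <- apply_label_rules(generate_library(cfg), default_label_rules(), cfg)

# train a 5-member ensemble (reduced width for the example)
ens <- train_ensemble(
  lib[1:240],
  model_config(hidden_width = 64, mlp_width = 64),
  train_config(learning_rate = 1e-3, n_epochs = 30, n_members = 5))

pred <- predict(ens, lib[241:300])
head(pred$table[, c("molecule_id", "atom", "element", "bma", "call",
                    "u_tot", "u_ale", "u_epi", "category")], 4)
#>   molecule_id atom element     bma call  u_tot  u_ale    u_epi category
#> 1     syn0241    1       N 0.02946    0 0.1917 0.1882 0.003466 reliable
#> 2     syn0241    2       C 0.01654    0 0.1215 0.1195 0.001986 reliable
#> 3     syn0241    3       O 0.01328    0 0.1018 0.1005 0.001292 reliable
#> 4     syn0241    4       N 0.00946    0 0.0772 0.0765 0.000726 reliable

m <- compute_metrics(pred$table$label, pred$table$bma, pred$table$call,
                     pred$table$molecule_id)
round(unlist(m[c("mcc", "top2", "roc_auc")]), 3)
#>     mcc    top2 roc_auc
#>   0.751   0.933   0.961
```

Each row is one heavy atom: `bma` is the ensemble-mean SOM probability,
`call` the 0.5-threshold decision, and the three uncertainties are in bits
with `u_tot = u_ale + u_epi`. On this small 240-molecule training set the
ensemble recovers the synthetic labeling rules well (MCC 0.75) and places
a true SOM among the top-2 ranked atoms for 93% of test molecules; at the
1000-molecule scale used by the test suite the MCC rises above 0.9.

The same workflow is scriptable:

```sh
Rscript inst/scripts/uqsom-cli.R synth --config run.yaml --out data/
Rscript inst/scripts/uqsom-cli.R train --config run.yaml --in data/library.csv --out model/
Rscript inst/scripts/uqsom-cli.R predict --config run.yaml --in data/library.csv --model model/ --out pred/
```

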