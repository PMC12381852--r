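# Deep-ensemble training, Bayesian model averaging, and the decomposition of
# predictive entropy into aleatoric and epistemic components (in bits).

#' Training configuration for the deep ensemble
#'
#' Defaults follow the reference setup: AdamW, weighted binary cross-entropy
#' with positive-class weight 2.1, batch size 32, an ensemble of 10 members,
#' and a 0.5 decision threshold on the ensemble mean.
#'
#' @param learning_rate AdamW learning rate (default 1e-4).
#' @param n_epochs Training epochs per member (default 100).
#' @param batch_size Molecules per mini-batch (default 32).
#' @param pos_weight Positive-class weight in the loss (default 2.1).
#' @param weight_decay AdamW decoupled weight decay (default 0.01).
#' @param base_seed Base RNG seed; member m uses `base_seed + m`.
#' @param n_members Ensemble size M (default 10).
#' @param threshold Decision threshold on the BMA probability (default 0.5).
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, n_epochs = 100L,
                         batch_size = 32L, pos_weight = 2.1,
                         weight_decay = 1e-2, base_seed = 0L,
                         n_members = 10L, threshold = 0.5) {
  stopifnot(pos_weight > 0, n_members >= 1, threshold > 0, threshold < 1,
            batch_size >= 1, n_epochs >= 1, learning_rate > 0)
  structure(list(learning_rate = learning_rate,
                 n_epochs = as.integer(n_epochs),
                 batch_size = as.integer(batch_size), pos_weight = pos_weight,
                 weight_decay = weight_decay, base_seed = as.integer(base_seed),
                 n_members = as.integer(n_members), threshold = threshold),
            class = "train_config")
}

#' Weighted binary cross-entropy
#'
#' `-(w_pos * y * log p + (1 - y) * log(1 - p))` in nats, with probabilities
#' clamped to `[eps, 1 - eps]` before the logarithm.
#'
#' @param p Predicted probabilities.
#' @param y Binary labels.
#' @param w_pos Positive-class weight.
#' @param eps Clamping epsilon (default 1e-7).
#' @return Per-observation loss vector (nonnegative).
#' @export
weighted_bce <- function(p, y, w_pos = 2.1, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -(w_pos * y * log(p) + (1 - y) * log(1 - p))
}

#' Binary entropy in bits
#'
#' `H2(p) = -p log2 p - (1-p) log2 (1-p)` with the convention
#' `0 * log 0 = 0`.
#'
#' @param p Probabilities in `[0, 1]`.
#' @return Entropy values in bits, in `[0, 1]`.
#' @export
binary_entropy <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("range error: p must be in [0,1]")
  term <- function(q) ifelse(q <= 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' Decompose ensemble predictive uncertainty
#'
#' Total uncertainty is the binary entropy of the ensemble mean (the
#' Bayesian model average); aleatoric uncertainty is the mean binary entropy
#' of the individual member probabilities; epistemic uncertainty is their
#' difference (the mutual information between parameters and label), which
#' is nonnegative by concavity of the entropy. All values in bits.
#'
#' @param member_probs Numeric vector of M member probabilities for one
#'   atom, or an `n x M` matrix (atoms in rows).
#' @return A list with `bma`, `u_tot`, `u_ale`, `u_epi` (vectors of length
#'   n). `u_tot = u_ale + u_epi` holds to floating-point accuracy.
#' @export
decompose_uncertainty <- function(member_probs) {
  if (is.null(member_probs) || length(member_probs) == 0) {
    stop("contract error: empty member probability vector")
  }
  P <- if (is.matrix(member_probs)) member_probs else
    matrix(member_probs, nrow = 1)
  bma <- rowMeans(P)
  u_tot <- binary_entropy(bma)
  u_ale <- rowMeans(matrix(binary_entropy(as.vector(P)), nrow(P), ncol(P)))
  u_epi <- u_tot - u_ale
  list(bma = bma, u_tot = u_tot, u_ale = u_ale, u_epi = u_epi)
}

#' Limiting epistemic uncertainty under logit-uniform disagreement
#'
#' For an infinite ensemble whose pre-sigmoid logits for one atom are
#' uniformly distributed on `[-x, x]`, the epistemic uncertainty converges
#' to `H2(E[sigmoid(L)]) - E[H2(sigmoid(L))] = 1 - E[H2(sigmoid(L))]` bits
#' (the mean sigmoid output is 1/2 by symmetry). The expectation is
#' evaluated by numerical quadrature.
#'
#' @param x Logit half-range (nonnegative).
#' @param n_points Trapezoid points (default 100001).
#' @return Epistemic uncertainty in bits.
#' @export
theoretical_epistemic_max <- function(x, n_points = 100001L) {
  if (any(x < 0)) stop("range error: x must be nonnegative")
  vapply(x, function(xx) {
    if (xx == 0) return(0)
    l <- seq(-xx, xx, length.out = n_points)
    s <- 1 / (1 + exp(-l))
    h <- binary_entropy(s)
    w <- rep(1, n_points); w[c(1, n_points)] <- 0.5
    e_h <- sum(w * h) / (n_points - 1)
    e_s <- sum(w * s) / (n_points - 1)
    binary_entropy(e_s) - e_h
  }, numeric(1))
}

# featurize a list of records once; returns per-molecule feature lists
.featurize_records <- function(records, fc = feature_config()) {
  lapply(records, function(r) {
    g <- build_graph(r)
    list(X = node_features(g, fc), E = edge_features(g, fc), y = r$labels,
         id = r$id, element = g$element, atom_type = atom_type_key(g))
  })
}

# one member's training loop; returns the trained model and the loss trace
.train_member <- function(feats, model_cfg, train_cfg, seed, verbose = FALSE) {
  model <- init_model(model_cfg, seed)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed + 10000L)
  opt <- list(m = list(), v = list(), t = 0)
  n_mol <- length(feats)
  losses <- numeric(train_cfg$n_epochs)
  for (epoch in seq_len(train_cfg$n_epochs)) {
    ord <- sample.int(n_mol)
    batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    tot_loss <- 0; tot_atoms <- 0
    for (bi in batches) {
      batch <- gnn_batch(feats[bi])
      fw <- .gnn_forward(model, batch, training = TRUE)
      model <- fw$model
      p <- fw$p; y <- batch$y
      n <- length(p)
      tot_loss <- tot_loss + sum(weighted_bce(p, y, train_cfg$pos_weight))
      tot_atoms <- tot_atoms + n
      # d/dlogit of mean weighted BCE
      w <- train_cfg$pos_weight
      dlogit <- (p * (1 + (w - 1) * y) - w * y) / n
      grads <- .gnn_backward(model, batch, fw$cache, dlogit)
      st <- .adamw_step(model$par, grads, opt, lr = train_cfg$learning_rate,
                        weight_decay = train_cfg$weight_decay)
      model$par <- st$par; opt <- st$state
    }
    losses[epoch] <- tot_loss / tot_atoms
    if (verbose) message(sprintf("  epoch %3d  loss %.4f", epoch,
                                 losses[epoch]))
  }
  model$loss_trace <- losses
  model
}

#' Train a deep ensemble of GNN SOM predictors
#'
#' Trains M identically configured models on the same data; member m is
#' seeded with `base_seed + m`, which controls both weight initialisation
#' and batch shuffling, so a rerun with identical inputs reproduces the
#' ensemble bitwise.
#'
#' @param records List of labeled [molecule_record()] objects (both classes
#'   must be present).
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param feature_cfg A [feature_config()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `som_ensemble`.
#' @export
train_ensemble <- function(records, model_cfg = model_config(),
                           train_cfg = train_config(),
                           feature_cfg = feature_config(), verbose = FALSE) {
  if (!length(records)) stop("empty training set")
  labels <- unlist(lapply(records, `[[`, "labels"))
  if (length(unique(labels)) < 2) {
    stop("training error: both classes must be present in the training set")
  }
  feats <- .featurize_records(records, feature_cfg)
  members <- vector("list", train_cfg$n_members)
  for (m in seq_len(train_cfg$n_members)) {
    if (verbose) message("training member ", m, "/", train_cfg$n_members)
    members[[m]] <- .train_member(feats, model_cfg, train_cfg,
                                  seed = train_cfg$base_seed + m,
                                  verbose = verbose)
  }
  structure(list(members = members, model_cfg = model_cfg,
                 train_cfg = train_cfg, feature_cfg = feature_cfg),
            class = "som_ensemble")
}

#' @export
print.som_ensemble <- function(x, ...) {
  cat(sprintf("<som_ensemble: %d members, %d conv layers x %d, head %d>\n",
              length(x$members), x$model_cfg$n_conv_layers,
              x$model_cfg$hidden_width, x$model_cfg$mlp_width))
  invisible(x)
}

#' Predict SOM probabilities and uncertainties
#'
#' Runs every member in inference mode on each molecule, forms the per-atom
#' Bayesian model average, thresholds it into a binary call, decomposes the
#' predictive entropy, and applies the interpretation framework.
#'
#' @param object A [train_ensemble()] `som_ensemble`.
#' @param records List of [molecule_record()] objects.
#' @param epi_threshold,ale_threshold Passed to [interpret_uncertainty()].
#' @param ... Unused.
#' @return A list with `table` (one row per heavy atom: `molecule_id`,
#'   `atom`, `element`, `atom_type`, `label`, `bma`, `call`, `u_tot`,
#'   `u_ale`, `u_epi`, `category`) and `member_probs` (atoms x M matrix).
#' @export
predict.som_ensemble <- function(object, records, epi_threshold = 0.10,
                                 ale_threshold = 0.70, ...) {
  feats <- .featurize_records(records, object$feature_cfg)
  batch <- gnn_batch(feats)
  M <- length(object$members)
  P <- matrix(NA_real_, nrow(batch$X), M)
  for (m in seq_len(M)) P[, m] <- gnn_forward(object$members[[m]], batch)
  dec <- decompose_uncertainty(P)
  category <- interpret_uncertainty(dec$u_epi, dec$u_ale,
                                    epi_threshold, ale_threshold)
  tab <- data.frame(
    molecule_id = unlist(lapply(feats, function(f) rep(f$id, nrow(f$X)))),
    atom = unlist(lapply(feats, function(f) seq_len(nrow(f$X)))),
    element = unlist(lapply(feats, `[[`, "element")),
    atom_type = unlist(lapply(feats, `[[`, "atom_type")),
    label = if (!is.null(batch$y)) batch$y else NA_integer_,
    bma = dec$bma,
    call = as.integer(dec$bma >= object$train_cfg$threshold),
    u_tot = dec$u_tot, u_ale = dec$u_ale, u_epi = dec$u_epi,
    category = category,
    stringsAsFactors = FALSE
  )
  list(table = tab, member_probs = P)
}

#' Map an uncertainty decomposition to a reliability category
#'
#' Epistemic uncertainty is assessed first: at or above `epi_threshold` the
#' atom is `"out-of-coverage"` (insufficiently represented in training
#' data). Otherwise, aleatoric uncertainty at or above `ale_threshold`
#' marks the `"noisy-label-regime"`; below both thresholds the prediction is
#' `"reliable"`.
#'
#' @param u_epi,u_ale Epistemic and aleatoric uncertainties in bits.
#' @param epi_threshold Epistemic threshold (default 0.10).
#' @param ale_threshold Aleatoric threshold (default 0.70).
#' @return Character vector of categories.
#' @export
interpret_uncertainty <- function(u_epi, u_ale, epi_threshold = 0.10,
                                  ale_threshold = 0.70) {
  ifelse(u_epi >= epi_threshold, "out-of-coverage",
         ifelse(u_ale >= ale_threshold, "noisy-label-regime", "reliable"))
}
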