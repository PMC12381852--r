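# Random-forest baseline over circular atom fingerprints plus the
# 14-descriptor block. The forest is an explicit bagging loop over rpart
# trees so that observation weights can be recomputed as inverse class
# frequencies *within each tree's bootstrap sample*; no packaged forest
# exposes that weighting scheme.

#' Random-forest baseline configuration
#'
#' @param n_trees Number of trees (default 250).
#' @param threshold Decision threshold on the forest probability
#'   (default 0.3).
#' @param mtry Features sampled per tree (default `floor(p / 3)`, resolved
#'   at fit time; the subspace is drawn per tree, not per split, so it is
#'   wider than the classic per-split heuristic).
#' @param seed RNG seed.
#' @return An object of class `rf_config`.
#' @export
rf_config <- function(n_trees = 250L, threshold = 0.3, mtry = NULL,
                      seed = 0L) {
  stopifnot(n_trees >= 1, threshold > 0, threshold < 1)
  structure(list(n_trees = as.integer(n_trees), threshold = threshold,
                 mtry = mtry, seed = as.integer(seed)),
            class = "rf_config")
}

#' Featurize a molecule library for the baseline
#'
#' One row per heavy atom: circular fingerprint bits concatenated with the
#' 14 electronic/topological descriptors.
#'
#' @param records List of [molecule_record()] objects.
#' @param feature_cfg A [feature_config()] (controls fingerprint radius and
#'   length).
#' @return List with `X` (matrix `n_atoms x (fp_length + 14)`), `y` (labels),
#'   `molecule_id`, `atom`.
#' @export
featurize_dataset <- function(records, feature_cfg = feature_config()) {
  rows <- lapply(records, function(rec) {
    g <- build_graph(rec)
    adj <- .adjacency(g)
    attr(g, "adj") <- adj
    fp <- t(vapply(seq_len(g$n), function(k)
      fame_fingerprint(g, k, feature_cfg$fp_radius, feature_cfg$fp_length),
      integer(feature_cfg$fp_length)))
    desc <- atom_descriptors(g)
    list(X = cbind(fp, desc), y = rec$labels, id = rec$id, n = g$n)
  })
  X <- do.call(rbind, lapply(rows, `[[`, "X"))
  colnames(X) <- c(paste0("fp", seq_len(feature_cfg$fp_length)),
                   colnames(rows[[1]]$X)[feature_cfg$fp_length +
                                           seq_len(14)])
  list(X = X,
       y = unlist(lapply(rows, `[[`, "y")),
       molecule_id = unlist(lapply(rows, function(r) rep(r$id, r$n))),
       atom = unlist(lapply(rows, function(r) seq_len(r$n))))
}

#' Train the class-weighted random-forest baseline
#'
#' Each tree is fit on a bootstrap resample of the atoms with observation
#' weights proportional to the inverse class frequency computed within that
#' resample, and on a random feature subspace of size `mtry`.
#' Reproducible given `cfg$seed`.
#'
#' @param features Feature matrix (atoms x features).
#' @param labels Binary label vector (both classes required).
#' @param cfg An [rf_config()].
#' @return An object of class `fame_rf` (list of rpart trees plus their
#'   feature subsets).
#' @export
train_rf <- function(features, labels, cfg = rf_config()) {
  if (length(unique(labels)) < 2) {
    stop("training error: both classes must be present")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  n <- nrow(features); p <- ncol(features)
  mtry <- if (is.null(cfg$mtry)) max(1L, p %/% 3L) else
    min(as.integer(cfg$mtry), p)
  trees <- vector("list", cfg$n_trees)
  for (t in seq_len(cfg$n_trees)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- labels[idx]
      if (length(unique(yb)) == 2) break
    }
    freq <- table(factor(yb, levels = c(0, 1)))
    w <- as.numeric(1 / freq[as.character(yb)])
    w <- w * length(yb) / sum(w)
    cols <- sort(sample.int(p, mtry))
    df <- as.data.frame(features[idx, cols, drop = FALSE])
    df$.y <- factor(yb, levels = c(0, 1))
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(cp = 0.001,
                                                       minsplit = 10,
                                                       xval = 0))
    trees[[t]] <- list(fit = fit, cols = cols)
  }
  structure(list(trees = trees, cfg = cfg, p = p,
                 col_names = colnames(features)),
            class = "fame_rf")
}

#' Predict with the random-forest baseline
#'
#' The probability is the mean of the per-tree class-1 probability
#' estimates; the binary call thresholds it at `threshold`.
#'
#' @param model A [train_rf()] `fame_rf` object.
#' @param features Feature matrix with the training column layout.
#' @param threshold Decision threshold (default from the model config).
#' @return List with `prob` and `call` vectors.
#' @export
predict_rf <- function(model, features, threshold = NULL) {
  if (ncol(features) != model$p) {
    stop("contract error: feature column count mismatch")
  }
  if (is.null(threshold)) threshold <- model$cfg$threshold
  acc <- numeric(nrow(features))
  for (tr in model$trees) {
    df <- as.data.frame(features[, tr$cols, drop = FALSE])
    pr <- predict(tr$fit, newdata = df, type = "prob")
    acc <- acc + pr[, "1"]
  }
  prob <- acc / length(model$trees)
  list(prob = prob, call = as.integer(prob >= threshold))
}
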