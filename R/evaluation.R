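# Metric battery: threshold metrics from the confusion table, rank metrics
# on the continuous scores, per-molecule top-2 success, Brier score and
# uncertainty-retention curves, molecule-level bootstrap and k-fold CV.

.confusion <- function(y_true, calls) {
  tp <- sum(y_true == 1 & calls == 1); fp <- sum(y_true == 0 & calls == 1)
  tn <- sum(y_true == 0 & calls == 0); fn <- sum(y_true == 1 & calls == 0)
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

.mcc <- function(cm) {
  num <- cm["tp"] * cm["tn"] - cm["fp"] * cm["fn"]
  den <- sqrt(prod(c(cm["tp"] + cm["fp"], cm["tp"] + cm["fn"],
                     cm["tn"] + cm["fp"], cm["tn"] + cm["fn"])))
  if (den == 0) return(0)
  unname(num / den)
}

# Mann-Whitney ROC-AUC with midrank tie handling
.roc_auc <- function(y_true, scores) {
  pos <- y_true == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# PR-AUC as average precision: sum over descending score thresholds of
# precision times recall increment (ties collapse to one threshold)
.pr_auc <- function(y_true, scores) {
  n_pos <- sum(y_true == 1)
  if (n_pos == 0) return(NA_real_)
  ord <- order(-scores)
  y <- y_true[ord]; s <- scores[ord]
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index within each tie group
  tp <- tp[last]; fp <- fp[last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' labels; a strictly proper scoring rule.
#'
#' @param y_true Binary labels.
#' @param probs Predicted probabilities in `[0, 1]`.
#' @return Scalar in `[0, 1]`.
#' @export
brier_score <- function(y_true, probs) {
  stopifnot(length(y_true) == length(probs))
  mean((probs - y_true)^2)
}

#' Per-molecule top-k success
#'
#' A molecule scores 1 if at least one true SOM ranks among its `k`
#' highest-scoring atoms (ties broken by ascending atom index). Molecules
#' without any true SOM are excluded from the aggregate rate.
#'
#' @param y_true,scores Equal-length vectors over the atoms of molecules.
#' @param molecule_ids Molecule identifier per atom.
#' @param k Number of top positions (default 2).
#' @return List with `rate` and per-molecule `hits` (named 0/1 vector over
#'   molecules that have at least one SOM).
#' @export
top2_success <- function(y_true, scores, molecule_ids, k = 2L) {
  hits <- c()
  for (mid in unique(molecule_ids)) {
    sel <- molecule_ids == mid
    y <- y_true[sel]; s <- scores[sel]
    if (!any(y == 1)) next
    top <- order(-s, seq_along(s))[seq_len(min(k, length(s)))]
    hits[mid] <- as.integer(any(y[top] == 1))
  }
  list(rate = if (length(hits)) mean(hits) else NA_real_, hits = hits)
}

#' Compute the full metric report
#'
#' Threshold metrics (F1, MCC, precision, recall) come from the binary
#' calls; ROC-AUC and PR-AUC from the continuous scores; TOP-2 from the
#' per-molecule ranking of scores. Degenerate single-class truth yields
#' `NA` AUCs with a warning.
#'
#' @param y_true Binary labels per atom.
#' @param scores Continuous scores (e.g. BMA probabilities) per atom.
#' @param calls Binary calls per atom.
#' @param molecule_ids Molecule id per atom (required for TOP-2; `NULL`
#'   skips it).
#' @return A named list of class `metric_report`: `roc_auc`, `pr_auc`,
#'   `f1`, `mcc`, `precision`, `recall`, `top2`, `brier`, `confusion`.
#' @export
compute_metrics <- function(y_true, scores, calls, molecule_ids = NULL) {
  stopifnot(length(y_true) == length(scores),
            length(y_true) == length(calls))
  if (length(unique(y_true)) < 2) {
    warning("single-class truth: AUCs undefined, reported as NA")
  }
  cm <- .confusion(y_true, calls)
  precision <- if (cm["tp"] + cm["fp"] > 0)
    unname(cm["tp"] / (cm["tp"] + cm["fp"])) else NA_real_
  recall <- if (cm["tp"] + cm["fn"] > 0)
    unname(cm["tp"] / (cm["tp"] + cm["fn"])) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  top2 <- if (!is.null(molecule_ids))
    top2_success(y_true, scores, molecule_ids)$rate else NA_real_
  structure(list(
    roc_auc = .roc_auc(y_true, scores),
    pr_auc = .pr_auc(y_true, scores),
    f1 = f1, mcc = .mcc(cm), precision = precision, recall = recall,
    top2 = top2, brier = brier_score(y_true, scores), confusion = cm
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  v <- unlist(x[c("roc_auc", "pr_auc", "f1", "mcc", "precision", "recall",
                  "top2", "brier")])
  cat("<metric_report>\n")
  print(round(v, 4))
  invisible(x)
}

#' Brier score against uncertainty-sorted retention
#'
#' Atoms are sorted ascending by the chosen uncertainty (ties broken by
#' stable original order) and the Brier score is computed on each retained
#' prefix. An informative uncertainty yields a curve that rises towards the
#' full-set Brier score.
#'
#' @param y_true Binary labels.
#' @param probs Predicted probabilities.
#' @param uncertainties Named list of per-atom uncertainty vectors (e.g.
#'   `list(tot = ..., ale = ..., epi = ...)`).
#' @param fractions Increasing retention fractions in (0, 1], ending at 1.
#' @return Data frame with `uncertainty_type`, `fraction`, `brier`.
#' @export
retention_curve <- function(y_true, probs, uncertainties,
                            fractions = seq(0.1, 1, by = 0.1)) {
  stopifnot(all(fractions > 0), all(fractions <= 1),
            !is.unsorted(fractions, strictly = TRUE))
  n <- length(y_true)
  out <- list()
  for (uty in names(uncertainties)) {
    u <- uncertainties[[uty]]
    ord <- order(u, seq_len(n))  # stable
    briers <- vapply(fractions, function(f) {
      keep <- ord[seq_len(max(1L, floor(f * n)))]
      brier_score(y_true[keep], probs[keep])
    }, numeric(1))
    out[[uty]] <- data.frame(uncertainty_type = uty, fraction = fractions,
                             brier = briers, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Molecule-level bootstrap of the metric report
#'
#' Resamples molecules (all their atoms move together) with replacement B
#' times and recomputes every metric per replicate. Replicates with
#' single-class truth contribute `NA` AUCs and are counted.
#'
#' @param prediction_table Data frame with columns `molecule_id`, `label`,
#'   `bma`, `call` (as from [predict.som_ensemble()]).
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return List with `point` (the full-sample `metric_report`), `mean`,
#'   `sd` (named vectors across replicates, `NA`s removed), `n_degenerate`.
#' @export
bootstrap_metrics <- function(prediction_table, B = 1000L, seed = 0L) {
  stopifnot(B >= 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tab <- prediction_table
  mols <- unique(tab$molecule_id)
  idx_by_mol <- split(seq_len(nrow(tab)), tab$molecule_id)[mols]
  point <- suppressWarnings(
    compute_metrics(tab$label, tab$bma, tab$call, tab$molecule_id))
  keys <- c("roc_auc", "pr_auc", "f1", "mcc", "precision", "recall", "top2",
            "brier")
  reps <- matrix(NA_real_, B, length(keys), dimnames = list(NULL, keys))
  n_degenerate <- 0L
  for (b in seq_len(B)) {
    pick <- sample(mols, length(mols), replace = TRUE)
    rows <- unlist(idx_by_mol[pick], use.names = FALSE)
    # molecule ids must stay distinct per bootstrap copy for TOP-2
    rep_ids <- rep(seq_along(pick), vapply(idx_by_mol[pick], length,
                                           integer(1)))
    sub <- tab[rows, ]
    if (length(unique(sub$label)) < 2) n_degenerate <- n_degenerate + 1L
    m <- suppressWarnings(compute_metrics(sub$label, sub$bma, sub$call,
                                          rep_ids))
    reps[b, ] <- unlist(m[keys])
  }
  list(point = point,
       mean = colMeans(reps, na.rm = TRUE),
       sd = apply(reps, 2, stats::sd, na.rm = TRUE),
       n_degenerate = n_degenerate, B = B)
}

#' k-fold cross-validation over molecules
#'
#' Molecules (never atoms) are partitioned into k disjoint folds; `trainer`
#' is called on each training partition and must return an object whose
#' `predict` method yields a prediction table with `label`, `bma`, `call`,
#' `molecule_id` columns.
#'
#' @param records List of [molecule_record()] objects.
#' @param k Number of folds (default 10).
#' @param trainer Function `records -> model`.
#' @param predictor Function `(model, records) -> prediction table`.
#' @param seed Seed controlling the fold assignment.
#' @return List with `folds` (assignment vector), `reports` (per-fold
#'   `metric_report`), `mean`, `sd`.
#' @export
kfold_cv <- function(records, k = 10L, trainer, predictor, seed = 0L) {
  n <- length(records)
  if (k < 2) stop("config error: k must be at least 2")
  if (k > n) stop("config error: more folds than molecules")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  keys <- c("roc_auc", "pr_auc", "f1", "mcc", "precision", "recall", "top2",
            "brier")
  reports <- vector("list", k)
  vals <- matrix(NA_real_, k, length(keys), dimnames = list(NULL, keys))
  for (fold in seq_len(k)) {
    train <- records[folds != fold]
    test <- records[folds == fold]
    model <- trainer(train)
    tab <- predictor(model, test)
    reports[[fold]] <- suppressWarnings(
      compute_metrics(tab$label, tab$bma, tab$call, tab$molecule_id))
    vals[fold, ] <- unlist(reports[[fold]][keys])
  }
  list(folds = folds, reports = reports,
       mean = colMeans(vals, na.rm = TRUE),
       sd = apply(vals, 2, stats::sd, na.rm = TRUE))
}
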