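# Controlled studies: element-agnostic ablation, label-noise injection,
# per-atom-type uncertainty summaries, ensemble-size sweep, learning curve.

# stable content checksum of a record list (ids, structures, labels)
.records_checksum <- function(records) {
  s <- paste(vapply(records, function(r)
    paste(r$id, r$smiles, paste(r$labels, collapse = ""), sep = "#"),
    character(1)), collapse = "|")
  .str_hash(s)
}

.eval_scenario <- function(ensemble, test, elements, B = 200L, seed = 1L) {
  pred <- predict(ensemble, test)
  tab <- pred$table
  boot <- bootstrap_metrics(tab, B = B, seed = seed)
  is_target <- tab$element %in% elements
  list(
    metrics = boot,
    prediction_table = tab,
    p_target_mean = mean(tab$bma[is_target]),
    p_target_sd = stats::sd(tab$bma[is_target]),
    n_pos = sum(tab$call[is_target] == 1),
    n_neg = sum(tab$call[is_target] == 0),
    u_ale_target = mean(tab$u_ale[is_target]),
    u_epi_target = mean(tab$u_epi[is_target]),
    u_ale_other = mean(tab$u_ale[!is_target]),
    u_epi_other = mean(tab$u_epi[!is_target])
  )
}

#' Element-agnostic and noise-injected ablation study
#'
#' Trains three ensembles with one shared configuration -- on the original
#' training set, on the subset excluding all molecules containing the
#' target elements ("agnostic"), and on the set augmented with duplicated,
#' element-mislabeled molecules ("noise-injected") -- and evaluates all
#' three on the identical untouched test set. The test set is checksummed
#' before and after to enforce immutability.
#'
#' @param train,test Labeled record lists.
#' @param elements Target element symbols (default halogens).
#' @param model_cfg,train_cfg,feature_cfg Shared configurations.
#' @param bootstrap_B Bootstrap replicates per scenario (default 200).
#' @return An `ablation_report`: per scenario, the metric bootstrap, mean
#'   predicted SOM probability over target-element atoms with sd, counts of
#'   target atoms called positive/negative, and mean aleatoric/epistemic
#'   uncertainty over target and non-target atoms.
#' @export
run_ablation <- function(train, test, elements = HALOGENS,
                         model_cfg = model_config(),
                         train_cfg = train_config(),
                         feature_cfg = feature_config(),
                         bootstrap_B = 200L) {
  checksum_before <- .records_checksum(test)
  scenarios <- list(
    baseline = train,
    agnostic = exclude_element(train, elements),
    noise_injected = inject_element_noise(train, elements)
  )
  report <- list()
  for (sc in names(scenarios)) {
    ens <- tryCatch(
      train_ensemble(scenarios[[sc]], model_cfg, train_cfg, feature_cfg),
      error = function(e) stop("scenario '", sc, "' failed: ",
                               conditionMessage(e)))
    report[[sc]] <- .eval_scenario(ens, test, elements, B = bootstrap_B,
                                   seed = train_cfg$base_seed + 1L)
    report[[sc]]$ensemble <- ens
  }
  if (.records_checksum(test) != checksum_before) {
    stop("test-set immutability violated")
  }
  structure(list(scenarios = report, elements = elements,
                 checksum = checksum_before),
            class = "ablation_report")
}

#' @export
print.ablation_report <- function(x, ...) {
  cat("<ablation_report> target elements:",
      paste(x$elements, collapse = ","), "\n")
  for (sc in names(x$scenarios)) {
    s <- x$scenarios[[sc]]
    cat(sprintf(
      "  %-15s MCC %.3f  p_target %.3f+-%.3f  N+/N- %d/%d  u_ale %.3f  u_epi %.3f\n",
      sc, s$metrics$point$mcc, s$p_target_mean, s$p_target_sd,
      s$n_pos, s$n_neg, s$u_ale_target, s$u_epi_target))
  }
  invisible(x)
}

#' Summarise uncertainties by atom type
#'
#' Aggregates aleatoric and epistemic uncertainty per atom-type key
#' ([atom_type_key()] convention: halogens by element, C/N/O/S by
#' element-hybridization).
#'
#' @param prediction_table Table from [predict.som_ensemble()] (needs
#'   `atom_type`, `u_ale`, `u_epi`).
#' @return Data frame keyed by `atom_type` with count, median, quartiles,
#'   mean and sd for both uncertainty types.
#' @export
atom_type_uncertainty_summary <- function(prediction_table) {
  sp <- split(prediction_table, prediction_table$atom_type)
  rows <- lapply(names(sp), function(key) {
    s <- sp[[key]]
    qa <- stats::quantile(s$u_ale, c(0.25, 0.5, 0.75))
    qe <- stats::quantile(s$u_epi, c(0.25, 0.5, 0.75))
    data.frame(atom_type = key, n = nrow(s),
               ale_q1 = qa[1], ale_median = qa[2], ale_q3 = qa[3],
               ale_mean = mean(s$u_ale), ale_sd = stats::sd(s$u_ale),
               epi_q1 = qe[1], epi_median = qe[2], epi_q3 = qe[3],
               epi_mean = mean(s$u_epi), epi_sd = stats::sd(s$u_epi),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ensemble-size sweep
#'
#' Trains `max(sizes)` members once; smaller ensembles are prefixes of the
#' largest (shared members), so comparisons across sizes are seed-consistent.
#'
#' @param train,test Labeled record lists.
#' @param sizes Strictly increasing ensemble sizes (default 1, 5, 10, 50,
#'   100).
#' @param model_cfg,train_cfg,feature_cfg Configurations; `train_cfg`'s
#'   `n_members` is overridden by `max(sizes)`.
#' @return A `sweep_report` data frame: one row per size with the metric
#'   suite on the fixed test set.
#' @export
ensemble_size_sweep <- function(train, test, sizes = c(1L, 5L, 10L, 50L, 100L),
                                model_cfg = model_config(),
                                train_cfg = train_config(),
                                feature_cfg = feature_config()) {
  if (any(sizes < 1)) stop("config error: ensemble sizes must be positive")
  if (is.unsorted(sizes, strictly = TRUE)) {
    stop("config error: sizes must be strictly increasing")
  }
  train_cfg$n_members <- max(sizes)
  full <- train_ensemble(train, model_cfg, train_cfg, feature_cfg)
  rows <- lapply(sizes, function(M) {
    sub <- full
    sub$members <- full$members[seq_len(M)]
    tab <- predict(sub, test)$table
    m <- suppressWarnings(compute_metrics(tab$label, tab$bma, tab$call,
                                          tab$molecule_id))
    data.frame(size = M, mcc = m$mcc, f1 = m$f1, roc_auc = m$roc_auc,
               pr_auc = m$pr_auc, precision = m$precision,
               recall = m$recall, top2 = m$top2, brier = m$brier,
               mean_u_epi = mean(tab$u_epi))
  })
  out <- do.call(rbind, rows)
  attr(out, "ensemble") <- full
  class(out) <- c("sweep_report", class(out))
  out
}

#' Training-set size learning curve
#'
#' Molecule-level nested subsampling: the molecules used at a smaller
#' fraction are a subset of those at any larger fraction, reducing
#' sampling variance across the grid. One ensemble is trained per fraction
#' and evaluated on the fixed test set.
#'
#' @param train,test Labeled record lists.
#' @param fractions Increasing fractions in (0, 1] (default 0.1..1.0).
#' @param model_cfg,train_cfg,feature_cfg Configurations.
#' @param seed Seed for the nested subsample order.
#' @return A `sweep_report` data frame: one row per fraction.
#' @export
learning_curve <- function(train, test, fractions = seq(0.1, 1, by = 0.1),
                           model_cfg = model_config(),
                           train_cfg = train_config(),
                           feature_cfg = feature_config(), seed = 0L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ord <- sample(seq_along(train))  # one permutation => nested subsets
  rows <- lapply(fractions, function(f) {
    n_take <- max(2L, floor(f * length(train)))
    sub <- train[ord[seq_len(n_take)]]
    labels <- unlist(lapply(sub, `[[`, "labels"))
    if (length(unique(labels)) < 2) {
      stop("config error: fraction ", f, " yields a single-class subset")
    }
    ens <- train_ensemble(sub, model_cfg, train_cfg, feature_cfg)
    tab <- predict(ens, test)$table
    m <- suppressWarnings(compute_metrics(tab$label, tab$bma, tab$call,
                                          tab$molecule_id))
    data.frame(fraction = f, n_molecules = n_take, mcc = m$mcc, f1 = m$f1,
               roc_auc = m$roc_auc, pr_auc = m$pr_auc,
               precision = m$precision, recall = m$recall, top2 = m$top2,
               brier = m$brier)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_report", class(out))
  out
}
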