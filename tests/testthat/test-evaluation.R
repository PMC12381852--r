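test_that("worked metric examples are reproduced", {
  # TP=2 FP=1 TN=6 FN=1 -> MCC = 11/21
  y <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  calls <- c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)
  m <- suppressWarnings(compute_metrics(y, calls, calls))
  expect_equal(m$mcc, 11 / 21, tolerance = 1e-12)

  y <- c(1, 0, 1, 0)
  m <- compute_metrics(y, c(0.9, 0.1, 0.8, 0.2), y)
  expect_equal(m$mcc, 1); expect_equal(m$f1, 1)
  expect_equal(m$roc_auc, 1); expect_equal(m$pr_auc, 1)

  # anti-correlated scores mirror the AUC
  s <- c(0.9, 0.1, 0.8, 0.2)
  expect_equal(compute_metrics(y, 1 - s, y)$roc_auc,
               1 - compute_metrics(y, s, y)$roc_auc)
})

test_that("metrics match naive oracles on random instances", {
  set.seed(123)
  for (i in 1:300) {
    n <- sample(4:40, 1)
    y <- rbinom(n, 1, runif(1, 0.15, 0.6))
    if (length(unique(y)) < 2) next
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    calls <- as.integer(s >= 0.5)
    ids <- sample(paste0("m", 1:max(1, n %/% 4)), n, replace = TRUE)
    m <- suppressWarnings(compute_metrics(y, s, calls, ids))
    expect_equal(m$mcc, naive_mcc(y, calls), tolerance = 1e-12)
    expect_equal(m$precision, naive_precision(y, calls), tolerance = 1e-12)
    expect_equal(m$recall, naive_recall(y, calls), tolerance = 1e-12)
    expect_equal(m$f1, naive_f1(y, calls), tolerance = 1e-12)
    expect_equal(m$roc_auc, naive_roc_auc(y, s), tolerance = 1e-12)
    expect_equal(m$pr_auc, naive_pr_auc(y, s), tolerance = 1e-12)
    expect_equal(m$brier, naive_brier(y, s), tolerance = 1e-12)
    expect_equal(m$top2, naive_top2(y, s, ids), tolerance = 1e-12)
  }
})

test_that("ROC-AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  y <- rbinom(60, 1, 0.3); s <- runif(60)
  if (length(unique(y)) == 2) {
    ref <- as.numeric(suppressMessages(
      pROC::auc(y, s, direction = "<", levels = c(0, 1))))
    expect_equal(suppressWarnings(compute_metrics(y, s, y)$roc_auc), ref,
                 tolerance = 1e-12)
  }
})

test_that("single-class truth yields NA AUCs with a warning", {
  expect_warning(m <- compute_metrics(c(0, 0), c(0.2, 0.3), c(0, 0)),
                 "single-class")
  expect_true(is.na(m$roc_auc)); expect_true(is.na(m$pr_auc))
})

test_that("top-2 success follows the ranking with index tie-breaks", {
  expect_equal(top2_success(c(0, 1, 0), c(0.9, 0.8, 0.1), rep("m", 3))$rate,
               1)
  expect_equal(top2_success(c(0, 0, 1), c(0.9, 0.8, 0.1), rep("m", 3))$rate,
               0)
  ids <- rep(c("a", "b"), each = 3)
  r <- top2_success(c(0, 1, 0, 0, 0, 1), c(0.9, 0.8, 0.1, 0.9, 0.8, 0.1),
                    ids)
  expect_equal(r$rate, 0.5)
  # all-equal scores: positions 1 and 2 win deterministically
  expect_equal(top2_success(c(0, 1, 0), c(0.5, 0.5, 0.5), rep("m", 3))$rate,
               1)
  expect_equal(top2_success(c(0, 0, 1), c(0.5, 0.5, 0.5), rep("m", 3))$rate,
               0)
  # molecules without a SOM are excluded
  r2 <- top2_success(c(1, 0, 0, 0), c(1, 0, 1, 0), rep(c("a", "b"), each = 2))
  expect_equal(r2$rate, 1)
  expect_length(r2$hits, 1)
  # top-1 never beats top-2
  set.seed(2)
  for (i in 1:50) {
    y <- rbinom(9, 1, 0.4); s <- runif(9); ids <- rep(c("a", "b", "c"), 3)
    expect_gte(top2_success(y, s, ids, k = 2)$rate %||% 0,
               top2_success(y, s, ids, k = 1)$rate %||% 0)
  }
})

test_that("Brier score matches its definition", {
  expect_equal(brier_score(c(1, 0), c(1, 0)), 0)
  expect_equal(brier_score(c(1, 0, 1, 0), rep(0.5, 4)), 0.25)
  expect_equal(brier_score(c(0, 1), c(1, 0)), 1)
})

test_that("retention curves end at the global Brier and detect order", {
  set.seed(3)
  n <- 500
  y <- rbinom(n, 1, 0.3)
  p <- pmin(pmax(y * 0.8 + runif(n, -0.3, 0.3), 0.01), 0.99)
  u_informative <- abs(p - y)
  rc <- retention_curve(y, p, list(inf = u_informative, rnd = runif(n)))
  full_rows <- rc$fraction == 1
  expect_true(all(abs(rc$brier[full_rows] - brier_score(y, p)) < 1e-12))
  inf <- rc[rc$uncertainty_type == "inf", ]
  expect_true(!is.unsorted(inf$brier))
  # random uncertainty gives a roughly flat curve around the global score
  rnd <- rc[rc$uncertainty_type == "rnd", ]
  expect_lt(max(abs(rnd$brier - brier_score(y, p))), 0.08)
  expect_error(retention_curve(y, p, list(u = u_informative),
                               fractions = c(0.5, 0.2)), "sorted|strictly")
})

test_that("bootstrap resamples molecules and degenerates to B=1 sanely", {
  ens <- tiny_ensemble(2)
  tab <- predict(ens, small_library(30, seed = 5)[1:10])$table
  b1 <- bootstrap_metrics(tab, B = 1, seed = 4)
  expect_true(all(b1$sd[!is.na(b1$sd)] == 0))
  b <- bootstrap_metrics(tab, B = 50, seed = 4)
  b2 <- bootstrap_metrics(tab, B = 50, seed = 4)
  expect_identical(b$mean, b2$mean)  # seeded determinism
  expect_true(all(b$sd >= 0, na.rm = TRUE))
  expect_equal(unname(b$point$brier), brier_score(tab$label, tab$bma))
})

test_that("k-fold CV partitions molecules disjointly and reproducibly", {
  recs <- small_library(12, seed = 9)
  trainer <- function(tr) tr  # trivial "model": memorise nothing
  predictor <- function(model, te) {
    labs <- unlist(lapply(te, `[[`, "labels"))
    data.frame(label = labs, bma = runif(length(labs)),
               call = rbinom(length(labs), 1, 0.2),
               molecule_id = rep(vapply(te, `[[`, character(1), "id"),
                                 vapply(te, `[[`, integer(1), "n_heavy")))
  }
  cv1 <- kfold_cv(recs, k = 3, trainer, predictor, seed = 5)
  cv2 <- kfold_cv(recs, k = 3, trainer, predictor, seed = 5)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(sort(unique(cv1$folds)), 1:3)
  expect_length(cv1$folds, 12)
  expect_equal(as.vector(table(cv1$folds)), c(4, 4, 4))
  expect_error(kfold_cv(recs, k = 13, trainer, predictor), "config error")
  expect_error(kfold_cv(recs, k = 1, trainer, predictor), "config error")
})
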