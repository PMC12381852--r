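test_that("weighted binary cross-entropy matches its closed form", {
  expect_equal(weighted_bce(0.5, 0, 2.1), -log(0.5), tolerance = 1e-12)
  expect_equal(weighted_bce(0.5, 1, 2.1), 2.1 * log(2), tolerance = 1e-12)
  expect_equal(weighted_bce(0.5, 1, 2.1), 1.4556, tolerance = 1e-4)
  expect_lt(weighted_bce(1 - 1e-9, 1, 2.1), 1e-5)
  expect_lt(weighted_bce(1e-9, 0, 2.1), 1e-5)
  expect_true(is.finite(weighted_bce(0, 1, 2.1)))  # clamped, not -Inf
  expect_true(all(weighted_bce(runif(100), rbinom(100, 1, 0.5)) >= 0))
})

test_that("binary entropy matches closed form and rejects bad input", {
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(c(0, 1)), c(0, 0))
  expect_equal(binary_entropy(0.25), 0.8113, tolerance = 1e-4)
  expect_error(binary_entropy(1.2), "range")
  expect_error(binary_entropy(-0.1), "range")
})

test_that("uncertainty decomposition reproduces worked examples", {
  d <- decompose_uncertainty(c(0.5, 0.5))
  expect_equal(d$bma, 0.5)
  expect_equal(d$u_tot, 1); expect_equal(d$u_ale, 1)
  expect_equal(d$u_epi, 0)

  d <- decompose_uncertainty(c(0, 1))
  expect_equal(d$bma, 0.5)
  expect_equal(d$u_tot, 1); expect_equal(d$u_ale, 0)
  expect_equal(d$u_epi, 1)

  d <- decompose_uncertainty(c(0.25, 0.75))
  expect_equal(d$u_tot, 1)
  expect_equal(d$u_ale, 0.8113, tolerance = 1e-4)
  expect_equal(d$u_epi, 1 - binary_entropy(0.25), tolerance = 1e-12)

  expect_error(decompose_uncertainty(numeric(0)), "contract error")
})

test_that("decomposition is additive and epistemic is nonnegative", {
  set.seed(1)
  for (rep in 1:200) {
    M <- sample(1:100, 1)
    P <- matrix(runif(5 * M), 5, M)
    d <- decompose_uncertainty(P)
    expect_true(all(abs(d$u_tot - (d$u_ale + d$u_epi)) < 1e-9))
    expect_true(all(d$u_epi >= -1e-12))
    expect_true(all(d$u_ale >= 0 & d$u_ale <= 1))
    expect_true(all(d$u_tot <= 1))
  }
})

test_that("logit-uniform epistemic limits match quadrature and MC oracle", {
  expect_equal(theoretical_epistemic_max(0), 0)
  expect_equal(round(theoretical_epistemic_max(1), 2), 0.06)
  expect_equal(round(theoretical_epistemic_max(5), 2), 0.54)
  expect_equal(round(theoretical_epistemic_max(10), 2), 0.76)
  for (x in c(0.5, 1, 2, 5, 10)) {
    expect_lt(abs(theoretical_epistemic_max(x) - mc_epistemic_max(x)),
              0.005)
  }
  expect_error(theoretical_epistemic_max(-1), "range")
})

test_that("interpretation framework triages epistemic before aleatoric", {
  expect_equal(interpret_uncertainty(0.24, 0.5), "out-of-coverage")
  expect_equal(interpret_uncertainty(0.02, 0.98), "noisy-label-regime")
  expect_equal(interpret_uncertainty(0, 0), "reliable")
  expect_equal(interpret_uncertainty(c(0.2, 0.05, 0), c(0.1, 0.9, 0.2)),
               c("out-of-coverage", "noisy-label-regime", "reliable"))
  # thresholds are configurable
  expect_equal(interpret_uncertainty(0.24, 0.5, epi_threshold = 0.3),
               "reliable")
})

test_that("ensemble training is reproducible and validates its inputs", {
  recs <- small_library(12, seed = 9)
  mc <- model_config(n_conv_layers = 1, hidden_width = 4, mlp_width = 4,
                     n_mlp_hidden_layers = 1)
  tc <- train_config(learning_rate = 1e-3, n_epochs = 2, n_members = 2,
                     base_seed = 1)
  e1 <- train_ensemble(recs, mc, tc)
  e2 <- train_ensemble(recs, mc, tc)
  expect_length(e1$members, 2)
  expect_identical(e1$members[[1]]$par, e2$members[[1]]$par)
  expect_identical(e1$members[[2]]$par, e2$members[[2]]$par)
  expect_false(identical(e1$members[[1]]$par, e1$members[[2]]$par))
  # single-class data rejected
  unl <- lapply(recs, function(r) molecule_record(r$id, r$smiles, r$n_heavy))
  expect_error(train_ensemble(unl, mc, tc), "training error")
  expect_error(train_ensemble(list(), mc, tc), "empty")
})

test_that("an ensemble of identical members has zero epistemic uncertainty", {
  ens <- tiny_ensemble(1)
  clone <- ens
  clone$members <- rep(ens$members, 3)
  pred <- predict(clone, small_library(30, seed = 5)[1:5])
  expect_true(all(abs(pred$table$u_epi) < 1e-12))
  expect_equal(pred$table$u_tot, pred$table$u_ale, tolerance = 1e-12)
})

test_that("prediction is batch-size invariant and internally consistent", {
  ens <- tiny_ensemble(2)
  recs <- small_library(30, seed = 5)[1:4]
  joint <- predict(ens, recs)
  solo <- predict(ens, recs[2])
  sel <- joint$table$molecule_id == recs[[2]]$id
  expect_equal(solo$table$bma, joint$table$bma[sel], tolerance = 1e-12)
  tab <- joint$table
  expect_equal(tab$u_tot, tab$u_ale + tab$u_epi, tolerance = 1e-9)
  expect_equal(tab$bma, rowMeans(joint$member_probs), tolerance = 1e-12)
  expect_identical(tab$call, as.integer(tab$bma >= ens$train_cfg$threshold))
  expect_equal(nrow(tab), sum(vapply(recs, `[[`, integer(1), "n_heavy")))
})
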