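test_that("library generation is a pure function of the config seed", {
  cfg <- synth_config(n_molecules = 25, seed = 42)
  l1 <- generate_library(cfg)
  l2 <- generate_library(cfg)
  expect_length(l1, 25)
  expect_identical(vapply(l1, `[[`, character(1), "smiles"),
                   vapply(l2, `[[`, character(1), "smiles"))
  l3 <- generate_library(synth_config(n_molecules = 25, seed = 43))
  expect_false(identical(vapply(l1, `[[`, character(1), "smiles"),
                         vapply(l3, `[[`, character(1), "smiles")))
})

test_that("generated molecules are valid and within the size envelope", {
  lib <- generate_library(synth_config(n_molecules = 60, seed = 1))
  nh <- vapply(lib, `[[`, integer(1), "n_heavy")
  expect_true(all(nh >= 5 & nh <= 50))
  for (r in lib[1:10]) {
    g <- build_graph(r)  # parses and sanitizes
    expect_equal(g$n, r$n_heavy)
  }
})

test_that("halogenated fraction tracks the configured rate", {
  lib <- generate_library(synth_config(n_molecules = 400, seed = 2,
                                       halogen_fraction = 0.3))
  hal <- vapply(lib, function(r)
    any(build_graph(r)$element %in% HALOGENS), logical(1))
  # binomial 99.9% band around 0.3 at n=400
  expect_gt(mean(hal), 0.3 - 3.3 * sqrt(0.3 * 0.7 / 400))
  expect_lt(mean(hal), 0.3 + 3.3 * sqrt(0.3 * 0.7 / 400))
  lib0 <- generate_library(synth_config(n_molecules = 50, seed = 2,
                                        halogen_fraction = 0))
  expect_false(any(vapply(lib0, function(r)
    any(build_graph(r)$element %in% HALOGENS), logical(1))))
})

test_that("label rules fire on their motifs with first-match precedence", {
  cfg <- synth_config(seed = 0)
  eth <- list(molecule_record("e", "CCO", 3))
  lab <- apply_label_rules(eth, default_label_rules(), cfg)
  expect_identical(lab[[1]]$som_indices, 2L)  # carbon alpha to the hydroxyl
  tol <- apply_label_rules(list(molecule_record("t", "Cc1ccccc1", 7)),
                           default_label_rules(), cfg)
  expect_identical(tol[[1]]$som_indices, 1L)  # benzylic methyl
  # a zero-probability ruleset realises no positives -> labeling error
  null_rule <- list(label_rule("never", "nothing",
                               function(g) rep(TRUE, g$n), prob = 0))
  expect_error(apply_label_rules(eth, null_rule, cfg), "labeling error")
  expect_error(apply_label_rules(eth, list(), cfg), "nonempty")
})

test_that("halogens are never labeled SOM under the default convention", {
  cfg <- synth_config(n_molecules = 80, seed = 3)
  lab <- apply_label_rules(generate_library(cfg), default_label_rules(), cfg)
  for (r in lab) {
    g <- build_graph(r)
    expect_true(all(r$labels[g$element %in% HALOGENS] == 0))
  }
})

test_that("realised imbalance lies in the curated-data band", {
  cfg <- synth_config(n_molecules = 500, seed = 0)
  lab <- apply_label_rules(generate_library(cfg), default_label_rules(), cfg)
  ratio <- attr(lab, "som_ratio")
  expect_gt(ratio, 1 / 14)
  expect_lt(ratio, 1 / 7)
  expect_gt(attr(lab, "mean_soms_per_molecule"), 1)
})

test_that("flip_noise is identity at 0, involutive at 1, binomial between", {
  recs <- small_library(25, seed = 13)
  all_atoms <- function(g) rep(TRUE, g$n)
  f0 <- flip_noise(recs, all_atoms, 0, seed = 1)
  expect_identical(lapply(f0, `[[`, "labels"), lapply(recs, `[[`, "labels"))
  f1 <- flip_noise(recs, all_atoms, 1, seed = 1)
  for (k in seq_along(recs)) {
    expect_identical(f1[[k]]$labels, 1L - recs[[k]]$labels)
  }
  n_total <- sum(vapply(recs, `[[`, integer(1), "n_heavy"))
  f5 <- flip_noise(recs, all_atoms, 0.5, seed = 1)
  nf <- attr(f5, "n_flipped")
  expect_gt(nf, 0.5 * n_total - 3.3 * sqrt(n_total * 0.25))
  expect_lt(nf, 0.5 * n_total + 3.3 * sqrt(n_total * 0.25))
})

test_that("element exclusion removes exactly the matching molecules", {
  lib <- small_library(40, seed = 11)
  kept <- exclude_element(lib, HALOGENS)
  for (r in kept) expect_false(any(build_graph(r)$element %in% HALOGENS))
  n_hal <- sum(vapply(lib, function(r)
    any(build_graph(r)$element %in% HALOGENS), logical(1)))
  expect_length(kept, length(lib) - n_hal)
  # absent element: identity
  expect_length(exclude_element(lib, "Xx"), length(lib))
})

test_that("element-noise injection balances element labels exactly", {
  lib <- small_library(40, seed = 11)
  has_hal <- vapply(lib, function(r)
    any(build_graph(r)$element %in% HALOGENS), logical(1))
  aug <- inject_element_noise(lib, HALOGENS)
  expect_length(aug, length(lib) + sum(has_hal))
  hal_labels <- unlist(lapply(aug, function(r) {
    g <- build_graph(r)
    r$labels[g$element %in% HALOGENS]
  }))
  expect_equal(sum(hal_labels == 1), sum(hal_labels == 0))
  # duplicates only mislabel the target element
  dup <- aug[[length(lib) + 1]]
  orig <- lib[has_hal][[1]]
  g <- build_graph(orig)
  non_hal <- !(g$element %in% HALOGENS)
  expect_identical(dup$labels[non_hal], orig$labels[non_hal])
  expect_true(all(dup$labels[!non_hal] == 1))
  expect_error(inject_element_noise(lib, "Xx"), "contract error")
})
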