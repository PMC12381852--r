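test_that("molecule_record enforces label/index invariants", {
  r <- molecule_record("m", "CCO", 3, 2)
  expect_identical(r$labels, c(0L, 1L, 0L))
  expect_identical(which(r$labels == 1L), r$som_indices)
  expect_error(molecule_record("m", "CCO", 3, 4), "out of range")
  expect_error(molecule_record("m", "CCO", 3, 0), "out of range")
  r0 <- molecule_record("m", "CCO", 3)
  expect_length(r0$som_indices, 0)
})

test_that("SDF and SMILES-table inputs yield identical records", {
  tf_sdf <- tempfile(fileext = ".sdf")
  tf_csv <- tempfile(fileext = ".csv")
  recs <- list(molecule_record("m1", "CCO", 3, 2))
  write_molecules(recs, tf_sdf, "sdf")
  write_molecules(recs, tf_csv, "smiles-table")
  from_sdf <- read_molecules(tf_sdf, "sdf")
  from_csv <- read_molecules(tf_csv, "smiles-table")
  expect_length(from_sdf, 1)
  expect_equal(from_sdf[[1]]$n_heavy, 3)
  expect_equal(from_sdf[[1]]$som_indices, 2L)
  expect_equal(from_csv[[1]]$n_heavy, 3)
  expect_equal(from_csv[[1]]$som_indices, 2L)
})

test_that("unparseable entries are skipped and counted", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("id,smiles,som_indices",
               "a,CCO,2", "b,xx((bad,", "c,c1ccccc1,"), tf)
  expect_warning(recs <- read_molecules(tf, "smiles-table"), "skipped")
  expect_length(recs, 2)
  expect_identical(attr(recs, "n_skipped"), 1L)
  expect_identical(vapply(recs, `[[`, character(1), "id"), c("a", "c"))
})

test_that("read_molecules errors on missing or empty input", {
  expect_error(read_molecules(tempfile(), "sdf"), "not found")
  tf <- tempfile(fileext = ".csv")
  writeLines(c("id,smiles,som_indices", "a,notparseable((,1"), tf)
  expect_error(suppressWarnings(read_molecules(tf, "smiles-table")),
               "no parseable")
})

test_that("molecule round-trip preserves som_indices and n_heavy", {
  recs <- small_library(15, seed = 7)
  for (fmt in c("sdf", "smiles-table")) {
    tf <- tempfile(fileext = if (fmt == "sdf") ".sdf" else ".csv")
    write_molecules(recs, tf, fmt)
    back <- read_molecules(tf, fmt)
    expect_length(back, length(recs))
    for (k in seq_along(recs)) {
      expect_identical(back[[k]]$n_heavy, recs[[k]]$n_heavy)
      expect_identical(back[[k]]$som_indices, recs[[k]]$som_indices)
    }
  }
})

test_that("build_graph produces the expected heavy-atom topology", {
  g <- build_graph(molecule_record("e", "CCO", 3))
  expect_equal(g$n, 3)
  expect_equal(nrow(g$bonds), 2)
  expect_false(any(g$aromatic))
  expect_equal(g$n_h, c(3L, 2L, 1L))

  gb <- build_graph(molecule_record("b", "c1ccccc1", 6))
  expect_equal(gb$n, 6)
  expect_equal(nrow(gb$bonds), 6)
  expect_true(all(gb$aromatic))
  expect_true(all(gb$bonds$aromatic))
  expect_true(all(gb$ring))

  gm <- build_graph(molecule_record("m", "[CH4]", 1))
  expect_equal(gm$n, 1)
  expect_equal(nrow(gm$bonds), 0)
  expect_equal(gm$n_h, 4L)
})

test_that("build_graph has no self-loops and symmetric implied edges", {
  recs <- small_library(10, seed = 3)
  for (r in recs) {
    g <- build_graph(r)
    expect_false(any(g$bonds$i == g$bonds$j))
    key <- paste(pmin(g$bonds$i, g$bonds$j), pmax(g$bonds$i, g$bonds$j))
    expect_false(any(duplicated(key)))
    expect_true(all(g$bonds$i >= 1 & g$bonds$i <= g$n))
    expect_true(all(g$bonds$j >= 1 & g$bonds$j <= g$n))
  }
})

test_that("build_graph is invariant to atom reordering up to permutation", {
  # same molecule written in two atom orders: 1-propanol
  g1 <- build_graph(molecule_record("a", "CCCO", 4))
  g2 <- build_graph(molecule_record("b", "OCCC", 4))
  perm <- c(4, 3, 2, 1)  # maps atoms of g1 onto g2
  expect_identical(g1$element, g2$element[perm])
  expect_identical(g1$n_h, g2$n_h[perm])
  expect_identical(g1$degree, g2$degree[perm])
})

test_that("prediction tables round-trip at 6-decimal precision", {
  tab <- data.frame(
    molecule_id = c("m1", "m1", "m1"), atom = 1:3,
    element = c("C", "C", "O"), bma = c(0.123456789, 0.5, 0.9),
    call = c(0L, 1L, 1L), u_tot = c(0.1234567, 1, 0.3),
    u_ale = c(0.1, 0.9, 0.25), u_epi = c(0.0234567, 0.1, 0.05),
    category = c("reliable", "noisy-label-regime", "out-of-coverage"),
    stringsAsFactors = FALSE
  )
  for (fmt in c("csv", "json")) {
    tf <- tempfile()
    write_predictions(tab, tf, fmt)
    back <- read_predictions(tf, fmt)
    expect_equal(nrow(back), 3)
    expect_equal(back$bma, round(tab$bma, 6), tolerance = 1e-12)
    expect_equal(back$u_epi, round(tab$u_epi, 6), tolerance = 1e-12)
    expect_identical(back$category, tab$category)
  }
})

test_that("write_predictions flags empty tables and contract violations", {
  tab <- data.frame(molecule_id = character(0))
  tf <- tempfile()
  expect_warning(write_predictions(tab, tf, "csv"), "empty")
  bad <- data.frame(molecule_id = "m", atom = 1)
  expect_error(write_predictions(bad, tempfile(), "csv"), "lacks columns")
})
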