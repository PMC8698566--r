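test_that("profile generation is deterministic and validates parameters", {
  a <- generate_profiles(60, seed = 5)
  b <- generate_profiles(60, seed = 5)
  expect_identical(a, b)
  c_ <- generate_profiles(60, seed = 6)
  expect_false(identical(a$table$values, c_$table$values))
  expect_error(generate_profiles(10), class = "parameter_error")
  expect_error(generate_profiles(60, archetype_mix = c(A = 0.5, B = 0.2)),
               class = "parameter_error")
  expect_error(generate_profiles(60, noise_sd = -1),
               class = "parameter_error")
})

test_that("zero-noise single-archetype data reproduces the archetype exactly", {
  sim <- generate_profiles(60, archetype_mix = c(A = 1), noise_sd = 0,
                           replicate_sd = 0, frac_low_peptides = 0,
                           frac_missing = 0, seed = 3)
  prof <- quiet_profiles(sim$table)
  expect_equal(nrow(prof), 60)
  tmpl <- archetype_profiles()["A", ]
  for (i in seq_len(nrow(prof)))
    expect_equal(unname(prof[i, ]), unname(tmpl), tolerance = 1e-10)
})

test_that("time 0 is the shared untreated control (ratio exactly 1)", {
  sim <- generate_profiles(80, seed = 2)
  rat <- suppressMessages(compute_ratios(sim$table))
  t0 <- rat$ratios[, rat$layout$time == 0]
  expect_true(all(abs(t0 - 1) < 1e-12, na.rm = TRUE))
})

test_that("per-archetype mean profiles match an independent simulation oracle", {
  ## Oracle: direct Monte-Carlo of the construction (standardize the raw
  ## archetype curve plus t>0 noise), independent of the generator code.
  n <- 1000
  sim <- generate_profiles(n, archetype_mix = c(A = .2, B = .2, C = .2,
                                                D = .2, E = .2),
                           noise_sd = 0.3, seed = 17, replicate_sd = 0,
                           frac_low_peptides = 0, frac_missing = 0)
  prof <- quiet_profiles(sim$table)
  raw <- archetype_profiles(standardized = FALSE)
  set.seed(424242)
  for (arch in rownames(raw)) {
    ids <- sim$truth$proteins$protein_id[
      sim$truth$proteins$archetype == arch]
    got <- colMeans(prof[ids, ])
    mc <- replicate(4000, {
      q <- raw[arch, ] + c(0, stats::rnorm(4, 0, 0.3))
      (q - mean(q)) / stats::sd(q)
    })
    oracle <- rowMeans(mc)
    oracle_sd <- apply(mc, 1, stats::sd)
    band <- 3 * oracle_sd * (1 / sqrt(length(ids)) + 1 / sqrt(4000))
    expect_true(all(abs(got - oracle) < band),
                info = sprintf("archetype %s", arch))
  }
})

test_that("annotation generation plants the documented biases", {
  sim <- generate_profiles(400, seed = 8)
  ann <- generate_annotations(sim$truth, bias_odds = 8, seed = 8)
  expect_s3_class(ann, "annotation_table")
  expect_identical(ann, generate_annotations(sim$truth, 8, seed = 8))
  expect_error(generate_annotations(sim$truth, bias_odds = 0.5),
               class = "parameter_error")
  planted <- attr(ann, "planted")
  expect_true(all(c("archetype", "kind", "category") %in% names(planted)))
  ## null setting carries no planted table
  ann0 <- generate_annotations(sim$truth, bias_odds = 1, seed = 8)
  expect_equal(nrow(attr(ann0, "planted")), 0)
  ## direction of the bias: plasma membrane more common in A than baseline
  lab <- sim$truth$proteins$archetype
  pmA <- mean(ann$compartment[lab == "A"] == "plasma membrane")
  pm0 <- mean(ann0$compartment[lab == "A"] == "plasma membrane")
  expect_gt(pmA, pm0)
})

test_that("PPI generation honors hub degrees and determinism", {
  sim <- generate_profiles(300, seed = 4)
  g <- generate_ppi(sim$truth, base_rate = 0.01,
                    hub_spec = c(P00001 = 97), seed = 9)
  expect_equal(unname(igraph::degree(g, "P00001")), 97)
  expect_equal(igraph::vcount(g), 300)
  expect_true(igraph::is_simple(g))
  g2 <- generate_ppi(sim$truth, base_rate = 0.01,
                     hub_spec = c(P00001 = 97), seed = 9)
  expect_true(igraph::identical_graphs(g, g2))
  expect_error(generate_ppi(sim$truth, base_rate = 0),
               class = "parameter_error")
})

test_that("planted cluster-pair excess shows up in raw edge counts", {
  sim <- generate_profiles(600, seed = 12)
  g <- generate_ppi(sim$truth, base_rate = 0.003,
                    pair_excess = c("C/E" = 5, "D/E" = 5, "C/D" = 5),
                    seed = 12)
  lab <- stats::setNames(sim$truth$proteins$archetype,
                         sim$truth$proteins$protein_id)
  el <- igraph::as_edgelist(g)
  key <- paste(pmin(lab[el[, 1]], lab[el[, 2]]),
               pmax(lab[el[, 1]], lab[el[, 2]]), sep = "/")
  tab <- table(key)
  ## planted pairs should hold roughly 5x the edges of a same-size null pair
  expect_gt(tab[["C/E"]], 2 * tab[["A/B"]])
  expect_gt(tab[["C/D"]], 2 * tab[["A/E"]])
})

test_that("concept and marker generators are deterministic with planted truth", {
  sim <- generate_profiles(200, seed = 3)
  con <- generate_concepts(sim$truth, n_concepts = 7, overlap_odds = 10,
                           seed = 5)
  expect_length(con, 7)
  expect_identical(con, generate_concepts(sim$truth, 7, 10, seed = 5))
  expect_length(attr(con, "designated"), 7)
  expect_error(generate_concepts(sim$truth, overlap_odds = 0.2),
               class = "parameter_error")

  mk <- generate_marker_datasets(n_datasets = 3, n_genes = 50,
                                 planted = c(FASN = 1, CDC42 = -1),
                                 effect = 2, n_per_group = 5,
                                 n_support = 2, seed = 6)
  expect_length(mk, 3)
  expect_identical(mk, generate_marker_datasets(3, 50,
                                                c(FASN = 1, CDC42 = -1),
                                                2, 5, 2, seed = 6))
  expect_true(all(lengths(attr(mk, "support")) == 2))
  expect_true(all(c("FASN", "CDC42") %in% rownames(mk[[1]]$exprs)))

  pd <- generate_paired_dataset(50, planted = c(FASN = 1), n_pairs = 10,
                                seed = 2)
  expect_equal(ncol(pd$exprs), 20)
  expect_equal(pd$pair_id, rep(1:10, 2))
})
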