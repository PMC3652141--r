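test_that("analog enumeration is deterministic and covers the core chemistry", {
  lib <- substituent_library()
  expect_true(all(startsWith(lib$smiles, "*")))

  a <- enumerate_analogs(lib, n = 6, seed = 42)
  b <- enumerate_analogs(lib, n = 6, seed = 42)
  expect_identical(vapply(a, `[[`, character(1), "smiles"),
                   vapply(b, `[[`, character(1), "smiles"))
  c1 <- enumerate_analogs(lib, n = 15, seed = 1, replace = TRUE)
  c2 <- enumerate_analogs(lib, n = 15, seed = 2, replace = TRUE)
  expect_false(identical(vapply(c1, `[[`, character(1), "smiles"),
                         vapply(c2, `[[`, character(1), "smiles")))
})

test_that("the cyclohexyl fragment reconstructs lomustine", {
  lom <- enumerate_analogs(substituent_library()[1, ], n = 1, seed = 1)[[1]]
  expect_equal(formula_weight(lom), 233.7, tolerance = 0.05 / 233.7)
  expect_identical(heavy_atom_count(lom), 15L)
  expect_equal(tpsa(lom), 61.77, tolerance = 1e-6)
})

test_that("every generated analog parses and carries the nitrosourea warhead", {
  lib <- substituent_library()
  mols <- enumerate_analogs(lib, n = nrow(lib), seed = 3)
  for (m in mols) {
    expect_s3_class(m, "molecule")
    # the core alone contributes amide, carbonyl and nitroso polar atoms
    expect_gte(tpsa(m), 61.77 - 1e-9)
    expect_gte(hba_count(m), 5L)
    expect_identical(grepl("N(N=O)", m$smiles, fixed = TRUE), TRUE)
    rec <- compute_descriptors(m)   # descriptor stack never errors on these
    expect_true(all(is.finite(unlist(rec[-1]))))
  }
})

test_that("adding a chlorine substituent never decreases formula weight", {
  lib <- substituent_library()
  plain <- enumerate_analogs(lib[lib$name == "cyclohexyl", ], 1, seed = 1)[[1]]
  chloro <- enumerate_analogs(lib[lib$name == "4-chlorocyclohexyl", ], 1, seed = 1)[[1]]
  expect_gt(formula_weight(chloro), formula_weight(plain))
})

test_that("fragment attachment points are validated", {
  bad0 <- data.frame(name = "x", smiles = "CC", category = "alkyl")
  expect_error(enumerate_analogs(bad0, 1, seed = 1), "no attachment")
  bad2 <- data.frame(name = "x", smiles = "*C*", category = "alkyl")
  expect_error(enumerate_analogs(bad2, 1, seed = 1), "2 attachment")
  lib <- substituent_library()
  expect_error(enumerate_analogs(lib, nrow(lib) + 1, seed = 1), "replace")
})

test_that("simulated tables are reproducible and track the target distribution", {
  a <- simulate_descriptor_table(50, seed = 9)
  b <- simulate_descriptor_table(50, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, simulate_descriptor_table(50, seed = 10)))

  big <- simulate_descriptor_table(1000, seed = 42)
  expect_lt(abs(mean(big$log_p) - 2.524), 3 * 0.5337 / sqrt(1000))
  expect_true(all(big$log_p >= 1.0 & big$log_p <= 4.5))
  expect_true(all(big$fw >= 190 & big$fw <= 315))
  expect_true(all(big$n_atoms %in% 12:17))
  expect_true(all(big$n_rot %in% 4:8))

  none <- simulate_descriptor_table(30, seed = 1, hydroxylated_fraction = 0)
  expect_true(all(none$psa == 61.77))
  expect_true(all(none$n_on == 5L))

  expect_error(simulate_descriptor_table(10, seed = 1, log_p_sd = 0), "positive")
  expect_error(simulate_descriptor_table(0, seed = 1), "at least 1")
})

test_that("an 18-record fixture-mode table passes all three screens", {
  tab <- simulate_descriptor_table(18, seed = 4, n_hydroxylated = 1)
  rep <- screen_library(tab)
  expect_equal(rep$overall_fraction, 1)
  expect_true(all(tab$n_ro5_violations == 0L))
})

test_that("synthetic hydroxylated records reproduce the clustering isolation", {
  hits <- 0L
  for (s in 1:100) {
    tab <- simulate_descriptor_table(18, seed = s, n_hydroxylated = 1)
    hydroxy <- tab$agent_id[tab$psa > 70]
    ct <- suppressMessages(cluster_tree(tab))
    hits <- hits + identical(last_merged_singleton(ct), hydroxy)
  }
  expect_gte(hits, 95L)
})

test_that("regression on model-generated tables recovers the generating coefficients", {
  truth <- c(-24.859, 0.9578, -0.04598, 19.236, -3.947)
  err <- vapply(c(8, 1, 0.01), function(noise) {
    tab <- simulate_descriptor_table(120, seed = 77, fw_noise_sd = noise,
                                     fw_range = c(0, 1000))
    fit <- ols_fit(tab, "fw", c("log_p", "psa", "n_atoms", "n_rot"))
    max(abs(c(fit$intercept, fit$coefficients) - truth))
  }, numeric(1))
  expect_true(all(diff(err) < 0))         # shrinks as noise shrinks
  expect_lt(err[3], err[1] / 100)         # error scales down with the noise
})
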