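test_that("property summaries reproduce the tabulated statistics", {
  s <- summarize_properties(builtin_table1())
  lp <- s[s$property == "log_p", ]
  expect_equal(round(lp$mean, 3), 2.524)
  expect_equal(lp$minimum, 1.537)
  expect_equal(lp$maximum, 3.924)
  expect_equal(lp$median, 2.458)
  expect_equal(round(lp$sd, 4), 0.5337)

  fw <- s[s$property == "fw", ]
  expect_equal(round(fw$mean, 1), 232.8)
  expect_equal(round(fw$sd, 2), 30.76)

  ro5 <- s[s$property == "n_ro5_violations", ]
  expect_identical(c(ro5$sd, ro5$minimum, ro5$maximum, ro5$median, ro5$mean),
                   rep(0, 5))

  expect_error(summarize_properties(builtin_table1()[1, ]), "at least 2")
})

test_that("summary, correlation and OLS agree with first-principles formulas", {
  for (seed in 1:3) {
    tab <- random_table(25, seed)
    s <- summarize_properties(tab)
    x <- tab$fw
    n <- length(x)
    expect_equal(s$mean[s$property == "fw"], sum(x) / n, tolerance = 1e-10)
    expect_equal(s$sd[s$property == "fw"],
                 sqrt(sum((x - sum(x) / n)^2) / (n - 1)), tolerance = 1e-10)
    xs <- sort(x)
    med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
    expect_equal(s$median[s$property == "fw"], med, tolerance = 1e-10)

    cm <- pearson_matrix(tab, c("fw", "log_p"))
    num <- sum((tab$fw - mean(tab$fw)) * (tab$log_p - mean(tab$log_p)))
    den <- sqrt(sum((tab$fw - mean(tab$fw))^2) * sum((tab$log_p - mean(tab$log_p))^2))
    expect_equal(cm["fw", "log_p"], num / den, tolerance = 1e-10)

    fit <- ols_fit(tab, "fw", c("log_p", "psa", "n_atoms", "n_rot"))
    oracle <- ols_oracle(tab$fw, tab[, c("log_p", "psa", "n_atoms", "n_rot")])
    expect_equal(unname(c(fit$intercept, fit$coefficients)),
                 unname(oracle$beta), tolerance = 1e-10)
    expect_equal(fit$r_squared, oracle$r_squared, tolerance = 1e-10)
    expect_equal(fit$fitted + fit$residuals, tab$fw, tolerance = 1e-10)
  }
})

test_that("reference-set correlations match the reported claims", {
  cm <- suppressMessages(pearson_matrix(builtin_table1()))
  expect_gt(cm["fw", "n_atoms"], 0.8700)
  expect_gt(cm["volume", "n_atoms"], 0.8700)
  expect_gt(cm["volume", "fw"], 0.8700)
  expect_gt(cm["log_p", "fw"], 0.5000)
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)))
})

test_that("pearson_matrix drops constant fields and rejects degenerate requests", {
  expect_message(pearson_matrix(builtin_table1()), "n_ro5_violations")
  expect_error(suppressMessages(pearson_matrix(builtin_table1(),
                                               "n_ro5_violations")),
               "zero variance")
  expect_error(pearson_matrix(builtin_table1()[1:2, ], "fw"), "at least 3")
})

test_that("Grubbs' critical values match the published two-sided 5% table", {
  set.seed(1)
  expect_equal(grubbs_test(rnorm(10))$g_critical, 2.290, tolerance = 0.01 / 2.29)
  expect_equal(grubbs_test(rnorm(18))$g_critical, 2.651, tolerance = 0.01 / 2.651)
  expect_equal(grubbs_test(rnorm(30))$g_critical, 2.908, tolerance = 0.01 / 2.908)
})

test_that("no outlier is flagged in the reference property columns", {
  t1 <- builtin_table1()
  for (col in c("log_p", "fw", "volume")) {
    g <- grubbs_test(t1[[col]], alpha = 0.05)
    expect_false(g$outlier_flag)
    expect_true(g$g_statistic >= 0)
  }
  expect_false(grubbs_test(bbb_table(t1)$bb, alpha = 0.05)$outlier_flag)
})

test_that("Grubbs flags a gross outlier and validates input", {
  g <- grubbs_test(c(0, 0, 0, 100), alpha = 0.05)
  expect_true(g$outlier_flag)
  expect_identical(g$outlier_index, 4L)
  expect_equal(g$g_statistic, 1.5)
  expect_equal(g$g_critical, 1.4812, tolerance = 1e-4)
  expect_error(grubbs_test(c(1, 2)), "at least 3")
  expect_error(grubbs_test(rep(1, 5)), "zero standard deviation")
})

test_that("the formula-weight regression reproduces the printed equation", {
  fit <- ols_fit(builtin_table1(), "fw", c("log_p", "psa", "n_atoms", "n_rot"))
  expect_equal(round(fit$r_squared, 4), 0.7934)
  printed <- c(-24.859, 0.9578, -0.04598, 19.236, -3.947)
  got <- unname(c(fit$intercept, fit$coefficients))
  expect_true(all(abs(got - printed) / abs(printed) < 0.005))
})

test_that("OLS handles exact fits and names collinear predictors", {
  exact <- data.frame(agent_id = as.character(1:10), x = 1:10, y = 2 * (1:10))
  fit <- suppressWarnings(ols_fit(exact, "y", "x"))  # exact fit warns in summary()
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)

  dup <- random_table(12, 9)
  dup$fw2 <- dup$fw
  expect_error(ols_fit(dup, "log_p", c("fw", "fw2")), "fw2")
  expect_error(ols_fit(dup, "nope", "fw"), "unknown field")
  expect_error(ols_fit(dup[1:3, ], "fw", c("log_p", "psa", "n_atoms")),
               "more records")
})

test_that("path coefficients equal OLS on z-scored variables", {
  for (seed in 11:13) {
    tab <- random_table(20, seed)
    preds <- c("log_p", "psa", "n_atoms", "n_rot")
    pc <- path_coefficients(tab, "fw", preds)
    z <- as.data.frame(scale(tab[, c("fw", preds)]))
    z$agent_id <- tab$agent_id
    ref <- ols_fit(z, "fw", preds)
    expect_equal(pc$coefficients, ref$coefficients, tolerance = 1e-10)
    # full-rank minimum-norm solution coincides with OLS
    mn <- path_coefficients(tab, "fw", preds, method = "minnorm")
    expect_equal(mn$coefficients, pc$coefficients, tolerance = 1e-8)

    one <- path_coefficients(tab, "fw", "log_p")
    expect_equal(unname(one$coefficients), cor(tab$fw, tab$log_p),
                 tolerance = 1e-10)
  }
})

test_that("near-collinear reference predictors error under OLS, resolve under minnorm", {
  t1 <- builtin_table1()
  preds7 <- c("log_p", "psa", "n_atoms", "n_on", "n_ohnh", "n_rot", "volume")
  expect_error(path_coefficients(t1, "fw", preds7), "collinear")
  mn <- path_coefficients(t1, "fw", preds7, method = "minnorm")
  expect_true(all(is.finite(mn$coefficients)))
  expect_true(all(abs(mn$coefficients) < 5))  # no exploding collinear pair
  expect_error(path_coefficients(t1, "fw", "n_ro5_violations"), "zero-variance")
})

test_that("ANOSIM attains R = 1 under complete group separation", {
  set.seed(42)
  x <- rbind(matrix(rnorm(20, 0, 0.1), 5), matrix(rnorm(20, 10, 0.1), 5))
  g <- rep(c("a", "b"), each = 5)
  res <- anosim_test(stats::dist(x), g, n_permutations = 199, seed = 1)
  expect_equal(res$r_statistic, 1)
  expect_lt(res$p_value, 0.05)
  expect_true(abs(res$r_statistic) <= 1)
})

test_that("the ANOSIM statistic matches vegan and is seed-deterministic", {
  skip_if_not_installed("vegan")
  t1 <- builtin_table1()
  g <- rep(c("a", "b", "c"), times = 6)
  ours <- suppressMessages(anosim_test(t1, g, n_permutations = 99, seed = 3))
  z <- scale(as.matrix(as.data.frame(t1)[, c("log_p", "psa", "n_atoms", "fw",
                                             "n_on", "n_ohnh", "n_rot", "volume")]))
  ref <- vegan::anosim(stats::dist(z), factor(g), permutations = 19)
  expect_equal(ours$r_statistic, unname(ref$statistic), tolerance = 1e-12)

  again <- suppressMessages(anosim_test(t1, g, n_permutations = 99, seed = 3))
  expect_identical(ours$p_value, again$p_value)
  expect_error(anosim_test(t1, rep("a", 18), n_permutations = 9, seed = 1),
               "two groups")
})

test_that("ANOSIM type-I error is near nominal on exchangeable data", {
  reject <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    x <- matrix(rnorm(12 * 4), 12)
    g <- rep(c("a", "b"), each = 6)
    anosim_test(stats::dist(x), g, n_permutations = 199, seed = i)$p_value <= 0.05
  }, logical(1))
  # binomial 3-sigma band around the nominal 5% level
  expect_lt(abs(mean(reject) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})
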