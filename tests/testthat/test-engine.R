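test_that("scenario_config validates the burn-in/treatment split", {
  expect_error(scenario_config(burn_in = 300, generations = 300), "burn_in")
  expect_error(scenario_config(bm = 0), "bm")
  s <- scenario_config(eta = 0.02, alpha = -0.7, pR = 0.5, bm = 25)
  expect_equal(scenario_id(s), "eta0.02_alpha-0.7_pR0.5_bm25_gamma2.2")
})

test_that("identical (scenario, seed) pairs give bit-identical series", {
  s <- tiny_scenario(eta = 0.04, pR = 1)
  r1 <- run_replicate(s, seed = 123)
  r2 <- run_replicate(s, seed = 123)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$final_mean_mu, r2$final_mean_mu)
  # a different seed gives a different trajectory
  r3 <- run_replicate(s, seed = 124)
  expect_false(identical(r1$series$mean_z, r3$series$mean_z))
})

test_that("a non-extinct run records one row per generation", {
  s <- tiny_scenario(K = 200, generations = 50, burn_in = 20)
  r <- run_replicate(s, seed = 5)
  expect_false(r$extinct)
  expect_equal(nrow(r$series), 50)
  expect_equal(r$series$generation, 1:50)
  # the trend switches on after the burn-in
  expect_true(all(r$series$theta_t[1:20] == 0))
  expect_equal(r$series$theta_t[21:50], s$eta * (1:30))
  # exact decomposition of the realized optimum
  expect_equal(r$series$theta_star, r$series$theta_t + r$series$phi_t)
})

test_that("a stable, well-adapted population persists for 300 generations", {
  s <- scenario_config(eta = 0, K = 300, replicates = 20, base_seed = 31,
                       mutator_init = 1000)  # mutation disabled
  res <- run_experiment(s)
  expect_gte(sum(!res$replicates$extinct), 19)  # >= 95% of 20
  expect_true(all(res$replicates$final_N[!res$replicates$extinct] > 0))
})

test_that("run_experiment produces one row per replicate plus a summary row", {
  s <- tiny_scenario(replicates = 5)
  res <- run_experiment(s)
  expect_s3_class(res, "experiment_results")
  expect_equal(nrow(res$replicates), 5)
  expect_equal(nrow(res$summary), 1)
  expect_equal(res$summary$n_replicates, 5)
  # seeds are recorded and distinct across replicates
  expect_equal(length(unique(res$replicates$seed)), 5)
})

test_that("base_seed changes values but not the schema", {
  s1 <- tiny_scenario(replicates = 3, base_seed = 1)
  s2 <- tiny_scenario(replicates = 3, base_seed = 2)
  r1 <- run_experiment(s1)
  r2 <- run_experiment(s2)
  expect_identical(names(r1$replicates), names(r2$replicates))
  expect_false(identical(r1$replicates$final_mean_mu,
                         r2$replicates$final_mean_mu))
})

test_that("series collection stacks per-generation rows across replicates", {
  s <- tiny_scenario(replicates = 2, K = 80, generations = 20, burn_in = 5)
  res <- run_experiment(s, series = TRUE)
  expect_false(is.null(res$series))
  expect_setequal(unique(res$series$replicate), 1:2)
  expect_lte(nrow(res$series), 2 * 20)
})

test_that("summarize_final_mutation_rate excludes extinct runs and flags empty cells", {
  df <- data.frame(
    scenario = rep(c("a", "b"), c(4, 3)),
    eta = 0, alpha = 0, pR = 0, bm = 50, gamma = 2.2,
    final_mean_mu = c(1e-3, 1e-2, 1e-1, 5, NA, NA, NA),
    extinct = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  )
  out <- summarize_final_mutation_rate(df)
  a <- out[out$scenario == "a", ]
  expect_equal(a$n_used, 3)
  expect_equal(a$median_mu, 1e-2)  # mixed set {1e-3, 1e-2, 1e-1}
  expect_equal(a$median_log10_mu, -2)
  b <- out[out$scenario == "b", ]
  expect_true(b$no_data)
  expect_equal(b$n_used, 0)
  expect_true(is.na(b$median_mu))
  # degenerate all-equal set
  df2 <- df[1:2, ]
  df2$final_mean_mu <- 1e-3
  expect_equal(summarize_final_mutation_rate(df2)$median_mu, 1e-3)
})

test_that("extinction is recorded with its generation and excluded from summaries", {
  # harsh scenario: very fast change, strong selection, tiny population
  s <- scenario_config(eta = 0.5, K = 30, gamma = 1, bm = 10,
                       generations = 150, burn_in = 20, replicates = 5,
                       base_seed = 17)
  res <- run_experiment(s)
  ext <- res$replicates[res$replicates$extinct, ]
  expect_gt(nrow(ext), 0)
  expect_true(all(is.finite(ext$extinct_generation)))
  expect_true(all(is.na(ext$final_mean_mu)))
  if (all(res$replicates$extinct)) expect_true(res$summary$no_data)
})
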