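test_that("mutation_rate maps mutator alleles to 10^-(mean exponent), clamped", {
  expect_equal(mutation_rate(3, 3), 1e-3)
  expect_equal(mutation_rate(2, 4), 1e-3)  # same allele mean
  expect_equal(mutation_rate(-1, -1), 1)   # clamped at the declared bound
  # symmetric in the two alleles, vectorized
  m1 <- c(2, 3.5, -2, 8); m2 <- c(4, 1, 0, 8)
  expect_equal(mutation_rate(m1, m2), mutation_rate(m2, m1))
  expect_true(all(mutation_rate(m1, m2) >= 0 & mutation_rate(m1, m2) <= 1))
})

test_that("effect_mean places exactly mass q above the cut", {
  expect_equal(effect_mean(0.5, 0.2), 0)
  # frozen values, independently verified by root-finding on the normal CDF
  expect_equal(effect_mean(0.25, 0.2), -0.3016409863, tolerance = 1e-8)
  expect_equal(effect_mean(0.10, 0.2), -0.5731272834, tolerance = 1e-8)
  # defining property, checked through the CDF for several (q, MV)
  for (q in c(0.1, 0.25, 0.4, 0.5)) {
    for (MV in c(0.1, 0.2)) {
      x <- effect_mean(q, MV)
      expect_equal(1 - pnorm(0, mean = x, sd = sqrt(MV)), q)
    }
  }
  expect_error(effect_mean(0, 0.2), "q")
  expect_error(effect_mean(1, 0.2), "q")
  expect_error(effect_mean(0.5, -1), "MV")
})

test_that("mutation_model resolves the DFE mean and validates input", {
  m <- mutation_model(bm = 25, MV = 0.2)
  expect_equal(m$q, 0.25)
  expect_equal(m$x, effect_mean(0.25, 0.2))
  expect_equal(mutation_model(bm = 25, symmetric = TRUE)$x, 0)
  expect_error(mutation_model(bm = 0), "bm")
  expect_error(mutation_model(bm = 100), "bm")
  expect_error(mutation_model(bm = 50, MV = 0), "MV")
})

test_that("empirical beneficial fraction matches q within 3 binomial SEs", {
  set.seed(42)
  n <- 1e6
  for (q in c(0.10, 0.25, 0.40, 0.50)) {
    model <- mutation_model(bm = 100 * q, MV = 0.2)
    eff <- draw_effects(n, model)
    frac <- mean(eff > 0)
    expect_lt(abs(frac - q), 3 * sqrt(q * (1 - q) / n))
    # sample moments match the construction
    expect_equal(mean(eff), model$x, tolerance = 3 * sqrt(0.2 / n) / max(abs(model$x), 0.01))
    expect_equal(var(eff), 0.2, tolerance = 0.01)
  }
})

test_that("mutator steps are uniform on {-1, 0, +1}", {
  set.seed(7)
  steps <- draw_mutator_steps(1e5)
  expect_true(all(steps %in% c(-1L, 0L, 1L)))
  p <- chisq.test(table(factor(steps, levels = c(-1, 0, 1))))$p.value
  expect_gt(p, 0.001)
})

test_that("apply_mutations leaves genomes unchanged when mu ~ 0", {
  set.seed(1)
  pop <- new_population(a1 = rnorm(50), a2 = rnorm(50),
                        m1 = rep(1000, 50), m2 = rep(1000, 50),
                        female = rep(c(TRUE, FALSE), 25))
  out <- apply_mutations(pop, mutation_model(bm = 25))
  expect_identical(out$a1, pop$a1)
  expect_identical(out$m1, pop$m1)
  expect_identical(out$z, pop$z)
})

test_that("apply_mutations perturbs all four alleles when mu = 1", {
  set.seed(2)
  n <- 200
  pop <- new_population(a1 = numeric(n), a2 = numeric(n),
                        m1 = numeric(n), m2 = numeric(n),
                        female = rep(c(TRUE, FALSE), n / 2))
  expect_equal(unique(mutation_rate(pop$m1, pop$m2)), 1)
  out <- apply_mutations(pop, mutation_model(bm = 25, MV = 0.2))
  # adaptation effects are continuous: a zero change has probability 0
  expect_true(all(out$a1 != 0) && all(out$a2 != 0))
  # mutator steps land in {-1, 0, +1} around the old value 0
  expect_true(all(out$m1 %in% c(-1, 0, 1)) && all(out$m2 %in% c(-1, 0, 1)))
  # mu was frozen from pre-mutation alleles, so every row got 4 trials at mu=1
  expect_equal(out$z, out$a1 + out$a2)
})

test_that("pooled mutation effects through apply_mutations match the target q", {
  set.seed(3)
  n <- 2e5
  pop <- new_population(a1 = numeric(n), a2 = numeric(n),
                        m1 = numeric(n), m2 = numeric(n),
                        female = rep(c(TRUE, FALSE), n / 2))
  out <- apply_mutations(pop, mutation_model(bm = 25, MV = 0.2))
  eff <- c(out$a1, out$a2)  # a1/a2 started at 0, so values ARE the effects
  expect_equal(mean(eff > 0), 0.25, tolerance = 0.01)
})

test_that("per_locus trial mode mutates at most one allele per locus", {
  set.seed(4)
  n <- 300
  pop <- new_population(a1 = numeric(n), a2 = numeric(n),
                        m1 = numeric(n), m2 = numeric(n),
                        female = rep(c(TRUE, FALSE), n / 2))
  out <- apply_mutations(pop, mutation_model(bm = 50, trials = "per_locus"))
  changed_a <- (out$a1 != 0) + (out$a2 != 0)
  expect_true(all(changed_a <= 1))
  # at mu = 1 the locus trial always fires: exactly one allele changes
  expect_true(all(changed_a == 1))
})
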