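# Shared fixture builders. Everything is generated in code under a seed
# set by the calling test.

# A parent population with fully tagged haplotypes: every allele value is
# distinct so transmitted haplotypes can be traced back.
tagged_parents <- function() {
  new_population(
    a1 = c(1, 100), a2 = c(2, 200),
    m1 = c(10, 1000), m2 = c(20, 2000),
    female = c(TRUE, FALSE),
    stage = "adult"
  )
}

# n couples of identical adults placed so that each has fitness w at the
# given optimum; mutation effectively disabled via huge mutator alleles.
couple_population <- function(n_adults, w = 1, gamma = 2.2, theta_star = 0) {
  d <- sqrt(-2 * gamma^2 * log(w))  # |z - theta*| giving fitness w
  half <- n_adults %/% 2
  new_population(
    a1 = rep((theta_star + d) / 2, n_adults),
    a2 = rep((theta_star + d) / 2, n_adults),
    m1 = rep(1000, n_adults), m2 = rep(1000, n_adults),
    female = rep(c(TRUE, FALSE), length.out = n_adults),
    stage = "adult"
  )
}

no_mutation_model <- function() mutation_model(bm = 50, symmetric = TRUE)

# Small, fast scenario for engine/io tests.
tiny_scenario <- function(...) {
  args <- utils::modifyList(
    list(K = 100, generations = 30, burn_in = 10, replicates = 2,
         base_seed = 99),
    list(...)
  )
  do.call(scenario_config, args)
}
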