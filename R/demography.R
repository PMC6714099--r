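#' Population container
#'
#' A population is a data frame with one row per individual and columns
#' `a1`, `a2` (adaptation-locus allele values, haplotypes 1 and 2), `m1`,
#' `m2` (mutator-locus allele values), `female` (logical sex), `stage`
#' (`"adult"` or `"juvenile"`), `z` (phenotype, the additive sum of the
#' two adaptation alleles) and `w` (degree of local adaptation, `NA`
#' until evaluated). Haplotype pairing is columnwise: (`a1`, `m1`) came
#' from one transmitted haplotype and (`a2`, `m2`) from the other.
#'
#' @param a1,a2 Adaptation-locus allele values.
#' @param m1,m2 Mutator-locus allele values.
#' @param female Logical vector; `TRUE` for females.
#' @param stage `"adult"` or `"juvenile"` (recycled).
#' @return An object of classes `population` and `data.frame`.
#' @export
new_population <- function(a1, a2, m1, m2, female, stage = "adult") {
  n <- length(a1)
  pop <- data.frame(a1 = a1, a2 = a2, m1 = m1, m2 = m2,
                    female = female,
                    stage = rep_len(as.character(stage), n),
                    z = a1 + a2, w = rep(NA_real_, n))
  class(pop) <- c("population", "data.frame")
  pop
}

#' Population configuration
#'
#' @param K Carrying capacity (>= 2 individuals).
#' @param VG Initial genetic variance of the phenotype (> 0).
#' @param L Number of loci per evolving trait (the model fixes 1).
#' @param gamma Strength of stabilizing selection (> 0, trait units);
#'   2.2 is the default (moderate) regime, 3.2 the weaker one.
#' @return An object of class `pop_config`.
#' @export
pop_config <- function(K = 1000, VG = 0.2, L = 1, gamma = 2.2) {
  if (!is.numeric(K) || K < 2) stop("K must be >= 2", call. = FALSE)
  if (!is.numeric(VG) || VG <= 0) stop("VG must be positive", call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (!is.numeric(L) || L < 1) stop("L must be >= 1", call. = FALSE)
  structure(list(K = as.integer(K), VG = VG, L = as.integer(L), gamma = gamma),
            class = "pop_config")
}

#' Initialize a locally adapted population at carrying capacity
#'
#' Creates exactly `K` adults. Each adaptation allele is drawn from
#' N(`theta0`, VG / (2 L)), so the initial phenotypic variance is about
#' `VG`; each mutator allele is drawn uniformly from \{2, 3, 4\}, giving
#' an initial mean mutation rate of 10^-3 (on the exponent scale) with
#' standing variation between individuals. Sex is Bernoulli(0.5).
#'
#' @param cfg A [pop_config()].
#' @param theta0 Initial environmental optimum the population is adapted
#'   to.
#' @param mutator_init Values the initial mutator alleles are sampled
#'   (uniformly) from; the default \{2, 3, 4\} gives the standard initial
#'   mean exponent of 3. A single huge value (e.g. 1000) effectively
#'   disables mutation.
#' @return A [new_population()] of `K` adults.
#' @export
initialize_population <- function(cfg, theta0 = 0, mutator_init = 2:4) {
  K <- cfg$K
  V <- cfg$VG / (2 * cfg$L)
  new_population(
    a1 = stats::rnorm(K, theta0, sqrt(V)),
    a2 = stats::rnorm(K, theta0, sqrt(V)),
    m1 = mutator_init[sample.int(length(mutator_init), K, replace = TRUE)],
    m2 = mutator_init[sample.int(length(mutator_init), K, replace = TRUE)],
    female = stats::runif(K) < 0.5,
    stage = "adult"
  )
}

#' Gaussian stabilizing-selection fitness
#'
#' Degree of local adaptation
#' \eqn{w_i = \exp(-(z_i - \theta^*_t)^2 / (2\gamma^2))}: 1 at the
#' optimum, decaying symmetrically with squared distance. With the
#' default gamma = 2.2, a phenotype 1 SD unit from the optimum has
#' fitness ~90%.
#'
#' @param z Phenotype(s).
#' @param theta_star Realized environmental optimum.
#' @param gamma Strength of selection (> 0); smaller = stronger.
#' @return Fitness value(s) in (0, 1\].
#' @examples
#' fitness(1, 0, 2.2)  # ~0.902
#' @export
fitness <- function(z, theta_star, gamma) {
  if (any(gamma <= 0)) stop("gamma must be positive", call. = FALSE)
  exp(-(z - theta_star)^2 / (2 * gamma^2))
}

#' Density-dependent scaled fitness
#'
#' \eqn{w'_i = w_i e^{1 - N/K}}: boosts fecundity below carrying
#' capacity, suppresses it above, leaves it unchanged at N = K.
#'
#' @param w Fitness value(s).
#' @param N Current population size.
#' @param K Carrying capacity.
#' @return Scaled fitness value(s).
#' @export
scaled_fitness <- function(w, N, K) {
  w * exp(1 - N / K)
}

#' One round of lottery-polygyny reproduction
#'
#' Evaluates fitness against `theta_star`, scales it by density, pairs
#' every female with a male drawn uniformly with replacement (males can
#' mate repeatedly, females mate once), draws each couple's offspring
#' count from Poisson(w'_mother + w'_father), and assembles offspring
#' genomes via [make_offspring()]. With no females or no males the
#' returned population is empty (the extinction pathway).
#'
#' @param adults A [population] of adults.
#' @param theta_star Realized optimum used for fitness evaluation.
#' @param cfg A [pop_config()].
#' @param linkage A [linkage_config()].
#' @param model A [mutation_model()].
#' @return A population of juveniles (possibly empty).
#' @export
reproduce <- function(adults, theta_star, cfg, linkage, model) {
  N <- nrow(adults)
  females <- which(adults$female)
  males <- which(!adults$female)
  if (length(females) == 0L || length(males) == 0L)
    return(empty_population())
  w <- fitness(adults$z, theta_star, cfg$gamma)
  wp <- scaled_fitness(w, N, cfg$K)
  mates <- males[sample.int(length(males), length(females), replace = TRUE)]
  n_off <- stats::rpois(length(females), wp[females] + wp[mates])
  mothers <- rep.int(females, n_off)
  fathers <- rep.int(mates, n_off)
  if (length(mothers) == 0L) return(empty_population())
  make_offspring(adults, mothers, fathers, linkage, model)
}

empty_population <- function() {
  new_population(a1 = numeric(0), a2 = numeric(0),
                 m1 = numeric(0), m2 = numeric(0),
                 female = logical(0), stage = character(0))
}
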