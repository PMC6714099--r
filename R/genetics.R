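#' Mutation rate from mutator-locus alleles
#'
#' The genome-wide mutation probability is \eqn{\mu = 10^{-e}} with
#' \eqn{e = (l_{m,1} + l_{m,2}) / 2}, the mean of the two mutator alleles.
#' \eqn{\mu} is clamped to \[0, 1\]; the alleles themselves are unbounded.
#' Symmetric in the two alleles, vectorized over individuals.
#'
#' @param m1,m2 Mutator allele values (haplotype 1 and 2).
#' @return Mutation probabilities in \[0, 1\].
#' @examples
#' mutation_rate(3, 3)   # 1e-3
#' mutation_rate(2, 4)   # 1e-3, same allele mean
#' mutation_rate(-1, -1) # clamped to 1
#' @export
mutation_rate <- function(m1, m2) {
  pmin(1, pmax(0, 10^(-(m1 + m2) / 2)))
}

#' Mean of the quantile-shifted mutation-effect distribution
#'
#' The effect of a new mutation on the adaptation locus is drawn from a
#' normal distribution with variance `MV` whose mean `x` is shifted so
#' that exactly a fraction `q` of its mass lies on the beneficial side of
#' the cut `epsilon`: \eqn{x = \epsilon - Q(1 - q)\sqrt{MV}}, with `Q` the
#' standard-normal quantile function.
#'
#' @param q Target beneficial fraction, strictly between 0 and 1.
#' @param MV Variance of the effect-size distribution (> 0).
#' @param epsilon Z-score cut between deleterious and beneficial
#'   (default 0).
#' @return The distribution mean `x`.
#' @examples
#' effect_mean(0.5, 0.2)   # 0: centered Gaussian, 50% beneficial
#' effect_mean(0.25, 0.2)  # about -0.3016
#' @export
effect_mean <- function(q, MV, epsilon = 0) {
  if (!is.numeric(q) || any(q <= 0) || any(q >= 1))
    stop("q must lie strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(MV) || any(MV <= 0))
    stop("MV must be positive", call. = FALSE)
  epsilon - stats::qnorm(1 - q) * sqrt(MV)
}

#' Mutation model
#'
#' Bundles the distribution of fitness effects (DFE) and the mutator-step
#' rule. In `symmetric` mode (stable environment, and the burn-in phase of
#' every run) effects are drawn from a centered normal, N(0, MV) — under
#' directional change this is equivalent to the 50% beneficial scenario.
#' Otherwise the mean is shifted via [effect_mean()] so a fraction
#' `bm/100` of effects pushes the trait towards the moving optimum.
#'
#' @param bm Percentage of beneficial mutations, in (0, 100).
#' @param MV Variance of the effect-size distribution.
#' @param epsilon Beneficial/deleterious cut (default 0).
#' @param direction Sign of environmental change: +1 when the optimum
#'   increases. Effects are drawn from N(`x * direction`, MV).
#' @param symmetric If `TRUE`, use the centered distribution (x = 0)
#'   regardless of `bm`.
#' @param trials Mutation trial convention: `"per_allele"` (default) runs
#'   an independent Bernoulli(mu) trial for each of the four offspring
#'   alleles; `"per_locus"` runs one trial per locus and, on success,
#'   mutates one of the locus's two alleles chosen at random.
#' @return An object of class `mutation_model` with fields `q`, `MV`,
#'   `epsilon`, `x`, `direction`, `symmetric`, `trials`.
#' @examples
#' mutation_model(bm = 25)                 # treatment-phase shifted DFE
#' mutation_model(bm = 50, symmetric = TRUE) # burn-in / stable control
#' @export
mutation_model <- function(bm = 50, MV = 0.2, epsilon = 0, direction = 1,
                           symmetric = FALSE,
                           trials = c("per_allele", "per_locus")) {
  trials <- match.arg(trials)
  if (!is.numeric(bm) || length(bm) != 1L || bm <= 0 || bm >= 100)
    stop("bm must be a percentage strictly between 0 and 100", call. = FALSE)
  if (!is.numeric(MV) || length(MV) != 1L || MV <= 0)
    stop("MV must be a single positive number", call. = FALSE)
  q <- bm / 100
  x <- if (symmetric) 0 else effect_mean(q, MV, epsilon)
  structure(
    list(q = q, MV = MV, epsilon = epsilon, x = x,
         direction = sign(direction), symmetric = symmetric,
         trials = trials),
    class = "mutation_model"
  )
}

#' Draw mutation effects for the adaptation locus
#'
#' @param n Number of effects to draw.
#' @param model A [mutation_model()].
#' @return `n` draws from N(x * direction, MV).
#' @export
draw_effects <- function(n, model) {
  stats::rnorm(n, mean = model$x * model$direction, sd = sqrt(model$MV))
}

#' Draw mutator-locus steps
#'
#' A mutation at the mutator locus adds a value drawn uniformly from
#' \{-1, 0, +1\} to the mutated allele.
#'
#' @param n Number of steps to draw.
#' @return Integer vector of steps.
#' @export
draw_mutator_steps <- function(n) {
  sample(c(-1L, 0L, 1L), n, replace = TRUE)
}

#' Apply mutations to freshly assembled offspring genomes
#'
#' For each offspring, mu is computed from its inherited (pre-mutation)
#' mutator alleles and frozen; adaptation alleles are then perturbed with
#' probability mu by a draw from the model's effect distribution, and
#' mutator alleles with probability mu by a uniform step from
#' \{-1, 0, +1\}. Operates on a whole [population] of juveniles at once.
#'
#' @param pop A [population] of offspring (post-transmission,
#'   pre-mutation).
#' @param model A [mutation_model()].
#' @return The mutated population (phenotype `z` is recomputed).
#' @export
apply_mutations <- function(pop, model) {
  n <- nrow(pop)
  if (n == 0L) return(pop)
  mu <- mutation_rate(pop$m1, pop$m2)
  if (model$trials == "per_allele") {
    hit_a1 <- stats::runif(n) < mu
    hit_a2 <- stats::runif(n) < mu
    hit_m1 <- stats::runif(n) < mu
    hit_m2 <- stats::runif(n) < mu
  } else {
    # one trial per locus; on success one of the two alleles mutates
    locus_a <- stats::runif(n) < mu
    locus_m <- stats::runif(n) < mu
    pick_a1 <- stats::runif(n) < 0.5
    pick_m1 <- stats::runif(n) < 0.5
    hit_a1 <- locus_a & pick_a1
    hit_a2 <- locus_a & !pick_a1
    hit_m1 <- locus_m & pick_m1
    hit_m2 <- locus_m & !pick_m1
  }
  na1 <- sum(hit_a1); na2 <- sum(hit_a2)
  nm1 <- sum(hit_m1); nm2 <- sum(hit_m2)
  if (na1) pop$a1[hit_a1] <- pop$a1[hit_a1] + draw_effects(na1, model)
  if (na2) pop$a2[hit_a2] <- pop$a2[hit_a2] + draw_effects(na2, model)
  if (nm1) pop$m1[hit_m1] <- pop$m1[hit_m1] + draw_mutator_steps(nm1)
  if (nm2) pop$m2[hit_m2] <- pop$m2[hit_m2] + draw_mutator_steps(nm2)
  pop$z <- pop$a1 + pop$a2
  pop
}
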