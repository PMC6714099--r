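#' Linkage configuration
#'
#' `pR` is the probability that the mutator allele is co-transmitted with
#' the adaptation allele from the same parental haplotype: `pR = 1` is
#' complete linkage (the two loci always travel together), `pR = 0` is
#' the unlinked case (the mutator allele is picked independently and
#' uniformly from the parent's two), and intermediate values interpolate.
#' Note the effective same-haplotype frequency is `pR + (1 - pR)/2`,
#' because an independent pick still lands on the same haplotype half the
#' time.
#'
#' @param pR Co-transmission probability in \[0, 1\].
#' @return An object of class `linkage_config`.
#' @export
linkage_config <- function(pR = 0) {
  if (!is.numeric(pR) || length(pR) != 1L || pR < 0 || pR > 1)
    stop("pR must be a single probability in [0, 1]", call. = FALSE)
  structure(list(pR = pR), class = "linkage_config")
}

#' Transmit one haplotype from each of a set of parents
#'
#' For every parent index, the transmitted adaptation allele is chosen
#' uniformly from the parent's two; with probability `pR` the mutator
#' allele comes from the same parental haplotype, otherwise it is chosen
#' independently (uniformly) from the parent's two mutator alleles.
#' Vectorized over parents: a single transmission is the `length(idx) == 1`
#' case.
#'
#' @param pop A [population].
#' @param idx Integer vector of parent row indices (one transmission per
#'   entry; indices may repeat).
#' @param pR Co-transmission probability (see [linkage_config()]).
#' @return A list with components `adapt` and `mut` (transmitted allele
#'   values) and `hap_adapt`, `hap_mut` (which parental haplotype, 1 or
#'   2, each came from — useful for tagging tests).
#' @export
transmit_haplotype <- function(pop, idx, pR) {
  n <- length(idx)
  hap_a <- 1L + (stats::runif(n) < 0.5)
  co <- stats::runif(n) < pR
  hap_m_free <- 1L + (stats::runif(n) < 0.5)
  hap_m <- ifelse(co, hap_a, hap_m_free)
  adapt <- ifelse(hap_a == 1L, pop$a1[idx], pop$a2[idx])
  mut <- ifelse(hap_m == 1L, pop$m1[idx], pop$m2[idx])
  list(adapt = adapt, mut = mut, hap_adapt = hap_a, hap_mut = hap_m)
}

#' Assemble offspring from mother/father pairs
#'
#' Each offspring receives one transmitted haplotype from its mother and
#' one from its father ([transmit_haplotype()]), then mutations are
#' applied ([apply_mutations()]), the phenotype is recomputed as the sum
#' of the two adaptation alleles, sex is assigned Bernoulli(0.5) and the
#' stage set to juvenile. Vectorized over couples: `mothers` and
#' `fathers` are parallel index vectors, one offspring per entry.
#'
#' @param pop A [population] containing the parents.
#' @param mothers,fathers Parallel integer vectors of parent row indices;
#'   mothers must be female adults and fathers male adults.
#' @param linkage A [linkage_config()].
#' @param model A [mutation_model()].
#' @return A [population] of juveniles.
#' @export
make_offspring <- function(pop, mothers, fathers, linkage, model) {
  stopifnot(length(mothers) == length(fathers))
  if (!all(pop$female[mothers]) || any(pop$female[fathers]))
    stop("mothers must be female and fathers male", call. = FALSE)
  if (!all(pop$stage[mothers] == "adult") || !all(pop$stage[fathers] == "adult"))
    stop("parents must be adults", call. = FALSE)
  mat <- transmit_haplotype(pop, mothers, linkage$pR)
  pat <- transmit_haplotype(pop, fathers, linkage$pR)
  off <- new_population(
    a1 = mat$adapt, a2 = pat$adapt,
    m1 = mat$mut, m2 = pat$mut,
    female = stats::runif(length(mothers)) < 0.5,
    stage = "juvenile"
  )
  apply_mutations(off, model)
}
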