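---
title: "mutorsim: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mutorsim: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutorsim)
```

## The question the model addresses

Can the genomic mutation rate itself evolve upward in a *sexual* species
whose environment deteriorates directionally (e.g. a warming climate)?
In asexual organisms, alleles that raise the mutation rate can hitchhike
to fixation with the beneficial mutations they cause. Recombination
breaks that association, so theory expects mutation rates in sexual
species to stay pinned near the minimum set by the cost of replication
fidelity or by the drift limit. `mutorsim` implements an
individual-based model to probe the parameter region — linkage between
mutator and trait, fraction of beneficial mutations, speed of
environmental change, color of environmental noise — in which that
expectation breaks down.

## Model

### Environment

The optimum phenotype moves linearly, $\theta_t = \theta_0 + \eta t$,
and is perturbed by AR(1) noise
$\phi_t = \alpha\,\phi_{t-1} + \beta\,\xi_t$ with
$\xi_t \sim N(0, 1)$. The realized optimum is
$\theta^*_t = \theta_t + \phi_t$. The innovation scale is normalized as
$\beta = \sigma\sqrt{1-\alpha^2}$, so the stationary variance of
$\phi_t$ equals $\sigma^2$ for every autocorrelation $\alpha$: blue
($\alpha = -0.7$), white ($\alpha = 0$) and red ($\alpha = 0.7$) noise
describe equally variable but differently correlated habitats.

Two choices here were genuinely open:

* **Initial noise.** The starting value $\phi_0$ is unspecified in the
  model's written description. We draw it from the stationary
  distribution $N(0, \sigma^2)$ so the noise process is stationary from
  generation 0; initializing at 0 would make early-run environmental
  variance depend on $\alpha$.
* **Noise across the phase boundary.** Noise color is a property of the
  habitat, so the AR(1) process runs continuously through the whole run;
  only the trend $\eta$ switches on when the treatment starts.

### Individuals and genetics

Each diploid individual carries two haplotypes, each holding one
adaptation allele (real-valued, additive: the phenotype $z$ is the sum
of the two alleles) and one mutator allele. The mutation probability is

$$\mu = 10^{-(l_{m,1} + l_{m,2})/2},$$

clamped to $[0, 1]$ ($\mu$, not the alleles, is bounded — the alleles
are unbounded reals after mutation). Initial adaptation alleles are
$N(\theta_0, V_G/2L)$ with $L = 1$, giving initial phenotypic variance
$\approx V_G$; initial mutator alleles are uniform on $\{2, 3, 4\}$, so
the initial mean *exponent* is 3 and $10^{-\bar e} = 10^{-3}$. (The
arithmetic mean of $\mu$ itself is $\approx 2.6\times10^{-3}$ for that
allele distribution; we read "initial mean mutation rate of $10^{-3}$"
on the exponent scale, where it is exact.)

### Selection, density dependence, mating

Stabilizing selection gives each individual a degree of local adaptation

$$w_i = \exp\!\left(-\frac{(z_i - \theta^*_t)^2}{2\gamma^2}\right),$$

with $\gamma = 2.2$ by default (an individual 1 SD unit from the optimum
retains 90% fitness; $\gamma = 3.2$ is the weaker regime). Density
dependence rescales it to $w'_i = w_i e^{1 - N/K}$. Mating is lottery
polygyny: every female mates exactly once with a male drawn uniformly
with replacement; each couple's offspring count is
Poisson($w'_i + w'_j$). There is no hard cap at $K$ — regulation is
purely through the fecundity scaling, and $N$ may transiently exceed
$K$. Generations do not overlap: all adults die after reproduction.

### Inheritance and linkage

Each parent transmits one haplotype. The adaptation allele is picked
uniformly from the parent's two; with probability `pR` the mutator
allele is *co-transmitted* from the same parental haplotype, otherwise
it is picked independently. `pR = 1` is complete linkage, `pR = 0`
unlinked. Note two conventions collide in the source material: the
parameter is named a "probability of recombination" while its scenario
labels (0 = unlinked, 1 = complete linkage) describe co-transmission. We
follow the scenario labels. The effective same-haplotype frequency is
$p_R + (1 - p_R)/2$ (an independent pick still lands on the same
haplotype half the time): 0.5, 0.75, 1 for `pR` = 0, 0.5, 1.

### Mutation and the beneficial fraction

After transmission, $\mu$ is computed from the offspring's inherited
mutator alleles and frozen; each of the four alleles then mutates
independently with probability $\mu$ (a per-allele Bernoulli trial — the
original description does not state the trial unit; a per-locus variant
is available via `mutation_trials = "per_locus"`). A mutated adaptation
allele receives an effect drawn from $N(x, MV)$; a mutated mutator
allele moves by a uniform draw from $\{-1, 0, +1\}$.

The mean $x$ controls what fraction $q$ of effects is beneficial
(pushes the trait toward the moving optimum):

$$x = \epsilon - Q(1 - q)\sqrt{MV}, \qquad \epsilon = 0,$$

with $Q$ the standard-normal quantile function — a normal with mean $x$
and variance $MV$ has exactly mass $q$ above zero. $q = 0.5$ recovers
the centered Gaussian. The shifted distribution is used only during the
directional-change treatment; burn-in and stable-environment controls
use the centered one. The default $MV = 0.2$ follows the parameter
table of the source model; its DFE figure caption says 0.1 — we default
to the table and expose `MV` as a parameter rather than silently
resolving the discrepancy.

### Schedule

A run lasts 300 generations: 100 of stable environment (burn-in), then
200 of treatment. Per generation the order is: environment update,
fitness evaluation of the current adults, reproduction, death of all
adults, promotion of offspring (with recomputed phenotypes). A
replicate is *extinct* when $N = 0$ or one sex is absent; extinct
replicates stay in the raw output but are excluded from summary
statistics.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `K` | 1000 | carrying capacity (individuals) |
| `gamma` | 2.2 (alt. 3.2) | width of the stabilizing-selection function (trait units) |
| `sigma2` | 1 | environmental variance (trait units²) |
| `theta0` | 0 | initial optimum |
| `eta` | 0–0.04 | optimum displacement per generation |
| `alpha` | −0.7 / 0 / 0.7 | noise color |
| `VG` | 0.2 | initial genetic variance (trait units²) |
| `L` | 1 | loci per trait |
| `MV` | 0.2 | variance of mutation effects (trait units²) |
| `bm` | 10–50 | % beneficial mutations during treatment |
| `pR` | 0 / 0.5 / 1 | mutator–trait co-transmission probability |
| `generations`, `burn_in` | 300, 100 | run length and stable phase |

## What the simulated world is, and is not

All data are synthetic by construction: the generator *is* the model.
Green tests therefore establish internal consistency — that the
implementation realizes the stated distributions, transmission rules and
orderings — not that any real species behaves this way. Features of real
systems deliberately absent: spatial structure and migration, age
structure, multiple loci per trait (`L` is a hook but fixed at 1),
skewed or lethal-class DFEs, soma/germline distinction, plasticity, and
any cost of replication fidelity (so the lower end of the mutation-rate
scale is governed by drift, not physiology).

## Numerical and design choices

* **Vectorized engine, single code path.** Transmission and offspring
  assembly are vectorized over parent-index vectors; the engine calls
  exactly the functions the contract tests exercise (a single
  transmission is the length-1 case). One replicate at `K = 1000` for
  300 generations takes ~0.35 s in pure R.
* **Seeding.** Each replicate gets its own seed drawn (reproducibly)
  from the scenario's `base_seed`; the per-replicate seed is recorded in
  the output, and a JSON manifest allows bit-identical replay.
* **Paired comparisons by common random numbers.** The desk-scale
  reproduction of the headline result (30 replicates per cell instead of
  200) gives every grid cell the *same* `base_seed`, so a treated cell
  and its stable control share bit-identical burn-ins and the comparison
  isolates the treatment effect. With independent seeds at this scale,
  the between-replicate spread of the control's final mean mutation rate
  — arithmetic-mean $\mu$ is convex in the drifting mutator exponent, so
  it is strongly right-skewed — can mask the modest elevation expected
  in the unlinked scenario.
* **Mean vs. log-mean.** Per-generation output reports the arithmetic
  mean of individual $\mu$ and its log10; summaries report medians and
  quartiles across replicates, computed over non-extinct runs only, with
  an explicit `no_data` flag (not NaN) when a cell lost all replicates.
* **Degenerate inputs.** `mu` is clamped to $[0,1]$; a population with a
  missing sex reproduces to an empty offspring list (the extinction
  pathway) rather than erroring; an extinct cell's summary is flagged,
  not propagated as NaN.

## A worked example

```{r example, eval = FALSE}
library(mutorsim)
grid <- build_grid(list(eta = c(0, 0.04), pR = c(0, 1), bm = 50,
                        replicates = 30, base_seed = 1))
res <- run_experiment(grid)
res$summary[, c("scenario", "n_used", "median_mu", "median_log10_mu")]
write_results(res, "out")   # replicates.csv, summary.csv, manifest.json
```

The same sweep is available from the command line:

```sh
Rscript inst/cli/mutorsim.R run --eta 0.04 --pR 1 --bm 50 \
    --replicates 30 --seed 1 --out out
```

## Known limitations

* The original implementation's RNG and unstated tie-breaks make
  bit-level replication of its figures impossible; reproduction is
  qualitative (ordinal comparisons of evolved mutation rates), as the
  test suite encodes.
* At desk scale (30 replicates) the medians of heavy-tailed quantities
  are noisy; the paired-seed design above is what makes the ordinal
  comparisons stable.
* The per-allele mutation-trial convention is an interpretation; the
  `per_locus` switch exists precisely because the source description is
  silent on the trial unit.
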