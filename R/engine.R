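#' Scenario configuration
#'
#' One cell of the experiment grid: the environmental regime, linkage,
#' beneficial-mutation percentage and demographic parameters for a set of
#' replicate runs. Each run lasts `generations` generations: `burn_in`
#' generations of stable environment (no trend, centered mutation-effect
#' distribution) followed by the directional-change treatment. Under a
#' stable treatment (`eta = 0`) the centered distribution is kept for the
#' whole run, serving as the control.
#'
#' @param eta Rate of environmental change per generation (0 = stable).
#' @param alpha Noise autocorrelation (blue < 0, white = 0, red > 0).
#' @param pR Mutator/adaptation co-transmission probability (see
#'   [linkage_config()]).
#' @param bm Percentage of beneficial mutations during the treatment
#'   phase (only meaningful when `eta > 0`).
#' @param gamma Strength of stabilizing selection.
#' @param MV Variance of the mutation effect-size distribution.
#' @param K Carrying capacity.
#' @param VG Initial genetic variance.
#' @param L Loci per trait.
#' @param sigma2 Environmental variance.
#' @param theta0 Initial environmental optimum.
#' @param generations Total generations per run.
#' @param burn_in Stable generations before the treatment starts; must be
#'   less than `generations`.
#' @param replicates Number of replicate runs for this scenario.
#' @param base_seed Seed from which per-replicate seeds are derived.
#' @param mutation_trials `"per_allele"` (default) or `"per_locus"`; see
#'   [mutation_model()].
#' @param mutator_init Values the initial mutator alleles are sampled
#'   from (see [initialize_population()]).
#' @return An object of class `scenario_config`.
#' @examples
#' scenario_config(eta = 0.04, pR = 1, bm = 50, replicates = 5)
#' @export
scenario_config <- function(eta = 0, alpha = 0, pR = 0, bm = 50,
                            gamma = 2.2, MV = 0.2, K = 1000, VG = 0.2,
                            L = 1, sigma2 = 1, theta0 = 0,
                            generations = 300, burn_in = 100,
                            replicates = 200, base_seed = 1,
                            mutation_trials = "per_allele",
                            mutator_init = 2:4) {
  if (burn_in >= generations)
    stop("burn_in must be smaller than generations", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  # constructor side validation happens in the component constructors
  env <- env_config(theta0, eta, alpha, sigma2)
  popc <- pop_config(K, VG, L, gamma)
  link <- linkage_config(pR)
  if (bm <= 0 || bm >= 100)
    stop("bm must be a percentage strictly between 0 and 100", call. = FALSE)
  structure(
    list(eta = eta, alpha = alpha, pR = pR, bm = bm, gamma = gamma,
         MV = MV, K = as.integer(K), VG = VG, L = as.integer(L),
         sigma2 = sigma2, theta0 = theta0,
         generations = as.integer(generations),
         burn_in = as.integer(burn_in),
         replicates = as.integer(replicates),
         base_seed = as.integer(base_seed),
         mutation_trials = mutation_trials,
         mutator_init = mutator_init,
         env = env, popc = popc, link = link),
    class = "scenario_config"
  )
}

#' Label identifying a scenario (grid cell)
#' @param scenario A [scenario_config()].
#' @return A single string.
#' @export
scenario_id <- function(scenario) {
  sprintf("eta%g_alpha%g_pR%g_bm%g_gamma%g", scenario$eta, scenario$alpha,
          scenario$pR, scenario$bm, scenario$gamma)
}

#' Run one replicate
#'
#' Executes one seeded run: population initialization, `burn_in` stable
#' generations, then the treatment phase. Per generation the sequence is:
#' update of the environmental optimum, evaluation of the degree of local
#' adaptation, reproduction, mortality of all adults, and promotion of
#' the offspring (with recomputed phenotypes) to the next generation's
#' adults. Identical `(scenario, seed)` pairs produce identical results.
#'
#' @param scenario A [scenario_config()].
#' @param seed Integer seed for this replicate's RNG stream.
#' @param series If `TRUE` (default) keep the full per-generation series.
#' @return An object of class `run_result`: a list with `series` (a data
#'   frame with columns `generation`, `N`, `mean_mu`, `mean_z`, `var_z`,
#'   `theta_t`, `phi_t`, `theta_star`), `final_mean_mu`, `extinct`,
#'   `extinct_generation` (NA if not extinct), `seed` and
#'   `scenario_id`.
#' @export
run_replicate <- function(scenario, seed, series = TRUE) {
  set.seed(seed)
  s <- scenario
  pop <- initialize_population(s$popc, s$theta0, s$mutator_init)
  phi <- init_noise(s$env)
  burn_model <- mutation_model(bm = s$bm, MV = s$MV, symmetric = TRUE,
                               trials = s$mutation_trials)
  treat_model <- if (s$eta > 0) {
    mutation_model(bm = s$bm, MV = s$MV, direction = sign(s$eta),
                   symmetric = FALSE, trials = s$mutation_trials)
  } else burn_model
  G <- s$generations
  rec <- list(
    generation = integer(G), N = integer(G), mean_mu = rep(NA_real_, G),
    mean_z = rep(NA_real_, G), var_z = rep(NA_real_, G),
    theta_t = numeric(G), phi_t = numeric(G), theta_star = numeric(G)
  )
  extinct <- FALSE
  extinct_gen <- NA_integer_
  n_rec <- 0L
  for (t in seq_len(G)) {
    t_trend <- max(0L, t - s$burn_in)
    theta_t <- optimum_at(t_trend, s$env)
    phi <- advance_noise(phi, s$alpha, s$env$beta, stats::rnorm(1L))
    theta_star <- theta_t + phi
    model <- if (t > s$burn_in) treat_model else burn_model
    pop <- reproduce(pop, theta_star, s$popc, s$link, model)
    pop$stage <- rep("adult", nrow(pop))
    N <- nrow(pop)
    n_rec <- t
    rec$generation[t] <- t
    rec$N[t] <- N
    rec$theta_t[t] <- theta_t
    rec$phi_t[t] <- phi
    rec$theta_star[t] <- theta_star
    if (N > 0L) {
      rec$mean_mu[t] <- mean(mutation_rate(pop$m1, pop$m2))
      rec$mean_z[t] <- mean(pop$z)
      rec$var_z[t] <- if (N > 1L) stats::var(pop$z) else 0
    }
    if (N == 0L || all(pop$female) || !any(pop$female)) {
      extinct <- TRUE
      extinct_gen <- t
      break
    }
  }
  ser <- as.data.frame(lapply(rec, function(x) x[seq_len(n_rec)]))
  final_mu <- if (extinct) NA_real_ else ser$mean_mu[n_rec]
  structure(
    list(series = if (series) ser else NULL,
         final_mean_mu = final_mu,
         final_N = ser$N[n_rec],
         extinct = extinct, extinct_generation = extinct_gen,
         seed = seed, scenario_id = scenario_id(s)),
    class = "run_result"
  )
}

#' Run an experiment grid
#'
#' Runs every scenario in `grid` for its configured number of replicates.
#' Per-replicate seeds are derived deterministically from each scenario's
#' `base_seed` (recorded in the output for exact replay), so replicate
#' streams are independent and the whole experiment is reproducible.
#'
#' @param grid A list of [scenario_config()] objects (a single scenario
#'   is accepted too).
#' @param series If `TRUE`, also collect the per-generation series of
#'   every replicate (can be large).
#' @param verbose If `TRUE`, log per-replicate progress.
#' @return An object of class `experiment_results`: a list with
#'   `replicates` (one row per replicate: scenario labels, replicate id,
#'   seed, final mean mutation rate and its log10, final population size,
#'   extinction flag and generation) and `summary` (per-scenario
#'   statistics over non-extinct replicates, see
#'   [summarize_final_mutation_rate()]); `series` is a combined
#'   per-generation data frame when requested.
#' @export
run_experiment <- function(grid, series = FALSE, verbose = FALSE) {
  if (inherits(grid, "scenario_config")) grid <- list(grid)
  stopifnot(length(grid) > 0L)
  rep_rows <- vector("list", length(grid))
  ser_rows <- if (series) vector("list", length(grid)) else NULL
  for (g in seq_along(grid)) {
    s <- grid[[g]]
    sid <- scenario_id(s)
    set.seed(s$base_seed)
    seeds <- sample.int(.Machine$integer.max, s$replicates)
    rows <- vector("list", s$replicates)
    sers <- if (series) vector("list", s$replicates) else NULL
    for (r in seq_len(s$replicates)) {
      res <- run_replicate(s, seeds[r], series = series)
      rows[[r]] <- data.frame(
        scenario = sid, eta = s$eta, alpha = s$alpha, pR = s$pR,
        bm = s$bm, gamma = s$gamma, MV = s$MV, K = s$K,
        replicate = r, seed = seeds[r],
        final_mean_mu = res$final_mean_mu,
        final_log10_mu = log10(res$final_mean_mu),
        final_N = res$final_N,
        extinct = res$extinct,
        extinct_generation = res$extinct_generation
      )
      if (series) {
        sr <- res$series
        sr$scenario <- sid
        sr$replicate <- r
        sers[[r]] <- sr
      }
      if (verbose)
        message(sprintf("[%s] replicate %d/%d%s", sid, r, s$replicates,
                        if (res$extinct)
                          sprintf(" EXTINCT at generation %d",
                                  res$extinct_generation) else ""))
    }
    rep_rows[[g]] <- do.call(rbind, rows)
    if (series) ser_rows[[g]] <- do.call(rbind, sers)
  }
  replicates <- do.call(rbind, rep_rows)
  out <- structure(
    list(replicates = replicates,
         summary = summarize_final_mutation_rate(replicates),
         series = if (series) do.call(rbind, ser_rows) else NULL,
         grid = grid),
    class = "experiment_results"
  )
  out
}

#' Summarize the final mean mutation rate per scenario
#'
#' Extinct replicates are excluded (their data is retained in the raw
#' replicate table but not used for statistics, mirroring the exclusion
#' rule of the original experiments). A scenario whose replicates all
#' went extinct is flagged `no_data` with `NA` statistics rather than
#' propagating NaN.
#'
#' @param results An `experiment_results` object or its `replicates`
#'   data frame.
#' @return A data frame with one row per scenario: replicate counts
#'   (total, non-extinct), median / quartiles / mean of the final mean
#'   mutation rate, the log10 of the median, and a `no_data` flag.
#' @export
summarize_final_mutation_rate <- function(results) {
  df <- if (inherits(results, "experiment_results")) results$replicates
        else results
  stopifnot(is.data.frame(df))
  out <- lapply(split(df, df$scenario), function(d) {
    used <- d[!d$extinct, , drop = FALSE]
    n_used <- nrow(used)
    stats_row <- if (n_used > 0L) {
      qs <- stats::quantile(used$final_mean_mu, c(0.25, 0.5, 0.75),
                            names = FALSE)
      data.frame(median_mu = qs[2], q1_mu = qs[1], q3_mu = qs[3],
                 mean_mu = mean(used$final_mean_mu),
                 median_log10_mu = log10(qs[2]))
    } else {
      data.frame(median_mu = NA_real_, q1_mu = NA_real_, q3_mu = NA_real_,
                 mean_mu = NA_real_, median_log10_mu = NA_real_)
    }
    cbind(
      d[1L, c("scenario", "eta", "alpha", "pR", "bm", "gamma"), drop = FALSE],
      data.frame(n_replicates = nrow(d), n_used = n_used,
                 no_data = n_used == 0L),
      stats_row
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.experiment_results <- function(x, ...) {
  cat("Experiment:", length(x$grid), "scenario(s),",
      nrow(x$replicates), "replicate run(s)\n")
  print(x$summary, ...)
  invisible(x)
}

#' @export
print.run_result <- function(x, ...) {
  cat("Run", x$scenario_id, "(seed", paste0(x$seed, ")"),
      if (x$extinct) sprintf("- EXTINCT at generation %d", x$extinct_generation)
      else sprintf("- final N = %d, final mean mu = %.3g",
                   x$final_N, x$final_mean_mu), "\n")
  invisible(x)
}
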