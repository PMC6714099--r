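# Keys accepted in a config file / manifest; scalar-only keys cannot be
# swept in a grid.
.grid_keys <- c("eta", "alpha", "pR", "bm", "gamma")
.scalar_keys <- c("MV", "K", "VG", "L", "sigma2", "theta0", "generations",
                  "burn_in", "replicates", "base_seed", "mutation_trials")
# vector-valued per-scenario key (not part of the sweep)
.list_keys <- "mutator_init"

.default_config <- function() {
  list(eta = 0, alpha = 0, pR = 0, bm = 50, gamma = 2.2, MV = 0.2,
       K = 1000, VG = 0.2, L = 1, sigma2 = 1, theta0 = 0,
       generations = 300, burn_in = 100, replicates = 200, base_seed = 1,
       mutation_trials = "per_allele", mutator_init = 2:4)
}

#' Load a scenario grid from a JSON config file
#'
#' The config is a flat JSON object. The sweep keys `eta`, `alpha`, `pR`,
#' `bm` and `gamma` may hold arrays; the grid is their Cartesian product.
#' All other keys are scalars applied to every cell. Unspecified keys
#' take the model's default values (K = 1000, gamma = 2.2, VG = 0.2,
#' MV = 0.2, L = 1, sigma2 = 1, 300 generations with a 100-generation
#' burn-in, 200 replicates). Unknown keys and out-of-range values fail
#' with an error naming the offending key.
#'
#' @param path Path to the JSON config file.
#' @return A list of [scenario_config()] objects (the resolved grid).
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_grid(raw)
}

#' Build a scenario grid from a named list of parameter values
#'
#' Programmatic equivalent of [load_config()]; see there for the key
#' semantics.
#'
#' @param params Named list; sweep keys may be vectors.
#' @return A list of [scenario_config()] objects.
#' @export
build_grid <- function(params = list()) {
  known <- c(.grid_keys, .scalar_keys, .list_keys)
  unknown <- setdiff(names(params), known)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  bad <- intersect(names(params),
                   .scalar_keys)[vapply(params[intersect(names(params),
                                                         .scalar_keys)],
                                        length, 1L) > 1L]
  if (length(bad) > 0L)
    stop("key(s) must be scalar, not arrays: ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(.default_config(), params)
  validate_config_values(cfg)
  cells <- expand.grid(cfg[.grid_keys], KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(cells)), function(i) {
    args <- c(as.list(cells[i, , drop = FALSE]), cfg[.scalar_keys],
              cfg[.list_keys])
    do.call(scenario_config, args)
  })
}

validate_config_values <- function(cfg) {
  chk <- function(ok, key, what) {
    if (!ok) stop("invalid value for '", key, "': ", what, call. = FALSE)
  }
  chk(all(is.finite(cfg$eta)), "eta", "must be finite")
  chk(all(abs(cfg$alpha) < 1), "alpha", "must lie strictly in (-1, 1)")
  chk(all(cfg$pR >= 0 & cfg$pR <= 1), "pR", "must lie in [0, 1]")
  chk(all(cfg$bm > 0 & cfg$bm < 100), "bm",
      "must be a percentage strictly between 0 and 100")
  chk(all(cfg$gamma > 0), "gamma", "must be positive")
  chk(cfg$MV > 0, "MV", "must be positive")
  chk(cfg$K >= 2, "K", "must be >= 2")
  chk(cfg$VG > 0, "VG", "must be positive")
  chk(cfg$L >= 1, "L", "must be >= 1")
  chk(cfg$sigma2 > 0, "sigma2", "must be positive")
  chk(cfg$burn_in < cfg$generations, "burn_in",
      "must be smaller than generations")
  chk(cfg$replicates >= 1, "replicates", "must be >= 1")
  chk(cfg$mutation_trials %in% c("per_allele", "per_locus"),
      "mutation_trials", "must be 'per_allele' or 'per_locus'")
  invisible(cfg)
}

scenario_as_list <- function(s) {
  s[c(.grid_keys, .scalar_keys, .list_keys)]
}

#' Write experiment results to a directory
#'
#' Emits plain CSV files with a header row plus a JSON manifest capturing
#' the fully resolved configuration of every scenario (including
#' `base_seed`), so the run can be replayed bit-identically with
#' [run_from_manifest()].
#'
#' @param results An `experiment_results` object from [run_experiment()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named character vector of written file paths
#'   (`replicates`, `summary`, `manifest`, and `series` when present).
#' @export
write_results <- function(results, out_dir) {
  stopifnot(inherits(results, "experiment_results"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2L) != 0L)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  paths <- c(
    replicates = file.path(out_dir, "replicates.csv"),
    summary = file.path(out_dir, "summary.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  utils::write.csv(results$replicates, paths[["replicates"]],
                   row.names = FALSE)
  utils::write.csv(results$summary, paths[["summary"]], row.names = FALSE)
  manifest <- list(
    package = "mutorsim",
    version = as.character(utils::packageVersion("mutorsim")),
    scenarios = lapply(results$grid, scenario_as_list)
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(results$series)) {
    paths <- c(paths, series = file.path(out_dir, "series.csv"))
    utils::write.csv(results$series, paths[["series"]], row.names = FALSE)
  }
  invisible(paths)
}

#' Replay an experiment from a manifest
#'
#' Rebuilds every scenario recorded in a manifest written by
#' [write_results()] and reruns the experiment; seeded determinism makes
#' the result bit-identical to the original.
#'
#' @param path Path to a `manifest.json`.
#' @param series Collect per-generation series (see [run_experiment()]).
#' @return An `experiment_results` object.
#' @export
run_from_manifest <- function(path, series = FALSE) {
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  grid <- lapply(manifest$scenarios, function(sc) {
    do.call(scenario_config, sc)
  })
  run_experiment(grid, series = series)
}
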