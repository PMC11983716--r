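#' Write / read a run configuration
#'
#' Human-readable YAML description of a complete run: mutation spec, scheme,
#' toy well depths (or explicit `h`/`J` Hamiltonian entries), sampler
#' settings, estimator settings and seed.  `read_msld_config()`
#' reconstructs the topology and Hamiltonians, ready for [msld()] or the
#' command-line workflow.
#'
#' Schema (keys; all energies kcal/mol, temperature kelvin):
#' \preformatted{
#' native: GGTCAA            # sequences
#' mutants: [GATAAA]
#' scheme: one_lambda_per_pair | two_lambda | coupled_two_lambda
#' coupling_strength: -2     # coupled scheme only
#' bound_depths:  {GGTCAA: 0.0, GATCAA: 4.0, ...}   # per matched sequence
#' unbound_depths: {...}
#' mispair_penalty: 2
#' settings: {timestep: 0.01, friction: 5, temperature: 298,
#'            save_interval: 10, mass: 1, steepness: 5.5, theta_restraint: 1}
#' estimator: {lambda_c: 0.99, n_boot: 50}
#' replicas: 5
#' seed: 1
#' }
#'
#' @param config for writing: a list as produced by [toy_config()].
#' @param path file path.
#' @return `read_msld_config()` returns a list with `spec` ([toy_spec()]),
#'   `scheme`, `system` (from [make_toy_pair()]), `settings`, `replicas`,
#'   `lambda_c`, `n_boot`, `seed` and the raw `config` list.
#' @export
write_msld_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

#' @rdname write_msld_config
#' @export
read_msld_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (k in c("native", "mutants", "bound_depths", "unbound_depths"))
    if (is.null(cfg[[k]])) stop_msldyn("config is missing required key '", k, "'")
  spec <- toy_spec(cfg$native, unlist(cfg$mutants),
                   unlist(cfg$bound_depths), unlist(cfg$unbound_depths),
                   mispair_penalty = cfg$mispair_penalty %||% 2,
                   seed = cfg$seed %||% 1L)
  scheme <- normalize_scheme(cfg$scheme %||% "one_lambda_per_pair")
  system <- make_toy_pair(spec, scheme,
                          coupling_strength = cfg$coupling_strength %||% -2)
  st <- cfg$settings %||% list()
  settings <- sampler_settings(
    n_steps = st$n_steps %||% 50000L, timestep = st$timestep %||% 0.01,
    friction = st$friction %||% 5, temperature = st$temperature %||% 298,
    save_interval = st$save_interval %||% 10L, mass = st$mass %||% 1,
    steepness = st$steepness %||% 5.5,
    theta_restraint = st$theta_restraint %||% 1)
  est <- cfg$estimator %||% list()
  list(spec = spec, scheme = scheme, system = system, settings = settings,
       replicas = as.integer(cfg$replicas %||% 5L),
       lambda_c = est$lambda_c %||% 0.99,
       n_boot = as.integer(est$n_boot %||% 50L),
       seed = as.integer(cfg$seed %||% 1L),
       config = cfg)
}

#' Emit a complete toy-system configuration
#'
#' Produces the configuration list for a ready-to-run W-box style toy
#' system (topology + bound/unbound well depths + scheme + seed), suitable
#' for [write_msld_config()] and the `toy` CLI subcommand.
#'
#' @param spec a [toy_spec()] (default [toy_wbox()]).
#' @param scheme scheme selector.
#' @param seed master seed recorded in the config.
#' @param replicas production replica count.
#' @return A plain list following the schema in [write_msld_config()].
#' @export
toy_config <- function(spec = toy_wbox(), scheme = "one_lambda_per_pair",
                       seed = 1L, replicas = 5L) {
  list(native = spec$native, mutants = as.list(spec$mutants),
       scheme = normalize_scheme(scheme),
       coupling_strength = -2,
       bound_depths = as.list(spec$bound_depths),
       unbound_depths = as.list(spec$unbound_depths),
       mispair_penalty = spec$mispair_penalty,
       settings = list(timestep = 0.01, friction = 5, temperature = 298,
                       save_interval = 10L, mass = 1, steepness = 5.5,
                       theta_restraint = 1),
       estimator = list(lambda_c = 0.99, n_boot = 50L),
       replicas = as.integer(replicas), seed = as.integer(seed))
}

#' Write analysis results
#'
#' Writes the ranked mutant table as CSV (sequence, ddG, se, frame and
#' transition counts) and a JSON summary with provenance (seed, lambda_c,
#' replica count).
#'
#' @param fit an [msld()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(fit, dir) {
  stopifnot(inherits(fit, "msld_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "ddg_report.csv")
  js <- file.path(dir, "summary.json")
  write.csv(fit$report, csv, row.names = FALSE)
  jsonlite::write_json(
    list(reference = attr(fit$ddg, "reference"),
         lambda_c = fit$lambda_c, replicas = fit$replicas,
         production_steps = fit$production_steps, seed = fit$seed,
         ddg = fit$report),
    js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv = csv, json = js))
}
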