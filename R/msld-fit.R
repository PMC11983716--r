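#' Fit relative binding free energies by multisite lambda-dynamics
#'
#' Runs the whole pipeline for a bound/unbound pair of model Hamiltonians on
#' one alchemical topology: adaptive landscape flattening of each leg,
#' production replicas under the converged bias, endstate binning at
#' `lambda_c`, population-based free energies with block-bootstrap errors,
#' and thermodynamic-cycle assembly of per-mutant \eqn{\Delta\Delta G_b}.
#'
#' @param topology an [alch_topology()] (typically from [build_scheme()]).
#' @param bound,unbound [model_hamiltonian()]s for the two ensembles.
#' @param schedule an [alf_schedule()] used for both legs.
#' @param settings a [sampler_settings()] template (per-run steps and seeds
#'   are overridden internally).
#' @param replicas number of production trajectories per leg (default 5).
#' @param production_steps length of each production replica, steps.
#' @param lambda_c endstate bin cutoff.
#' @param n_boot bootstrap resamples for the standard errors.
#' @param seed master seed; every run derives its stream via
#'   [derive_seed()].
#' @param reference reference sequence (default: the native endstate).
#' @param keep_trajectories keep the production trajectories in the fit
#'   (memory permitting); `simulate()` works either way.
#' @return An object of class `msld_fit` with components `ddg`
#'   (a [ddg_cycle()] table), `report` (the ranked
#'   [multi_mutant_report()]), `legs` (per-leg free-energy estimates,
#'   biases, ALF logs and transition counts) and the call arguments.
#'   Methods: `print`, `summary`, `coef` (named \eqn{\Delta\Delta G}
#'   vector), `confint`, `plot` (final flattening profiles), `simulate`
#'   (fresh production trajectories under the fitted biases).
#' @export
#' @examples
#' \donttest{
#' sys <- make_toy_pair(toy_wbox(), "one_lambda_per_pair")
#' fit <- msld(sys$topology, sys$bound, sys$unbound,
#'             schedule = alf_schedule(10, 1000, 4, 5000, 2e4),
#'             production_steps = 2e4, replicas = 2, seed = 7)
#' coef(fit)
#' }
msld <- function(topology, bound, unbound, schedule = alf_schedule(),
                 settings = sampler_settings(), replicas = 5L,
                 production_steps = 5e4, lambda_c = 0.99, n_boot = 50L,
                 seed = 1L, reference = NULL, keep_trajectories = FALSE) {
  stopifnot(inherits(topology, "alch_topology"),
            inherits(bound, "model_hamiltonian"),
            inherits(unbound, "model_hamiltonian"))
  cl <- match.call()
  legs <- list()
  for (leg in c("bound", "unbound")) {
    H <- if (leg == "bound") bound else unbound
    leg_seed <- derive_seed(seed, if (leg == "bound") 1L else 2L)
    alf <- alf_flatten(topology, H, schedule, settings, seed = leg_seed,
                       n_boot = n_boot)
    trajs <- lapply(seq_len(replicas), function(r) {
      st <- settings
      st$n_steps <- as.integer(production_steps)
      st$seed <- derive_seed(leg_seed, 1000L + r)
      run_trajectory(topology, H, alf$bias, st, replica = r)
    })
    series <- lapply(trajs, assign_endstates, lambda_c = lambda_c)
    est <- free_energy_from_populations(
      series, alf$bias, temperature = settings$temperature, n_boot = n_boot,
      seed = derive_seed(leg_seed, 999L), reference = reference)
    legs[[leg]] <- list(
      estimate = est, bias = alf$bias, alf_log = alf$log,
      profile = tail(alf$profiles, 1L)[[1L]],
      transitions = attr(est, "transitions"),
      trajectories = if (keep_trajectories) trajs else NULL)
  }
  ddg <- ddg_cycle(legs$bound$estimate, legs$unbound$estimate)
  structure(list(ddg = ddg,
                 report = multi_mutant_report(ddg, topology),
                 legs = legs, topology = topology,
                 hamiltonians = list(bound = bound, unbound = unbound),
                 settings = settings, schedule = schedule,
                 replicas = as.integer(replicas),
                 production_steps = as.integer(production_steps),
                 lambda_c = lambda_c, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), call = cl),
            class = "msld_fit")
}

#' @export
print.msld_fit <- function(x, ...) {
  cat("Multisite lambda-dynamics fit\n")
  cat("  topology: ", length(x$topology$n_sub), " site(s), ",
      sum(x$topology$vertices$matched), " matched endstates; lambda_c = ",
      x$lambda_c, "\n", sep = "")
  cat("  production: ", x$replicas, " x ", x$production_steps,
      " steps per leg (seed ", x$seed, ")\n\n", sep = "")
  print(x$ddg)
  invisible(x)
}

#' @export
summary.msld_fit <- function(object, ...) {
  structure(list(report = object$report,
                 transitions = list(
                   bound = object$legs$bound$transitions$counts,
                   unbound = object$legs$unbound$transitions$counts),
                 imbalance = c(
                   bound = tail(object$legs$bound$alf_log$imbalance, 1L),
                   unbound = tail(object$legs$unbound$alf_log$imbalance, 1L)),
                 lambda_c = object$lambda_c, seed = object$seed),
            class = "summary.msld_fit")
}

#' @export
print.summary.msld_fit <- function(x, ...) {
  cat("Ranked mutants (ddG in kcal/mol, bootstrap SE):\n")
  y <- x$report
  y$ddG <- ifelse(y$available, sprintf("%.3f", y$ddG), "--")
  y$se <- ifelse(y$available, sprintf("%.3f", y$se), "--")
  print(y[, c("sequence", "ddG", "se", "transitions_bound",
              "transitions_unbound")], row.names = FALSE)
  cat(sprintf("\nfinal flattening imbalance: bound %.3g, unbound %.3g kcal/mol\n",
              x$imbalance["bound"], x$imbalance["unbound"]))
  invisible(x)
}

#' @export
coef.msld_fit <- function(object, ...) {
  setNames(object$ddg$ddG, object$ddg$sequence)
}

#' @export
confint.msld_fit <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  est <- object$ddg
  ci <- cbind(est$ddG - z * est$se, est$ddG + z * est$se)
  rownames(ci) <- est$sequence
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
plot.msld_fit <- function(x, leg = c("bound", "unbound"), ...) {
  leg <- match.arg(leg)
  plot(x$legs[[leg]]$profile,
       main = paste("final flattening profile,", leg, "leg"), ...)
}

#' @export
simulate.msld_fit <- function(object, nsim = 1, seed = NULL,
                              leg = c("bound", "unbound"), ...) {
  leg <- match.arg(leg)
  seed <- seed %||% object$seed + 77L
  H <- object$hamiltonians[[leg]]
  lapply(seq_len(nsim), function(r) {
    st <- object$settings
    st$n_steps <- object$production_steps
    st$seed <- derive_seed(seed, r)
    run_trajectory(object$topology, H, object$legs[[leg]]$bias, st,
                   replica = r)
  })
}
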