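#' Sampler settings for lambda-dynamics runs
#'
#' Time is in model units: the reduced Hamiltonian carries no physical
#' timescale, so timestep, friction and masses are engineering choices tuned
#' so that flattened toy systems show usable transition rates.  The sampled
#' potential is the composite potential plus a harmonic theta confinement
#' `theta_restraint/2 * |theta|^2` which regularises the flat softmax gauge
#' directions and gives the endstate bins finite theta-space volume (the
#' quadrature oracle integrates the same term).
#'
#' @param n_steps number of integration steps (>= 1).
#' @param timestep integration timestep, model time units.
#' @param friction Langevin friction, inverse model time (>= 0; 0 gives
#'   velocity-Verlet, NVE).
#' @param temperature target temperature, kelvin.
#' @param save_interval record a frame every this many steps.
#' @param seed integer RNG seed, or `NULL` to continue the current R stream.
#' @param mass mass per theta coordinate (model units).
#' @param steepness softmax steepness of the implicit-constraint transform.
#' @param theta_restraint harmonic confinement constant (kcal/mol per
#'   theta^2).
#' @return An object of class `sampler_settings`.
#' @export
sampler_settings <- function(n_steps = 50000L, timestep = 0.01, friction = 5,
                             temperature = 298, save_interval = 10L,
                             seed = NULL, mass = 1, steepness = 5.5,
                             theta_restraint = 1) {
  stopifnot(timestep > 0, friction >= 0, temperature > 0,
            n_steps >= 1, save_interval >= 1, mass > 0, steepness > 0,
            theta_restraint >= 0)
  structure(list(n_steps = as.integer(n_steps), timestep = timestep,
                 friction = friction, temperature = temperature,
                 save_interval = as.integer(save_interval),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 mass = mass, steepness = steepness,
                 theta_restraint = theta_restraint),
            class = "sampler_settings")
}

#' One BAOAB Langevin step
#'
#' Reference R implementation of the splitting used by the compiled
#' trajectory engine: half kick (B), half drift (A), full
#' Ornstein-Uhlenbeck velocity update (O), half drift (A), half kick (B).
#' With `friction = 0` the O step is skipped and the update reduces to
#' velocity-Verlet.  The O step draws `length(theta)` standard normals from
#' the R RNG, so identical seeds give bit-identical successors.
#'
#' @param theta,velocity numeric coordinate and velocity vectors.
#' @param force current force vector `-dV/dtheta` at `theta` (from the
#'   previous step; pass `force_fn(theta)` on the first call).
#' @param force_fn function of theta returning the force vector.
#' @param settings a [sampler_settings()] (its `seed` field is ignored here;
#'   seed the R RNG yourself).
#' @return List with updated `theta`, `velocity` and `force`.
#' @export
#' @examples
#' set.seed(1)
#' st <- step_langevin(0, 1, 0, function(th) -th, sampler_settings(friction = 0))
step_langevin <- function(theta, velocity, force, force_fn, settings) {
  stopifnot(inherits(settings, "sampler_settings"))
  dt <- settings$timestep; m <- settings$mass
  kT <- .kB * settings$temperature
  v <- velocity + 0.5 * dt * force / m
  th <- theta + 0.5 * dt * v
  if (settings$friction > 0) {
    c1 <- exp(-settings$friction * dt)
    c2 <- sqrt((1 - c1^2) * kT / m)
    v <- c1 * v + c2 * rnorm(length(v))
  }
  th <- th + 0.5 * dt * v
  f <- force_fn(th)
  v <- v + 0.5 * dt * f / m
  list(theta = th, velocity = v, force = f)
}

#' Run a lambda-dynamics trajectory
#'
#' Integrates the theta coordinates with the compiled BAOAB engine and
#' records the lambda vectors (and theta) every `save_interval` steps.
#' Initial theta is standard normal and initial velocities are
#' Maxwell-Boltzmann at the target temperature, both drawn from the seeded
#' RNG, unless explicit starts are supplied.
#'
#' @param topology an [alch_topology()].
#' @param H a [model_hamiltonian()].
#' @param bias a [bias_parameters()] or `NULL` for zero bias.
#' @param settings a [sampler_settings()].
#' @param theta0,velocity0 optional explicit initial state.
#' @param replica integer replica id recorded in the trajectory.
#' @return An object of class `lambda_trajectory`: fields `lambda` (frames x
#'   P matrix, site-major columns named `site:substituent`), `theta`, `step`
#'   (strictly increasing step indices), `topology`, `settings`, `bias`,
#'   `replica`.
#' @export
run_trajectory <- function(topology, H, bias = NULL, settings = sampler_settings(),
                           theta0 = NULL, velocity0 = NULL, replica = 1L) {
  stopifnot(inherits(topology, "alch_topology"),
            inherits(H, "model_hamiltonian"),
            inherits(settings, "sampler_settings"))
  if (is.null(bias)) bias <- zero_bias(topology)
  P <- topology$P
  if (!is.null(settings$seed)) set.seed(settings$seed)
  kT <- .kB * settings$temperature
  if (is.null(theta0)) theta0 <- rnorm(P)
  if (is.null(velocity0)) velocity0 <- rnorm(P, sd = sqrt(kT / settings$mass))
  stopifnot(length(theta0) == P, length(velocity0) == P,
            all(is.finite(theta0)), all(is.finite(velocity0)))

  out <- msld_run_cpp(theta0, velocity0,
                      H$h - bias$b, quad_matrix(H, bias),
                      topology$offset, topology$n_sub,
                      settings$steepness, settings$theta_restraint,
                      settings$timestep, settings$friction, kT, settings$mass,
                      settings$n_steps, settings$save_interval)
  if (out$bad_step >= 0)
    stop_msldyn("non-finite state encountered at step ", out$bad_step,
                "; reduce the timestep or energy scales")
  lam <- out$lambda; theta <- out$theta
  colnames(lam) <- colnames(theta) <- coord_names(topology)
  structure(list(lambda = lam, theta = theta, step = out$step,
                 final_theta = out$final_theta,
                 final_velocity = out$final_velocity,
                 topology = topology, settings = settings, bias = bias,
                 replica = as.integer(replica)),
            class = "lambda_trajectory")
}

#' @export
print.lambda_trajectory <- function(x, ...) {
  cat("Lambda trajectory: ", nrow(x$lambda), " frames x ", ncol(x$lambda),
      " coordinates (replica ", x$replica, ")\n", sep = "")
  cat("model time:", max(x$step) * x$settings$timestep,
      "units; T =", x$settings$temperature, "K\n")
  invisible(x)
}

# model time covered by a trajectory (or list of trajectories)
model_time <- function(traj) {
  if (inherits(traj, "lambda_trajectory")) traj <- list(traj)
  sum(vapply(traj, function(tr) nrow(tr$lambda) * tr$settings$save_interval *
               tr$settings$timestep, numeric(1)))
}

#' Write / read a lambda trajectory as delimited text
#'
#' Tab-delimited with a header row naming the columns `step` then
#' `site:substituent` in site-major order, one row per saved frame.  Values
#' are printed with 10 significant digits; writer and reader round-trip
#' bit-exactly in decimal.
#'
#' @param traj a `lambda_trajectory`.
#' @param path file path.
#' @param topology,settings objects to attach on read (the file carries data
#'   only).
#' @return `read_trajectory()` returns a `lambda_trajectory` (without theta,
#'   which is simulation-internal).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "lambda_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("step", colnames(traj$lambda)), collapse = "\t"), con)
  body <- apply(traj$lambda, 1L, function(r)
    paste(formatC(r, format = "g", digits = 10), collapse = "\t"))
  writeLines(paste(traj$step, body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path, topology, settings = sampler_settings()) {
  tab <- read.delim(path, check.names = FALSE)
  lam <- as.matrix(tab[, -1L, drop = FALSE])
  structure(list(lambda = lam, theta = NULL, step = as.integer(tab$step),
                 topology = topology, settings = settings,
                 bias = zero_bias(topology), replica = 1L),
            class = "lambda_trajectory")
}
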