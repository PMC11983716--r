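#' Flattening schedule for adaptive landscape flattening
#'
#' The ALF loop alternates short biased runs with bias updates.  The default
#' schedule mirrors the standard protocol structure: many short flattening
#' iterations, up to ten medium refinement iterations, then four production
#' phases of increasing length with further refinement after each run.  The
#' phase step counts keep the same ratios as the usual 100 ps / 1 ns /
#' (5, 20, 20, 100) ns protocol, mapped to model-time steps.
#'
#' @param short_iters,short_steps number and length of initial short
#'   flattening iterations.
#' @param medium_iters,medium_steps number and length of refinement
#'   iterations.
#' @param production_steps vector of production run lengths (steps); at
#'   least one is required.
#' @return An object of class `alf_schedule`: a data frame of phases with
#'   columns `phase`, `n_iter`, `n_steps`, `update`, `production`.
#' @export
#' @examples
#' alf_schedule()                        # full default protocol
#' alf_schedule(10, 1000, 5, 5000, 2e4)  # reduced schedule for small toys
alf_schedule <- function(short_iters = 20L, short_steps = 1000L,
                         medium_iters = 10L, medium_steps = 10000L,
                         production_steps = c(5e4, 2e5, 2e5, 1e6)) {
  stopifnot(short_iters >= 1, medium_iters >= 0, length(production_steps) >= 1,
            all(c(short_steps, medium_steps, production_steps) >= 1))
  phases <- rbind(
    data.frame(phase = "short", n_iter = as.integer(short_iters),
               n_steps = as.integer(short_steps), update = TRUE,
               production = FALSE),
    if (medium_iters > 0)
      data.frame(phase = "medium", n_iter = as.integer(medium_iters),
                 n_steps = as.integer(medium_steps), update = TRUE,
                 production = FALSE),
    data.frame(phase = paste0("production", seq_along(production_steps)),
               n_iter = 1L, n_steps = as.integer(production_steps),
               update = TRUE, production = TRUE))
  structure(phases, class = c("alf_schedule", "data.frame"))
}

#' Estimate per-coordinate free-energy profiles from lambda trajectories
#'
#' Histograms each lambda coordinate marginal over `bins` equal bins
#' covering \[0, 1\], converts to \eqn{-k_BT\log p}, and subtracts the
#' applied bias energy along that coordinate (the linear term
#' \eqn{-b_{si}\lambda}) to estimate the unbiased profile.  Profiles are
#' reported shifted so their minimum is 0.  Per-bin standard errors come
#' from a block bootstrap over trajectory blocks (block length =
#' frames / 20, at least 1).  Empty bins are flagged, never imputed.
#'
#' @param trajs a `lambda_trajectory` or list of them, all generated under
#'   `bias`.
#' @param bias the [bias_parameters()] the trajectories were run under.
#' @param bins number of bins over \[0, 1\].
#' @param n_boot number of block-bootstrap resamples.
#' @param seed optional RNG seed for the bootstrap.
#' @return An object of class `fe_profile`: `edges`, `centers`, `value`
#'   (bins x P matrix, kcal/mol), `se`, `occupied` (logical), `degenerate`
#'   (per-coordinate flag: all frames in a single bin), `temperature`.
#' @export
estimate_profile <- function(trajs, bias, bins = 25L, n_boot = 50L,
                             seed = NULL) {
  if (inherits(trajs, "lambda_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1, inherits(bias, "bias_parameters"))
  if (!is.null(seed)) set.seed(seed)
  top <- bias$topology
  P <- top$P
  kT <- .kB * trajs[[1]]$settings$temperature
  edges <- seq(0, 1, length.out = bins + 1L)
  centers <- (edges[-1L] + edges[-(bins + 1L)]) / 2

  bin_of <- function(lam_mat) {
    # clamp exact 1 into the last bin
    b <- pmin(floor(lam_mat * bins) + 1L, bins)
    matrix(as.integer(b), nrow = nrow(lam_mat))
  }
  counts_from <- function(idx_list) {
    cnt <- matrix(0L, bins, P)
    for (idx in idx_list)
      for (p in seq_len(P))
        cnt[, p] <- cnt[, p] + tabulate(idx[, p], nbins = bins)
    cnt
  }
  profile_from <- function(cnt) {
    n_tot <- colSums(cnt)
    val <- -kT * log(sweep(cnt, 2L, n_tot, "/"))
    val[!is.finite(val)] <- NA_real_
    val <- val + outer(centers, bias$b)  # subtract -b*lambda along the coordinate
    sweep(val, 2L, apply(val, 2L, min, na.rm = TRUE), "-")
  }

  idx_full <- lapply(trajs, function(tr) bin_of(tr$lambda))
  cnt <- counts_from(idx_full)
  value <- profile_from(cnt)
  occupied <- cnt > 0L
  degenerate <- colSums(occupied) <= 1L

  boot <- array(NA_real_, dim = c(bins, P, n_boot))
  for (k in seq_len(n_boot)) {
    res <- lapply(idx_full, function(idx) {
      n <- nrow(idx)
      bl <- max(1L, n %/% 20L)
      starts <- seq(1L, n, by = bl)
      pick <- sample(starts, length(starts), replace = TRUE)
      rows <- unlist(lapply(pick, function(s) s:min(s + bl - 1L, n)))
      idx[rows, , drop = FALSE]
    })
    boot[, , k] <- profile_from(counts_from(res))
  }
  se <- apply(boot, c(1L, 2L), function(v) {
    v <- v[is.finite(v)]
    if (length(v) > 1) sd(v) else 0
  })
  se[!occupied] <- NA_real_

  structure(list(edges = edges, centers = centers, value = value, se = se,
                 occupied = occupied, degenerate = degenerate,
                 temperature = trajs[[1]]$settings$temperature,
                 settings = trajs[[1]]$settings,
                 coord = coord_names(top), topology = top),
            class = "fe_profile")
}

#' @export
print.fe_profile <- function(x, ...) {
  cat("Free-energy profile:", nrow(x$value), "bins x", ncol(x$value),
      "coordinates\n")
  d <- endpoint_differences(x)
  cat("endpoint differences (kcal/mol):",
      paste(sprintf("%.3g", d), collapse = " "), "\n")
  if (any(x$degenerate)) cat("degenerate support on:",
                             paste(x$coord[x$degenerate], collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.fe_profile <- function(x, ...) {
  graphics::matplot(x$centers, x$value, type = "l", lty = 1,
                    xlab = expression(lambda), ylab = "free energy (kcal/mol)",
                    ...)
  graphics::legend("top", legend = x$coord, col = seq_len(ncol(x$value)),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}

# Per-coordinate endpoint bookkeeping.  An endpoint counts as reached when
# any bin in the outer quarter of the lambda range on that side is
# occupied.  `full` is the endpoint free-energy difference
# F(lambda ~ 1) - F(lambda ~ 0) (NA when either end is unexplored);
# `partial` is the difference between the extreme occupied bins, a
# progress-guaranteeing lower-bound surrogate used when an end has not yet
# been sampled.
endpoint_state <- function(profile) {
  bins <- nrow(profile$value)
  outer_q <- max(1L, bins %/% 4L)
  P <- ncol(profile$value)
  out <- data.frame(full = rep(NA_real_, P), partial = NA_real_,
                    lo = FALSE, hi = FALSE)
  for (p in seq_len(P)) {
    occ <- which(profile$occupied[, p])
    if (length(occ) < 2L) next
    lo <- occ[occ <= outer_q]
    hi <- occ[occ > bins - outer_q]
    out$lo[p] <- length(lo) > 0L
    out$hi[p] <- length(hi) > 0L
    out$partial[p] <- profile$value[max(occ), p] - profile$value[min(occ), p]
    if (out$lo[p] && out$hi[p])
      out$full[p] <- profile$value[max(hi), p] - profile$value[min(lo), p]
  }
  out
}

# Endpoint free-energy difference per coordinate (NA when unexplored).
endpoint_differences <- function(profile) endpoint_state(profile)$full

# Residual flattening imbalance (kcal/mol): how far the biased,
# baseline-corrected landscape still is from flat at the endpoints.
residual_imbalance <- function(profile, bias) {
  prof0 <- profile
  prof0$value <- profile$value - baseline_matrix(profile)
  d <- endpoint_state(prof0)$full - bias$b
  if (all(is.na(d))) NA_real_ else max(abs(d), na.rm = TRUE)
}

# --- measure baseline -------------------------------------------------------
# The lambda-marginal of a *flat* energy landscape is not flat: the softmax
# transform piles theta-space volume onto the vertices and the harmonic
# confinement weights the transition region, producing an apparent
# mid-lambda barrier of order kT that is parametrisation entropy, not
# kinetics (the theta-space landscape really is flat).  ALF must flatten
# profiles *relative to this baseline*, otherwise the quadratic bias digs a
# mid-simplex trap.  The baseline depends only on (N_s, bins, steepness,
# restraint, kT) and is computed once by quadrature and cached.
.baseline_cache <- new.env(parent = emptyenv())

measure_baseline <- function(n, bins, steepness, restraint, kT) {
  key <- paste(n, bins, signif(steepness, 10), signif(restraint, 10),
               signif(kT, 10), sep = "|")
  hit <- .baseline_cache[[key]]
  if (!is.null(hit)) return(hit)
  dims <- n - 1L
  npts <- c(4001L, 201L, 81L)[min(dims, 3L)]
  pts <- as.matrix(do.call(expand.grid,
                           rep(list(seq(-8, 8, length.out = npts)), dims)))
  B <- sumzero_basis(n)
  z <- steepness * (pts %*% t(B))
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  lam1 <- e[, 1L] / rowSums(e)   # all substituents equivalent by symmetry
  w <- exp(-(0.5 * restraint * rowSums(pts^2)) / kT)
  bin <- pmin(floor(lam1 * bins) + 1L, bins)
  p0 <- vapply(seq_len(bins), function(b) sum(w[bin == b]), numeric(1))
  F0 <- -kT * log(p0 / sum(p0))
  F0 <- F0 - min(F0[is.finite(F0)])
  .baseline_cache[[key]] <- F0
  F0
}

# bins x P matrix of baselines matching a profile's topology/settings
baseline_matrix <- function(profile) {
  top <- profile$topology
  st <- profile$settings
  kT <- .kB * profile$temperature
  bins <- length(profile$centers)
  out <- matrix(0, bins, ncol(profile$value))
  for (s in seq_along(top$n_sub)) {
    F0 <- measure_baseline(top$n_sub[s], bins, st$steepness,
                           st$theta_restraint, kT)
    for (i in seq_len(top$n_sub[s])) out[, flat_index(top, s, i)] <- F0
  }
  out
}

# Signed residual mid-lambda barrier per coordinate: mean of the *sampled*
# (biased) marginal profile over the central third of the lambda range,
# minus its mean at the extreme occupied bins.  Positive means a barrier
# remains between the endstates; negative means the current bias
# over-stabilises the transition region (a mid-lambda trap), which the
# quadratic update must be able to undo.  Averages over bins (rather than
# an interior maximum) so that histogram noise does not bias the estimate
# upward.
residual_barriers <- function(profile, bias) {
  ctr <- profile$centers
  bins <- length(ctr)
  central <- which(ctr > 1 / 3 & ctr < 2 / 3)
  vapply(seq_len(ncol(profile$value)), function(p) {
    eff <- profile$value[, p] - bias$b[p] * ctr  # back to the sampled profile
    occ <- which(profile$occupied[, p])
    mid <- intersect(occ, central)
    if (length(occ) < 3L || !length(mid)) return(0)
    ends <- c(min(occ), max(occ))
    mean(eff[mid]) - mean(eff[ends])
  }, numeric(1))
}

#' Update bias parameters from a free-energy profile (one ALF iteration)
#'
#' Linear coefficients are moved toward the estimated unbiased endpoint
#' free-energy difference: `b <- b + damping * (D - b)` with the change
#' clipped to `+/- cap` per iteration, so a converged landscape
#' (`b = D`) is a fixed point and a flat unbiased profile with zero bias
#' stays at zero.  When one lambda endpoint of a coordinate was never
#' sampled in the iteration, the full difference is unknown; the update
#' then targets the partial climb observed so far plus an exploratory push
#' of one thermal energy toward the unexplored end, which guarantees
#' progress and recovers from a mis-tilted bias instead of deadlocking.
#' Intra-site quadratic terms are adjusted to cancel the signed residual
#' mid-lambda barrier (central region minus endpoint mean), same damping
#' and cap.  Both updates are measured relative to the exactly computed
#' parametrisation-entropy baseline: the lambda-marginal a flat theta-space
#' landscape would produce under the softmax transform and harmonic
#' confinement, which carries an apparent mid-lambda barrier of order kT
#' that must not be "corrected" away.  The inter-site coupling `Psi` is a
#' scheme-level bias and is never touched by ALF.  The input object is not
#' modified.
#'
#' @param profile an [estimate_profile()] result.
#' @param bias current [bias_parameters()].
#' @param damping update damping in (0, 1].
#' @param cap maximum parameter change per iteration, kcal/mol.
#' @return A new `bias_parameters` object; attribute `no_update` is `TRUE`
#'   when no coordinate had usable endpoints (both profile endpoints empty).
#' @export
update_bias <- function(profile, bias, damping = 0.5, cap = 5) {
  stopifnot(inherits(profile, "fe_profile"), inherits(bias, "bias_parameters"),
            damping > 0, damping <= 1, cap > 0)
  top <- bias$topology
  # flatten relative to the parametrisation-entropy baseline (see above)
  prof0 <- profile
  prof0$value <- profile$value - baseline_matrix(profile)
  es <- endpoint_state(prof0)
  if (!any(es$lo | es$hi)) {
    # both profile endpoints empty for every coordinate: stuck mid-simplex
    out <- bias
    attr(out, "no_update") <- TRUE
    return(out)
  }
  push <- .kB * profile$temperature
  target <- ifelse(es$lo & es$hi, es$full,
            ifelse(es$lo & !es$hi, es$partial + push,          # never activated
            ifelse(es$hi & !es$lo, es$partial - push, bias$b)))# never deactivated
  clip <- function(x) pmax(-cap, pmin(cap, x))
  db <- clip(damping * (target - bias$b))
  db[is.na(db)] <- 0
  b_new <- bias$b + db

  barrier <- residual_barriers(prof0, bias)
  psi_new <- bias$psi
  for (s in seq_along(top$n_sub)) {
    idx <- top$offset[s] + seq_len(top$n_sub[s])
    bs <- mean(barrier[idx])
    dpsi <- clip(-2 * damping * bs)
    if (dpsi != 0)
      for (i in idx) for (j in idx) if (i != j)
        psi_new[i, j] <- psi_new[i, j] + dpsi
  }
  out <- bias_parameters(top, b = b_new, psi = psi_new, Psi = bias$Psi)
  attr(out, "no_update") <- FALSE
  out
}

#' Adaptive landscape flattening
#'
#' Starting from zero linear and intra-site quadratic bias (any scheme-level
#' inter-site coupling `Psi` attached to the topology is kept fixed), this
#' alternates [run_trajectory()] and [update_bias()] through the phases of
#' the schedule, refining the bias after each production run.  Fully
#' reproducible from `seed`: every iteration's RNG stream is derived with
#' [derive_seed()].
#'
#' @param topology an [alch_topology()]; a `Psi` field (from
#'   [build_scheme()] with the coupled scheme) seeds the fixed coupling
#'   bias.
#' @param H a [model_hamiltonian()].
#' @param schedule an [alf_schedule()].
#' @param settings a [sampler_settings()]; `n_steps` and `seed` are
#'   overridden per phase.
#' @param seed master seed.
#' @param damping,cap,bins,n_boot passed to [estimate_profile()] and
#'   [update_bias()].
#' @return An object of class `alf_result`: `bias` (final
#'   [bias_parameters()]), `log` (data frame with phase, iteration, steps,
#'   imbalance, max |b|), `profiles` (list of per-iteration profiles),
#'   `trajectories` (the production trajectories).
#' @export
alf_flatten <- function(topology, H, schedule = alf_schedule(),
                        settings = sampler_settings(), seed = 1L,
                        damping = 0.5, cap = 5, bins = 25L, n_boot = 50L) {
  stopifnot(inherits(schedule, "alf_schedule"))
  bias <- bias_parameters(topology, Psi = topology$Psi)
  log_rows <- list()
  profiles <- list()
  prod_trajs <- list()
  counter <- 0L
  theta <- NULL; vel <- NULL
  degen_run <- 0L
  for (ph in seq_len(nrow(schedule))) {
    for (it in seq_len(schedule$n_iter[ph])) {
      counter <- counter + 1L
      st <- settings
      st$n_steps <- schedule$n_steps[ph]
      st$seed <- derive_seed(seed, counter)
      traj <- run_trajectory(topology, H, bias, st,
                             theta0 = theta, velocity0 = vel)
      theta <- traj$final_theta; vel <- traj$final_velocity
      prof <- estimate_profile(traj, bias, bins = bins, n_boot = n_boot,
                               seed = derive_seed(seed, counter + 100000L))
      imb <- residual_imbalance(prof, bias)
      if (schedule$phase[ph] == "short") {
        degen_run <- if (all(prof$degenerate)) degen_run + 1L else 0L
        if (degen_run >= schedule$n_iter[ph])
          stop_msldyn("persistent degenerate lambda support during flattening; ",
                      "reduce energy gaps or lengthen the iterations")
      }
      if (schedule$production[ph]) prod_trajs[[length(prod_trajs) + 1L]] <- traj
      if (schedule$update[ph]) bias <- update_bias(prof, bias, damping, cap)
      log_rows[[counter]] <- data.frame(
        phase = schedule$phase[ph], iteration = it,
        n_steps = schedule$n_steps[ph], imbalance = imb,
        max_abs_b = max(abs(bias$b)))
      profiles[[counter]] <- prof
    }
  }
  structure(list(bias = bias, log = do.call(rbind, log_rows),
                 profiles = profiles, trajectories = prod_trajs,
                 topology = topology, seed = seed),
            class = "alf_result")
}

#' @export
print.alf_result <- function(x, ...) {
  cat("ALF flattening:", nrow(x$log), "iterations\n")
  cat("final linear bias b:", paste(sprintf("%.3g", x$bias$b), collapse = " "),
      "kcal/mol\n")
  cat("final imbalance:", sprintf("%.3g", tail(x$log$imbalance, 1)),
      "kcal/mol\n")
  invisible(x)
}
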