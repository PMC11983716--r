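#' Specify a reduced toy system with known ground truth
#'
#' A toy system emulates a transcription-factor/DNA binding-specificity
#' scenario at desk scale: every properly paired sequence has a prescribed
#' well depth (kcal/mol) in the bound and unbound ensembles, and mispaired
#' vertices in the two-lambda schemes pay a per-position penalty.  The
#' default emulates the W-box scenario: native GGTCAA mutated to GATAAA,
#' with bound depths echoing the reported ordering of the intermediates
#' (GATCAA stronger destabilisation than GGTAAA) and a flat unbound leg.
#'
#' @param native native sequence.
#' @param mutants mutant sequences.
#' @param bound_depths,unbound_depths named numeric vectors of well depths
#'   (kcal/mol) covering *all* properly paired sequences of the implied
#'   topology.
#' @param mispair_penalty penalty (kcal/mol, >= 0) per mispaired position
#'   in two-lambda schemes.
#' @param seed integer recorded with the spec.
#' @return An object of class `toy_spec`.
#' @export
#' @examples
#' toy_wbox()
toy_spec <- function(native, mutants, bound_depths, unbound_depths,
                     mispair_penalty = 2, seed = 1L) {
  ms <- mutation_spec(native, mutants, "one_lambda_per_pair")
  seqs <- build_scheme(ms)$vertices$label
  for (nm in c("bound_depths", "unbound_depths")) {
    d <- get(nm)
    if (is.null(names(d)) || !all(seqs %in% names(d)))
      stop_msldyn(nm, " must name a depth for every properly paired sequence: ",
                  paste(seqs, collapse = ", "))
  }
  stopifnot(mispair_penalty >= 0)
  structure(list(native = native, mutants = mutants,
                 sequences = seqs,
                 bound_depths = bound_depths[seqs],
                 unbound_depths = unbound_depths[seqs],
                 mispair_penalty = mispair_penalty, seed = as.integer(seed)),
            class = "toy_spec")
}

#' @rdname toy_spec
#' @param ... overrides passed to [toy_spec()].
#' @export
toy_wbox <- function(...) {
  args <- list(
    native = "GGTCAA", mutants = "GATAAA",
    bound_depths = c(GGTCAA = 0, GATCAA = 4, GGTAAA = 2, GATAAA = 5.7),
    unbound_depths = c(GGTCAA = 0, GATCAA = 0, GGTAAA = 0, GATAAA = 0),
    mispair_penalty = 2, seed = 1L)
  do.call(toy_spec, modifyList(args, list(...)))
}

#' Build bound and unbound model Hamiltonians for a toy system
#'
#' Sequence-level well depths are realised exactly on the topology of the
#' requested scheme: with one or two variant positions the depths are
#' placed on per-substituent energies `h` (single site) or on inter-site
#' couplings `J` between the variant positions (two sites), so that each
#' matched vertex's energy equals its prescribed depth.  In two-lambda
#' schemes the depths live on the primary-strand sites and every mispaired
#' site pair adds `mispair_penalty` through the `J` block between the
#' paired sites.  The exact free energy of every mutant is then computable
#' with [quadrature_dg()].
#'
#' @param spec a [toy_spec()].
#' @param scheme scheme selector (see [mutation_spec()]).
#' @param coupling_strength Psi fill for the coupled scheme.
#' @return List with `topology`, `bound` and `unbound`
#'   ([model_hamiltonian()]s), and `spec`.
#' @export
#' @examples
#' sys <- make_toy_pair(toy_wbox(), "one_lambda_per_pair")
make_toy_pair <- function(spec, scheme = c("one_lambda_per_pair", "two_lambda",
                                           "coupled_two_lambda"),
                          coupling_strength = -2) {
  stopifnot(inherits(spec, "toy_spec"))
  scheme <- normalize_scheme(scheme)
  ms <- mutation_spec(spec$native, spec$mutants, scheme, coupling_strength)
  top <- build_scheme(ms)
  M <- length(top$n_sub)
  prim <- which(top$strand != "complement")
  n_pos <- length(prim)
  if (n_pos > 2L)
    stop_msldyn("toy construction supports at most two variant positions")

  build_H <- function(depths) {
    h <- numeric(top$P)
    J <- matrix(0, top$P, top$P)
    if (n_pos == 1L) {
      s <- prim[1L]
      for (i in seq_len(top$n_sub[s])) {
        v <- which(top$vertices[, s] == i & top$vertices$matched)[1L]
        h[flat_index(top, s, i)] <- depths[[top$vertices$label[v]]]
      }
    } else {
      s <- prim[1L]; t <- prim[2L]
      for (i in seq_len(top$n_sub[s])) for (j in seq_len(top$n_sub[t])) {
        v <- which(top$vertices[, s] == i & top$vertices[, t] == j &
                     top$vertices$matched)[1L]
        J[flat_index(top, s, i), flat_index(top, t, j)] <-
          J[flat_index(top, t, j), flat_index(top, s, i)] <-
          depths[[top$vertices$label[v]]]
      }
    }
    if (spec$mispair_penalty > 0) {
      for (s in seq_len(M)) {
        t <- top$pairing[s]
        if (!is.na(t) && s < t) {
          for (i in seq_len(top$n_sub[s])) for (j in seq_len(top$n_sub[t])) {
            if (wc_complement(top$sub_labels[[s]][i]) != top$sub_labels[[t]][j]) {
              p <- flat_index(top, s, i); q <- flat_index(top, t, j)
              J[p, q] <- J[q, p] <- J[p, q] + spec$mispair_penalty
            }
          }
        }
      }
    }
    model_hamiltonian(top, env = 0, h = h, J = J)
  }

  list(topology = top, bound = build_H(spec$bound_depths),
       unbound = build_H(spec$unbound_depths), spec = spec)
}

# Quadrature grid aligned so the lambda_c bin boundaries of two-substituent
# sites (+/- v_c in the orthonormal gauge coordinate) fall exactly midway
# between grid points: the indicator-function integration error then
# shrinks quadratically with the spacing instead of linearly.
aligned_grid <- function(npts, range, steepness, lambda_c) {
  vc <- log(lambda_c / (1 - lambda_c)) / (steepness * sqrt(2))
  h <- 2 * vc / max(1L, round(2 * vc / (2 * range / (npts - 1L))))
  kmax <- ceiling((range - vc) / h) + 1L
  vc + h / 2 + h * seq(-as.integer(round(2 * vc / h)) - kmax, kmax - 1L)
}

# Orthonormal basis of the sum-zero subspace of R^n (n x (n-1) matrix).
sumzero_basis <- function(n) {
  Q <- qr.Q(qr(cbind(rep(1, n), diag(n)[, -n, drop = FALSE])))
  Q[, -1L, drop = FALSE]
}

# Evaluate lambda and total reduced energy on a gauge-fixed quadrature grid.
# Returns list(lam = n x P matrix, V = total potential incl. restraint).
quadrature_grid_energy <- function(H, bias, grid_pts, steepness, restraint) {
  top <- H$topology
  dims_per_site <- top$n_sub - 1L
  dims <- sum(dims_per_site)
  pts <- as.matrix(do.call(expand.grid,
                           c(rep(list(grid_pts), dims), KEEP.OUT.ATTRS = FALSE)))
  n <- nrow(pts)
  lam <- matrix(0, n, top$P)
  col0 <- 0L
  for (s in seq_along(top$n_sub)) {
    ns <- top$n_sub[s]
    B <- sumzero_basis(ns)
    d <- pts[, col0 + seq_len(ns - 1L), drop = FALSE] %*% t(B)  # n x ns
    z <- steepness * d
    z <- z - apply(z, 1L, max)
    e <- exp(z)
    lam[, top$offset[s] + seq_len(ns)] <- e / rowSums(e)
    col0 <- col0 + ns - 1L
  }
  b <- if (is.null(bias)) numeric(top$P) else bias$b
  C <- quad_matrix(H, bias)
  V <- H$env + as.numeric(lam %*% (H$h - b)) +
    0.5 * rowSums((lam %*% C) * lam) +
    0.5 * restraint * rowSums(pts^2)
  list(lam = lam, V = V, pts = pts)
}

#' Exact free energies by dense quadrature (the brute-force oracle)
#'
#' Integrates the Boltzmann weight \eqn{e^{-V(\theta)/k_BT}} of the total
#' sampled potential (composite potential plus harmonic theta confinement)
#' over gauge-fixed theta space on a dense tensor grid, accumulates the
#' weight inside each sequence's \eqn{\lambda_c} bin, and returns
#' \eqn{-k_BT\log} mass ratios with the same vertex bias correction as the
#' population estimator.  The per-site softmax centre coordinate factorises
#' and cancels in all ratios, so only \eqn{\sum_s (N_s - 1)} dimensions are
#' integrated; the oracle refuses more than 4.  Bin-volume entropy is
#' integrated exactly rather than assumed to cancel.
#'
#' @param H a [model_hamiltonian()].
#' @param bias a [bias_parameters()] or `NULL`.
#' @param temperature kelvin.
#' @param lambda_c endstate bin cutoff.
#' @param grid points per dimension.
#' @param range half-width of the per-dimension grid (model theta units).
#' @param steepness,theta_restraint must match the sampler settings.
#' @param reference reference sequence (default native endstate).
#' @param bias_correction as in [free_energy_from_populations()].
#' @param check_convergence when TRUE, re-evaluate at doubled resolution
#'   and record the maximum change as attribute `convergence`.
#' @return Data frame with `sequence` and exact `dG` (kcal/mol) for every
#'   matched sequence, relative to the reference.
#' @export
quadrature_dg <- function(H, bias = NULL, temperature = 298, lambda_c = 0.99,
                          grid = 201L, range = 6, steepness = 5.5,
                          theta_restraint = 1, reference = NULL,
                          bias_correction = TRUE, check_convergence = FALSE) {
  stopifnot(inherits(H, "model_hamiltonian"))
  top <- H$topology
  dims <- sum(top$n_sub - 1L)
  if (dims > 4L)
    stop_msldyn("quadrature oracle supports at most 4 gauge-fixed theta ",
                "dimensions (got ", dims, ")")
  matched <- matched_state_filter(top)
  seqs <- matched$label
  reference <- reference %||% seqs[1L]
  stopifnot(reference %in% seqs)
  kT <- .kB * temperature

  eval_masses <- function(npts) {
    ge <- quadrature_grid_energy(H, bias,
                                 aligned_grid(npts, range, steepness, lambda_c),
                                 steepness, theta_restraint)
    w <- exp(-(ge$V - min(ge$V)) / kT)
    mass <- setNames(numeric(length(seqs)), seqs)
    for (k in seq_along(seqs)) {
      v <- as.integer(rownames(matched))[k]
      sel <- rep(TRUE, length(w))
      for (s in seq_along(top$n_sub)) {
        p <- flat_index(top, s, top$vertices[v, s])
        sel <- sel & (ge$lam[, p] >= lambda_c)
      }
      mass[k] <- sum(w[sel])
    }
    mass
  }

  Bv <- if (bias_correction && !is.null(bias)) {
    all_B <- vertex_bias_energy(bias)
    setNames(all_B[match(seqs, top$vertices$label)], seqs)
  } else setNames(numeric(length(seqs)), seqs)

  mass <- eval_masses(as.integer(grid))
  if (any(mass == 0))
    stop_msldyn("empty lambda_c bin in quadrature; widen 'range' or refine 'grid'")
  dG <- -kT * log(mass / mass[reference]) - (Bv - Bv[reference])
  out <- data.frame(sequence = seqs, dG = unname(dG), stringsAsFactors = FALSE)
  if (check_convergence) {
    mass2 <- eval_masses(2L * as.integer(grid) - 1L)
    dG2 <- -kT * log(mass2 / mass2[reference]) - (Bv - Bv[reference])
    attr(out, "convergence") <- max(abs(dG2 - dG))
  }
  attr(out, "reference") <- reference
  out
}

#' Boltzmann density of the gauge-invariant theta difference (1-site oracle)
#'
#' For a single-site, two-substituent system, the distribution sampled by
#' the Langevin dynamics is fully characterised by the difference
#' \eqn{u = \theta_2 - \theta_1} (the centre coordinate factorises as a
#' free Gaussian).  This returns the normalised density of `u` under the
#' total potential, for Kolmogorov-Smirnov checks of sampler fidelity.
#'
#' @inheritParams quadrature_dg
#' @param n number of quadrature points.
#' @param range half-width of the `u` grid.
#' @return Data frame with `u`, `density` and `cdf` columns.
#' @export
theta_difference_density <- function(H, bias = NULL, temperature = 298,
                                     n = 4001L, range = 8, steepness = 5.5,
                                     theta_restraint = 1) {
  top <- H$topology
  stopifnot(length(top$n_sub) == 1L, top$n_sub[1L] == 2L)
  u <- seq(-range, range, length.out = n)
  lam2 <- 1 / (1 + exp(-steepness * u))
  lam <- cbind(1 - lam2, lam2)
  b <- if (is.null(bias)) numeric(2) else bias$b
  C <- quad_matrix(H, bias)
  V <- H$env + as.numeric(lam %*% (H$h - b)) + 0.5 * rowSums((lam %*% C) * lam) +
    0.25 * theta_restraint * u^2  # |d|^2 = u^2/2 in the sum-zero subspace
  kT <- .kB * temperature
  w <- exp(-(V - min(V)) / kT)
  du <- u[2L] - u[1L]
  dens <- w / (sum(w) * du)
  data.frame(u = u, density = dens, cdf = cumsum(dens) * du)
}
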