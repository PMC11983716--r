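#' Reduced model Hamiltonian for an alchemical topology
#'
#' The composite potential of multisite lambda-dynamics contains an
#' environment self-term, substituent-environment and substituent self-terms
#' that scale linearly with \eqn{\lambda_{si}}, and substituent-substituent
#' terms between different sites that scale bilinearly with
#' \eqn{\lambda_{si}\lambda_{tj}}.  In the reduced model the Cartesian
#' interaction terms are collapsed to scalar effective energies: a constant
#' `env` (kcal/mol), a per-(site, substituent) energy vector `h`, and a
#' symmetric inter-site coupling matrix `J` whose within-site blocks are
#' identically zero (two substituents at one site are never simultaneously
#' physical).
#'
#' @param topology an [alch_topology()].
#' @param env environment self-energy constant (kcal/mol).
#' @param h numeric vector of length `topology$P` (site-major,
#'   substituent-minor), kcal/mol.  Scalar is recycled.
#' @param J `P x P` symmetric matrix of inter-site couplings (kcal/mol), or
#'   `NULL` for no couplings.  Entries within a site block must be zero.
#' @return An object of class `model_hamiltonian`.
#' @export
#' @examples
#' top <- alch_topology(list(pos4 = c("C", "A")))
#' H <- model_hamiltonian(top, h = c(0, 1.5))
model_hamiltonian <- function(topology, env = 0, h = 0, J = NULL) {
  stopifnot(inherits(topology, "alch_topology"))
  P <- topology$P
  h <- rep_len(as.numeric(h), P)
  if (is.null(J)) J <- matrix(0, P, P)
  J <- as.matrix(J)
  if (!all(dim(J) == c(P, P))) stop_msldyn("J must be ", P, " x ", P)
  if (max(abs(J - t(J))) > 1e-12)
    stop_msldyn("J must be symmetric under (s,i) <-> (t,j) exchange")
  for (s in seq_along(topology$n_sub)) {
    idx <- topology$offset[s] + seq_len(topology$n_sub[s])
    if (any(J[idx, idx] != 0))
      stop_msldyn("J entries within site ", s, " must be zero")
  }
  if (any(!is.finite(env)) || any(!is.finite(h)) || any(!is.finite(J)))
    stop_msldyn("non-finite Hamiltonian parameters")
  structure(list(env = as.numeric(env), h = h, J = J, topology = topology),
            class = "model_hamiltonian")
}

#' @export
print.model_hamiltonian <- function(x, ...) {
  cat("Reduced model Hamiltonian: env =", x$env, "kcal/mol\n")
  cat("h:", paste(sprintf("%.3g", x$h), collapse = " "), "\n")
  cat("non-zero J couplings:", sum(x$J[upper.tri(x$J)] != 0), "\n")
  invisible(x)
}

#' Softmax implicit-constraint transform from theta to lambda
#'
#' The simplex constraints (\eqn{0 \le \lambda_{si} \le 1},
#' \eqn{\sum_i \lambda_{si} = 1}) are maintained implicitly by propagating
#' unconstrained coordinates \eqn{\theta_{si}} and mapping them through a
#' per-site exponential normalisation,
#' \deqn{\lambda_{si} = \frac{e^{c\,\theta_{si}}}{\sum_j e^{c\,\theta_{sj}}},}
#' with steepness constant \eqn{c} (default 5.5).  The per-site maximum is
#' subtracted before exponentiation for numerical stability; for very
#' negative relative theta a lambda can underflow to exactly 0, which is
#' acceptable.
#'
#' @param theta numeric vector of length `topology$P`, all finite.
#' @param topology an [alch_topology()].
#' @param steepness positive steepness constant \eqn{c}.
#' @return Numeric lambda vector of length `topology$P`; each site block
#'   sums to 1 to within floating-point normalisation.
#' @export
#' @examples
#' top <- alch_topology(list(pos4 = c("C", "A")))
#' theta_to_lambda(c(0, 0), top)       # symmetric split
#' theta_to_lambda(c(1, 0), top)       # strongly favours the first substituent
theta_to_lambda <- function(theta, topology, steepness = 5.5) {
  stopifnot(inherits(topology, "alch_topology"))
  if (length(theta) != topology$P)
    stop_msldyn("theta has length ", length(theta), ", expected ", topology$P)
  if (any(!is.finite(theta))) stop_msldyn("non-finite theta")
  if (!is.numeric(steepness) || length(steepness) != 1L || steepness <= 0)
    stop_msldyn("steepness must be a positive number")
  lam <- numeric(topology$P)
  for (s in seq_along(topology$n_sub)) {
    idx <- topology$offset[s] + seq_len(topology$n_sub[s])
    z <- steepness * theta[idx]
    z <- z - max(z)
    e <- exp(z)
    lam[idx] <- e / sum(e)
  }
  lam
}

# Combined quadratic lambda-coupling matrix: Hamiltonian J, intra-site
# quadratic bias (ordered-pair convention, hence factor 2) and the inter-site
# coupling bias Psi (attractive when positive, hence minus sign).  The total
# quadratic energy is lambda' %*% Cmat %*% lambda / 2.
quad_matrix <- function(H, bias) {
  C <- H$J
  if (!is.null(bias)) C <- C + 2 * bias$psi - bias$Psi
  C
}

#' Composite potential energy of a lambda state
#'
#' Evaluates the reduced composite potential
#' \deqn{V(\lambda) = E_{env} + \sum_{s,i} \lambda_{si} h_{si}
#'   + \sum_{s<t}\sum_{i,j} \lambda_{si}\lambda_{tj} J_{si,tj}
#'   + V_{bias}(\lambda),}
#' where the bias term is evaluated by [bias_energy()].
#'
#' @param lam lambda vector satisfying the simplex constraints.
#' @param H a [model_hamiltonian()].
#' @param bias a [bias_parameters()] object, or `NULL` for zero bias.
#' @return Energy in kcal/mol.
#' @export
potential_energy <- function(lam, H, bias = NULL) {
  stopifnot(inherits(H, "model_hamiltonian"))
  top <- H$topology
  check_lambda(lam, top)
  v <- H$env + sum(lam * H$h) + 0.5 * sum(lam * (H$J %*% lam))
  if (!is.null(bias)) v <- v + bias_energy(lam, bias)
  v
}

#' Analytic gradient of the composite potential with respect to theta
#'
#' Chain rule through the softmax implicit-constraint transform:
#' \eqn{\partial V/\partial\theta_{sj} = c\,\lambda_{sj}\,(g_{sj} -
#' \sum_i g_{si}\lambda_{si})} with \eqn{g = \partial V/\partial\lambda}.
#' An optional harmonic theta restraint (the confinement term used by the
#' sampler) can be included via `restraint`.
#'
#' @inheritParams theta_to_lambda
#' @inheritParams potential_energy
#' @param restraint harmonic restraint constant `k_r` adding
#'   `restraint * theta` to the gradient (set 0 to differentiate the bare
#'   composite potential).
#' @return Gradient vector, kcal/mol per unit theta; agrees with central
#'   finite differences of [potential_energy()] composed with
#'   [theta_to_lambda()].
#' @export
potential_gradient_theta <- function(theta, H, bias = NULL, steepness = 5.5,
                                     restraint = 0) {
  stopifnot(inherits(H, "model_hamiltonian"))
  top <- H$topology
  lam <- theta_to_lambda(theta, top, steepness)
  b <- if (is.null(bias)) numeric(top$P) else bias$b
  g_lam <- H$h - b + as.numeric(quad_matrix(H, bias) %*% lam)
  grad <- numeric(top$P)
  for (s in seq_along(top$n_sub)) {
    idx <- top$offset[s] + seq_len(top$n_sub[s])
    dot <- sum(g_lam[idx] * lam[idx])
    grad[idx] <- steepness * lam[idx] * (g_lam[idx] - dot)
  }
  grad + restraint * theta
}

# Total potential at theta, as sampled: composite potential + harmonic
# theta restraint.  Used by oracles and diagnostics.
total_potential_theta <- function(theta, H, bias = NULL, steepness = 5.5,
                                  restraint = 1) {
  lam <- theta_to_lambda(theta, H$topology, steepness)
  potential_energy(lam, H, bias) + 0.5 * restraint * sum(theta^2)
}
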