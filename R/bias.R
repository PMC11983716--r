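#' Bias potential parameters
#'
#' The biasing potential applied to the lambda coordinates has three parts:
#' a linear term \eqn{-\sum b_{si}\lambda_{si}} (positive `b` stabilises the
#' corresponding endstate), an intra-site quadratic term
#' \eqn{\sum_s \sum_{i\ne j} \psi_{s,ij}\lambda_{si}\lambda_{sj}} that tunes
#' the mid-lambda barrier, and an inter-site coupling term
#' \eqn{-\sum_{(s,t)\ paired} \sum_{i,j} \Psi_{si,tj}\lambda_{si}\lambda_{tj}}
#' acting on Watson-Crick paired sites, attractive for matched substituent
#' pairs when \eqn{\Psi > 0}.  Rows and columns of \eqn{\Psi} belonging to
#' the reference substituent (index 1) are zero by convention
#' (\eqn{\Psi_{s1,tj} = \Psi_{si,t1} = 0}).
#'
#' @param topology an [alch_topology()].
#' @param b linear coefficients, numeric of length `topology$P` (kcal/mol);
#'   scalar recycled.
#' @param psi `P x P` symmetric matrix with zero diagonal, non-zero only
#'   within site blocks, or `NULL` for zeros.
#' @param Psi `P x P` symmetric matrix, non-zero only between paired site
#'   blocks and zero on reference-substituent rows/columns, or `NULL`.
#' @return An object of class `bias_parameters`.
#' @export
#' @examples
#' top <- alch_topology(list(pos4 = c("C", "A")))
#' zero_bias(top)
bias_parameters <- function(topology, b = 0, psi = NULL, Psi = NULL) {
  stopifnot(inherits(topology, "alch_topology"))
  P <- topology$P
  b <- rep_len(as.numeric(b), P)
  if (is.null(psi)) psi <- matrix(0, P, P)
  if (is.null(Psi)) Psi <- matrix(0, P, P)
  psi <- as.matrix(psi); Psi <- as.matrix(Psi)
  stopifnot(all(dim(psi) == c(P, P)), all(dim(Psi) == c(P, P)))
  if (max(abs(psi - t(psi))) > 1e-12 || any(diag(psi) != 0))
    stop_msldyn("psi must be symmetric with zero diagonal")
  if (max(abs(Psi - t(Psi))) > 1e-12)
    stop_msldyn("Psi must be symmetric")
  M <- length(topology$n_sub)
  site_of <- rep(seq_len(M), topology$n_sub)
  for (p in seq_len(P)) for (q in seq_len(P)) {
    s <- site_of[p]; t <- site_of[q]
    if (s != t && psi[p, q] != 0)
      stop_msldyn("psi must be zero between different sites")
    if (Psi[p, q] != 0) {
      if (is.na(topology$pairing[s]) || topology$pairing[s] != t)
        stop_msldyn("Psi coupling between unpaired sites ", s, " and ", t)
      if (p == topology$offset[s] + 1L || q == topology$offset[t] + 1L)
        stop_msldyn("Psi rows/columns for reference substituents must be zero")
    }
  }
  if (any(!is.finite(b)) || any(!is.finite(psi)) || any(!is.finite(Psi)))
    stop_msldyn("non-finite bias parameters")
  structure(list(b = b, psi = psi, Psi = Psi, topology = topology),
            class = "bias_parameters")
}

#' @rdname bias_parameters
#' @export
zero_bias <- function(topology) bias_parameters(topology)

#' @export
print.bias_parameters <- function(x, ...) {
  cat("Bias parameters\n  b  :", paste(sprintf("%.4g", x$b), collapse = " "), "\n")
  cat("  psi:", sum(x$psi[upper.tri(x$psi)] != 0), "non-zero intra-site entries\n")
  cat("  Psi:", sum(x$Psi[upper.tri(x$Psi)] != 0), "non-zero coupling entries\n")
  invisible(x)
}

#' Bias potential energy at a lambda state
#'
#' @param lam lambda vector satisfying the simplex constraints.
#' @param bias a [bias_parameters()] object.
#' @return Energy in kcal/mol:
#'   \eqn{-\sum b\lambda + \sum_{s,i\ne j}\psi\lambda\lambda -
#'   \sum_{paired}\sum_{ij}\Psi\lambda\lambda}.
#' @export
bias_energy <- function(lam, bias) {
  stopifnot(inherits(bias, "bias_parameters"))
  top <- bias$topology
  check_lambda(lam, top)
  -sum(bias$b * lam) +
    0.5 * sum(lam * ((2 * bias$psi) %*% lam)) -
    0.5 * sum(lam * (bias$Psi %*% lam))
}

# Bias energy at every vertex of the topology (used by the estimators for
# the explicit bias correction; the intra-site quadratic vanishes at a
# vertex, the linear and Psi terms do not).
vertex_bias_energy <- function(bias) {
  top <- bias$topology
  vapply(seq_len(nrow(top$vertices)),
         function(v) bias_energy(vertex_lambda(top, v), bias),
         numeric(1))
}

#' Write / read bias parameters
#'
#' Serialises a [bias_parameters()] object to JSON with full decimal
#' precision; `read_bias()` restores it exactly (decimal round-trip).
#'
#' @param bias a [bias_parameters()] object.
#' @param path file path.
#' @param topology topology to attach on read.
#' @return `read_bias()` returns a [bias_parameters()] object.
#' @export
write_bias <- function(bias, path) {
  stopifnot(inherits(bias, "bias_parameters"))
  # 17 significant digits guarantee an exact double round-trip in decimal
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  jsonlite::write_json(
    list(b = fmt(bias$b), psi = fmt(bias$psi), Psi = fmt(bias$Psi)),
    path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_bias
#' @export
read_bias <- function(path, topology) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  P <- topology$P
  num <- function(v) as.numeric(unlist(v))
  bias_parameters(topology, b = num(x$b),
                  psi = matrix(num(x$psi), P, P),
                  Psi = matrix(num(x$Psi), P, P))
}
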