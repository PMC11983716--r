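# Independent brute-force oracles and small fixture builders.  These are
# deliberately written as naive nested loops over the composite-potential
# definition, sharing no code with the package's vectorised implementation.

kT298 <- 0.0019872041 * 298

# naive composite potential: env + sum_si lam*h + sum_{s<t} sum_ij lam lam J
brute_potential <- function(lam, H, bias = NULL) {
  top <- H$topology
  M <- length(top$n_sub)
  v <- H$env
  for (s in seq_len(M)) for (i in seq_len(top$n_sub[s]))
    v <- v + lam[top$offset[s] + i] * H$h[top$offset[s] + i]
  for (s in seq_len(M)) for (t in seq_len(M)) if (s < t)
    for (i in seq_len(top$n_sub[s])) for (j in seq_len(top$n_sub[t])) {
      p <- top$offset[s] + i; q <- top$offset[t] + j
      v <- v + lam[p] * lam[q] * H$J[p, q]
    }
  if (!is.null(bias)) v <- v + brute_bias(lam, bias)
  v
}

# naive bias: -sum b lam + sum_s sum_{i != j} psi lam lam
#             - sum_{paired s<t} sum_ij Psi lam lam
brute_bias <- function(lam, bias) {
  top <- bias$topology
  M <- length(top$n_sub)
  v <- 0
  for (s in seq_len(M)) for (i in seq_len(top$n_sub[s])) {
    p <- top$offset[s] + i
    v <- v - bias$b[p] * lam[p]
    for (j in seq_len(top$n_sub[s])) if (i != j)
      v <- v + bias$psi[p, top$offset[s] + j] * lam[p] * lam[top$offset[s] + j]
  }
  for (s in seq_len(M)) {
    t <- top$pairing[s]
    if (!is.na(t) && s < t)
      for (i in seq_len(top$n_sub[s])) for (j in seq_len(top$n_sub[t])) {
        p <- top$offset[s] + i; q <- top$offset[t] + j
        v <- v - bias$Psi[p, q] * lam[p] * lam[q]
      }
  }
  v
}

# random topology with 1..4 sites of 2..3 substituents; optionally the
# first two sites are Watson-Crick paired (complementary substituents)
random_topology <- function(paired = FALSE) {
  M <- sample(1:4, 1)
  if (paired) M <- max(M, 2L)
  bases <- c("A", "C", "G", "T")
  sites <- list()
  for (s in seq_len(M)) {
    n <- sample(2:3, 1)
    sites[[paste0("s", s)]] <- sample(bases, n)
  }
  if (paired) {
    n <- length(sites[[1]])
    comp <- c(A = "T", T = "A", G = "C", C = "G")
    sites[[2]] <- unname(comp[sites[[1]]])
    alch_topology(sites, pairing = list(c(1L, 2L)))
  } else {
    alch_topology(sites)
  }
}

# random Hamiltonian on a topology (symmetric J with zero intra-site blocks)
random_hamiltonian <- function(top, scale = 2) {
  P <- top$P
  M <- length(top$n_sub)
  J <- matrix(0, P, P)
  for (s in seq_len(M)) for (t in seq_len(M)) if (s < t)
    for (i in seq_len(top$n_sub[s])) for (j in seq_len(top$n_sub[t])) {
      p <- top$offset[s] + i; q <- top$offset[t] + j
      J[p, q] <- J[q, p] <- runif(1, -scale, scale)
    }
  model_hamiltonian(top, env = runif(1, -1, 1), h = runif(P, -scale, scale),
                    J = J)
}

# random bias (Psi only on the paired site pair if any)
random_bias <- function(top, scale = 1.5) {
  P <- top$P
  M <- length(top$n_sub)
  psi <- matrix(0, P, P)
  for (s in seq_len(M)) {
    idx <- top$offset[s] + seq_len(top$n_sub[s])
    for (i in idx) for (j in idx) if (i < j)
      psi[i, j] <- psi[j, i] <- runif(1, -scale, scale)
  }
  Psi <- matrix(0, P, P)
  for (s in seq_len(M)) {
    t <- top$pairing[s]
    if (!is.na(t) && s < t)
      for (i in 2:top$n_sub[s]) for (j in 2:top$n_sub[t]) {
        p <- top$offset[s] + i; q <- top$offset[t] + j
        Psi[p, q] <- Psi[q, p] <- runif(1, -scale, scale)
      }
  }
  bias_parameters(top, b = runif(P, -scale, scale), psi = psi, Psi = Psi)
}

# random point on the per-site simplex
random_lambda <- function(top) {
  lam <- numeric(top$P)
  for (s in seq_along(top$n_sub)) {
    idx <- top$offset[s] + seq_len(top$n_sub[s])
    x <- rexp(length(idx))
    lam[idx] <- x / sum(x)
  }
  lam
}

# hand-built lambda trajectory (for estimator tests that need exact frames)
fake_trajectory <- function(lam_mat, top, temperature = 298) {
  structure(list(lambda = lam_mat, theta = NULL,
                 step = seq_len(nrow(lam_mat)) * 10L,
                 topology = top,
                 settings = sampler_settings(n_steps = nrow(lam_mat) * 10L,
                                             temperature = temperature),
                 bias = zero_bias(top), replica = 1L),
            class = "lambda_trajectory")
}

# hand-built endstate series over a topology's labels
fake_series <- function(labels, top, lambda_c = 0.99) {
  structure(list(label = labels, step = seq_along(labels) * 10L,
                 frame_time = 0.1, lambda_c = lambda_c, topology = top),
            class = "endstate_series")
}

# hand-built flat-or-shaped profile on top of the parametrisation baseline,
# so that update_bias sees exactly the prescribed unbiased profile shape
fake_profile <- function(top, shape_fn, bins = 25L, temperature = 298) {
  st <- sampler_settings(temperature = temperature)
  edges <- seq(0, 1, length.out = bins + 1L)
  centers <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  kT <- 0.0019872041 * temperature
  base <- matrix(0, bins, top$P)
  for (s in seq_along(top$n_sub)) {
    F0 <- msldyn:::measure_baseline(top$n_sub[s], bins, st$steepness,
                                    st$theta_restraint, kT)
    for (i in seq_len(top$n_sub[s])) base[, top$offset[s] + i] <- F0
  }
  value <- base + vapply(seq_len(top$P), function(p) shape_fn(centers, p),
                         numeric(bins))
  structure(list(edges = edges, centers = centers, value = value,
                 se = matrix(0.01, bins, top$P),
                 occupied = matrix(TRUE, bins, top$P),
                 degenerate = rep(FALSE, top$P),
                 temperature = temperature, settings = st,
                 coord = msldyn:::coord_names(top), topology = top),
            class = "fe_profile")
}

# reduced flattening schedule used by fast unit tests
sched_small <- function() alf_schedule(10, 1000, 5, 5000, c(2e4, 5e4))

top_2sub <- function(labels = c("C", "A"))
  alch_topology(setNames(list(labels), "s1"))
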