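# Composite potential, softmax implicit constraints, analytic gradients.

test_that("softmax transform reproduces closed-form values and the simplex", {
  top <- top_2sub()
  expect_equal(theta_to_lambda(c(0, 0), top), c(0.5, 0.5))

  # scalar oracle: lambda_1 = e^(c*1) / (e^(c*1) + e^0) for theta = (1, 0)
  lam <- theta_to_lambda(c(1, 0), top, steepness = 5.5)
  expect_equal(lam[1], exp(5.5) / (exp(5.5) + 1), tolerance = 1e-14)

  set.seed(1)
  top3 <- alch_topology(list(a = c("A", "C", "G"), b = c("A", "T")))
  for (k in 1:50) {
    lam <- theta_to_lambda(rnorm(top3$P, sd = 3), top3)
    expect_true(all(lam >= 0 & lam <= 1))
    expect_equal(sum(lam[1:3]), 1, tolerance = 1e-12)
    expect_equal(sum(lam[4:5]), 1, tolerance = 1e-12)
  }
})

test_that("invalid theta and steepness are rejected", {
  top <- top_2sub()
  expect_error(theta_to_lambda(c(NA, 0), top), "non-finite")
  expect_error(theta_to_lambda(c(Inf, 0), top), "non-finite")
  expect_error(theta_to_lambda(c(0, 0), top, steepness = 0), "steepness")
  expect_error(theta_to_lambda(c(0, 0, 0), top), "length")
})

test_that("potential energy reduces correctly at vertices and under symmetry", {
  set.seed(2)
  top <- alch_topology(list(a = c("G", "A"), b = c("C", "A")))
  H <- random_hamiltonian(top)
  b0 <- zero_bias(top)
  # vertex selecting substituent 2 at site 1, substituent 1 at site 2
  lam <- c(0, 1, 1, 0)
  expect_equal(potential_energy(lam, H, b0),
               H$env + H$h[2] + H$h[3] + H$J[2, 3], tolerance = 1e-12)

  # one site, equal h: sum lambda = 1 collapses the sum to env + h
  top1 <- top_2sub()
  H1 <- model_hamiltonian(top1, env = 0.7, h = c(1.3, 1.3))
  for (k in 1:10) {
    lam1 <- random_lambda(top1)
    expect_equal(potential_energy(lam1, H1, zero_bias(top1)), 0.7 + 1.3,
                 tolerance = 1e-12)
  }
})

test_that("potential energy matches the brute-force loop oracle", {
  set.seed(3)
  for (k in 1:100) {
    top <- random_topology()
    H <- random_hamiltonian(top)
    bias <- random_bias(top)
    lam <- random_lambda(top)
    expect_equal(potential_energy(lam, H, bias),
                 brute_potential(lam, H, bias), tolerance = 1e-10)
  }
})

test_that("energy is invariant under substituent relabelling", {
  set.seed(4)
  for (k in 1:20) {
    top <- alch_topology(list(a = c("A", "C", "G"), b = c("A", "T")))
    H <- random_hamiltonian(top)
    bias <- random_bias(top)
    lam <- random_lambda(top)
    v0 <- potential_energy(lam, H, bias)
    # permute the substituents of site 1 and all parameters accordingly
    perm <- c(sample(1:3), 4:5)
    top2 <- alch_topology(list(a = top$sub_labels[[1]][perm[1:3]],
                               b = top$sub_labels[[2]]))
    H2 <- model_hamiltonian(top2, env = H$env, h = H$h[perm],
                            J = H$J[perm, perm])
    bias2 <- bias_parameters(top2, b = bias$b[perm],
                             psi = bias$psi[perm, perm])
    expect_equal(potential_energy(lam[perm], H2, bias2), v0,
                 tolerance = 1e-12)
  }
})

test_that("analytic theta-gradient is zero by symmetry and matches FD", {
  top <- top_2sub()
  Hsym <- model_hamiltonian(top, h = c(1, 1))
  g <- potential_gradient_theta(c(0, 0), Hsym)
  expect_equal(g, c(0, 0), tolerance = 1e-14)

  set.seed(5)
  for (k in 1:100) {
    top <- random_topology()
    H <- random_hamiltonian(top)
    bias <- random_bias(top)
    th <- rnorm(top$P)
    g <- potential_gradient_theta(th, H, bias)
    fd <- vapply(seq_len(top$P), function(i) {
      e <- numeric(top$P); e[i] <- 1e-5
      (potential_energy(theta_to_lambda(th + e, top), H, bias) -
         potential_energy(theta_to_lambda(th - e, top), H, bias)) / 2e-5
    }, numeric(1))
    expect_lt(max(abs(g - fd)), 1e-6)
  }
})

test_that("single-site gradient matches the closed-form derivative", {
  top <- top_2sub()
  Delta <- 1.7
  H <- model_hamiltonian(top, h = c(0, Delta))
  th <- c(0.3, -0.2)
  lam <- theta_to_lambda(th, top)
  # V = Delta * lambda_2, dV/dtheta_2 = Delta * c * lambda_2 (1 - lambda_2)
  g <- potential_gradient_theta(th, H)
  expect_equal(g[2], Delta * 5.5 * lam[2] * (1 - lam[2]), tolerance = 1e-12)
  expect_equal(g[1], -g[2], tolerance = 1e-12)
})

test_that("Hamiltonian validation enforces symmetry and intra-site zeros", {
  top <- alch_topology(list(a = c("G", "A"), b = c("C", "A")))
  J_bad <- matrix(0, 4, 4); J_bad[1, 3] <- 1          # asymmetric
  expect_error(model_hamiltonian(top, J = J_bad), "symmetric")
  J_intra <- matrix(0, 4, 4); J_intra[1, 2] <- J_intra[2, 1] <- 1
  expect_error(model_hamiltonian(top, J = J_intra), "within site")
})
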