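# Langevin sampler: integrator limits, determinism, constraints, file I/O.

test_that("free-particle limit advances position by velocity times timestep", {
  st <- sampler_settings(friction = 0, timestep = 0.02)
  s <- step_langevin(theta = 1, velocity = 3, force = 0,
                     force_fn = function(th) 0, st)
  expect_equal(s$theta, 1 + 3 * 0.02, tolerance = 1e-15)
  expect_equal(s$velocity, 3)
})

test_that("identical seeds give bit-identical trajectories, distinct seeds differ", {
  top <- top_2sub()
  H <- model_hamiltonian(top, h = c(0, 1))
  st <- sampler_settings(n_steps = 2000, seed = 7)
  tr1 <- run_trajectory(top, H, NULL, st)
  tr2 <- run_trajectory(top, H, NULL, st)
  expect_identical(tr1$lambda, tr2$lambda)
  expect_identical(tr1$final_theta, tr2$final_theta)
  st$seed <- 8L
  tr3 <- run_trajectory(top, H, NULL, st)
  expect_false(identical(tr1$lambda, tr3$lambda))
})

test_that("frame counts follow n_steps / save_interval exactly", {
  top <- top_2sub()
  H <- model_hamiltonian(top)
  tr <- run_trajectory(top, H, NULL,
                       sampler_settings(n_steps = 1, save_interval = 1, seed = 1))
  expect_identical(nrow(tr$lambda), 1L)
  tr <- run_trajectory(top, H, NULL,
                       sampler_settings(n_steps = 1000, save_interval = 10, seed = 1))
  expect_identical(nrow(tr$lambda), 100L)
  expect_true(all(diff(tr$step) > 0))
})

test_that("every saved frame satisfies the simplex constraints", {
  set.seed(20)
  for (k in 1:5) {
    top <- random_topology()
    H <- random_hamiltonian(top)
    tr <- run_trajectory(top, H, random_bias(top),
                         sampler_settings(n_steps = 5000, seed = 20 + k))
    for (s in seq_along(top$n_sub)) {
      idx <- top$offset[s] + seq_len(top$n_sub[s])
      sums <- rowSums(tr$lambda[, idx, drop = FALSE])
      expect_lt(max(abs(sums - 1)), 1e-10)
    }
    expect_true(all(tr$lambda >= 0 & tr$lambda <= 1))
  }
})

test_that("harmonic theta sampling satisfies equipartition", {
  st <- sampler_settings(friction = 5, timestep = 0.01, temperature = 298)
  k <- 2
  kT <- kB_kcal() * 298
  set.seed(21)
  th <- 0; v <- 0; f <- -k * th
  n <- 4e4
  vals <- numeric(n)
  for (i in seq_len(n)) {
    s <- step_langevin(th, v, f, function(x) -k * x, st)
    th <- s$theta; v <- s$velocity; f <- s$force
    vals[i] <- th
  }
  vals <- vals[-(1:4000)]
  ac <- acf(vals, lag.max = 2000, plot = FALSE)$acf
  tau <- 1 + 2 * sum(ac[ac > 0.05])
  se <- var(vals) * sqrt(2 * tau / length(vals))
  expect_lt(abs(var(vals) - kT / k), 3 * se)
})

test_that("symmetric two-state system splits endstate occupancy evenly", {
  top <- top_2sub()
  H <- model_hamiltonian(top, h = c(0, 0))
  tr <- run_trajectory(top, H, NULL, sampler_settings(n_steps = 2e5, seed = 22))
  lab <- assign_endstates(tr)$label
  n1 <- sum(lab == "C", na.rm = TRUE); n2 <- sum(lab == "A", na.rm = TRUE)
  # 3-sigma band over ~n_indep independent visits; random dwell lengths
  # roughly double the per-visit variance relative to a plain binomial
  n_indep <- count_transitions(assign_endstates(tr))$total + 1
  expect_gt(n1 + n2, 0)
  expect_lt(abs(n1 - n2) / (n1 + n2), 3 / sqrt(n_indep))
})

test_that("a flat linear bias cancels an energy gap in the populations", {
  top <- top_2sub()
  H <- model_hamiltonian(top, h = c(0, 1))
  bias <- bias_parameters(top, b = c(0, 1))  # -b*lambda cancels the gap
  tr <- run_trajectory(top, H, bias, sampler_settings(n_steps = 2e5, seed = 23))
  lab <- assign_endstates(tr)$label
  n1 <- sum(lab == "C", na.rm = TRUE); n2 <- sum(lab == "A", na.rm = TRUE)
  n_indep <- count_transitions(assign_endstates(tr))$total + 1
  expect_lt(abs(n1 - n2) / (n1 + n2), 3 / sqrt(n_indep))
  # and the bias-corrected estimator recovers the gap
  est <- free_energy_from_populations(assign_endstates(tr), bias,
                                      n_boot = 50, seed = 23)
  expect_equal(est$dG[2], 1, tolerance = 3 * est$se[2] + 0.15)
})

test_that("trajectory files round-trip bit-exactly in decimal", {
  top <- top_2sub()
  H <- model_hamiltonian(top, h = c(0, 0.5))
  tr <- run_trajectory(top, H, NULL, sampler_settings(n_steps = 500, seed = 30))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, p1)
  back <- read_trajectory(p1, top, tr$settings)
  expect_identical(back$step, as.integer(tr$step))
  write_trajectory(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(unname(back$lambda), unname(signif(tr$lambda, 10)),
               tolerance = 1e-12)
})

test_that("aborting on non-finite states names the step", {
  top <- top_2sub()
  H <- model_hamiltonian(top, h = c(0, 1))
  st <- sampler_settings(n_steps = 1000, timestep = 50, seed = 3)  # unstable
  expect_error(run_trajectory(top, H, NULL, st), "step")
})
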