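# Free-energy profiles, bias updates, and the flattening loop.

test_that("uniform frames give a flat profile and constant frames zero SE", {
  top <- top_2sub()
  bins <- 25L
  centers <- (seq_len(bins) - 0.5) / bins
  lam <- cbind(centers, 1 - centers)        # one frame per bin, both coords
  prof <- estimate_profile(fake_trajectory(lam, top), zero_bias(top),
                           bins = bins, n_boot = 20, seed = 1)
  expect_true(all(prof$occupied))
  expect_equal(max(abs(prof$value)), 0, tolerance = 1e-12)

  lam_const <- matrix(rep(c(0.5, 0.5), each = 50), ncol = 2)
  prof2 <- estimate_profile(fake_trajectory(lam_const, top), zero_bias(top),
                            bins = bins, n_boot = 20, seed = 1)
  expect_true(all(prof2$degenerate))
  occ <- which(prof2$occupied[, 1])
  expect_identical(prof2$se[occ, 1], 0)
})

test_that("two-bin occupancy ratio gives the closed-form kT log ratio", {
  top <- top_2sub()
  lam <- rbind(matrix(rep(c(0.01, 0.99), 100), ncol = 2, byrow = TRUE),
               matrix(rep(c(0.99, 0.01), 10), ncol = 2, byrow = TRUE))
  prof <- estimate_profile(fake_trajectory(lam, top), zero_bias(top),
                           bins = 25, n_boot = 10, seed = 2)
  # coordinate 1: 100 frames near 0, 10 near 1 -> F(1) - F(0) = kT ln 10
  expect_equal(prof$value[25, 1] - prof$value[1, 1],
               kT298 * log(10), tolerance = 1e-10)
  expect_equal(prof$value[1, 2] - prof$value[25, 2],
               kT298 * log(10), tolerance = 1e-10)
})

test_that("bias update follows the damped endpoint rule with cap", {
  top <- top_2sub()
  b0 <- zero_bias(top)

  flat <- fake_profile(top, function(ctr, p) rep(0, length(ctr)))
  expect_identical(update_bias(flat, b0, damping = 1)$b, c(0, 0))

  # antisymmetric step: coordinate 2 disfavoured by 2 kcal/mol
  step2 <- fake_profile(top, function(ctr, p)
    (if (p == 2) 2 else -2) * (ctr >= 0.5))
  up <- update_bias(step2, b0, damping = 1, cap = 5)
  expect_equal(up$b[2], 2, tolerance = 1e-10)
  expect_equal(up$b[1], -2, tolerance = 1e-10)
  # damping scales the increment
  up_d <- update_bias(step2, b0, damping = 0.5, cap = 5)
  expect_equal(up_d$b[2], 1, tolerance = 1e-10)

  # cap clips a +10 endpoint difference to +3
  step10 <- fake_profile(top, function(ctr, p)
    (if (p == 2) 10 else -10) * (ctr >= 0.5))
  up_cap <- update_bias(step10, b0, damping = 1, cap = 3)
  expect_equal(up_cap$b[2], 3, tolerance = 1e-10)

  # input object is never modified
  expect_identical(b0$b, c(0, 0))
})

test_that("a profile with both endpoints empty returns the bias unchanged", {
  top <- top_2sub()
  prof <- fake_profile(top, function(ctr, p) rep(0, length(ctr)))
  prof$occupied[] <- FALSE
  prof$occupied[12:14, ] <- TRUE     # only mid-simplex bins seen
  b1 <- bias_parameters(top, b = c(0.4, -0.4))
  out <- update_bias(prof, b1)
  expect_true(attr(out, "no_update"))
  expect_identical(out$b, b1$b)
})

test_that("flattening a symmetric system leaves the linear bias at zero", {
  top <- top_2sub()
  H <- model_hamiltonian(top, h = c(0, 0))
  alf <- alf_flatten(top, H, sched_small(), sampler_settings(), seed = 31)
  prof <- tail(alf$profiles, 1)[[1]]
  seD <- sqrt(prof$se[1, 2]^2 + prof$se[nrow(prof$se), 2]^2)
  expect_lt(abs(alf$bias$b[2] - alf$bias$b[1]) / 2, 3 * seD + 0.05)
  expect_s3_class(alf, "alf_result")
  expect_true(all(c("phase", "imbalance") %in% names(alf$log)))
})

test_that("flattening is reproducible from the seed", {
  top <- top_2sub()
  H <- model_hamiltonian(top, h = c(0, 1))
  sched <- alf_schedule(5, 500, 2, 2000, 5000)
  a1 <- alf_flatten(top, H, sched, sampler_settings(), seed = 5)
  a2 <- alf_flatten(top, H, sched, sampler_settings(), seed = 5)
  expect_identical(a1$bias$b, a2$bias$b)
  expect_identical(a1$log$imbalance, a2$log$imbalance)
})

test_that("restarting from a converged bias leaves coefficients unchanged within noise", {
  top <- top_2sub()
  H <- model_hamiltonian(top, h = c(0, 1.5))
  st <- sampler_settings()
  a1 <- alf_flatten(top, H, sched_small(), st, seed = 32)
  # rerun the production tail starting from the converged bias
  s2 <- st; s2$n_steps <- 5e4; s2$seed <- 33L
  tr <- run_trajectory(top, H, a1$bias, s2)
  prof <- estimate_profile(tr, a1$bias, seed = 33)
  b2 <- update_bias(prof, a1$bias)
  expect_lt(max(abs(b2$b - a1$bias$b)), 0.35)
})

test_that("block-bootstrap intervals have sane coverage on a known system", {
  # pre-flattened symmetric construction: true dG equals the quadrature value
  top <- top_2sub()
  H <- model_hamiltonian(top, h = c(0, 1))
  bias <- bias_parameters(top, b = c(0, 1))   # exact cancelling bias
  truth <- quadrature_dg(H, bias, grid = 301)$dG[2]
  st <- sampler_settings(n_steps = 2e4)
  cover <- logical(200)
  for (k in seq_len(200)) {
    st$seed <- 5000L + k
    tr <- run_trajectory(top, H, bias, st)
    est <- free_energy_from_populations(assign_endstates(tr), bias,
                                        n_boot = 40, seed = k)
    cover[k] <- is.finite(est$dG[2]) &&
      abs(est$dG[2] - truth) <= est$se[2]
  }
  expect_gte(mean(cover), 0.55)
  expect_lte(mean(cover), 0.80)
})
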