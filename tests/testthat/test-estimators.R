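# Endstate binning, transition counting, population free energies, cycles.

test_that("frames are assigned by the lambda_c rule", {
  top <- top_2sub()
  lam <- rbind(c(1, 0),            # exact vertex
               c(0.995, 0.005),    # above the 0.99 cutoff
               c(0.95, 0.05),      # below -> unassigned
               c(0.005, 0.995))
  se <- assign_endstates(fake_trajectory(lam, top), lambda_c = 0.99)
  expect_identical(se$label, c("C", "C", NA, "A"))
  expect_error(assign_endstates(fake_trajectory(lam, top), lambda_c = 0.4))
})

test_that("raising lambda_c never increases the number of assigned frames", {
  set.seed(40)
  top <- alch_topology(list(a = c("G", "A"), b = c("C", "A")))
  H <- random_hamiltonian(top, scale = 1)
  tr <- run_trajectory(top, H, NULL, sampler_settings(n_steps = 2e4, seed = 40))
  cuts <- c(0.6, 0.8, 0.9, 0.95, 0.99, 0.995)
  n_assigned <- vapply(cuts, function(lc)
    sum(!is.na(assign_endstates(tr, lc)$label)), numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("transition counting collapses gaps and counts entries", {
  top <- top_2sub(c("A", "B"))
  expect_identical(count_transitions(fake_series(c("A", "A", "B", "B"), top))$total, 1L)
  expect_identical(count_transitions(fake_series(c("A", NA, "A"), top))$total, 0L)
  ct <- count_transitions(fake_series(c("A", "B", "A", "B"), top))
  expect_identical(ct$total, 3L)
  expect_identical(unname(ct$counts["A"]), 1L)
  expect_identical(unname(ct$counts["B"]), 2L)
  expect_identical(count_transitions(fake_series(rep(NA_character_, 5), top))$total, 0L)
  # rates are counts per model time
  expect_equal(unname(ct$rates["B"]), 2 / (4 * 0.1), tolerance = 1e-12)
})

test_that("population free energies match the closed-form kT log ratio", {
  top <- top_2sub(c("A", "B"))
  series <- fake_series(c(rep("A", 100), rep("B", 10)), top)
  est <- free_energy_from_populations(series, zero_bias(top),
                                      n_boot = 30, seed = 41)
  expect_equal(est$dG[est$sequence == "B"],
               0.0019872041 * 298 * log(10), tolerance = 1e-12)
  expect_identical(est$dG[est$sequence == "A"], 0)
  expect_identical(est$se[est$sequence == "A"], 0)
})

test_that("equal counts give zero dG and unobserved sequences go unavailable", {
  top <- alch_topology(list(s1 = c("A", "B", "C")))
  series <- fake_series(c(rep("A", 50), rep("B", 50)), top)
  est <- free_energy_from_populations(series, zero_bias(top),
                                      n_boot = 20, seed = 42)
  expect_identical(est$dG[est$sequence == "B"], 0)
  expect_true(is.na(est$dG[est$sequence == "C"]))
  expect_false(est$available[est$sequence == "C"])
  expect_true(all(is.finite(est$dG[est$available])))

  expect_error(
    free_energy_from_populations(fake_series(rep("B", 10), top),
                                 zero_bias(top), n_boot = 5, reference = "A"),
    "never observed")
  expect_error(
    free_energy_from_populations(series, zero_bias(top), reference = "ZZZ"),
    "unknown reference")
})

test_that("the vertex bias correction is applied and switchable", {
  top <- top_2sub(c("A", "B"))
  bias <- bias_parameters(top, b = c(0, 2))
  series <- fake_series(c(rep("A", 40), rep("B", 40)), top)
  est_on <- free_energy_from_populations(series, bias, n_boot = 5, seed = 1)
  est_off <- free_energy_from_populations(series, bias, n_boot = 5, seed = 1,
                                          bias_correction = FALSE)
  # equal populations: corrected dG recovers the cancelled gap of 2
  expect_equal(est_on$dG[2], 2, tolerance = 1e-12)
  expect_identical(est_off$dG[2], 0)
})

test_that("dG antisymmetry and additivity hold exactly on a shared table", {
  top <- alch_topology(list(s1 = c("A", "B", "C")))
  series <- fake_series(c(rep("A", 60), rep("B", 25), rep("C", 11)), top)
  b0 <- zero_bias(top)
  eA <- free_energy_from_populations(series, b0, n_boot = 5, seed = 2,
                                     reference = "A")
  eB <- free_energy_from_populations(series, b0, n_boot = 5, seed = 2,
                                     reference = "B")
  dg <- function(est, s) est$dG[est$sequence == s]
  expect_equal(dg(eA, "B"), -dg(eB, "A"), tolerance = 1e-12)
  expect_equal(dg(eA, "C"), dg(eA, "B") + dg(eB, "C"), tolerance = 1e-12)
})

test_that("thermodynamic cycle assembly subtracts legs and combines errors", {
  top <- top_2sub(c("A", "B"))
  series <- fake_series(c(rep("A", 30), rep("B", 20)), top)
  est <- free_energy_from_populations(series, zero_bias(top),
                                      n_boot = 20, seed = 43)
  # identical legs close the cycle exactly
  dd0 <- ddg_cycle(est, est)
  expect_identical(dd0$ddG, c(0, 0))

  eb <- est; eu <- est
  eb$dG <- c(0, 1.2); eb$se <- c(0, 0.3)
  eu$dG <- c(0, 0.2); eu$se <- c(0, 0.4)
  dd <- ddg_cycle(eb, eu)
  expect_equal(dd$ddG[2], 1.0, tolerance = 1e-12)
  expect_equal(dd$se[2], 0.5, tolerance = 1e-12)

  # unavailable legs propagate
  eu$available[2] <- FALSE
  dd2 <- ddg_cycle(eb, eu)
  expect_true(is.na(dd2$ddG[2]))

  # mismatched sequence sets are rejected
  top3 <- alch_topology(list(s1 = c("A", "B", "C")))
  s3 <- fake_series(c(rep("A", 5), rep("B", 5), rep("C", 5)), top3)
  e3 <- free_energy_from_populations(s3, zero_bias(top3), n_boot = 5, seed = 3)
  expect_error(ddg_cycle(est, e3), "different sequence sets")
})

test_that("the multi-mutant report ranks constructed orderings", {
  top <- alch_topology(list(a = c("G", "A"), b = c("C", "A")))
  lab <- top$vertices$label
  counts <- c(1000, 300, 100, 30)          # decreasing population = increasing dG
  series <- fake_series(rep(lab, counts), top)
  est <- free_energy_from_populations(series, zero_bias(top),
                                      n_boot = 10, seed = 44)
  flat <- est; flat$dG <- rep(0, 4); flat$se <- rep(0, 4)
  rep_tab <- multi_mutant_report(ddg_cycle(est, flat), top)
  expect_identical(nrow(rep_tab), 4L)
  expect_identical(rep_tab$sequence, lab)
  expect_true(all(c("transitions_bound", "n_unbound") %in% names(rep_tab)))
})
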