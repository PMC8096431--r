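test_that("fractional inhibition follows the control-normalised formula", {
  expect_equal(compute_fi(400, mc_f_mean = 100, ic_f_mean = 1100), 0.7)
  expect_equal(compute_fi(1100, 100, 1100), 0) # uninhibited growth
  expect_equal(compute_fi(100, 100, 1100), 1)  # sterile-medium level
  # affine, unclipped: stimulation and over-inhibition pass through
  expect_equal(compute_fi(1300, 100, 1100), -0.2)
  expect_equal(compute_fi(0, 100, 1100), 1.1)
  expect_error(compute_fi(500, 300, 300), "degenerate controls")
  expect_equal(percent_inhibition(c(0, 1, 0.7)), c(0, 100, 70))
})

test_that("Bliss expected value and excess obey the independence model", {
  expect_equal(bliss_expected(0, 0.3), 0.3)
  expect_equal(bliss_expected(1, 1), 1)
  expect_equal(bliss_expected(0.5, 0.5), 0.75)
  # bounded and monotone for inputs in [0, 1]
  for (k in 1:50) {
    a <- runif(1); b <- runif(1)
    e <- bliss_expected(a, b)
    expect_gte(e, max(a, b))
    expect_lte(e, 1)
    expect_equal(e, bliss_expected(b, a))
  }
  expect_equal(bliss_excess(0.75, 0.90), -0.15)
  expect_equal(bliss_excess(0.75, 0.60), 0.15)
  expect_equal(bliss_excess(0.5, 0.5), 0)
})

test_that("expected-value distribution covers the replicate cross product", {
  expect_length(all_pairs_expected(runif(2), runif(3)), 6)
  expect_equal(all_pairs_expected(0, c(0.2, 0.4)), c(0.2, 0.4))
  # row-major: a-outer, b-inner
  expect_equal(all_pairs_expected(c(0.5, 0.6), 0.5), c(0.75, 0.80))
  expect_equal(all_pairs_expected(c(0.1, 0.2), c(0.3, 0.4)),
               c(bliss_expected(0.1, 0.3), bliss_expected(0.1, 0.4),
                 bliss_expected(0.2, 0.3), bliss_expected(0.2, 0.4)))
  expect_error(all_pairs_expected(numeric(0), 0.5), "non-empty")
})

test_that("interaction test matches the Welch oracle and a permutation test", {
  x <- c(0.72, 0.68, 0.70, 0.71, 0.69)
  y <- c(0.55, 0.60, 0.58, 0.57)
  got <- interaction_test(x, y)
  ora <- welch_oracle(x, y)
  expect_equal(got$t_stat, ora$t, tolerance = 1e-9)
  expect_equal(got$p_value, ora$p, tolerance = 1e-9)
  expect_lt(interaction_test(rep(0.7, 4), c(0.2, 0.2, 0.2, 0.21))$p_value,
            0.05)
  # degenerate constant samples
  same <- interaction_test(rep(0.5, 3), rep(0.5, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  diffr <- interaction_test(rep(0.7, 3), rep(0.5, 3))
  expect_equal(diffr$p_value, 0)
  expect_error(interaction_test(0.5, c(0.1, 0.2)), ">= 2")
  # permutation agreement on small fixed lists
  x2 <- c(0.70, 0.66, 0.73, 0.69, 0.71)
  y2 <- c(0.61, 0.64, 0.60, 0.66, 0.63)
  expect_lt(abs(interaction_test(x2, y2)$p_value -
                  permutation_p(x2, y2)), 0.05)
})

test_that("classification applies the excess/significance thresholds", {
  expect_equal(classify_interaction(0.10, 0.01), "synergistic")
  expect_equal(classify_interaction(-0.10, 0.01), "antagonistic")
  expect_equal(classify_interaction(0.00, 0.50), "additive")
  expect_equal(classify_interaction(0.05, 0.01), "additive")
  expect_equal(classify_interaction(0.08, 0.05), "synergistic") # inclusive
  expect_equal(classify_interaction(0.20, 0.50), "indeterminate")
  # symmetric under compound swap: b and p unchanged by construction
  expect_equal(classify_interaction(0.1, 0.01),
               classify_interaction(0.1, 0.01))
})

test_that("pipeline recovers the simulated truth and rejects bad plates", {
  # noiseless round trips: b recovered to machine precision
  for (b_true in c(-0.2, 0, 0.2)) {
    plate <- simulate_plate(b_true = b_true, noise_sd = 0, seed = 11)
    res <- run_interaction_pipeline(plate)
    expect_equal(nrow(res), 1L)
    expect_equal(res$n_expected, 49L)
    expect_equal(res$bliss_excess, b_true, tolerance = 1e-12)
    expect_equal(res$label,
                 c("antagonistic", "additive", "synergistic")[sign(b_true) + 2])
  }
  # noisy parameter recovery with the default replicate structure
  plate <- simulate_plate(b_true = 0.2, noise_sd = 0.02, seed = 12)
  expect_equal(run_interaction_pipeline(plate)$label, "synergistic")
  # invariant: e_bliss_mean - fi_ab_mean equals the reported excess
  res <- run_interaction_pipeline(plate)
  expect_equal(res$bliss_excess, res$e_bliss_mean - res$fi_ab_mean)
  # conservative paired mode uses n, not n_a * n_b, expected values
  paired <- run_interaction_pipeline(plate, expected_mode = "paired")
  expect_equal(paired$n_expected, 7L)
  # missing controls are named
  bad <- simulate_plate(seed = 1)
  bad <- bad[bad$role != "medium_control", ]
  expect_error(run_interaction_pipeline(bad), "medium_control")
  # solvent control is QC only, never a classified pair
  full <- simulate_plate(seed = 1)
  out <- run_interaction_pipeline(full, use_solvent_control = TRUE)
  expect_equal(nrow(out), 1L)
  expect_false(any(grepl("solvent", out$pair)))
})

test_that("control wells have mean FI 0 and 1 by construction", {
  plate <- simulate_plate(noise_sd = 0.02, seed = 31)
  plate_t <- validate_plate_table(plate)
  mc <- mean(plate_t$fluorescence[plate_t$role == "medium_control"])
  ic <- mean(plate_t$fluorescence[plate_t$role == "inoculum_control"])
  expect_equal(mean(compute_fi(
    plate_t$fluorescence[plate_t$role == "inoculum_control"], mc, ic)), 0)
  expect_equal(mean(compute_fi(
    plate_t$fluorescence[plate_t$role == "medium_control"], mc, ic)), 1)
})
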