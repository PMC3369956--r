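test_that("make_truth assigns classes, counts and rates as requested", {
  t0 <- make_truth(10, 0, 0, effect_size = 0.3, seed = 1)
  expect_equal(t0$true_call, rep("neutral", 10))
  expect_equal(t0$growth_rate_treatment, rep(1, 10))
  expect_equal(t0$growth_rate_control, rep(1, 10))

  t1 <- make_truth(100, 0.05, 0.05, effect_size = 0.3, seed = 7)
  expect_equal(as.vector(table(t1$true_call)[c("sensitive", "resistant", "neutral")]),
               c(5L, 5L, 90L))
  expect_false(anyDuplicated(t1$strain_id) > 0)
  # call labels consistent with the rate difference, all rates non-negative
  diff <- t1$growth_rate_treatment - t1$growth_rate_control
  expect_true(all(diff[t1$true_call == "sensitive"] < 0))
  expect_true(all(diff[t1$true_call == "resistant"] > 0))
  expect_true(all(diff[t1$true_call == "neutral"] == 0))
  expect_true(all(t1$growth_rate_treatment >= 0))

  expect_identical(t1, make_truth(100, 0.05, 0.05, effect_size = 0.3, seed = 7))
  expect_error(make_truth(10, -0.1, 0), "fraction")
  expect_error(make_truth(10, 0.6, 0.6), "exceed 1")
  expect_error(make_truth(10, 0, 0, effect_size = -1), "positive")
})

test_that("pool growth matches the closed-form composition and doubles per generation", {
  # two strains, w = (1, 0.5): slow-strain fraction after 4 generations is
  # 2^2 / (2^4 + 2^2) = 0.2; cross-check by stepwise brute-force propagation
  tr <- make_truth(2, seed = 1)
  tr$growth_rate_treatment <- c(1, 0.5)
  traj <- simulate_pool_growth(tr, "treatment", 4, 100)
  frac <- traj$abundance[, 5] / sum(traj$abundance[, 5])
  expect_equal(unname(frac[2]), 0.2, tolerance = 1e-12)

  a <- c(100, 100)
  for (g in 1:4) a <- a * 2^c(1, 0.5)
  expect_equal(unname(traj$abundance[, 5]), a, tolerance = 1e-9)

  # fractions sum to 1 everywhere
  totals <- colSums(traj$abundance)
  fr <- sweep(traj$abundance, 2, totals, "/")
  expect_true(all(abs(colSums(fr) - 1) < 1e-9))
})

test_that("neutral pools keep fractions flat and zero-growth strains constant", {
  tr <- make_truth(8, seed = 3)
  traj <- simulate_pool_growth(tr, "treatment", 15, 50)
  frac <- traj$abundance[, 16] / sum(traj$abundance[, 16])
  expect_equal(unname(frac), rep(1 / 8, 8), tolerance = 1e-12)
  # a neutral pool's total biomass doubles every pool generation
  expect_equal(colSums(traj$abundance), 400 * 2^(0:15), tolerance = 1e-9,
               ignore_attr = TRUE)

  tr$growth_rate_treatment[1] <- 0
  traj0 <- simulate_pool_growth(tr, "treatment", 6, 50)
  expect_equal(unname(traj0$abundance[1, ]), rep(50, 7), tolerance = 1e-9)
})

test_that("bottlenecks resample at the stated generation and validate their index", {
  tr <- make_truth(6, seed = 4)
  bt <- list(size = 600, at = 3)
  expected <- simulate_pool_growth(tr, "control", 5, 1000, bottleneck = bt)
  expect_equal(sum(expected$abundance[, 4]), 600, tolerance = 1e-9)
  expect_equal(sum(expected$abundance[, 6]), 600 * 4, tolerance = 1e-9)

  sampled <- simulate_pool_growth(tr, "control", 5, 1000, bottleneck = bt,
                                  mode = "sampled", seed = 9)
  expect_equal(sum(sampled$abundance[, 4]), 600)
  expect_identical(sampled$abundance,
                   simulate_pool_growth(tr, "control", 5, 1000, bottleneck = bt,
                                        mode = "sampled", seed = 9)$abundance)
  expect_error(simulate_pool_growth(tr, "control", 5, 1000,
                                    bottleneck = list(size = 10, at = 6)),
               "1..generations")
})

test_that("signal model is exact log2 when noiseless and affinity cancels in ratios", {
  ab <- matrix(1024, nrow = 12, ncol = 2,
               dimnames = list(sprintf("S%02d", 1:12), NULL))
  sm <- abundance_to_signals(ab, ab, affinity_sd = 0, noise_sd = 0,
                             pseudocount = 0, seed = 1)
  expect_equal(unname(sm$values), matrix(10, 12, 4))

  # with affinity but no noise, the treatment/control log2 ratio equals the
  # log2 abundance ratio regardless of the per-strain affinity
  tr_ab <- matrix(2^c(3:14), nrow = 12, ncol = 2,
                  dimnames = list(sprintf("S%02d", 1:12), NULL))
  ct_ab <- matrix(2^c(5:16), nrow = 12, ncol = 2,
                  dimnames = list(sprintf("S%02d", 1:12), NULL))
  sm2 <- abundance_to_signals(tr_ab, ct_ab, affinity_sd = 2, noise_sd = 0,
                              pseudocount = 0, seed = 5)
  r <- pair_log_ratios(sm2, build_pairs(sm2, "matched"))
  expect_equal(unname(r[, 1]), rep(-2, 12), tolerance = 1e-12)
  expect_error(abundance_to_signals(ab, ab, noise_sd = -1), ">= 0")
})

test_that("per-strain ratio spread matches the noise model (Monte Carlo)", {
  # difference of two independent N(0, 0.25) noises has SD 0.25 * sqrt(2)
  n_rep <- 2000
  ab <- matrix(1000, nrow = 10, ncol = n_rep,
               dimnames = list(sprintf("S%02d", 1:10), NULL))
  sm <- abundance_to_signals(ab, ab, affinity_sd = 1, noise_sd = 0.25,
                             pseudocount = 0, seed = 8)
  r <- sm$values[, 1:n_rep] - sm$values[, n_rep + 1:n_rep]
  expect_equal(mean(apply(r, 1, sd)), 0.25 * sqrt(2), tolerance = 0.05)
})

test_that("flow mixtures hit the requested composition and boundaries", {
  all_tagged <- simulate_flow_mixture(0, n_events = 500, seed = 1)
  expect_equal(nrow(all_tagged), 500)
  expect_true(all(!attr(all_tagged, "truth")))

  all_mut <- simulate_flow_mixture(1, n_events = 500, seed = 1)
  expect_true(all(attr(all_mut, "truth")))

  ev <- simulate_flow_mixture(0.5, n_events = 20000, seed = 2)
  expect_identical(ev$gfp, simulate_flow_mixture(0.5, 20000, seed = 2)$gfp)
  expect_error(simulate_flow_mixture(0.5, n_events = 0), "positive integer")
  expect_error(simulate_flow_mixture(0.5, tagged_gfp_mean = 2,
                                     untagged_gfp_mean = 2), "distinct")
})

test_that("growth curves sit on the stated grid and integrate like the closed form", {
  gc <- simulate_growth_curve(1.2, rate = 0.4, lag = 2, duration = 24,
                              interval = 15, noise_sd = 0)
  expect_equal(nrow(gc), 97)

  flat <- simulate_growth_curve(1.2, rate = 0, duration = 10, interval = 30,
                                od0 = 0.05, noise_sd = 0)
  expect_equal(flat$od, rep(0.05, nrow(flat)), tolerance = 1e-12)

  # trapezoid AUC of the noiseless curve vs adaptive quadrature of the
  # closed-form logistic; trapezoid error bound ~ (K r^2 / 12) * h^2 * T
  auc <- growth_auc(gc)
  exact <- stats::integrate(logistic_od, 0, 24, carrying_capacity = 1.2,
                            rate = 0.4, lag = 2)$value
  expect_equal(auc, exact, tolerance = 1e-3)
  expect_error(simulate_growth_curve(-1, 0.5), "positive")
})
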