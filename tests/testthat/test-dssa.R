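test_that("pair construction follows the scheme and validates conditions", {
  x <- tiny_signals(n = 12, n_t = 4, n_c = 4)
  expect_equal(nrow(build_pairs(x, "all_cross")), 16)
  expect_equal(nrow(build_pairs(x, "matched")), 4)
  x2 <- tiny_signals(n = 12, n_t = 3, n_c = 4)
  expect_equal(nrow(build_pairs(x2, "matched")), 3)
  p <- build_pairs(x, "all_cross")
  expect_false(anyDuplicated(p$pair_id) > 0)
  expect_error(signal_matrix(matrix(1, 3, 3,
                                    dimnames = list(letters[1:3], NULL)),
                             rep("treatment", 3), 1:3),
               "2 arrays per condition")
})

test_that("pair log ratios are plain signal differences", {
  x <- tiny_signals(n = 15, n_t = 3, n_c = 2, seed = 4)
  pairs <- build_pairs(x, "all_cross")
  r <- pair_log_ratios(x, pairs)
  # brute-force subtraction oracle
  for (j in seq_len(nrow(pairs))) {
    expect_equal(unname(r[, j]),
                 unname(x$values[, pairs$treatment[j]] -
                          x$values[, pairs$control[j]]))
  }

  same <- null_signals(n = 15, n_rep = 2)
  expect_true(all(pair_log_ratios(same, build_pairs(same, "matched")) == 0))

  shifted <- x
  shifted$values[, x$condition == "treatment"] <-
    shifted$values[, x$condition == "treatment"] + 1
  x1 <- signal_matrix(shifted$values, x$condition, x$replicate)
  expect_equal(unname(pair_log_ratios(x1, pairs)), unname(r + 1))
})

test_that("outlier analysis is robust, location-invariant and degenerate-safe", {
  expect_error(outlier_qvalues(rnorm(9)), "at least 10")

  same <- outlier_qvalues(rep(0.7, 30))
  expect_equal(same$p, rep(1, 30))
  expect_equal(same$q, rep(1, 30))

  set.seed(5)
  r <- rnorm(50)
  base <- outlier_qvalues(r)
  shift <- outlier_qvalues(r + 3.7)
  expect_equal(base$p, shift$p)
  expect_equal(base$q, shift$q)
  expect_true(all(base$q >= base$p - 1e-12))

  # one strain at 10 robust SDs attains the pair's minimum q
  r2 <- c(rnorm(99, sd = 0.1), 0)
  r2[100] <- median(r2[1:99]) + 10 * mad(r2[1:99])
  out <- outlier_qvalues(r2)
  expect_equal(which.min(out$q), 100L)
  expect_lte(out$q[100], 0.05)
  # direct evaluation of the stated formula for that strain
  z100 <- (r2[100] - median(r2)) / mad(r2)
  expect_equal(out$p[100], 2 * pnorm(abs(z100), lower.tail = FALSE))
})

test_that("exact binomial consistency p-values match closed cases and enumeration", {
  expect_equal(binomial_consistency_pvalue(4, 4), 0.0625)
  expect_equal(binomial_consistency_pvalue(0, 4), 1)
  expect_equal(binomial_consistency_pvalue(13, 16), 697 / 65536)
  # spot-check the enumeration oracle at a few (k, n); the full n <= 16 sweep
  # lives in the acceptance suite
  for (n in c(5, 9)) {
    for (k in c(0, 2, n)) {
      expect_equal(binomial_consistency_pvalue(k, n), enum_binom_tail(k, n))
    }
  }
  expect_error(binomial_consistency_pvalue(5, 4), "0 <= k <= n")
})

test_that("BH q-values follow the step-up rule and its invariants", {
  expect_equal(bh_qvalues(0.03), 0.03)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(rep(0.2, 6)), rep(0.2, 6))
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(6)
  for (i in 1:5) {
    p <- runif(40)
    q <- bh_qvalues(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p-rank
    # Storey variant never exceeds plain BH
    expect_true(all(bh_qvalues(p, method = "storey") <= q + 1e-12))
  }
})

test_that("DSSA is null-identical, antisymmetric and chip-shift invariant", {
  x0 <- null_signals(n = 25, n_rep = 3)
  res0 <- strain_results(x0)
  expect_equal(res0$fitness_score, rep(0, 25))
  expect_equal(unique(res0$call), "unaffected")

  set.seed(7)
  x <- tiny_signals(n = 40, n_t = 4, n_c = 4, seed = 7)
  x$values[3, x$condition == "treatment"] <- x$values[3, x$condition == "treatment"] - 4
  res <- strain_results(x)
  swapped <- strain_results(swap_conditions(x))
  expect_equal(swapped$fitness_score, -res$fitness_score)
  expect_equal(swapped$k, res$k)
  expect_equal(swapped$q, res$q)
  expect_equal(swapped$call == "sensitive", res$call == "resistant")

  # adding a constant to one array's signals changes no q-values and shifts
  # every fitness score by constant / n_treatment_arrays
  xs <- x
  first_tr <- which(x$condition == "treatment")[1]
  xs$values[, first_tr] <- xs$values[, first_tr] + 2.5
  xs <- signal_matrix(xs$values, x$condition, x$replicate)
  res_s <- strain_results(xs)
  expect_equal(res_s$q, res$q)
  expect_equal(res_s$k, res$k)
  expect_equal(res_s$fitness_score, res$fitness_score + 2.5 / 4)
})

test_that("DSSA recovers a planted sensitive strain and calls its direction", {
  truth <- make_truth(200, frac_sensitive = 0.05, frac_resistant = 0.05,
                      effect_size = 0.4, seed = 12)
  sm <- simulate_experiment(truth, generations = 15, n_replicates = 4,
                            inoculum_per_strain = 1600,
                            bottleneck = list(size = 2e5, at = 8),
                            noise_sd = 0.25, seed = 12)
  res <- strain_results(sm)
  sens <- truth$strain_id[truth$true_call == "sensitive"]
  resst <- truth$strain_id[truth$true_call == "resistant"]
  expect_gte(mean(sens %in% res$strain[res$call == "sensitive"]), 0.8)
  expect_gte(mean(resst %in% res$strain[res$call == "resistant"]), 0.8)
  # sensitive calls must carry negative fitness scores and q below cutoff
  called <- res[res$call == "sensitive", ]
  expect_true(all(called$fitness_score < 0))
  expect_true(all(called$q <= 0.05))
})
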