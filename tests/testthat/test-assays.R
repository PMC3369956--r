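test_that("gating splits well-separated mixtures within binomial error", {
  ev <- simulate_flow_mixture(0.5, n_events = 20000, seed = 21)
  g <- gate_events(ev, threshold = "auto")
  binom_sd <- 100 * sqrt(0.5 * 0.5 / 20000)
  expect_lt(abs(g$percent_untagged - 50), 3 * binom_sd)
  # agreement with the hidden class labels
  expect_equal(g$percent_untagged, 100 * mean(attr(ev, "truth")),
               tolerance = 0.5)

  # explicit threshold boundaries
  expect_equal(gate_events(ev, threshold = min(ev$gfp) - 1)$percent_untagged, 0)
  expect_equal(gate_events(ev, threshold = max(ev$gfp) + 1)$percent_untagged, 100)

  # unimodal distribution under auto -> gating-failure error
  uni <- simulate_flow_mixture(0, n_events = 5000, seed = 3)
  expect_error(gate_events(uni, "auto"), "unimodal")
  expect_error(gate_events(uni[1:50, ], "auto"), "at least 100")
})

test_that("competition ratios reproduce published table rows at table precision", {
  # control and confirmation rows: (low-zinc mean %, replete mean %) -> ratio
  rows <- list(
    tsa1  = c(0.62, 27.89, 0.02),
    icy2  = c(1.21, 55.22, 0.02),
    ire1  = c(3.84, 46.60, 0.08),
    zrg17 = c(16.00, 53.73, 0.3),
    pex6  = c(5.66, 23.13, 0.2),
    atg15 = c(2.82, 40.10, 0.07),
    atg11 = c(44.97, 36.37, 1.2),
    rpl2b = c(39.10, 8.16, 4.8)
  )
  for (nm in names(rows)) {
    r <- rows[[nm]]
    expect_equal(as.numeric(competition_ratio(r[1], r[2])), r[3],
                 info = nm)
  }
  expect_equal(as.numeric(competition_ratio(13.7, 13.7)), 1)
  # scale invariance of the underlying ratio
  expect_equal(attr(competition_ratio(5, 20), "raw"),
               attr(competition_ratio(50, 200), "raw"))
  expect_error(competition_ratio(10, 0), "positive")
})

test_that("prevalence t-test is the pooled two-sided Student test", {
  expect_message(p_same <- prevalence_ttest(c(10, 10, 10), c(10, 10, 10)),
                 "zero variance")
  expect_equal(p_same, 1)
  expect_lt(prevalence_ttest(c(10, 10.01, 9.99), c(20, 20.01, 19.99)), 0.001)

  # groups built so the pooled t statistic is exactly 2.776 at df = 4,
  # the 97.5th percentile of t(4): p should be ~0.05
  d <- 2.776 * sqrt(2 / 3)
  p <- prevalence_ttest(c(-1, 0, 1) + d, c(-1, 0, 1))
  expect_equal(p, 2 * pt(2.776, df = 4, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(p, 0.05, tolerance = 1e-3)
  expect_error(prevalence_ttest(1, c(1, 2)), "at least 2")
})

test_that("competition summary combines gating, ratio and test", {
  lz <- lapply(1:3, function(i) simulate_flow_mixture(0.05, 5000, seed = i))
  rp <- lapply(1:3, function(i) simulate_flow_mixture(0.45, 5000, seed = 10 + i))
  s <- competition_summary(lz, rp, initial_pct = 50)
  expect_equal(s$mean_lowzinc, 5, tolerance = 1.5)
  expect_equal(s$mean_replete, 45, tolerance = 1.5)
  expect_equal(as.numeric(s$ratio), 0.1, tolerance = 0.05)
  expect_lt(s$p_value, 0.001)
})

test_that("growth AUC is trapezoidal, additive, and floors negatives", {
  expect_equal(growth_auc(seq(0, 12, by = 0.5), rep(0.8, 25)), 0.8 * 12)
  expect_equal(growth_auc(0:10, rep(0, 11)), 0)
  expect_equal(growth_auc(0:10, seq(0, 1, by = 0.1)), 5)
  expect_error(growth_auc(3, 1), "2 timepoints")

  # additivity over contiguous segments (exact)
  set.seed(4)
  t_h <- seq(0, 24, by = 0.25)
  od <- cumsum(abs(rnorm(length(t_h), 0.01)))
  cut <- 49
  expect_equal(growth_auc(t_h, od),
               growth_auc(t_h[1:cut], od[1:cut]) +
                 growth_auc(t_h[cut:length(t_h)], od[cut:length(od)]))

  expect_message(a <- growth_auc(0:2, c(-0.1, 0.5, 0.5)), "floored")
  expect_equal(a, growth_auc(0:2, c(0, 0.5, 0.5)))

  # background correction uses the first-timepoint minimum by default
  gc <- data.frame(time_h = c(0, 1, 2), od = c(0.09, 0.5, 1.0))
  corrected <- correct_background(gc)
  expect_equal(corrected$od, c(0, 0.41, 0.91))
})

test_that("generation arithmetic reproduces quoted culture designs and is additive", {
  g8 <- generations_from_od(0.005, 1.2)
  expect_equal(g8$doublings, log2(240))
  expect_equal(g8$generations, 8)
  expect_equal(generations_from_od(0.04, 1.2)$generations, 5)
  expect_equal(generations_from_od(0.7, 0.7)$doublings, 0)

  # additivity over serial intervals (exact)
  expect_equal(generations_from_od(0.005, 0.3)$doublings +
                 generations_from_od(0.3, 1.2)$doublings,
               generations_from_od(0.005, 1.2)$doublings)
  expect_error(generations_from_od(0, 1), "positive")
})

test_that("per-genotype inoculum arithmetic matches the quoted range", {
  expect_equal(cells_per_strain(100, 6e5, 4607), 13000)
  expect_equal(cells_per_strain(100, 7.5e4, 4607), 1600)
  expect_equal(cells_per_strain(1, 4607, 4607), 1)
  expect_error(cells_per_strain(100, 6e5, 0), "positive integer")
})
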