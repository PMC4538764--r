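test_that("power estimates are reproducible and carry binomial Monte Carlo errors", {
  d <- swt_design(allocate_clusters(9, 5), 6, 20)
  m <- continuous_model(0)
  spec <- analysis_spec("normal")
  p1 <- estimate_power(d, m, spec, S = 100, seed = 99)
  p2 <- estimate_power(d, m, spec, S = 100, seed = 99)
  expect_identical(p1[c("power", "mc_se", "n_sims", "n_nonconverged")],
                   p2[c("power", "mc_se", "n_sims", "n_nonconverged")])
  expect_equal(p1$mc_se, sqrt(p1$power * (1 - p1$power) / 100))
  expect_equal(p1$power * 100, round(p1$power * 100))  # a count / S
  expect_error(estimate_power(d, m, spec, S = 50), ">= 100")
})

test_that("a null intervention effect rejects at about the nominal level", {
  d <- swt_design(allocate_clusters(9, 5), 6, 20)
  m0 <- outcome_model("normal", 0.3, 0,
                      variance_components(0.1, worked$sd_y^2, "within"))
  pe <- estimate_power(d, m0, analysis_spec("normal"), S = 300, seed = 12)
  expect_lt(abs(pe$power - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("simulated power matches the analytic value at the zero-ICC worked example", {
  d9 <- swt_design(allocate_clusters(9, 5), 6, 20)
  vc <- variance_components(0, worked$sd_y^2, "within")
  m <- continuous_model(0)
  analytic <- hh_power(d9, vc, worked$theta)
  pe <- estimate_power(d9, m, analysis_spec("normal"), S = 400, seed = 71)
  expect_lt(abs(pe$power - analytic), 3 * pe$mc_se)
})

test_that("the cluster search accepts the first candidate meeting the threshold", {
  m <- continuous_model(0)
  spec <- analysis_spec("normal")
  # degenerate threshold: smallest candidate trivially accepted
  sr0 <- find_min_clusters(m, spec, 6, 20, threshold = 0, S = 100,
                           seed = 1, start = 2)
  expect_equal(sr0$n_clusters, 2)
  sr <- find_min_clusters(m, spec, 6, 20, threshold = 0.8, S = 150,
                          seed = 31, start = 6)
  traj <- sr$trajectory
  expect_equal(sr$n_clusters, max(traj$n_clusters))
  expect_true(all(traj$power[-nrow(traj)] < 0.8))
  expect_gte(traj$power[nrow(traj)], 0.8)
  expect_error(find_min_clusters(m, spec, 6, 20, threshold = 0.99,
                                 S = 100, seed = 3, start = 2,
                                 max_clusters = 4), "clusters")
})

test_that("a sensitivity grid of one point equals a single power estimate", {
  base <- list(n_clusters = 9, n_times = 6, cluster_size = 20,
               family = "normal", baseline = 0.3, effect = worked$theta,
               icc = 0, var = worked$sd_y^2, mode = "within")
  g <- sensitivity_grid(base, vary = list(icc = 0.1), S = 100, seed = 41)
  d <- swt_design(allocate_clusters(9, 5), 6, 20)
  pe <- estimate_power(d, continuous_model(0.1), analysis_spec("normal"),
                       S = 100, seed = 41)
  expect_equal(g$power, pe$power)
  expect_equal(nrow(g), 1)
})

test_that("omitting a real time trend from the analysis inflates estimated power", {
  # trend in the direction of the effect: the unadjusted analysis absorbs
  # it into the treatment contrast and overstates the evidence
  base <- list(n_clusters = 9, n_times = 6, cluster_size = 20,
               family = "normal", baseline = 0.3, effect = worked$theta,
               icc = 0.1, var = worked$sd_y^2, mode = "within",
               time = time_effect("linear", slope = -0.15))
  g <- sensitivity_grid(base,
                        vary = list(time_adjustment = c("none", "linear")),
                        S = 200, seed = 61)
  p_none <- g$power[g$time_adjustment == "none"]
  p_adj <- g$power[g$time_adjustment == "linear"]
  se <- sqrt(g$mc_se[1]^2 + g$mc_se[2]^2)
  expect_gt(p_none, p_adj + 3 * se)
})

test_that("point-mass priors reproduce the fixed-parameter power estimate", {
  d <- swt_design(allocate_clusters(9, 5), 6, 20)
  m <- continuous_model(0.1)
  spec <- analysis_spec("normal")
  pe_fixed <- estimate_power(d, m, spec, S = 200, seed = 81)
  theta <- worked$theta
  pe_point <- bayesian_power(d, m, spec,
                             priors = list(effect = list(dist = "uniform",
                                                         min = theta,
                                                         max = theta)),
                             S = 200, seed = 81)
  expect_lt(abs(pe_point$power - pe_fixed$power),
            3 * sqrt(pe_fixed$mc_se^2 + pe_point$mc_se^2 + 1e-12))
})

test_that("expected power under a uniform effect prior lies between the endpoint powers", {
  d <- swt_design(allocate_clusters(9, 5), 6, 20)
  m <- continuous_model(0)
  spec <- analysis_spec("normal")
  lo <- 0.25; hi <- 0.55  # |effect| endpoints; power is monotone in between
  p_lo <- estimate_power(d, outcome_model("normal", 0.3, lo, m$vc), spec,
                         S = 200, seed = 91)
  p_hi <- estimate_power(d, outcome_model("normal", 0.3, hi, m$vc), spec,
                         S = 200, seed = 92)
  p_prior <- bayesian_power(d, m, spec,
                            priors = list(effect = list(dist = "uniform",
                                                        min = lo, max = hi)),
                            S = 300, seed = 93)
  slack <- 3 * sqrt(p_prior$mc_se^2 + max(p_lo$mc_se, p_hi$mc_se)^2)
  expect_gt(p_prior$power, min(p_lo$power, p_hi$power) - slack)
  expect_lt(p_prior$power, max(p_lo$power, p_hi$power) + slack)
  expect_error(
    bayesian_power(d, m, spec,
                   priors = list(between_sd = list(dist = "uniform",
                                                   min = -1, max = 1)),
                   S = 200),
    "negative")
  expect_error(
    bayesian_power(d, m, spec, priors = list(foo = list(dist = "uniform",
                                                        min = 0, max = 1)),
                   S = 200),
    "named list")
})
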