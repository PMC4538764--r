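test_that("time-effect specifications are validated per kind", {
  expect_equal(time_effect("none")$kind, "none")
  expect_equal(time_effect("linear", slope = 0.1)$slope, 0.1)
  expect_error(time_effect("linear"), "slope")
  expect_error(time_effect("none", slope = 1), "none")
  expect_error(time_effect("categorical", values = 1:3, sd = 1), "values")
  expect_error(time_effect("random", sd = -1), "non-negative")
})

test_that("random-effect draws are reproducible and respect degenerate variances", {
  d <- swt_design(allocate_clusters(6, 3), 4, 5)
  m <- continuous_model(0)
  dr <- draw_random_effects(d, m, seed = 9)
  expect_equal(dr$alpha, rep(0, 6))  # sigma2_a = 0 -> exact zeros
  expect_null(dr$u)
  expect_null(dr$v)
  m2 <- continuous_model(0.3)
  expect_identical(draw_random_effects(d, m2, seed = 4),
                   draw_random_effects(d, m2, seed = 4))
  dr_c <- draw_random_effects(d, m2, cohort = TRUE, seed = 2)
  expect_equal(dim(dr_c$v), c(6, 5))
})

test_that("the sample variance of cluster effects approaches sigma2_a", {
  big <- swt_design(allocate_clusters(10000, 2), 3, 1)
  m <- continuous_model(0.25)  # sigma2_a = 2.4025/3
  dr <- draw_random_effects(big, m, seed = 123)
  expect_equal(var(dr$alpha), m$vc$sigma2_a, tolerance = 0.05)
})

test_that("the linear predictor assembles mu + alpha + beta + X(theta + u) (+ v)", {
  d <- swt_design(c(1, 1), 3, 2)
  m0 <- outcome_model("normal", baseline = 1.5, effect = 0.7,
                      vc = variance_components(0, 1, "within"))
  dr <- draw_random_effects(d, m0, seed = 1)
  phi <- linear_predictor(d, m0, dr)
  expect_equal(phi, 1.5 + 0.7 * d$treatment_matrix)
  # linear trend: untreated cluster gains slope*(J-1) from baseline to end
  m_tr <- outcome_model("normal", 0, 0,
                        vc = variance_components(0, 1, "within"),
                        time = time_effect("linear", slope = 0.1))
  d6 <- swt_design(allocate_clusters(5, 5), 6, 2)
  phi6 <- linear_predictor(d6, m_tr, draw_random_effects(d6, m_tr))
  expect_equal(phi6[1, 6] - phi6[1, 1], 0.5)
  # zero slope variance collapses to the common effect
  m_u0 <- outcome_model("normal", 0, 0.7,
                        vc = variance_components(0, 1, "within",
                                                 slope_var = 0))
  expect_equal(linear_predictor(d, m_u0, draw_random_effects(d, m_u0)),
               0.7 * d$treatment_matrix)
  expect_error(linear_predictor(d, m0, list(alpha = c(0, 0, 0))),
               "per cluster")
})

test_that("simulated datasets have the right shape, treatments and id semantics", {
  d <- swt_design(allocate_clusters(9, 5), 6, 20)
  m <- continuous_model(0.1)
  dat <- simulate_trial(d, m, seed = 77)
  expect_equal(nrow(dat), 9 * 6 * 20)
  expect_equal(dat$treatment,
               d$treatment_matrix[cbind(dat$cluster, dat$time)])
  # cross-sectional: no individual id is ever reused across times
  expect_equal(anyDuplicated(dat$individual), 0)
  # cohort: each cluster's K ids recur at all J times
  datc <- simulate_trial(d, m, cohort = TRUE, seed = 77)
  expect_equal(length(unique(datc$individual)), 9 * 20)
  per_id <- table(datc$individual)
  expect_true(all(per_id == 6))
  # determinism
  expect_identical(simulate_trial(d, m, seed = 5),
                   simulate_trial(d, m, seed = 5))
})

test_that("simulated normal outcomes recover their mean, total variance and ICC", {
  # null effect, residual noise only: grand mean ~ mu within 3 SE
  d_big <- swt_design(allocate_clusters(100, 4), 5, 200)
  m0 <- outcome_model("normal", baseline = 0.3, effect = 0,
                      vc = variance_components(0, worked$sd_y^2, "within"))
  y <- simulate_trial(d_big, m0, seed = 201)$outcome
  expect_lt(abs(mean(y) - 0.3), 3 * worked$sd_y / sqrt(length(y)))

  # with clustering, null effect: total variance within 3 SE (per-cluster
  # moments are iid across clusters)
  d2k <- swt_design(allocate_clusters(2000, 2), 3, 10)
  m <- outcome_model("normal", baseline = 0.3, effect = 0,
                     vc = variance_components(0.2, worked$sd_y^2, "within"))
  dat <- simulate_trial(d2k, m, seed = 202)
  dev2 <- (dat$outcome - mean(dat$outcome))^2
  per_cl <- tapply(dev2, dat$cluster, mean)
  v_hat <- mean(per_cl)
  se_v <- sd(per_cl) / sqrt(length(per_cl))
  expect_lt(abs(v_hat - m$vc$sigma2_y), 3 * se_v)

  # one-way ANOVA ICC estimator on clusters recovers rho (Swiger SE)
  k <- 3 * 10
  I <- 2000
  cl_means <- tapply(dat$outcome, dat$cluster, mean)
  msb <- k * sum((cl_means - mean(dat$outcome))^2) / (I - 1)
  msw <- sum((dat$outcome - cl_means[dat$cluster])^2) / (I * k - I)
  rho_hat <- (msb - msw) / (msb + (k - 1) * msw)
  se_rho <- sqrt(2 * (1 - 0.2)^2 * (1 + (k - 1) * 0.2)^2 /
                   (k * (k - 1) * (2000 - 1)))
  expect_lt(abs(rho_hat - 0.2), 3 * se_rho)
})

test_that("binary simulation reproduces the odds-ratio-implied treated risk", {
  # all-treated-after-baseline design, no random effects: treated cells are
  # iid Bernoulli with p = plogis(logit(p0) + log(OR))
  d <- swt_design(allocate_clusters(200, 1), 2, 150)
  m <- outcome_model("bernoulli", baseline = qlogis(worked$p0),
                     effect = log(worked$or),
                     vc = variance_components(0, 1, "within"))
  dat <- simulate_trial(d, m, seed = 301)
  p1 <- binary_risk_from_or(worked$p0, worked$or)
  treated <- dat$outcome[dat$treatment == 1]
  expect_lt(abs(mean(treated) - p1), 3 * sqrt(p1 * (1 - p1) / length(treated)))
})

test_that("closed cohorts correlate repeat measurements within individuals", {
  d <- swt_design(allocate_clusters(2000, 2), 3, 2)
  vc <- icc_to_variances(0.1, 0.3, 1)
  m <- outcome_model("normal", 0, 0, vc)
  dat <- simulate_trial(d, m, cohort = TRUE, seed = 404)
  wide <- reshape(dat[, c("cluster", "individual", "time", "outcome")],
                  idvar = c("cluster", "individual"), timevar = "time",
                  direction = "wide")
  r_within_id <- cor(wide$outcome.1, wide$outcome.2)
  # across individuals, same cluster, same time
  first <- dat[dat$time == 1, ]
  y_by_cl <- matrix(first$outcome, nrow = 2)
  r_across <- cor(y_by_cl[1, ], y_by_cl[2, ])
  expect_gt(r_within_id, r_across + 0.05)
  # theory: (s2a + s2v)/total vs s2a/total = 0.4 vs 0.1
  expect_lt(abs(r_within_id - 0.4), 0.05)
  expect_lt(abs(r_across - 0.1), 0.05)
})

test_that("simulated datasets round-trip through CSV with their metadata sidecar", {
  d <- swt_design(c(1, 1), 3, 4)
  m <- outcome_model("poisson", baseline = log(1.5), effect = log(0.8),
                     vc = variance_components(0.1, 1.35, "within"),
                     time = time_effect("linear", slope = 0.05))
  dat <- simulate_trial(d, m, seed = 11)
  f <- withr::local_tempfile(fileext = ".csv")
  write_sim_dataset(dat, f)
  dat2 <- read_sim_dataset(f)
  expect_equal(dat2[names(dat)], as.data.frame(dat)[names(dat)],
               ignore_attr = TRUE)
  m2 <- attr(dat2, "model")
  expect_equal(m2$family, "poisson")
  expect_equal(m2$vc$sigma2_a, m$vc$sigma2_a)
  expect_equal(m2$time$slope, 0.05)
  expect_equal(attr(dat2, "design")$treatment_matrix, d$treatment_matrix)
})
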