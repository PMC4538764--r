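test_that("the closed-form effect variance matches its frozen values and the zero-ICC reduction", {
  d10 <- swt_design(c(2, 2, 2, 2, 2), 6, 20)
  vc0 <- variance_components(0, 1.55^2, "total")
  expect_equal(hh_variance(d10, vc0), 10 * (2.4025 / 20) / 80,
               tolerance = 1e-12)
  expect_equal(hh_variance(d10, vc0), 0.01501563, tolerance = 1e-6)
  # rho = 0 reduces to I * sigma2 / (I*U - W) for any design
  set.seed(5)
  for (rep in 1:20) {
    d <- random_swt_design()
    s <- design_summaries(d)
    vc <- variance_components(0, 3.7, "within")
    expect_equal(hh_variance(d, vc),
                 d$n_clusters * (3.7 / d$cluster_size) /
                   (d$n_clusters * s$U - s$W))
  }
  d13 <- swt_design(allocate_clusters(13, 5), 6, 20)
  vcw <- variance_components(0.1, 1.55^2, "within")
  expect_equal(hh_variance(d13, vcw), 0.01927748, tolerance = 1e-6)
})

test_that("the closed-form variance equals the GLS information oracle on random designs", {
  set.seed(17)
  for (rep in 1:40) {
    d <- random_swt_design(max_clusters = 12, max_times = 8)
    icc <- runif(1, 0, 0.6)
    vc <- variance_components(icc, runif(1, 0.5, 4), "within")
    v_closed <- hh_variance(d, vc)
    v_gls <- gls_treatment_variance(d$treatment_matrix, vc$sigma2_e,
                                    vc$sigma2_a, d$cluster_size)
    expect_equal(v_closed, v_gls, tolerance = 1e-8)
  }
})

test_that("a design with a single shared sequence and no clustering is singular", {
  # all clusters switch at the same crossover: I*U == W when rho = 0
  d <- swt_design(allocate_clusters(4, 1, "explicit", 4), 2, 10)
  expect_error(hh_variance(d, variance_components(0, 1, "total")),
               "singular")
})

test_that("analytic power follows the normal CDF of the standardized effect", {
  d9 <- swt_design(allocate_clusters(9, 5), 6, 20)
  vc <- variance_components(0, 1.55^2, "total")
  expect_equal(hh_power(d9, vc, 0.3785), 0.805, tolerance = 1e-3)
  expect_equal(hh_power(d9, vc, 0), 0.025, tolerance = 1e-10)
  # sign of the effect is immaterial; power strictly increasing in |theta|
  expect_equal(hh_power(d9, vc, -0.3785), hh_power(d9, vc, 0.3785))
  thetas <- seq(0.1, 1, by = 0.1)
  pw <- vapply(thetas, function(t) hh_power(d9, vc, t), 0)
  expect_true(all(diff(pw) > 0))
})

test_that("minimum-cluster search reproduces the worked-example requirements at ICC 0", {
  cont <- hh_min_clusters(variance_components(0, worked$sd_y^2, "total"),
                          worked$theta, 6, 20)
  expect_equal(cont$n_clusters, 9)
  p1 <- binary_risk_from_or(worked$p0, worked$or)
  bin_total <- hh_min_clusters(
    binary_variance_components(worked$p0, p1, 0, "total"),
    p1 - worked$p0, 6, 20)
  expect_equal(bin_total$n_clusters, 10)
  bin_within <- hh_min_clusters(
    binary_variance_components(worked$p0, p1, 0, "within"),
    p1 - worked$p0, 6, 20)
  expect_equal(bin_within$n_clusters, 11)
})

test_that("required clusters shrink with larger effects and lower target power", {
  vc <- variance_components(0.1, worked$sd_y^2, "within")
  effects <- c(0.2, 0.3, 0.4, 0.6)
  n_eff <- vapply(effects, function(t)
    hh_min_clusters(vc, t, 6, 20)$n_clusters, 0L)
  expect_true(all(diff(n_eff) <= 0))
  targets <- c(0.7, 0.8, 0.9)
  n_tgt <- vapply(targets, function(p)
    hh_min_clusters(vc, 0.3785, 6, 20, target_power = p)$n_clusters, 0L)
  expect_true(all(diff(n_tgt) >= 0))
  expect_error(hh_min_clusters(vc, 0.3785, 6, 20, max_clusters = 3),
               "clusters")
})

test_that("the CRT inflation factor and cluster conversion match hand arithmetic", {
  expect_equal(crt_design_effect(20, 0), 1)
  expect_equal(crt_design_effect(20, 0.1), 2.9)
  expect_equal(crt_design_effect(120, 0.1), 12.9)
  expect_equal(crt_required_clusters(506, 20, 0.1), 74)
  expect_equal(crt_required_clusters(506, 120, 0.1), 55)
  expect_equal(crt_required_clusters(486, 20, 0.5), 256)
  expect_error(crt_design_effect(20, 1.2), "\\[0, 1\\)")
})

test_that("the Woertman correction factor matches hand evaluation and its zero-ICC form", {
  expect_equal(woertman_cf(0, 5, 1, 1, 20), 0.3125)
  expect_equal(woertman_cf(0.1, 5, 1, 1, 20), 0.4592563, tolerance = 1e-6)
  expect_equal(woertman_cf(0.5, 5, 1, 1, 20), 0.2662852, tolerance = 1e-6)
  for (J in 2:8) for (T in 1:3)
    expect_equal(woertman_cf(0, J, T, 1, 10), 3 / (2 * T * (J - 1 / J)))
  expect_error(woertman_cf(0.1, 1, 1, 1, 10), ">= 2")
})

test_that("Woertman cluster requirements match the worked design-effect route", {
  expect_equal(woertman_required_clusters(506, 0.1, 5, 1, 1, 20), 12)
  expect_equal(woertman_required_clusters(506, 0.5, 5, 1, 1, 20), 7)
  expect_equal(woertman_required_clusters(472, 0.1, 5, 1, 1, 20), 11)
})

test_that("parallel-RCT base sizes follow the two-sample normal approximation", {
  expect_equal(rct_sample_size("count", lambda0 = 1.5, lambda1 = 1.2), 236)
  expect_equal(rct_sample_size("continuous", effect = 1, sd = 1), 16)
  expect_error(rct_sample_size("binary", p0 = 0.3, p1 = 0.3), "differ")
  expect_error(rct_sample_size("continuous", effect = 0, sd = 1),
               "non-zero")
})
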