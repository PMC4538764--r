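#' Hussey-Hughes variance of the intervention effect estimator
#'
#' Closed-form generalized-least-squares variance of the treatment effect in
#' the cross-sectional stepped wedge mixed model
#' `Y_ijk = mu + alpha_i + beta_j + X_ij * theta + e_ijk`, with cluster
#' random intercepts `alpha_i ~ N(0, sigma2_a)` and residuals
#' `e_ijk ~ N(0, sigma2_e)`:
#' \deqn{V(\theta) = \frac{I \sigma^2 (\sigma^2 + J \sigma^2_\alpha)}
#'   {(IU - W)\sigma^2 + (U^2 + IJU - JW - IV)\sigma^2_\alpha}}
#' where `sigma^2 = sigma2_e / K` is the variance of a cluster-period mean
#' and `U`, `W`, `V` are the design summaries of [design_summaries()].
#'
#' @param design An [swt_design()] object.
#' @param vc A [variance_components()] object.
#' @return The variance `V(theta)` of the effect estimator (a scalar).
#' @seealso [hh_power()], [hh_min_clusters()]
#' @examples
#' d <- swt_design(c(2, 2, 2, 2, 2), 6, 20)
#' hh_variance(d, variance_components(0, 1.55^2, "total"))
#' @export
hh_variance <- function(design, vc) {
  stopifnot(inherits(design, "swt_design"),
            inherits(vc, "variance_components"))
  I <- design$n_clusters
  J <- design$n_times
  s2 <- vc$sigma2_e / design$cluster_size
  s2a <- vc$sigma2_a
  s <- design_summaries(design)
  denom <- (I * s$U - s$W) * s2 +
    (s$U^2 + I * J * s$U - J * s$W - I * s$V) * s2a
  if (denom <= 0 || !is.finite(denom))
    stop("singular design: the intervention effect is not identified ",
         "(zero information)", call. = FALSE)
  I * s2 * (s2 + J * s2a) / denom
}

#' Hussey-Hughes analytic power
#'
#' Two-sided Wald power of the stepped wedge design under the
#' Hussey-Hughes model:
#' `Power = Phi(|theta| / sqrt(V(theta)) - z_{alpha/2})`, with `Phi` the
#' standard normal distribution function.
#'
#' @inheritParams hh_variance
#' @param effect Intervention effect `theta` on the outcome scale (mean,
#'   risk or rate difference).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power, in (0, 1).
#' @examples
#' d <- swt_design(allocate_clusters(9, 5), 6, 20)
#' hh_power(d, variance_components(0, 1.55^2, "total"), effect = 0.3785)
#' @export
hh_power <- function(design, vc, effect, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  v <- hh_variance(design, vc)
  stats::pnorm(abs(effect) / sqrt(v) - stats::qnorm(1 - alpha / 2))
}

#' Minimum clusters by the Hussey-Hughes formula
#'
#' Searches for the smallest number of clusters `I >= 2` whose analytic
#' power reaches `target_power`, incrementing `I` by one and allocating
#' clusters to crossovers by `rule` (see [allocate_clusters()]).
#'
#' @inheritParams hh_power
#' @param n_times Total measurement times `J` (including baseline).
#' @param cluster_size Individuals per cluster per time, `K`.
#' @param target_power Required power (default 0.8).
#' @param rule Allocation rule passed to [allocate_clusters()].
#' @param max_clusters Search cap; exceeding it is an error (default 1000).
#' @return A list with `n_clusters` (the minimum `I`), the achieved
#'   `power`, and the `design` at the minimum.
#' @examples
#' hh_min_clusters(variance_components(0, 1.55^2, "total"),
#'                 effect = -0.3785, n_times = 6, cluster_size = 20)
#' @export
hh_min_clusters <- function(vc, effect, n_times, cluster_size,
                            target_power = 0.8, alpha = 0.05,
                            rule = "even-earliest", max_clusters = 1000) {
  if (effect == 0) stop("'effect' must be non-zero", call. = FALSE)
  if (target_power <= 0 || target_power >= 1)
    stop("'target_power' must be in (0, 1)", call. = FALSE)
  for (I in 2:max_clusters) {
    alloc <- allocate_clusters(I, n_times - 1L, rule = rule)
    d <- swt_design(alloc, n_times, cluster_size)
    p <- tryCatch(hh_power(d, vc, effect, alpha), error = function(e) NA_real_)
    if (!is.na(p) && p >= target_power)
      return(list(n_clusters = I, power = p, design = d))
  }
  stop("no design with at most ", max_clusters, " clusters reaches the ",
       "target power", call. = FALSE)
}

#' Standard cluster-randomised-trial design effect
#'
#' The conventional variance inflation factor `1 + (K - 1) * rho` for a
#' parallel CRT with `K` measurements per cluster and intracluster
#' correlation `rho`.
#'
#' @param n_per_cluster Measurements per cluster, `K >= 1`.
#' @param icc Intracluster correlation in `[0, 1)`.
#' @return The design effect (>= 1).
#' @export
crt_design_effect <- function(n_per_cluster, icc) {
  if (!is_count(n_per_cluster))
    stop("'n_per_cluster' must be a positive integer", call. = FALSE)
  if (icc < 0 || icc >= 1) stop("'icc' must be in [0, 1)", call. = FALSE)
  1 + (n_per_cluster - 1) * icc
}

#' Clusters required for a parallel CRT
#'
#' Inflates a parallel individually-randomised sample size (both arms) by
#' the CRT design effect and converts it to whole clusters:
#' `ceiling(rct_total * DE / n_per_cluster)`.
#'
#' @param rct_total Total sample size (both arms) of the corresponding
#'   individually randomised trial.
#' @inheritParams crt_design_effect
#' @return Number of clusters (integer).
#' @examples
#' crt_required_clusters(506, 20, 0.1)  # 74
#' @export
crt_required_clusters <- function(rct_total, n_per_cluster, icc) {
  if (!is_count(rct_total))
    stop("'rct_total' must be a positive integer", call. = FALSE)
  ceiling(rct_total * crt_design_effect(n_per_cluster, icc) / n_per_cluster)
}

#' Woertman correction factor and design effect
#'
#' The stepped wedge correction factor of the Woertman design-effect
#' approach, for a design with `n_crossovers` crossover points (`J` in the
#' Woertman sense, i.e. the design's total times minus the baseline), `B`
#' baseline measurement times, `T` measurement times per crossover and `K`
#' participants measured per cluster per time:
#' \deqn{CF = \frac{1 + \rho(JTK + BK - 1)}{1 + \rho(\frac{1}{2}JTK + BK - 1)}
#'   \cdot \frac{3(1-\rho)}{2T(J - 1/J)}}
#' The proper design effect is `DE_W = (B + J*T) * CF`; the total number of
#' measurements is `n = n_RCT * DE_W`, where `n_RCT` is the two-arm parallel
#' RCT size without baseline data. For continuous-recruitment short-exposure
#' designs set `times_per_step = 1` and `baseline_times` to the ratio of
#' pre-rollout measurements to measurements per crossover.
#'
#' @param icc Intracluster correlation in `[0, 1)`.
#' @param n_crossovers Number of crossover points (>= 2).
#' @param times_per_step Measurement times during each crossover, `T`.
#' @param baseline_times Baseline measurement times, `B`.
#' @param per_time_size Participants measured per cluster per time, `K`.
#' @return `woertman_cf()`: the correction factor; `woertman_de()`: the
#'   design effect `(B + J*T) * CF`.
#' @examples
#' woertman_cf(0, 5, 1, 1, 20)    # 0.3125
#' woertman_de(0.1, 5, 1, 1, 20)
#' @export
woertman_cf <- function(icc, n_crossovers, times_per_step = 1,
                        baseline_times = 1, per_time_size = 1) {
  if (icc < 0 || icc >= 1) stop("'icc' must be in [0, 1)", call. = FALSE)
  if (!is_count(n_crossovers) || n_crossovers < 2)
    stop("'n_crossovers' must be an integer >= 2", call. = FALSE)
  if (!is_count(times_per_step) || !is_count(baseline_times) ||
      !is_count(per_time_size))
    stop("'times_per_step', 'baseline_times' and 'per_time_size' must be ",
         "positive integers", call. = FALSE)
  J <- n_crossovers; T <- times_per_step; B <- baseline_times
  K <- per_time_size
  ratio <- (1 + icc * (J * T * K + B * K - 1)) /
    (1 + icc * (0.5 * J * T * K + B * K - 1))
  ratio * 3 * (1 - icc) / (2 * T * (J - 1 / J))
}

#' @rdname woertman_cf
#' @export
woertman_de <- function(icc, n_crossovers, times_per_step = 1,
                        baseline_times = 1, per_time_size = 1) {
  (baseline_times + n_crossovers * times_per_step) *
    woertman_cf(icc, n_crossovers, times_per_step, baseline_times,
                per_time_size)
}

#' Clusters required under the Woertman design effect
#'
#' Applies `DE_W` to a two-arm parallel RCT sample size and converts the
#' resulting total number of measurements to whole clusters, each
#' contributing `per_time_size * (B + J*T)` measurements.
#'
#' @param rct_total Two-arm parallel RCT sample size.
#' @inheritParams woertman_cf
#' @return Number of clusters (integer).
#' @examples
#' woertman_required_clusters(506, 0.1, 5, 1, 1, 20)  # 12
#' @export
woertman_required_clusters <- function(rct_total, icc, n_crossovers,
                                       times_per_step = 1, baseline_times = 1,
                                       per_time_size = 1) {
  if (!is_count(rct_total))
    stop("'rct_total' must be a positive integer", call. = FALSE)
  n <- rct_total * woertman_de(icc, n_crossovers, times_per_step,
                               baseline_times, per_time_size)
  meas_per_cluster <- per_time_size *
    (baseline_times + n_crossovers * times_per_step)
  ceiling(n / meas_per_cluster)
}

#' Parallel-RCT base sample size (normal approximation)
#'
#' Two-sample normal-approximation sample sizes per arm, rounded up:
#' * continuous: `2 * (z_{alpha/2} + z_beta)^2 * sigma^2 / theta^2`
#' * binary: `(z_{alpha/2} + z_beta)^2 * (p0 q0 + p1 q1) / (p0 - p1)^2`
#' * count: `(z_{alpha/2} + z_beta)^2 * (lambda0 + lambda1) /
#'   (lambda0 - lambda1)^2`
#'
#' @param family `"continuous"`, `"binary"` or `"count"`.
#' @param effect Mean difference `theta` (continuous only).
#' @param sd Common standard deviation (continuous only).
#' @param p0,p1 Event probabilities (binary only).
#' @param lambda0,lambda1 Event rates (count only).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Sample size per arm (integer).
#' @examples
#' rct_sample_size("count", lambda0 = 1.5, lambda1 = 1.2)  # 236
#' @export
rct_sample_size <- function(family = c("continuous", "binary", "count"),
                            effect = NULL, sd = NULL, p0 = NULL, p1 = NULL,
                            lambda0 = NULL, lambda1 = NULL,
                            alpha = 0.05, power = 0.8) {
  family <- match.arg(family)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n <- switch(family,
    continuous = {
      if (is.null(effect) || is.null(sd))
        stop("continuous outcomes need 'effect' and 'sd'", call. = FALSE)
      if (effect == 0) stop("'effect' must be non-zero", call. = FALSE)
      2 * (za + zb)^2 * sd^2 / effect^2
    },
    binary = {
      if (is.null(p0) || is.null(p1))
        stop("binary outcomes need 'p0' and 'p1'", call. = FALSE)
      if (p0 == p1) stop("'p0' and 'p1' must differ", call. = FALSE)
      (za + zb)^2 * (p0 * (1 - p0) + p1 * (1 - p1)) / (p0 - p1)^2
    },
    count = {
      if (is.null(lambda0) || is.null(lambda1))
        stop("count outcomes need 'lambda0' and 'lambda1'", call. = FALSE)
      if (lambda0 == lambda1)
        stop("'lambda0' and 'lambda1' must differ", call. = FALSE)
      (za + zb)^2 * (lambda0 + lambda1) / (lambda0 - lambda1)^2
    })
  as.integer(ceiling(n))
}
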