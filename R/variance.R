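#' Variance components of the stepped wedge outcome model
#'
#' Collects the variance parameters of the mixed model underlying both the
#' analytic calculations and the simulator: the within-cluster (individual
#' residual) variance `sigma2_e`, the between-cluster variance `sigma2_a`,
#' the within-individual variance `sigma2_v` (closed cohorts only) and the
#' random-intervention-slope variance `sigma2_u`. The intracluster
#' correlation is always `rho = sigma2_a / (sigma2_a + sigma2_e)`.
#'
#' Two input conventions are supported, because practitioners quote variances
#' both ways:
#' * `mode = "total"`: `var` is the total variance `sigma2_y`; then
#'   `sigma2_a = var * icc` and `sigma2_e = var * (1 - icc)`.
#' * `mode = "within"`: `var` is the within-cluster variance `sigma2_e`; then
#'   `sigma2_a = var * icc / (1 - icc)`.
#'
#' @param icc Intracluster correlation `rho`, in `[0, 1)`.
#' @param var The variance being supplied (see `mode`), non-negative.
#' @param mode `"total"` or `"within"`.
#' @param individual_var Within-individual variance `sigma2_v` (closed
#'   cohort designs), default 0.
#' @param slope_var Random-intervention-effect variance `sigma2_u`, default 0.
#' @return An object of class `"variance_components"`: a list with
#'   `sigma2_e`, `sigma2_a`, `sigma2_v`, `sigma2_u`, `sigma2_y`
#'   (`= sigma2_a + sigma2_e`), `icc` and `input_mode`.
#' @examples
#' variance_components(icc = 0.1, var = 1.55^2, mode = "within")
#' @export
variance_components <- function(icc, var, mode = c("total", "within"),
                                individual_var = 0, slope_var = 0) {
  mode <- match.arg(mode)
  if (!is.numeric(icc) || length(icc) != 1L || icc < 0 || icc >= 1)
    stop("'icc' must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(var) || length(var) != 1L || var < 0)
    stop("'var' must be a non-negative number", call. = FALSE)
  if (individual_var < 0 || slope_var < 0)
    stop("variances must be non-negative", call. = FALSE)
  if (mode == "total") {
    sigma2_a <- var * icc
    sigma2_e <- var * (1 - icc)
  } else {
    sigma2_e <- var
    sigma2_a <- var * icc / (1 - icc)
  }
  structure(
    list(sigma2_e = sigma2_e, sigma2_a = sigma2_a,
         sigma2_v = individual_var, sigma2_u = slope_var,
         sigma2_y = sigma2_a + sigma2_e, icc = icc, input_mode = mode),
    class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "Variance components (%s-variance input): sigma2_e = %.5g, sigma2_a = %.5g, icc = %.4g\n",
    x$input_mode, x$sigma2_e, x$sigma2_a, x$icc))
  if (x$sigma2_v > 0)
    cat(sprintf("  within-individual sigma2_v = %.5g\n", x$sigma2_v))
  if (x$sigma2_u > 0)
    cat(sprintf("  intervention-slope sigma2_u = %.5g\n", x$sigma2_u))
  invisible(x)
}

#' Convert cluster- and individual-level ICCs to variance components
#'
#' For closed-cohort designs the total outcome variance decomposes as
#' `sigma2_a + sigma2_v + sigma2_e`. Given the cluster-level ICC
#' (share of total variance between clusters), the individual-level ICC
#' (share within individuals over time) and the residual within variance,
#' returns the implied components:
#' `sigma2_a = within_var * rho_c / (1 - rho_c - rho_i)` and
#' `sigma2_v = within_var * rho_i / (1 - rho_c - rho_i)`.
#'
#' @param cluster_icc Cluster-level ICC, `rho_c` in `[0, 1)`.
#' @param individual_icc Individual-level ICC, `rho_i` in `[0, 1)`;
#'   `cluster_icc + individual_icc < 1`.
#' @param within_var Residual within-cluster variance `sigma2_e > 0`.
#' @return A [variance_components()] object with `sigma2_v` set.
#' @examples
#' icc_to_variances(0.1, 0, 2.4025)  # sigma2_a = 0.26694
#' @export
icc_to_variances <- function(cluster_icc, individual_icc, within_var) {
  if (cluster_icc < 0 || individual_icc < 0 ||
      cluster_icc + individual_icc >= 1)
    stop("ICC shares must be non-negative and sum to less than 1",
         call. = FALSE)
  if (within_var <= 0)
    stop("'within_var' must be positive", call. = FALSE)
  rest <- 1 - cluster_icc - individual_icc
  vc <- variance_components(icc = cluster_icc / (cluster_icc + rest),
                            var = within_var, mode = "within",
                            individual_var = within_var * individual_icc / rest)
  vc
}

#' Event probability under an odds ratio
#'
#' Transforms a baseline probability through an odds ratio:
#' `p1 = OR * odds0 / (1 + OR * odds0)` with `odds0 = p0 / (1 - p0)`.
#'
#' @param p0 Baseline probability, strictly inside (0, 1).
#' @param odds_ratio Positive odds ratio.
#' @return The treated-arm probability `p1`.
#' @examples
#' binary_risk_from_or(0.26, 0.56)  # 0.1644
#' @export
binary_risk_from_or <- function(p0, odds_ratio) {
  if (p0 <= 0 || p0 >= 1) stop("'p0' must be in (0, 1)", call. = FALSE)
  if (odds_ratio <= 0) stop("'odds_ratio' must be positive", call. = FALSE)
  odds <- odds_ratio * p0 / (1 - p0)
  odds / (1 + odds)
}

#' Outcome-scale variances for binary and count outcomes
#'
#' Normal-approximation variance conventions used by the analytic
#' calculations on the risk/rate-difference scale.
#'
#' For a binary outcome, `mode = "total"` uses the pooled Bernoulli variance
#' `pbar * (1 - pbar)` with `pbar = (p0 + p1) / 2` as the total variance,
#' while `mode = "within"` uses the baseline variance `p0 * (1 - p0)` as the
#' within-cluster variance. For a count outcome the Poisson variance is the
#' average rate `(lambda0 + lambda1) / 2` in either mode.
#'
#' @param p0,p1 Control and treated event probabilities.
#' @param lambda0,lambda1 Control and treated event rates.
#' @param icc Intracluster correlation.
#' @param mode `"total"` or `"within"`; determines both which variance is
#'   used and how `icc` converts it to a between-cluster variance (see
#'   [variance_components()]).
#' @return A [variance_components()] object.
#' @export
binary_variance_components <- function(p0, p1, icc,
                                       mode = c("total", "within")) {
  mode <- match.arg(mode)
  v <- if (mode == "total") {
    pbar <- (p0 + p1) / 2
    pbar * (1 - pbar)
  } else p0 * (1 - p0)
  variance_components(icc = icc, var = v, mode = mode)
}

#' @rdname binary_variance_components
#' @export
count_variance_components <- function(lambda0, lambda1, icc,
                                      mode = c("total", "within")) {
  mode <- match.arg(mode)
  if (lambda0 < 0 || lambda1 < 0)
    stop("rates must be non-negative", call. = FALSE)
  variance_components(icc = icc, var = (lambda0 + lambda1) / 2, mode = mode)
}
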