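#' Time-effect specification for the data-generating process
#'
#' Secular trend `beta_j` entering the linear predictor on the link scale:
#' * `"none"`: `beta_j = 0`;
#' * `"linear"`: `beta_j = slope * (j - 1)` (zero at baseline);
#' * `"categorical"`: user-supplied values, one per measurement time;
#' * `"random"`: `beta_j ~ Normal(0, sd^2)`, drawn per simulated trial.
#'
#' @param kind One of `"none"`, `"linear"`, `"categorical"`, `"random"`.
#' @param slope Per-period trend (linear kind only).
#' @param values Numeric vector of length `J` (categorical kind only).
#' @param sd Standard deviation `sigma_beta` (random kind only).
#' @return An object of class `"time_effect"`.
#' @export
time_effect <- function(kind = c("none", "linear", "categorical", "random"),
                        slope = NULL, values = NULL, sd = NULL) {
  kind <- match.arg(kind)
  given <- c(slope = !is.null(slope), values = !is.null(values),
             sd = !is.null(sd))
  need <- switch(kind, none = character(), linear = "slope",
                 categorical = "values", random = "sd")
  if (!setequal(names(given)[given], need))
    stop("time_effect kind '", kind, "' takes exactly the field(s): ",
         if (length(need)) paste(need, collapse = ", ") else "(none)",
         call. = FALSE)
  if (kind == "random" && sd < 0)
    stop("'sd' must be non-negative", call. = FALSE)
  structure(list(kind = kind, slope = slope, values = values, sd = sd),
            class = "time_effect")
}

time_effect_values <- function(te, n_times, draws = NULL) {
  switch(te$kind,
    none = rep.int(0, n_times),
    linear = te$slope * (seq_len(n_times) - 1),
    categorical = {
      if (length(te$values) != n_times)
        stop("categorical time effect needs one value per time point",
             call. = FALSE)
      te$values
    },
    random = {
      if (is.null(draws$beta)) stop("random time effects were not drawn",
                                    call. = FALSE)
      draws$beta
    })
}

#' Outcome model for trial simulation
#'
#' The generalized linear mixed data-generating process for one arm
#' structure: on the link scale the cluster-period mean is
#' `phi_ij = mu + alpha_i + beta_j + X_ij * (theta + u_i)` (plus `v_ik` for
#' closed cohorts), and outcomes are drawn from the family's distribution.
#' The link is fixed by the family: identity for `"normal"`, logit for
#' `"bernoulli"`, log for `"poisson"`; `baseline` and `effect` are specified
#' on that scale (e.g. `effect = log(0.56)` for an odds ratio of 0.56).
#'
#' @param family `"normal"`, `"bernoulli"` or `"poisson"`.
#' @param baseline Intercept `mu` on the link scale.
#' @param effect Intervention effect `theta` on the link scale.
#' @param vc A [variance_components()] object; `sigma2_e` is the residual
#'   variance (normal family only, must be positive there), `sigma2_a` the
#'   cluster variance, `sigma2_v` the individual variance (cohorts) and
#'   `sigma2_u` the random-intervention-slope variance.
#' @param time A [time_effect()] specification (default none).
#' @return An object of class `"outcome_model"`.
#' @examples
#' m <- outcome_model("bernoulli", baseline = qlogis(0.26),
#'                    effect = log(0.56),
#'                    vc = variance_components(0.1, 0.26 * 0.74, "within"))
#' @export
outcome_model <- function(family = c("normal", "bernoulli", "poisson"),
                          baseline, effect, vc, time = time_effect("none")) {
  family <- match.arg(family)
  stopifnot(inherits(vc, "variance_components"),
            inherits(time, "time_effect"))
  if (family == "normal" && vc$sigma2_e <= 0)
    stop("the normal family needs a positive within-cluster variance",
         call. = FALSE)
  link <- switch(family, normal = "identity", bernoulli = "logit",
                 poisson = "log")
  structure(list(family = family, link = link, baseline = baseline,
                 effect = effect, vc = vc, time = time),
            class = "outcome_model")
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf("Outcome model: %s (%s link), baseline %.4g, effect %.4g, time effect '%s'\n",
              x$family, x$link, x$baseline, x$effect, x$time$kind))
  print(x$vc)
  invisible(x)
}

#' Draw the random effects of one simulated trial
#'
#' Draws cluster intercepts `alpha_i ~ N(0, sigma2_a)`, and, where the
#' model calls for them, individual effects `v_ik ~ N(0, sigma2_v)` (closed
#' cohorts), cluster-specific intervention slopes `u_i ~ N(0, sigma2_u)` and
#' random time effects `beta_j ~ N(0, sigma_beta^2)`. All draws are
#' independent zero-mean normals; a zero variance yields exact zeros.
#'
#' @param design An [swt_design()] object.
#' @param model An [outcome_model()].
#' @param cohort Closed-cohort flag; if `TRUE`, individual effects are drawn.
#' @param seed Optional integer seed (identical seeds give identical draws).
#' @return A list with `alpha` (length `I`), `v` (`I x K` matrix or `NULL`),
#'   `u` (length `I` or `NULL`) and `beta` (length `J` or `NULL`).
#' @export
draw_random_effects <- function(design, model, cohort = FALSE, seed = NULL) {
  stopifnot(inherits(design, "swt_design"), inherits(model, "outcome_model"))
  if (!is.null(seed)) set.seed(seed)
  vc <- model$vc
  I <- design$n_clusters; J <- design$n_times; K <- design$cluster_size
  rnorm0 <- function(n, s2) if (s2 > 0) stats::rnorm(n, 0, sqrt(s2)) else
    rep.int(0, n)
  list(
    alpha = rnorm0(I, vc$sigma2_a),
    v = if (cohort) matrix(rnorm0(I * K, vc$sigma2_v), I, K) else NULL,
    u = if (vc$sigma2_u > 0) rnorm0(I, vc$sigma2_u) else NULL,
    beta = if (model$time$kind == "random")
      rnorm0(J, model$time$sd^2) else NULL)
}

#' Linear predictor of the data-generating process
#'
#' Assembles `phi_ij = mu + alpha_i + beta_j + X_ij * (theta + u_i)` on the
#' link scale, adding `v_ik` when individual effects are present (closed
#' cohort), in which case the result has an individual dimension.
#'
#' @inheritParams draw_random_effects
#' @param draws Random-effect draws from [draw_random_effects()].
#' @return An `I x J` matrix of `phi_ij`, or an `I x J x K` array when
#'   `draws$v` is present.
#' @export
linear_predictor <- function(design, model, draws) {
  stopifnot(inherits(design, "swt_design"), inherits(model, "outcome_model"))
  I <- design$n_clusters; J <- design$n_times; K <- design$cluster_size
  X <- design$treatment_matrix
  if (length(draws$alpha) != I)
    stop("'draws$alpha' must have one entry per cluster", call. = FALSE)
  beta <- time_effect_values(model$time, J, draws)
  slope <- model$effect + (if (is.null(draws$u)) 0 else draws$u)
  phi <- model$baseline + outer(draws$alpha, beta, `+`) + X * slope
  if (is.null(draws$v)) return(phi)
  if (!all(dim(draws$v) == c(I, K)))
    stop("'draws$v' must be an I x K matrix", call. = FALSE)
  out <- array(0, dim = c(I, J, K))
  for (k in seq_len(K)) out[, , k] <- phi + draws$v[, k]
  out
}

#' Simulate one stepped wedge trial dataset
#'
#' Draws random effects, builds the linear predictor and samples outcomes:
#' normal `Y = phi + e`, `e ~ N(0, sigma2_e)`; bernoulli
#' `Y ~ Bern(plogis(phi))`; poisson `Y ~ Pois(exp(phi))`.
#'
#' Cross-sectional datasets give every record a globally unique individual
#' id (no individual appears at two times); closed-cohort datasets reuse the
#' same `K` ids of each cluster across all times.
#'
#' @inheritParams draw_random_effects
#' @return A `data.frame` of `I * J * K` records with columns `cluster`,
#'   `time`, `individual`, `treatment`, `outcome`, and attributes `design`,
#'   `model`, `cohort` and `seed`.
#' @examples
#' d <- swt_design(c(1, 1), 3, 4)
#' m <- outcome_model("normal", 0, 0.5,
#'                    variance_components(0.1, 1, "within"))
#' head(simulate_trial(d, m, seed = 1))
#' @export
simulate_trial <- function(design, model, cohort = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draws <- draw_random_effects(design, model, cohort = cohort, seed = NULL)
  phi <- linear_predictor(design, model, draws)
  I <- design$n_clusters; J <- design$n_times; K <- design$cluster_size
  # long format ordered by cluster, time, individual-within-cell
  cl <- rep(seq_len(I), each = J * K)
  tm <- rep(rep(seq_len(J), each = K), times = I)
  kk <- rep(seq_len(K), times = I * J)
  phi_long <- if (length(dim(phi)) == 3)
    phi[cbind(cl, tm, kk)] else phi[cbind(cl, tm)]
  n <- length(phi_long)
  y <- switch(model$family,
    normal = phi_long + stats::rnorm(n, 0, sqrt(model$vc$sigma2_e)),
    bernoulli = stats::rbinom(n, 1L, stats::plogis(phi_long)),
    poisson = {
      rate <- exp(phi_long)
      if (any(!is.finite(rate))) {
        bad <- which(!is.finite(rate))[1L]
        stop(sprintf(
          "linear predictor gives a non-finite rate at cluster %d, time %d",
          cl[bad], tm[bad]), call. = FALSE)
      }
      stats::rpois(n, rate)
    })
  id <- if (cohort) (cl - 1L) * K + kk else seq_len(n)
  out <- data.frame(
    cluster = cl, time = tm, individual = id,
    treatment = design$treatment_matrix[cbind(cl, tm)],
    outcome = y)
  attr(out, "design") <- design
  attr(out, "model") <- model
  attr(out, "cohort") <- cohort
  attr(out, "seed") <- seed
  out
}

#' Read and write simulated trial datasets
#'
#' The dataset itself is a 5-column CSV (`cluster, time, individual,
#' treatment, outcome`); design and model parameters, the cohort flag and
#' the seed go to a structured YAML sidecar (`<file>.meta.yml`) so that a
#' stored dataset is self-describing.
#'
#' @param data A dataset from [simulate_trial()].
#' @param file CSV path; the sidecar is written next to it.
#' @return `read_sim_dataset()` returns the dataset with its attributes
#'   restored; `write_sim_dataset()` returns `file` invisibly.
#' @export
write_sim_dataset <- function(data, file) {
  utils::write.csv(data, file, row.names = FALSE)
  design <- attr(data, "design"); model <- attr(data, "model")
  meta <- list(
    cohort = isTRUE(attr(data, "cohort")),
    seed = attr(data, "seed"),
    design = list(allocation = design$allocation,
                  n_times = design$n_times,
                  cluster_size = design$cluster_size),
    model = list(family = model$family, baseline = model$baseline,
                 effect = model$effect,
                 time = model$time[!vapply(model$time, is.null, TRUE)],
                 vc = list(icc = model$vc$icc,
                           var = if (model$vc$input_mode == "total")
                             model$vc$sigma2_y else model$vc$sigma2_e,
                           mode = model$vc$input_mode,
                           individual_var = model$vc$sigma2_v,
                           slope_var = model$vc$sigma2_u)))
  yaml::write_yaml(meta, paste0(file, ".meta.yml"))
  invisible(file)
}

#' @rdname write_sim_dataset
#' @export
read_sim_dataset <- function(file) {
  out <- utils::read.csv(file)
  meta_file <- paste0(file, ".meta.yml")
  if (file.exists(meta_file)) {
    meta <- yaml::read_yaml(meta_file)
    design <- swt_design(unlist(meta$design$allocation),
                         meta$design$n_times, meta$design$cluster_size)
    te <- do.call(time_effect, meta$model$time)
    vc <- variance_components(meta$model$vc$icc, meta$model$vc$var,
                              meta$model$vc$mode,
                              individual_var = meta$model$vc$individual_var,
                              slope_var = meta$model$vc$slope_var)
    attr(out, "design") <- design
    attr(out, "model") <- outcome_model(meta$model$family,
                                        meta$model$baseline,
                                        meta$model$effect, vc, te)
    attr(out, "cohort") <- meta$cohort
    attr(out, "seed") <- meta$seed
  }
  out
}
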