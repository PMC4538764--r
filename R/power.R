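#' @keywords internal
new_power_estimate <- function(n_sig, S, n_nonconverged, settings) {
  p <- n_sig / S
  structure(list(power = p, mc_se = sqrt(p * (1 - p) / S),
                 n_sims = S, n_nonconverged = n_nonconverged,
                 settings = settings),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Monte Carlo power: %.4f (MC SE %.4f, S = %d)\n",
              x$power, x$mc_se, x$n_sims))
  if (x$n_nonconverged > 0)
    cat(sprintf("  non-converged fits (counted non-significant): %d\n",
                x$n_nonconverged))
  invisible(x)
}

trial_seeds <- function(seed, S) {
  if (is.null(seed)) return(rep_len(list(NULL), S))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, S))
}

#' Monte Carlo power of a stepped wedge design
#'
#' Estimates power by repeated simulation: `S` trials are generated from
#' the data-generating [outcome_model()], each is analysed with
#' [fit_swt()], and the proportion whose Wald test is significant at
#' `spec$alpha` is the estimated power, with Monte Carlo standard error
#' `sqrt(p (1 - p) / S)`. Each trial runs on its own deterministically
#' derived random sub-stream, so a master `seed` makes the whole estimate
#' reproducible and independent of execution order.
#'
#' @param design An [swt_design()] object.
#' @param model An [outcome_model()] (the data-generating process).
#' @param spec An [analysis_spec()] (the analysis model).
#' @param S Number of simulated trials (at least 100; the default 1000
#'   gives an MC standard error of about 0.013 near 80 % power).
#' @param seed Master seed (integer) for reproducibility.
#' @param cohort Closed-cohort flag passed to [simulate_trial()].
#' @return A `"power_estimate"`: `power`, `mc_se`, `n_sims`,
#'   `n_nonconverged` (non-converged fits, counted as non-significant) and
#'   a `settings` fingerprint.
#' @export
estimate_power <- function(design, model, spec, S = 1000, seed = NULL,
                           cohort = FALSE) {
  stopifnot(inherits(design, "swt_design"), inherits(model, "outcome_model"),
            inherits(spec, "analysis_spec"))
  if (!is_count(S) || S < 100)
    stop("'S' must be an integer >= 100 (Monte Carlo error is otherwise ",
         "too large to be meaningful)", call. = FALSE)
  seeds <- trial_seeds(seed, S)
  n_sig <- 0L
  n_nc <- 0L
  for (s in seq_len(S)) {
    dat <- simulate_trial(design, model, cohort = cohort, seed = seeds[[s]])
    fit <- fit_swt(dat, spec)
    if (!isTRUE(fit$converged)) n_nc <- n_nc + 1L
    if (wald_significant(fit, spec$alpha)) n_sig <- n_sig + 1L
  }
  new_power_estimate(n_sig, S, n_nc,
                     settings = list(n_clusters = design$n_clusters,
                                     n_times = design$n_times,
                                     cluster_size = design$cluster_size,
                                     family = model$family, cohort = cohort,
                                     alpha = spec$alpha, seed = seed))
}

#' Minimum clusters by simulation
#'
#' Increments the number of clusters `I` (allocated to crossovers by
#' `rule`) and estimates power at each candidate until the Monte Carlo
#' estimate reaches `threshold`. Candidates are evaluated in increasing
#' order without early stopping on Monte Carlo noise; with
#' `refine = TRUE` any candidate whose estimate lands within two Monte
#' Carlo standard errors of the threshold — on either side — is re-run at
#' `4 * S` simulations and the refined estimate decides, which stabilises
#' the reported minimum when the true power sits near the threshold.
#'
#' @inheritParams estimate_power
#' @param n_times,cluster_size Design dimensions (see [swt_design()]).
#' @param threshold Required power (default 0.8).
#' @param rule Allocation rule (see [allocate_clusters()]).
#' @param start First candidate `I` (default 2).
#' @param max_clusters Search cap; exceeding it is an error.
#' @param refine Re-check the boundary candidate at `4 * S` (default off).
#' @return A list of class `"swt_search"`: `n_clusters` (the minimum),
#'   `power` (its estimate), `threshold`, and `trajectory` (a data frame
#'   with one row per evaluated candidate).
#' @export
find_min_clusters <- function(model, spec, n_times, cluster_size,
                              threshold = 0.8, S = 1000, rule = "even-earliest",
                              seed = NULL, cohort = FALSE, start = 2,
                              max_clusters = 100, refine = FALSE) {
  if (threshold < 0 || threshold >= 1)
    stop("'threshold' must be in [0, 1)", call. = FALSE)
  cand_seeds <- if (is.null(seed)) NULL else {
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, max_clusters)
  }
  rows <- list()
  for (I in start:max_clusters) {
    d <- swt_design(allocate_clusters(I, n_times - 1L, rule = rule),
                    n_times, cluster_size)
    cs <- if (is.null(cand_seeds)) NULL else cand_seeds[I]
    pe <- estimate_power(d, model, spec, S = S, seed = cs, cohort = cohort)
    if (refine && abs(pe$power - threshold) < 2 * pe$mc_se) {
      pe <- estimate_power(d, model, spec, S = 4L * S,
                           seed = if (is.null(cs)) NULL else cs + 1L,
                           cohort = cohort)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      n_clusters = I, power = pe$power, mc_se = pe$mc_se,
      n_sims = pe$n_sims, n_nonconverged = pe$n_nonconverged)
    if (pe$power >= threshold) {
      return(structure(list(n_clusters = I, power = pe$power,
                            threshold = threshold,
                            trajectory = do.call(rbind, rows)),
                       class = "swt_search"))
    }
  }
  stop("no design with at most ", max_clusters,
       " clusters reaches the target power", call. = FALSE)
}

#' @export
print.swt_search <- function(x, ...) {
  cat(sprintf(
    "Minimum clusters for power >= %.2f: %d (estimated power %.4f)\n",
    x$threshold, x$n_clusters, x$power))
  invisible(x)
}

#' Sensitivity grid of Monte Carlo power estimates
#'
#' Evaluates [estimate_power()] over the cross product of one or more
#' varied parameters, holding everything else at the base settings. All
#' cells share the same master seed policy, so differences across cells
#' reflect the parameters, not fresh Monte Carlo noise streams.
#'
#' @param base Named list of base settings: `n_clusters`, `n_times`,
#'   `cluster_size`, `family`, `baseline`, `effect`, `icc`, `var`, `mode`
#'   (variance input mode), and optionally `individual_var`, `slope_var`,
#'   `time` (a [time_effect()]), `time_adjustment`, `cohort`, `alpha`.
#' @param vary Named list of vectors; names must be base-setting names
#'   (`time_slope` varies the slope of a linear time trend).
#' @param S,seed As in [estimate_power()].
#' @return A data frame with one row per grid cell: the varied columns
#'   plus `power`, `mc_se`, `n_sims`, `n_nonconverged`.
#' @export
sensitivity_grid <- function(base, vary, S = 1000, seed = NULL) {
  stopifnot(is.list(base), is.list(vary), length(vary) >= 1)
  grid <- expand.grid(vary, stringsAsFactors = FALSE)
  res <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    st <- utils::modifyList(base, as.list(grid[r, , drop = FALSE]))
    if (!is.null(st$time_slope))
      st$time <- time_effect("linear", slope = st$time_slope)
    pe <- do.call(estimate_power_settings,
                  list(settings = st, S = S, seed = seed))
    res[[r]] <- cbind(grid[r, , drop = FALSE],
                      data.frame(power = pe$power, mc_se = pe$mc_se,
                                 n_sims = pe$n_sims,
                                 n_nonconverged = pe$n_nonconverged))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Build design/model/spec from a flat settings list and estimate power.
estimate_power_settings <- function(settings, S, seed) {
  st <- settings
  defaults <- list(mode = "within", individual_var = 0, slope_var = 0,
                   time = time_effect("none"), time_adjustment = "categorical",
                   cohort = FALSE, alpha = 0.05)
  st <- utils::modifyList(defaults, st)
  d <- swt_design(allocate_clusters(st$n_clusters, st$n_times - 1L),
                  st$n_times, st$cluster_size)
  vc <- variance_components(st$icc, st$var, st$mode,
                            individual_var = st$individual_var,
                            slope_var = st$slope_var)
  m <- outcome_model(st$family, st$baseline, st$effect, vc, time = st$time)
  a <- analysis_spec(st$family, time_adjustment = st$time_adjustment,
                     random_terms = c("cluster",
                                      if (st$cohort) "individual"),
                     alpha = st$alpha)
  estimate_power(d, m, a, S = S, seed = seed, cohort = st$cohort)
}

#' Monte Carlo power under parameter uncertainty (Bayesian variant)
#'
#' Expected power over prior distributions on designated parameters: for
#' each simulated trial, the uncertain parameters are first drawn from
#' their priors, the trial is then simulated and analysed as usual, and
#' the proportion of significant results estimates the power averaged
#' over the prior (sometimes called assurance).
#'
#' @inheritParams estimate_power
#' @param priors Named list of priors; names among `"effect"`,
#'   `"baseline"`, `"icc"`, `"between_sd"`, `"individual_sd"`,
#'   `"slope_sd"`. Each prior is `list(dist = "uniform", min = a,
#'   max = b)`; a degenerate prior (`min == max`) is a point mass and
#'   reproduces [estimate_power()].
#' @return A `"power_estimate"` (expected power over the prior).
#' @export
bayesian_power <- function(design, model, spec, priors, S = 1000,
                           seed = NULL, cohort = FALSE) {
  stopifnot(inherits(design, "swt_design"), inherits(model, "outcome_model"),
            inherits(spec, "analysis_spec"))
  validate_priors(priors)
  if (!is_count(S) || S < 100)
    stop("'S' must be an integer >= 100", call. = FALSE)
  seeds <- trial_seeds(seed, S)
  n_sig <- 0L
  n_nc <- 0L
  for (s in seq_len(S)) {
    if (!is.null(seeds[[s]])) set.seed(seeds[[s]])
    m_s <- model
    for (nm in names(priors)) {
      pr <- priors[[nm]]
      value <- stats::runif(1, pr$min, pr$max)
      m_s <- set_model_parameter(m_s, nm, value)
    }
    dat <- simulate_trial(design, m_s, cohort = cohort, seed = NULL)
    fit <- fit_swt(dat, spec)
    if (!isTRUE(fit$converged)) n_nc <- n_nc + 1L
    if (wald_significant(fit, spec$alpha)) n_sig <- n_sig + 1L
  }
  new_power_estimate(n_sig, S, n_nc,
                     settings = list(priors = priors, family = model$family,
                                     n_clusters = design$n_clusters,
                                     cohort = cohort, seed = seed))
}

validate_priors <- function(priors) {
  allowed <- c("effect", "baseline", "icc", "between_sd", "individual_sd",
               "slope_sd")
  if (!is.list(priors) || is.null(names(priors)) ||
      !all(names(priors) %in% allowed))
    stop("'priors' must be a named list over: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  for (nm in names(priors)) {
    pr <- priors[[nm]]
    if (!identical(pr$dist, "uniform") || is.null(pr$min) || is.null(pr$max)
        || pr$min > pr$max)
      stop("prior on '", nm, "' must be list(dist = 'uniform', min, max) ",
           "with min <= max", call. = FALSE)
    if (nm %in% c("between_sd", "individual_sd", "slope_sd") && pr$min < 0)
      stop("prior on '", nm, "' has negative support", call. = FALSE)
    if (nm == "icc" && (pr$min < 0 || pr$max >= 1))
      stop("prior on 'icc' must be supported inside [0, 1)", call. = FALSE)
  }
  invisible(priors)
}

set_model_parameter <- function(model, name, value) {
  vc <- model$vc
  switch(name,
    effect = { model$effect <- value },
    baseline = { model$baseline <- value },
    icc = {
      model$vc <- variance_components(value,
        if (vc$input_mode == "total") vc$sigma2_y else vc$sigma2_e,
        vc$input_mode, individual_var = vc$sigma2_v,
        slope_var = vc$sigma2_u)
    },
    between_sd = {
      # hold the within variance fixed and set sigma2_a = value^2
      s2a <- value^2
      model$vc <- variance_components(s2a / (s2a + vc$sigma2_e),
        vc$sigma2_e, "within", individual_var = vc$sigma2_v,
        slope_var = vc$sigma2_u)
    },
    individual_sd = {
      model$vc <- variance_components(vc$icc,
        if (vc$input_mode == "total") vc$sigma2_y else vc$sigma2_e,
        vc$input_mode, individual_var = value^2, slope_var = vc$sigma2_u)
    },
    slope_sd = {
      model$vc <- variance_components(vc$icc,
        if (vc$input_mode == "total") vc$sigma2_y else vc$sigma2_e,
        vc$input_mode, individual_var = vc$sigma2_v, slope_var = value^2)
    })
  model
}
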