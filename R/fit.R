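#' Analysis model specification
#'
#' Describes the mixed model fitted to a (simulated or real) stepped wedge
#' dataset: the outcome family, how calendar time is adjusted for, which
#' random terms are included and the test size. In a correctly specified
#' analysis these match the data-generating [outcome_model()]; mismatches
#' (e.g. omitting a real time trend) are allowed on purpose, to study
#' misspecification.
#'
#' @param family `"normal"`, `"bernoulli"` or `"poisson"`.
#' @param time_adjustment `"categorical"` (one indicator per time, the
#'   default), `"linear"` (a single slope) or `"none"`.
#' @param random_terms Character subset of `"cluster"`, `"individual"`,
#'   `"cluster-slope"`. `"individual"` is only meaningful for closed-cohort
#'   data; `"cluster-slope"` adds an independent random intervention effect.
#' @param alpha Two-sided significance level of the Wald test.
#' @return An object of class `"analysis_spec"`.
#' @export
analysis_spec <- function(family = c("normal", "bernoulli", "poisson"),
                          time_adjustment = c("categorical", "linear", "none"),
                          random_terms = "cluster", alpha = 0.05) {
  family <- match.arg(family)
  time_adjustment <- match.arg(time_adjustment)
  bad <- setdiff(random_terms, c("cluster", "individual", "cluster-slope"))
  if (length(bad))
    stop("unknown random term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  structure(list(family = family, time_adjustment = time_adjustment,
                 random_terms = random_terms, alpha = alpha),
            class = "analysis_spec")
}

swt_fit_formula <- function(spec) {
  time_term <- switch(spec$time_adjustment,
                      categorical = "factor(time)", linear = "time",
                      none = NULL)
  ran <- character()
  if ("cluster" %in% spec$random_terms) ran <- c(ran, "(1 | cluster)")
  if ("individual" %in% spec$random_terms)
    ran <- c(ran, "(1 | individual)")
  if ("cluster-slope" %in% spec$random_terms)
    ran <- c(ran, "(0 + treatment | cluster)")
  if (!length(ran))
    stop("at least one random term is required", call. = FALSE)
  stats::as.formula(paste("outcome ~",
                          paste(c("1", time_term, "treatment", ran),
                                collapse = " + ")))
}

#' Fit the analysis model to a trial dataset
#'
#' Fits the mixed model described by an [analysis_spec()] to a long-format
#' dataset (columns `cluster`, `time`, `individual`, `treatment`,
#' `outcome`) and returns the Wald test for the intervention effect.
#' Normal outcomes are fitted by maximum likelihood ([lme4::lmer()] with
#' `REML = FALSE`, so the Wald statistic matches the likelihood the power
#' formula is based on); bernoulli and poisson outcomes by the Laplace
#' approximation to maximum likelihood ([lme4::glmer()], `nAGQ = 1`).
#' These fitting methods are held fixed throughout the package. The Wald reference distribution is
#' the standard normal (a known small-sample liberality, matching the
#' analytic power formula).
#'
#' Fits never raise on numerical trouble: optimizer failures are returned
#' with `converged = FALSE` and the captured diagnostics; variance
#' estimates on the zero boundary are legitimate fits, flagged `singular`
#' but converged.
#'
#' @param data A dataset from [simulate_trial()] (or any data frame with
#'   the same columns).
#' @param spec An [analysis_spec()].
#' @return An object of class `"swt_fit"`: a list with `estimate` (the
#'   intervention effect on the link scale), `se`, `wald_z`, `wald_p`,
#'   `converged`, `singular`, `variance_estimates` (named, per random term,
#'   plus `residual` for normal outcomes) and `messages`.
#' @export
fit_swt <- function(data, spec) {
  stopifnot(inherits(spec, "analysis_spec"))
  need <- c("cluster", "time", "individual", "treatment", "outcome")
  if (!all(need %in% names(data)))
    stop("'data' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  fml <- swt_fit_formula(spec)
  msgs <- character()
  fit <- withCallingHandlers(
    tryCatch({
      if (spec$family == "normal") {
        lme4::lmer(fml, data = data, REML = FALSE)
      } else {
        fam <- if (spec$family == "bernoulli") stats::binomial()
               else stats::poisson()
        lme4::glmer(fml, data = data, family = fam, nAGQ = 1L)
      }
    }, error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  if (inherits(fit, "error")) {
    return(structure(list(estimate = NA_real_, se = NA_real_,
                          wald_z = NA_real_, wald_p = NA_real_,
                          converged = FALSE, singular = NA,
                          variance_estimates = NULL,
                          messages = c(msgs, conditionMessage(fit))),
                     class = "swt_fit"))
  }
  est <- lme4::fixef(fit)[["treatment"]]
  se <- sqrt(diag(as.matrix(stats::vcov(fit)))[["treatment"]])
  z <- est / se
  # boundary (singular) fits are legitimate converged fits; only genuine
  # optimizer trouble counts as non-convergence
  conv_msgs <- unlist(fit@optinfo$conv$lme4$messages)
  real_trouble <- conv_msgs[!grepl("boundary \\(singular\\)", conv_msgs)]
  opt_ok <- isTRUE(fit@optinfo$conv$opt == 0) && length(real_trouble) == 0
  vcs <- as.data.frame(lme4::VarCorr(fit))
  var_est <- stats::setNames(vcs$vcov,
                             ifelse(is.na(vcs$var1), vcs$grp,
                                    paste(vcs$grp, vcs$var1, sep = ".")))
  structure(list(estimate = est, se = se, wald_z = z,
                 wald_p = 2 * stats::pnorm(-abs(z)),
                 converged = opt_ok, singular = lme4::isSingular(fit),
                 variance_estimates = var_est, messages = msgs),
            class = "swt_fit")
}

#' @export
print.swt_fit <- function(x, ...) {
  cat(sprintf(
    "Intervention effect: %.4f (SE %.4f), Wald z = %.3f, p = %.4g%s%s\n",
    x$estimate, x$se, x$wald_z, x$wald_p,
    if (isTRUE(x$singular)) " [singular]" else "",
    if (!isTRUE(x$converged)) " [NOT converged]" else ""))
  invisible(x)
}

#' Wald significance decision
#'
#' `TRUE` iff the fit converged and `|estimate| / se` strictly exceeds
#' `z_{alpha/2}`; ties at the critical value and non-converged fits count
#' as non-significant (the conservative policy used by the power engine).
#'
#' @param fit An [fit_swt()] result.
#' @param alpha Two-sided significance level.
#' @return Logical flag.
#' @export
wald_significant <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "swt_fit"))
  if (!isTRUE(fit$converged) || !is.finite(fit$wald_z)) return(FALSE)
  abs(fit$wald_z) > stats::qnorm(1 - alpha / 2)
}
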