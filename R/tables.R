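#' Worked sample-size grids for the three calculation routes
#'
#' Recomputes the package's two reference grids of cluster requirements for
#' 80 % power at a standardised effect size of about 0.25, across outcome
#' families and ICC values, for a stepped wedge design with `J = 6` times
#' (one baseline plus 5 crossovers) and `K = 20` subjects per cluster-period:
#'
#' * `"table1"` compares routes that start from a parallel two-arm RCT size
#'   (CRT inflation factor at `K = 20` and `K = 120`; Woertman design
#'   effect) with the Hussey-Hughes analytic search, all on the
#'   total-variance convention.
#' * `"table2"` uses the within-cluster variance convention (the natural
#'   input scale for non-normal simulation) and reports the Hussey-Hughes
#'   analytic search, optionally alongside the simulation-based search.
#'
#' The worked settings are: continuous — effect -0.3785, SD 1.55;
#' binary — baseline probability 0.26, odds ratio 0.56;
#' count — baseline rate 1.5, rate ratio 0.8. The parallel-RCT base sizes
#' for the design-effect routes are 253, 243 and 236 per arm respectively.
#' Cells whose analytic power lands within rounding distance of the target
#' at one fewer cluster (power >= 0.795 at `I - 1`) carry a note, since
#' published values for such cells depend on whether power was rounded to
#' two decimals.
#'
#' @param which `"table1"` or `"table2"`.
#' @param simulate For `"table2"`, also run the simulation-based
#'   minimum-cluster search (slow; roughly `S` mixed-model fits per
#'   candidate cluster count).
#' @param S,seed Simulation size and master seed, when `simulate = TRUE`.
#' @return A tidy data frame with columns `family`, `icc`, `method`,
#'   `clusters`, `power` (analytic power at the reported size, where
#'   defined) and `note`.
#' @export
reproduce_table <- function(which = c("table1", "table2"),
                            simulate = FALSE, S = 1000, seed = NULL) {
  which <- match.arg(which)
  iccs <- seq(0, 0.5, by = 0.1)
  fams <- c("continuous", "binary", "count")
  # worked-example parameters
  theta_c <- -0.3785; sd_y <- 1.55
  p0 <- 0.26; p1 <- binary_risk_from_or(p0, 0.56)
  l0 <- 1.5; l1 <- 1.5 * 0.8
  rct_per_arm <- c(continuous = 253, binary = 243, count = 236)
  eff <- c(continuous = theta_c, binary = p1 - p0, count = l1 - l0)
  mode <- if (which == "table1") "total" else "within"
  vc_for <- function(fam, icc) switch(fam,
    continuous = variance_components(icc, sd_y^2, mode),
    binary = binary_variance_components(p0, p1, icc, mode),
    count = count_variance_components(l0, l1, icc, mode))
  rows <- list()
  add <- function(fam, icc, method, clusters, power = NA_real_,
                  note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      family = fam, icc = icc, method = method, clusters = clusters,
      power = power, note = note, stringsAsFactors = FALSE)
  }
  for (fam in fams) for (icc in iccs) {
    if (which == "table1") {
      n_rct <- 2L * rct_per_arm[[fam]]
      add(fam, icc, "crt_k20", crt_required_clusters(n_rct, 20, icc))
      add(fam, icc, "crt_k120", crt_required_clusters(n_rct, 120, icc))
      add(fam, icc, "woertman",
          woertman_required_clusters(n_rct, icc, n_crossovers = 5,
                                     times_per_step = 1, baseline_times = 1,
                                     per_time_size = 20))
    }
    vc <- vc_for(fam, icc)
    hh <- hh_min_clusters(vc, eff[[fam]], n_times = 6, cluster_size = 20)
    note <- ""
    if (hh$n_clusters > 2) {
      d_below <- swt_design(allocate_clusters(hh$n_clusters - 1L, 5L), 6, 20)
      p_below <- hh_power(d_below, vc, eff[[fam]])
      if (p_below >= 0.795)
        note <- sprintf(
          "power %.4f at %d clusters: rounds to 0.80 at two decimals",
          p_below, hh$n_clusters - 1L)
    }
    add(fam, icc, "hh", hh$n_clusters, hh$power, note)
    if (which == "table2" && simulate) {
      fam_map <- c(continuous = "normal", binary = "bernoulli",
                   count = "poisson")
      m <- switch(fam,
        continuous = outcome_model("normal", 0.3, theta_c, vc),
        binary = outcome_model("bernoulli", stats::qlogis(p0), log(0.56), vc),
        count = outcome_model("poisson", log(l0), log(0.8), vc))
      a <- analysis_spec(fam_map[[fam]])
      sr <- find_min_clusters(m, a, n_times = 6, cluster_size = 20,
                              threshold = 0.8, S = S, seed = seed)
      add(fam, icc, "simulation", sr$n_clusters, sr$power)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
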