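#' Incidence table for the Moulton log-rank design effect
#'
#' Per-time counts of new cases and numbers at risk in the control (`0`) and
#' intervention (`1`) arms. Entries are non-negative and each arm's cases
#' cannot exceed its at-risk count; non-integer values are permitted so that
#' *expected* counts (e.g. from [expected_incidence()]) can be represented.
#'
#' @param time Time indices (1..J).
#' @param d0,d1 New cases at each time in untreated / treated clusters.
#' @param Y0,Y1 Numbers at risk at each time in untreated / treated clusters.
#' @return A data frame of class `"incidence_table"` with columns
#'   `time, d0, d1, Y0, Y1`.
#' @seealso [moulton_logrank()], [moulton_de()]
#' @export
incidence_table <- function(time, d0, d1, Y0, Y1) {
  n <- length(time)
  if (!all(lengths(list(d0, d1, Y0, Y1)) == n))
    stop("all columns must have the same length", call. = FALSE)
  tab <- data.frame(time = time, d0 = d0, d1 = d1, Y0 = Y0, Y1 = Y1)
  if (any(tab[-1] < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(tab$d0 > tab$Y0 + 1e-9) || any(tab$d1 > tab$Y1 + 1e-9))
    stop("new cases cannot exceed the number at risk", call. = FALSE)
  class(tab) <- c("incidence_table", "data.frame")
  tab
}

#' @rdname incidence_table
#' @param file Path to a CSV file with header `time,d0,d1,Y0,Y1`.
#' @export
read_incidence_table <- function(file) {
  tab <- utils::read.csv(file)
  need <- c("time", "d0", "d1", "Y0", "Y1")
  if (!all(need %in% names(tab)))
    stop("incidence CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  incidence_table(tab$time, tab$d0, tab$d1, tab$Y0, tab$Y1)
}

#' @rdname incidence_table
#' @param tab An `incidence_table`.
#' @export
write_incidence_table <- function(tab, file) {
  stopifnot(inherits(tab, "incidence_table"))
  utils::write.csv(as.data.frame(tab), file, row.names = FALSE)
  invisible(file)
}

#' Log-rank statistic from an incidence table
#'
#' The standardized log-rank statistic comparing treated with untreated
#' clusters over discrete times:
#' \deqn{Z = \frac{\sum_j \left[d^1_j - Y^1_j (d^*_j / Y^*_j)\right]}
#'  {\sqrt{\sum_j \frac{Y^1_j}{Y^*_j}\left(1 - \frac{Y^1_j}{Y^*_j}\right)
#'   \frac{Y^*_j - d^*_j}{Y^*_j - 1} d^*_j}}}
#' with `d*_j = d0_j + d1_j` and `Y*_j = Y0_j + Y1_j`. Times with
#' `Y*_j <= 1` carry no information and contribute zero to both sums.
#'
#' @param tab An [incidence_table()].
#' @return The signed statistic `Z` (positive when the treated arm has an
#'   excess of cases over expectation).
#' @examples
#' moulton_logrank(incidence_table(1, d0 = 0, d1 = 1, Y0 = 10, Y1 = 10))
#' @export
moulton_logrank <- function(tab) {
  stopifnot(inherits(tab, "incidence_table"))
  Ys <- tab$Y0 + tab$Y1
  ds <- tab$d0 + tab$d1
  use <- Ys > 1
  if (!any(use))
    stop("degenerate incidence table: no time has at least 2 at risk",
         call. = FALSE)
  p1 <- tab$Y1[use] / Ys[use]
  num <- sum(tab$d1[use] - tab$Y1[use] * ds[use] / Ys[use])
  vr <- sum(p1 * (1 - p1) * (Ys[use] - ds[use]) / (Ys[use] - 1) * ds[use])
  if (vr <= 0)
    stop("degenerate incidence table: log-rank variance is zero ",
         "(no informative events)", call. = FALSE)
  num / sqrt(vr)
}

#' Moulton design effect for a stepped wedge trial
#'
#' Compares the log-rank statistic computed under the stepped wedge
#' (time-varying) allocation with the statistic computed under a standard
#' CRT allocation of the same clusters, on incidence tables generated from
#' the same event-rate scenario:
#' `DE = (Z_CRT / Z_SWT)^2`, a variance-inflation ratio. The two tables are
#' supplied by the caller; [expected_incidence()] produces matched
#' expected-count tables for a constant-hazard scenario.
#'
#' @param swt_table Incidence table under the stepped wedge allocation.
#' @param crt_table Incidence table under the parallel CRT allocation.
#' @return The design effect (positive scalar).
#' @export
moulton_de <- function(swt_table, crt_table) {
  z_swt <- moulton_logrank(swt_table)
  z_crt <- moulton_logrank(crt_table)
  if (z_swt == 0)
    stop("degenerate incidence table: stepped wedge statistic is zero",
         call. = FALSE)
  (z_crt / z_swt)^2
}

#' Incidence tables under a constant-hazard scenario
#'
#' Generates the per-time incidence table implied by a discrete-time
#' constant-hazard survival scenario on an allocation matrix: every cluster
#' starts with `cluster_size` subjects at risk; an untreated cluster-period
#' carries per-period event risk `p0`, a treated one
#' `1 - (1 - p0)^hazard_ratio` (proportional hazards on the discrete time
#' scale). Subjects leave the risk set at the period of their event. At each
#' time clusters are classified as treated or untreated by the current
#' column of the allocation matrix, so a stepped wedge matrix yields a
#' time-varying comparison and [crt_allocation_matrix()] the parallel-arms
#' one.
#'
#' `expected_incidence()` returns the deterministic expected counts;
#' `simulate_incidence()` draws binomial event counts with the same
#' structure.
#'
#' @param allocation_matrix 0/1 cluster-by-time matrix (an
#'   [swt_design()]`$treatment_matrix` or [crt_allocation_matrix()]).
#' @param cluster_size Subjects initially at risk per cluster.
#' @param p0 Per-period event probability under control, in (0, 1).
#' @param hazard_ratio Intervention hazard ratio (>0; < 1 is protective).
#' @return An [incidence_table()].
#' @export
expected_incidence <- function(allocation_matrix, cluster_size, p0,
                               hazard_ratio) {
  if (p0 <= 0 || p0 >= 1) stop("'p0' must be in (0, 1)", call. = FALSE)
  if (hazard_ratio <= 0) stop("'hazard_ratio' must be positive", call. = FALSE)
  X <- allocation_matrix
  p1 <- 1 - (1 - p0)^hazard_ratio
  I <- nrow(X); J <- ncol(X)
  at_risk <- rep.int(as.numeric(cluster_size), I)
  out <- matrix(0, J, 4, dimnames = list(NULL, c("d0", "d1", "Y0", "Y1")))
  for (j in seq_len(J)) {
    treated <- X[, j] == 1
    risk <- ifelse(treated, p1, p0)
    cases <- at_risk * risk
    out[j, "d0"] <- sum(cases[!treated]); out[j, "d1"] <- sum(cases[treated])
    out[j, "Y0"] <- sum(at_risk[!treated]); out[j, "Y1"] <- sum(at_risk[treated])
    at_risk <- at_risk - cases
  }
  incidence_table(seq_len(J), out[, "d0"], out[, "d1"],
                  out[, "Y0"], out[, "Y1"])
}

#' @rdname expected_incidence
#' @param seed Integer seed for the binomial draws.
#' @export
simulate_incidence <- function(allocation_matrix, cluster_size, p0,
                               hazard_ratio, seed) {
  if (p0 <= 0 || p0 >= 1) stop("'p0' must be in (0, 1)", call. = FALSE)
  if (hazard_ratio <= 0) stop("'hazard_ratio' must be positive", call. = FALSE)
  X <- allocation_matrix
  p1 <- 1 - (1 - p0)^hazard_ratio
  I <- nrow(X); J <- ncol(X)
  if (!missing(seed)) set.seed(seed)
  at_risk <- rep.int(as.integer(cluster_size), I)
  out <- matrix(0, J, 4, dimnames = list(NULL, c("d0", "d1", "Y0", "Y1")))
  for (j in seq_len(J)) {
    treated <- X[, j] == 1
    risk <- ifelse(treated, p1, p0)
    cases <- stats::rbinom(I, at_risk, risk)
    out[j, "d0"] <- sum(cases[!treated]); out[j, "d1"] <- sum(cases[treated])
    out[j, "Y0"] <- sum(at_risk[!treated]); out[j, "Y1"] <- sum(at_risk[treated])
    at_risk <- at_risk - cases
  }
  incidence_table(seq_len(J), out[, "d0"], out[, "d1"],
                  out[, "Y0"], out[, "Y1"])
}
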