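#' Allocate clusters to crossover points
#'
#' Distributes `n_clusters` clusters over `n_crossovers` sequential crossover
#' points. Under the default `"even-earliest"` rule each crossover receives
#' `floor(n_clusters / n_crossovers)` clusters and any remainder is assigned,
#' one cluster each, to the earliest crossover points (with fewer clusters
#' than crossovers, the latest crossovers are left empty). An `"explicit"`
#' allocation passes a user-supplied vector through unchanged, e.g. to place
#' empty crossovers elsewhere for sensitivity studies.
#'
#' @param n_clusters Total number of clusters `I` (positive integer).
#' @param n_crossovers Number of crossover points, i.e. one fewer than the
#'   total number of measurement times (positive integer).
#' @param rule `"even-earliest"` (default) or `"explicit"`.
#' @param allocation For `rule = "explicit"`, a vector of non-negative
#'   integers of length `n_crossovers` summing to `n_clusters`.
#' @return Integer vector of length `n_crossovers` summing to `n_clusters`:
#'   the number of clusters switching to intervention at each crossover.
#' @examples
#' allocate_clusters(10, 5)  # 2,2,2,2,2
#' allocate_clusters(13, 5)  # 3,3,3,2,2
#' @export
allocate_clusters <- function(n_clusters, n_crossovers,
                              rule = c("even-earliest", "explicit"),
                              allocation = NULL) {
  rule <- match.arg(rule)
  if (!is_count(n_clusters) || !is_count(n_crossovers))
    stop("'n_clusters' and 'n_crossovers' must be positive integers",
         call. = FALSE)
  if (rule == "even-earliest") {
    base <- n_clusters %/% n_crossovers
    rem <- n_clusters %% n_crossovers
    out <- rep.int(base, n_crossovers)
    if (rem > 0L) out[seq_len(rem)] <- out[seq_len(rem)] + 1L
    return(as.integer(out))
  }
  if (is.null(allocation) || length(allocation) != n_crossovers ||
      any(allocation < 0) || any(allocation != round(allocation)))
    stop("explicit 'allocation' must be ", n_crossovers,
         " non-negative integers", call. = FALSE)
  if (sum(allocation) != n_clusters)
    stop("explicit 'allocation' must sum to 'n_clusters'", call. = FALSE)
  as.integer(allocation)
}

#' Construct a stepped wedge trial design
#'
#' Builds the binary treatment-allocation matrix `X` of a complete stepped
#' wedge design with `I = sum(allocation)` clusters and `n_times` measurement
#' times. Time is 1-based with time 1 the baseline at which every cluster is
#' in the control condition; a cluster assigned to crossover `c` has
#' `X[i, j] = 1` for every `j >= c + 1` (once treated, always treated).
#'
#' @param allocation Clusters switching at each crossover; length must equal
#'   `n_times - 1`. See [allocate_clusters()].
#' @param n_times Total number of measurement times `J`, including the
#'   baseline.
#' @param cluster_size Individuals measured per cluster at each time, `K`.
#' @return An object of class `"swt_design"`: a list with `n_clusters`,
#'   `n_times`, `cluster_size`, `allocation` and the `I x J` integer
#'   `treatment_matrix`.
#' @examples
#' d <- swt_design(allocate_clusters(9, 5), n_times = 6, cluster_size = 20)
#' d
#' @export
swt_design <- function(allocation, n_times, cluster_size) {
  if (!is_count(n_times) || n_times < 2L)
    stop("'n_times' must be an integer >= 2", call. = FALSE)
  if (!is_count(cluster_size))
    stop("'cluster_size' must be a positive integer", call. = FALSE)
  if (length(allocation) != n_times - 1L)
    stop("length(allocation) must equal n_times - 1 (one entry per ",
         "crossover point)", call. = FALSE)
  if (any(allocation < 0) || any(allocation != round(allocation)) ||
      sum(allocation) < 1)
    stop("'allocation' must be non-negative integers with a positive sum",
         call. = FALSE)
  allocation <- as.integer(allocation)
  I <- sum(allocation)
  X <- matrix(0L, nrow = I, ncol = n_times)
  crossover <- rep.int(seq_along(allocation), allocation)
  for (i in seq_len(I)) {
    first <- crossover[i] + 1L
    X[i, first:n_times] <- 1L
  }
  structure(
    list(n_clusters = I, n_times = as.integer(n_times),
         cluster_size = as.integer(cluster_size),
         allocation = allocation, treatment_matrix = X),
    class = "swt_design")
}

#' @export
print.swt_design <- function(x, ...) {
  cat("Stepped wedge design:", x$n_clusters, "clusters x", x$n_times,
      "times,", x$cluster_size, "per cluster-period\n")
  cat("Allocation at crossovers:", paste(x$allocation, collapse = ", "), "\n")
  cat("Treated cluster-periods per time:",
      paste(colSums(x$treatment_matrix), collapse = ", "), "\n")
  invisible(x)
}

#' Design matrix summaries U, W, V
#'
#' The three scalar summaries of the treatment matrix that enter the
#' Hussey-Hughes variance: `U` is the total number of treated cluster-periods,
#' `W` the sum of squared column (time) totals and `V` the sum of squared row
#' (cluster) totals.
#'
#' @param design An [swt_design()] object, or a bare 0/1 matrix.
#' @return A list with integer components `U`, `W` and `V`.
#' @examples
#' design_summaries(swt_design(c(2, 2, 2, 2, 2), 6, 20))  # U=30, W=220, V=110
#' @export
design_summaries <- function(design) {
  X <- if (inherits(design, "swt_design")) design$treatment_matrix else design
  if (!is.matrix(X) || !all(X %in% c(0, 1)))
    stop("'design' must be an swt_design or a 0/1 matrix", call. = FALSE)
  list(U = as.integer(sum(X)),
       W = as.integer(sum(colSums(X)^2)),
       V = as.integer(sum(rowSums(X)^2)))
}

#' Read and write stepped wedge designs as CSV
#'
#' The on-disk format is a plain CSV 0/1 matrix: one row per cluster, one
#' column per measurement time, with a header row of time labels
#' (`t1, ..., tJ`). The cluster size is carried in a leading comment line
#' `# cluster_size: K`.
#'
#' @param design An [swt_design()] object.
#' @param file Path to the CSV file.
#' @return `read_swt_design()` returns an [swt_design()] object;
#'   `write_swt_design()` returns `file` invisibly.
#' @export
write_swt_design <- function(design, file) {
  stopifnot(inherits(design, "swt_design"))
  X <- design$treatment_matrix
  colnames(X) <- paste0("t", seq_len(ncol(X)))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# cluster_size: ", design$cluster_size), con)
  utils::write.csv(as.data.frame(X), con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_swt_design
#' @export
read_swt_design <- function(file) {
  header <- readLines(file, n = 1L)
  K <- if (grepl("^# cluster_size:", header))
    as.integer(sub("^# cluster_size:\\s*", "", header)) else 1L
  X <- as.matrix(utils::read.csv(file, comment.char = "#"))
  if (!all(X %in% c(0L, 1L)))
    stop("design file must contain only 0/1 entries", call. = FALSE)
  rows_ok <- apply(X, 1L, function(r) all(diff(r) >= 0L))
  if (any(X[, 1L] != 0L) || !all(rows_ok))
    stop("design file is not a valid stepped wedge allocation (baseline ",
         "column must be 0 and rows non-decreasing)", call. = FALSE)
  first_treated <- apply(X, 1L, function(r) match(1L, r))
  allocation <- tabulate(first_treated - 1L, nbins = ncol(X) - 1L)
  swt_design(allocation, n_times = ncol(X), cluster_size = K)
}

#' Parallel cluster-randomised comparator allocation
#'
#' Builds the treatment matrix of a parallel CRT on the same measurement grid
#' as a stepped wedge trial: `n_treated` clusters receive the intervention at
#' every time (including the first) and the remainder never do. Used as the
#' comparator scenario for the Moulton log-rank design effect.
#'
#' @param n_clusters Total clusters.
#' @param n_treated Clusters in the intervention arm (default: half,
#'   rounded up).
#' @param n_times Measurement times.
#' @return An `n_clusters x n_times` 0/1 integer matrix.
#' @export
crt_allocation_matrix <- function(n_clusters, n_treated = ceiling(n_clusters / 2),
                                  n_times) {
  if (!is_count(n_clusters) || !is_count(n_times) ||
      n_treated < 0 || n_treated > n_clusters)
    stop("invalid CRT allocation arguments", call. = FALSE)
  X <- matrix(0L, n_clusters, n_times)
  if (n_treated > 0) X[seq_len(n_treated), ] <- 1L
  X
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}
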