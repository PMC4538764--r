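#' Run a structured sample-size configuration
#'
#' Executes one sample-size or power calculation described by a structured
#' config (a YAML file or an equivalent nested list) and writes its results
#' as a tidy CSV plus a log of every resolved parameter and seed, so the
#' run is self-describing and re-runnable. The config is validated against
#' the chosen method before any computation; on a validation failure no
#' output file is written.
#'
#' Supported methods and their blocks:
#' * `hh` — analytic power/size: `model` (family and its parameters,
#'   `icc`, `mode`), `design` (`n_times`, `cluster_size`, optionally
#'   `n_clusters` for a power evaluation instead of a search), `engine`
#'   (`target_power`, `alpha`).
#' * `crt-de` — CRT inflation: `de` (`rct_total`, `n_per_cluster`, `icc`).
#' * `woertman` — Woertman design effect: `de` (`rct_total`, `icc`,
#'   `n_crossovers`, `times_per_step`, `baseline_times`, `per_time_size`).
#' * `moulton` — log-rank design effect: `moulton` (`swt_table`,
#'   `crt_table`, CSV paths).
#' * `simulate` — Monte Carlo power: `model`, `design` (with
#'   `n_clusters`), `analysis`, `engine` (`S`, `seed`).
#' * `search` — simulated minimum clusters: as `simulate` plus
#'   `engine$threshold`.
#' * `tables` — the worked grids: `tables` (`which`).
#'
#' @param config Path to a YAML file, or a named list with the same
#'   structure.
#' @param out_dir Directory for `results.csv` and `run.log` (created if
#'   missing).
#' @return Invisibly, the results data frame (also written to
#'   `<out_dir>/results.csv`).
#' @export
run_swt_config <- function(config, out_dir = ".") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg) || is.null(cfg$method))
    stop("config must be a list/YAML mapping with a 'method' field",
         call. = FALSE)
  methods <- c("hh", "crt-de", "woertman", "moulton", "simulate", "search",
               "tables")
  if (!cfg$method %in% methods)
    stop("field 'method' must be one of: ", paste(methods, collapse = ", "),
         call. = FALSE)
  # validate + compute first; only then touch the filesystem
  res <- switch(cfg$method,
    "hh" = run_cfg_hh(cfg),
    "crt-de" = run_cfg_crt(cfg),
    "woertman" = run_cfg_woertman(cfg),
    "moulton" = run_cfg_moulton(cfg),
    "simulate" = run_cfg_simulate(cfg),
    "search" = run_cfg_search(cfg),
    "tables" = run_cfg_tables(cfg))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  num <- vapply(res$table, is.numeric, TRUE) &
    !vapply(res$table, is.integer, TRUE)
  res$table[num] <- lapply(res$table[num], round, digits = 4L)
  tmp <- tempfile(tmpdir = out_dir, fileext = ".csv")
  utils::write.csv(res$table, tmp, row.names = FALSE)
  file.rename(tmp, file.path(out_dir, "results.csv"))
  log <- c("swtpower run", paste0("method: ", cfg$method), "resolved config:",
           strsplit(yaml::as.yaml(res$resolved), "\n")[[1]])
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(res$table)
}

need_fields <- function(block, fields, where) {
  missing <- setdiff(fields, names(block))
  if (length(missing))
    stop("config field(s) missing in '", where, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  block
}

# family parameters -> analytic effect (outcome scale) + variance components
cfg_analytic_inputs <- function(model) {
  need_fields(model, c("family", "icc"), "model")
  mode <- if (is.null(model$mode)) "within" else model$mode
  icc <- model$icc
  switch(model$family,
    continuous = {
      need_fields(model, c("effect", "sd"), "model")
      list(effect = model$effect,
           vc = variance_components(icc, model$sd^2, mode))
    },
    binary = {
      need_fields(model, c("p0"), "model")
      p1 <- if (!is.null(model$p1)) model$p1 else {
        need_fields(model, "odds_ratio", "model")
        binary_risk_from_or(model$p0, model$odds_ratio)
      }
      list(effect = p1 - model$p0,
           vc = binary_variance_components(model$p0, p1, icc, mode))
    },
    count = {
      need_fields(model, c("lambda0"), "model")
      l1 <- if (!is.null(model$lambda1)) model$lambda1 else {
        need_fields(model, "rate_ratio", "model")
        model$lambda0 * model$rate_ratio
      }
      list(effect = l1 - model$lambda0,
           vc = count_variance_components(model$lambda0, l1, icc, mode))
    },
    stop("model 'family' must be continuous, binary or count",
         call. = FALSE))
}

# family parameters -> simulation outcome_model (link scale)
cfg_sim_model <- function(model) {
  inp <- cfg_analytic_inputs(model)
  te <- if (is.null(model$time)) time_effect("none") else
    do.call(time_effect, model$time)
  vc <- inp$vc
  if (!is.null(model$individual_var) || !is.null(model$slope_var)) {
    vc <- variance_components(vc$icc,
      if (vc$input_mode == "total") vc$sigma2_y else vc$sigma2_e,
      vc$input_mode,
      individual_var = if (is.null(model$individual_var)) 0 else
        model$individual_var,
      slope_var = if (is.null(model$slope_var)) 0 else model$slope_var)
  }
  switch(model$family,
    continuous = outcome_model("normal",
      baseline = if (is.null(model$baseline)) 0 else model$baseline,
      effect = model$effect, vc = vc, time = te),
    binary = outcome_model("bernoulli",
      baseline = stats::qlogis(model$p0),
      effect = if (!is.null(model$odds_ratio)) log(model$odds_ratio) else
        stats::qlogis(model$p1) - stats::qlogis(model$p0),
      vc = vc, time = te),
    count = outcome_model("poisson",
      baseline = log(model$lambda0),
      effect = if (!is.null(model$rate_ratio)) log(model$rate_ratio) else
        log(model$lambda1 / model$lambda0),
      vc = vc, time = te))
}

cfg_engine <- function(cfg) {
  eng <- if (is.null(cfg$engine)) list() else cfg$engine
  utils::modifyList(list(S = 1000L, seed = NULL, threshold = 0.8,
                         target_power = 0.8, alpha = 0.05), eng)
}

cfg_analysis <- function(cfg, family) {
  blk <- if (is.null(cfg$analysis)) list() else cfg$analysis
  fam_map <- c(continuous = "normal", binary = "bernoulli",
               count = "poisson")
  analysis_spec(fam_map[[family]],
                time_adjustment = if (is.null(blk$time_adjustment))
                  "categorical" else blk$time_adjustment,
                random_terms = if (is.null(blk$random_terms)) "cluster" else
                  unlist(blk$random_terms),
                alpha = if (is.null(blk$alpha)) 0.05 else blk$alpha)
}

run_cfg_hh <- function(cfg) {
  need_fields(cfg, c("model", "design"), "config")
  design <- need_fields(cfg$design, c("n_times", "cluster_size"), "design")
  inp <- cfg_analytic_inputs(cfg$model)
  eng <- cfg_engine(cfg)
  if (!is.null(design$n_clusters)) {
    d <- swt_design(allocate_clusters(design$n_clusters,
                                      design$n_times - 1L),
                    design$n_times, design$cluster_size)
    pw <- hh_power(d, inp$vc, inp$effect, eng$alpha)
    tab <- data.frame(method = "hh", family = cfg$model$family,
                      icc = cfg$model$icc, clusters = design$n_clusters,
                      power = pw)
  } else {
    r <- hh_min_clusters(inp$vc, inp$effect, design$n_times,
                         design$cluster_size, eng$target_power, eng$alpha)
    tab <- data.frame(method = "hh", family = cfg$model$family,
                      icc = cfg$model$icc, clusters = r$n_clusters,
                      power = r$power)
  }
  list(table = tab, resolved = list(method = "hh", model = cfg$model,
                                    design = design, engine = eng))
}

run_cfg_crt <- function(cfg) {
  de <- need_fields(cfg$de, c("rct_total", "n_per_cluster", "icc"), "de")
  tab <- data.frame(method = "crt-de", icc = de$icc,
                    design_effect = crt_design_effect(de$n_per_cluster,
                                                      de$icc),
                    clusters = crt_required_clusters(de$rct_total,
                                                     de$n_per_cluster,
                                                     de$icc))
  list(table = tab, resolved = list(method = "crt-de", de = de))
}

run_cfg_woertman <- function(cfg) {
  de <- need_fields(cfg$de, c("rct_total", "icc", "n_crossovers"), "de")
  de <- utils::modifyList(list(times_per_step = 1L, baseline_times = 1L,
                               per_time_size = 1L), de)
  tab <- data.frame(
    method = "woertman", icc = de$icc,
    cf = woertman_cf(de$icc, de$n_crossovers, de$times_per_step,
                     de$baseline_times, de$per_time_size),
    design_effect = woertman_de(de$icc, de$n_crossovers, de$times_per_step,
                                de$baseline_times, de$per_time_size),
    clusters = woertman_required_clusters(de$rct_total, de$icc,
                                          de$n_crossovers, de$times_per_step,
                                          de$baseline_times,
                                          de$per_time_size))
  list(table = tab, resolved = list(method = "woertman", de = de))
}

run_cfg_moulton <- function(cfg) {
  blk <- need_fields(cfg$moulton, c("swt_table", "crt_table"), "moulton")
  swt <- read_incidence_table(blk$swt_table)
  crt <- read_incidence_table(blk$crt_table)
  tab <- data.frame(method = "moulton",
                    z_swt = moulton_logrank(swt),
                    z_crt = moulton_logrank(crt),
                    design_effect = moulton_de(swt, crt))
  list(table = tab, resolved = list(method = "moulton", moulton = blk))
}

run_cfg_simulate <- function(cfg) {
  need_fields(cfg, c("model", "design"), "config")
  design <- need_fields(cfg$design,
                        c("n_clusters", "n_times", "cluster_size"), "design")
  m <- cfg_sim_model(cfg$model)
  a <- cfg_analysis(cfg, cfg$model$family)
  eng <- cfg_engine(cfg)
  cohort <- isTRUE(cfg$design$cohort)
  d <- swt_design(allocate_clusters(design$n_clusters, design$n_times - 1L),
                  design$n_times, design$cluster_size)
  pe <- estimate_power(d, m, a, S = eng$S, seed = eng$seed, cohort = cohort)
  tab <- data.frame(method = "simulate", family = cfg$model$family,
                    icc = cfg$model$icc, clusters = design$n_clusters,
                    power = pe$power, mc_se = pe$mc_se, n_sims = pe$n_sims,
                    n_nonconverged = pe$n_nonconverged)
  list(table = tab, resolved = list(method = "simulate", model = cfg$model,
                                    design = design, engine = eng))
}

run_cfg_search <- function(cfg) {
  need_fields(cfg, c("model", "design"), "config")
  design <- need_fields(cfg$design, c("n_times", "cluster_size"), "design")
  m <- cfg_sim_model(cfg$model)
  a <- cfg_analysis(cfg, cfg$model$family)
  eng <- cfg_engine(cfg)
  sr <- find_min_clusters(m, a, design$n_times, design$cluster_size,
                          threshold = eng$threshold, S = eng$S,
                          seed = eng$seed,
                          cohort = isTRUE(cfg$design$cohort))
  tab <- cbind(data.frame(method = "search", family = cfg$model$family,
                          icc = cfg$model$icc), sr$trajectory)
  list(table = tab, resolved = list(method = "search", model = cfg$model,
                                    design = design, engine = eng))
}

run_cfg_tables <- function(cfg) {
  blk <- need_fields(cfg$tables, "which", "tables")
  tab <- reproduce_table(blk$which)
  list(table = tab, resolved = list(method = "tables", tables = blk))
}
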