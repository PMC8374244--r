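# Output logging, summary analysis, replicate-count analysis, grouped
# one-at-a-time sensitivity analysis, and scenario sweeps.

#' Gini index
#'
#' Relative mean absolute difference divided by two.  Negative values
#' (indebted households) are clamped at zero before the index is computed;
#' the index is zero when every value is equal and lies in [0, 1].
#'
#' @param values Numeric vector (household cash stocks).
#' @return Gini index in [0, 1].
#' @export
gini <- function(values) {
  if (!length(values)) stop("gini of an empty vector")
  x <- pmax(values, 0)
  if (mean(x) == 0) return(0)
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

## ---- run logs ----------------------------------------------------------------

#' Write a run's CSV log
#'
#' One CSV per run, named by [encode_run_name()] unless \code{path} is
#' given.  The file holds four sections, each introduced by a
#' \code{#SECTION <name>} marker line followed by a CSV header and rows:
#' \code{scenario} (settings and seed), \code{yields} (annual multipliers),
#' \code{events}, \code{households} and \code{villagers} (daily state).
#'
#' @param result A [run_simulation()] result (run with \code{log_data=TRUE}).
#' @param dir Output directory (created if missing).
#' @param path Optional explicit file path overriding \code{dir}/name.
#' @return The file path, invisibly.
#' @export
write_run_log <- function(result, dir = ".", path = NULL) {
  if (is.null(result$hh_log))
    stop("run was executed without log_data; nothing to write")
  if (is.null(path)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    path <- file.path(dir, encode_run_name(result$config$scenario,
                                           result$config$seed))
  }
  sc <- result$config$scenario
  cat("#SECTION scenario\n",
      "earthquake,fertility_rate,crop_variability,seed,length_days\n",
      paste(sc$earthquake, sc$fertility_rate, sc$crop_variability,
            result$config$seed, result$config$simulation_length_days,
            sep = ","), "\n",
      sep = "", file = path)
  ym <- result$yields
  ydt <- data.table::data.table(
    year = rep(rownames(ym), ncol(ym)),
    crop = rep(colnames(ym), each = nrow(ym)),
    multiplier = as.vector(ym))
  sections <- list(yields = ydt, events = result$events,
                   households = result$hh_log, villagers = result$vill_log)
  for (sec in names(sections)) {
    cat("#SECTION ", sec, "\n", sep = "", file = path, append = TRUE)
    dt <- sections[[sec]]
    if (is.null(dt)) next
    cat(paste(names(dt), collapse = ","), "\n", sep = "", file = path,
        append = TRUE)
    data.table::fwrite(dt, path, append = TRUE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a run log written by [write_run_log()]
#' @param path File path.
#' @return Named list of data.tables, one per section.
#' @export
read_run_log <- function(path) {
  lines <- readLines(path)
  marks <- grep("^#SECTION ", lines)
  out <- list()
  for (i in seq_along(marks)) {
    name <- sub("^#SECTION ", "", lines[marks[i]])
    from <- marks[i] + 1L
    to <- if (i < length(marks)) marks[i + 1L] - 1L else length(lines)
    if (to < from) { out[[name]] <- NULL; next }
    out[[name]] <- data.table::fread(text = lines[from:to])
  }
  out
}

#' Recompute the eight summary statistics from a run log
#' @param log A [read_run_log()] result.
#' @return Named list matching \code{run_simulation()$summary}.
#' @export
summary_from_log <- function(log) {
  hdt <- log$households
  last <- hdt[hdt$day == max(hdt$day)]
  daily_debt <- hdt[, list(in_debt = sum(debt > 0)), by = "day"]
  ever <- hdt[, list(ever = any(debt > 0)), by = "hh"]
  list(final_households = nrow(last),
       mean_household_size = mean(last$size),
       final_villagers = nrow(log$villagers[
         log$villagers$day == max(log$villagers$day)]),
       household_debt_days = sum(daily_debt$in_debt),
       households_ever_in_debt = sum(ever$ever),
       total_household_cash = sum(last$cash),
       total_household_loans = sum(last$debt + last$recon_loan),
       gini_household_cash = gini(last$cash))
}

## ---- replicate-count analysis (coefficient of variation) ---------------------

#' Coefficient of variation versus number of replicates
#'
#' For each n, the coefficient of variation (sd/mean) of a summary metric
#' over the first n runs; used to judge how many replicates a scenario
#' needs (the original analysis found the CV of its metrics largely
#' stabilises by 200 runs, the recommended minimum).
#'
#' @param values Numeric vector of per-run metric values, in run order.
#' @return data.table with columns \code{n} and \code{cv} (NA where
#'   undefined: n < 2 or zero mean).
#' @export
cv_vs_runs <- function(values) {
  if (length(values) < 2) stop("need at least two replicates")
  n <- seq_along(values)
  cv <- vapply(n, function(k) {
    if (k < 2) return(NA_real_)
    m <- mean(values[1:k])
    if (m == 0) return(NA_real_)
    stats::sd(values[1:k]) / m
  }, numeric(1))
  data.table::data.table(n = n, cv = cv)
}

#' Recommended minimum replicate count
#' @export
recommended_replicates <- function() 200L

## ---- seed schedule and scenario sweeps ---------------------------------------

#' Deterministic seed for replicate i of a scenario
#'
#' \code{f(s, i)}: a stable hash of the scenario code XOR the replicate
#' index, kept below 2^31.
#'
#' @param settings [scenario_settings()].
#' @param i Replicate index (>= 1).
#' @return Integer seed.
#' @export
replicate_seed <- function(settings, i) {
  code <- encode_run_name(settings, 0)
  h <- 0
  for (ch in utf8ToInt(code)) h <- (h * 131 + ch) %% 2147483647
  as.integer(bitwXor(as.integer(h), as.integer(i)))
}

#' Run the eight-scenario sweep
#'
#' Simulates every scenario combination \code{n_runs} times, each replicate
#' with its deterministic seed, optionally writing one uniquely named CSV
#' log per run.
#'
#' @param n_runs Replicates per scenario combination.
#' @param out_dir Directory for CSV logs, or NULL to skip writing.
#' @param simulation_length_days Run length.
#' @param parameters Parameter overrides.
#' @param ... Further arguments to [sim_config()].
#' @return data.table of per-run summary statistics (one row per run).
#' @export
scenario_sweep <- function(n_runs = 1L, out_dir = NULL,
                           simulation_length_days = 5475L,
                           parameters = list(), ...) {
  rows <- list()
  for (sc in all_scenarios()) {
    for (i in seq_len(n_runs)) {
      seed <- replicate_seed(sc, i)
      cfg <- sim_config(seed = seed,
                        simulation_length_days = simulation_length_days,
                        scenario = sc, parameters = parameters,
                        log_data = !is.null(out_dir), ...)
      res <- run_simulation(cfg)
      if (!is.null(out_dir)) write_run_log(res, dir = out_dir)
      rows[[length(rows) + 1L]] <- c(
        list(file = encode_run_name(sc, i), replicate = i),
        res$summary)
    }
  }
  data.table::rbindlist(rows)
}

## ---- grouped OAT sensitivity analysis (Table 7 procedure) --------------------

#' Grouped one-at-a-time sensitivity analysis
#'
#' Runs \code{reps} baseline simulations with every parameter at its default
#' C value, then \code{reps} runs per parameter group at the group's upper
#' (C+) and lower (C-) extremes with all other parameters at C - a total of
#' \code{reps * (1 + 2 * length(groups))} runs.  For each of the eight
#' summary statistics it reports the percentage change of the mean relative
#' to baseline and the two-sided Mann-Whitney (Wilcoxon rank-sum) p-value.
#'
#' @param reps Replicates per condition (the original analysis used 200).
#' @param groups Parameter groups, as from [parameter_groups()].
#' @param scenario Scenario held fixed across conditions.
#' @param simulation_length_days Run length.
#' @param ... Further arguments to [sim_config()].
#' @return A list with \code{effects} (data.table: group, direction,
#'   statistic, baseline_mean, mean, pct_change, p_value) and
#'   \code{n_runs}.
#' @export
oat_sensitivity <- function(reps = 200L, groups = parameter_groups(),
                            scenario = scenario_settings(),
                            simulation_length_days = 5475L, ...) {
  if (reps < 2) stop("reps must be >= 2")
  stats_of <- function(parameters, tag) {
    t(vapply(seq_len(reps), function(i) {
      cfg <- sim_config(seed = replicate_seed(scenario, i) %% 2147483647L,
                        simulation_length_days = simulation_length_days,
                        scenario = scenario, parameters = parameters,
                        log_data = FALSE, ...)
      unlist(run_simulation(cfg)$summary)
    }, numeric(8)))
  }
  base_params <- list()
  for (g in groups) for (j in seq_len(nrow(g)))
    base_params[[g$parameter[j]]] <- g$C[j]
  baseline <- stats_of(base_params, "C")
  rows <- list()
  for (gn in names(groups)) {
    g <- groups[[gn]]
    for (dir in c("Cminus", "Cplus")) {
      pp <- base_params
      for (j in seq_len(nrow(g))) pp[[g$parameter[j]]] <- g[[dir]][j]
      res <- stats_of(pp, paste(gn, dir))
      for (statn in colnames(baseline)) {
        b <- baseline[, statn]; x <- res[, statn]
        p <- tryCatch(stats::wilcox.test(x, b, exact = FALSE)$p.value,
                      error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- list(
          group = gn, direction = if (dir == "Cminus") "C-" else "C+",
          statistic = statn, baseline_mean = mean(b), mean = mean(x),
          pct_change = if (mean(b) != 0) 100 * (mean(x) - mean(b)) / abs(mean(b))
                       else NA_real_,
          p_value = p)
      }
    }
  }
  list(effects = data.table::rbindlist(rows),
       n_runs = as.integer(reps) * (1L + 2L * length(groups)),
       reps = reps, alpha = 0.05)
}
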