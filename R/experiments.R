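#' Derive a reproducible run seed
#'
#' Deterministic seed derivation for grid cells and replicates: the base seed
#' is mixed with the level index, duration index and replicate number through
#' an exact 31-bit multiplicative hash, so any run of a sweep can be
#' reproduced in isolation and runs are independent of execution order.
#'
#' @param seed_base Integer base seed.
#' @param level_index,duration_index,replicate Non-negative integers
#'   identifying the run.
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(seed_base, level_index = 0, duration_index = 0,
                        replicate = 1) {
  M <- 2147483647
  h <- seed_base %% M
  for (x in c(level_index, duration_index, replicate)) {
    h <- (h * 48271) %% M
    h <- (h + x) %% M
  }
  h <- (h * 48271) %% M
  as.integer(h %% (M - 1) + 1)
}

#' Run one simulation
#'
#' Initializes a founder population and iterates the per-step engine through
#' the full schedule: burn-in, disruption window, and the 30,000-step
#' recovery period, capturing observer records at time-points A (end of
#' burn-in, immediately prior to disruption onset), B (last disrupted step),
#' C1 and C2. A run that reaches zero individuals terminates early and is
#' flagged extinct; records after extinction are absent.
#'
#' @param p A `sim_params` object.
#' @param seed RNG seed for the run; defaults to `p$seed`.
#' @param log_births If `TRUE`, birth events are logged and a burn-in
#'   generation-time estimate is attached.
#' @return A `sim_run` object: list with `params`, `schedule`, `records`
#'   (data frame of captured time-points), `extinct`, `extinction_time`,
#'   `final_state`, and when logged, `birth_log` and
#'   `generation_time_estimate`.
#' @export
run_single <- function(p, seed = p$seed, log_births = FALSE) {
  validate_params(p)
  if (!is.null(seed)) set.seed(seed)
  sched <- disruption_schedule(p)
  state <- initialize_population(p)
  capture_at <- c(sched$A, sched$B, sched$C1, sched$C2)
  out <- advance(state, p, sched, n_steps = sched$end,
                 capture_at = capture_at, log_births = log_births)
  build_run(p, sched, out, seed, log_births,
            labels = c(A = sched$A, B = sched$B, C1 = sched$C1,
                       C2 = sched$C2))
}

#' Run a disruption-free burn-in
#'
#' Runs the establishment period only (`burn_in` steps with zero
#' disruption), capturing a single record at its end — the state of the
#' evolved sexual-selection system at time-point A. Used by the calibration
#' search and by burn-in equilibrium checks.
#'
#' @inheritParams run_single
#' @return A `sim_run` object whose `records` holds at most the `A` row.
#' @export
run_burn_in <- function(p, seed = p$seed, log_births = FALSE) {
  validate_params(p)
  if (!is.null(seed)) set.seed(seed)
  p0 <- modify_params(p, disruption = 0)
  sched <- disruption_schedule(p0)
  state <- initialize_population(p0)
  out <- advance(state, p0, sched, n_steps = p0$burn_in,
                 capture_at = p0$burn_in, log_births = log_births)
  build_run(p0, sched, out, seed, log_births, labels = c(A = p0$burn_in))
}

build_run <- function(p, sched, out, seed, log_births, labels) {
  recmat <- attr(out, "records")
  records <- data.frame(label = character(0))
  if (nrow(recmat) > 0) {
    idx <- match(unname(labels), recmat[, "t"])
    keep <- !is.na(idx)
    records <- data.frame(label = names(labels)[keep],
                          recmat[idx[keep], , drop = FALSE],
                          stringsAsFactors = FALSE)
    rownames(records) <- NULL
  }
  run <- list(params = p, schedule = sched, seed = seed,
              records = records,
              extinct = attr(out, "extinct"),
              extinction_time = attr(out, "extinction_time"),
              final_state = out)
  if (log_births) {
    run$birth_log <- attr(out, "births")
    bl <- run$birth_log[run$birth_log$t < p$burn_in, , drop = FALSE]
    run$generation_time_estimate <-
      if (nrow(bl) > 0) mean(bl$mother_age) else NA_real_
  }
  class(run) <- "sim_run"
  run
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("<sim_run> seed %s, %s at t = %s\n",
              format(x$seed),
              if (x$extinct) "EXTINCT" else "completed",
              format(if (x$extinct) x$extinction_time else x$schedule$end)))
  if (nrow(x$records) > 0) print(x$records, digits = 4)
  invisible(x)
}

#' Specify a disruption sweep
#'
#' The experiment grid: every combination of disruption level and duration,
#' each replicated with independently seeded runs. The published design is
#' levels 0 to 0.7 by 0.1, durations 500 to 5000 by 500 and 100 replicates
#' (8000 runs per mutation setting).
#'
#' @param disruption_levels Numeric grid of disruption magnitudes.
#' @param durations Integer grid of disruption durations (steps).
#' @param replicates Runs per grid cell.
#' @param preference_mutation Preference mutation setting for the whole sweep.
#' @param base_params `sim_params` supplying all other values.
#' @param seed_base Base seed for [derive_seed()].
#' @return A `sweep_spec` object.
#' @export
sweep_spec <- function(disruption_levels = seq(0, 0.7, by = 0.1),
                       durations = seq(500, 5000, by = 500),
                       replicates = 100,
                       preference_mutation = 0.001,
                       base_params = sim_params(),
                       seed_base = 1) {
  stopifnot(length(disruption_levels) > 0, length(durations) > 0,
            replicates >= 1)
  validate_params(base_params)
  structure(list(disruption_levels = disruption_levels,
                 durations = durations,
                 replicates = as.integer(replicates),
                 preference_mutation = preference_mutation,
                 base_params = base_params,
                 seed_base = as.integer(seed_base)),
            class = "sweep_spec")
}

#' Run a disruption sweep
#'
#' Executes every run of the grid with deterministically derived seeds and
#' stacks one row per run: the cell, the seed, the extinction outcome and
#' all time-point observables (absent — `NA` — after extinction). With a
#' `checkpoint_dir` each completed cell is persisted as CSV and a re-run
#' resumes from the completed cells.
#'
#' @param spec A `sweep_spec`.
#' @param checkpoint_dir Optional directory for per-cell checkpoints.
#' @param progress If `TRUE`, one status line per cell on standard error.
#' @return A data frame (the sweep table), one row per run.
#' @export
run_sweep <- function(spec, checkpoint_dir = NULL, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir))
    dir.create(checkpoint_dir, recursive = TRUE)
  rows <- list()
  for (i in seq_along(spec$disruption_levels)) {
    for (j in seq_along(spec$durations)) {
      cell_file <- if (!is.null(checkpoint_dir))
        file.path(checkpoint_dir, sprintf("cell_%02d_%02d.csv", i, j))
      if (!is.null(checkpoint_dir) && file.exists(cell_file)) {
        rows[[length(rows) + 1]] <- read_sweep_table(cell_file)
        next
      }
      cell_rows <- lapply(seq_len(spec$replicates), function(r) {
        seed <- derive_seed(spec$seed_base, i, j, r)
        p <- modify_params(spec$base_params,
                           disruption = spec$disruption_levels[i],
                           disruption_duration = spec$durations[j],
                           preference_mutation = spec$preference_mutation)
        run <- run_single(p, seed = seed)
        sweep_row(run, replicate = r)
      })
      cell <- do.call(rbind, cell_rows)
      if (progress)
        message(sprintf("cell disruption=%g duration=%d: %d/%d extinct",
                        spec$disruption_levels[i], spec$durations[j],
                        sum(cell$extinct), nrow(cell)))
      if (!is.null(checkpoint_dir)) write_results(cell, cell_file)
      rows[[length(rows) + 1]] <- cell
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

sweep_row <- function(run, replicate) {
  base <- data.frame(disruption = run$params$disruption,
                     duration = run$params$disruption_duration,
                     preference_mutation = run$params$preference_mutation,
                     replicate = replicate,
                     seed = run$seed,
                     extinct = run$extinct,
                     extinction_time = if (run$extinct)
                       run$extinction_time else NA_integer_)
  obs <- c("n", "n_males", "n_females", "n_juveniles",
           "mean_pref_pat", "mean_pref_mat", "mean_viab_pat",
           "mean_viab_mat", "mean_signal_males")
  for (lab in c("A", "B", "C1", "C2")) {
    row <- run$records[run$records$label == lab, , drop = FALSE]
    vals <- if (nrow(row) == 1) as.numeric(row[1, obs]) else
      rep(NA_real_, length(obs))
    base[paste0(lab, "_", obs)] <- as.list(vals)
  }
  base
}

#' Pearson correlation with t-based test
#'
#' Sample Pearson correlation and the two-sided p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   non-zero variance.
#' @return List with `r`, `p_value` and `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx == 0 || syy == 0)
    stop("degenerate input: a vector with zero variance has no correlation")
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Calibration correlation between evolved preference and signal
#'
#' The calibration statistic of the parameter search: runs disruption-free
#' burn-ins and correlates, across runs, the final population mean of the
#' preference trait with the final mean male signal. Strong positive
#' correlation indicates settings under which female preference co-evolves
#' with the male signal, i.e. established inter-sexual selection. Runs that
#' end with no individuals (or no males) are excluded and counted.
#'
#' @param p A `sim_params` object (the setting under test).
#' @param n_runs Number of calibration runs (the published search used 200
#'   per setting).
#' @param seed_base Base seed; run `r` uses `derive_seed(seed_base, 0, 0, r)`.
#' @return List with `r`, `p_value`, `n_used`, `n_excluded`.
#' @export
calibration_correlation <- function(p, n_runs = 200, seed_base = 1) {
  stopifnot(n_runs >= 3)
  pref <- sig <- numeric(0)
  excluded <- 0L
  for (r in seq_len(n_runs)) {
    run <- run_burn_in(p, seed = derive_seed(seed_base, 0, 0, r))
    pop <- run$final_state$pop
    males <- pop[, "sex"] == 1
    if (run$extinct || nrow(pop) == 0 || !any(males)) {
      excluded <- excluded + 1L
      next
    }
    pref <- c(pref, mean(pop[, "preference"]))
    sig <- c(sig, mean(pop[males, "signal"]))
  }
  pc <- pearson_correlation(pref, sig)
  list(r = pc$r, p_value = pc$p_value, n_used = pc$n,
       n_excluded = excluded)
}

#' Summarise extinction proportions
#'
#' Tabulates extinction outcomes of a sweep table overall or by a factor:
#' disruption level, disruption duration, or the binned level of the mean
#' paternal preference allele at time-point A (fixed bin width 0.025).
#'
#' @param table A sweep table from [run_sweep()].
#' @param by One of `"overall"`, `"disruption"`, `"duration"`,
#'   `"preference_bin"`.
#' @param bin_width Bin width for `"preference_bin"`.
#' @return Data frame with columns `level`, `n`, `n_extinct`, `proportion`.
#' @export
extinction_summary <- function(table,
                               by = c("overall", "disruption", "duration",
                                      "preference_bin"),
                               bin_width = 0.025) {
  by <- match.arg(by)
  if (nrow(table) == 0) stop("empty sweep table")
  fac <- switch(by,
    overall = rep("overall", nrow(table)),
    disruption = table$disruption,
    duration = table$duration,
    preference_bin = floor(table$A_mean_pref_pat / bin_width) * bin_width)
  agg <- aggregate(table$extinct, by = list(level = fac),
                   FUN = function(e) c(n = length(e), n_extinct = sum(e)))
  out <- data.frame(level = agg$level,
                    n = agg$x[, "n"],
                    n_extinct = agg$x[, "n_extinct"])
  out$proportion <- out$n_extinct / out$n
  out
}
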