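#' Deterministic per-replicate seeds
#'
#' Derives `n` replicate seeds from one master seed by seeding R's RNG
#' with the master seed and sampling without replacement from the 31-bit
#' integer range. Replicate `k` of a given master seed is therefore fixed
#' and can be re-run in isolation.
#'
#' @param master_seed Integer master seed.
#' @param n Number of replicate seeds.
#' @return Integer vector of length `n`.
#' @export
replicate_seeds <- function(master_seed, n) {
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max, n)
}

#' Run an ensemble of independent replicates
#'
#' Repeats [run_simulation()] with per-replicate seeds derived from
#' `master_seed` via [replicate_seeds()] and summarizes host, virus and
#' nutrient trajectories across replicates by per-time-step mean and
#' standard deviation.
#'
#' @param params A [sim_params()] object.
#' @param n_reps Number of replicates (>= 1).
#' @param master_seed Master seed the replicate seeds derive from.
#' @param keep_trajectories Retain the individual `sim_trajectory`
#'   objects (memory permitting) in the result.
#' @param n_bins Gene-histogram bin count passed to each run.
#' @return An `ensemble_summary`: list with `records` (data frame `t`,
#'   `mean_Nh`, `sd_Nh`, `mean_Nv`, `sd_Nv`, `mean_Pd`, `sd_Pd`),
#'   `n_reps`, `master_seed`, `params`, `mean_hist` (per-gene mean
#'   histogram counts across replicates) and optionally `trajectories`.
#' @export
run_ensemble <- function(params, n_reps, master_seed,
                         keep_trajectories = FALSE, n_bins = 50L) {
  stopifnot(n_reps >= 1L)
  np <- if (inherits(params, "sim_params_norm")) params else normalize_params(params)
  seeds <- replicate_seeds(master_seed, n_reps)
  runs <- lapply(seeds, function(s) run_simulation(np, seed = s, n_bins = n_bins))

  get <- function(col) vapply(runs, function(r) r$records[[col]], numeric(np$T + 1L))
  Nh <- get("N_h"); Nv <- get("N_v"); Pd <- get("P_d")
  sd0 <- function(m) if (ncol(m) > 1L) apply(m, 1L, stats::sd) else rep(0, nrow(m))
  rec <- data.frame(t = runs[[1L]]$records$t,
                    mean_Nh = rowMeans(Nh), sd_Nh = sd0(Nh),
                    mean_Nv = rowMeans(Nv), sd_Nv = sd0(Nv),
                    mean_Pd = rowMeans(Pd), sd_Pd = sd0(Pd))
  mean_hist <- lapply(c(g_alpha = "g_alpha", g_nu = "g_nu", g_beta = "g_beta"),
                      function(g) {
                        Reduce(`+`, lapply(runs, function(r) r$hist[[g]])) / n_reps
                      })
  out <- list(records = rec, n_reps = as.integer(n_reps),
              master_seed = as.integer(master_seed), seeds = seeds,
              params = np, n_bins = as.integer(n_bins),
              mean_hist = mean_hist,
              trajectories = if (keep_trajectories) runs else NULL)
  class(out) <- "ensemble_summary"
  out
}

#' @export
print.ensemble_summary <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("Ensemble of %d replicates, %d h (master seed %d)\n",
              x$n_reps, n - 1L, x$master_seed))
  cat(sprintf("  final mean N_h = %.1f (sd %.1f), mean N_v = %.1f (sd %.1f)\n",
              x$records$mean_Nh[n], x$records$sd_Nh[n],
              x$records$mean_Nv[n], x$records$sd_Nv[n]))
  invisible(x)
}

#' Specify a one-parameter sweep
#'
#' @param param Name of the swept field of [sim_params()], or `"VHR"`
#'   to sweep the initial virus-to-host ratio by scaling `N_v0` at fixed
#'   `N_h0`.
#' @param values Numeric values the parameter takes.
#' @param n_reps Replicates per value.
#' @param base_params Base parameter set the sweep perturbs.
#' @param master_seed Master seed; each grid point gets an independent,
#'   deterministic sub-seed.
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(param, values, n_reps, base_params = sim_params(),
                       master_seed = 1L) {
  if (!identical(param, "VHR") && !param %in% names(unclass(base_params))) {
    stop(sprintf("unknown swept parameter '%s'", param), call. = FALSE)
  }
  stopifnot(length(values) >= 1L, n_reps >= 1L)
  for (v in values) {
    p <- apply_sweep_value(base_params, param, v)
    bad <- validate_params(p)
    if (length(bad) > 0L) {
      stop(sprintf("swept value %s = %g is invalid: %s", param, v, bad[1L]),
           call. = FALSE)
    }
  }
  structure(list(param = param, values = values, n_reps = as.integer(n_reps),
                 base_params = base_params,
                 master_seed = as.integer(master_seed)),
            class = "sweep_spec")
}

apply_sweep_value <- function(base_params, param, value) {
  p <- unclass(base_params)
  if (identical(param, "VHR")) {
    p$N_v0 <- as.integer(round(value * p$N_h0))
  } else if (param %in% c("T", "N_h0", "N_v0", "kappa")) {
    p[[param]] <- as.integer(round(value))
  } else {
    p[[param]] <- value
  }
  class(p) <- "sim_params"
  p
}

#' Run a parameter sweep
#'
#' One [run_ensemble()] per swept value. Grid points are independent:
#' each derives its own master seed deterministically from the sweep's
#' master seed, so results do not depend on execution order and any
#' point can be recomputed alone.
#'
#' @param spec A [sweep_spec()].
#' @param keep_trajectories Passed through to [run_ensemble()].
#' @return Named list of `ensemble_summary` objects (names are the swept
#'   values), with attributes `param` and `spec`.
#' @export
run_sweep <- function(spec, keep_trajectories = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  point_seeds <- replicate_seeds(spec$master_seed, length(spec$values))
  out <- vector("list", length(spec$values))
  names(out) <- as.character(spec$values)
  for (i in seq_along(spec$values)) {
    p <- apply_sweep_value(spec$base_params, spec$param, spec$values[i])
    out[[i]] <- run_ensemble(p, spec$n_reps, point_seeds[i],
                             keep_trajectories = keep_trajectories)
  }
  attr(out, "param") <- spec$param
  attr(out, "spec") <- spec
  out
}

#' Long-term closed/open x kernel factorial experiment
#'
#' Runs the full 2 x 2 x 2 factorial of {closed (`omega = 0`), open
#' (`omega = 0.2`)} x {trade-off, random} compatibility x {trade-off,
#' random} virulence over a long horizon (default 720 h = 30 days), one
#' ensemble per cell.
#'
#' @param base_params Base parameters; `T`, `omega` and the kernel modes
#'   are overridden per cell.
#' @param n_reps Replicates per cell.
#' @param master_seed Master seed; cells get independent deterministic
#'   sub-seeds.
#' @param T Horizon in hours.
#' @param omega_open Washout rate of the open-system cells, h^-1.
#' @return Data-frame-like list: `conditions` (data frame with `system`,
#'   `compatibility_mode`, `virulence_mode`, `outcome`) and `summaries`
#'   (list of 8 `ensemble_summary` objects in matching order).
#' @export
run_factorial_longterm <- function(base_params = sim_params(), n_reps = 20L,
                                   master_seed = 1L, T = 720L,
                                   omega_open = 0.2) {
  grid <- expand.grid(system = c("closed", "open"),
                      compatibility_mode = c("tradeoff", "random"),
                      virulence_mode = c("tradeoff", "random"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cell_seeds <- replicate_seeds(master_seed, nrow(grid))
  summaries <- vector("list", nrow(grid))
  outcome <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- unclass(base_params)
    p$T <- as.integer(T)
    p$omega <- if (grid$system[i] == "closed") 0 else omega_open
    p$compatibility_mode <- grid$compatibility_mode[i]
    p$virulence_mode <- grid$virulence_mode[i]
    class(p) <- "sim_params"
    summaries[[i]] <- run_ensemble(p, n_reps, cell_seeds[i])
    outcome[i] <- classify_outcome(summaries[[i]])
  }
  grid$outcome <- outcome
  list(conditions = grid, summaries = summaries)
}

#' Classify the long-term fate of an ensemble
#'
#' Labels an ensemble by its ensemble-mean final abundances against an
#' absolute threshold of one individual: both populations at or above
#' the threshold is `"coexistence"`, hosts only is `"host_only"`, and
#' neither is `"double_extinction"`.
#'
#' @param summary An `ensemble_summary`.
#' @param threshold Abundance threshold, individuals.
#' @return One of `"coexistence"`, `"host_only"`, `"double_extinction"`.
#' @export
classify_outcome <- function(summary, threshold = 1) {
  stopifnot(inherits(summary, "ensemble_summary"))
  n <- nrow(summary$records)
  h <- summary$records$mean_Nh[n] >= threshold
  v <- summary$records$mean_Nv[n] >= threshold
  if (h && v) "coexistence" else if (h) "host_only" else "double_extinction"
}

#' Flatten sweep results to a tidy data frame
#'
#' @param sweep Result of [run_sweep()].
#' @return Data frame with columns `swept_param`, `value`, `t`,
#'   `mean_Nh`, `sd_Nh`, `mean_Nv`, `sd_Nv`, `mean_Pd`.
#' @export
sweep_records <- function(sweep) {
  param <- attr(sweep, "param")
  do.call(rbind, lapply(names(sweep), function(v) {
    r <- sweep[[v]]$records
    data.frame(swept_param = param, value = as.numeric(v),
               r[c("t", "mean_Nh", "sd_Nh", "mean_Nv", "sd_Nv", "mean_Pd")])
  }))
}

#' Locate the crash-and-recovery structure of a host trajectory
#'
#' Infection cycles show a first bloom peak, a virus-driven crash, and a
#' recovery of (partially resistant) hosts. This helper finds the first
#' local maximum, the subsequent minimum (the crash), and the highest
#' point after the crash (the recovery peak, which may sit at the end of
#' the window while the population is still growing back).
#'
#' @param x Numeric trajectory (e.g. ensemble-mean host abundance), one
#'   value per time step starting at t = 0.
#' @return List with `first_peak`, `crash`, `recovery_peak` values and
#'   their times `first_peak_t`, `crash_t`, `recovery_peak_t` (hours).
#' @export
crash_recovery_stats <- function(x) {
  n <- length(x)
  stopifnot(n >= 3L)
  fp <- NA_integer_
  for (i in 2:(n - 1L)) {
    # bloom-scale local maximum; the height requirement ignores small
    # stochastic wiggles on rising ensemble means
    if (x[i] >= x[i - 1L] && x[i] > x[i + 1L] && x[i] >= 0.5 * max(x)) {
      fp <- i
      break
    }
  }
  if (is.na(fp)) fp <- which.max(x)  # monotone rise: bloom peak at the end
  crash <- fp - 1L + which.min(x[fp:n])
  rec <- crash - 1L + which.max(x[crash:n])
  list(first_peak = x[fp], first_peak_t = fp - 1L,
       crash = x[crash], crash_t = crash - 1L,
       recovery_peak = x[rec], recovery_peak_t = rec - 1L)
}
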