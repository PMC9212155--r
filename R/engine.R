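#' Construct a chemostat state by hand
#'
#' Mostly useful for testing the individual simulation rounds in
#' isolation; [init_simulation()] builds the state a run actually starts
#' from. Hosts are column-bound vectors of biomass `m` (host-equivalent
#' phosphorus units) and nutrient-affinity gene `g_alpha`; viruses of
#' host-range gene `g_nu` and adsorption gene `g_beta`. `P_d0` is the
#' dissolved-phosphorus level that inflowing medium relaxes towards.
#'
#' @param time Simulated time, hours.
#' @param P_d Dissolved phosphorus, host-equivalent units.
#' @param P_d0 Initial (inflow) dissolved phosphorus level.
#' @param m,g_alpha Host biomass and gene vectors (equal length).
#' @param g_nu,g_beta Virus gene vectors (equal length).
#' @param cumulative_inflow,cumulative_outflow Phosphorus ledger terms.
#' @return A `chemostat_state` list.
#' @export
chemostat_state <- function(time = 0, P_d = 0, P_d0 = P_d,
                            m = numeric(0), g_alpha = numeric(0),
                            g_nu = numeric(0), g_beta = numeric(0),
                            cumulative_inflow = 0, cumulative_outflow = 0) {
  stopifnot(length(m) == length(g_alpha), length(g_nu) == length(g_beta),
            P_d >= 0)
  structure(list(time = time, P_d = P_d, P_d0 = P_d0,
                 cumulative_inflow = cumulative_inflow,
                 cumulative_outflow = cumulative_outflow,
                 m = as.numeric(m), g_alpha = as.numeric(g_alpha),
                 g_nu = as.numeric(g_nu), g_beta = as.numeric(g_beta)),
            class = "chemostat_state")
}

as_state <- function(x) structure(x, class = "chemostat_state")

#' Initialize a simulation state
#'
#' Inoculates the chemostat: `N_h0` hosts, each with gene `g_alpha0` and
#' biomass drawn uniformly from `[1/2, 1]`; `N_v0` identical viruses with
#' genes `(g_nu0, g_beta0)`; dissolved phosphorus set to the total budget
#' minus the inoculated biomass. Uses the current R RNG stream, so call
#' `set.seed()` first for reproducibility.
#'
#' @param nparams Normalized parameters from [normalize_params()].
#' @return A `chemostat_state`.
#' @export
init_simulation <- function(nparams) {
  stopifnot(inherits(nparams, "sim_params_norm"))
  as_state(cpp_init_state(nparams))
}

#' Simulation rounds
#'
#' The three phases of one 1 h time step, exposed individually (mainly
#' for testing; [run_simulation()] loops over them internally).
#' `nutrient_update()` relaxes dissolved phosphorus towards its inflow
#' level at rate `omega`. `host_round()` processes every host in random
#' order: washout, death (biomass recycled), metabolic loss, Monod growth
#' drawing on the shared nutrient pool, and division with possible
#' mutation once biomass exceeds 1. `virus_round()` processes every
#' virion in random order: washout, decay, then a scan over surviving
#' hosts in random order where each pair infects with probability
#' C x V; the first infection lyses the host (biomass recycled), consumes
#' the virion and buffers `kappa` progeny that join the population after
#' the round. `step_simulation()` runs the three in sequence and advances
#' time by one hour.
#'
#' @param state A `chemostat_state`.
#' @param nparams Normalized parameters from [normalize_params()].
#' @return The updated `chemostat_state`.
#' @name rounds
NULL

#' @rdname rounds
#' @export
nutrient_update <- function(state, nparams) {
  as_state(cpp_nutrient_update(state, nparams))
}

#' @rdname rounds
#' @export
host_round <- function(state, nparams) {
  as_state(cpp_host_round(state, nparams))
}

#' @rdname rounds
#' @export
virus_round <- function(state, nparams) {
  as_state(cpp_virus_round(state, nparams))
}

#' @rdname rounds
#' @export
step_simulation <- function(state, nparams) {
  as_state(cpp_step(state, nparams))
}

#' Run one stochastic simulation
#'
#' Initializes the chemostat and advances it `T` one-hour steps,
#' recording population sizes, the nutrient pool, mean gene values and
#' binned gene distributions at every step (including t = 0). With the
#' 1 uL reference volume, recorded abundances are directly cells (or
#' virions) per microlitre.
#'
#' @param params A [sim_params()] object (validated and normalized
#'   internally), or an already-normalized `sim_params_norm`.
#' @param seed Integer seed for the run; every stochastic draw derives
#'   from it.
#' @param n_bins Number of equal-width bins on `[0, 1]` used for the
#'   recorded gene histograms (trait-diversity bookkeeping).
#' @param snapshot_times Integer vector of times (hours) at which full
#'   per-individual biomass/gene vectors are retained.
#' @return A `sim_trajectory` object: list with `records` (data frame
#'   with one row per time step: `t`, `N_h`, `N_v`, `P_d`, total host
#'   biomass `M_h`, mean genes, phosphorus ledger), `hist` (per-gene
#'   `n_bins x (T+1)` count matrices), `snapshots`, `params`, `n_bins`
#'   and `seed`.
#' @examples
#' \donttest{
#' tr <- run_simulation(sim_params(T = 36L), seed = 1)
#' tr
#' }
#' @export
run_simulation <- function(params, seed, n_bins = 50L,
                           snapshot_times = integer(0)) {
  np <- if (inherits(params, "sim_params_norm")) params else normalize_params(params)
  stopifnot(length(seed) == 1L, is.finite(seed), n_bins >= 1L)
  set.seed(as.integer(seed))
  raw <- cpp_run(np, np$T, as.integer(n_bins), as.integer(snapshot_times))
  rec <- as.data.frame(raw$records)
  traj <- list(records = rec,
               hist = list(g_alpha = raw$hist_g_alpha,
                           g_nu = raw$hist_g_nu,
                           g_beta = raw$hist_g_beta),
               snapshots = raw$snapshots,
               final_state = as_state(raw$final_state),
               params = np, n_bins = as.integer(n_bins),
               seed = as.integer(seed))
  class(traj) <- "sim_trajectory"
  traj
}

#' @export
print.sim_trajectory <- function(x, ...) {
  r <- x$records
  n <- nrow(r)
  cat(sprintf("Simulation trajectory: %d h, seed %d (%s compatibility, %s virulence)\n",
              n - 1L, x$seed, x$params$compatibility_mode, x$params$virulence_mode))
  cat(sprintf("  start: N_h = %d, N_v = %d, P_d = %.1f\n",
              as.integer(r$N_h[1]), as.integer(r$N_v[1]), r$P_d[1]))
  cat(sprintf("  end:   N_h = %d, N_v = %d, P_d = %.1f\n",
              as.integer(r$N_h[n]), as.integer(r$N_v[n]), r$P_d[n]))
  invisible(x)
}

#' Write / read a trajectory as tidy CSV
#'
#' One row per time step with the seed as leading column; numbers are
#' written at full double precision so a round-trip reproduces the
#' trajectory records exactly.
#'
#' @param trajectory A `sim_trajectory`.
#' @param path File path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a data frame.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "sim_trajectory"))
  d <- cbind(seed = trajectory$seed, trajectory$records)
  utils::write.csv(format(d, digits = 17, trim = TRUE, scientific = NA),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}
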