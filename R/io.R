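#' Load simulation parameters from a YAML configuration file
#'
#' The configuration dialect is YAML with one top-level key per
#' [sim_params()] field, named exactly as the function arguments
#' (`T`, `t_step`, `V`, `P`, `P_h`, `omega`, `N_h0`, `N_v0`, `alpha`,
#' `mu_h`, `g_alpha0`, `pi_h`, `sigma_h`, `delta_h`, `eps_h`, `beta`,
#' `g_nu0`, `g_beta0`, `pi_v`, `sigma_v`, `kappa`, `delta_v`,
#' `compatibility_mode`, `virulence_mode`, `gene_floor_eps`). Absent
#' keys take the package defaults; unknown keys are an error; the
#' resulting parameter set is validated before being returned.
#'
#' @param path Path to the YAML file. An empty file yields the defaults.
#' @param quiet Suppress the provenance message listing the overrides.
#' @return A validated [sim_params()] object.
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a YAML mapping of parameter: value",
                          call. = FALSE)
  known <- names(formals(sim_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  for (k in names(cfg)) {
    want_char <- k %in% c("compatibility_mode", "virulence_mode")
    if (want_char && !is.character(cfg[[k]])) {
      stop(sprintf("config key '%s' must be a string", k), call. = FALSE)
    }
    if (!want_char && !is.numeric(cfg[[k]])) {
      stop(sprintf("config key '%s' must be numeric", k), call. = FALSE)
    }
  }
  p <- do.call(sim_params, cfg)
  bad <- validate_params(p)
  if (length(bad) > 0L) {
    stop(sprintf("invalid configuration (%s):\n  %s", path,
                 paste(bad, collapse = "\n  ")), call. = FALSE)
  }
  if (!quiet) {
    ov <- if (length(cfg) > 0L) paste(names(cfg), collapse = ", ") else "none"
    message(sprintf("loaded config %s (overrides: %s)", path, ov))
  }
  p
}

#' Read a plate-reader OD600 timeseries CSV
#'
#' Reads the layout used for the companion infection experiment: optical
#' density at 600 nm as a proxy for host abundance, recorded per
#' virus-to-host-ratio (VHR) group as replicate count, mean and standard
#' deviation over time. Expected columns (case-insensitive): `time`,
#' `group`, `n`, `mean`, `sd`. No unit conversion is attempted; OD600
#' serves only for qualitative side-by-side plotting against simulated
#' host trajectories.
#'
#' @param path CSV file path.
#' @return Named list of data frames (`time`, `n`, `mean`, `sd`), one
#'   per group, ordered as first encountered.
#' @export
read_experimental_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  d <- tryCatch(utils::read.csv(path, check.names = FALSE),
                error = function(e) stop("malformed experimental CSV: ",
                                         conditionMessage(e), call. = FALSE))
  names(d) <- tolower(names(d))
  need <- c("time", "group", "n", "mean", "sd")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0L) {
    stop(sprintf("experimental CSV lacks required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(d) == 0L) stop("experimental CSV contains no data rows", call. = FALSE)
  groups <- unique(as.character(d$group))
  out <- lapply(groups, function(g) {
    rows <- d[as.character(d$group) == g, c("time", "n", "mean", "sd")]
    rownames(rows) <- NULL
    rows
  })
  names(out) <- groups
  out
}

#' Write sweep or factorial results as tidy CSV
#'
#' @param x Result of [run_sweep()] (written via [sweep_records()]) or
#'   of [run_factorial_longterm()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(x, path) {
  d <- if (is.data.frame(x)) {
    x
  } else if (!is.null(attr(x, "param"))) {
    sweep_records(x)
  } else if (is.list(x) && !is.null(x$conditions) && !is.null(x$summaries)) {
    do.call(rbind, lapply(seq_len(nrow(x$conditions)), function(i) {
      r <- x$summaries[[i]]$records
      data.frame(system = x$conditions$system[i],
                 compat_mode = x$conditions$compatibility_mode[i],
                 virulence_mode = x$conditions$virulence_mode[i],
                 outcome_class = x$conditions$outcome[i],
                 r[c("t", "mean_Nh", "sd_Nh", "mean_Nv", "sd_Nv", "mean_Pd")])
    }))
  } else {
    stop("unsupported result object", call. = FALSE)
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
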