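#' Simulation parameters
#'
#' Constructs the full parameter set of the individual-based chemostat
#' model: environmental parameters (duration, volume, phosphorus budget,
#' dilution rate, inoculum sizes) and organismal parameters (host growth,
#' mortality and mutation; virus adsorption, burst size, decay and
#' mutation), plus the choice of infection kernels. Defaults are the
#' model's reference conditions for a 36 h infection cycle in a 1 uL
#' chemostat.
#'
#' Physical units: `P` in umol-P per litre, `P_h` in umol-P per cell,
#' `alpha` and `beta` in litres per hour, `V` in litres; all rates in
#' per hour. With a 1 h time step, rates act directly as per-step
#' probabilities (or fractions), which is why they must lie in `[0, 1]`.
#'
#' @param T Simulation duration, hours (integer; 36 by default, 720 for
#'   long-term experiments).
#' @param t_step Time step duration, hours. Must be 1; other values are
#'   rejected rather than rescaled.
#' @param V Chemostat volume, litres.
#' @param P Total phosphorus concentration, umol-P L^-1.
#' @param P_h Maximum phosphorus content of one host cell, umol-P.
#' @param omega Chemostat dilution (washout) rate, h^-1. Use 0 for a
#'   closed system.
#' @param N_h0,N_v0 Initial host and virus counts (individuals).
#' @param alpha Host nutrient affinity, L h^-1.
#' @param mu_h Maximum host growth rate, h^-1.
#' @param g_alpha0 Initial nutrient-affinity gene value in `[0, 1]`.
#' @param pi_h,sigma_h Host mutation probability and mutation standard
#'   deviation (per division event).
#' @param delta_h,eps_h Host mortality and metabolic loss rates, h^-1.
#' @param beta Virus adsorption coefficient, L h^-1.
#' @param g_nu0,g_beta0 Initial virus host-range (memory) and adsorption
#'   gene values in `[0, 1]`.
#' @param pi_v,sigma_v Virus mutation probability and standard deviation
#'   (per progeny virion).
#' @param kappa Burst size: progeny virions per lysed host.
#' @param delta_v Virus decay rate, h^-1.
#' @param compatibility_mode,virulence_mode `"tradeoff"` or `"random"`:
#'   which compatibility/virulence kernel governs infection.
#' @param gene_floor_eps Numerical floor applied to `g_nu` where it
#'   appears in a denominator.
#'
#' @return An object of class `sim_params`: a named list of all fields.
#' @seealso [normalize_params()], [validate_params()], [run_simulation()]
#' @examples
#' p <- sim_params()
#' p$N_v0 / p$N_h0  # initial virus-to-host ratio, 17.6
#' @export
sim_params <- function(T = 36L, t_step = 1, V = 1e-6, P = 71, P_h = 8.3e-8,
                       omega = 0.2, N_h0 = 46L, N_v0 = 810L,
                       alpha = 1.6e-7, mu_h = 0.738, g_alpha0 = 0.1,
                       pi_h = 6e-2, sigma_h = 5e-2,
                       delta_h = 1.4e-2, eps_h = 1.4e-2,
                       beta = 6.2e-11, g_nu0 = 0.1, g_beta0 = 0.1,
                       pi_v = 6e-3, sigma_v = 5e-3,
                       kappa = 10L, delta_v = 1.4e-2,
                       compatibility_mode = c("tradeoff", "random"),
                       virulence_mode = c("tradeoff", "random"),
                       gene_floor_eps = 1e-9) {
  p <- list(
    T = as.integer(T), t_step = t_step, V = V, P = P, P_h = P_h,
    omega = omega, N_h0 = as.integer(N_h0), N_v0 = as.integer(N_v0),
    alpha = alpha, mu_h = mu_h, g_alpha0 = g_alpha0,
    pi_h = pi_h, sigma_h = sigma_h, delta_h = delta_h, eps_h = eps_h,
    beta = beta, g_nu0 = g_nu0, g_beta0 = g_beta0,
    pi_v = pi_v, sigma_v = sigma_v,
    kappa = as.integer(kappa), delta_v = delta_v,
    compatibility_mode = match.arg(compatibility_mode),
    virulence_mode = match.arg(virulence_mode),
    gene_floor_eps = gene_floor_eps)
  class(p) <- "sim_params"
  p
}

#' Validate a parameter set
#'
#' Checks every model invariant and returns the violations found instead
#' of raising, so configuration errors can be reported together.
#' With a 1 h step, all rates double as per-step probabilities and must
#' lie in `[0, 1]`.
#'
#' @param params A [sim_params()] object (or plain named list with the
#'   same fields).
#' @return Character vector of human-readable violations; empty when the
#'   parameter set is valid.
#' @export
validate_params <- function(params) {
  p <- params
  bad <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) bad <<- c(bad, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

  for (f in c("T", "t_step", "V", "P", "P_h", "omega", "N_h0", "N_v0",
              "alpha", "mu_h", "g_alpha0", "pi_h", "sigma_h", "delta_h",
              "eps_h", "beta", "g_nu0", "g_beta0", "pi_v", "sigma_v",
              "kappa", "delta_v", "gene_floor_eps")) {
    if (!num1(p[[f]])) {
      bad <- c(bad, sprintf("%s: must be a single finite number", f))
    }
  }
  if (length(bad) > 0L) return(bad)

  chk(p$t_step == 1, "t_step: must equal 1 h (rates are used as per-step probabilities)")
  chk(p$T >= 0 && p$T == round(p$T), "T: must be a non-negative integer number of hours")
  chk(p$V > 0, "V: chemostat volume must be positive")
  chk(p$P >= 0, "P: total phosphorus concentration must be non-negative")
  chk(p$P_h > 0, "P_h: phosphorus content per host must be positive")
  for (f in c("omega", "mu_h", "delta_h", "eps_h", "delta_v")) {
    chk(p[[f]] >= 0 && p[[f]] <= 1,
        sprintf("%s: rate must lie in [0, 1] to act as a per-step probability", f))
  }
  for (f in c("pi_h", "pi_v")) {
    chk(p[[f]] >= 0 && p[[f]] <= 1, sprintf("%s: probability must lie in [0, 1]", f))
  }
  for (f in c("sigma_h", "sigma_v")) {
    chk(p[[f]] >= 0, sprintf("%s: standard deviation must be non-negative", f))
  }
  for (f in c("N_h0", "N_v0", "kappa")) {
    chk(p[[f]] >= 0 && p[[f]] == round(p[[f]]),
        sprintf("%s: must be a non-negative integer", f))
  }
  for (f in c("g_alpha0", "g_nu0", "g_beta0")) {
    chk(p[[f]] >= 0 && p[[f]] <= 1, sprintf("%s: gene value must lie in [0, 1]", f))
  }
  chk(p$alpha >= 0, "alpha: nutrient affinity must be non-negative")
  chk(p$beta >= 0, "beta: adsorption coefficient must be non-negative")
  chk(p$gene_floor_eps > 0, "gene_floor_eps: must be positive")
  chk(p$compatibility_mode %in% c("tradeoff", "random"),
      "compatibility_mode: must be 'tradeoff' or 'random'")
  chk(p$virulence_mode %in% c("tradeoff", "random"),
      "virulence_mode: must be 'tradeoff' or 'random'")
  bad
}

#' Normalize parameters to simulation units
#'
#' Converts the physical parameter set to the internal bookkeeping units
#' of the simulation: phosphorus is expressed in host-equivalent units
#' (the maximum phosphorus content of one cell, so `P_units = P * V / P_h`
#' is the total budget in "cells worth" of phosphorus), and the per-pair
#' rate coefficients are scaled to the simulated volume
#' (`alpha_n = alpha / V`, `beta_n = beta / V`). All other fields pass
#' through unchanged.
#'
#' At the reference conditions this gives `P_units` of about 855.42
#' host-equivalents, `alpha_n = 0.16` and `beta_n = 6.2e-5`.
#'
#' @param params A valid [sim_params()] object.
#' @return An object of class `sim_params_norm`: `params` plus `P_units`,
#'   `alpha_n`, `beta_n`.
#' @export
normalize_params <- function(params) {
  bad <- validate_params(params)
  if (length(bad) > 0L) {
    stop("invalid simulation parameters:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  np <- unclass(params)
  np$P_units <- params$P * params$V / params$P_h
  np$alpha_n <- params$alpha / params$V
  np$beta_n <- params$beta / params$V
  class(np) <- c("sim_params_norm", "sim_params")
  np
}

#' @export
print.sim_params <- function(x, ...) {
  kind <- if (inherits(x, "sim_params_norm")) "Normalized simulation parameters"
          else "Simulation parameters"
  cat(kind, "\n", sep = "")
  cat(sprintf("  horizon T = %d h, omega = %g /h, P = %g umol-P/L, V = %g L\n",
              x$T, x$omega, x$P, x$V))
  cat(sprintf("  inoculum: %d hosts, %d viruses (VHR = %.3g)\n",
              x$N_h0, x$N_v0, if (x$N_h0 > 0) x$N_v0 / x$N_h0 else NA_real_))
  cat(sprintf("  kernels: compatibility = %s, virulence = %s\n",
              x$compatibility_mode, x$virulence_mode))
  if (inherits(x, "sim_params_norm")) {
    cat(sprintf("  normalized: P_units = %.4g, alpha_n = %.4g, beta_n = %.4g\n",
                x$P_units, x$alpha_n, x$beta_n))
  }
  invisible(x)
}
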