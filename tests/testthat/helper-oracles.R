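# Brute-force reference implementations used as independent oracles.
# These follow the model description literally (explicit loops, one or two
# uniform draws per virus-host pair) and are deliberately independent of the
# engine's geometric-thinning scan.

# One virus-host interaction round, literal pair loop.
brute_virus_round <- function(state, np) {
  m <- state$m; ga <- state$g_alpha
  gnu <- state$g_nu; gb <- state$g_beta
  Pd <- state$P_d
  alive <- rep(TRUE, length(m))
  n_surv <- 0L
  prog_nu <- numeric(0); prog_b <- numeric(0)
  for (i in sample.int(length(gnu))) {
    if (stats::runif(1) < np$omega) next
    if (stats::runif(1) < np$delta_v) next
    infected <- FALSE
    for (j in sample(which(alive))) {
      C <- if (np$compatibility_mode == "random") stats::runif(1) else
        exp(-abs(ga[j] - gb[i]) / max(gnu[i], np$gene_floor_eps))
      V <- if (np$virulence_mode == "random") np$beta_n * stats::runif(1) else
        min(1, np$beta_n * gb[i] / max(gnu[i], np$gene_floor_eps))
      if (stats::runif(1) < C && stats::runif(1) < V) {
        alive[j] <- FALSE
        Pd <- Pd + m[j]
        infected <- TRUE
        for (k in seq_len(np$kappa)) {
          if (stats::runif(1) < np$pi_v) {
            prog_nu <- c(prog_nu, min(1, max(0, stats::rnorm(1, gnu[i], np$sigma_v))))
            prog_b <- c(prog_b, min(1, max(0, stats::rnorm(1, gb[i], np$sigma_v))))
          } else {
            prog_nu <- c(prog_nu, gnu[i]); prog_b <- c(prog_b, gb[i])
          }
        }
        break
      }
    }
    if (!infected) n_surv <- n_surv + 1L
  }
  list(N_h = sum(alive), N_v = n_surv + length(prog_nu), P_d = Pd)
}

# A random heterogeneous mid-simulation state for round-level comparisons.
random_test_state <- function(n_h = 60L, n_v = 40L, P_d = 10) {
  chemostat_state(P_d = P_d, P_d0 = P_d,
                  m = stats::runif(n_h, 0.5, 1),
                  g_alpha = stats::runif(n_h),
                  g_nu = stats::runif(n_v, 0.05, 1),
                  g_beta = stats::runif(n_v))
}
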