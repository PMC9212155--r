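np_default <- normalize_params(sim_params())

test_that("initialization inoculates the budgeted chemostat", {
  set.seed(1)
  st <- init_simulation(np_default)
  expect_length(st$m, 46L)
  expect_length(st$g_nu, 810L)
  expect_true(all(st$m >= 0.5 & st$m <= 1))
  expect_true(all(st$g_alpha == 0.1))
  expect_true(all(st$g_nu == 0.1) && all(st$g_beta == 0.1))
  # dissolved P is the budget minus inoculated biomass, bounded by mass range
  expect_equal(st$P_d, np_default$P_units - sum(st$m))
  expect_gte(st$P_d, np_default$P_units - 46)
  expect_lte(st$P_d, np_default$P_units - 23)

  # empty inoculum leaves the budget fully dissolved
  np0 <- normalize_params(sim_params(N_h0 = 0L))
  set.seed(2)
  expect_equal(init_simulation(np0)$P_d, np0$P_units)

  set.seed(33)
  a <- init_simulation(np_default)
  set.seed(33)
  expect_identical(init_simulation(np_default), a)
})

test_that("nutrient update relaxes dissolved P towards its inflow level", {
  st <- chemostat_state(P_d = 300, P_d0 = 800)
  np <- normalize_params(sim_params(omega = 0))
  expect_equal(nutrient_update(st, np)$P_d, 300)
  np1 <- normalize_params(sim_params(omega = 1))
  expect_equal(nutrient_update(st, np1)$P_d, 800)
  np02 <- normalize_params(sim_params(omega = 0.2))
  s2 <- nutrient_update(st, np02)
  expect_equal(s2$P_d, 400)
  expect_equal(s2$cumulative_inflow, 100)
})

test_that("host round: growth, division and the division mass arithmetic", {
  # no nutrient, no loss processes: masses unchanged
  np <- normalize_params(sim_params(omega = 0, delta_h = 0, eps_h = 0))
  st <- chemostat_state(P_d = 0, m = c(0.6, 0.8), g_alpha = c(0.1, 0.1))
  s2 <- host_round(st, np)
  expect_equal(sort(s2$m), c(0.6, 0.8))
  expect_equal(s2$P_d, 0)

  # saturating nutrient: Monod gain -> mu_h, division into (m + mu_h)/2
  np <- normalize_params(sim_params(omega = 0, delta_h = 0, eps_h = 0, pi_h = 0))
  st <- chemostat_state(P_d = 1e9, m = 0.9, g_alpha = 0.1)
  set.seed(4)
  s2 <- host_round(st, np)
  expect_length(s2$m, 2L)
  expect_equal(s2$m, rep((0.9 + 0.738) / 2, 2), tolerance = 1e-6)
  expect_equal(s2$g_alpha, c(0.1, 0.1))
})

test_that("without mutation the host gene pool stays monomorphic", {
  tr <- run_simulation(sim_params(T = 20L, pi_h = 0, pi_v = 0), seed = 5,
                       snapshot_times = c(10L, 20L))
  for (snap in tr$snapshots) {
    expect_true(all(snap$g_alpha == 0.1))
    expect_true(all(snap$g_nu == 0.1) && all(snap$g_beta == 0.1))
  }
})

test_that("virus round respects the no-host and zero-burst edge cases", {
  # no hosts: only washout and decay act
  np <- normalize_params(sim_params(omega = 0.5, delta_v = 0.5))
  st <- chemostat_state(P_d = 10, g_nu = rep(0.1, 4000), g_beta = rep(0.1, 4000))
  set.seed(6)
  s2 <- virus_round(st, np)
  n <- length(s2$g_nu)
  expect_lt(abs(n - 1000), 4 * sqrt(4000 * 0.25 * 0.75))
  expect_equal(s2$P_d, 10)

  # kappa = 0: each infection removes exactly one host and one virus
  np <- normalize_params(sim_params(omega = 0, delta_v = 0, kappa = 0L,
                                    compatibility_mode = "random",
                                    virulence_mode = "random", beta = 1e-6))
  set.seed(7)
  st <- chemostat_state(P_d = 0, m = runif(50, 0.5, 1), g_alpha = runif(50),
                        g_nu = rep(0.1, 30), g_beta = rep(0.1, 30))
  s2 <- virus_round(st, np)
  n_inf <- 50 - length(s2$m)
  expect_equal(30 - length(s2$g_nu), n_inf)
  expect_gt(n_inf, 0)
  # lysed biomass is recirculated
  expect_equal(s2$P_d + sum(s2$m), sum(st$m))
})

test_that("engine pair scan matches the literal brute-force pair loop", {
  # heterogeneous genes, adsorption raised so infections are common
  cfgs <- list(
    sim_params(beta = 2e-8, omega = 0.1, kappa = 3L),
    sim_params(beta = 2e-8, omega = 0.1, kappa = 3L,
               compatibility_mode = "random"),
    sim_params(beta = 5e-7, omega = 0, kappa = 2L,
               virulence_mode = "random"))
  for (p in cfgs) {
    np <- normalize_params(p)
    set.seed(11)
    B <- replicate(350, {
      r <- brute_virus_round(random_test_state(), np)
      c(r$N_h, r$N_v, r$P_d)
    })
    set.seed(12)
    E <- replicate(350, {
      s2 <- virus_round(random_test_state(), np)
      c(length(s2$m), length(s2$g_nu), s2$P_d)
    })
    for (k in 1:3) {
      se <- sqrt(stats::var(B[k, ]) / 350 + stats::var(E[k, ]) / 350)
      expect_lt(abs(mean(B[k, ]) - mean(E[k, ])), 4 * max(se, 1e-8))
    }
  }
})

test_that("random kernels give the 1/4 per-pair infection rate", {
  # one virus, one host, both kernels random, adsorption scale 1:
  # infection iff U1 < C and U2 < V with C, V ~ Unif(0,1), probability 1/4
  np <- normalize_params(sim_params(omega = 0, delta_v = 0, kappa = 0L,
                                    beta = 1e-6, compatibility_mode = "random",
                                    virulence_mode = "random"))
  set.seed(13)
  hits <- replicate(20000, {
    s2 <- virus_round(chemostat_state(P_d = 0, m = 0.7, g_alpha = 0.4,
                                      g_nu = 0.5, g_beta = 0.5), np)
    length(s2$m) == 0L
  })
  expect_lt(abs(mean(hits) - 0.25), 3 * sqrt(0.25 * 0.75 / 20000))
})

test_that("virus-free closed runs plateau below the division-mass bound", {
  tr <- run_simulation(sim_params(T = 36L, N_v0 = 0L, omega = 0), seed = 14)
  expect_true(all(tr$records$N_v == 0))
  # every host carries mass > 1/2 right after division, so the phosphorus
  # budget bounds the population by P_units / 0.5
  expect_lte(max(tr$records$N_h), np_default$P_units / 0.5)
  expect_gt(tr$records$N_h[37], 1000)
})

test_that("trajectories are deterministic in the seed and well-formed", {
  p <- sim_params(T = 12L)
  t1 <- run_simulation(p, seed = 15)
  t2 <- run_simulation(p, seed = 15)
  expect_identical(t1$records, t2$records)
  expect_identical(t1$hist, t2$hist)
  expect_false(identical(t1$records, run_simulation(p, seed = 16)$records))

  expect_equal(nrow(t1$records), 13L)
  expect_identical(nrow(run_simulation(sim_params(T = 0L), seed = 1)$records), 1L)
  expect_true(all(t1$records$N_h >= 0 & t1$records$N_v >= 0))
  expect_true(all(t1$records$N_h == floor(t1$records$N_h)))
  expect_true(all(t1$records$P_d >= 0))
})

test_that("masses and genes stay within their domains along a run", {
  tr <- run_simulation(sim_params(T = 24L, pi_h = 0.3, sigma_h = 0.3,
                                  pi_v = 0.3, sigma_v = 0.3),
                       seed = 17, snapshot_times = 0:24)
  for (snap in tr$snapshots) {
    if (length(snap$m) > 0) {
      expect_true(all(snap$m > 0 & snap$m <= 1))
      expect_true(all(snap$g_alpha >= 0 & snap$g_alpha <= 1))
    }
    if (length(snap$g_nu) > 0) {
      expect_true(all(snap$g_nu >= 0 & snap$g_nu <= 1))
      expect_true(all(snap$g_beta >= 0 & snap$g_beta <= 1))
    }
  }
})

test_that("the phosphorus ledger balances in open systems", {
  # P_d + host biomass + outflow - inflow == initial budget, every step
  tr <- run_simulation(sim_params(T = 36L, omega = 0.3), seed = 18)
  r <- tr$records
  ledger <- r$P_d + r$M_h + r$cumulative_outflow - r$cumulative_inflow
  expect_equal(ledger, rep(r$P_d[1] + r$M_h[1], nrow(r)), tolerance = 1e-9)
})
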