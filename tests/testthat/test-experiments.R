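p_small <- sim_params(T = 10L)

test_that("ensemble summaries equal a brute-force recomputation", {
  en <- run_ensemble(p_small, n_reps = 6, master_seed = 21,
                     keep_trajectories = TRUE)
  Nh <- sapply(en$trajectories, function(tr) tr$records$N_h)
  Nv <- sapply(en$trajectories, function(tr) tr$records$N_v)
  expect_equal(en$records$mean_Nh, rowMeans(Nh))
  expect_equal(en$records$sd_Nh, apply(Nh, 1, sd))
  expect_equal(en$records$mean_Nv, rowMeans(Nv))
  expect_equal(en$records$sd_Nv, apply(Nv, 1, sd))
  expect_equal(nrow(en$records), 11L)

  # single replicate: zero spread
  e1 <- run_ensemble(p_small, n_reps = 1, master_seed = 22)
  expect_true(all(e1$records$sd_Nh == 0) && all(e1$records$sd_Nv == 0))

  # reproducibility in the master seed
  e2 <- run_ensemble(p_small, n_reps = 6, master_seed = 21)
  expect_identical(en$records, e2$records)
})

test_that("replicate seeds allow re-running one replicate in isolation", {
  en <- run_ensemble(p_small, n_reps = 5, master_seed = 23,
                     keep_trajectories = TRUE)
  s3 <- replicate_seeds(23, 5)[3]
  solo <- run_simulation(p_small, seed = s3)
  expect_identical(solo$records, en$trajectories[[3]]$records)
})

test_that("sweeps cover the grid and reduce to plain ensembles", {
  sp <- sweep_spec("omega", c(0, 0.2, 0.4), n_reps = 3, base_params = p_small,
                   master_seed = 24)
  sw <- run_sweep(sp)
  expect_length(sw, 3L)
  expect_named(sw, c("0", "0.2", "0.4"))

  # degenerate one-value sweep reproduces run_ensemble at the derived seed
  sp1 <- sweep_spec("omega", 0.2, n_reps = 3, base_params = p_small,
                    master_seed = 24)
  sw1 <- run_sweep(sp1)
  en <- run_ensemble(p_small, 3, replicate_seeds(24, 1))
  expect_identical(sw1[["0.2"]]$records, en$records)

  # VHR sweeps scale N_v0 at fixed N_h0
  spv <- sweep_spec("VHR", c(1.76, 17.6), n_reps = 2, base_params = p_small,
                    master_seed = 25)
  swv <- run_sweep(spv)
  expect_equal(swv[["1.76"]]$params$N_v0, 81L)
  expect_equal(swv[["1.76"]]$params$N_h0, 46L)
  expect_equal(swv[["17.6"]]$params$N_v0, 810L)

  expect_error(sweep_spec("not_a_param", 1, 2), "unknown swept parameter")
  expect_error(sweep_spec("omega", c(0.1, 1.5), 2), "invalid")

  rec <- sweep_records(sw)
  expect_equal(nrow(rec), 3 * 11)
  expect_true(all(c("swept_param", "value", "t", "mean_Nh") %in% names(rec)))
})

test_that("outcome classification applies the one-individual threshold", {
  en <- run_ensemble(p_small, n_reps = 1, master_seed = 26)
  fake <- function(nh, nv) {
    en$records$mean_Nh[nrow(en$records)] <- nh
    en$records$mean_Nv[nrow(en$records)] <- nv
    en
  }
  expect_equal(classify_outcome(fake(800, 50)), "coexistence")
  expect_equal(classify_outcome(fake(900, 0)), "host_only")
  expect_equal(classify_outcome(fake(0, 0)), "double_extinction")
  expect_equal(classify_outcome(fake(0.5, 0.5)), "double_extinction")
})

test_that("the factorial experiment spans all eight conditions", {
  fac <- run_factorial_longterm(p_small, n_reps = 2, master_seed = 27, T = 5L)
  expect_equal(nrow(fac$conditions), 8L)
  expect_setequal(unique(fac$conditions$system), c("closed", "open"))
  expect_length(fac$summaries, 8L)
  closed_rows <- fac$conditions$system == "closed"
  for (i in which(closed_rows)) {
    expect_equal(fac$summaries[[i]]$params$omega, 0)
  }
  for (i in which(!closed_rows)) {
    expect_equal(fac$summaries[[i]]$params$omega, 0.2)
  }
  expect_true(all(fac$conditions$outcome %in%
                  c("coexistence", "host_only", "double_extinction")))
})

test_that("crash-recovery detection finds bloom, crash and regrowth", {
  x <- c(50, 400, 900, 1200, 800, 400, 300, 500, 800, 1000, 950)
  s <- crash_recovery_stats(x)
  expect_equal(s$first_peak, 1200)
  expect_equal(s$crash, 300)
  expect_equal(s$crash_t, 6)
  expect_equal(s$recovery_peak, 1000)
  # monotone rise: everything collapses onto the endpoint
  s2 <- crash_recovery_stats(c(1, 2, 4, 8, 16))
  expect_equal(s2$recovery_peak, 16)
})
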