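rc_test <- rate_constants(r_g_scale = 2e-3)

test_that("runs are reproducible from the seed and refuse to start unseeded", {
  cc <- cell_cycle_params(40)
  cfg <- simulation_config(cc, rc_test, t_end_hours = 2, seed = 11,
                           burnin_generations = 3)
  a <- simulate_lineage(cfg)
  b <- simulate_lineage(cfg)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$final, b$final)
  cfg2 <- cfg; cfg2$seed <- 12
  expect_false(identical(simulate_lineage(cfg2)$trajectory, a$trajectory))
  expect_error(simulation_config(cc, rc_test, seed = NULL), "seed")
  expect_error(simulation_config(cc, rc_test), "seed")
})

test_that("sampled copy numbers follow the analytic replication schedule", {
  cc <- cell_cycle_params(45)
  cfg <- simulation_config(cc, rc_test, t_end_hours = 8, seed = 5,
                           record_dt_s = 30, burnin_generations = 5)
  tr <- simulate_lineage(cfg)$trajectory
  loci <- default_loci()
  keep <- tr$age_s / 60 < cc$T
  age <- tr$age_s[keep] / 60
  expect_equal(tr$N_ori[keep], copies_at_age(loci$ori, cc, age))
  expect_equal(tr$N_ter[keep], copies_at_age(loci$ter, cc, age))
  # volume tracks the exponential growth law and never exceeds 2 V0
  expect_equal(tr$V[keep], volume_at_age(cc, age))
  expect_true(all(tr$V <= 2 * volume_at_age(cc, 0) + 1e-12))
})

test_that("division keeps one copy per replicated pair and splits molecules binomially", {
  cc <- cell_cycle_params(45)  # both loci double mid-cycle
  st <- list(copies = c(2L, 4L), active = c(1L, 3L),
             m = c(10L, 6L), p = c(40L, 20L), d = c(8L, 4L))
  out <- vapply(1:2000, function(s) {
    dt <- partition_at_division(st, cc, seed = s)
    c(dt$copies, dt$active, dt$m[1], dt$p[1], dt$d[1], dt$bound_lost)
  }, numeric(9))
  expect_true(all(out[1, ] == 1) && all(out[2, ] == 2))   # half the copies
  # hypergeometric retention of active copies: means 0.5 and 1.5
  expect_equal(mean(out[3, ]), 0.5, tolerance = 0.1)
  expect_equal(mean(out[4, ]), 1.5, tolerance = 0.1)
  expect_true(all(out[4, ] >= 1))  # at most one of 4 copies was repressed
  # binomial halves for free molecules: mean n/2, variance n/4
  expect_equal(mean(out[5, ]), 5, tolerance = 0.2)
  expect_equal(mean(out[6, ]), 20, tolerance = 0.5)
  expect_equal(var(out[6, ]), 10, tolerance = 2)
  expect_equal(mean(out[7, ]), 4, tolerance = 0.3)
  # bound dimers leave with the sibling when their copy is not kept
  expect_equal(mean(out[8, ]), 0.5, tolerance = 0.1)
  expect_true(all(out[8, ] + (1 - out[3, ]) == 1))
})

test_that("a doubling that coincides with division releases repressors", {
  cc <- cell_cycle_params(20)  # x is a multiple of T for both default loci
  st <- list(copies = c(8L, 2L), active = c(5L, 2L),
             m = c(0L, 0L), p = c(0L, 0L), d = c(0L, 0L))
  dt <- partition_at_division(st, cc, seed = 3)
  expect_equal(dt$copies, c(8L, 2L))        # constant count over the cycle
  expect_equal(dt$active, dt$copies)        # all copies restart active
  expect_equal(dt$released, c(3, 0))        # the three bound dimers freed
  # freed dimers join the other free pool before the binomial split
  d2 <- vapply(1:2000, function(s)
    partition_at_division(st, cc, seed = s)$d[2], numeric(1))
  expect_true(all(d2 %in% 0:3))
  expect_equal(mean(d2), 1.5, tolerance = 0.1)
})

test_that("dimer bookkeeping balances over a full run", {
  for (Tm in c(28, 45)) {
    cc <- cell_cycle_params(Tm)
    cfg <- simulation_config(cc, rate_constants(r_g_scale = 3.5e-3),
                             t_end_hours = 6, seed = 21, record_dt_s = 0,
                             burnin_generations = 4)
    run <- simulate_lineage(cfg)
    au <- run$audit
    for (i in 1:2) {
      bound0 <- run$initial$copies[i] - run$initial$active[i]
      bound1 <- run$final$copies[i] - run$final$active[i]
      expect_equal(bound1 - bound0,
                   au$n_repress[i] - au$n_activate[i] -
                     au$n_rep_release[i] - au$n_div_bound_lost[i])
    }
    expect_gt(au$n_repress[1] + au$n_repress[2], 0)
    expect_gt(au$n_divisions, 0)
  }
})

test_that("with repression off the ensemble mean matches the deterministic ratio", {
  cc <- cell_cycle_params(20)
  rc0 <- rate_constants(r_g_scale = 0)
  cfg <- simulation_config(cc, rc0, t_end_hours = 10, seed = 2,
                           record_dt_s = 0, burnin_generations = 15)
  en <- run_ensemble(cfg, 60)
  per <- en$per_lineage
  mo <- mean(per$tot_ori); mt <- mean(per$tot_ter); R <- mo / mt
  n <- nrow(per)
  se <- R * sqrt(var(per$tot_ori) / (n * mo^2) +
                 var(per$tot_ter) / (n * mt^2) -
                 2 * cov(per$tot_ori, per$tot_ter) / (n * mo * mt))
  ode <- state_protein_ratio(relax_to_steady_state(deterministic_state(),
                                                   rc0, cc))
  expect_equal(ode, 2, tolerance = 1e-6)
  expect_lt(abs(R - ode), 3 * se)
})

test_that("frozen volume and disabled schedule hold the reduced model fixed", {
  cc <- cell_cycle_params(40)
  st <- list(copies = c(1L, 1L), active = c(1L, 1L), m = c(0L, 0L),
             p = c(6L, 6L), d = c(0L, 0L), age = 0)
  cfg <- simulation_config(cc, rc_test, t_end_hours = 1, seed = 9,
                           record_dt_s = 60, init = "explicit",
                           init_state = st, fixed_volume = 1,
                           replication_schedule = FALSE)
  tr <- simulate_lineage(cfg)$trajectory
  expect_true(all(tr$N_ori == 1) && all(tr$N_ter == 1))
  expect_true(all(tr$V == 1))
  expect_equal(simulate_lineage(cfg)$audit$n_divisions, 0)
})

test_that("channel propensities match their mass-action definitions", {
  cc <- cell_cycle_params(40)
  er <- effective_rates(rc_test, cc, t = 0)
  st <- list(copies = c(2L, 4L), active = c(1L, 4L),
             m = c(3L, 1L), p = c(10L, 4L), d = c(5L, 2L))
  a <- propensities(st, er)
  expect_length(a, 14)
  expect_equal(unname(a["activate_ori"]), er$k_g * 1)
  expect_equal(unname(a["repress_ori"]), er$r_g * 2 * 1)   # d_ter * active_ori
  expect_equal(unname(a["transcribe_ori"]), er$k_m * 1)
  expect_equal(unname(a["dimerize_ori"]), er$k_d * 10 * 9)
  expect_equal(unname(a["dissociate_ter"]), er$r_d * 2)
  expect_equal(unname(a["translate_ter"]), er$k_p * 1)
  st$active <- c(3L, 4L)
  expect_error(propensities(st, er), "invalid state")
})
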