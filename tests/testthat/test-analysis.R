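test_that("switch detection needs both monomers and dimers to cross", {
  t_h <- 0:10
  traj <- data.frame(
    time_s = t_h * 3600,
    P_ori = rep(100, 11), D_ori = rep(50, 11),
    P_ter = c(rep(10, 5), rep(150, 6)),           # monomers cross at 5 h
    D_ter = c(rep(2, 7), rep(80, 4)))             # dimers only at 7 h
  expect_equal(detect_switch(traj, "ori-dominant"), 7)
  # relative to a ter-dominant start this trajectory is switched from t = 0
  expect_equal(detect_switch(traj, "ter-dominant"), 0)
  # ties are not a switch: strict inequality on both species
  tie <- data.frame(time_s = c(0, 3600), P_ori = c(5, 5), D_ori = c(3, 3),
                    P_ter = c(5, 5), D_ter = c(3, 4))
  expect_true(is.na(detect_switch(tie, "ori-dominant")))
})

test_that("the tail fit recovers the mean of exponential passage times", {
  set.seed(42)
  x <- rexp(4000, rate = 1 / 25)
  fit <- mfpt_fit(x)
  expect_true(fit$converged)
  se <- fit$mfpt_h / sqrt(sum(x > fit$threshold_h))
  expect_lt(abs(fit$mfpt_h - 25), 2 * se + abs(mean(x) - 25))
  # a 5% contaminant of fast recrossings is excluded by the truncation
  y <- c(x, runif(200, 0, 0.5))
  fit_c <- mfpt_fit(y)
  expect_equal(fit_c$mfpt_h, 25, tolerance = 0.06)
})

test_that("the tail fit rejects unusable samples", {
  expect_error(mfpt_fit(rexp(30, 1)), "transitions")
  expect_error(mfpt_fit(rep(2, 200)), "degenerate")
  expect_error(mfpt_fit(c(-1, rexp(200, 1))), "positive")
  small <- mfpt_fit(rexp(150, 1 / 10), min_transitions = 100)
  expect_s3_class(small, "mfpt_fit")
  expect_equal(small$n_transitions, 150)
})

test_that("response_time recovers the time constant of a clean relaxation", {
  t_h <- seq(0, 12, by = 0.1)
  y <- -1.5 + (2.5 + 1.5) * exp(-t_h / 2)
  tau <- response_time(t_h, y)
  expect_equal(as.numeric(tau), 2, tolerance = 1e-5)
  expect_equal(attr(tau, "y_inf"), -1.5, tolerance = 1e-5)
  expect_error(response_time(t_h, rep(1, length(t_h))), "flat")
})

test_that("protein_ratio reads window averages and recorded series", {
  cc <- cell_cycle_params(20)
  rc0 <- rate_constants(r_g_scale = 0)
  cfg <- simulation_config(cc, rc0, t_end_hours = 4, seed = 3,
                           record_dt_s = 300, burnin_generations = 8)
  en <- run_ensemble(cfg, 10, record = TRUE, avg_start_hours = 1)
  expect_equal(protein_ratio(en), en$R_protein)
  r_win <- protein_ratio(en, window = c(1, 4))
  expect_equal(r_win, en$R_protein, tolerance = 0.2)
  expect_error(protein_ratio(en, window = c(90, 99)), "window")
})

test_that("state lifetimes account for every simulated hour", {
  cc <- cell_cycle_params(40)
  lt <- state_lifetimes(cc, rate_constants(r_g_scale = 0), seed = 4,
                        hours = 40, n_runs = 2)
  expect_s3_class(lt, "state_lifetimes")
  expect_equal(sum(lt$occupancy), 1)
  expect_equal(unname(sum(lt$exposure_h)), 80, tolerance = 1e-6)
  expect_true(all(lt$tau_h > 0))
})

test_that("sensitivity scan aggregates injected metrics and drops broken points", {
  rc <- rate_constants()
  fns <- list(
    bistability = function(r) if (r$r_d > 0.15) NA_real_ else 2,
    switching = function(r) 10 * r$k_g / 2e-3,
    sensitivity = function(r) 100 * r$k_g / 2e-3,
    response = function(r) 5 * r$k_g / 2e-3)
  rep <- sensitivity_scan(rc, parameters = c("k_g", "r_d"),
                          factors = c(2, 0.5), metric_fns = fns)
  tab <- rep$table
  expect_equal(nrow(tab), 5)  # base + 2 parameters x 2 factors
  broken <- tab$parameter == "r_d" & tab$factor == 2
  expect_true(all(is.na(tab$switching_time_h[broken])))
  expect_equal(tab$switching_time_h[tab$parameter == "k_g" & tab$factor == 2],
               20)
  # metrics proportional to each other correlate perfectly on the log scale
  expect_equal(rep$cor_switch_sensitivity, 1, tolerance = 1e-12)
  expect_equal(rep$cor_switch_response, 1, tolerance = 1e-12)
})

test_that("a doubling-time shift relaxes the ensemble ratio to a new level", {
  sr <- shift_response(rate_constants(r_g_scale = 0), T_from = 40,
                       T_to = 25, n_cells = 12, hours = 6, seed = 6,
                       record_dt_s = 600)
  expect_true(is.finite(sr$tau_geo_h) && sr$tau_geo_h > 0)
  y <- sr$series[[1]]$log2_ratio
  # faster growth raises the ori-proximal gene's share
  expect_gt(mean(y[(length(y) - 3):length(y)]), y[1])
})
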