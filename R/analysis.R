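#' Population protein-expression ratio
#'
#' `R_protein`: the ratio of the population-average total protein content
#' (monomers + 2 x dimers) of the ori-proximal gene to that of the
#' ter-proximal gene, over a time window.
#'
#' @param summary an [run_ensemble()] result.
#' @param window optional `c(from, to)` in hours, applied to the recorded
#'   time series when present; without a recorded series the per-lineage
#'   exact window averages are used as-is.
#' @return R_protein (real).
#' @export
protein_ratio <- function(summary, window = NULL) {
  stopifnot(inherits(summary, "ensemble_summary"))
  if (!is.null(window) && !is.null(summary$time_series)) {
    ts <- summary$time_series
    t_h <- ts$time_s / 3600
    keep <- t_h >= window[1] & t_h <= window[2]
    if (!any(keep)) stop("window outside recorded time", call. = FALSE)
    return(mean(ts$mean_tot_ori[keep]) / mean(ts$mean_tot_ter[keep]))
  }
  summary$R_protein
}

#' First passage out of a toggle state in a recorded trajectory
#'
#' The switch is called at the first sampled time at which BOTH the monomer
#' and the free-dimer count of the initially repressed gene strictly exceed
#' those of the initially dominant gene.
#'
#' @param traj a trajectory data frame (columns as written by
#'   [simulate_lineage()]).
#' @param initial_state `"ori-dominant"` or `"ter-dominant"`.
#' @return first passage time in hours, or `NA` (censored).
#' @export
detect_switch <- function(traj, initial_state = c("ori-dominant",
                                                  "ter-dominant")) {
  initial_state <- match.arg(initial_state)
  if (initial_state == "ori-dominant") {
    hit <- traj$P_ter > traj$P_ori & traj$D_ter > traj$D_ori
  } else {
    hit <- traj$P_ori > traj$P_ter & traj$D_ori > traj$D_ter
  }
  if (!any(hit)) return(NA_real_)
  traj$time_s[which(hit)[1]] / 3600
}

#' MFPT from the exponential tail of transition times
#'
#' State-to-state passage times are exponential except for the shortest
#' passages (recrossings near the unstable intermediate state), so the MFPT
#' is estimated from truncated samples: for each truncation threshold `u` the
#' maximum-likelihood exponential-tail estimate is the mean excess
#' `mean(x - u | x > u)`; the reported value is the first plateau, where
#' successive estimates change by less than `plateau_rel`.
#'
#' @param durations_h transition durations in hours.
#' @param truncation_grid thresholds in hours (default: 12 evenly spaced
#'   from 0 to the 80% quantile).
#' @param min_transitions minimum sample size required.
#' @param plateau_rel relative change between successive estimates below
#'   which the curve is called flat.
#' @param n_censored number of censored runs (recorded, not used in the fit).
#' @return list of class `mfpt_fit`: `mfpt_h` (plateau 1/lambda),
#'   `threshold_h`, `table` (threshold, estimate, n, se), `converged`.
#' @export
mfpt_fit <- function(durations_h, truncation_grid = NULL,
                     min_transitions = 100, plateau_rel = 0.05,
                     n_censored = 0) {
  x <- durations_h[is.finite(durations_h)]
  if (any(x <= 0)) stop("durations must be positive", call. = FALSE)
  if (length(x) < min_transitions)
    stop(sprintf(paste("only %d uncensored transitions (< %d);",
                       "extend the runs or lower min_transitions"),
                 length(x), min_transitions), call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate sample: all durations equal, no exponential tail to fit",
         call. = FALSE)
  if (is.null(truncation_grid))
    truncation_grid <- seq(0, stats::quantile(x, 0.8), length.out = 12)
  est <- vapply(truncation_grid, function(u) {
    tail <- x[x > u]
    if (length(tail) < 20) return(c(NA_real_, NA_real_, length(tail)))
    m <- mean(tail - u)
    c(m, m / sqrt(length(tail)), length(tail))
  }, numeric(3))
  tab <- data.frame(threshold_h = truncation_grid, mfpt_h = est[1, ],
                    se_h = est[2, ], n = est[3, ])
  ok <- which(!is.na(tab$mfpt_h))
  rel <- abs(diff(tab$mfpt_h[ok])) / tab$mfpt_h[ok][-length(ok)]
  plat <- which(rel < plateau_rel)
  converged <- length(plat) > 0
  idx <- if (converged) ok[plat[1] + 1] else ok[length(ok)]
  structure(list(mfpt_h = tab$mfpt_h[idx], threshold_h = tab$threshold_h[idx],
                 table = tab, converged = converged,
                 n_transitions = length(x), n_censored = n_censored),
            class = "mfpt_fit")
}

#' @export
print.mfpt_fit <- function(x, ...) {
  cat(sprintf("MFPT = %.3g h (tail fit above %.2g h, %d transitions%s)\n",
              x$mfpt_h, x$threshold_h, x$n_transitions,
              if (x$converged) "" else "; no plateau reached"))
  invisible(x)
}

#' Toggle switching time (state-to-state MFPT) by simulation
#'
#' Simulates lineages committed to one toggle state, records successive
#' state-to-state passages, and returns the exponential-tail MFPT. At the
#' symmetric point (T = 40 min with the default design) the two directions
#' are equivalent and are pooled; otherwise `direction` selects the passages
#' that start from the given state.
#'
#' @param cc a [cell_cycle_params()].
#' @param rc a [rate_constants()].
#' @param seed integer seed.
#' @param direction `"both"`, `"ori-to-ter"` or `"ter-to-ori"`.
#' @param min_transitions transitions required before fitting.
#' @param chunk_hours model time per lineage chunk.
#' @param max_chunks simulation budget.
#' @param loci gene placement.
#' @param ... passed to [mfpt_fit()].
#' @return an `mfpt_fit` with the collected `durations_h` attached.
#' @export
switching_time <- function(cc, rc, seed, direction = "both",
                           min_transitions = 100, chunk_hours = 400,
                           max_chunks = 400, loci = default_loci(), ...) {
  col <- collect_passages(cc, rc, seed, direction, min_transitions,
                          chunk_hours, max_chunks, loci)
  fit <- mfpt_fit(col$durations_h, min_transitions = min_transitions, ...)
  fit$durations_h <- col$durations_h
  fit$hours_simulated <- col$hours_simulated
  fit
}

# chunked collection of state-to-state passages in one direction (or pooled)
collect_passages <- function(cc, rc, seed, direction, min_transitions,
                             chunk_hours, max_chunks, loci) {
  direction <- match.arg(direction, c("both", "ori-to-ter", "ter-to-ori"))
  start <- if (direction == "ter-to-ori") "ter-dominant" else "ori-dominant"
  keep_from <- switch(direction, "ori-to-ter" = "ori", "ter-to-ori" = "ter",
                      NULL)
  durations <- numeric(0)
  hours <- 0
  for (i in seq_len(max_chunks)) {
    cfg <- simulation_config(cc, rc, loci = loci, t_end_hours = chunk_hours,
                             seed = seed + i * 7919, record_dt_s = 0,
                             init = start, burnin_generations = 10)
    run <- simulate_lineage(cfg, collect_transitions = TRUE)
    hours <- hours + chunk_hours
    tr <- run$transitions
    if (!is.null(keep_from)) tr <- tr[tr$from == keep_from, , drop = FALSE]
    # a passage of zero length can only be the initial state sitting on the
    # boundary; it carries no first-passage information
    durations <- c(durations, tr$duration_h[tr$duration_h > 0])
    if (length(durations) >= min_transitions) break
  }
  list(durations_h = durations, hours_simulated = hours)
}

#' Mean lifetimes and stationary occupancies of the two toggle states
#'
#' Follows a few very long lineages through many alternating dominance
#' periods and reports, per state, the total time spent dominant (exposure),
#' the number of completed exits, the mean lifetime (exposure per exit) and
#' the stationary occupancy (exposure fraction, the ergodic time average).
#' The runs are never restarted between switches -- restarting in a
#' committed state would re-inject that state's occupancy and bias the time
#' fractions. Unlike the exponential-tail MFPT of [switching_time()], these
#' means include short recrossing dwells, which is what occupancies require.
#' A state that never exits within the budget gets lifetime `Inf` (censored,
#' with its exposure as the lower bound).
#'
#' @inheritParams switching_time
#' @param hours model time per lineage; must be much longer than both
#'   lifetimes for the occupancies to be meaningful.
#' @param n_runs number of independent lineages.
#' @return list of class `state_lifetimes`: `tau_h` (named `ori`/`ter` mean
#'   lifetimes, hours), `occupancy` (named, sums to 1), `censored` (named
#'   logical), `exposure_h` (time observed in each state), `n` (exits).
#' @export
state_lifetimes <- function(cc, rc, seed, hours = 30000, n_runs = 2,
                            loci = default_loci()) {
  exposure <- c(ori = 0, ter = 0)
  exits <- c(ori = 0L, ter = 0L)
  for (i in seq_len(n_runs)) {
    cfg <- simulation_config(cc, rc, loci = loci, t_end_hours = hours,
                             seed = seed + i * 7919, record_dt_s = 0,
                             init = "ori-dominant", burnin_generations = 10)
    run <- simulate_lineage(cfg, collect_transitions = TRUE)
    tr <- run$transitions
    tr <- tr[tr$duration_h > 0, , drop = FALSE]
    for (s in c("ori", "ter")) {
      exposure[s] <- exposure[s] + sum(tr$duration_h[tr$from == s])
      exits[s] <- exits[s] + sum(tr$from == s)
    }
    # the unfinished final dwell: the state entered by the last exit (or the
    # start state when nothing happened) holds the run's remaining time
    open_state <- if (nrow(tr) > 0)
      c(ori = "ter", ter = "ori")[[tr$from[nrow(tr)]]] else "ori"
    exposure[open_state] <- exposure[open_state] +
      max(hours - sum(tr$duration_h), 0)
  }
  tau <- ifelse(exits > 0, exposure / exits, Inf)
  names(tau) <- c("ori", "ter")
  occ <- exposure / sum(exposure)
  names(occ) <- c("ori", "ter")
  structure(list(tau_h = tau, occupancy = occ,
                 censored = is.infinite(tau),
                 exposure_h = exposure, n = exits),
            class = "state_lifetimes")
}

#' @export
print.state_lifetimes <- function(x, ...) {
  cat(sprintf("state lifetimes: ori %.3g h (n=%d)%s, ter %.3g h (n=%d)%s; occupancy ori %.3g / ter %.3g\n",
              x$tau_h["ori"], x$n["ori"],
              if (x$censored["ori"]) sprintf(" [censored, >= %g h observed]", x$exposure_h["ori"]) else "",
              x$tau_h["ter"], x$n["ter"],
              if (x$censored["ter"]) sprintf(" [censored, >= %g h observed]", x$exposure_h["ter"]) else "",
              x$occupancy["ori"], x$occupancy["ter"]))
  invisible(x)
}

#' Equilibrium expression ratio of a bistable toggle
#'
#' Stationary-ensemble estimate of R_protein for a bistable toggle. In deep
#' bistability the state lifetimes (10^2-10^3 h) far exceed any affordable
#' ensemble horizon, so a plain ensemble never equilibrates; instead the
#' stationary distribution is sampled by stratification: committed ensembles
#' of each toggle state give the within-state mean total protein contents,
#' lifetimes from [state_lifetimes()] give the stationary state occupancies,
#' and the equilibrium ratio is the occupancy-weighted mixture
#' `R = sum_s p_s E[tot_ori | s] / sum_s p_s E[tot_ter | s]`.
#'
#' Within-state means are exact time averages over `[settle_hours, t_stop]`
#' where `t_stop` is the first exit from the state (or the horizon), so
#' short-lived states contribute their committed expression, not the
#' post-switch values.
#'
#' @inheritParams switching_time
#' @param n_cells total lineages, split evenly between the two strata.
#' @param hours model time per lineage.
#' @param settle_hours discarded from the start of each averaging window.
#' @param lifetimes optional precomputed [state_lifetimes()]; measured with
#'   the given budget parameters when `NULL`.
#' @param lifetime_hours,lifetime_runs occupancy measurement budget, see
#'   [state_lifetimes()].
#' @return list of class `equilibrium_ratio`: `R_protein`, `occupancy`,
#'   `state_means` (2x2: rows ori-/ter-state, columns tot_ori/tot_ter),
#'   `lifetimes`, `n_cells`, `hours`.
#' @export
equilibrium_ratio <- function(cc, rc, seed, n_cells = 200, hours = 30,
                              settle_hours = 1, lifetimes = NULL,
                              lifetime_hours = 30000, lifetime_runs = 2,
                              loci = default_loci()) {
  if (is.null(lifetimes))
    lifetimes <- state_lifetimes(cc, rc, seed = seed,
                                 hours = lifetime_hours,
                                 n_runs = lifetime_runs, loci = loci)
  stopifnot(inherits(lifetimes, "state_lifetimes"))
  n_half <- max(1L, floor(n_cells / 2))
  stratum <- function(init, seed_off) {
    acc <- c(0, 0); w <- 0
    for (i in seq_len(n_half)) {
      cfg <- simulation_config(cc, rc, loci = loci, t_end_hours = hours,
                               seed = seed + seed_off + i, record_dt_s = 0,
                               init = init, burnin_generations = 20)
      run <- simulate_lineage(cfg, avg_start_hours = settle_hours,
                              stop_at_switch = TRUE)
      if (run$avg$window > 0) {
        acc <- acc + run$avg$total_protein * run$avg$window
        w <- w + run$avg$window
      }
    }
    if (w == 0) stop(sprintf(
      "no lineage of the %s stratum survived past settle_hours", init),
      call. = FALSE)
    acc / w
  }
  e_ori <- stratum("ori-dominant", 0L)
  e_ter <- stratum("ter-dominant", 500000L)
  p <- lifetimes$occupancy
  num <- p["ori"] * e_ori[1] + p["ter"] * e_ter[1]
  den <- p["ori"] * e_ori[2] + p["ter"] * e_ter[2]
  sm <- rbind("ori-state" = e_ori, "ter-state" = e_ter)
  colnames(sm) <- c("tot_ori", "tot_ter")
  structure(list(R_protein = unname(num / den), occupancy = p,
                 state_means = sm, lifetimes = lifetimes,
                 n_cells = 2 * n_half, hours = hours),
            class = "equilibrium_ratio")
}

#' @export
print.equilibrium_ratio <- function(x, ...) {
  cat(sprintf("equilibrium R_protein = %.4g (occupancy ori %.3g, %d lineages x %g h)\n",
              x$R_protein, x$occupancy["ori"], x$n_cells, x$hours))
  invisible(x)
}

#' Characteristic response time of a relaxing expression ratio
#'
#' Fits `y(t) = y_inf + (y0 - y_inf) exp(-t / tau)` to a (typically
#' ensemble-averaged) log2 expression-ratio time series after a growth-rate
#' shift and returns the characteristic time `tau`.
#'
#' @param time_h times in hours.
#' @param y the log2 total-protein ratio at those times.
#' @return `tau` in hours, with attributes `y0`, `y_inf` and `fitted`.
#' @export
response_time <- function(time_h, y) {
  stopifnot(length(time_h) == length(y), length(y) >= 5)
  if (stats::sd(y) < 1e-12)
    stop("flat series: no relaxation to fit (was the doubling time shifted?)",
         call. = FALSE)
  y_inf0 <- mean(y[time_h >= stats::quantile(time_h, 0.8)])
  y00 <- y[which.min(time_h)]
  # log-linear initial guess for tau on the early deviation from y_inf
  dev <- (y - y_inf0) / (y00 - y_inf0)
  use <- dev > 0.05 & time_h > min(time_h)
  tau0 <- if (sum(use) >= 2)
    -1 / stats::coef(stats::lm(log(dev[use]) ~ time_h[use]))[[2]]
  else diff(range(time_h)) / 3
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- diff(range(time_h)) / 3
  fit <- stats::nls(y ~ yi + (y0 - yi) * exp(-time_h / tau),
                    start = list(yi = y_inf0, y0 = y00, tau = tau0),
                    control = stats::nls.control(maxiter = 200,
                                                 warnOnly = TRUE,
                                                 scaleOffset = 1))
  cf <- stats::coef(fit)
  structure(unname(cf["tau"]), y0 = unname(cf["y0"]), y_inf = unname(cf["yi"]),
            fitted = stats::fitted(fit))
}

#' Ensemble response to a doubling-time shift
#'
#' Equilibrates an ensemble at `T_from`, switches the doubling time to each
#' `T_to` (molecule counts carry over; the cell-age fraction of the cycle is
#' preserved), records the ensemble-mean log2 total-protein ratio and fits
#' [response_time()]. The scalar summary is the geometric mean of the fitted
#' times over the listed shifts.
#'
#' @param rc a [rate_constants()].
#' @param T_from,T_to doubling times in minutes (`T_to` may be a vector).
#' @param n_cells lineages per shift.
#' @param hours recorded time after the shift.
#' @param seed integer seed.
#' @param loci gene placement.
#' @param equil_generations burn-in generations at `T_from`.
#' @param record_dt_s sampling interval of the ensemble series.
#' @return list: `tau_geo_h` (geometric mean), `per_shift` (data frame of
#'   `T_to` and `tau_h`), `series` (list of ensemble-mean series).
#' @export
shift_response <- function(rc, T_from = 40, T_to = c(30, 60), n_cells = 100,
                           hours = 12, seed, loci = default_loci(),
                           equil_generations = 15, record_dt_s = 300) {
  cc_from <- cell_cycle_params(T_from)
  taus <- numeric(length(T_to))
  series <- vector("list", length(T_to))
  for (k in seq_along(T_to)) {
    cc_to <- cell_cycle_params(T_to[k])
    acc <- NULL
    for (i in seq_len(n_cells)) {
      s_i <- seed + 104729 * k + i
      cfg_eq <- simulation_config(cc_from, rc, loci = loci,
                                  t_end_hours = 1e-6, seed = s_i,
                                  record_dt_s = 0,
                                  burnin_generations = equil_generations)
      st <- prepare_initial_state(cfg_eq, s_i)
      st$age <- st$age / (T_from * 60) * (cc_to$T * 60) / 60 # keep phase; min
      cfg_sh <- simulation_config(cc_to, rc, loci = loci,
                                  t_end_hours = hours, seed = s_i + 31,
                                  record_dt_s = record_dt_s,
                                  init = "explicit", init_state = st)
      run <- simulate_lineage(cfg_sh)
      tp <- run$trajectory
      v <- cbind(tp$P_ori + 2 * tp$D_ori, tp$P_ter + 2 * tp$D_ter)
      if (is.null(acc)) { acc <- v; tgrid <- tp$time_s / 3600 }
      else acc <- acc + v
    }
    y <- log2(acc[, 1] / acc[, 2])
    series[[k]] <- data.frame(time_h = tgrid, log2_ratio = y)
    taus[k] <- as.numeric(response_time(tgrid, y))
  }
  list(tau_geo_h = exp(mean(log(taus))),
       per_shift = data.frame(T_to = T_to, tau_h = taus),
       series = series)
}

#' Two-fold parameter sensitivity scan
#'
#' Perturbs each listed rate constant by the given factors (default x2 and
#' x1/2) and recomputes the four toggle metrics: switching time at the
#' symmetric point, deterministic bistability-range ratio, sensitivity
#' (R_protein at T = 30 over T = 60 min) and response time. Perturbations
#' that destroy bistability get `NA` metrics and are excluded from the
#' log-log Pearson correlations of switching time with sensitivity and with
#' response time.
#'
#' The metric evaluators can be swapped out (e.g. for cheaper surrogates or
#' for testing) via `metric_fns`; each receives the perturbed
#' [rate_constants()] and must return a single number or `NA`.
#'
#' @param rc base [rate_constants()] (must yield a bistable toggle).
#' @param parameters names of `rc` entries to perturb.
#' @param factors multiplicative perturbations.
#' @param metric_fns named list of functions `switching`, `bistability`,
#'   `sensitivity`, `response`.
#' @param seed integer seed handed to the default metric evaluators.
#' @param ... tuning for the default evaluators: `n_cells`, `hours`,
#'   `min_transitions`.
#' @return list of class `sensitivity_report`: `table` (one row per
#'   parameter x factor plus the base), `cor_switch_sensitivity`,
#'   `cor_switch_response`.
#' @export
sensitivity_scan <- function(rc, parameters = c("k_g", "r_g_scale",
                                                "k_m_scale", "k_p_scale",
                                                "k_d_scale", "r_d", "r_m"),
                             factors = c(2, 0.5), metric_fns = NULL,
                             seed = 1, ...) {
  if (is.null(metric_fns)) metric_fns <- default_metric_fns(seed, ...)
  rows <- list()
  eval_point <- function(rc_i, label, factor) {
    bi <- metric_fns$bistability(rc_i)
    if (is.na(bi) || bi <= 1) {
      return(data.frame(parameter = label, factor = factor,
                        switching_time_h = NA_real_,
                        bistability_range = bi,
                        sensitivity = NA_real_, response_time_h = NA_real_))
    }
    data.frame(parameter = label, factor = factor,
               switching_time_h = metric_fns$switching(rc_i),
               bistability_range = bi,
               sensitivity = metric_fns$sensitivity(rc_i),
               response_time_h = metric_fns$response(rc_i))
  }
  rows[[1]] <- eval_point(rc, "base", 1)
  for (p in parameters) for (f in factors) {
    rc_i <- rc
    rc_i[[p]] <- rc[[p]] * f
    class(rc_i) <- "rate_constants"
    rows[[length(rows) + 1]] <- eval_point(rc_i, p, f)
  }
  tab <- do.call(rbind, rows)
  ok <- stats::complete.cases(tab[, c("switching_time_h", "sensitivity",
                                      "response_time_h")])
  corr <- function(a, b) if (sum(ok) >= 3)
    stats::cor(log10(a[ok]), log10(b[ok])) else NA_real_
  structure(list(table = tab,
                 cor_switch_sensitivity =
                   corr(tab$switching_time_h, tab$sensitivity),
                 cor_switch_response =
                   corr(tab$switching_time_h, tab$response_time_h)),
            class = "sensitivity_report")
}

default_metric_fns <- function(seed, n_cells = 50, hours = 12,
                               min_transitions = 60) {
  list(
    switching = function(rc) switching_time(
      cell_cycle_params(40), rc, seed = seed,
      min_transitions = min_transitions)$mfpt_h,
    bistability = function(rc) {
      hs <- hysteresis_scan(rc, step = 2)
      if (hs$bistable) hs$range_ratio else NA_real_
    },
    sensitivity = function(rc) {
      r_at <- function(T_min) {
        cfg <- simulation_config(cell_cycle_params(T_min), rc,
                                 t_end_hours = hours, seed = seed,
                                 record_dt_s = 0, burnin_generations = 15)
        run_ensemble(cfg, n_cells)$R_protein
      }
      r_at(30) / r_at(60)
    },
    response = function(rc) shift_response(rc, n_cells = n_cells,
                                           hours = hours,
                                           seed = seed)$tau_geo_h)
}
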