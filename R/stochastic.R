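#' Configuration of a stochastic lineage simulation
#'
#' Collects everything an exact simulation run needs: cell-cycle geometry,
#' kinetic constants, gene placement, horizon, seed and the initial-condition
#' mode. A single daughter lineage is followed across divisions.
#'
#' @param cc a [cell_cycle_params()].
#' @param rc a [rate_constants()].
#' @param loci list with `ori` and `ter` [locus_spec()]s.
#' @param t_end_hours simulated time after burn-in, hours.
#' @param seed integer seed; required (runs refuse to start unseeded).
#' @param record_dt_s trajectory sampling interval in seconds (0 = no
#'   trajectory, summaries only).
#' @param init one of `"symmetric"` (all genes active, no molecules, long
#'   burn-in), `"ori-dominant"`, `"ter-dominant"` (burn-in under transiently
#'   biased dosage so the lineage starts committed to that state) or
#'   `"explicit"` (supply `init_state`).
#' @param init_state for `init = "explicit"`: list with integer vectors
#'   `copies`, `active`, `m`, `p`, `d` (ori first) and scalar `age` (minutes).
#' @param burnin_generations burn-in length in generations before recording.
#' @param fixed_volume if non-NULL, freeze the volume at this value (no
#'   growth); used with `replication_schedule = FALSE` for reduced-model
#'   validation against the chemical master equation.
#' @param replication_schedule if FALSE, no replication or division events
#'   fire and gene copy numbers stay at their initial values.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(cc, rc, loci = default_loci(),
                              t_end_hours = 10, seed,
                              record_dt_s = 60, init = "symmetric",
                              init_state = NULL, burnin_generations = 20,
                              fixed_volume = NULL,
                              replication_schedule = TRUE) {
  stopifnot(inherits(cc, "cell_cycle_params"), inherits(rc, "rate_constants"))
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("an explicit integer seed is required for stochastic runs",
         call. = FALSE)
  if (t_end_hours <= 0) stop("t_end_hours must be positive", call. = FALSE)
  init <- match.arg(init, c("symmetric", "ori-dominant", "ter-dominant",
                            "explicit"))
  if (init == "explicit" && is.null(init_state))
    stop("init = 'explicit' needs init_state", call. = FALSE)
  structure(list(cc = cc, rc = rc, loci = loci, t_end_hours = t_end_hours,
                 seed = as.numeric(seed), record_dt_s = record_dt_s,
                 init = init, init_state = init_state,
                 burnin_generations = burnin_generations,
                 fixed_volume = fixed_volume,
                 replication_schedule = replication_schedule),
            class = "simulation_config")
}

# parameter block handed to the C++ core (everything in seconds)
ssa_par <- function(cfg, loci = cfg$loci) {
  cc <- cfg$cc; rc <- cfg$rc
  er <- effective_rates(rc, cc, t = 0)
  ph <- lapply(loci, locus_phase, cc = cc)
  list(T = cc$T * 60,
       k_g = rc$k_g, r_g_scale = rc$r_g_scale,
       k_m = er$k_m, k_p = er$k_p,
       k_d_scale = rc$k_d_scale, r_d = rc$r_d, r_m = rc$r_m,
       V0 = v0_of_T(cc$T),
       vol_fixed = if (is.null(cfg$fixed_volume)) -1 else cfg$fixed_volume,
       no_schedule = !cfg$replication_schedule,
       base_copies = c(ph$ori$base, ph$ter$base),
       rep_age = vapply(ph, function(z)
         if (is.na(z$rep_age)) -1 else z$rep_age * 60, numeric(1)))
}

fresh_state <- function(cfg, loci = cfg$loci) {
  ph <- lapply(loci, locus_phase, cc = cfg$cc)
  copies <- vapply(ph, function(z) z$base, numeric(1))
  list(copies = as.integer(copies), active = as.integer(copies),
       m = c(0L, 0L), p = c(0L, 0L), d = c(0L, 0L), age = 0)
}

# run the core once; state in, state out
ssa_call <- function(par, state, t_end_s, seed, record_dt = 0, avg_start = 0,
                     detect = FALSE, dominant = 0L, stop_at_switch = FALSE,
                     collect = FALSE) {
  ssa_run_cpp(par, state, t_end_s, record_dt, avg_start, seed,
              detect, as.integer(dominant), stop_at_switch, collect)
}

# a run can stop exactly on a division boundary; restart just before it so
# the division fires first in the continuation
clamp_age <- function(st, T_s) {
  if (st$age >= T_s) st$age <- T_s * (1 - 1e-12)
  st
}

# burn-in producing the configured initial condition; returns a state list
prepare_initial_state <- function(cfg, seed) {
  T_s <- cfg$cc$T * 60
  if (cfg$init == "explicit") {
    st <- cfg$init_state
    st$age <- st$age * 60
    return(clamp_age(st, T_s))
  }
  st <- fresh_state(cfg)
  gens <- cfg$burnin_generations
  if (!cfg$replication_schedule || gens <= 0) return(st)
  if (cfg$init %in% c("ori-dominant", "ter-dominant")) {
    # transient dosage bias: the favored gene is carried at 4x its inserted
    # copy number during most of the burn-in, committing the lineage
    fav <- sub("-dominant", "", cfg$init)
    biased <- cfg$loci
    biased[[fav]] <- locus_spec(biased[[fav]]$L,
                                biased[[fav]]$n_inserted * 4L)
    par_b <- ssa_par(cfg, loci = biased)
    st_b <- fresh_state(cfg, loci = biased)
    res <- ssa_call(par_b, st_b, max(gens - 2, 1) * T_s, seed = seed + 1000003)
    st <- res$final
    # gene bookkeeping back to the unbiased design
    st$copies <- fresh_state(cfg)$copies
    st$active <- pmin(st$active, st$copies)
    st$age <- 0
    res <- ssa_call(ssa_par(cfg), st, 2 * T_s, seed = seed + 2000003)
    return(clamp_age(res$final, T_s))
  }
  res <- ssa_call(ssa_par(cfg), st, gens * T_s, seed = seed + 1000003)
  clamp_age(res$final, T_s)
}

traj_df <- function(mat) {
  df <- as.data.frame(mat)
  names(df) <- c("time_s", "age_s", "N_ori", "N_ter", "G_active_ori",
                 "G_active_ter", "M_ori", "M_ter", "P_ori", "P_ter",
                 "D_ori", "D_ter", "V")
  df
}

#' Simulate a single cell lineage
#'
#' Exact stochastic simulation of the toggle in a growing cell, following one
#' daughter after each division, after the configured burn-in. Identical
#' seeds give identical trajectories.
#'
#' @param cfg a [simulation_config()].
#' @param avg_start_hours start of the window for time-averaged summaries
#'   (hours into the recorded run).
#' @param detect detect first passage out of the initial dominant state
#'   (requires `init` "ori-dominant" or "ter-dominant").
#' @param stop_at_switch end the run at the first detected switch (implies
#'   `detect`); time averages then cover only the pre-switch window, which
#'   gives uncontaminated within-state expression for short-lived states.
#' @param collect_transitions keep simulating through successive switches and
#'   collect every state-to-state passage time.
#' @return a list of class `lineage_run`: `trajectory` (data frame, one row
#'   per sample), `avg` (time-averaged molecule contents over the window),
#'   `audit` (event-accounting counters), `fpt_hours` (first passage, NA if
#'   censored), `transitions` (data frame of passage durations in hours and
#'   the gene dominant before each), and `final` state.
#' @export
simulate_lineage <- function(cfg, avg_start_hours = 0, detect = FALSE,
                             stop_at_switch = FALSE,
                             collect_transitions = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  st <- prepare_initial_state(cfg, cfg$seed)
  dominant <- switch(cfg$init, "ori-dominant" = 0L, "ter-dominant" = 1L, 0L)
  if ((detect || stop_at_switch || collect_transitions) &&
      !cfg$init %in% c("ori-dominant", "ter-dominant"))
    stop("switch detection needs an ori-dominant or ter-dominant start",
         call. = FALSE)
  res <- ssa_call(ssa_par(cfg), st, cfg$t_end_hours * 3600, seed = cfg$seed,
                  record_dt = cfg$record_dt_s,
                  avg_start = avg_start_hours * 3600,
                  detect = detect || stop_at_switch || collect_transitions,
                  dominant = dominant, stop_at_switch = stop_at_switch,
                  collect = collect_transitions)
  tr <- res$transitions
  structure(list(
    trajectory = if (cfg$record_dt_s > 0) traj_df(res$trajectory) else NULL,
    avg = res$avg,
    audit = res$audit,
    fpt_hours = if (res$fpt >= 0) res$fpt / 3600 else NA_real_,
    transitions = data.frame(duration_h = tr$duration_s / 3600,
                             from = c("ori", "ter")[tr$from_gene + 1]),
    final = res$final,
    initial = st,
    config = cfg
  ), class = "lineage_run")
}

#' Run an ensemble of independent lineages
#'
#' Lineage `i` uses seed `base_seed + i`. Population summaries are taken over
#' per-lineage time averages (exact time-weighted means, not sampled) and
#' over final-time states.
#'
#' @param cfg a [simulation_config()].
#' @param n_cells number of lineages.
#' @param base_seed base seed (defaults to the config seed).
#' @param avg_start_hours start of the per-lineage averaging window (hours).
#' @param record keep and average full trajectories (memory-heavier); when
#'   TRUE the summary carries a `time_series` data frame of population means.
#' @return an object of class `ensemble_summary` with per-lineage window
#'   averages, final-state counts, the population `R_protein` (ratio of mean
#'   total ori protein to mean total ter protein) and optional time series.
#' @export
run_ensemble <- function(cfg, n_cells, base_seed = cfg$seed,
                         avg_start_hours = 0, record = FALSE) {
  stopifnot(n_cells >= 1)
  per <- vector("list", n_cells)
  ts_acc <- NULL
  for (i in seq_len(n_cells)) {
    cfg_i <- cfg
    cfg_i$seed <- base_seed + i
    if (!record) cfg_i$record_dt_s <- 0
    run <- simulate_lineage(cfg_i, avg_start_hours = avg_start_hours)
    per[[i]] <- data.frame(
      lineage = i, seed = cfg_i$seed,
      tot_ori = run$avg$total_protein[1], tot_ter = run$avg$total_protein[2],
      final_tot_ori = run$final$p[1] + 2 * run$final$d[1],
      final_tot_ter = run$final$p[2] + 2 * run$final$d[2])
    if (record) {
      tp <- run$trajectory
      v <- cbind(tp$P_ori + 2 * tp$D_ori, tp$P_ter + 2 * tp$D_ter)
      if (is.null(ts_acc)) {
        ts_acc <- v; ts_time <- tp$time_s
      } else ts_acc <- ts_acc + v
    }
  }
  per <- do.call(rbind, per)
  out <- list(
    per_lineage = per,
    n_cells = n_cells,
    R_protein = mean(per$tot_ori) / mean(per$tot_ter),
    final_tot = per[, c("final_tot_ori", "final_tot_ter")],
    config = cfg, base_seed = base_seed)
  if (record)
    out$time_series <- data.frame(time_s = ts_time,
                                  mean_tot_ori = ts_acc[, 1] / n_cells,
                                  mean_tot_ter = ts_acc[, 2] / n_cells)
  structure(out, class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("ensemble of %d lineages: R_protein = %.4g\n",
              x$n_cells, x$R_protein))
  invisible(x)
}

#' Reaction-channel propensities of a stochastic state
#'
#' Pure-R evaluation of the 14 aggregated reaction channels (the per-copy
#' gene channels grouped over the exchangeable copies of each gene), mainly
#' as an independently checkable reference for the simulator core.
#'
#' @param state list with `copies`, `active`, `m`, `p`, `d` (ori first).
#' @param er an [effective_rates()] evaluated at the state's volume.
#' @return named numeric vector of channel rates (1/s).
#' @export
propensities <- function(state, er) {
  stopifnot(inherits(er, "effective_rates"))
  with(state, {
    if (any(c(m, p, d) < 0) || any(active < 0) || any(active > copies))
      stop("invalid state", call. = FALSE)
    a <- numeric(0)
    for (i in 1:2) {
      o <- 3 - i
      a <- c(a,
             er$k_g * (copies[i] - active[i]),
             er$r_g * d[o] * active[i],
             er$k_m * active[i],
             er$r_m * m[i],
             er$k_p * m[i],
             er$k_d * p[i] * (p[i] - 1),
             er$r_d * d[i])
    }
    names(a) <- as.vector(outer(c("activate", "repress", "transcribe",
                                  "mrna_decay", "translate", "dimerize",
                                  "dissociate"), c("ori", "ter"),
                                function(x, y) paste(x, y, sep = "_")))
    a
  })
}

#' Binomial partitioning at cell division
#'
#' Applies the division rule to a pre-division state: every free molecule
#' goes to the followed daughter with probability 1/2; loci that doubled
#' within the cycle keep one copy of each replicated pair (uniformly chosen,
#' carrying its repression state and any bound dimer); loci whose doubling
#' coincides with division release their bound repressors and restart fully
#' active.
#'
#' @param state list with `copies`, `active`, `m`, `p`, `d` (ori first).
#' @param cc a [cell_cycle_params()].
#' @param loci list with `ori` and `ter` [locus_spec()]s.
#' @param seed integer seed.
#' @return list with the daughter state plus `bound_lost` and `released`
#'   dimer counts per gene.
#' @export
partition_at_division <- function(state, cc, loci = default_loci(), seed) {
  ph <- lapply(loci, locus_phase, cc = cc)
  rep_age <- vapply(ph, function(z)
    if (is.na(z$rep_age)) -1 else z$rep_age * 60, numeric(1))
  ssa_partition_cpp(as.integer(state$copies), as.integer(state$active),
                    as.integer(state$m), as.integer(state$p),
                    as.integer(state$d), rep_age, seed)
}
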