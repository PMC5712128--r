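#' Deterministic state of the toggle switch
#'
#' Continuous-variable approximation: gene activities `G` in `[0, 1]`, mRNA
#' `M`, protein monomer `P` and dimer `D` levels for both genes. Copy numbers
#' enter as cycle averages, division as a dilution term `ln(2)/T`, and the
#' volume is held at its pre-division value `2 V0(T)`.
#'
#' @param G_ori,G_ter gene activities in `[0, 1]`.
#' @param M_ori,M_ter,P_ori,P_ter,D_ori,D_ter non-negative molecule levels.
#' @return a named numeric state vector of class `deterministic_state`.
#' @export
deterministic_state <- function(G_ori = 1, G_ter = 1, M_ori = 0, M_ter = 0,
                                P_ori = 0, P_ter = 0, D_ori = 0, D_ter = 0) {
  s <- vapply(list(G_ori, G_ter, M_ori, M_ter, P_ori, P_ter, D_ori, D_ter),
              function(v) as.numeric(v)[1], numeric(1))
  names(s) <- c("G_ori", "G_ter", "M_ori", "M_ter",
                "P_ori", "P_ter", "D_ori", "D_ter")
  if (any(!is.finite(s))) stop("state must be finite", call. = FALSE)
  if (s["G_ori"] < 0 || s["G_ori"] > 1 || s["G_ter"] < 0 || s["G_ter"] > 1)
    stop("gene activities must lie in [0, 1]", call. = FALSE)
  if (any(s[3:8] < 0)) stop("molecule levels must be >= 0", call. = FALSE)
  structure(s, class = c("deterministic_state", "numeric"))
}

# effective rates at the constant deterministic volume 2 V0(T)
det_rates <- function(rc, cc) {
  effective_rates(rc, cc, volume = 2 * v0_of_T(cc$T))
}

# cycle-average copy numbers of the two inserted genes (exact schedule)
det_copies <- function(cc, loci) {
  c(ori = mean_copies(loci$ori, cc), ter = mean_copies(loci$ter, cc))
}

# precomputed constants for the RHS (rates are T-dependent but state-free)
det_parms <- function(rc, cc, loci) {
  er <- det_rates(rc, cc)
  S <- det_copies(cc, loci)
  list(kg = er$k_g, rg = er$r_g, km = er$k_m, kp = er$k_p, kd = er$k_d,
       rd = er$r_d, rm = er$r_m, dil = log(2) / (cc$T * 60),
       S_ori = S[["ori"]], S_ter = S[["ter"]])
}

det_rhs_core <- function(y, pp) {
  c(pp$kg * (1 - y[1]) - pp$rg * y[8] * y[1],
    pp$kg * (1 - y[2]) - pp$rg * y[7] * y[2],
    pp$S_ori * pp$km * y[1] - (pp$rm + pp$dil) * y[3],
    pp$S_ter * pp$km * y[2] - (pp$rm + pp$dil) * y[4],
    pp$kp * y[3] - pp$dil * y[5] + 2 * (pp$rd * y[7] - 0.5 * pp$kd * y[5]^2),
    pp$kp * y[4] - pp$dil * y[6] + 2 * (pp$rd * y[8] - 0.5 * pp$kd * y[6]^2),
    0.5 * pp$kd * y[5]^2 - (pp$rd + pp$dil) * y[7],
    0.5 * pp$kd * y[6]^2 - (pp$rd + pp$dil) * y[8])
}

#' Right-hand side of the deterministic toggle equations
#'
#' Eight coupled ODEs: each gene's activity relaxes toward 1 at rate `k_g`
#' and is pulled down by the competing dimer at rate `r_g D`; transcription is
#' proportional to the cycle-averaged copy number; monomers and dimers
#' exchange through mass-action dimerization `(1/2) k_d P^2` and dissociation
#' `r_d D`; every molecular species is diluted at `ln(2)/T`.
#'
#' @param s a [deterministic_state()] (or named numeric vector in its order).
#' @param rc a [rate_constants()].
#' @param cc a [cell_cycle_params()].
#' @param loci list with `ori` and `ter` [locus_spec()]s (defaults: one copy
#'   at ori, two at ter).
#' @return named numeric vector of time derivatives (per second).
#' @export
ode_rhs <- function(s, rc, cc, loci = default_loci()) {
  pp <- det_parms(rc, cc, loci)
  dy <- det_rhs_core(as.numeric(s)[1:8], pp)
  names(dy) <- c("G_ori", "G_ter", "M_ori", "M_ter",
                 "P_ori", "P_ter", "D_ori", "D_ter")
  dy
}

#' Relax the deterministic system to a steady state
#'
#' Integrates the stiff system (gene switching at ~1e-3/s against dimer
#' kinetics at 1e-1/s) with lsoda in chunks until the scaled derivative norm
#' `max(|ds/dt| / max(|s|, 1))` falls below `tol`, or flags non-convergence.
#'
#' @inheritParams ode_rhs
#' @param s0 initial [deterministic_state()].
#' @param tol steady-state tolerance on scaled derivatives (1/s).
#' @param t_max integration horizon in seconds.
#' @return the final state with attributes `converged` (logical) and
#'   `residual` (scaled derivative norm).
#' @export
relax_to_steady_state <- function(s0, rc, cc, loci = default_loci(),
                                  tol = 1e-9, t_max = 4e7) {
  y <- as.numeric(unclass(s0))[1:8]
  pp <- det_parms(rc, cc, loci)
  rhs <- function(t, y, parms) list(det_rhs_core(y, pp))
  chunk <- 2e5
  t_done <- 0
  resid <- function(y) max(abs(det_rhs_core(y, pp)) / pmax(abs(y), 1))
  while (t_done < t_max) {
    out <- deSolve::lsoda(y, c(0, chunk), rhs, parms = NULL,
                          rtol = 1e-8, atol = 1e-10, maxsteps = 50000)
    y <- out[nrow(out), -1]
    # integration cannot leave the invariant region; clip roundoff only
    y[3:8] <- pmax(y[3:8], 0)
    y[1:2] <- pmin(pmax(y[1:2], 0), 1)
    t_done <- t_done + chunk
    if (resid(y) < tol) break
    chunk <- min(chunk * 2, 8e6)
  }
  r <- resid(y)
  out <- deterministic_state(y[1], y[2], y[3], y[4], y[5], y[6], y[7], y[8])
  attr(out, "converged") <- r < tol
  attr(out, "residual") <- r
  if (r >= tol)
    warning(sprintf("steady-state relaxation did not converge (residual %.3g)", r),
            call. = FALSE)
  out
}

#' Total-protein expression ratio of a deterministic state
#'
#' `(P_ori + 2 D_ori) / (P_ter + 2 D_ter)`.
#'
#' @param s a [deterministic_state()].
#' @return the ratio (real).
#' @export
state_protein_ratio <- function(s) {
  (s[["P_ori"]] + 2 * s[["D_ori"]]) / (s[["P_ter"]] + 2 * s[["D_ter"]])
}

#' Quasi-static hysteresis scan over the doubling time
#'
#' Sweeps T upward and downward over a grid, relaxing to a steady state at
#' each T from the previous sweep state (continuation). A fold is detected as
#' a jump of the log2 total-protein ratio exceeding `jump_log2` between
#' adjacent grid points; the system is bistable when the two sweeps place
#' their folds at different T (up-sweep fold at larger T than down-sweep).
#'
#' @param rc a [rate_constants()].
#' @param T_lo,T_hi sweep limits in minutes.
#' @param step grid step in minutes.
#' @param loci list with `ori` and `ter` [locus_spec()]s.
#' @param jump_log2 fold-detection threshold on `|delta log2 ratio|`.
#' @param tol,t_max passed to [relax_to_steady_state()].
#' @return a list of class `hysteresis_result`: `bistable`, `T_up_fold`,
#'   `T_down_fold`, `range_ratio` (= T_up_fold/T_down_fold when bistable) and
#'   a data frame `sweep` with (T, direction, ratio, P_ori, P_ter).
#' @export
hysteresis_scan <- function(rc, T_lo = 20, T_hi = 120, step = 0.5,
                            loci = default_loci(), jump_log2 = 1,
                            tol = 1e-9, t_max = 4e7) {
  grid <- seq(T_lo, T_hi, by = step)
  sweep_one <- function(Ts, start_extreme) {
    s <- start_extreme
    res <- vector("list", length(Ts))
    for (i in seq_along(Ts)) {
      cc <- cell_cycle_params(Ts[i])
      s <- relax_to_steady_state(s, rc, cc, loci, tol = tol, t_max = t_max)
      res[[i]] <- c(T = Ts[i], ratio = state_protein_ratio(s),
                    P_ori = s[["P_ori"]], P_ter = s[["P_ter"]],
                    converged = as.numeric(attr(s, "converged")))
      class(s) <- c("deterministic_state", "numeric")
    }
    as.data.frame(do.call(rbind, res))
  }
  # sweep starting states: the corresponding single-gene-dominant extremes
  ori_hi <- deterministic_state(1, 1, 10, 0, 200, 0, 100, 0)
  ter_hi <- deterministic_state(1, 1, 0, 10, 0, 200, 0, 100)
  up <- sweep_one(grid, ori_hi)
  down <- sweep_one(rev(grid), ter_hi)
  down <- down[nrow(down):1, ]
  up$direction <- "up"; down$direction <- "down"

  fold_T <- function(df) {
    jumps <- which(abs(diff(log2(df$ratio))) > jump_log2)
    if (length(jumps)) df$T[jumps[1] + 1] else NA_real_
  }
  T_up <- fold_T(up)       # ori branch lost while increasing T
  T_down <- fold_T(down[nrow(down):1, ]) # ter branch lost while decreasing T
  bistable <- !is.na(T_up) && !is.na(T_down) && T_up > T_down + step / 2
  structure(list(
    bistable = bistable,
    T_up_fold = T_up, T_down_fold = T_down,
    range_ratio = if (bistable) T_up / T_down else 1,
    sweep = rbind(up, down)
  ), class = "hysteresis_result")
}

#' @export
print.hysteresis_result <- function(x, ...) {
  if (x$bistable)
    cat(sprintf("bistable: folds at T = %.1f (up) / %.1f (down) min, range ratio %.3f\n",
                x$T_up_fold, x$T_down_fold, x$range_ratio))
  else cat("monostable over the scanned range\n")
  invisible(x)
}

#' Default gene placement: one copy at ori, two at ter
#'
#' @return list with `ori` and `ter` [locus_spec()]s.
#' @export
default_loci <- function() list(ori = locus_spec(0, 1L), ter = locus_spec(1, 2L))
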