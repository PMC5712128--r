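#' Cell-cycle and replication-geometry parameters
#'
#' Bundles the doubling time `T`, the genome replication (C-period) time and
#' the termination-to-division (D-period) gap that together determine when a
#' chromosomal locus doubles its copy number within the cell cycle
#' (Cooper-Helmstetter geometry). All three are in minutes.
#'
#' @param T_min doubling time in minutes (supported regime 20-120).
#' @param C_min replication time in minutes (default 40, the E. coli C period).
#' @param D_min termination-to-division period in minutes (default 20).
#' @return an object of class `cell_cycle_params`.
#' @examples
#' cc <- cell_cycle_params(40)
#' mean_copies(locus_spec(0), cc)
#' @export
cell_cycle_params <- function(T_min, C_min = 40, D_min = 20) {
  stopifnot(is.numeric(T_min), length(T_min) == 1L, is.finite(T_min))
  if (T_min < 20 || T_min > 120)
    stop("doubling time T must be in [20, 120] minutes", call. = FALSE)
  if (C_min <= 0) stop("replication time C must be positive", call. = FALSE)
  if (D_min < 0) stop("D period must be non-negative", call. = FALSE)
  structure(list(T = T_min, C = C_min, D = D_min),
            class = "cell_cycle_params")
}

#' @export
print.cell_cycle_params <- function(x, ...) {
  cat(sprintf("cell cycle: T = %g min, C = %g min, D = %g min\n",
              x$T, x$C, x$D))
  invisible(x)
}

#' Chromosomal locus of an inserted gene
#'
#' @param L distance from the replication origin, in units where the ori-ter
#'   distance is 1 (so `L = 0` is at ori, `L = 1` at ter).
#' @param n_inserted number of identical tandem-inserted copies at the locus.
#' @return an object of class `locus_spec`.
#' @export
locus_spec <- function(L, n_inserted = 1L) {
  stopifnot(is.numeric(L), length(L) == 1L, is.finite(L))
  if (L < 0 || L > 1) stop("locus distance L must be in [0, 1]", call. = FALSE)
  n_inserted <- as.integer(n_inserted)
  if (is.na(n_inserted) || n_inserted < 1L)
    stop("n_inserted must be a positive integer", call. = FALSE)
  structure(list(L = L, n_inserted = n_inserted), class = "locus_spec")
}

# Age (minutes, in [0, T)) at which a locus doubles, or NA when the doubling
# coincides with division (x is a multiple of T) and the count stays constant.
# x = C*(1-L) + D is the time from a locus' replication to the division that
# separates the two new chromosomes.
locus_phase <- function(locus, cc) {
  x <- cc$C * (1 - locus$L) + cc$D
  r <- x %% cc$T
  list(x = x, base = locus$n_inserted * 2^floor(x / cc$T),
       rep_age = if (r == 0) NA_real_ else cc$T - r)
}

#' Instantaneous gene copy number at a given cell age
#'
#' Copy number of a locus at cell age `t` under steady-state overlapping
#' replication rounds: all copies of a locus double once per cycle at the age
#' set by its distance from ori, or stay constant over the whole cycle when
#' that doubling coincides with division.
#'
#' @param locus a [locus_spec()].
#' @param cc a [cell_cycle_params()].
#' @param t cell age in minutes, in `[0, T)`; vectorised.
#' @return integer copy count(s).
#' @export
copies_at_age <- function(locus, cc, t) {
  stopifnot(inherits(locus, "locus_spec"), inherits(cc, "cell_cycle_params"))
  if (any(t < 0 | t >= cc$T))
    stop("cell age t must be in [0, T)", call. = FALSE)
  ph <- locus_phase(locus, cc)
  if (is.na(ph$rep_age)) rep(ph$base, length(t))
  else ph$base * ifelse(t >= ph$rep_age, 2L, 1L)
}

#' Cycle-averaged gene copy number (exact)
#'
#' Exact time average of [copies_at_age()] over one cell cycle, by piecewise
#' integration of the replication schedule. For `L = 0` and `L = 1` with the
#' default C and D periods this reproduces the classical piecewise-in-T ori
#' and ter averages (e.g. 8 ori and 2 ter copies at T = 20 min).
#'
#' @inheritParams copies_at_age
#' @return average copy count (real).
#' @export
mean_copies <- function(locus, cc) {
  stopifnot(inherits(locus, "locus_spec"), inherits(cc, "cell_cycle_params"))
  ph <- locus_phase(locus, cc)
  if (is.na(ph$rep_age)) ph$base
  else ph$base * (1 + (cc$T - ph$rep_age) / cc$T)
}

#' Cycle-averaged gene copy number (exponential approximation)
#'
#' The smooth approximation `n * S_ter(T) * 2^((1-L) C/T)`, with
#' `S_ter(T) = 1 + D/T` the terminus average. Agrees with [mean_copies()] to
#' within ~10% over the supported regime.
#'
#' @inheritParams copies_at_age
#' @return average copy count (real).
#' @export
mean_copies_approx <- function(locus, cc) {
  stopifnot(inherits(locus, "locus_spec"), inherits(cc, "cell_cycle_params"))
  s_ter <- 1 + cc$D / cc$T
  locus$n_inserted * s_ter * 2^((1 - locus$L) * cc$C / cc$T)
}

#' Genome-wide average gene copy number S(T)
#'
#' DNA content per cell in genome equivalents: the gene copy number averaged
#' over all loci and over the cell cycle. The exact form is piecewise in T;
#' `approx = TRUE` returns the smooth variant
#' `(1/ln 2) (T/40 + 1/2) (2^(40/T) - 1)`.
#'
#' @param cc a [cell_cycle_params()].
#' @param approx use the smooth approximation instead of the piecewise form.
#' @return S(T) (real, >= 1).
#' @export
genome_average_copies <- function(cc, approx = FALSE) {
  stopifnot(inherits(cc, "cell_cycle_params"))
  T <- cc$T
  if (approx)
    return((1 / log(2)) * (T / 40 + 1 / 2) * (2^(40 / T) - 1))
  if (T < 30) 9 * T / 80 + 175 / T - 6.5
  else if (T < 60) T / 80 + 85 / T - 0.5
  else 1 + 40 / T
}

#' Cycle-averaged dosage ratio of two loci
#'
#' The average copy-number ratio of a locus at distance `L2` to one at `L1`
#' is `2^((C/T)(L2 - L1))`: one extra ori-ter span of separation multiplies
#' the ratio by `2^(C/T)` (about 4 at T = 20 min, 2 at T = 40 min).
#'
#' @param L1,L2 locus distances from ori in `[0, 1]`.
#' @param cc a [cell_cycle_params()].
#' @return the average copy number at L1 divided by that at L2, i.e.
#'   `2^((C/T)(L2 - L1))` (> 1 when L1 is closer to ori).
#' @export
dosage_ratio <- function(L1, L2, cc) {
  stopifnot(inherits(cc, "cell_cycle_params"))
  if (any(c(L1, L2) < 0 | c(L1, L2) > 1))
    stop("locus distances must be in [0, 1]", call. = FALSE)
  2^((cc$C / cc$T) * (L2 - L1))
}

#' Locus distance balancing a given inserted-copy ratio
#'
#' For a design with inserted-copy ratio `R = n_ori/n_ter` (gene at ori in
#' fewer copies), the distance `L2 = -(T/C) log2 R` places the second gene so
#' that the average effective copy numbers (and hence average expression under
#' equal kinetics) of the two genes are equal at doubling time T. The value
#' may exceed 1; admissibility is the caller's decision.
#'
#' @param R inserted-copy ratio in `(0, 1]`.
#' @param cc a [cell_cycle_params()].
#' @return the balancing distance L2 (real, >= 0).
#' @export
balanced_locus <- function(R, cc) {
  stopifnot(inherits(cc, "cell_cycle_params"))
  if (any(R <= 0 | R > 1))
    stop("copy ratio R must be in (0, 1]", call. = FALSE)
  -(cc$T / cc$C) * log2(R)
}

#' Best admissible balanced design at a given doubling time
#'
#' Enumerates candidate inserted-copy ratios and returns the one whose
#' balancing locus distance [balanced_locus()] is the largest while still on
#' the chromosome (`L2 <= 1`); sensitivity to the doubling time grows with
#' the loci separation, so the largest admissible `L2` is the best design.
#' Ties are broken toward the smaller ratio.
#'
#' @param cc a [cell_cycle_params()].
#' @param candidate_ratios candidate inserted-copy ratios; the default set
#'   covers designs with 1-4 copies of the ori-proximal and 2-5 copies of the
#'   ter-proximal gene.
#' @return a list with elements `ratio`, `L2` and `admissible` (FALSE with
#'   `ratio`/`L2` NA when no candidate fits on the chromosome).
#' @export
best_balanced_design <- function(cc,
                                 candidate_ratios = c(1/4, 1/3, 2/5, 1/2,
                                                      3/5, 2/3, 3/4, 4/5)) {
  stopifnot(inherits(cc, "cell_cycle_params"), length(candidate_ratios) >= 1)
  l2 <- vapply(candidate_ratios, balanced_locus, numeric(1), cc = cc)
  ok <- l2 <= 1
  if (!any(ok))
    return(list(ratio = NA_real_, L2 = NA_real_, admissible = FALSE))
  best <- max(l2[ok])
  # ties toward smaller R
  cand <- candidate_ratios[ok & abs(l2 - best) < 1e-12]
  list(ratio = min(cand), L2 = best, admissible = TRUE)
}

#' Scaled cell volume
#'
#' Volume just after division is `V0(T) = (1/6)(40/T)^2 + 1/3` in scaled
#' units (V0 = 0.5 at T = 40 min), decreasing with the doubling time as
#' observed for E. coli cell size; growth is exponential, doubling over one
#' cycle: `V(t) = V0 * 2^(t/T)`.
#'
#' @param cc a [cell_cycle_params()].
#' @param t cell age in minutes in `[0, T]`; vectorised.
#' @return scaled volume(s).
#' @export
volume_at_age <- function(cc, t) {
  stopifnot(inherits(cc, "cell_cycle_params"))
  if (any(t < 0 | t > cc$T)) stop("cell age t must be in [0, T]", call. = FALSE)
  v0_of_T(cc$T) * 2^(t / cc$T)
}

v0_of_T <- function(T_min) (1 / 6) * (40 / T_min)^2 + 1 / 3
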