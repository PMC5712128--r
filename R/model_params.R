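#' Kinetic rate constants of the toggle switch
#'
#' Holds the kinetic parametrization of the two-gene toggle. All rates are per
#' second. Bimolecular rates (repressor-promoter binding, dimerization) are
#' stored as numerators and divided by the scaled cell volume when evaluated;
#' transcription is stored as a numerator divided by the genome-average copy
#' number S(T) (free RNA polymerase, not DNA, limits total transcription);
#' translation scales with the growth rate times the post-division volume so
#' that protein concentration stays constant across growth rates. Proteins are
#' not degraded, only diluted by growth and division.
#'
#' @param k_g gene activation (repressor unbinding) rate, 1/s.
#' @param r_g_scale repressor-promoter binding numerator; the effective rate
#'   is `r_g_scale / V(t,T)`. The reference settings are 5e-4, 2e-3 and
#'   3.5e-3 (see [rg_label()]); 0 uncouples the two genes.
#' @param k_m_scale transcription numerator; effective rate `k_m_scale/S(T)`
#'   per active gene copy.
#' @param k_p_scale translation scale; effective rate
#'   `2 V0(T) (40/T) k_p_scale` per mRNA.
#' @param k_d_scale dimerization numerator; effective rate `k_d_scale/V(t,T)`.
#' @param r_d dimer dissociation rate, 1/s.
#' @param r_m mRNA degradation rate, 1/s.
#' @return an object of class `rate_constants`.
#' @export
rate_constants <- function(k_g = 2e-3, r_g_scale = 2e-3, k_m_scale = 5e-3,
                           k_p_scale = 1e-2, k_d_scale = 1e-3,
                           r_d = 1e-1, r_m = 3e-3) {
  vals <- c(k_g = k_g, r_g_scale = r_g_scale, k_m_scale = k_m_scale,
            k_p_scale = k_p_scale, k_d_scale = k_d_scale, r_d = r_d, r_m = r_m)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all rate constants must be finite and non-negative", call. = FALSE)
  structure(as.list(vals), class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("rate constants (1/s):\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-10s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Map a published repression-strength label to its numerator
#'
#' The repression settings are referred to by the values 0.0005, 0.002 and
#' 0.0035; these are exactly the numerators of the volume-scaled binding rate
#' `r_g(t,T) = r_g_scale / V(t,T)`, so the mapping is the identity on any
#' non-negative value (0 means uncoupled genes).
#'
#' @param label one of 5e-4, 2e-3, 3.5e-3 or any non-negative number.
#' @return the `r_g_scale` numerator.
#' @export
rg_label <- function(label) {
  stopifnot(is.numeric(label), length(label) == 1L)
  if (!is.finite(label) || label < 0)
    stop("r_g label must be a non-negative number", call. = FALSE)
  label
}

#' Effective (volume- and T-dependent) reaction rates
#'
#' Evaluates the concrete per-second rates at a given cell age: bimolecular
#' rates are divided by the current volume, transcription by S(T), and
#' translation picks up its growth-rate scaling.
#'
#' @param rc a [rate_constants()].
#' @param cc a [cell_cycle_params()].
#' @param t cell age in minutes in `[0, T]`.
#' @param volume optional volume override (e.g. the constant volume `2 V0(T)`
#'   used by the deterministic approximation); defaults to
#'   [volume_at_age()] at age `t`.
#' @return a list of class `effective_rates` with elements `k_g`, `r_g`,
#'   `k_m`, `k_p`, `k_d`, `r_d`, `r_m` (all 1/s) plus `volume` and `S`.
#' @export
effective_rates <- function(rc, cc, t = 0, volume = NULL) {
  stopifnot(inherits(rc, "rate_constants"), inherits(cc, "cell_cycle_params"))
  V <- if (is.null(volume)) volume_at_age(cc, t) else volume
  if (V <= 0) stop("cell volume must be positive", call. = FALSE)
  S <- genome_average_copies(cc)
  structure(list(
    k_g = rc$k_g,
    r_g = rc$r_g_scale / V,
    k_m = rc$k_m_scale / S,
    k_p = 2 * v0_of_T(cc$T) * (40 / cc$T) * rc$k_p_scale,
    k_d = rc$k_d_scale / V,
    r_d = rc$r_d,
    r_m = rc$r_m,
    volume = V,
    S = S
  ), class = "effective_rates")
}
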