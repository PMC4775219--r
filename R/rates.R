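#' Rate constants for the GTPase-cycle models
#'
#' Bundles the microscopic rate constants used by the model builders. Time is
#' in seconds and concentrations in nM throughout, so bimolecular constants
#' are nM^-1 s^-1 and unimolecular constants s^-1.
#'
#' GEF is not modeled as an explicit enzyme in the constitutive models;
#' its activity is folded into the nucleotide-release rate on Ras-GDP via
#' `k_exch = k_per_gef * gef_conc`. Pass `k_exch` directly to override this
#' conversion (the two-state model conventionally runs at 0.05 s^-1).
#'
#' @param k_nt_on nucleotide association rate, nM^-1 s^-1.
#' @param k_exch GEF-driven nucleotide release rate on Ras-GDP, s^-1. When
#'   `NULL` (default) it is computed as `k_per_gef * gef_conc`.
#' @param gef_conc GEF concentration in nM used to derive `k_exch`; ignored
#'   when `k_exch` is given. Default 1000 nM (1 uM), giving 0.005 s^-1.
#' @param k_per_gef conversion factor from GEF concentration to exchange
#'   rate, nM^-1 s^-1.
#' @param k_hyd intrinsic GTP hydrolysis rate from free Ras-GTP, s^-1.
#' @param k_hyd_eff hydrolysis rate from the effector-bound state, s^-1.
#'   Hydrolysis continues underneath a bound effector by default.
#' @param k_eff_on,k_eff_off effector binding/unbinding to Ras-GTP
#'   (c-Raf-like defaults, Kd = 10 nM).
#' @param k_gap_on,k_gap_off,k_gap_cat GAP binding, unbinding and committed
#'   catalysis from the GT_GAP complex.
#' @param k_gi_reset relaxation of the GEF-refractory post-hydrolysis state
#'   GI back to ordinary Ras-GDP, s^-1.
#' @return An object of class `rate_constants` (a named list).
#' @examples
#' rate_constants()                    # canonical models 2-3 constants
#' rate_constants(gef_conc = 200)      # 200 nM GEF input
#' rate_constants(k_gap_off = 0.01, k_gap_cat = 0.1)  # NF1-like GAP
#' @export
rate_constants <- function(k_nt_on = 1,
                           k_exch = NULL,
                           gef_conc = 1000,
                           k_per_gef = 5e-6,
                           k_hyd = 1e-4,
                           k_hyd_eff = 1e-4,
                           k_eff_on = 1e-4,
                           k_eff_off = 1e-3,
                           k_gap_on = 1e-4,
                           k_gap_off = 1e-2,
                           k_gap_cat = 1,
                           k_gi_reset = 1e-4) {
  if (is.null(k_exch)) k_exch <- k_per_gef * gef_conc
  k <- list(k_nt_on = k_nt_on, k_exch = k_exch, gef_conc = gef_conc,
            k_per_gef = k_per_gef, k_hyd = k_hyd, k_hyd_eff = k_hyd_eff,
            k_eff_on = k_eff_on, k_eff_off = k_eff_off,
            k_gap_on = k_gap_on, k_gap_off = k_gap_off,
            k_gap_cat = k_gap_cat, k_gi_reset = k_gi_reset)
  bad <- names(k)[vapply(k, function(x) !is.numeric(x) || length(x) != 1 ||
                           is.na(x) || x < 0, logical(1))]
  if (length(bad))
    stop("rate constants must be single non-negative numbers: ",
         paste(bad, collapse = ", "))
  structure(k, class = "rate_constants")
}

#' GAP kinetic presets
#'
#' Off-rate/catalytic-rate pairs characterising different GAPs, with the
#' binding rate fixed at 1e-4 nM^-1 s^-1:
#' * `"physiologic"`: k_off = 0.01 s^-1, k_cat = 1 s^-1.
#' * `"non_physiologic"`: k_off = 1e-4 s^-1, k_cat = 1e-4 s^-1 (slow-release,
#'   slow-catalysis regime in which even a two-state competition model can
#'   overshoot).
#' * `"nf1_like"`: k_off = 0.01 s^-1, k_cat = 0.1 s^-1.
#' * `"p120_like"`: k_off = 0.25 s^-1, k_cat = 0.4 s^-1.
#'
#' @param preset one of `"physiologic"`, `"non_physiologic"`, `"nf1_like"`,
#'   `"p120_like"`.
#' @param ... further overrides passed to [rate_constants()].
#' @return A `rate_constants` object.
#' @export
gap_preset <- function(preset = c("physiologic", "non_physiologic",
                                  "nf1_like", "p120_like"), ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
    physiologic     = c(0.01, 1),
    non_physiologic = c(1e-4, 1e-4),
    nf1_like        = c(0.01, 0.1),
    p120_like       = c(0.25, 0.4))
  rate_constants(k_gap_off = p[1], k_gap_cat = p[2], ...)
}

#' Mutant specification
#'
#' Dimensionless multipliers describing a GTPase point mutant relative to
#' wild type. The canonical oncogenic G12V mutant abolishes GAP-stimulated
#' catalysis (`gap_cat_factor = 0`) while GAP binding is retained, so G12V
#' still sequesters GAP.
#'
#' @param gap_cat_factor multiplier on the GAP-stimulated catalytic rate.
#' @param hyd_factor multiplier on intrinsic hydrolysis (free and
#'   effector-bound states).
#' @param effector_affinity_factor multiplier on the effector off-rate.
#' @return An object of class `mutant_spec`.
#' @examples
#' mutant_spec()           # wild type (1, 1, 1)
#' mutant_g12v()           # (0, 1, 1)
#' @export
mutant_spec <- function(gap_cat_factor = 1, hyd_factor = 1,
                        effector_affinity_factor = 1) {
  m <- list(gap_cat_factor = gap_cat_factor, hyd_factor = hyd_factor,
            effector_affinity_factor = effector_affinity_factor)
  if (any(vapply(m, function(x) !is.numeric(x) || length(x) != 1 || x < 0,
                 logical(1))))
    stop("mutant factors must be single non-negative numbers")
  structure(m, class = "mutant_spec")
}

#' @rdname mutant_spec
#' @export
mutant_g12v <- function() mutant_spec(gap_cat_factor = 0)
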