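#' Recruitment-based positive feedback parameters
#'
#' Parameters of the synthetic GEF design in which a Ras-binding domain
#' (RBD) arm fused to the GEF binds active Ras, assembling GEF on the bead
#' surface where its effective exchange activity is `alpha`-fold that of
#' the same GEF in solution.
#'
#' Arm binding is treated as a rapid equilibrium against the active Ras
#' pool (dissociation constant `k_gef_off / k_gef_on`); the surface-bound
#' fraction is not modeled as a separate sequestered species, so effector
#' binding and GAP action on Ras are untouched by recruitment and the
#' feedback acts purely through the exchange rate (see
#' [build_recruitment_feedback_model()]).
#'
#' Defaults (`alpha = 5000`, c-Raf-like arm kinetics) are tuning choices
#' that make recruitment ignite a low-GEF / high-GAP network, not measured
#' quantities; the paper-scale experiments constrain only the qualitative
#' behavior.
#'
#' @param gef_conc total synthetic GEF, nM.
#' @param k_gef_on,k_gef_off RBD-arm binding kinetics (c-Raf-like defaults,
#'   arm Kd = 10 nM). `k_gef_on = 0` disables the feedback arm entirely.
#' @param alpha dimensionless surface-enhancement factor (>= 1) multiplying
#'   the exchange activity of Ras-bound GEF.
#' @return An object of class `recruitment_params`.
#' @export
recruitment_params <- function(gef_conc = 100, k_gef_on = 1e-4,
                               k_gef_off = 1e-3, alpha = 5000) {
  if (alpha < 1) stop("alpha must be >= 1")
  if (any(c(gef_conc, k_gef_on, k_gef_off) < 0))
    stop("parameters must be non-negative")
  structure(list(gef_conc = gef_conc, k_gef_on = k_gef_on,
                 k_gef_off = k_gef_off, alpha = alpha),
            class = "recruitment_params")
}

#' Allosteric positive feedback parameters
#'
#' Parameters of the SOS-like design in which active Ras binding to a
#' distal allosteric site stimulates GEF activity, turning a step input in
#' GEF protein into a ramp input in GEF activity.
#'
#' @param k_exch_max fully stimulated exchange rate, s^-1.
#' @param k_exch_basal unstimulated exchange rate, s^-1 (default
#'   `0.1 * k_exch_max`).
#' @param K_A half-activation level of total active Ras, nM.
#' @return An object of class `allosteric_params`.
#' @export
allosteric_params <- function(k_exch_max, k_exch_basal = 0.1 * k_exch_max,
                              K_A = 5) {
  if (K_A <= 0) stop("K_A must be positive")
  if (k_exch_basal < 0 || k_exch_max < k_exch_basal)
    stop("need k_exch_max >= k_exch_basal >= 0")
  structure(list(k_exch_basal = k_exch_basal, k_exch_max = k_exch_max,
                 K_A = K_A), class = "allosteric_params")
}

#' Build a recruitment-feedback network
#'
#' Makes the exchange rate on Ras-GDP depend on how much GEF the active Ras
#' pool has recruited to the surface. With `A = GT + sum(GT_EFF_i)` (GAP
#' commits its complex to hydrolysis, so GAP-bound Ras recruits no GEF) and
#' total GEF `G`, the surface-bound GEF `B` is the 1:1 rapid-equilibrium
#' amount, the smaller root of `B^2 - (A + G + Kd) B + A G = 0`, and
#'
#' `k_exch(x) = k_per_gef * ((G - B) + alpha * B)`.
#'
#' With `alpha = 1` or `k_gef_on = 0` this reduces exactly to the
#' constitutive network with `k_exch = k_per_gef * G`.
#'
#' @param base a three-state `reaction_network`.
#' @param p a [recruitment_params()].
#' @return A `reaction_network` with state-dependent exchange.
#' @export
build_recruitment_feedback_model <- function(base, p = recruitment_params()) {
  stopifnot(inherits(base, "reaction_network"),
            inherits(p, "recruitment_params"))
  if (!identical(base$model, "three_state"))
    stop("feedback models are built on a three-state base network")
  net <- base
  active_sp <- intersect(
    c("GT", vapply(net$effectors, gt_eff_species, "")), net$species)
  G <- p$gef_conc
  alpha <- p$alpha
  Kd <- if (p$k_gef_on > 0) p$k_gef_off / p$k_gef_on else Inf
  k_per_gef <- net$k$k_per_gef
  net$exch_rate_fn <- function(x) {
    A <- sum(x[active_sp])
    B <- if (is.finite(Kd)) {
      s <- A + G + Kd
      (s - sqrt(s * s - 4 * A * G)) / 2
    } else 0
    k_per_gef * ((G - B) + alpha * B)
  }
  net$feedback <- list(type = "recruitment", params = p)
  net
}

#' Build an allosteric-feedback network
#'
#' Makes the exchange rate on Ras-GDP a saturable function of total active
#' Ras: `k_exch(x) = k_basal + (k_max - k_basal) * GT_tot / (K_A + GT_tot)`
#' with `GT_tot = GT + sum(GT_EFF_i) + GT_GAP`. A non-mass-action rate law;
#' all other reactions are unchanged.
#'
#' @param base a three-state `reaction_network`.
#' @param p an [allosteric_params()].
#' @return A `reaction_network` with state-dependent exchange.
#' @export
build_allosteric_feedback_model <- function(base, p) {
  stopifnot(inherits(base, "reaction_network"),
            inherits(p, "allosteric_params"))
  if (!identical(base$model, "three_state"))
    stop("feedback models are built on a three-state base network")
  net <- base
  gt_sp <- intersect(
    c("GT", "GT_GAP", vapply(net$effectors, gt_eff_species, "")),
    net$species)
  basal <- p$k_exch_basal; kmax <- p$k_exch_max; K_A <- p$K_A
  net$exch_rate_fn <- function(x) {
    gt_tot <- sum(x[gt_sp])
    basal + (kmax - basal) * gt_tot / (K_A + gt_tot)
  }
  net$feedback <- list(type = "allosteric", params = p)
  net
}
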