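#' Build the two-state GTPase cycle model
#'
#' Simplest activation/deactivation cycle: Ras alternates between GDP- and
#' GTP-bound states; GAP activity is not an explicit species but is lumped
#' into the deactivation rate, `k_hyd * gap_level`. The effector binds only
#' the GTP-bound state and hydrolysis proceeds underneath a bound effector.
#'
#' Reactions: `G + T -> GT`, `GT -> GD` (lumped GAP), `GD -> G + D`
#' (GEF-driven exchange), `GT + EFF <-> GT_EFF`, `GT_EFF -> GD + EFF`.
#'
#' @param k a [rate_constants()] object. The two-state model conventionally
#'   runs with `k_exch = 0.05` s^-1, the default here.
#' @param gap_level dimensionless multiplier on the lumped deactivation rate
#'   (a stand-in for titrating GAP over orders of magnitude).
#' @param eff_conc default effector concentration (nM) recorded in the
#'   network's canonical initial state.
#' @return A `reaction_network`.
#' @export
build_two_state_model <- function(k = rate_constants(k_exch = 0.05),
                                  gap_level = 1, eff_conc = 50) {
  if (!is.numeric(gap_level) || gap_level < 0)
    stop("gap_level must be non-negative")
  species <- c("G", "T", "GT", "GD", "D", "EFF", "GT_EFF")
  rx <- list(
    new_reaction(c("G", "T"), "GT", k$k_nt_on, role_fwd = "nt_on"),
    new_reaction("GT", "GD", k$k_hyd * gap_level, role_fwd = "gap_lumped"),
    new_reaction("GD", c("G", "D"), k$k_exch, role_fwd = "exch"),
    new_reaction(c("GT", "EFF"), "GT_EFF", k$k_eff_on, k$k_eff_off,
                 role_fwd = "eff_on", role_rev = "eff_off"),
    new_reaction("GT_EFF", c("GD", "EFF"), k$k_hyd_eff, role_fwd = "hyd_eff"))
  net <- new_network("two_state", species, rx, k,
                     effectors = "EFF", ic_defaults = c(EFF = eff_conc))
  validate_network(net)
}

#' Build the two-state model with explicit GAP/effector competition
#'
#' Extends [build_two_state_model()] with an explicit GAP species that binds
#' Ras-GTP (excluding the effector) and commits it to hydrolysis:
#' `GT + GAP <-> GT_GAP`, `GT_GAP -> GD + GAP`. Intrinsic hydrolysis
#' `GT -> GD` runs alongside. GAP concentration is set in the initial state.
#'
#' @inheritParams build_two_state_model
#' @return A `reaction_network`.
#' @export
build_competition_model <- function(k = rate_constants(), eff_conc = 50) {
  species <- c("G", "T", "GT", "GD", "D", "EFF", "GT_EFF", "GAP", "GT_GAP")
  rx <- list(
    new_reaction(c("G", "T"), "GT", k$k_nt_on, role_fwd = "nt_on"),
    new_reaction("GT", "GD", k$k_hyd, role_fwd = "hyd"),
    new_reaction("GD", c("G", "D"), k$k_exch, role_fwd = "exch"),
    new_reaction(c("GT", "EFF"), "GT_EFF", k$k_eff_on, k$k_eff_off,
                 role_fwd = "eff_on", role_rev = "eff_off"),
    new_reaction("GT_EFF", c("GD", "EFF"), k$k_hyd_eff, role_fwd = "hyd_eff"),
    new_reaction(c("GT", "GAP"), "GT_GAP", k$k_gap_on, k$k_gap_off,
                 role_fwd = "gap_on", role_rev = "gap_off"),
    new_reaction("GT_GAP", c("GD", "GAP"), k$k_gap_cat, role_fwd = "gap_cat"))
  net <- new_network("competition", species, rx, k,
                     effectors = "EFF", ic_defaults = c(EFF = eff_conc))
  validate_network(net)
}

#' Build the three-state GTPase model with a GEF-refractory state
#'
#' Adds a post-hydrolysis state `GI` that cannot be re-activated by GEF and
#' relaxes to ordinary Ras-GDP on a slow timescale (`GI -> GD`,
#' `k_gi_reset`). Hydrolysis products are routed to `GI` (configurable per
#' channel); GEF-driven exchange acts on `GD` only, so after a burst of
#' activation the recyclable pool is depleted and the output overshoots.
#'
#' @inheritParams build_two_state_model
#' @param route_intrinsic,route_gap,route_effector logical; whether
#'   hydrolysis from free GT, from the GAP complex, and from the
#'   effector-bound state, respectively, produces `GI` rather than `GD`.
#'   By default only GAP-catalyzed hydrolysis is routed through the
#'   refractory state: this reproduces both a monotone response in GAP-free
#'   networks and a transient one in high-GAP networks. Routing the
#'   intrinsic channels to `GI` as well makes even GAP-free responses
#'   overshoot on the slow `k_gi_reset` timescale.
#' @return A `reaction_network`.
#' @export
build_three_state_model <- function(k = rate_constants(), eff_conc = 50,
                                    route_intrinsic = FALSE,
                                    route_gap = TRUE,
                                    route_effector = FALSE) {
  species <- c("G", "T", "GT", "GD", "GI", "D", "EFF", "GT_EFF",
               "GAP", "GT_GAP")
  hyd_to <- function(route) if (route) "GI" else "GD"
  rx <- list(
    new_reaction(c("G", "T"), "GT", k$k_nt_on, role_fwd = "nt_on"),
    new_reaction("GT", hyd_to(route_intrinsic), k$k_hyd, role_fwd = "hyd"),
    new_reaction("GI", "GD", k$k_gi_reset, role_fwd = "gi_reset"),
    new_reaction("GD", c("G", "D"), k$k_exch, role_fwd = "exch"),
    new_reaction(c("GT", "EFF"), "GT_EFF", k$k_eff_on, k$k_eff_off,
                 role_fwd = "eff_on", role_rev = "eff_off"),
    new_reaction("GT_EFF", c(hyd_to(route_effector), "EFF"), k$k_hyd_eff,
                 role_fwd = "hyd_eff"),
    new_reaction(c("GT", "GAP"), "GT_GAP", k$k_gap_on, k$k_gap_off,
                 role_fwd = "gap_on", role_rev = "gap_off"),
    new_reaction("GT_GAP", c(hyd_to(route_gap), "GAP"), k$k_gap_cat,
                 role_fwd = "gap_cat"))
  net <- new_network("three_state", species, rx, k,
                     effectors = "EFF", ic_defaults = c(EFF = eff_conc),
                     routing = list(intrinsic = route_intrinsic,
                                    gap = route_gap,
                                    effector = route_effector))
  validate_network(net)
}

#' Apply a mutant specification to a network
#'
#' Scales GAP-stimulated catalysis (including the two-state model's lumped
#' GAP rate), intrinsic hydrolysis (free and effector-bound channels) and
#' effector off-rates by the mutant's factors. GAP binding reactions are
#' retained even when catalysis is abolished, so a G12V-like mutant still
#' sequesters GAP.
#'
#' @param net a `reaction_network` from one of the builders.
#' @param m a [mutant_spec()].
#' @return A modified copy of `net`.
#' @export
apply_mutant <- function(net, m = mutant_g12v()) {
  stopifnot(inherits(net, "reaction_network"), inherits(m, "mutant_spec"))
  net$reactions <- lapply(net$reactions, function(r) {
    if (identical(r$role_fwd, "gap_cat") || identical(r$role_fwd, "gap_lumped"))
      r$k_fwd <- r$k_fwd * m$gap_cat_factor
    if (identical(r$role_fwd, "hyd") || identical(r$role_fwd, "hyd_eff"))
      r$k_fwd <- r$k_fwd * m$hyd_factor
    if (identical(r$role_rev, "eff_off"))
      r$k_rev <- r$k_rev * m$effector_affinity_factor
    r
  })
  net$mutant <- m
  net
}

#' Add a named effector to a network
#'
#' Adds species `EFF_<name>` and `GT_EFF_<name>` with binding/unbinding to
#' Ras-GTP and hydrolysis from the bound state. All effectors compete for
#' the same Ras-GTP pool: GT binds at most one partner at a time.
#'
#' @param net a `reaction_network`.
#' @param name effector name (must be unused).
#' @param conc default concentration (nM) recorded in the canonical initial
#'   state.
#' @param k_on,k_off binding kinetics (nM^-1 s^-1, s^-1). A c-Raf-like
#'   effector has `k_off = 1e-3`; a B-Raf-like one `k_off = 2.5e-4`.
#' @param k_hyd_eff hydrolysis rate from the bound state; defaults to the
#'   network's value.
#' @return A modified copy of `net`.
#' @export
add_effector <- function(net, name, conc, k_on = 1e-4, k_off = 1e-3,
                         k_hyd_eff = net$k$k_hyd_eff) {
  stopifnot(inherits(net, "reaction_network"))
  if (name %in% net$effectors) stop("effector name already used: ", name)
  if (any(c(k_on, k_off, conc, k_hyd_eff) < 0)) stop("parameters must be >= 0")
  esp <- eff_species(name); bsp <- gt_eff_species(name)
  if (any(c(esp, bsp) %in% net$species)) stop("species name clash for ", name)
  hyd_to <- if (identical(net$model, "three_state") && net$routing$effector)
    "GI" else "GD"
  net$species <- c(net$species, esp, bsp)
  net$reactions <- c(net$reactions, list(
    new_reaction(c("GT", esp), bsp, k_on, k_off,
                 role_fwd = "eff_on", role_rev = "eff_off"),
    new_reaction(bsp, c(hyd_to, esp), k_hyd_eff, role_fwd = "hyd_eff")))
  net$effectors <- c(net$effectors, name)
  net$ic_defaults[esp] <- conc
  validate_network(net)
}

#' Canonical initial state of a network
#'
#' Returns the canonical starting concentrations: 10 nM Ras-GDP, an
#' effectively infinite nucleotide supply (1e5 nM GTP), each effector at its
#' recorded default (50 nM for the base effector), GAP at `gap` nM and (for
#' recruitment networks) GEF at its configured concentration. Any species
#' can be overridden by name through `...`.
#'
#' @param net a `reaction_network`.
#' @param gap GAP concentration in nM (ignored for two-state networks).
#' @param ... named species overrides, e.g. `GD = 0, GT = 10`.
#' @return Named numeric vector over `net$species`.
#' @examples
#' net <- build_three_state_model()
#' initial_state(net, gap = 1000)
#' initial_state(net, GD = 0, GT = 10, EFF = 2500)  # turn-off scenario
#' @export
initial_state <- function(net, gap = 0, ...) {
  x <- stats::setNames(numeric(length(net$species)), net$species)
  x["GD"] <- 10
  x["T"] <- 1e5
  defaults <- net$ic_defaults
  x[names(defaults)] <- defaults
  if ("GAP" %in% net$species) x["GAP"] <- gap
  ov <- list(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), net$species)
    if (length(unknown))
      stop("unknown species in initial state: ", paste(unknown, collapse = ", "))
    x[names(ov)] <- unlist(ov)
  }
  if (any(x < 0)) stop("initial concentrations must be non-negative")
  x
}
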