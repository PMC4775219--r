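#' Simulate a reaction network
#'
#' Deterministic mass-action integration of `dx/dt = S v(x)` with a
#' stiff-capable adaptive solver ([deSolve::lsoda]). The nucleotide-binding
#' step (1 nM^-1 s^-1 against 1e5 nM nucleotide) makes the system stiff;
#' tolerances default to rtol 1e-8 / atol 1e-12 nM.
#'
#' Samples are returned on a regular grid (`t = 0, sample_dt, 2 sample_dt,
#' ...`), mirroring a 15-min imaging interval over the canonical 42000 s
#' (~700 min) run.
#'
#' @param net a `reaction_network`.
#' @param ic named initial concentration vector (nM); defaults to
#'   [initial_state()] of the network (absent species start at 0).
#' @param t_end simulation end time, s.
#' @param sample_dt sampling interval, s.
#' @param rtol,atol integration tolerances.
#' @return An object of class `ras_sim` with elements `times` (s), `conc`
#'   (time x species matrix, nM), `observables` (time x observable matrix;
#'   `bound_<effector>` for each effector plus `bound_effector_total`),
#'   and `network`.
#' @export
simulate <- function(net, ic = initial_state(net), t_end = 42000,
                     sample_dt = 900, rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(net, "reaction_network"))
  unknown <- setdiff(names(ic), net$species)
  if (length(unknown))
    stop("initial state names unknown species: ", paste(unknown, collapse = ", "))
  x0 <- stats::setNames(numeric(length(net$species)), net$species)
  x0[names(ic)] <- ic
  times <- unique(c(0, seq(sample_dt, t_end, by = sample_dt), t_end))
  cmp <- compile_network(net)
  out <- deSolve::lsoda(x0, times, make_derivs(cmp), parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("integrator failed to converge (istate = ", attr(out, "istate")[1],
         "); rtol = ", rtol, ", atol = ", atol)
  conc <- out[, net$species, drop = FALSE]
  if (min(conc) < -1e-9)
    stop("negative concentration beyond tolerance: min = ", min(conc))
  res <- structure(list(times = out[, "time"], conc = conc,
                        observables = compute_observables(net, conc),
                        network = net),
                   class = "ras_sim")
  res
}

compute_observables <- function(net, conc) {
  obs <- list()
  for (e in net$effectors) {
    sp <- intersect(c(gt_eff_species(e), gt_gef_eff_species(e)), net$species)
    obs[[paste0("bound_", e)]] <- rowSums(conc[, sp, drop = FALSE])
  }
  obs$bound_effector_total <- Reduce(`+`, obs, accumulate = FALSE)
  if (is.null(obs$bound_effector_total))
    obs$bound_effector_total <- numeric(nrow(conc))
  do.call(cbind, obs)
}

#' Extract an observable as a timecourse
#'
#' @param sim a `ras_sim`.
#' @param observable column name in `sim$observables` (default: bound base
#'   effector if present, otherwise the total).
#' @return A [timecourse()].
#' @export
sim_timecourse <- function(sim, observable = NULL) {
  stopifnot(inherits(sim, "ras_sim"))
  if (is.null(observable))
    observable <- if ("bound_EFF" %in% colnames(sim$observables))
      "bound_EFF" else "bound_effector_total"
  timecourse(sim$times, sim$observables[, observable])
}

#' @export
print.ras_sim <- function(x, ...) {
  cat("<ras_sim>", x$network$model, "model,",
      length(x$times), "samples over", max(x$times), "s\n")
  tc <- sim_timecourse(x)
  cat(sprintf("  bound effector: peak %.4g nM, final %.4g nM\n",
              max(tc$values), tc$values[length(tc$values)]))
  invisible(x)
}

#' Long-time limit of a network
#'
#' Integrates until `max |dx/dt| < tol` (nM/s) or a hard time cap of
#' 10 x 42000 s, whichever comes first. The free nucleotides `T` and `D`
#' are excluded from the convergence criterion: the cycle burns GTP at its
#' nonequilibrium steady state, so the (effectively infinite) nucleotide
#' reservoir drifts forever by design.
#'
#' @inheritParams simulate
#' @param tol steady-state derivative tolerance, nM/s.
#' @return Named concentration vector with attribute `converged`.
#' @export
steady_state <- function(net, ic = initial_state(net), tol = 1e-9) {
  stopifnot(inherits(net, "reaction_network"))
  cmp <- compile_network(net)
  derivs <- make_derivs(cmp)
  x <- stats::setNames(numeric(length(net$species)), net$species)
  x[names(ic)] <- ic
  t_cap <- 10 * 42000
  chunk <- 42000
  t_now <- 0
  watch <- !(net$species %in% c("T", "D"))
  resid <- function(x) max(abs(derivs(0, x, NULL)[[1]][watch]))
  converged <- resid(x) < tol
  while (!converged && t_now < t_cap) {
    out <- deSolve::lsoda(x, c(0, chunk), derivs, parms = NULL,
                          rtol = 1e-8, atol = 1e-10, maxsteps = 500000)
    x <- stats::setNames(out[nrow(out), -1], net$species)
    t_now <- t_now + chunk
    converged <- resid(x) < tol
  }
  attr(x, "converged") <- converged
  x
}

#' Fixed-step explicit-Euler integration (cross-check integrator)
#'
#' Independent fixed-step integrator for pure mass-action networks, used to
#' cross-validate the adaptive solver. The step must resolve the fastest
#' pseudo-first-order rate in the system (for the canonical nucleotide
#' supply of 1e5 nM that means dt well below 2e-5 s); it is implemented in
#' C++ so small steps remain affordable.
#'
#' @inheritParams simulate
#' @param dt fixed Euler step, s.
#' @return A `ras_sim` (no adaptive error control).
#' @export
euler_simulate <- function(net, ic = initial_state(net), t_end = 42000,
                           sample_dt = 900, dt = 1e-4) {
  stopifnot(inherits(net, "reaction_network"))
  if (!is.null(net$exch_rate_fn))
    stop("euler_simulate supports pure mass-action networks only")
  x0 <- stats::setNames(numeric(length(net$species)), net$species)
  x0[names(ic)] <- ic
  times <- unique(c(0, seq(sample_dt, t_end, by = sample_dt), t_end))
  cmp <- compile_network(net)
  n_rx <- length(cmp$k)
  p1 <- integer(n_rx); p2 <- integer(n_rx)
  for (j in seq_len(n_rx)) {
    # products = consumed reactants + net stoichiometry (handles species
    # appearing on both sides with net change 0)
    cons <- tabulate(c(cmp$i1[j], if (cmp$i2[j] > 0) cmp$i2[j]),
                     nbins = nrow(cmp$S))
    prod <- cons + cmp$S[, j]
    prod_idx <- rep(seq_along(prod), pmax(prod, 0))
    p1[j] <- prod_idx[1]
    p2[j] <- if (length(prod_idx) > 1) prod_idx[2] else 0L
  }
  conc <- euler_mass_action(x0, cmp$i1, cmp$i2, p1, p2, cmp$k, dt, times)
  colnames(conc) <- net$species
  structure(list(times = times, conc = conc,
                 observables = compute_observables(net, conc),
                 network = net),
            class = "ras_sim")
}

#' Tidy and wide exports of a simulation
#'
#' @param sim a `ras_sim`.
#' @return `sim_to_tidy`: data.frame with columns `time_s`, `species`,
#'   `conc_nM`; `sim_to_wide`: data.frame with `time_s` plus one column per
#'   observable.
#' @export
sim_to_tidy <- function(sim) {
  stopifnot(inherits(sim, "ras_sim"))
  data.frame(time_s = rep(sim$times, ncol(sim$conc)),
             species = rep(colnames(sim$conc), each = length(sim$times)),
             conc_nM = as.vector(sim$conc))
}

#' @rdname sim_to_tidy
#' @export
sim_to_wide <- function(sim) {
  stopifnot(inherits(sim, "ras_sim"))
  data.frame(time_s = sim$times, sim$observables, check.names = FALSE)
}
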