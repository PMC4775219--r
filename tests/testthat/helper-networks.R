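# Shared fixtures: canonical networks and small helpers.

canonical_three_state <- function(gef = 1000, ...)
  build_three_state_model(rate_constants(gef_conc = gef, ...))

# bound-effector trace of a canonical run
bound_trace <- function(net, gap = 0, ...) {
  sim <- simulate(net, initial_state(net, gap = gap, ...))
  sim_timecourse(sim)
}

# relative deviation of conserved totals over a simulation
conservation_drift <- function(sim) {
  tot <- t(apply(sim$conc, 1, function(x)
    conserved_totals(sim$network, x)))
  ref <- tot[1, ]
  keep <- ref > 0
  max(abs(sweep(tot[, keep, drop = FALSE], 2, ref[keep], "/") - 1))
}

zero_rates <- function()
  rate_constants(k_nt_on = 0, k_exch = 0, k_hyd = 0, k_hyd_eff = 0,
                 k_eff_on = 0, k_eff_off = 0, k_gap_on = 0, k_gap_off = 0,
                 k_gap_cat = 0, k_gi_reset = 0)

# log-uniform multiplier over +/- `decades` decades
rlogunif <- function(decades = 2) 10^stats::runif(1, -decades, decades)
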