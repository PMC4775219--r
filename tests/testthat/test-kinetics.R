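test_that("model builders assemble the expected networks and reject bad input", {
  n2 <- build_two_state_model()
  expect_setequal(n2$species, c("G", "T", "GT", "GD", "D", "EFF", "GT_EFF"))
  expect_false("GAP" %in% n2$species)

  nc <- build_competition_model()
  expect_true(all(c("GAP", "GT_GAP") %in% nc$species))
  n3 <- build_three_state_model()
  expect_true("GI" %in% n3$species)
  # refractory routing: GAP catalysis produces GI, intrinsic channel GD
  gap_rx <- Filter(function(r) identical(r$role_fwd, "gap_cat"), n3$reactions)
  expect_equal(gap_rx[[1]]$products, c("GI", "GAP"))
  hyd_rx <- Filter(function(r) identical(r$role_fwd, "hyd"), n3$reactions)
  expect_equal(hyd_rx[[1]]$products, "GD")

  expect_error(build_two_state_model(gap_level = -1), "non-negative")
  expect_error(rate_constants(k_hyd = -1), "non-negative")
  expect_error(initial_state(n3, GD = -5), "non-negative")
})

test_that("zero-rate and zero-source networks stay constant", {
  net <- build_two_state_model(zero_rates(), gap_level = 0)
  sim <- simulate(net, initial_state(net), t_end = 9000)
  expect_true(all(apply(sim$conc, 2, function(col) all(col == col[1]))))

  # gap_level = 0 and k_exch = 0 from an all-GD start: no source of GT
  net2 <- build_two_state_model(rate_constants(k_exch = 0), gap_level = 0)
  sim2 <- simulate(net2, initial_state(net2), t_end = 9000)
  expect_equal(max(sim2$observables[, "bound_EFF"]), 0)
  expect_equal(sim2$conc[, "GD"], rep(10, length(sim2$times)),
               ignore_attr = TRUE)
})

test_that("mass conservation and non-negativity hold across canonical runs", {
  runs <- list(
    list(net = build_two_state_model(), gap = NULL),
    list(net = build_competition_model(), gap = 100),
    list(net = build_three_state_model(), gap = 1000),
    list(net = build_three_state_model(), gap = 0))
  for (r in runs) {
    ic <- if (is.null(r$gap)) initial_state(r$net)
          else initial_state(r$net, gap = r$gap)
    sim <- simulate(r$net, ic)
    expect_lt(conservation_drift(sim), 1e-6)
    expect_gt(min(sim$conc), -1e-9)
  }
})

test_that("two-state cycle matches the closed-form active fraction", {
  # linear 3-species cycle GD -> G -> GT -> GD with effector decoupled:
  # GT fraction = k_exch / (k_exch + k_hyd_app), k_hyd_app = 1e-4 * 10
  k <- rate_constants(k_exch = 0.05, k_eff_on = 0)
  net <- build_two_state_model(k, gap_level = 10)
  ss <- steady_state(net, initial_state(net))
  ras <- ss[c("G", "GT", "GD", "GT_EFF")]
  expect_equal((ras["GT"] + ras["GT_EFF"]) / sum(ras),
               0.05 / (0.05 + 1e-3), tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("GAP kinetics decide whether the competition model can overshoot", {
  gaps <- c(0, 10, 100, 300, 1000, 3000)
  phys <- build_competition_model(gap_preset("physiologic"))
  for (g in gaps) {
    tc <- bound_trace(phys, gap = g)
    expect_lt(transient_score(tc), 0.01)
  }
  nonphys <- build_competition_model(gap_preset("non_physiologic"))
  expect_gt(transient_score(bound_trace(nonphys, gap = 1000)), 0.1)
})

test_that("competition model at zero GAP reduces to the two-state model", {
  k <- rate_constants()   # shared constants, k_exch = 0.005
  nc <- build_competition_model(k)
  n2 <- build_two_state_model(k, gap_level = 1)  # lumped rate = k_hyd
  s_c <- simulate(nc, initial_state(nc, gap = 0))
  s_2 <- simulate(n2, initial_state(n2))
  expect_equal(s_c$observables[, "bound_EFF"], s_2$observables[, "bound_EFF"],
               tolerance = 1e-8)
})

test_that("three-state model overshoots at high GAP but not without GAP", {
  net <- build_three_state_model()
  expect_gt(transient_score(bound_trace(net, gap = 1000)), 0.1)
  expect_lt(transient_score(bound_trace(net, gap = 0)), 0.02)
  # steady output approached from above at high GAP
  tc <- bound_trace(net, gap = 1000)
  expect_lt(tc$values[length(tc$values)], max(tc$values))
})

test_that("fast refractory reset recovers the competition model", {
  k <- rate_constants(k_gi_reset = 1e4)
  n3 <- build_three_state_model(k, route_intrinsic = TRUE,
                                route_effector = TRUE)
  nc <- build_competition_model(k)
  for (g in c(0, 1000)) {
    v3 <- simulate(n3, initial_state(n3, gap = g))$observables[, "bound_EFF"]
    vc <- simulate(nc, initial_state(nc, gap = g))$observables[, "bound_EFF"]
    expect_equal(v3, vc, tolerance = 1e-3)
  }
})

test_that("mutant application scales the right constants", {
  net <- build_three_state_model()
  wt <- apply_mutant(net, mutant_spec(1, 1, 1))
  expect_equal(wt$reactions, net$reactions)

  mv <- apply_mutant(net, mutant_g12v())
  cat_rx <- Filter(function(r) identical(r$role_fwd, "gap_cat"), mv$reactions)
  expect_equal(cat_rx[[1]]$k_fwd, 0)
  # GAP binding retained: G12V still sequesters GAP
  on_rx <- Filter(function(r) identical(r$role_fwd, "gap_on"), mv$reactions)
  expect_gt(on_rx[[1]]$k_fwd, 0)
})

test_that("G12V sustains output at high GAP and matches WT without GAP", {
  wt <- build_three_state_model()
  mv <- apply_mutant(wt, mutant_g12v())
  tc_wt <- bound_trace(wt, gap = 1000)
  tc_mv <- bound_trace(mv, gap = 1000)
  expect_gt(tc_mv$values[length(tc_mv$values)],
            tc_wt$values[length(tc_wt$values)])
  # GAP-free: outputs within 10% throughout (after onset)
  v_wt <- bound_trace(wt, gap = 0)$values[-1]
  v_mv <- bound_trace(mv, gap = 0)$values[-1]
  expect_lt(max(abs(v_mv - v_wt) / v_wt), 0.1)
})

test_that("added effectors compete for the same active Ras pool", {
  net <- build_three_state_model(eff_conc = 50)
  expect_error(add_effector(net, "EFF", 50), "already used")
  with0 <- add_effector(net, "extra", 0, 1e-4, 1e-3)
  s_base <- simulate(net, initial_state(net, gap = 100))
  s_with <- simulate(with0, initial_state(with0, gap = 100))
  expect_equal(s_with$observables[, "bound_EFF"],
               s_base$observables[, "bound_EFF"], tolerance = 1e-7)
  expect_equal(max(s_with$observables[, "bound_extra"]), 0)
})

test_that("slow-release effector responds sustained while fast one is transient", {
  net <- build_three_state_model(rate_constants(), eff_conc = 0)
  net <- add_effector(net, "cRaf", 50, 1e-4, 1e-3)
  net <- add_effector(net, "bRaf", 50, 1e-4, 2.5e-4)
  sim <- simulate(net, initial_state(net, gap = 1000))
  sc_c <- transient_score(sim_timecourse(sim, "bound_cRaf"))
  sc_b <- transient_score(sim_timecourse(sim, "bound_bRaf"))
  expect_gt(sc_c, 0.5)              # c-Raf-like: clear transient
  expect_lt(sc_b, sc_c - 0.1)       # B-Raf-like: markedly more sustained
  fin_frac <- function(o) {
    tc <- sim_timecourse(sim, o); tc$values[length(tc$values)] / max(tc$values)
  }
  expect_gt(fin_frac("bound_bRaf"), 1.5 * fin_frac("bound_cRaf"))
})

test_that("staggered effector parameters produce an ordered peak sequence", {
  net <- build_three_state_model(rate_constants(gef_conc = 50), eff_conc = 0)
  net <- add_effector(net, "e3", 250, 1e-4, 1e-2)
  net <- add_effector(net, "e2", 50, 1e-4, 1e-3)
  net <- add_effector(net, "e1", 50, 2e-5, 1e-4)
  sim <- simulate(net, initial_state(net, gap = 1000))
  pk <- vapply(c("bound_e3", "bound_e2", "bound_e1"), function(o) {
    tc <- sim_timecourse(sim, o)
    tc$times[which.max(tc$values)]
  }, numeric(1))
  expect_true(pk[1] < pk[2] && pk[2] < pk[3])   # 3 THEN 2 THEN 1
})

test_that("GAP-free turn-off decays with the intrinsic hydrolysis rate", {
  # 0.01 min^-1 hydrolysis; saturating effector must not mask it
  k <- rate_constants(k_exch = 0, k_hyd = 1.667e-4, k_hyd_eff = 1.667e-4)
  net <- build_three_state_model(k)
  for (eff in c(50, 2500)) {
    ic <- initial_state(net, GD = 0, GT = 10, EFF = eff)
    tc <- sim_timecourse(simulate(net, ic, t_end = 18000))
    fit <- stats::lm(log(tc$values[-1]) ~ tc$times[-1])
    rate_per_min <- -stats::coef(fit)[[2]] * 60
    expect_equal(rate_per_min, 0.01, tolerance = 0.05)
  }
})

test_that("steady state is reached and start-state independent", {
  net <- build_two_state_model(rate_constants(k_exch = 0), gap_level = 1)
  ss0 <- steady_state(net, initial_state(net))
  expect_equal(ss0[["GD"]], 10)

  n3 <- build_three_state_model()
  ss_gd <- steady_state(n3, initial_state(n3, gap = 1000))
  ss_gt <- steady_state(n3, initial_state(n3, gap = 1000, GD = 0, GT = 10))
  # free nucleotides differ by construction of the two loadings
  keep <- ss_gd > 1e-8 & !names(ss_gd) %in% c("T", "D")
  expect_equal(ss_gt[keep], ss_gd[keep], tolerance = 1e-4)
  expect_true(attr(ss_gd, "converged"))
})

test_that("adaptive integration matches the explicit-Euler cross-check", {
  scenarios <- list(
    list(net = build_three_state_model(), gap = 1000),
    list(net = build_three_state_model(), gap = 0),
    list(net = build_competition_model(), gap = 100))
  for (s in scenarios) {
    # moderate nucleotide supply keeps the Euler step stable at dt = 5e-4 s
    ic <- initial_state(s$net, gap = s$gap, T = 1000)
    eu <- euler_simulate(s$net, ic, t_end = 3600, sample_dt = 300, dt = 5e-4)
    ad <- simulate(s$net, ic, t_end = 3600, sample_dt = 300)
    ve <- sim_timecourse(eu)$values[-1]
    va <- sim_timecourse(ad)$values[-1]
    expect_lt(max(abs(ve - va) / pmax(va, 1e-12)), 1e-3)
  }
})

test_that("randomly parameterized two-state systems never overshoot measurably", {
  set.seed(7)
  for (i in 1:100) {
    k <- rate_constants(k_exch = 0.05 * rlogunif(),
                        k_eff_on = 1e-4 * rlogunif(),
                        k_eff_off = 1e-3 * rlogunif(),
                        k_hyd_eff = 1e-4 * rlogunif())
    net <- build_two_state_model(k, gap_level = rlogunif())
    tc <- bound_trace(net)
    if (max(tc$values) > 0)
      expect_lt(transient_score(tc), 1e-3)
  }
})

test_that("simulation results export to tidy and wide tables", {
  net <- build_three_state_model()
  sim <- simulate(net, t_end = 1800, sample_dt = 900)
  td <- sim_to_tidy(sim)
  expect_named(td, c("time_s", "species", "conc_nM"))
  expect_equal(nrow(td), 3 * length(net$species))
  wd <- sim_to_wide(sim)
  expect_true(all(c("time_s", "bound_EFF") %in% names(wd)))
})

test_that("a YAML configuration reproduces a directly built simulation", {
  cfg <- list(model = "three_state",
              rates = list(gef_conc = 1000),
              initial = list(GAP = 1000),
              mutant = list(gap_cat_factor = 0),
              t_end = 9000, sample_dt = 900)
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, f)
  s_cfg <- run_model_config(f)
  net <- apply_mutant(build_three_state_model(rate_constants(gef_conc = 1000)),
                      mutant_g12v())
  s_dir <- simulate(net, initial_state(net, gap = 1000), t_end = 9000)
  expect_equal(s_cfg$observables, s_dir$observables)
})
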