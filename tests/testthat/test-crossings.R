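geo <- membrane_geometry(h_half = 20, z_mid = 4, H = 80)

test_that("hand-built series produce the expected event kinds", {
  # monotone descent from top water through the midplane: one crossing
  tr <- make_traj(seq(39, -21, by = -2))
  ev <- detect_events(tr, geo)
  expect_equal(ev$kind, "crossing")
  expect_equal(ev$side_entry, 1L)
  expect_equal(ev$side_exit, -1L)

  # started at the midplane, later exits the top: one initial escape
  tr2 <- make_traj(c(0, 5, 12, 18, 22, 30))
  ev2 <- detect_events(tr2, geo)
  expect_equal(ev2$kind, "initial-escape")
  expect_true(is.na(ev2$t_entry))
  expect_equal(ev2$side_exit, 1L)

  # enter top, visit midplane, exit top: one rebound, zero crossings
  tr3 <- make_traj(c(30, 18, 10, 3, 10, 18, 30))
  ev3 <- detect_events(tr3, geo)
  expect_equal(ev3$kind, "rebound")

  # membrane transit without an observed midplane visit is ambiguous
  tr4 <- make_traj(c(30, 18, 6, -6, -18, -30))
  expect_equal(detect_events(tr4, geo)$kind, "unresolved")

  # wrap through the periodic water slab: side toggles, no event
  tr5 <- make_traj(c(30, 38, -38, -30, -38, 38, 30))
  expect_equal(nrow(detect_events(tr5, geo)), 0)

  # direct water-to-water jump through a thin membrane in one frame: the
  # minimum image passes through the slab, so the path is ambiguous
  thin <- membrane_geometry(h_half = 10, z_mid = 4, H = 80)
  tr6 <- make_traj(c(30, 12, -12, -30))
  expect_equal(detect_events(tr6, thin)$kind, "unresolved")

  # unfinished residence at the end of the series
  tr7 <- make_traj(c(30, 10, 5))
  expect_equal(detect_events(tr7, geo)$kind, "unresolved-at-end")
})

test_that("the state machine matches a brute-force per-frame labeler on
           randomized telegraph series", {
  set.seed(42)
  for (i in 1:300) {
    tr <- make_traj(random_z_series(60))
    a <- detect_events(tr, geo)
    b <- brute_force_events(tr, geo)
    expect_identical(nrow(a), nrow(b))
    if (nrow(a) > 0) {
      expect_identical(a$kind, b$kind)
      expect_identical(a$t_entry, b$t_entry)
      expect_identical(a$t_mid, b$t_mid)
      expect_identical(a$t_exit, b$t_exit)
      expect_identical(as.integer(a$side_exit), as.integer(b$side_exit))
    }
  }
})

test_that("episode counts are conserved when trajectories are concatenated
           at a frame boundary outside the membrane", {
  set.seed(7)
  z1 <- c(random_z_series(50), 35)       # end in water
  z2 <- c(35, random_z_series(50))       # start in water, same side
  whole <- make_traj(c(z1, z2))
  parts <- rbind(as.data.frame(detect_events(make_traj(z1), geo)),
                 as.data.frame(detect_events(make_traj(z2), geo)))
  ev <- detect_events(whole, geo)
  expect_equal(table(factor(ev$kind, unique(c(ev$kind, parts$kind)))),
               table(factor(parts$kind, unique(c(ev$kind, parts$kind)))))
})

test_that("counting permeability applies the 0.5 rule, scales with T_sim,
           and handles zero counts", {
  log1 <- detect_events(make_traj(seq(39, -21, by = -2)), geo)  # crossing
  log2 <- detect_events(make_traj(c(0, 5, 12, 18, 22, 30)), geo) # initial
  cp <- counting_permeability(list(log1, log2), A = 100, T_total = 1000,
                              c_w = 1e-4)
  expect_equal(cp$count, 1.5)
  expect_equal(cp$rate_A2ps, 1.5 / (100 * 1000))
  expect_equal(cp$P_cm_s, cp$rate_A2ps / (2 * 1e-4) * 1e4)
  # doubling T_sim halves the rate exactly
  cp2 <- counting_permeability(list(log1, log2), A = 100, T_total = 2000,
                               c_w = 1e-4)
  expect_equal(cp2$rate_A2ps, cp$rate_A2ps / 2)
  # no events: P = 0 with a one-sided upper bound
  log0 <- detect_events(make_traj(rep(35, 5)), geo)
  cp0 <- counting_permeability(list(log0), A = 100, T_total = 1000,
                               c_w = 1e-4)
  expect_equal(cp0$P_cm_s, 0)
  expect_equal(cp0$ci_cm_s[1], 0)
  expect_gt(cp0$ci_cm_s[2], 0)
  expect_equal(cp0$ci_method, "poisson-upper")
  expect_error(counting_permeability(list(log1), c_w = 0), "positive")
})

test_that("characteristic times come from the episode timestamps", {
  # entry at t = 10, first midplane visit at t = 25, exit at t = 60
  t <- seq(0, 60, by = 5)
  z <- c(30, 25, 15, 10, 8, 3, 3, 3, 6, 8, 10, 15, 30)
  ev <- detect_events(make_traj(z, t = t), geo)
  expect_equal(ev$t_entry, 10)
  expect_equal(ev$t_mid, 25)
  expect_equal(ev$t_exit, 60)
  ct <- characteristic_times(ev)
  expect_equal(unname(ct$tau_entr["mean"]), 15)
  expect_equal(unname(ct$tau_esc["mean"]), 35)
})

test_that("a deep midplane well traps the permeant: the escape-to-entrance
           ratio far exceeds its flat-membrane (no-trapping) baseline", {
  # tau_esc runs from the FIRST midplane visit, so even without trapping it
  # exceeds tau_entr by the free diffusive wandering inside the membrane;
  # trapping shows up as a multiplicative increase over that baseline
  geo60 <- membrane_geometry(16, H = 60)
  ratio_of <- function(f_coef, seed, total_ps) {
    sp <- profile_spec(f_coef = f_coef, H = 60, D_perp0 = 0.3)
    logs <- lapply(simulate_permeants(
      synthetic_run_spec(sp, n_permeants = 40, total_ps = total_ps,
                         seed = seed)),
      detect_events, geometry = geo60)
    tt <- characteristic_times(logs)
    unname(tt$tau_esc["mean"] / tt$tau_entr["mean"])
  }
  baseline <- ratio_of(numeric(), 31, 8000)
  trapped <- ratio_of(c(-1.0, -0.5), 35, 12000)   # ~2.5 kcal/mol well
  expect_lt(baseline, 8)
  expect_gt(trapped, 3 * baseline)
})

test_that("lateral escape distances follow free-diffusion scaling", {
  # an episode with no lateral motion contributes zero
  ev <- detect_events(make_traj(c(30, 18, 3, 18, 30)), geo)
  expect_equal(lateral_escape_distance(ev)$L_par, 0)

  run <- function(dpar, seed) {
    sp <- profile_spec(H = 60, D_perp0 = 0.3, D_par0 = dpar)
    lapply(simulate_permeants(
      synthetic_run_spec(sp, n_permeants = 25, total_ps = 4000,
                         seed = seed)),
      detect_events, geometry = membrane_geometry(16, H = 60))
  }
  logs <- run(0.3, 41)
  L <- lateral_escape_distance(logs)
  # mean residence time of resolved episodes
  pooled <- pool_event_logs(logs)
  res <- pooled[pooled$kind %in% c("crossing", "rebound"), ]
  tbar <- mean(res$t_exit - res$t_entry)
  expect_equal(L$L_par^2 / (4 * 0.3 * tbar), 1, tolerance = 0.25)
  # larger Dpar at fixed Dperp and matched seed increases L_par
  expect_gt(lateral_escape_distance(run(0.9, 41))$L_par, L$L_par)
})
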