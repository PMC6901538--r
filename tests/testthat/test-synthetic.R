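test_that("profile evaluation matches the cosine basis exactly", {
  z <- seq(-29.5, 29.5, by = 0.5)
  flat <- profile_spec(H = 60, D_perp0 = 0.3, D_par0 = 0.4)
  ev <- evaluate_profiles(flat, z)
  expect_equal(ev$F, rep(0, length(z)))
  expect_equal(ev$D_perp, rep(0.3, length(z)))
  expect_equal(ev$D_par, rep(0.4, length(z)))

  one <- profile_spec(f_coef = c(1.2), H = 60)
  expect_equal(evaluate_profiles(one, z)$F, 1.2 * cos(2 * pi * z / 60))

  # analytic derivatives agree with central finite differences
  sp <- profile_spec(f_coef = c(0.7, -0.4, 0.2),
                     ld_perp_coef = c(0.3, 0.1), H = 60)
  h <- 1e-5
  num_dF <- (evaluate_profiles(sp, z + h)$F -
               evaluate_profiles(sp, z - h)$F) / (2 * h)
  num_dD <- (evaluate_profiles(sp, z + h)$D_perp -
               evaluate_profiles(sp, z - h)$D_perp) / (2 * h)
  ev <- evaluate_profiles(sp, z)
  expect_equal(ev$dF, num_dF, tolerance = 1e-6)
  expect_equal(ev$dD_perp, num_dD, tolerance = 1e-6)
})

test_that("free diffusion obeys the MSD law and seeds give bitwise repeats", {
  run <- synthetic_run_spec(profile_spec(H = 60, D_perp0 = 0.25,
                                         D_par0 = 0.35),
                            n_permeants = 150, total_ps = 120,
                            dt_ps = 0.05, save_ps = 1, seed = 7,
                            init = "uniform")
  tr <- simulate_permeants(run)
  # lateral MSD (unwrapped, no boundary effects): 4 Dpar t
  msd_l <- mean(sapply(tr, function(s)
    (s$x[101] - s$x[1])^2 + (s$y[101] - s$y[1])^2))
  expect_equal(msd_l / (4 * 100), 0.35, tolerance = 0.15)
  # z MSD at t = 20 ps (rms ~3 A): minimal-image difference across the wrap
  msd_z <- mean(sapply(tr, function(s) {
    d <- s$z[21] - s$z[1]
    (d - 60 * round(d / 60))^2
  }))
  expect_equal(msd_z / (2 * 20), 0.25, tolerance = 0.15)

  tr2 <- simulate_permeants(run)
  expect_identical(tr[[3]]$z, tr2[[3]]$z)
  expect_identical(tr[[3]]$x, tr2[[3]]$x)
})

test_that("long-run occupancy follows the Boltzmann distribution", {
  sp <- profile_spec(f_coef = c(0.8, 0.4), H = 50, D_perp0 = 0.3)
  run <- synthetic_run_spec(sp, n_permeants = 80, total_ps = 10000,
                            dt_ps = 0.05, save_ps = 2, seed = 11)
  tr <- simulate_permeants(run)
  n_bins <- 25
  dz <- 50 / n_bins
  centers <- seq(-25 + dz / 2, 25 - dz / 2, length.out = n_bins)
  # per-permeant bin frequencies give a replicate-based Monte-Carlo error,
  # honest about the time correlation of the samples
  freq <- sapply(tr, function(s)
    tabulate(pmin(floor((s$z + 25) / dz) + 1, n_bins), n_bins) /
      length(s$z))
  emp <- rowMeans(freq)
  se <- apply(freq, 1, sd) / sqrt(ncol(freq))
  beta <- beta_kcal(298)
  w <- exp(-beta * evaluate_profiles(sp, centers)$F)
  theo <- w / sum(w)
  expect_true(all(abs(emp - theo) < 4 * se))
  expect_lt(mean(abs(emp - theo) / theo), 0.07)
})

test_that("omitting the Ito spurious drift biases the sampled density", {
  # flat F with strongly varying Dperp: correct integrator samples uniform,
  # the ablated one accumulates where D is low (density ~ 1/D)
  sp <- profile_spec(ld_perp_coef = c(1.0), H = 50, D_perp0 = 0.25)
  run <- synthetic_run_spec(sp, n_permeants = 40, total_ps = 4000,
                            dt_ps = 0.02, save_ps = 2, seed = 13,
                            init = "uniform")
  # compare occupancy of the high-D region (cos > 0.5) against the low-D
  # region (cos < -0.5); without the drift term density piles up as ~1/D
  ratio_of <- function(trs) {
    zs <- unlist(lapply(trs, `[[`, "z"))
    cz <- cos(2 * pi * zs / 50)
    mean(cz > 0.5) / mean(cz < -0.5)
  }
  r_ok <- ratio_of(simulate_permeants(run))
  r_bad <- ratio_of(simulate_permeants(run, ito_drift = FALSE))
  expect_equal(r_ok, 1, tolerance = 0.25)
  expect_lt(r_bad, 0.5)             # bias is gross, not a sampling wiggle
})

test_that("synthesized saturation curves obey the closed-form limits", {
  # at P = P1/2 the amplitude is half the unsaturated extrapolation
  cv <- synthesize_saturation_curve(3, 8, powers = 8, noise_sd = 0)
  expect_equal(cv$amplitude, 3 * sqrt(8) / 2)
  # unsaturated limit: amplitude / sqrt(P) -> I0 as P -> 0
  lowP <- synthesize_saturation_curve(3, 8, powers = c(1e-4, 1e-3),
                                      noise_sd = 0)
  expect_equal(lowP$amplitude / sqrt(lowP$power_mW), c(3, 3),
               tolerance = 1e-3)
  expect_error(synthesize_saturation_curve(-1, 8, 1), "positive")
  # reproducible noise
  a <- synthesize_saturation_curve(3, 8, 1:5, noise_sd = 0.05, seed = 9)
  b <- synthesize_saturation_curve(3, 8, 1:5, noise_sd = 0.05, seed = 9)
  expect_identical(a$amplitude, b$amplitude)
})

test_that("toy membrane records ground truth consistent with site areas", {
  spec <- toy_membrane_spec(a = 5, nx = 10, ny = 10, domain_radius = 12,
                            seed = 3)
  toy <- generate_toy_membrane(spec, "uniform", n_permeants = 600, seed = 8)
  # every lattice site has exactly one chain of one type
  expect_length(toy$chain_frames[["0"]]$chains, 100)
  # permeant at the center of the pure domain is 3-sat by construction
  ctr <- which.min((toy$sites$x - spec$Lx / 2)^2 +
                     (toy$sites$y - spec$Ly / 2)^2)
  expect_true(toy$sites$in_domain[ctr])
  # uniform rule: truth-class frequencies match the area fractions of the
  # class regions, computed by an independent dense-grid counting oracle
  gx <- seq(0.25, spec$Lx - 0.25, by = 1.5)
  gy <- seq(0.25, spec$Ly - 0.25, by = 1.5)
  grid_class <- vapply(seq_len(length(gx) * length(gy)), function(i) {
    px <- gx[(i - 1) %% length(gx) + 1]
    py <- gy[(i - 1) %/% length(gx) + 1]
    dx <- toy$sites$x - px; dy <- toy$sites$y - py
    dx <- dx - spec$Lx * round(dx / spec$Lx)
    dy <- dy - spec$Ly * round(dy / spec$Ly)
    tt <- toy$sites$type[order(dx^2 + dy^2)[1:3]]
    if (length(unique(tt)) == 1) paste0("3-", tt[1]) else "Mix"
  }, "")
  for (cls in unique(toy$truth$class))
    expect_lt(abs(mean(toy$truth$class == cls) - mean(grid_class == cls)),
              0.06)
  # channel-biased placement needs channel sites
  tiny <- toy_membrane_spec(a = 5, nx = 4, ny = 4, domain_radius = 100)
  expect_error(generate_toy_membrane(tiny, "channel-biased", 10),
               "channel site")
})
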