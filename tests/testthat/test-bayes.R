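test_that("transition counting satisfies exact counting identities", {
  # static permeant: all counts on the diagonal
  tr <- make_traj(rep(5.2, 60), box = c(40, 40, 80))
  cnt <- count_transitions(tr, n_bins = 20, lags_ps = 10)
  expect_equal(sum(cnt[[1]]$N), 50)
  expect_equal(sum(diag(cnt[[1]]$N)), 50)

  # one permeant, two frames, one lag: exactly one count
  tr2 <- make_traj(c(-3, 7), box = c(40, 40, 80))
  cnt2 <- count_transitions(tr2, n_bins = 20, lags_ps = 1)
  expect_equal(sum(cnt2[[1]]$N), 1)

  # column sums equal the number of usable origins per start bin
  set.seed(5)
  tr3 <- make_traj(runif(200, -40, 40 - 1e-9), box = c(40, 40, 80))
  lag <- 7
  cnt3 <- count_transitions(tr3, n_bins = 16, lags_ps = lag)
  ib <- pmin(floor((tr3$z + 40) / 5) + 1, 16)
  origins <- tabulate(ib[1:(200 - lag)], 16)
  expect_equal(unname(colSums(cnt3[[1]]$N)), origins)

  # lag must be commensurate with the save interval
  expect_error(count_transitions(tr3, n_bins = 16, lags_ps = 2.5),
               "multiple of the save interval")
  # defaults follow the standard settings
  expect_equal(eval(formals(count_transitions)$lags_ps), c(20, 30, 40, 50))
  expect_equal(eval(formals(count_transitions)$n_bins), 100)
})

test_that("the rate matrix conserves probability, obeys detailed balance,
           and has the periodic diffusion spectrum in the flat limit", {
  H <- 50; n <- 25; dz <- H / n
  z <- seq(-H / 2 + dz / 2, H / 2 - dz / 2, length.out = n)
  beta <- beta_kcal(298)
  F <- 0.9 * cos(2 * pi * z / H) - 0.3 * cos(4 * pi * z / H)
  D <- 0.2 * exp(0.4 * cos(2 * pi * z / H))
  R <- build_rate_matrix(F, D, dz, beta)
  expect_lt(max(abs(colSums(R))), 1e-12)
  pi_eq <- exp(-beta * F)
  expect_lt(max(abs(R * rep(pi_eq, each = n) - t(R * rep(pi_eq, each = n)))),
            1e-12)
  expect_error(build_rate_matrix(F, -D, dz, beta), "positive")

  Rf <- build_rate_matrix(rep(0, n), rep(0.2, n), dz, beta)
  ev <- sort(eigen(Rf, only.values = TRUE)$values)
  theo <- sort(-(4 * 0.2 / dz^2) * sin(pi * (0:(n - 1)) / n)^2)
  expect_equal(ev, theo, tolerance = 1e-10)
})

test_that("the propagator is stochastic and the likelihood is gauge
           invariant with the correct ergodic and free-diffusion limits", {
  H <- 50; n <- 20; dz <- H / n
  z <- seq(-H / 2 + dz / 2, H / 2 - dz / 2, length.out = n)
  beta <- beta_kcal(298)
  model <- bayes_model(n_bins = n, n_f = 5, n_d = 3, n_modes = 12, H = H,
                       R_max = 30, n_radial = 60)
  par <- c(0.5, -0.2, 0.1, 0.3, log(0.25), 0.2, -0.1)
  pr <- memperm:::par_split(model, par, radial = FALSE)
  sym <- memperm:::symm_eigen(pr$F, pr$D_perp, dz, beta)
  for (tau in c(5, 50, 500)) {
    T <- memperm:::propagator(sym, tau)
    expect_lt(max(abs(colSums(T) - 1)), 1e-9)
    expect_gt(min(T), -1e-12)
  }
  # ergodic limit: columns converge to the Boltzmann weights of F
  Tinf <- memperm:::propagator(sym, 1e6)
  pi_eq <- exp(-beta * pr$F) / sum(exp(-beta * pr$F))
  expect_equal(unname(Tinf[, 3]), unname(pi_eq), tolerance = 1e-8)

  # gauge invariance: adding a constant to F leaves the likelihood alone
  set.seed(8)
  tr <- make_traj(runif(500, -25, 25 - 1e-9), box = c(40, 40, 50))
  cnt <- count_transitions(tr, n_bins = n, lags_ps = 10)
  # (a gauge shift lives outside the k >= 1 cosine span, so compare the
  # likelihood computed directly from shifted profiles)
  ll_of <- function(Fshift) {
    symp <- memperm:::symm_eigen(pr$F + Fshift, pr$D_perp, dz, beta)
    T <- memperm:::propagator(symp, 10)
    N <- cnt[[1]]$N
    sum(N[N > 0] * log(T[N > 0]))
  }
  expect_equal(ll_of(0), ll_of(2.7), tolerance = 1e-6)

  # radial mode: flat F, constant Dpar gives <dr^2> = 4 Dpar tau well
  # inside the reflecting wall
  xk <- bessel_j1_zeros(40)
  W <- memperm:::radial_weights(xk, 30, 120)
  expect_equal(unname(rowSums(W)), c(1, rep(0, 39)), tolerance = 1e-12)
  Dpar <- 0.25; tau <- 20
  symf <- memperm:::symm_eigen(rep(0, n), rep(0.2, n), dz, beta)
  Tk <- sapply(seq_along(xk), function(k)
    as.vector(memperm:::propagator(symf, tau,
                                   rep(Dpar, n) * xk[k]^2 / 30^2)))
  P <- Tk %*% W                        # joint (j, radial bin | i)
  pb <- colSums(P) / n                 # radial marginal, averaged over i
  rmid <- (seq_len(120) - 0.5) * 30 / 120
  msd <- sum(pb * rmid^2) / sum(pb)
  expect_equal(msd, 4 * Dpar * tau, tolerance = 0.02)
})

test_that("zero-probability transitions with observed counts yield -Inf", {
  H <- 50; n <- 10
  model <- bayes_model(n_bins = n, n_f = 3, n_d = 2, H = H)
  # near-zero diffusion makes the observed five-bin hops impossible at
  # lag 1 ps (periodic grid: -24 and 0 are five bins apart either way)
  tr <- make_traj(c(-24, 0, -24, 0), box = c(40, 40, 50))
  cnt <- count_transitions(tr, n_bins = n, lags_ps = 1)
  par <- c(0, 0, log(1e-8), 0)
  expect_identical(log_likelihood(par, cnt[[1]], model), -Inf)
})

test_that("the posterior concentrates near the generating profiles and two
           seeds agree within Monte-Carlo error", {
  sp <- profile_spec(f_coef = c(0.5, 0.3), ld_perp_coef = c(0.3, -0.1),
                     D_perp0 = 0.2, H = 50)
  tr <- cached("bayes_traj", simulate_permeants(
    synthetic_run_spec(sp, n_permeants = 16, total_ps = 15000, seed = 5)))
  cnt <- count_transitions(tr, n_bins = 25, lags_ps = c(20, 40))
  model <- bayes_model(n_bins = 25, n_f = 6, n_d = 4, H = 50)
  post <- sample_posterior(cnt, model, n_iter = 800, burn_in = 500,
                           seed = 2, radial = FALSE)
  expect_true(all(sapply(post, `[[`, "acceptance") > 0.05))
  gt <- evaluate_profiles(sp, model$z)
  beta <- beta_kcal(298)
  for (pl in post) {
    Ferr <- (pl$F_mean - mean(pl$F_mean)) - (gt$F - mean(gt$F))
    expect_lt(sqrt(mean(Ferr^2)) * beta, 0.3)
    expect_lt(max(abs(pl$D_perp_mean - gt$D_perp) / gt$D_perp), 0.2)
  }
  post2 <- sample_posterior(cnt, model, n_iter = 800, burn_in = 500,
                            seed = 9, radial = FALSE)
  for (i in seq_along(post)) {
    mc_tol <- 3 * sqrt(mean(post[[i]]$D_perp_sd^2) / post[[i]]$n_kept) +
      0.01 * mean(post[[i]]$D_perp_mean)
    expect_lt(mean(abs(post[[i]]$D_perp_mean - post2[[i]]$D_perp_mean)),
              5 * mc_tol)
  }
})

test_that("infinite-lag extrapolation is consistent for Markovian data and
           tracks the long-time MSD under short-time memory", {
  # Markovian synthetic per-lag profiles: lag-independent, intercept near
  # the per-lag mean
  sp <- profile_spec(f_coef = c(0.5, 0.3), ld_perp_coef = c(0.3, -0.1),
                     D_perp0 = 0.2, H = 50)
  tr <- cached("bayes_traj", simulate_permeants(
    synthetic_run_spec(sp, n_permeants = 16, total_ps = 15000, seed = 5)))
  cnt <- count_transitions(tr, n_bins = 25, lags_ps = c(20, 30, 40, 50))
  model <- bayes_model(n_bins = 25, n_f = 6, n_d = 4, H = 50)
  post <- sample_posterior(cnt, model, n_iter = 600, burn_in = 400,
                           seed = 3, radial = FALSE)
  ex <- extrapolate_infinite_lag(post)
  per_lag_mean <- rowMeans(sapply(post, `[[`, "D_perp_mean"))
  expect_equal(mean(ex$D$D_perp / per_lag_mean), 1, tolerance = 0.1)
  expect_error(extrapolate_infinite_lag(post[1]), "posterior_summary")

  # short-time memory: a moving-average filter correlates increments, so
  # small-lag apparent D is biased; the 1/tau intercept must land nearer
  # the long-time MSD slope than the most biased single lag
  set.seed(12)
  n <- 60000
  raw <- cumsum(rnorm(n, 0, sqrt(2 * 0.2)))      # D = 0.2, dt = 1 ps
  sm <- stats::filter(raw, rep(1 / 8, 8), sides = 1)
  sm <- sm[!is.na(sm)]
  app_D <- function(lag) mean(diff(sm, lag = lag)^2) / (2 * lag)
  lags <- c(4, 6, 8, 10)
  apps <- sapply(lags, app_D)
  fit <- lm(apps ~ I(1 / lags))
  icept <- unname(coef(fit)[1])
  expect_true(all(diff(apps) > 0) || all(diff(apps) < 0))  # monotone
  long_D <- app_D(200)
  expect_lt(abs(icept - long_D), min(abs(apps - long_D)))
})
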