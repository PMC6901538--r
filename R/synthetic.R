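## Synthetic permeant trajectories on known profiles.
##
## The generator propagates independent permeants with the overdamped Ito
## equation dz = [-beta Dperp F' + Dperp'] dt + sqrt(2 Dperp) dW on periodic
## cosine-series profiles, so its output satisfies the diffusive model class
## assumed by the Bayesian analysis exactly -- making it a ground-truth
## oracle for profile- and permeability-recovery tests.

#' Ground-truth profile specification
#'
#' Defines F(z), Dperp(z) and Dpar(z) as periodic cosine series over the box
#' height: `F(z) = sum_k a_k cos(2 pi k z / H)` (kcal/mol, k >= 1) and
#' `ln D(z) = ln D0 + sum_k b_k cos(2 pi k z / H)`.  The exponential
#' parametrization keeps both diffusion profiles positive by construction.
#'
#' @param f_coef cosine coefficients of F, kcal/mol (k = 1, 2, ...).
#' @param ld_perp_coef,ld_par_coef cosine coefficients of ln Dperp, ln Dpar
#'   (dimensionless, k = 1, 2, ...).
#' @param D_perp0,D_par0 base diffusion values in A^2/ps.
#' @param H box height in Angstrom.
#' @return object of class `profile_spec`.
#' @export
profile_spec <- function(f_coef = numeric(), ld_perp_coef = numeric(),
                         ld_par_coef = numeric(), D_perp0 = 0.2,
                         D_par0 = 0.2, H = 80) {
  stopifnot(D_perp0 > 0, D_par0 > 0, H > 0)
  structure(list(f_coef = as.numeric(f_coef),
                 ld_perp_coef = as.numeric(ld_perp_coef),
                 ld_par_coef = as.numeric(ld_par_coef),
                 D_perp0 = D_perp0, D_par0 = D_par0, H = H),
            class = "profile_spec")
}

cosine_eval <- function(coef, z, H, deriv = FALSE) {
  val <- numeric(length(z))
  for (k in seq_along(coef)) {
    w <- 2 * pi * k / H
    val <- val + if (deriv) -coef[k] * w * sin(w * z) else
      coef[k] * cos(w * z)
  }
  val
}

#' Evaluate ground-truth profiles on a grid
#'
#' @param spec a `profile_spec`.
#' @param z evaluation grid in `[-H/2, H/2]`.
#' @param reference_zone optional |z| interval; when given, F is returned
#'   relative to its mean over that zone (the water-reference convention).
#' @return list with `F` (kcal/mol), `D_perp`, `D_par` (A^2/ps), and the
#'   analytic derivatives `dF`, `dD_perp`.
#' @export
evaluate_profiles <- function(spec, z, reference_zone = NULL) {
  stopifnot(inherits(spec, "profile_spec"),
            all(abs(z) <= spec$H / 2 + 1e-9))
  F <- cosine_eval(spec$f_coef, z, spec$H)
  ldp <- cosine_eval(spec$ld_perp_coef, z, spec$H)
  ldl <- cosine_eval(spec$ld_par_coef, z, spec$H)
  D_perp <- spec$D_perp0 * exp(ldp)
  if (!is.null(reference_zone)) {
    zr <- seq(reference_zone[1], reference_zone[2], length.out = 101)
    ref <- mean(cosine_eval(spec$f_coef, c(-zr, zr), spec$H))
    F <- F - ref
  }
  list(F = F, D_perp = D_perp,
       D_par = spec$D_par0 * exp(ldl),
       dF = cosine_eval(spec$f_coef, z, spec$H, deriv = TRUE),
       dD_perp = D_perp * cosine_eval(spec$ld_perp_coef, z, spec$H,
                                      deriv = TRUE))
}

#' Built-in permeant profile shapes
#'
#' `oxygen_like` has a midplane free-energy well of about -1.5 kcal/mol with
#' head-group shoulders; `water_like` a central barrier of about 6 kcal/mol
#' with a shallow metastable dip at z = 0.  These are validation fixtures
#' emulating the qualitative shapes seen for oxygen and water in bilayers,
#' not measurements.
#'
#' @param which `"oxygen_like"` or `"water_like"`.
#' @param H box height in Angstrom.
#' @return a `profile_spec`.
#' @export
default_profile_spec <- function(which = c("oxygen_like", "water_like"),
                                 H = 80) {
  which <- match.arg(which)
  if (which == "oxygen_like") {
    # well at z=0 (~ -1.5 kcal/mol relative to water) + shoulders
    profile_spec(f_coef = c(-0.9, 0.45, 0.25), ld_perp_coef = c(0.25, 0.1),
                 ld_par_coef = c(0.45, 0.15), D_perp0 = 0.20, D_par0 = 0.25,
                 H = H)
  } else {
    # high central barrier with shallow dip at midplane
    profile_spec(f_coef = c(2.8, -0.5, 0.8), ld_perp_coef = c(-0.2, 0.05),
                 ld_par_coef = c(-0.1), D_perp0 = 0.25, D_par0 = 0.25, H = H)
  }
}

#' Synthetic run specification
#'
#' @param profile a `profile_spec`.
#' @param n_permeants number of independent permeants (>= 1).
#' @param total_ps simulated time per permeant, ps.
#' @param dt_ps integration step, ps (default 0.05).
#' @param save_ps save interval, ps (default 1); must be >= `dt_ps`.
#' @param seed RNG seed.
#' @param Lx,Ly lateral box lengths, Angstrom.
#' @param temperature temperature in K.
#' @param init `"boltzmann"` (equilibrium start, default), `"uniform"`, or
#'   `"water"` (uniform in `init_zone`).
#' @param init_zone |z| interval for `init = "water"`.
#' @param permeant_type species label for the emitted trajectories.
#' @return object of class `synthetic_run_spec`.
#' @export
synthetic_run_spec <- function(profile, n_permeants, total_ps, dt_ps = 0.05,
                               save_ps = 1, seed = 1, Lx = 60, Ly = 60,
                               temperature = 298,
                               init = c("boltzmann", "uniform", "water"),
                               init_zone = NULL,
                               permeant_type = "oxygen-like") {
  stopifnot(inherits(profile, "profile_spec"), n_permeants >= 1,
            save_ps >= dt_ps, total_ps > 0)
  structure(list(profile = profile, n_permeants = as.integer(n_permeants),
                 total_ps = total_ps, dt_ps = dt_ps, save_ps = save_ps,
                 seed = as.integer(seed), Lx = Lx, Ly = Ly,
                 temperature = temperature, init = match.arg(init),
                 init_zone = init_zone, permeant_type = permeant_type),
            class = "synthetic_run_spec")
}

draw_boltzmann_z <- function(spec, n, beta) {
  zg <- seq(-spec$H / 2, spec$H / 2, length.out = 4001)
  p <- exp(-beta * cosine_eval(spec$f_coef, zg, spec$H))
  cdf <- cumsum(p) / sum(p)
  zg[findInterval(runif(n), cdf) + 1]
}

#' Simulate permeant trajectories on known profiles
#'
#' Euler-Maruyama integration of the overdamped Ito equation with the
#' spurious-drift term `Dperp'(z)`; lateral motion is free diffusion with
#' `Dpar(z)` evaluated at the current depth.  z is wrapped periodically over
#' H; x and y are left unwrapped.  Identical seeds give bitwise-identical
#' trajectories.
#'
#' @param run a `synthetic_run_spec`.
#' @param ito_drift set `FALSE` only for ablation diagnostics (drops the
#'   `Dperp'` term, which biases the sampled density when Dperp varies).
#' @return list of `permeant_trajectory` objects.
#' @export
simulate_permeants <- function(run, ito_drift = TRUE) {
  stopifnot(inherits(run, "synthetic_run_spec"))
  sp <- run$profile
  beta <- beta_kcal(run$temperature)
  # step-size sanity: RMS step below the finest profile feature scale
  kmax <- max(1, length(sp$f_coef), length(sp$ld_perp_coef))
  Dmax <- sp$D_perp0 * exp(sum(abs(sp$ld_perp_coef)))
  if (sqrt(2 * Dmax * run$dt_ps) > sp$H / (4 * kmax))
    warning("integration step too coarse for the finest profile feature")
  set.seed(run$seed)
  z0 <- switch(run$init,
    boltzmann = draw_boltzmann_z(sp, run$n_permeants, beta),
    uniform = runif(run$n_permeants, -sp$H / 2, sp$H / 2),
    water = {
      if (is.null(run$init_zone)) stop("init = 'water' needs init_zone")
      abs_z <- runif(run$n_permeants, run$init_zone[1], run$init_zone[2])
      abs_z * sample(c(-1, 1), run$n_permeants, replace = TRUE)
    })
  x0 <- runif(run$n_permeants, 0, run$Lx)
  y0 <- runif(run$n_permeants, 0, run$Ly)
  sim <- .sim_overdamped(run$n_permeants, run$total_ps, run$dt_ps,
                         run$save_ps, z0, x0, y0, sp$f_coef,
                         sp$ld_perp_coef, sp$ld_par_coef, sp$D_perp0,
                         sp$D_par0, sp$H, beta, ito_drift)
  t <- seq(0, by = run$save_ps, length.out = sim$n_save)
  box <- c(run$Lx, run$Ly, sp$H)
  lapply(seq_len(run$n_permeants), function(p)
    permeant_trajectory(sprintf("perm%03d", p), run$permeant_type, t,
                        sim$x[, p], sim$y[, p], sim$z[, p], box,
                        run$temperature))
}

#' Synthesize a noisy power-saturation curve
#'
#' Amplitudes follow the homogeneous saturation law
#' `I = I0 sqrt(P) / (1 + (2^(2/3) - 1) P / P_half)^(3/2)` evaluated at the
#' given microwave powers, multiplied by `(1 + N(0, noise_sd))`.
#'
#' @param I0 unsaturated intensity parameter (> 0).
#' @param P_half half-saturation power in mW (> 0).
#' @param powers microwave powers in mW (all > 0).
#' @param noise_sd fractional (multiplicative) Gaussian noise sd.
#' @param seed RNG seed.
#' @param label condition label (e.g. gas).
#' @return object of class `saturation_curve` with fields `power_mW`,
#'   `amplitude`, `label`.
#' @export
synthesize_saturation_curve <- function(I0, P_half, powers, noise_sd = 0,
                                        seed = 1, label = "synthetic") {
  if (I0 <= 0 || P_half <= 0) stop("I0 and P_half must be positive")
  stopifnot(all(powers > 0))
  set.seed(seed)
  amp <- saturation_model(powers, I0, P_half) *
    (1 + rnorm(length(powers), 0, noise_sd))
  structure(list(power_mW = as.numeric(powers), amplitude = amp,
                 label = label),
            class = "saturation_curve")
}
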