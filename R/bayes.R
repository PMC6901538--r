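## Bayesian inference of F(z), Dperp(z), Dpar(z) from binned transition
## counts under a discretized Smoluchowski propagator.
##
## The generator is a periodic nearest-neighbor rate matrix obeying detailed
## balance; exp(tau R) is computed by eigendecomposition of the symmetrized
## generator S = diag(e^{+bF/2}) R diag(e^{-bF/2}), whose off-diagonals are
## simply D_{i+1/2}/dz^2.  Lateral displacements are modelled by a Bessel
## mode expansion on a disc of radius R_max with a reflecting wall: mode k
## relaxes with the modified generator R^(k) = R - diag(Dpar_i x_k^2/R_max^2)
## where x_k is the k-th zero of J1 (x_0 = 0 recovers the z-only propagator).

#' Count z-bin transitions (and lateral displacements) at given lag times
#'
#' Pairs `(frame t, frame t + tau)` are accumulated with a sliding origin.
#' z is binned on the periodic grid; the lateral displacement magnitude
#' `dr` (from the unwrapped coordinates) is histogrammed in uniform radial
#' bins up to `R_max`, with overflow accumulated in the last bin.
#'
#' @param trajs list of `permeant_trajectory` objects.
#' @param n_bins number of z-bins (default 100).
#' @param lags_ps lag times in ps; each must be an integer multiple of the
#'   save interval (default `c(20, 30, 40, 50)`).
#' @param radial also histogram lateral displacements.
#' @param R_max radial cutoff, Angstrom (default 50).
#' @param n_radial number of radial bins (default 100).
#' @return object of class `transition_counts`: one element per lag with
#'   the count matrix `N[j, i]` (from bin i to bin j) and, when requested,
#'   the radial count array `N3[j, i, b]`; grid metadata in attributes.
#' @export
count_transitions <- function(trajs, n_bins = 100,
                              lags_ps = c(20, 30, 40, 50), radial = FALSE,
                              R_max = 50, n_radial = 100) {
  if (inherits(trajs, "permeant_trajectory")) trajs <- list(trajs)
  H <- trajs[[1]]$box[3]
  dt_save <- trajs[[1]]$t[2] - trajs[[1]]$t[1]
  dz <- H / n_bins
  dr_bin <- R_max / n_radial
  per_lag <- lapply(lags_ps, function(lag) {
    lf <- lag / dt_save
    if (abs(lf - round(lf)) > 1e-6)
      stop(sprintf("lag %g ps is not a multiple of the save interval %g ps",
                   lag, dt_save))
    lf <- as.integer(round(lf))
    N <- matrix(0L, n_bins, n_bins)
    N3 <- if (radial) array(0L, c(n_bins, n_bins, n_radial)) else NULL
    overflow <- 0L
    for (tr in trajs) {
      nfr <- length(tr$t)
      if (nfr <= lf) next
      ib <- pmin(floor((tr$z + H / 2) / dz) + 1L, n_bins)
      i <- ib[1:(nfr - lf)]
      j <- ib[(1 + lf):nfr]
      N <- N + matrix(tabulate(j + n_bins * (i - 1L), n_bins^2),
                      n_bins, n_bins)
      if (radial) {
        dx <- tr$x[(1 + lf):nfr] - tr$x[1:(nfr - lf)]
        dy <- tr$y[(1 + lf):nfr] - tr$y[1:(nfr - lf)]
        rb <- floor(sqrt(dx^2 + dy^2) / dr_bin) + 1L
        overflow <- overflow + sum(rb > n_radial)
        rb <- pmin(rb, n_radial)
        idx <- j + n_bins * (i - 1L) + n_bins^2 * (rb - 1L)
        N3 <- N3 + array(tabulate(idx, n_bins^2 * n_radial),
                         c(n_bins, n_bins, n_radial))
      }
    }
    if (radial && overflow > 0)
      warning(sprintf("lag %g ps: %d displacement(s) beyond R_max collected in last bin",
                      lag, overflow))
    list(lag = lag, N = N, N3 = N3, overflow = overflow)
  })
  structure(per_lag, class = "transition_counts", n_bins = n_bins, H = H,
            dz = dz, lags = lags_ps, radial = radial, R_max = R_max,
            n_radial = n_radial, dt_save = dt_save,
            temperature = trajs[[1]]$temperature)
}

#' Periodic nearest-neighbor Smoluchowski rate matrix
#'
#' `R[i+1, i] = (D_{i+1/2}/dz^2) exp(-beta (F_{i+1} - F_i)/2)` with the
#' interface diffusion taken as the mean of the adjacent bin values, the
#' diagonal set so each column sums to zero, and periodic closure between
#' the first and last bins.  The construction satisfies detailed balance
#' with respect to exp(-beta F) exactly.
#'
#' @param F free energy on bin centers, kcal/mol.
#' @param D_perp normal diffusion on bin centers, A^2/ps (positive).
#' @param dz bin width, Angstrom.
#' @param beta inverse thermal energy, mol/kcal.
#' @return the n x n rate matrix.
#' @export
build_rate_matrix <- function(F, D_perp, dz, beta) {
  n <- length(F)
  stopifnot(length(D_perp) == n)
  if (any(D_perp <= 0)) stop("D_perp must be strictly positive")
  up <- c(2:n, 1)                     # periodic neighbor above
  Dmid <- (D_perp + D_perp[up]) / 2   # interface i -> i+1
  fwd <- (Dmid / dz^2) * exp(-beta * (F[up] - F) / 2)  # R[i+1, i]
  bwd <- (Dmid / dz^2) * exp(-beta * (F - F[up]) / 2)  # R[i, i+1]
  R <- matrix(0, n, n)
  R[cbind(up, 1:n)] <- fwd
  R[cbind(1:n, up)] <- bwd
  diag(R) <- -colSums(R)
  R
}

# eigendecomposition of the symmetrized generator; returns pieces needed to
# form exp(tau R^(k)) for any radial decay vector `decay` (0 = pure z).
symm_eigen <- function(F, D_perp, dz, beta) {
  n <- length(F)
  up <- c(2:n, 1)
  Dmid <- (D_perp + D_perp[up]) / 2
  off <- Dmid / dz^2
  # diagonal of R (negative column sums of the off-diagonal rates)
  fwd <- off * exp(-beta * (F[up] - F) / 2)
  bwd <- off * exp(-beta * (F - F[up]) / 2)
  diagR <- -(fwd + c(bwd[n], bwd[1:(n - 1)]))
  S <- matrix(0, n, n)
  S[cbind(up, 1:n)] <- off
  S[cbind(1:n, up)] <- off
  diag(S) <- diagR
  list(S = S, half = exp(-beta * F / 2), n = n)
}

# exp(tau (R - diag(decay))) via the symmetrized eigensystem
propagator <- function(sym, tau, decay = 0) {
  Sk <- sym$S
  if (any(decay != 0)) diag(Sk) <- diag(Sk) - decay
  e <- eigen(Sk, symmetric = TRUE)
  T <- e$vectors %*% (exp(tau * e$values) * t(e$vectors))
  # unsymmetrize: T_R = diag(half) T diag(1/half)
  sym$half * T * rep(1 / sym$half, each = sym$n)
}

#' First `n` zeros of the Bessel function J1, including x = 0
#' @param n number of modes.
#' @return numeric vector of length `n` (x_1 = 0).
#' @export
bessel_j1_zeros <- function(n) {
  zeros <- 0
  k <- 1
  while (length(zeros) < n) {
    lo <- (k - 0.25) * pi; hi <- (k + 0.75) * pi
    f <- function(x) besselJ(x, 1)
    if (f(lo) * f(hi) < 0)
      zeros <- c(zeros, stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
    k <- k + 1
  }
  zeros[seq_len(n)]
}

# radial bin weights w[k, b]: probability that a walker starting at r = 0 in
# mode k lands in radial bin b, for a disc of radius R_max with reflecting
# wall.  Rows are Bessel modes (x_k zeros of J1), columns radial bins.
radial_weights <- function(xk, R_max, n_radial) {
  edges <- seq(0, R_max, length.out = n_radial + 1)
  W <- matrix(0, length(xk), n_radial)
  W[1, ] <- (edges[-1]^2 - edges[-length(edges)]^2) / R_max^2
  for (k in seq_along(xk)[-1]) {
    x <- xk[k]
    g <- edges * besselJ(x * edges / R_max, 1)
    W[k, ] <- 2 * (g[-1] - g[-length(g)]) / (x * besselJ(x, 0)^2 * R_max)
  }
  W
}

#' Bayesian model settings for the Smoluchowski analysis
#'
#' @param n_bins number of z-bins (default 100).
#' @param n_f number of cosine basis functions for F (default 10; the
#'   constant mode is gauge and not a parameter).
#' @param n_d number of cosine basis functions for ln Dperp and ln Dpar
#'   (default 6, including the constant).
#' @param n_modes number of Bessel modes for the radial propagator
#'   (default 50, including the constant x = 0 mode).
#' @param H box height, Angstrom.
#' @param temperature temperature, K.
#' @param R_max radial cutoff, Angstrom.
#' @param n_radial number of radial bins.
#' @param f_bound flat-prior half-width on F coefficients, in units of kB T
#'   (default 10).
#' @param d_bound flat-prior half-width on ln-D coefficients around their
#'   initial estimate (default 4).
#' @return object of class `bayes_model`.
#' @export
bayes_model <- function(n_bins = 100, n_f = 10, n_d = 6, n_modes = 50,
                        H, temperature = 298, R_max = 50, n_radial = 100,
                        f_bound = 10, d_bound = 4) {
  dz <- H / n_bins
  z <- seq(-H / 2 + dz / 2, H / 2 - dz / 2, length.out = n_bins)
  # basis matrices on bin centers (F basis starts at k = 1)
  Bf <- sapply(seq_len(n_f - 1), function(k) cos(2 * pi * k * z / H))
  Bd <- cbind(1, if (n_d > 1)
    sapply(seq_len(n_d - 1), function(k) cos(2 * pi * k * z / H)))
  structure(list(n_bins = n_bins, n_f = n_f, n_d = n_d, n_modes = n_modes,
                 H = H, dz = dz, z = z, temperature = temperature,
                 beta = beta_kcal(temperature), R_max = R_max,
                 n_radial = n_radial, Bf = Bf, Bd = Bd,
                 f_bound = f_bound, d_bound = d_bound),
            class = "bayes_model")
}

# parameter vector layout: [a_1..a_{n_f-1} | b_0..b_{n_d-1} | c_0..c_{n_d-1}]
# (c block only in radial mode)
par_split <- function(model, par, radial) {
  nf <- model$n_f - 1
  nd <- model$n_d
  a <- par[seq_len(nf)]
  b <- par[nf + seq_len(nd)]
  cc <- if (radial) par[nf + nd + seq_len(nd)] else NULL
  list(F = as.vector(model$Bf %*% a),
       D_perp = exp(as.vector(model$Bd %*% b)),
       D_par = if (radial) exp(as.vector(model$Bd %*% cc)) else NULL)
}

#' Log-likelihood of transition counts under the rate-matrix model
#'
#' z-only mode: `sum_ij N[j,i] log [exp(tau R)]_{ji}`.  Radial mode: the
#' joint probability of (end bin j, radial bin b) is
#' `sum_k [exp(tau R^(k))]_{ji} w_k(b)` with the start treated as a point at
#' `dr = 0`.  Returns `-Inf` when a transition with nonzero count has
#' non-positive model probability.
#'
#' @param par parameter vector (see [bayes_model()]).
#' @param counts_lag one element of a `transition_counts` object.
#' @param model a `bayes_model` sharing the grid with `counts_lag`.
#' @param radial use the radial likelihood (requires `N3` counts).
#' @param xk cached Bessel zeros (optional).
#' @param W cached radial weight matrix (optional).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(par, counts_lag, model, radial = FALSE,
                           xk = NULL, W = NULL) {
  pr <- par_split(model, par, radial)
  sym <- symm_eigen(pr$F, pr$D_perp, model$dz, model$beta)
  tau <- counts_lag$lag
  if (!radial) {
    T <- propagator(sym, tau)
    N <- counts_lag$N
    # transition probabilities below the eigendecomposition's numerical
    # resolution are structural zeros: a count there vetoes the parameters
    if (any(N > 0 & T < 1e-14)) return(-Inf)
    sum(N[N > 0] * log(T[N > 0]))
  } else {
    if (is.null(counts_lag$N3)) stop("radial likelihood needs radial counts")
    if (is.null(xk)) xk <- bessel_j1_zeros(model$n_modes)
    if (is.null(W)) W <- radial_weights(xk, model$R_max, model$n_radial)
    n <- model$n_bins
    Tk <- matrix(0, n * n, length(xk))
    for (k in seq_along(xk))
      Tk[, k] <- as.vector(propagator(sym, tau,
                                      pr$D_par * xk[k]^2 / model$R_max^2))
    # structural zeros are judged on the z-marginal (the k = 0 mode, whose
    # weights sum to 1); tiny negative cell values from truncating the
    # Bessel series (Gibbs ringing near the J0 nodes) are floored instead
    N3 <- matrix(counts_lag$N3, n * n, model$n_radial)
    if (any(rowSums(N3) > 0 & Tk[, 1] <= 0)) return(-Inf)
    P <- pmax(Tk %*% W, 1e-12)                  # (n*n) x n_radial
    pos <- N3 > 0
    sum(N3[pos] * log(P[pos]))
  }
}

init_parameters <- function(model, counts, radial) {
  # histogram F from start-bin occupancy of the first lag, projected on the
  # cosine basis; constant-D from the short-lag mean squared displacement
  first <- counts[[1]]
  occ <- pmax(colSums(first$N), 0.5)
  Fh <- -log(occ / sum(occ)) / model$beta
  Fh <- Fh - mean(Fh)
  a <- as.vector(stats::lm.fit(model$Bf, Fh)$coefficients)
  zc <- model$z
  dzm <- wrap_centered(outer(zc, zc, "-"), model$H)    # dz[j, i]
  msd <- sum(first$N * dzm^2) / sum(first$N)
  b <- c(log(max(msd / (2 * first$lag), 1e-6)), rep(0, model$n_d - 1))
  par <- c(a, b)
  if (radial) {
    N3 <- first$N3
    rmid <- (seq_len(model$n_radial) - 0.5) * model$R_max / model$n_radial
    msdr <- sum(apply(N3, 3, sum) * rmid^2) / sum(N3)
    par <- c(par, log(max(msdr / (4 * first$lag), 1e-6)),
             rep(0, model$n_d - 1))
  }
  par
}

in_bounds <- function(model, par, init, radial) {
  nf <- model$n_f - 1
  fb <- model$f_bound / model$beta           # kB T units -> kcal/mol
  if (any(abs(par[seq_len(nf)]) > fb)) return(FALSE)
  rest <- par[-seq_len(nf)]
  all(abs(rest - init[-seq_len(nf)]) <= model$d_bound)
}

#' Sample the posterior of the profile coefficients
#'
#' Metropolis random walk over all basis coefficients with flat priors
#' inside bounds, run independently for each lag time.  Proposal scales are
#' adapted during burn-in toward an acceptance rate of 0.2-0.4 and then
#' frozen.  Reproducible given `seed`.
#'
#' @param counts a `transition_counts` object (>= 1 lag).
#' @param model a `bayes_model`.
#' @param n_iter post-burn-in iterations per lag (default 2000).
#' @param burn_in burn-in iterations (default 1000).
#' @param seed RNG seed.
#' @param radial use the radial likelihood (infers Dpar as well).
#' @param thin keep every `thin`-th sample (default 2).
#' @return object of class `posterior_summary`: per lag, posterior mean and
#'   sd of F, Dperp (and Dpar) on the bin grid plus acceptance statistics.
#' @export
sample_posterior <- function(counts, model, n_iter = 2000, burn_in = 1000,
                             seed = 1, radial = attr(counts, "radial"),
                             thin = 2) {
  stopifnot(inherits(counts, "transition_counts"), length(counts) >= 1)
  if (attr(counts, "n_bins") != model$n_bins ||
      abs(attr(counts, "H") - model$H) > 1e-9)
    stop("counts and model do not share the z-grid")
  xk <- if (radial) bessel_j1_zeros(model$n_modes) else NULL
  W <- if (radial) radial_weights(xk, model$R_max, attr(counts, "n_radial"))
       else NULL
  set.seed(seed)
  init <- init_parameters(model, counts, radial)
  npar <- length(init)
  per_lag <- lapply(counts, function(cl) {
    par <- init
    ll <- log_likelihood(par, cl, model, radial, xk, W)
    if (!is.finite(ll)) stop("initial point has zero likelihood")
    scale <- 0.02
    sig <- rep(1, npar)
    acc_win <- 0; tot_win <- 0; acc_tot <- 0
    sums <- NULL; sums2 <- NULL; nkeep <- 0
    for (it in seq_len(burn_in + n_iter)) {
      prop <- par + scale * sig * rnorm(npar)
      if (in_bounds(model, prop, init, radial)) {
        llp <- log_likelihood(prop, cl, model, radial, xk, W)
        if (is.finite(llp) && log(runif(1)) < llp - ll) {
          par <- prop; ll <- llp
          acc_win <- acc_win + 1
          if (it > burn_in) acc_tot <- acc_tot + 1
        }
      }
      tot_win <- tot_win + 1
      if (it <= burn_in && tot_win == 50) {
        rate <- acc_win / tot_win
        if (rate < 0.2) scale <- scale * 0.7
        if (rate > 0.4) scale <- scale * 1.4
        acc_win <- 0; tot_win <- 0
      }
      if (it == burn_in) { acc_win <- 0; tot_win <- 0 }
      if (it > burn_in && (it - burn_in) %% thin == 0) {
        pr <- par_split(model, par, radial)
        v <- c(pr$F, pr$D_perp, pr$D_par)
        if (is.null(sums)) { sums <- v * 0; sums2 <- v * 0 }
        sums <- sums + v; sums2 <- sums2 + v^2
        nkeep <- nkeep + 1
      }
    }
    acc_rate <- acc_tot / n_iter
    if (acc_rate < 0.01)
      stop(sprintf("acceptance collapsed (%.2f%%) at lag %g ps",
                   100 * acc_rate, cl$lag))
    mu <- sums / nkeep
    sdv <- sqrt(pmax(sums2 / nkeep - mu^2, 0))
    n <- model$n_bins
    take <- function(v, blk) v[(blk - 1) * n + seq_len(n)]
    list(lag = cl$lag,
         F_mean = take(mu, 1) - mean(take(mu, 1)),
         F_sd = take(sdv, 1),
         D_perp_mean = take(mu, 2), D_perp_sd = take(sdv, 2),
         D_par_mean = if (radial) take(mu, 3) else NULL,
         D_par_sd = if (radial) take(sdv, 3) else NULL,
         acceptance = acc_rate, scale = scale, n_kept = nkeep)
  })
  structure(per_lag, class = "posterior_summary", z = model$z,
            lags = attr(counts, "lags"), radial = radial, seed = seed,
            temperature = model$temperature)
}

#' Extrapolate per-lag diffusion profiles to infinite lag time
#'
#' Per-bin ordinary least-squares fit of `D(z; tau)` against `1/tau`; the
#' intercept is reported as the infinite-lag profile.  The free energy is
#' lag-independent in the model and is averaged over lags.
#'
#' @param post a `posterior_summary` with >= 2 lags.
#' @return list with `F` (a `free_energy_profile`), `D` (a
#'   `diffusion_profiles` carrying the intercepts), and per-bin fit
#'   `residuals` diagnostics.
#' @export
extrapolate_infinite_lag <- function(post) {
  stopifnot(inherits(post, "posterior_summary"), length(post) >= 2)
  z <- attr(post, "z")
  lags <- vapply(post, `[[`, 0, "lag")
  x <- 1 / lags
  fit_block <- function(field) {
    M <- sapply(post, `[[`, field)            # n_bins x n_lags
    X <- cbind(1, x)
    cf <- t(solve(crossprod(X), crossprod(X, t(M))))
    list(intercept = cf[, 1], resid = t(M) - X %*% t(cf))
  }
  dp <- fit_block("D_perp_mean")
  dl <- if (!is.null(post[[1]]$D_par_mean)) fit_block("D_par_mean") else NULL
  Fm <- rowMeans(sapply(post, `[[`, "F_mean"))
  Fse <- apply(sapply(post, `[[`, "F_mean"), 1, sd) / sqrt(length(post))
  Fprof <- free_energy_profile(z, Fm, F_ref = 0,
                               temperature = attr(post, "temperature"),
                               se = Fse, method = "bayes")
  D <- diffusion_profiles(z, pmax(dp$intercept, 1e-12),
                          D_par = if (is.null(dl)) NULL
                                  else pmax(dl$intercept, 1e-12),
                          se_perp = apply(sapply(post, `[[`, "D_perp_sd"),
                                          1, mean),
                          lags = lags)
  list(F = Fprof, D = D,
       residuals = list(D_perp = dp$resid,
                        D_par = if (is.null(dl)) NULL else dl$resid))
}
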