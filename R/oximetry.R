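## Spin-label oximetry: simulation-side probe-contact oxygen populations and
## experimental-side power-saturation analysis.

#' Probe-oxygen coordination curve n_O2(r) and g(r)
#'
#' Counts oxygen atoms within distance r of each probe position under the
#' full 3D periodic minimum image, averaged over frames and probes; g(r) is
#' the shell count normalized by shell volume and the mean oxygen density.
#'
#' @param probe_frames list (per frame) of n x 3 probe coordinate matrices.
#' @param oxygen_frames list (per frame) of m x 3 oxygen atom coordinates.
#' @param box `(Lx, Ly, H)`, Angstrom.
#' @param radii increasing radii grid, Angstrom.
#' @param c_w water-phase oxygen concentration (1/A^3) to attach for
#'   normalized populations (optional).
#' @return object of class `coordination_curve`: `r`, `n_O2`, `g`, `c_w`.
#' @export
coordination_curve <- function(probe_frames, oxygen_frames, box, radii,
                               c_w = NULL) {
  if (is.matrix(probe_frames)) probe_frames <- list(probe_frames)
  if (is.matrix(oxygen_frames)) oxygen_frames <- list(oxygen_frames)
  stopifnot(length(probe_frames) == length(oxygen_frames),
            length(probe_frames) >= 1, all(diff(radii) > 0))
  if (max(radii) > min(box) / 2)
    warning("radii beyond the inscribed sphere; g(r) shells are truncated")
  n_pairs_tot <- 0
  all_d <- list()
  n_probe_tot <- 0; n_ox_tot <- 0
  for (f in seq_along(probe_frames)) {
    P <- probe_frames[[f]]; O <- oxygen_frames[[f]]
    if (is.null(dim(P))) P <- matrix(P, ncol = 3)
    if (is.null(dim(O))) O <- matrix(O, ncol = 3)
    if (nrow(P) == 0 || nrow(O) == 0) stop("empty frame")
    dx <- outer(P[, 1], O[, 1], "-"); dx <- dx - box[1] * round(dx / box[1])
    dy <- outer(P[, 2], O[, 2], "-"); dy <- dy - box[2] * round(dy / box[2])
    dzv <- outer(P[, 3], O[, 3], "-"); dzv <- dzv - box[3] * round(dzv / box[3])
    all_d[[f]] <- sqrt(dx^2 + dy^2 + dzv^2)
    n_probe_tot <- n_probe_tot + nrow(P)
    n_ox_tot <- n_ox_tot + nrow(O)
  }
  d <- unlist(all_d)
  n_probe_mean <- n_probe_tot / length(probe_frames)
  n_frames <- length(probe_frames)
  n_O2 <- vapply(radii, function(r) sum(d <= r), 0) /
    (n_probe_mean * n_frames)
  rho <- (n_ox_tot / n_frames) / prod(box)
  edges <- c(0, radii)
  shell_counts <- diff(vapply(edges, function(r) sum(d <= r), 0))
  shell_vol <- diff(4 / 3 * pi * edges^3)
  g <- shell_counts / (n_probe_mean * n_frames) / (shell_vol * rho)
  structure(list(r = radii, n_O2 = n_O2, g = g, c_w = c_w),
            class = "coordination_curve")
}

#' Relaxation-ratio surrogate I(r)
#'
#' `I(r) = [n_O2(r)/c_w]_d / [n_O2(r)/c_w]_o`: the ratio of c_w-normalized
#' oxygen populations near the probe in the disordered vs ordered system.
#' The default contact radius is 4.5 Angstrom.
#'
#' @param curve_d,curve_o `coordination_curve` objects carrying their own
#'   `c_w`.
#' @param r contact radius (default 4.5); populations are interpolated on
#'   the radii grid.
#' @return the scalar ratio I(r).
#' @export
oxygen_ratio_I <- function(curve_d, curve_o, r = 4.5) {
  stopifnot(inherits(curve_d, "coordination_curve"),
            inherits(curve_o, "coordination_curve"),
            !is.null(curve_d$c_w), !is.null(curve_o$c_w))
  nd <- stats::approx(curve_d$r, curve_d$n_O2, xout = r)$y
  no <- stats::approx(curve_o$r, curve_o$n_O2, xout = r)$y
  if (is.na(nd) || is.na(no)) stop("r outside the radii grid")
  if (no <= 0) stop("zero oxygen population in the denominator system")
  (nd / curve_d$c_w) / (no / curve_o$c_w)
}

# homogeneous power-saturation law
saturation_model <- function(P, I0, P_half) {
  I0 * sqrt(P) / (1 + (2^(2 / 3) - 1) * P / P_half)^(3 / 2)
}

#' Fit a power-saturation curve
#'
#' Nonlinear least squares of
#' `I = I0 sqrt(P) / (1 + (2^(2/3) - 1) P / P_half)^(3/2)`.
#' `P_half` is the microwave power at which the first-derivative amplitude
#' falls to half its extrapolated unsaturated value `I0 sqrt(P_half)`.
#' Initial guesses come from the low-power linear region and the location
#' of the amplitude maximum.
#'
#' @param curve a `saturation_curve` (>= 4 distinct powers) or a data.frame
#'   with columns `power_mW`, `amplitude`.
#' @return list of class `saturation_fit`: `I0`, `P_half` (mW), standard
#'   errors, `residuals`.
#' @export
fit_saturation <- function(curve) {
  P <- curve$power_mW; I <- curve$amplitude
  if (length(unique(P)) < 4) stop("need >= 4 distinct powers")
  c1 <- 2^(2 / 3) - 1
  i0_init <- I[which.min(P)] / sqrt(min(P))
  p12_init <- 2 * c1 * P[which.max(I)]     # amplitude peaks at P12/(2 c1)
  df <- data.frame(P = P, I = I)
  fit <- minpack.lm::nlsLM(
    I ~ I0 * sqrt(P) / (1 + c1 * P / P12)^(3 / 2), data = df,
    start = list(I0 = i0_init, P12 = max(p12_init, 1e-3)),
    lower = c(1e-12, 1e-12), control = minpack.lm::nls.lm.control(
      maxiter = 200))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(NA_real_, NA_real_))
  structure(list(I0 = unname(cf["I0"]), P_half = unname(cf["P12"]),
                 se_I0 = unname(se[1]), se_P_half = unname(se[2]),
                 residuals = stats::resid(fit)),
            class = "saturation_fit")
}

#' Relaxation-enhancement ratio report for two systems
#'
#' Enhancements are differences between gas conditions (oxygen-exposed
#' minus inert) formed before taking ratios.  The transverse (R2) ratio
#' comes from linewidth enhancements; the longitudinal (R1) ratio from
#' enhancements of `P_half / linewidth`; the report also gives their
#' average, with errors propagated in quadrature where supplied.
#'
#' @param sys_d,sys_o per-system lists, each with elements `inert` and
#'   `oxygen`; every condition is a list with `linewidth` (and optionally
#'   `linewidth_se`), plus `fit` (a `saturation_fit`) for the R1 channel.
#' @return list of class `relaxation_ratio_report` with `R2_ratio`,
#'   `R1_ratio`, `average`, and their standard errors (NA when not
#'   propagatable).
#' @export
relaxation_ratio_report <- function(sys_d, sys_o) {
  need <- function(s, nm) {
    if (is.null(s$inert) || is.null(s$oxygen))
      stop(sprintf("system '%s' must supply both gas conditions", nm))
  }
  need(sys_d, "d"); need(sys_o, "o")
  dlw <- function(s) s$oxygen$linewidth - s$inert$linewidth
  dlw_se <- function(s) {
    a <- s$oxygen$linewidth_se; b <- s$inert$linewidth_se
    if (is.null(a) || is.null(b)) NA_real_ else sqrt(a^2 + b^2)
  }
  rho <- function(cond) cond$fit$P_half / cond$linewidth
  rho_se <- function(cond) {
    if (is.null(cond$fit$se_P_half) || is.na(cond$fit$se_P_half))
      return(NA_real_)
    abs(rho(cond)) * sqrt((cond$fit$se_P_half / cond$fit$P_half)^2 +
      (if (is.null(cond$linewidth_se)) 0
       else (cond$linewidth_se / cond$linewidth)^2))
  }
  ratio_se <- function(r, num, num_se, den, den_se) {
    if (any(is.na(c(num_se, den_se)))) NA_real_
    else abs(r) * sqrt((num_se / num)^2 + (den_se / den)^2)
  }
  R2_num <- dlw(sys_d); R2_den <- dlw(sys_o)
  R2 <- R2_num / R2_den
  R2_se <- ratio_se(R2, R2_num, dlw_se(sys_d), R2_den, dlw_se(sys_o))
  R1 <- NA_real_; R1_se <- NA_real_
  if (!is.null(sys_d$oxygen$fit) && !is.null(sys_o$oxygen$fit)) {
    n1 <- rho(sys_d$oxygen) - rho(sys_d$inert)
    d1 <- rho(sys_o$oxygen) - rho(sys_o$inert)
    R1 <- n1 / d1
    n1se <- sqrt(rho_se(sys_d$oxygen)^2 + rho_se(sys_d$inert)^2)
    d1se <- sqrt(rho_se(sys_o$oxygen)^2 + rho_se(sys_o$inert)^2)
    R1_se <- ratio_se(R1, n1, n1se, d1, d1se)
  }
  avg <- mean(c(R1, R2), na.rm = TRUE)
  avg_se <- if (any(is.na(c(R1_se, R2_se)))) NA_real_
            else sqrt(R1_se^2 + R2_se^2) / 2
  structure(list(R2_ratio = R2, R2_se = R2_se, R1_ratio = R1,
                 R1_se = R1_se, average = avg, average_se = avg_se),
            class = "relaxation_ratio_report")
}
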