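## Free energy from occupancy, water/membrane concentrations, and the
## thickness-dependent partition coefficient.

# integral of g over [a, b] on grid z (bin centers): interior trapezoid with
# linearly interpolated endpoints at a and b
integrate_window <- function(z, g, a, b) {
  stopifnot(a < b)
  inside <- z > a & z < b
  ga <- stats::approx(z, g, xout = a, rule = 2)$y
  gb <- stats::approx(z, g, xout = b, rule = 2)$y
  trapz(c(a, z[inside], b), c(ga, g[inside], gb))
}

#' Estimate the free-energy profile F(z) from occupancy
#'
#' Computes `F_i = -kB T ln p_i` from the pooled z-histogram of all supplied
#' trajectories (profiles are not symmetrized).  `F_ref` is the mean of F
#' over the water-reference zone; never-visited bins carry an `Inf` sentinel
#' and are excluded from the reference average.
#'
#' @param trajs list of `permeant_trajectory` objects (shared box).
#' @param n_bins number of z-bins (default 100, >= 10).
#' @param geometry a `membrane_geometry` (defines the water-reference zone).
#' @param replicates optional factor over `trajs`; per-bin standard errors
#'   are then the across-replicate standard error of the mean.
#' @param symmetrize diagnostic option: average F(z) with F(-z).
#' @return a `free_energy_profile`.
#' @export
estimate_pmf <- function(trajs, n_bins = 100, geometry, replicates = NULL,
                         symmetrize = FALSE) {
  if (inherits(trajs, "permeant_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1, n_bins >= 10,
            inherits(geometry, "membrane_geometry"))
  H <- trajs[[1]]$box[3]
  temp <- trajs[[1]]$temperature
  dz <- H / n_bins
  centers <- seq(-H / 2 + dz / 2, H / 2 - dz / 2, length.out = n_bins)
  bin_of <- function(z) pmin(floor((z + H / 2) / dz) + 1, n_bins)

  hist_of <- function(trs) {
    zs <- unlist(lapply(trs, `[[`, "z"))
    tabulate(bin_of(zs), nbins = n_bins)
  }
  counts <- hist_of(trajs)
  if (sum(counts) == 0) stop("empty histogram")
  F_of_counts <- function(cnt) {
    p <- cnt / sum(cnt)
    F <- rep(Inf, n_bins)
    F[p > 0] <- -kB_kcal * temp * log(p[p > 0] / dz)
    F
  }
  F <- F_of_counts(counts)
  if (any(!is.finite(F)))
    warning(sprintf("%d never-visited bin(s); infinite-F sentinel used",
                    sum(!is.finite(F))))
  if (symmetrize) {
    Fr <- rev(F)
    F <- ifelse(is.finite(F) & is.finite(Fr), (F + Fr) / 2, pmin(F, Fr))
  }
  se <- rep(NA_real_, n_bins)
  if (!is.null(replicates)) {
    replicates <- as.factor(replicates)
    stopifnot(length(replicates) == length(trajs))
    Fs <- sapply(levels(replicates), function(l)
      F_of_counts(hist_of(trajs[replicates == l])))
    fin <- is.finite(Fs)
    nrep <- rowSums(fin)
    Fs[!fin] <- NA
    se <- ifelse(nrep >= 2,
                 apply(Fs, 1, sd, na.rm = TRUE) / sqrt(pmax(nrep, 1)),
                 NA_real_)
  }
  in_water <- abs(centers) >= geometry$water_zone[1] &
    abs(centers) <= geometry$water_zone[2] & is.finite(F)
  if (!any(in_water)) stop("no finite bins in the water-reference zone")
  free_energy_profile(centers, F, F_ref = mean(F[in_water]),
                      temperature = temp, se = se, method = "histogram")
}

#' Water-phase permeant concentration
#'
#' Boltzmann-integral estimate
#' `c_w = (N/A) exp(-beta F_ref) / integral exp(-beta F(z)) dz`, and
#' (optionally) the far-zone time-average estimate: the mean number of
#' permeants in the water-reference zone divided by its volume.
#'
#' @param N total number of permeants in the box.
#' @param profile a `free_energy_profile` spanning the box.
#' @param A lateral cross-section area in Angstrom^2.
#' @param trajs optional trajectories for the far-zone count estimate.
#' @param geometry needed with `trajs` (defines the far zone).
#' @return list of class `concentration_result` with `c_w_A3` (1/A^3),
#'   `c_w_molL`, the method tag, and (when computed) `c_w_far_A3`.
#' @export
water_concentration <- function(N, profile, A, trajs = NULL,
                                geometry = NULL) {
  stopifnot(inherits(profile, "free_energy_profile"), N > 0, A > 0)
  beta <- beta_kcal(profile$temperature)
  g <- exp(-beta * profile$F)        # Inf sentinel -> weight 0
  if (all(g == 0)) stop("profile is all sentinel bins")
  dz <- profile$z[2] - profile$z[1]
  Zint <- sum(g) * dz                # periodic grid: midpoint rule is exact
  c_w <- (N / A) * exp(-beta * profile$F_ref) / Zint
  out <- list(c_w_A3 = c_w, c_w_molL = c_w * count_per_A3_to_mol_per_L,
              method = "boltzmann-integral")
  if (!is.null(trajs)) {
    stopifnot(inherits(geometry, "membrane_geometry"))
    wz <- geometry$water_zone
    counts <- vapply(trajs, function(tr)
      mean(abs(tr$z) >= wz[1] & abs(tr$z) <= wz[2]), 0)
    vol <- A * 2 * (wz[2] - wz[1])
    out$c_w_far_A3 <- sum(counts) / vol
    out$method <- c(out$method, "far-zone-count")
  }
  class(out) <- "concentration_result"
  out
}

#' Membrane permeant concentration at assumed thickness h
#'
#' `c_m(h) = (N / (A h)) * integral_{-h/2}^{h/2} exp(-beta F) dz /
#'  integral_{-H/2}^{H/2} exp(-beta F) dz`.
#'
#' @inheritParams water_concentration
#' @param h assumed membrane thickness in Angstrom (< H).
#' @return list with `c_m_A3`, `c_m_molL`, `h`.
#' @export
membrane_concentration <- function(N, profile, A, h) {
  beta <- beta_kcal(profile$temperature)
  g <- exp(-beta * profile$F)
  dz <- profile$z[2] - profile$z[1]
  num <- integrate_window(profile$z, g, -h / 2, h / 2)
  c_m <- (N / (A * h)) * num / (sum(g) * dz)
  list(c_m_A3 = c_m, c_m_molL = c_m * count_per_A3_to_mol_per_L, h = h)
}

#' Thickness-dependent partition coefficient K(h)
#'
#' `K(h) = (1/h) * integral_{-h/2}^{h/2} exp(-beta (F - F_ref)) dz`
#' by composite trapezoid with the dividing surfaces interpolated on the bin
#' grid.  K depends on the assumed membrane thickness h; ratios between two
#' systems (at their own h values) are nearly h-insensitive.
#'
#' @param profile a `free_energy_profile`.
#' @param h assumed membrane thickness, Angstrom.
#' @return list of class `partition_result` with `K`, `h`.
#' @export
partition_coefficient <- function(profile, h) {
  stopifnot(inherits(profile, "free_energy_profile"),
            h < 2 * max(profile$z) + (profile$z[2] - profile$z[1]))
  inside <- abs(profile$z) <= h / 2
  if (any(!is.finite(profile$F[inside])))
    stop("sentinel (never-visited) bins inside |z| < h/2; cannot integrate")
  beta <- beta_kcal(profile$temperature)
  g <- exp(-beta * (profile$F - profile$F_ref))
  K <- integrate_window(profile$z, g, -h / 2, h / 2) / h
  structure(list(K = K, h = h), class = "partition_result")
}

#' Ratio of two partition coefficients
#'
#' Each operand is evaluated at its own stated thickness.
#'
#' @param p1,p2 `partition_result` objects.
#' @return list with `ratio`, `K1`, `K2`, `h1`, `h2`.
#' @export
partition_ratio <- function(p1, p2) {
  stopifnot(inherits(p1, "partition_result"), inherits(p2, "partition_result"))
  list(ratio = p1$K / p2$K, K1 = p1$K, K2 = p2$K, h1 = p1$h, h2 = p2$h)
}
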