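## Membrane crossing events and the counting-method permeability.
##
## A transit counts as a crossing when the permeant enters through one
## dividing surface |z| = h/2, visits the midplane region |z| < z_mid, and
## exits through the other surface.  Re-exit through the entry surface is a
## rebound.  Permeants already inside the membrane at t = 0 have an unknown
## entry side; under the memoryless-exit assumption their first exit counts
## as 0.5 crossing ("initial escape").  The periodic water slab spans the
## box wrap: a wrap through water toggles the side label without creating
## any membrane event.

#' Detect membrane entry/rebound/crossing events for one trajectory
#'
#' Classifies every membrane-residence episode as exactly one of
#' `crossing`, `rebound`, `initial-escape`, `unresolved` (ambiguous path:
#' water-to-water jump through the membrane in one saved frame, or sides
#' differing without an observed midplane visit) or `unresolved-at-end`.
#'
#' @param traj a centered `permeant_trajectory`.
#' @param geometry a `membrane_geometry` with `h_half < H/2`.
#' @return a data.frame of class `crossing_event_log` with columns
#'   `permeant_id`, `kind`, `t_entry`, `side_entry`, `t_mid`, `t_exit`,
#'   `side_exit`, `dr_A`; attributes `T_sim` (ps) and `box`.
#' @export
detect_events <- function(traj, geometry) {
  stopifnot(inherits(traj, "permeant_trajectory"),
            inherits(geometry, "membrane_geometry"))
  H <- traj$box[3]
  stopifnot(geometry$h_half < H / 2)
  z <- traj$z; t <- traj$t
  region <- ifelse(abs(z) < geometry$h_half, 0L, ifelse(z > 0, 1L, -1L))
  r <- rle(region)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  ep <- list()
  add <- function(kind, i_entry, side_entry, i_mid, i_exit, side_exit) {
    dr <- if (!is.na(i_entry) && !is.na(i_exit))
      sqrt((traj$x[i_exit] - traj$x[i_entry])^2 +
           (traj$y[i_exit] - traj$y[i_entry])^2) else NA_real_
    ep[[length(ep) + 1L]] <<- data.frame(
      permeant_id = traj$id, kind = kind,
      t_entry = if (is.na(i_entry)) NA_real_ else t[i_entry],
      side_entry = side_entry,
      t_mid = if (is.na(i_mid)) NA_real_ else t[i_mid],
      t_exit = if (is.na(i_exit)) NA_real_ else t[i_exit],
      side_exit = side_exit, dr_A = dr, stringsAsFactors = FALSE)
  }
  first_mid <- function(k) {
    idx <- starts[k]:ends[k]
    hit <- idx[abs(z[idx]) < geometry$z_mid]
    if (length(hit)) hit[1] else NA_integer_
  }

  nr <- length(r$values)
  for (k in seq_len(nr)) {
    v <- r$values[k]
    if (v == 0L) {
      i_mid <- first_mid(k)
      i_exit <- if (k < nr) starts[k + 1L] else NA_integer_
      side_exit <- if (k < nr) r$values[k + 1L] else NA_integer_
      if (k == 1L) {
        # initially inside: entry history unknown, memoryless exit
        kind <- if (is.na(i_exit)) "unresolved-at-end" else "initial-escape"
        add(kind, NA_integer_, NA_integer_, i_mid, i_exit, side_exit)
      } else {
        side_entry <- r$values[k - 1L]
        i_entry <- starts[k]
        if (is.na(i_exit)) {
          add("unresolved-at-end", i_entry, side_entry, i_mid, NA_integer_,
              NA_integer_)
        } else if (side_exit == side_entry) {
          add("rebound", i_entry, side_entry, i_mid, i_exit, side_exit)
        } else if (!is.na(i_mid)) {
          add("crossing", i_entry, side_entry, i_mid, i_exit, side_exit)
        } else {
          add("unresolved", i_entry, side_entry, NA_integer_, i_exit,
              side_exit)
        }
      }
    } else if (k < nr && r$values[k + 1L] == -v) {
      # water -> opposite water with no membrane frames in between:
      # either a wrap through the periodic water slab (no event) or an
      # unobserved transit through the membrane (ambiguous -> unresolved)
      z1 <- z[ends[k]]; z2 <- z[starts[k + 1L]]
      dzm <- z2 - z1
      through_wrap <- abs(dzm) > H - abs(dzm)
      if (!through_wrap)
        add("unresolved", ends[k], v, NA_integer_, starts[k + 1L], -v)
    }
  }
  out <- if (length(ep)) do.call(rbind, ep) else
    data.frame(permeant_id = character(), kind = character(),
               t_entry = numeric(), side_entry = integer(),
               t_mid = numeric(), t_exit = numeric(),
               side_exit = integer(), dr_A = numeric())
  attr(out, "T_sim") <- t[length(t)] - t[1]
  attr(out, "box") <- traj$box
  class(out) <- c("crossing_event_log", class(out))
  out
}

#' Pool event logs from several trajectories
#' @param logs list of `crossing_event_log` objects (shared geometry/box).
#' @return one pooled `crossing_event_log`; `T_sim` is the per-trajectory
#'   duration (not summed), kept in attributes together with `n_traj`.
#' @export
pool_event_logs <- function(logs) {
  if (inherits(logs, "crossing_event_log")) logs <- list(logs)
  out <- do.call(rbind, lapply(logs, as.data.frame))
  attr(out, "T_sim") <- attr(logs[[1]], "T_sim")
  attr(out, "box") <- attr(logs[[1]], "box")
  attr(out, "n_traj") <- length(logs)
  class(out) <- c("crossing_event_log", class(out))
  out
}

effective_crossings <- function(log) {
  sum(log$kind == "crossing") + 0.5 * sum(log$kind == "initial-escape")
}

#' Counting-method permeability P = r / (2 c_w)
#'
#' The crossing rate is `r = (n_cross + 0.5 n_init_escape) / (A T_total)`
#' where `T_total` is the summed simulation time of all trajectories and A
#' the cross-sectional area of one leaflet; the factor 2 accounts for the
#' two directions.  The default 95% CI is the Poisson exact interval on the
#' effective count; with >= 3 replicates a t-interval across replicates is
#' used instead.
#'
#' The N permeants are treated as sharing one box of cross-section A over
#' the common simulation time `T_sim` -- the same convention under which
#' `c_w` is computed from the same N permeants -- so the default `T_total`
#' is the per-trajectory duration, not the summed permeant-time.
#'
#' @param logs a `crossing_event_log` or list of them (one per trajectory).
#' @param A cross-sectional area, Angstrom^2; defaults to Lx*Ly of the box.
#' @param T_total simulation time in ps; defaults to the duration of the
#'   first trajectory.
#' @param c_w water-phase concentration (1/A^3) or a `concentration_result`.
#' @param replicates optional factor over `logs` (>= 3 levels enables the
#'   replicate t-interval).
#' @return list of class `counting_permeability`: `count`, `rate_A2ps`,
#'   `P_cm_s`, `ci_cm_s` (95%), `ci_method`, `c_w_A3`.
#' @export
counting_permeability <- function(logs, A = NULL, T_total = NULL, c_w,
                                  replicates = NULL) {
  if (inherits(logs, "crossing_event_log")) logs <- list(logs)
  if (inherits(c_w, "concentration_result")) c_w <- c_w$c_w_A3
  if (c_w <= 0) stop("c_w must be positive")
  box <- attr(logs[[1]], "box")
  if (is.null(A)) A <- box[1] * box[2]
  if (is.null(T_total))
    T_total <- attr(logs[[1]], "T_sim")
  count <- sum(vapply(logs, effective_crossings, 0))
  rate <- count / (A * T_total)
  P <- rate / (2 * c_w)                        # Angstrom/ps
  to_P <- function(cnt) cnt / (A * T_total) / (2 * c_w) * A_per_ps_to_cm_per_s
  if (!is.null(replicates) && nlevels(as.factor(replicates)) >= 3) {
    replicates <- as.factor(replicates)
    Ps <- vapply(levels(replicates), function(l) {
      sub <- logs[replicates == l]
      Tsub <- attr(sub[[1]], "T_sim")
      sum(vapply(sub, effective_crossings, 0)) / (A * Tsub) / (2 * c_w) *
        A_per_ps_to_cm_per_s
    }, 0)
    m <- mean(Ps); s <- sd(Ps) / sqrt(length(Ps))
    ci <- m + c(-1, 1) * stats::qt(0.975, length(Ps) - 1) * s
    ci_method <- "replicate-t"
  } else if (count == 0) {
    ci <- c(0, to_P(qgamma(0.95, 1)))          # one-sided upper bound
    ci_method <- "poisson-upper"
  } else {
    ci <- to_P(c(qgamma(0.025, count), qgamma(0.975, count + 1)))
    ci_method <- "poisson-exact"
  }
  structure(list(count = count, rate_A2ps = rate,
                 P_cm_s = P * A_per_ps_to_cm_per_s,
                 ci_cm_s = ci, ci_method = ci_method, c_w_A3 = c_w,
                 A = A, T_total = T_total),
            class = "counting_permeability")
}

#' @export
print.counting_permeability <- function(x, ...) {
  cat(sprintf("counting permeability: P = %.4g cm/s (95%% CI %.4g-%.4g, %s)\n",
              x$P_cm_s, x$ci_cm_s[1], x$ci_cm_s[2], x$ci_method))
  cat(sprintf("  effective crossings = %.1f over %.4g ps, A = %.4g A^2\n",
              x$count, x$T_total, x$A))
  invisible(x)
}

#' Characteristic entrance and escape times
#'
#' `tau_entr` is the mean time from a surface entry to the first midplane
#' visit of the same episode; `tau_esc` the mean time from that first
#' midplane visit to the subsequent surface exit.  Initial-escape episodes
#' are excluded (their entry history is unknown).
#'
#' @param logs a `crossing_event_log` or list of them.
#' @return list of class `characteristic_times`: `tau_entr`, `tau_esc`
#'   (ps, with `se` and episode counts); `NA` marks unavailable.
#' @export
characteristic_times <- function(logs) {
  log <- if (is.data.frame(logs)) logs else pool_event_logs(logs)
  has_entry <- !is.na(log$t_entry) & !is.na(log$t_mid)
  entr <- log$t_mid[has_entry] - log$t_entry[has_entry]
  has_exit <- !is.na(log$t_mid) & !is.na(log$t_exit) &
    log$kind != "initial-escape"
  esc <- log$t_exit[has_exit] - log$t_mid[has_exit]
  msd <- function(v) if (length(v) >= 1)
    c(mean = mean(v), se = if (length(v) > 1) sd(v) / sqrt(length(v))
      else NA_real_, n = length(v))
    else c(mean = NA_real_, se = NA_real_, n = 0)
  structure(list(tau_entr = msd(entr), tau_esc = msd(esc)),
            class = "characteristic_times")
}

#' Lateral escape distance L_par
#'
#' Root-mean-square lateral displacement between membrane entry and exit
#' over all resolved residence episodes (crossings and rebounds), using the
#' unwrapped lateral coordinates.
#'
#' @param logs a `crossing_event_log` or list of them.
#' @return list with `L_par` (Angstrom), `se` (delta-method), `n`.
#' @export
lateral_escape_distance <- function(logs) {
  log <- if (is.data.frame(logs)) logs else pool_event_logs(logs)
  dr <- log$dr_A[log$kind %in% c("crossing", "rebound") & !is.na(log$dr_A)]
  if (length(dr) == 0) stop("no completed membrane-residence episodes")
  L <- sqrt(mean(dr^2))
  se <- if (length(dr) > 1)
    sd(dr^2) / (2 * L * sqrt(length(dr))) else NA_real_
  list(L_par = L, se = se, n = length(dr))
}

#' Monte-Carlo expectation of the initial-escape crossing contribution
#'
#' Walkers with constant diffusion in a flat-potential membrane slab are
#' initialized uniformly inside, assigned an entry side uniformly at random,
#' and run until first exit; a full crossing is scored when the exit side
#' differs from the assigned entry side.  Under the memoryless-exit
#' assumption the expectation is 0.5 crossing per initial escape, which is
#' the correction applied by [counting_permeability()].
#'
#' @param n number of walkers.
#' @param h_half slab half-width, Angstrom.
#' @param D diffusion coefficient, A^2/ps.
#' @param dt integration step, ps.
#' @param seed RNG seed.
#' @return list with `mean` (crossings per initial escape), `se`, `n`.
#' @export
initial_escape_expectation <- function(n = 10000, h_half = 15, D = 0.2,
                                       dt = 0.1, seed = 1) {
  set.seed(seed)
  z0 <- runif(n, -h_half, h_half)
  entry_side <- sample(c(-1L, 1L), n, replace = TRUE)
  exit_side <- .sim_first_exit_side(z0, h_half, D, dt)
  score <- as.numeric(exit_side != entry_side)
  list(mean = mean(score), se = sd(score) / sqrt(n), n = n)
}
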