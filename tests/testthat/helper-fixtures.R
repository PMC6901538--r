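# shared fixtures and independent oracles

# quick trajectory from a z-series (lateral at rest unless supplied)
make_traj <- function(z, t = seq_along(z) - 1, x = numeric(length(z)),
                      y = numeric(length(z)), box = c(40, 40, 80),
                      id = "p1", type = "test", temperature = 298) {
  permeant_trajectory(id, type, t, x, y, z, box, temperature)
}

# brute-force per-frame event labeler: explicit state walk, written
# independently of the rle-based detector in the package
brute_force_events <- function(traj, geometry) {
  z <- traj$z; t <- traj$t; H <- traj$box[3]
  reg <- function(zz) if (abs(zz) < geometry$h_half) 0L else
    if (zz > 0) 1L else -1L
  out <- data.frame(kind = character(), t_entry = numeric(),
                    side_entry = integer(), t_mid = numeric(),
                    t_exit = numeric(), side_exit = integer())
  push <- function(kind, te, se, tm, tx, sx)
    out <<- rbind(out, data.frame(kind = kind, t_entry = as.numeric(te),
                                  side_entry = as.integer(se),
                                  t_mid = as.numeric(tm),
                                  t_exit = as.numeric(tx),
                                  side_exit = as.integer(sx)))
  state <- reg(z[1])
  side <- if (state != 0L) state else NA_integer_
  in_mem <- state == 0L
  initial <- in_mem
  t_entry <- NA_real_; t_mid <- if (in_mem && abs(z[1]) < geometry$z_mid)
    t[1] else NA_real_
  for (i in seq_along(z)[-1]) {
    r <- reg(z[i])
    if (in_mem) {
      if (r == 0L) {
        if (is.na(t_mid) && abs(z[i]) < geometry$z_mid) t_mid <- t[i]
      } else {
        if (initial) {
          push("initial-escape", NA, NA, t_mid, t[i], r)
        } else if (r == side) {
          push("rebound", t_entry, side, t_mid, t[i], r)
        } else if (!is.na(t_mid)) {
          push("crossing", t_entry, side, t_mid, t[i], r)
        } else {
          push("unresolved", t_entry, side, NA, t[i], r)
        }
        in_mem <- FALSE; initial <- FALSE; side <- r
        t_entry <- NA; t_mid <- NA
      }
    } else {
      if (r == 0L) {
        in_mem <- TRUE; t_entry <- t[i]
        t_mid <- if (abs(z[i]) < geometry$z_mid) t[i] else NA_real_
      } else if (r == -side) {
        dz <- z[i] - z[i - 1]
        if (abs(dz) <= H - abs(dz))   # through the membrane, unobserved
          push("unresolved", t[i - 1], side, NA, t[i], r)
        side <- r                     # wrap through water: toggle only
      }
    }
  }
  if (in_mem)
    push("unresolved-at-end", if (initial) NA else t_entry,
         if (initial) NA else side, t_mid, NA, NA)
  out
}

# random telegraph-like z-series: piecewise jumps between water/membrane
# levels plus jitter, occasionally hopping across the wrap
random_z_series <- function(n, H = 80, h_half = 20) {
  levels <- c(-H / 2 + 2, -h_half - 3, -h_half + 3, -2, 0, 2,
              h_half - 3, h_half + 3, H / 2 - 2)
  idx <- cumsum(sample(c(-1, 0, 1), n, replace = TRUE,
                       prob = c(0.3, 0.4, 0.3)))
  idx <- 1 + (idx - min(idx)) %% length(levels)
  z <- levels[idx] + runif(n, -1, 1)
  pmin(pmax(z, -H / 2), H / 2 - 1e-6)
}

# cheap cache for simulations shared across tests in one file
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}
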