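## Domain types and plain-text tabular I/O.
##
## All trajectory coordinates are membrane-centered: z = 0 at the bilayer
## midplane, z periodic over the box height H with the single water slab
## spanning the wrap (the box edge lies in water).  Lateral coordinates x, y
## are stored unwrapped so that lateral displacements are direct differences.

#' Permeant trajectory
#'
#' Time-ordered membrane-centered positions of one permeant molecule.
#'
#' @param id permeant identifier (character or coercible).
#' @param type permeant species label, e.g. `"oxygen-like"`.
#' @param t time stamps in ps; strictly increasing, constant spacing.
#' @param x,y,z coordinates in Angstrom; `z` is wrapped into `[-H/2, H/2)`,
#'   `x` and `y` are unwrapped.
#' @param box numeric length-3 `(Lx, Ly, H)` in Angstrom.
#' @param temperature simulation temperature in K.
#' @param centered logical; `TRUE` when z = 0 is the membrane midplane.
#' @return an object of class `permeant_trajectory`.
#' @export
permeant_trajectory <- function(id, type, t, x, y, z, box, temperature,
                                centered = TRUE) {
  stopifnot(length(box) == 3, all(box > 0), temperature > 0)
  n <- length(t)
  if (length(x) != n || length(y) != n || length(z) != n)
    stop("t, x, y, z must have equal length")
  if (n > 1) {
    dt <- diff(t)
    if (any(dt <= 0))
      stop(sprintf("non-monotone time for permeant '%s'", id))
    if (max(dt) - min(dt) > 1e-6 * max(dt))
      warning(sprintf("non-constant time spacing for permeant '%s'", id))
  }
  H <- box[3]
  if (any(abs(z) > H / 2 + 1e-9))
    stop(sprintf("|z| exceeds H/2 for permeant '%s'; wrap first", id))
  structure(list(id = as.character(id), type = as.character(type),
                 t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 z = as.numeric(z), box = as.numeric(box),
                 temperature = as.numeric(temperature),
                 centered = isTRUE(centered)),
            class = "permeant_trajectory")
}

#' @export
print.permeant_trajectory <- function(x, ...) {
  cat(sprintf("permeant_trajectory '%s' (%s): %d frames, dt = %.4g ps,\n",
              x$id, x$type, length(x$t),
              if (length(x$t) > 1) x$t[2] - x$t[1] else NA_real_))
  cat(sprintf("  box %.4g x %.4g x %.4g A, T = %.4g K, centered = %s\n",
              x$box[1], x$box[2], x$box[3], x$temperature, x$centered))
  invisible(x)
}

#' Membrane geometry for event counting and integration
#'
#' @param h_half dividing-surface position h/2 in Angstrom: |z| < h/2 is
#'   "inside the membrane".
#' @param z_mid half-width of the midplane region in Angstrom (default 4):
#'   a transit must visit |z| < z_mid to count as a crossing.
#' @param water_zone numeric length-2 interval of |z| used as the
#'   water-reference zone for F_ref; default `c(h_half + 5, H/2)` when `H`
#'   is supplied.
#' @param H box height in Angstrom (only needed for the water-zone default).
#' @return object of class `membrane_geometry`.
#' @export
membrane_geometry <- function(h_half, z_mid = 4, water_zone = NULL, H = NULL) {
  if (is.null(water_zone)) {
    if (is.null(H)) stop("supply water_zone or H")
    water_zone <- c(h_half + 5, H / 2)
  }
  stopifnot(h_half > 0, z_mid > 0, z_mid < h_half,
            length(water_zone) == 2, water_zone[1] < water_zone[2],
            water_zone[1] >= h_half)
  structure(list(h_half = h_half, z_mid = z_mid,
                 water_zone = as.numeric(water_zone)),
            class = "membrane_geometry")
}

#' Free-energy profile F(z)
#'
#' @param z bin centers in Angstrom (uniform spacing).
#' @param F free energy in kcal/mol; `Inf` marks never-visited bins.
#' @param F_ref reference (water-phase) value in kcal/mol.
#' @param temperature temperature in K.
#' @param se optional per-bin standard errors.
#' @param method provenance tag.
#' @return object of class `free_energy_profile`.
#' @export
free_energy_profile <- function(z, F, F_ref, temperature, se = NULL,
                                method = "histogram") {
  stopifnot(length(z) == length(F), is.finite(F_ref), temperature > 0)
  if (length(z) > 2) {
    dz <- diff(z)
    if (max(dz) - min(dz) > 1e-6 * max(dz)) stop("non-uniform bin width")
  }
  structure(list(z = as.numeric(z), F = as.numeric(F),
                 F_ref = as.numeric(F_ref),
                 temperature = as.numeric(temperature),
                 se = if (is.null(se)) rep(NA_real_, length(z)) else se,
                 method = method),
            class = "free_energy_profile")
}

#' Position-dependent diffusion profiles
#'
#' @param z bin centers (Angstrom), same grid as the free-energy profile.
#' @param D_perp,D_par diffusion normal/parallel to the membrane, A^2/ps.
#' @param se_perp,se_par optional per-bin uncertainties.
#' @param lags lag times (ps) the profiles were derived from.
#' @return object of class `diffusion_profiles`.
#' @export
diffusion_profiles <- function(z, D_perp, D_par = NULL, se_perp = NULL,
                               se_par = NULL, lags = NULL) {
  stopifnot(length(z) == length(D_perp), all(D_perp > 0))
  if (!is.null(D_par)) stopifnot(length(D_par) == length(z), all(D_par > 0))
  structure(list(z = as.numeric(z), D_perp = as.numeric(D_perp),
                 D_par = if (is.null(D_par)) NULL else as.numeric(D_par),
                 se_perp = se_perp, se_par = se_par, lags = lags),
            class = "diffusion_profiles")
}

## ---------------------------------------------------------------------------
## Permeant trajectory TSV
##
## header lines:  #box Lx Ly H   /  #temperature T  /  #dt_ps dt
## data columns:  frame time_ps permeant_id permeant_type x y z

#' Write permeant trajectories to the tabular format
#'
#' @param trajs a `permeant_trajectory` or list of them (shared box and
#'   temperature).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_permeant_trajectory <- function(trajs, path) {
  if (inherits(trajs, "permeant_trajectory")) trajs <- list(trajs)
  box <- trajs[[1]]$box
  temp <- trajs[[1]]$temperature
  dt <- if (length(trajs[[1]]$t) > 1) trajs[[1]]$t[2] - trajs[[1]]$t[1] else 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#box\t%.10g\t%.10g\t%.10g", box[1], box[2], box[3]),
               sprintf("#temperature\t%.10g", temp),
               sprintf("#dt_ps\t%.10g", dt),
               paste("frame", "time_ps", "permeant_id", "permeant_type",
                     "x", "y", "z", sep = "\t")), con)
  for (tr in trajs) {
    df <- data.frame(frame = seq_along(tr$t) - 1L, time_ps = tr$t,
                     permeant_id = tr$id, permeant_type = tr$type,
                     x = tr$x, y = tr$y, z = tr$z)
    write.table(format(df, digits = 12, scientific = FALSE, trim = TRUE),
                con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

parse_header <- function(lines, key, path) {
  hit <- grep(paste0("^#", key, "\\b"), lines)
  if (length(hit) == 0)
    stop(sprintf("%s: missing header key '#%s'", path, key))
  as.numeric(strsplit(trimws(sub(paste0("^#", key), "", lines[hit[1]])),
                      "[ \t]+")[[1]])
}

#' Load permeant trajectories from the tabular format
#'
#' One trajectory per `permeant_id`; frames are time-sorted.  Malformed rows,
#' missing header keys, and duplicated time stamps raise errors naming the
#' offending line.
#'
#' @param path input file written by [write_permeant_trajectory()] or an
#'   external adapter.
#' @return list of `permeant_trajectory` objects.
#' @export
load_permeant_trajectory <- function(path) {
  lines <- readLines(path)
  box <- parse_header(lines, "box", path)
  if (length(box) != 3) stop(sprintf("%s: '#box' needs Lx Ly H", path))
  temp <- parse_header(lines, "temperature", path)[1]
  is_data <- !grepl("^#", lines) & nzchar(trimws(lines)) &
    !grepl("^frame\\b", lines)
  rows <- which(is_data)
  if (length(rows) == 0) stop(sprintf("%s: no data rows", path))
  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 7)
  if (length(bad))
    stop(sprintf("%s: malformed row at line %d (expected 7 fields)",
                 path, rows[bad[1]]))
  m <- matrix(unlist(fields), ncol = 7, byrow = TRUE)
  t_ps <- as.numeric(m[, 2])
  xyz <- matrix(as.numeric(m[, 5:7]), ncol = 3)
  if (anyNA(t_ps) || anyNA(xyz)) {
    bad <- which(is.na(t_ps) | is.na(xyz[, 1]) | is.na(xyz[, 2]) |
                   is.na(xyz[, 3]))[1]
    stop(sprintf("%s: non-numeric value at line %d", path, rows[bad]))
  }
  ids <- m[, 3]
  out <- list()
  for (id in unique(ids)) {
    sel <- which(ids == id)
    o <- order(t_ps[sel])
    sel <- sel[o]
    ti <- t_ps[sel]
    if (anyDuplicated(ti)) {
      d <- which(duplicated(ti))[1]
      stop(sprintf("%s: duplicated timestamp %.6g for permeant '%s' at line %d",
                   path, ti[d], id, rows[sel[d]]))
    }
    out[[id]] <- permeant_trajectory(id, m[sel[1], 4], ti,
                                     xyz[sel, 1], xyz[sel, 2], xyz[sel, 3],
                                     box, temp)
  }
  out
}

#' Re-center a trajectory on the membrane midplane and wrap z
#'
#' Subtracts a per-frame midplane offset (e.g. the membrane center of mass)
#' from z and wraps the result into `[-H/2, H/2)`.  Lateral coordinates are
#' untouched; wrapping is idempotent.
#'
#' @param traj a `permeant_trajectory`.
#' @param offsets midplane offset per frame in Angstrom; a scalar is recycled.
#' @return the re-centered `permeant_trajectory` with `centered = TRUE`.
#' @export
recenter_and_wrap <- function(traj, offsets = 0) {
  stopifnot(inherits(traj, "permeant_trajectory"), all(is.finite(offsets)))
  n <- length(traj$t)
  if (length(offsets) == 1) offsets <- rep(offsets, n)
  if (length(offsets) != n)
    stop(sprintf("offsets length %d != %d frames", length(offsets), n))
  traj$z <- wrap_centered(traj$z - offsets, traj$box[3])
  traj$centered <- TRUE
  traj
}

## ---------------------------------------------------------------------------
## Chain TSV:  #box header; columns frame chain_id lipid_type atom_idx x y z

#' One frame of lipid-chain carbon coordinates
#'
#' @param frame frame index (integer).
#' @param chains named list: each element has `chain_id`, `lipid_type`, and
#'   an n x 3 `xyz` coordinate matrix (Angstrom).
#' @param box `(Lx, Ly, H)`.
#' @return object of class `chain_frame`.
#' @export
chain_frame <- function(frame, chains, box) {
  types <- vapply(chains, `[[`, "", "lipid_type")
  ids <- vapply(chains, `[[`, "", "chain_id")
  if (anyDuplicated(ids)) stop("duplicated chain_id within a frame")
  for (ch in chains)
    if (!is.matrix(ch$xyz) || ncol(ch$xyz) != 3 || nrow(ch$xyz) < 1)
      stop(sprintf("chain '%s' needs an n x 3 coordinate matrix", ch$chain_id))
  structure(list(frame = as.integer(frame), chains = chains,
                 box = as.numeric(box)),
            class = "chain_frame")
}

#' Write chain frames to the tabular format
#' @param frames list of `chain_frame` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chain_frames <- function(frames, path) {
  if (inherits(frames, "chain_frame")) frames <- list(frames)
  box <- frames[[1]]$box
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#box\t%.10g\t%.10g\t%.10g", box[1], box[2], box[3]),
               paste("frame", "chain_id", "lipid_type", "atom_idx",
                     "x", "y", "z", sep = "\t")), con)
  for (fr in frames) for (ch in fr$chains) {
    df <- data.frame(frame = fr$frame, chain_id = ch$chain_id,
                     lipid_type = ch$lipid_type,
                     atom_idx = seq_len(nrow(ch$xyz)) - 1L,
                     x = ch$xyz[, 1], y = ch$xyz[, 2], z = ch$xyz[, 3])
    write.table(format(df, digits = 12, scientific = FALSE, trim = TRUE),
                con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Load chain frames from the tabular format
#'
#' Validates that every `chain_id` maps to exactly one `lipid_type` across
#' the whole file.
#'
#' @param path input file.
#' @return list of `chain_frame` objects keyed by frame index.
#' @export
load_chain_frames <- function(path) {
  lines <- readLines(path)
  box <- parse_header(lines, "box", path)
  rows <- which(!grepl("^#", lines) & nzchar(trimws(lines)) &
                  !grepl("^frame\\b", lines))
  if (length(rows) == 0) stop(sprintf("%s: no data rows", path))
  df <- read.table(text = lines[rows], sep = "\t",
                   col.names = c("frame", "chain_id", "lipid_type",
                                 "atom_idx", "x", "y", "z"),
                   colClasses = c("integer", "character", "character",
                                  "integer", "numeric", "numeric", "numeric"))
  tmap <- unique(df[, c("chain_id", "lipid_type")])
  dup <- tmap$chain_id[duplicated(tmap$chain_id)]
  if (length(dup))
    stop(sprintf("%s: chain '%s' listed with conflicting lipid types",
                 path, dup[1]))
  out <- list()
  for (f in sort(unique(df$frame))) {
    sub <- df[df$frame == f, ]
    chains <- lapply(split(sub, sub$chain_id), function(s) {
      s <- s[order(s$atom_idx), ]
      list(chain_id = s$chain_id[1], lipid_type = s$lipid_type[1],
           xyz = as.matrix(s[, c("x", "y", "z")]))
    })
    names(chains) <- vapply(chains, `[[`, "", "chain_id")
    out[[as.character(f)]] <- chain_frame(f, chains, box)
  }
  out
}

## ---------------------------------------------------------------------------
## Profile TSV: columns z_A value stderr (+ optional second value column)

#' Write a free-energy or diffusion profile as TSV
#'
#' Free-energy profiles are written as `z_A F_kcal_mol stderr` with `Inf`
#' as the sentinel token for never-visited bins; diffusion profiles as
#' `z_A D_perp_A2_ps D_par_A2_ps`.  Header lines record units, temperature
#' and provenance.
#'
#' @param profile a `free_energy_profile` or `diffusion_profiles` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(profile, "free_energy_profile")) {
    writeLines(c("#units\tz:A\tF:kcal/mol",
                 sprintf("#temperature\t%.10g", profile$temperature),
                 sprintf("#F_ref\t%.10g", profile$F_ref),
                 sprintf("#method\t%s", profile$method),
                 "z_A\tvalue\tstderr"), con)
    df <- data.frame(z = profile$z, value = profile$F, stderr = profile$se)
  } else if (inherits(profile, "diffusion_profiles")) {
    writeLines(c("#units\tz:A\tD:A^2/ps",
                 sprintf("#lags_ps\t%s",
                         paste(profile$lags, collapse = "\t")),
                 "z_A\tvalue\tstderr"), con)
    df <- data.frame(z = profile$z, value = profile$D_perp,
                     stderr = if (is.null(profile$D_par)) NA
                              else profile$D_par)
  } else stop("unsupported profile class")
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read back a profile TSV written by [write_profile_table()]
#'
#' @param path input file.
#' @return a `free_energy_profile` or `diffusion_profiles` object, keyed on
#'   the unit header.
#' @export
read_profile_table <- function(path) {
  lines <- readLines(path)
  rows <- which(!grepl("^#", lines) & nzchar(trimws(lines)) &
                  !grepl("^z_A\\b", lines))
  df <- read.table(text = lines[rows], sep = "\t",
                   col.names = c("z", "value", "stderr"))
  if (any(grepl("F:kcal/mol", lines, fixed = TRUE))) {
    free_energy_profile(df$z, df$value,
                        F_ref = parse_header(lines, "F_ref", path)[1],
                        temperature = parse_header(lines, "temperature",
                                                   path)[1],
                        se = df$stderr,
                        method = sub("^#method\t", "",
                                     grep("^#method", lines, value = TRUE)[1]))
  } else {
    lag_line <- grep("^#lags_ps", lines, value = TRUE)
    lags <- if (length(lag_line)) suppressWarnings(
      as.numeric(strsplit(lag_line, "\t")[[1]][-1])) else NULL
    diffusion_profiles(df$z, df$value,
                       D_par = if (all(is.na(df$stderr))) NULL else df$stderr,
                       lags = lags[is.finite(lags)])
  }
}
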