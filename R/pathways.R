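## Three-nearest-neighbor classification of permeant surroundings.
##
## The distance between a permeant and a lipid chain is the minimum over
## (permeant heavy atom, chain carbon) pairs under the lateral periodic
## minimum image.  The three closest chains define the class: "3-<type>"
## when all three share a lipid type, otherwise "Mix".

#' Assign the three nearest lipid chains and the neighbor class
#'
#' Ties at the third neighbor are broken deterministically by
#' (distance, chain_id) order.
#'
#' @param permeant n x 3 matrix of heavy-atom coordinates (a bare length-3
#'   vector is treated as a single point permeant).
#' @param frame a `chain_frame` with >= 3 chains.
#' @return list with `chain_ids` (3), `types` (3), `distances` (3), and the
#'   `class` label.
#' @export
assign_three_nearest <- function(permeant, frame) {
  stopifnot(inherits(frame, "chain_frame"))
  if (is.null(dim(permeant))) permeant <- matrix(permeant, ncol = 3)
  if (length(frame$chains) < 3) stop("need at least 3 chains")
  Lx <- frame$box[1]; Ly <- frame$box[2]
  d <- vapply(frame$chains, function(ch) {
    dx <- outer(permeant[, 1], ch$xyz[, 1], "-")
    dy <- outer(permeant[, 2], ch$xyz[, 2], "-")
    dzv <- outer(permeant[, 3], ch$xyz[, 3], "-")
    dx <- dx - Lx * round(dx / Lx)
    dy <- dy - Ly * round(dy / Ly)
    min(sqrt(dx^2 + dy^2 + dzv^2))
  }, 0)
  ids <- unname(vapply(frame$chains, `[[`, "", "chain_id"))
  d <- unname(d)
  o <- order(d, ids)[1:3]
  types <- unname(vapply(frame$chains[o], `[[`, "", "lipid_type"))
  cls <- if (length(unique(types)) == 1) paste0("3-", types[1]) else "Mix"
  list(chain_ids = ids[o], types = types, distances = d[o], class = cls)
}

#' Depth-resolved neighbor-class probabilities
#'
#' For every permeant sample in every shared frame, the three-nearest-chain
#' class is assigned and accumulated into z-slabs; per-slab class
#' frequencies are normalized to sum to 1 (samples pooled over frames).
#'
#' @param trajs list of `permeant_trajectory` objects (points; frame index
#'   f corresponds to the (f+1)-th saved frame).
#' @param chain_frames list of `chain_frame` objects keyed by frame index
#'   (as returned by [load_chain_frames()] / [generate_toy_membrane()]).
#' @param slab_width z-slab width in Angstrom (default 1).
#' @return data.frame of class `neighbor_profile`: slab center `z`, one
#'   probability column per class (`p_3_<type>`, `p_Mix`), and the sample
#'   count `n`.  Empty slabs are omitted.
#' @export
neighbor_profile <- function(trajs, chain_frames, slab_width = 1) {
  if (inherits(trajs, "permeant_trajectory")) trajs <- list(trajs)
  if (inherits(chain_frames, "chain_frame"))
    chain_frames <- list(`0` = chain_frames)
  frame_ids <- as.integer(names(chain_frames))
  types <- sort(unique(unlist(lapply(chain_frames, function(fr)
    vapply(fr$chains, `[[`, "", "lipid_type")))))
  classes <- c(paste0("3-", types), "Mix")
  samples_z <- numeric(0); samples_c <- character(0)
  for (tr in trajs) {
    use <- which((seq_along(tr$t) - 1L) %in% frame_ids)
    for (i in use) {
      fr <- chain_frames[[as.character(i - 1L)]]
      a <- assign_three_nearest(c(tr$x[i], tr$y[i], tr$z[i]), fr)
      samples_z <- c(samples_z, tr$z[i])
      samples_c <- c(samples_c, a$class)
    }
  }
  if (length(samples_z) == 0) stop("no shared frames between inputs")
  slab <- floor(samples_z / slab_width)
  tab <- table(slab, factor(samples_c, levels = classes))
  z <- (as.numeric(rownames(tab)) + 0.5) * slab_width
  p <- sweep(unclass(tab), 1, rowSums(tab), "/")
  out <- data.frame(z = z, p, n = as.integer(rowSums(tab)),
                    check.names = FALSE)
  names(out) <- c("z", paste0("p_", classes), "n")
  out <- out[order(out$z), ]
  rownames(out) <- NULL
  class(out) <- c("neighbor_profile", class(out))
  out
}
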