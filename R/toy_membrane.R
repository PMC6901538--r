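## Toy microdomain membrane: one leaflet of vertical lipid-chain columns on
## a triangular (hexagonally packed) lattice.  Ordered-chain microdomains
## (one lipid type) are surrounded by boundary "channels" of the remaining
## types -- the substructure that carries permeation in ordered phases.

#' Toy microdomain membrane specification
#'
#' Sites of an `nx` x `ny` triangular lattice (lattice constant `a`) are
#' assigned the `domain_type` when they lie within `domain_radius` (periodic
#' lateral distance) of a domain center, otherwise a type drawn from
#' `channel_types`.  Each site carries one vertical chain of carbons.
#'
#' @param a lattice constant, Angstrom.
#' @param nx,ny lattice dimensions (ny should be even for periodicity).
#' @param domain_centers m x 2 matrix of lateral domain centers; default is
#'   one centered domain.
#' @param domain_radius microdomain radius, Angstrom.
#' @param domain_type lipid type of the ordered microdomain (default "sat").
#' @param channel_types types filling the boundary channels (default
#'   `c("unsat", "sterol")`, assigned randomly per site).
#' @param chain_span z-interval `(zmin, zmax)` covered by the chain carbons.
#' @param carbon_spacing carbon spacing along z, Angstrom.
#' @param seed RNG seed for the channel-type assignment.
#' @return object of class `toy_membrane_spec`.
#' @export
toy_membrane_spec <- function(a = 5, nx = 12, ny = 12, domain_centers = NULL,
                              domain_radius = 14, domain_type = "sat",
                              channel_types = c("unsat", "sterol"),
                              chain_span = c(4, 20), carbon_spacing = 1,
                              seed = 1) {
  stopifnot(a > 0, nx >= 3, ny >= 2, domain_radius > 0,
            chain_span[1] < chain_span[2])
  Lx <- nx * a
  Ly <- ny * a * sqrt(3) / 2
  if (is.null(domain_centers))
    domain_centers <- matrix(c(Lx / 2, Ly / 2), ncol = 2)
  structure(list(a = a, nx = nx, ny = ny, Lx = Lx, Ly = Ly,
                 domain_centers = domain_centers,
                 domain_radius = domain_radius, domain_type = domain_type,
                 channel_types = channel_types, chain_span = chain_span,
                 carbon_spacing = carbon_spacing, seed = as.integer(seed)),
            class = "toy_membrane_spec")
}

toy_lattice_sites <- function(spec) {
  ij <- expand.grid(i = 0:(spec$nx - 1), j = 0:(spec$ny - 1))
  x <- (ij$i + 0.5 * (ij$j %% 2)) * spec$a
  y <- ij$j * spec$a * sqrt(3) / 2
  dmin <- rep(Inf, length(x))
  for (m in seq_len(nrow(spec$domain_centers))) {
    dx <- x - spec$domain_centers[m, 1]
    dy <- y - spec$domain_centers[m, 2]
    dx <- dx - spec$Lx * round(dx / spec$Lx)
    dy <- dy - spec$Ly * round(dy / spec$Ly)
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  data.frame(x = x, y = y, in_domain = dmin <= spec$domain_radius)
}

#' Generate a toy microdomain membrane and permeants with known classes
#'
#' Chains are vertical carbon columns at the lattice sites.  Permeants are
#' points placed by `rule`: `"uniform"` draws lateral positions uniformly
#' over the box, `"channel-biased"` places them near randomly chosen
#' channel (non-domain) sites; z is uniform inside the chain span.  The
#' ground-truth class of each permeant -- from its three laterally nearest
#' lattice sites -- is recorded independently of the carbon-based
#' classifier.
#'
#' @param spec a `toy_membrane_spec`.
#' @param rule `"uniform"` or `"channel-biased"`.
#' @param n_permeants number of permeant points.
#' @param seed RNG seed for permeant placement.
#' @return list with `chain_frames` (one `chain_frame`, key "0"),
#'   `permeants` (list of single-frame `permeant_trajectory`), `truth`
#'   (data.frame `permeant_id`, `class`), `sites`, and `box`.
#' @export
generate_toy_membrane <- function(spec, rule = c("uniform", "channel-biased"),
                                  n_permeants = 100, seed = 2) {
  stopifnot(inherits(spec, "toy_membrane_spec"))
  rule <- match.arg(rule)
  sites <- toy_lattice_sites(spec)
  set.seed(spec$seed)
  sites$type <- ifelse(sites$in_domain, spec$domain_type,
                       sample(spec$channel_types, nrow(sites),
                              replace = TRUE))
  H <- 2 * (spec$chain_span[2] + 8)
  box <- c(spec$Lx, spec$Ly, H)
  zs <- seq(spec$chain_span[1], spec$chain_span[2],
            by = spec$carbon_spacing)
  chains <- lapply(seq_len(nrow(sites)), function(s)
    list(chain_id = sprintf("ch%04d", s), lipid_type = sites$type[s],
         xyz = cbind(rep(sites$x[s], length(zs)),
                     rep(sites$y[s], length(zs)), zs)))
  names(chains) <- vapply(chains, `[[`, "", "chain_id")
  cf <- chain_frame(0L, chains, box)

  channel_idx <- which(!sites$in_domain)
  if (rule == "channel-biased" && length(channel_idx) == 0)
    stop("channel-biased rule requires at least one channel site")
  set.seed(seed)
  if (rule == "uniform") {
    px <- runif(n_permeants, 0, spec$Lx)
    py <- runif(n_permeants, 0, spec$Ly)
  } else {
    pick <- sample(channel_idx, n_permeants, replace = TRUE)
    jit <- spec$a / 4
    px <- sites$x[pick] + runif(n_permeants, -jit, jit)
    py <- sites$y[pick] + runif(n_permeants, -jit, jit)
  }
  pz <- runif(n_permeants, spec$chain_span[1], spec$chain_span[2])

  # ground truth from the three laterally nearest lattice sites
  truth_class <- vapply(seq_len(n_permeants), function(p) {
    dx <- sites$x - px[p]; dy <- sites$y - py[p]
    dx <- dx - spec$Lx * round(dx / spec$Lx)
    dy <- dy - spec$Ly * round(dy / spec$Ly)
    tt <- sites$type[order(dx^2 + dy^2)[1:3]]
    if (length(unique(tt)) == 1) paste0("3-", tt[1]) else "Mix"
  }, "")

  perms <- lapply(seq_len(n_permeants), function(p)
    permeant_trajectory(sprintf("perm%04d", p), "point", 0,
                        px[p], py[p], pz[p], box, 298))
  list(chain_frames = list(`0` = cf), permeants = perms,
       truth = data.frame(permeant_id = sprintf("perm%04d",
                                                seq_len(n_permeants)),
                          class = truth_class, stringsAsFactors = FALSE),
       sites = sites, box = box)
}
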