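#' Force-field parameter set
#'
#' Bead-spring worm-like-chain parameters in reduced Lennard-Jones units.
#' Bonded beads interact through a FENE spring plus the WCA repulsion; the
#' bending stiffness enters as `b * kT * (1 - cos of the bond-vector angle)`
#' per interior joint, equivalently `(B/l)(1 + cos theta)` with the valence
#' angle `theta` and bending modulus `B = b * l * kT`.
#'
#' @param b dimensionless stiffness (0 = fully flexible, 20 = semiflexible).
#' @param epsilon,sigma Lennard-Jones energy and length units (both 1).
#' @param kappa FENE spring constant (30 epsilon/sigma^2).
#' @param R_o maximal FENE bond extension (1.5 sigma).
#' @param w effective bead width entering the geometry mapping
#'   `d_p = D_p + w` (default 0.9).
#' @param l nominal effective bond length of the equilibrated FENE + WCA
#'   bond (0.97 sigma), used for the bending modulus `B = b * l * kT`.
#' @return object of class `forcefield`.
#' @export
forcefield <- function(b = 0, epsilon = 1, sigma = 1, kappa = 30,
                       R_o = 1.5, w = 0.9, l = 0.97) {
  stopifnot(b >= 0, epsilon > 0, sigma > 0, kappa > 0, R_o > sigma)
  structure(list(b = b, epsilon = epsilon, sigma = sigma, kappa = kappa,
                 R_o = R_o, w = w, l = l,
                 B = b * l * epsilon,
                 r_c = 2^(1 / 6) * sigma),
            class = "forcefield")
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf(
    "forcefield: b = %g (B = %g), kappa = %g, R_o = %g, eps = %g, sigma = %g\n",
    x$b, x$B, x$kappa, x$R_o, x$epsilon, x$sigma))
  invisible(x)
}

#' WCA bead-bead pair energy
#'
#' Purely repulsive, cut-and-shifted Lennard-Jones potential:
#' `4 eps [(sigma/r)^12 - (sigma/r)^6] + eps` for `r < 2^(1/6) sigma`, zero
#' beyond the cutoff.
#'
#' @param r centre-centre distance(s), > 0.
#' @param epsilon,sigma Lennard-Jones parameters.
#' @return energy (epsilon units), vectorised over `r`.
#' @export
wca_bead_bead <- function(r, epsilon = 1, sigma = 1) {
  if (any(r <= 0)) stop("r must be positive")
  sr6 <- (sigma / r)^6
  ifelse(r < 2^(1 / 6) * sigma, 4 * epsilon * (sr6^2 - sr6) + epsilon, 0)
}

#' WCA bead-post pair energy
#'
#' The bead-bead WCA repulsion applied to the distance from the post
#' *surface*, i.e. to `r - D_p/2` where `r` is the distance from the post
#' centre line and `D_p` the bare post diameter.
#'
#' @param r distance from the post centre line.
#' @param D_p bare post diameter.
#' @inheritParams wca_bead_bead
#' @export
wca_bead_post <- function(r, D_p, epsilon = 1, sigma = 1) {
  if (any(r <= D_p / 2))
    stop("bead inside the post core (r <= D_p/2): broken configuration")
  wca_bead_bead(r - D_p / 2, epsilon = epsilon, sigma = sigma)
}

#' FENE bond energy
#'
#' `-(kappa/2) R_o^2 log(1 - (l/R_o)^2)`, diverging at the maximal bond
#' length `R_o`. The full bonded interaction of the model is FENE plus the
#' WCA pair term.
#'
#' @param l_ij bond length(s) in `[0, R_o)`.
#' @param kappa spring constant; `R_o` maximal extension.
#' @param R_o maximal bond length.
#' @export
fene_bond <- function(l_ij, kappa = 30, R_o = 1.5) {
  if (any(l_ij < 0)) stop("bond length must be non-negative")
  if (any(l_ij >= R_o)) stop("bond overstretched: l_ij >= R_o")
  -(kappa / 2) * R_o^2 * log1p(-(l_ij / R_o)^2)
}

#' Bending energy of one joint
#'
#' `(B/l)(1 + cos theta) = b kT (1 - u_i . u_{i+1})` where `theta` is the
#' valence angle between consecutive bonds (the complement of the
#' bond-vector angle); a straight chain (`theta = pi`) costs nothing.
#'
#' @param theta valence angle(s) in `[0, pi]`.
#' @param b dimensionless stiffness; `kT` thermal energy (1).
#' @param kT thermal energy unit.
#' @export
bending_energy <- function(theta, b = 20, kT = 1) {
  if (any(theta < -1e-12 | theta > pi + 1e-12))
    stop("theta must lie in [0, pi]")
  b * kT * (1 + cos(theta))
}

#' Total energy and forces of a chain configuration
#'
#' Sums the four contributions -- FENE bonds, bending, bead-bead WCA over
#' all pairs (bonded neighbours included once), and bead-post WCA when an
#' array is present -- and returns the exact analytic forces (negative
#' gradients). Circular topology closes the bond ring and wraps the bending
#' terms. Bead-post forces act strictly in the yz-plane.
#'
#' @param chain a [chain_state] (or bare N x 3 position matrix, assumed
#'   linear).
#' @param ff a [forcefield].
#' @param array a [post_array] or `NULL` for a free chain.
#' @return list with `total`, `bond`, `bend`, `pair`, `post` energies and
#'   an N x 3 `forces` matrix.
#' @export
chain_energy <- function(chain, ff = forcefield(), array = NULL) {
  if (is.matrix(chain)) chain <- chain_state(chain, topology = "linear")
  has_array <- !is.null(array)
  np_energy_forces(chain$positions, chain$topology == "circular",
                   ff$epsilon, ff$sigma, ff$kappa, ff$R_o,
                   ff$b * ff$epsilon,
                   has_array,
                   if (has_array) array$S_p else 0,
                   if (has_array) array$D_p else 0,
                   if (has_array) array$origin[1] else 0,
                   if (has_array) array$origin[2] else 0)
}
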