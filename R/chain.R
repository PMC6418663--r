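#' Chain state
#'
#' A configuration of the bead-spring chain: bead positions, topology and
#' optional velocities. Circular chains have N bonds (the last bead bonds
#' back to the first), linear chains N - 1.
#'
#' @param positions N x 3 numeric matrix of bead coordinates (sigma units).
#' @param topology `"linear"` or `"circular"`.
#' @param velocities optional N x 3 matrix.
#' @return object of class `chain_state` with fields `positions`,
#'   `topology`, `velocities`, `N`.
#' @export
chain_state <- function(positions, topology = c("linear", "circular"),
                        velocities = NULL) {
  topology <- match.arg(topology)
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) >= 2,
            all(is.finite(positions)))
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    stopifnot(identical(dim(velocities), dim(positions)))
  }
  structure(list(positions = positions, topology = topology,
                 velocities = velocities, N = nrow(positions)),
            class = "chain_state")
}

#' @export
print.chain_state <- function(x, ...) {
  cat(sprintf("chain_state: %s, N = %d beads\n", x$topology, x$N))
  invisible(x)
}

#' Contour length of a chain
#'
#' `(N - 1) * l` for linear, `N * l` for circular topology, with `l` the
#' nominal bond length.
#'
#' @param chain a [chain_state], or an integer bead count.
#' @param topology used when `chain` is a bead count.
#' @param l nominal bond length.
#' @export
contour_length <- function(chain, topology = "linear", l = 0.97) {
  if (inherits(chain, "chain_state")) {
    N <- chain$N
    topology <- chain$topology
  } else {
    N <- as.integer(chain)
  }
  if (topology == "circular") N * l else (N - 1) * l
}

#' Build an initial chain conformation
#'
#' Linear chains start as a completely straightened backbone at the nominal
#' bond length; circular chains as a completely prolonged rectangular loop,
#' two parallel strands of length about L/2 separated by one bond length
#' and closed at both ends (even N required). With an array, the chain is
#' centred on an interstitial cell with its principal axis parallel to the
#' post axes (`orientation = "parallel"`, along x) or perpendicular to them
#' (`"perpendicular"`, along y, threading passage apertures); building
#' fails if any bead would start within the WCA interaction range of a
#' post surface, so initial conformations carry no bead-post energy.
#'
#' @param N bead count (>= 3; even for circular topology).
#' @param topology `"linear"` or `"circular"`.
#' @param l bond length (0.97).
#' @param orientation principal-axis orientation relative to the posts.
#' @param array optional [post_array] for in-array placement.
#' @param cell interstitial cell (i, j) on which to centre the chain.
#' @return a [chain_state].
#' @export
build_chain <- function(N, topology = c("linear", "circular"), l = 0.97,
                        orientation = c("parallel", "perpendicular"),
                        array = NULL, cell = c(0, 0)) {
  topology <- match.arg(topology)
  orientation <- match.arg(orientation)
  if (N < 3) stop("N must be at least 3")
  if (topology == "circular" && N %% 2 != 0)
    stop("circular chains require an even bead count for the rectangular loop")

  if (topology == "linear") {
    s <- (seq_len(N) - 1) * l
    s <- s - mean(s)
    pos <- cbind(s, 0, 0)
  } else {
    n <- N / 2
    xs <- (seq_len(n) - 1) * l
    xs <- xs - mean(xs)
    pos <- rbind(cbind(xs, -l / 2, 0),
                 cbind(rev(xs), l / 2, 0))
  }
  colnames(pos) <- NULL

  if (orientation == "perpendicular") {
    # principal axis x -> y
    pos <- pos[, c(2, 1, 3), drop = FALSE]
    pos[, 1] <- -pos[, 1]
  }

  if (!is.null(array)) {
    cc <- cell_center(cell, array)
    pos[, 2] <- pos[, 2] + cc[1, 1]
    pos[, 3] <- pos[, 3] + cc[1, 2]
    # zero initial bead-post interaction: surface clearance beyond the
    # WCA cutoff
    margin <- 2^(1 / 6)
    clearance <- vapply(seq_len(nrow(pos)), function(i) {
      min(nearest_posts(pos[i, 2:3], array, brute = TRUE)$r) - array$D_p / 2
    }, numeric(1))
    if (any(clearance < margin))
      stop(sprintf(
        paste0("placement error: %d bead(s) closer than %.2f sigma to a ",
               "post surface; try orientation = \"parallel\" or a wider array"),
        sum(clearance < margin), margin))
  }
  chain_state(pos, topology)
}

#' Maxwell-Boltzmann velocities
#'
#' Draws bead velocities at temperature `T`, removes the centre-of-mass
#' drift and rescales exactly to the target kinetic temperature. Uses R's
#' RNG stream (seed it with [set.seed()] for reproducibility).
#'
#' @param N bead count.
#' @param temperature target temperature (epsilon/k_B units).
#' @return N x 3 velocity matrix.
#' @export
maxwell_velocities <- function(N, temperature = 1) {
  v <- matrix(stats::rnorm(3 * N, sd = sqrt(temperature)), ncol = 3)
  v <- sweep(v, 2, colMeans(v))
  ke <- 0.5 * sum(v^2)
  v * sqrt(1.5 * N * temperature / ke)
}
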