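#' Deterministic conformation fixtures
#'
#' Generates synthetic chain conformations with known analytic properties,
#' so every analysis routine can be exercised without running dynamics:
#'
#' * `rod`: straight chain of `N` beads at bond length `l` along `axis`.
#' * `rectangle_ring`: prolonged rectangular loop (two strands of length
#'   about L/2 separated by `l`), the initial ring conformation.
#' * `regular_polygon_ring`: planar regular N-gon with side `l`; its bond
#'   correlations are exactly `cos(2 pi n_s / N)`.
#' * `ideal_wlc`: ideal (no excluded volume) discrete worm-like chain whose
#'   bond angles are drawn from `p(cos theta) ~ exp(k cos theta)`; pass
#'   either the stiffness `b` (then `k = b`) or a target persistence length
#'   `P`, in which case `k` is solved so that
#'   `<cos theta> = exp(-l / P)` exactly and the tangent correlations decay
#'   as `exp(-n_s l / P)` in expectation.
#' * `planted_cells`: beads at the centres of the given interstitial cells
#'   of `array` (occupation number equals the number of distinct cells).
#' * `two_bead`: two beads at distance `r` (closed-form structure factor
#'   `(1 + sinc(q r)) / 2`).
#'
#' @param kind fixture kind (see above).
#' @param N bead count (where applicable).
#' @param l bond length.
#' @param seed integer seed (used by `ideal_wlc`); the result is
#'   deterministic given the seed.
#' @param b,P stiffness or target persistence length for `ideal_wlc`.
#' @param axis axis (1, 2 or 3) for `rod`.
#' @param cells integer matrix / 2-column data.frame of cell indices for
#'   `planted_cells`.
#' @param array [post_array] for `planted_cells`.
#' @param r bead separation for `two_bead`.
#' @param n_frames for `ideal_wlc`, number of independent conformations;
#'   when > 1 a list of frames is returned.
#' @return a [chain_state] (or list of frames for `ideal_wlc` with
#'   `n_frames > 1`).
#' @export
generate_fixture <- function(kind = c("rod", "rectangle_ring",
                                      "regular_polygon_ring", "ideal_wlc",
                                      "planted_cells", "two_bead"),
                             N = 100, l = 0.97, seed = 1,
                             b = NULL, P = NULL, axis = 1,
                             cells = NULL, array = NULL, r = 1,
                             n_frames = 1) {
  kind <- match.arg(kind)
  switch(kind,
    rod = {
      s <- (seq_len(N) - 1) * l
      pos <- matrix(0, N, 3)
      pos[, axis] <- s
      chain_state(pos, "linear")
    },
    rectangle_ring = build_chain(N, "circular", l = l),
    regular_polygon_ring = {
      R <- l / (2 * sin(pi / N))
      th <- 2 * pi * (seq_len(N) - 1) / N
      chain_state(cbind(R * cos(th), R * sin(th), 0), "circular")
    },
    ideal_wlc = {
      if (is.null(b) && is.null(P)) stop("ideal_wlc needs b or P")
      k <- if (!is.null(b)) b else wlc_kappa_for_P(P, l)
      set.seed(seed)
      frames <- lapply(seq_len(n_frames), function(dummy) ideal_wlc_frame(N, l, k))
      if (n_frames == 1) chain_state(frames[[1]], "linear") else frames
    },
    planted_cells = {
      if (is.null(cells) || is.null(array))
        stop("planted_cells needs cells and array")
      cells <- as.matrix(cells)
      cc <- cell_center(cells, array)
      pos <- cbind(0.1 * (seq_len(nrow(cells)) - 1), cc[, 1], cc[, 2])
      chain_state(pos, "linear")
    },
    two_bead = chain_state(rbind(c(0, 0, 0), c(r, 0, 0)), "linear")
  )
}

# <cos theta> of p(c) ~ exp(k c) on [-1, 1] is the Langevin function
# coth(k) - 1/k; solve for k giving a target tangent-correlation decay.
wlc_kappa_for_P <- function(P, l) {
  target <- exp(-l / P)
  langevin <- function(k) 1 / tanh(k) - 1 / k
  uniroot(function(k) langevin(k) - target, c(1e-6, 1e4), tol = 1e-12)$root
}

# One ideal WLC conformation: successive bond directions tilted by angles
# with cos theta ~ exp(k cos theta) (inverse-CDF sampling), uniform azimuth.
ideal_wlc_frame <- function(N, l, k) {
  nb <- N - 1
  u <- matrix(0, nb, 3)
  u[1, ] <- c(1, 0, 0)
  cth <- 1 + log(runif(nb - 1) * (1 - exp(-2 * k)) + exp(-2 * k)) / k
  phi <- runif(nb - 1, 0, 2 * pi)
  for (i in seq_len(nb - 1)) {
    u[i + 1, ] <- rotate_about(u[i, ], cth[i], phi[i])
  }
  pos <- rbind(c(0, 0, 0), apply(u * l, 2, cumsum))
  pos
}

# New unit vector at angle acos(cth) from u, azimuth phi about it.
rotate_about <- function(u, cth, phi) {
  # orthonormal frame around u
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  sth <- sqrt(max(0, 1 - cth^2))
  v <- cth * u + sth * (cos(phi) * e1 + sin(phi) * e2)
  v / sqrt(sum(v^2))
}
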