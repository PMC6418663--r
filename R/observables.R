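#' Chain span along the post axes
#'
#' Per-frame extent `max(x_i) - min(x_i)` along the chosen axis (x, the
#' post direction, by default); the series mean is the mean span R_s. For a
#' strongly stretched linear chain the span approaches the end-to-end
#' distance, and unlike the end-to-end distance it is defined for rings.
#'
#' @param x a frame (N x 3 matrix), [chain_state], `np_traj` or list of
#'   frames.
#' @param axis coordinate index (1 = x).
#' @return numeric vector, one span per frame.
#' @export
span <- function(x, axis = 1) {
  vapply(as_frames(x), function(f) max(f[, axis]) - min(f[, axis]),
         numeric(1))
}

#' Gyration radius and its longitudinal/lateral components
#'
#' Per-frame gyration tensor diagonal: `R_gx` is the component along the
#' post axes and `R_gyz = sqrt((R_gy^2 + R_gz^2)/2)` the lateral component
#' (note the factor-1/2 average), so that `R_g^2 = R_gx^2 + 2 R_gyz^2`.
#'
#' @inheritParams span
#' @return data.frame with columns `R_g`, `R_gx`, `R_gy`, `R_gz`, `R_gyz`.
#' @export
gyration_components <- function(x) {
  out <- lapply(as_frames(x), function(f) {
    c2 <- colMeans(sweep(f, 2, colMeans(f))^2)
    data.frame(R_g = sqrt(sum(c2)), R_gx = sqrt(c2[1]),
               R_gy = sqrt(c2[2]), R_gz = sqrt(c2[3]),
               R_gyz = sqrt((c2[2] + c2[3]) / 2))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Interstitial occupation number
#'
#' Number of distinct interstitial cells containing at least one bead.
#' The yz-plane is partitioned into squares with vertices at the post
#' centres, so a bead sitting in a passage aperture counts toward the cell
#' it geometrically lies in.
#'
#' @inheritParams span
#' @param array a [post_array].
#' @return integer vector, one count per frame.
#' @export
occupation_number <- function(x, array) {
  vapply(as_frames(x), function(f) {
    ij <- cell_index(f[, 2:3, drop = FALSE], array)
    nrow(unique(ij))
  }, integer(1))
}

#' Single-chain structure factor
#'
#' Orientation-averaged Debye sum
#' `S(q) = (1/N^2) < sum_ij sin(q r_ij)/(q r_ij) >`, averaged over frames;
#' `S -> 1` as `q -> 0`. The direct O(N^2) double sum is the reference
#' path; `method = "histogram"` bins the pair distances first (bin width
#' `bin_width`) and agrees with the direct sum to within the bin-width
#' error.
#'
#' @inheritParams span
#' @param q wavevector grid; default logarithmic from `2 pi / (2 d_max)`
#'   (twice the largest pair distance) to `2 pi / (0.5 l)`, 200 points.
#' @param method `"direct"` or `"histogram"`.
#' @param bin_width histogram bin width (sigma).
#' @param l nominal bond length used for the default grid.
#' @param n_q grid size when `q` is NULL.
#' @return data.frame with columns `q`, `S`; attribute `N` carries the bead
#'   count.
#' @export
structure_factor <- function(x, q = NULL,
                             method = c("direct", "histogram"),
                             bin_width = 0.02, l = 0.97, n_q = 200) {
  method <- match.arg(method)
  frames <- as_frames(x)
  if (length(frames) == 0) stop("empty frame set")
  N <- nrow(frames[[1]])
  dists <- lapply(frames, function(f) as.vector(stats::dist(f)))
  if (is.null(q)) {
    dmax <- max(vapply(dists, max, numeric(1)))
    q <- exp(seq(log(2 * pi / (2 * dmax)), log(2 * pi / (0.5 * l)),
                 length.out = n_q))
  }
  if (any(q <= 0)) stop("q must be positive")

  S <- numeric(length(q))
  if (method == "direct") {
    for (d in dists) {
      for (k in seq_along(q)) S[k] <- S[k] + N + 2 * sum(sinc(q[k] * d))
    }
  } else {
    for (d in dists) {
      idx <- floor(d / bin_width) + 1L
      cnts <- tabulate(idx)
      mids <- (seq_along(cnts) - 0.5) * bin_width
      keep <- cnts > 0
      cnts <- cnts[keep]; mids <- mids[keep]
      for (k in seq_along(q)) {
        S[k] <- S[k] + N + 2 * sum(cnts * sinc(q[k] * mids))
      }
    }
  }
  out <- data.frame(q = q, S = S / (N^2 * length(frames)))
  attr(out, "N") <- N
  out
}

#' Local log-log slope of a structure factor
#'
#' Reporting utility for reading the scaling regimes off `S(q)`: central
#' finite-difference slope of `log S` versus `log q`, optionally smoothed
#' over `width` points.
#'
#' @param sf data.frame from [structure_factor()].
#' @param width half-width (in grid points) of the differencing stencil.
#' @return data.frame with columns `q`, `slope`.
#' @export
sq_local_slope <- function(sf, width = 3) {
  lq <- log(sf$q); lS <- log(sf$S)
  n <- length(lq)
  k <- seq(width + 1, n - width)
  slope <- (lS[k + width] - lS[k - width]) / (lq[k + width] - lq[k - width])
  data.frame(q = sf$q[k], slope = slope)
}

#' Tangent-tangent orientation correlations
#'
#' `C(n_s) = < u_i . u_{i+n_s} >` over all bond pairs separated by `n_s`
#' bonds and over all frames. For circular chains the bond index wraps, the
#' correlation is reported for `n_s = 0 .. N_bonds`, and it obeys the ring
#' inversion symmetry `C(n_s) = C(N_bonds - n_s)`.
#'
#' @inheritParams span
#' @param circular treat the chain as a ring (defaults to the trajectory's
#'   topology when `x` is an `np_traj` or `chain_state`).
#' @return data.frame with columns `n_s`, `C`.
#' @export
orientation_correlation <- function(x, circular = NULL) {
  if (is.null(circular)) {
    circular <- if (inherits(x, "np_traj")) x$chain$topology == "circular"
                else if (inherits(x, "chain_state")) x$topology == "circular"
                else FALSE
  }
  frames <- as_frames(x)
  nb <- nrow(bond_vectors(frames[[1]], circular))
  if (nb < 2) stop("need at least 2 bonds")

  if (circular) {
    acc <- numeric(nb)            # sums for n_s = 0 .. nb-1 (circular lags)
    for (f in frames) {
      u <- unit_rows(bond_vectors(f, TRUE))
      for (col in 1:3) {
        ft <- stats::fft(u[, col])
        acc <- acc + Re(stats::fft(ft * Conj(ft), inverse = TRUE)) / nb
      }
    }
    C <- acc / (nb * length(frames))
    data.frame(n_s = 0:nb, C = c(C, C[1]))   # close the lag axis at nb
  } else {
    acc <- numeric(nb)
    for (f in frames) {
      u <- unit_rows(bond_vectors(f, FALSE))
      for (col in 1:3) {
        v <- u[, col]
        cv <- stats::convolve(v, v, type = "open")  # cross-correlation of v
        acc <- acc + cv[nb:(2 * nb - 1)]     # sum_i v_i v_{i+k}, k = 0..nb-1
      }
    }
    C <- acc / ((nb - 0:(nb - 1)) * length(frames))
    data.frame(n_s = 0:(nb - 1), C = C)
  }
}

#' Persistence length from short-range correlation decay
#'
#' Fits the exponential decay `C(n_s) = exp(-n_s l / P)` over the short
#' length scale where it holds, i.e. `ln C = -(l/P) n_s` through the origin
#' over separations with `C >= threshold` (default 1/e, of the order of one
#' persistence length).
#'
#' @param corr data.frame with columns `n_s`, `C` from
#'   [orientation_correlation()], or any object accepted by it.
#' @param l bond length.
#' @param threshold smallest correlation included in the fit window.
#' @param min_points minimum window size.
#' @param circular passed on when `corr` is raw frames.
#' @return list with `P`, `se`, `window` (fit separations), `fit` (the lm).
#' @export
estimate_persistence_length <- function(corr, l = 0.97,
                                        threshold = exp(-1),
                                        min_points = 3, circular = NULL) {
  if (!is.data.frame(corr)) corr <- orientation_correlation(corr, circular)
  d <- corr[corr$n_s >= 1, , drop = FALSE]
  keep <- which(cumsum(d$C < threshold | d$C <= 0) == 0)  # contiguous window
  if (length(keep) < min_points)
    stop(sprintf(
      "fit window has %d point(s) with C >= %.3g; need at least %d",
      length(keep), threshold, min_points))
  d <- d[keep, , drop = FALSE]
  fit <- stats::lm(log(C) ~ 0 + n_s, data = d)
  slope <- coef(fit)[["n_s"]]
  # suppress the "essentially perfect fit" warning for noiseless input
  se_slope <- suppressWarnings(sqrt(vcov(fit)[1, 1]))
  list(P = -l / slope, se = l * se_slope / slope^2,
       window = d$n_s, fit = fit)
}

#' Mean bond length of sampled frames
#'
#' @inheritParams span
#' @param circular ring topology flag (inferred for `np_traj` input).
#' @return numeric vector, one per-frame mean bond length.
#' @export
mean_bond_length <- function(x, circular = NULL) {
  if (is.null(circular)) {
    circular <- if (inherits(x, "np_traj")) x$chain$topology == "circular"
                else if (inherits(x, "chain_state")) x$topology == "circular"
                else FALSE
  }
  vapply(as_frames(x), function(f) {
    mean(sqrt(rowSums(bond_vectors(f, circular)^2)))
  }, numeric(1))
}
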