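#' Occupancy threshold ratio
#'
#' A chain partitioned between an interstitial quasi-channel (diameter
#' `d_c`) and a passage quasi-slit (width `w_p`) has confinement free
#' energies scaling as `2 d_c^-m` and `w_p^-m` (a channel costs twice a
#' slit of equal size). The barrier to spreading into neighbouring
#' interstitial volumes vanishes when `2 d_c^-m = w_p^-m`, i.e. at
#' `d_c / w_p = 2^(1/m)`; for the de Gennes exponent `m = 5/3` this is
#' `2^(3/5) = 1.516`, so multiple occupancy is predicted below
#' `d_c / w_p` of about 1.52.
#'
#' @param m free-energy scaling exponent (default 5/3).
#' @return the threshold ratio `2^(1/m)`.
#' @export
occupancy_threshold_ratio <- function(m = 5 / 3) {
  if (any(m <= 0)) stop("m must be positive")
  2^(1 / m)
}

#' Odijk extension of a strongly confined chain
#'
#' In a channel narrower than the persistence length (`D < P`) the chain
#' deflects off the walls and extends to
#' `R = L * (1 - A (D/P)^(2/3))` with `A = 0.1701` for a cylindrical
#' channel. For circular chains the two strands each span roughly half the
#' contour, so `circular = TRUE` uses `L/2`.
#'
#' @param L contour length; `D` channel diameter; `P` persistence length.
#' @param D channel diameter.
#' @param P persistence length.
#' @param A numerical constant (0.1701).
#' @param circular halve the contour length for a ring.
#' @return predicted extension along the channel.
#' @export
odijk_extension <- function(L, D, P, A = 0.1701, circular = FALSE) {
  stopifnot(all(L > 0), all(D >= 0), all(P > 0))
  if (any(D > P))
    warning("Odijk regime assumes D < P; extrapolating beyond it")
  Leff <- if (circular) L / 2 else L
  Leff * (1 - A * (D / P)^(2 / 3))
}

#' de Gennes (blob) extension of a moderately confined chain
#'
#' For channels wider than the persistence length the chain is a string of
#' blobs with extension `R = L (w P / D^2)^(1/3)`; the log-log slope
#' against `D` is exactly -2/3 in both the classic and extended de Gennes
#' regimes.
#'
#' @inheritParams odijk_extension
#' @param w chain width.
#' @export
degennes_extension <- function(L, D, P, w) {
  stopifnot(all(L > 0), all(D > 0), all(P > 0), all(w > 0))
  if (any(D < P))
    warning("de Gennes regime assumes D > P; extrapolating beyond it")
  L * (w * P / D^2)^(1 / 3)
}

#' Odijk deflection length
#'
#' `lambda = c (P D^2)^(1/3)`: the contour length between successive
#' deflections off the channel wall; `c` is a prefactor of order one.
#'
#' @inheritParams odijk_extension
#' @param c prefactor (default 1).
#' @export
deflection_length <- function(P, D, c = 1) {
  stopifnot(all(P > 0), all(D > 0))
  c * (P * D^2)^(1 / 3)
}

#' Damped-oscillation orientation correlation profile
#'
#' Model for the tangent correlations of a linear chain strongly confined
#' in a channel:
#' `C(n_s) = 1 - (lambda / 2P) [1 + 2 exp(-n_s l / lambda)
#'  sin(n_s l / lambda - pi/4)]`.
#' The oscillation period is set by the deflection length `lambda`; the
#' first minimum reflects the first deflection off the wall, and the
#' large-separation plateau is `1 - lambda/(2P)`.
#'
#' @param n_s bond separation(s).
#' @param l bond length.
#' @param P persistence length; must exceed `lambda/2`.
#' @param lambda deflection length.
#' @export
damped_orientation_profile <- function(n_s, l, P, lambda) {
  stopifnot(l > 0, lambda > 0, P > 0)
  if (P <= lambda / 2)
    warning("P <= lambda/2: the profile dips below zero at the origin")
  s <- n_s * l / lambda
  1 - lambda / (2 * P) * (1 + 2 * exp(-s) * sin(s - pi / 4))
}

#' Fit the damped-oscillation profile to orientation correlations
#'
#' Nonlinear least squares for the persistence length `P` and deflection
#' prefactor `c` of [damped_orientation_profile()], with
#' `lambda = c (P D^2)^(1/3)` substituted so only `(P, c)` are free. The
#' default fit window runs to twice the location of the first local
#' minimum of the data.
#'
#' @param corr data.frame with columns `n_s`, `C`.
#' @param l bond length; `D` channel (quasi-channel) diameter.
#' @param D channel diameter.
#' @param start initial guesses, default `P = 19.4` (the nominal `b * l`)
#'   and `c = 1`.
#' @param window optional integer range of `n_s` to fit; default
#'   `[1, 2 * first minimum]`.
#' @return list with `P`, `c`, `se` (named vector), `lambda`, `fit` (the
#'   nls object), `window`.
#' @export
fit_orientation_profile <- function(corr, l, D,
                                    start = list(P = 19.4, c = 1),
                                    window = NULL) {
  stopifnot(is.data.frame(corr), all(c("n_s", "C") %in% names(corr)))
  d <- corr[corr$n_s >= 0, , drop = FALSE]
  if (is.null(window)) {
    im <- first_local_minimum(d$n_s, d$C)
    if (is.na(im)) stop("no local minimum found; supply a fit window")
    window <- c(0, 2 * d$n_s[im])
  }
  d <- d[d$n_s >= window[1] & d$n_s <= window[2], , drop = FALSE]
  if (nrow(d) < 4) stop("fit window too small")
  fit <- minpack.lm::nlsLM(
    C ~ 1 - (cc * (P * D^2)^(1 / 3)) / (2 * P) *
      (1 + 2 * exp(-n_s * l / (cc * (P * D^2)^(1 / 3))) *
         sin(n_s * l / (cc * (P * D^2)^(1 / 3)) - pi / 4)),
    data = cbind(d, D = D, l = l),
    start = list(P = start$P, cc = start$c),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  list(P = unname(est["P"]), c = unname(est["cc"]),
       se = c(P = unname(se["P"]), c = unname(se["cc"])),
       lambda = deflection_length(est[["P"]], D, est[["cc"]]),
       fit = fit, window = window)
}

# index of the first interior local minimum, NA if none
first_local_minimum <- function(n_s, C) {
  n <- length(C)
  if (n < 3) return(NA_integer_)
  for (i in 2:(n - 1)) {
    if (C[i] < C[i - 1] && C[i] <= C[i + 1]) return(i)
  }
  NA_integer_
}

#' Classify the channel-confinement regime
#'
#' Odijk for `D <= P` (ties go to the stiffer regime), extended de Gennes
#' for `P < D <= P^2/w` (anisometric blobs), classic de Gennes beyond
#' (isometric blobs). Also returns the schedule of log-log structure-factor
#' slopes expected in that regime: -1 on the persistence/rod scale
#' (`q > 2 pi / P`), -2 inside an anisometric blob or -5/3 inside an
#' isometric one, and -1 again for the low-q string of blobs.
#'
#' @param P persistence length; `w` chain width; `D` channel diameter.
#' @param w chain width.
#' @param D channel diameter.
#' @return list with `regime`, `boundaries` (`P`, `P2_over_w`) and
#'   `sq_slopes` (named numeric vector, high to low q).
#' @export
classify_regime <- function(P, w, D) {
  stopifnot(P > 0, w > 0, D > 0)
  p2w <- P^2 / w
  if (D <= P) {
    regime <- "odijk"
    slopes <- c(rod = -1)
  } else if (D <= p2w) {
    regime <- "extended_degennes"
    slopes <- c(persistence = -1, blob = -2, blob_string = -1)
  } else {
    regime <- "classic_degennes"
    slopes <- c(persistence = -1, blob = -5 / 3, blob_string = -1)
  }
  list(regime = regime, boundaries = c(P = P, P2_over_w = p2w),
       sq_slopes = slopes)
}
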