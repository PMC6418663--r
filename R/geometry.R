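#' Derived parameters of a square nanopost lattice
#'
#' For posts of effective diameter `d_p` on a square lattice with
#' centre-to-centre spacing `S_p`, the interstitial space among four
#' neighbouring posts is gauged by the quasi-channel diameter
#' `d_c = sqrt(2) * S_p - d_p`, and the gap between two nearest posts by the
#' passage (quasi-slit) width `w_p = S_p - d_p`. The post volume fraction is
#' `F = pi * d_p^2 / (4 * S_p^2)`.
#'
#' @param S_p centre-to-centre post spacing (sigma units), > 0.
#' @param d_p effective post diameter (bare diameter plus one bead width),
#'   in `[0, sqrt(2) * S_p]`.
#' @return list with `w_p`, `d_c`, `F`, `ratio` (= `d_c / w_p`, `Inf` when
#'   the passage closes).
#' @examples
#' derived_params(12, 1.9) # w_p = 10.1, d_c = 15.071, F = 0.020
#' @export
derived_params <- function(S_p, d_p) {
  if (any(S_p <= 0)) stop("S_p must be positive")
  if (any(d_p < 0)) stop("d_p must be non-negative")
  if (any(d_p > sqrt(2) * S_p + 1e-12))
    stop("d_p exceeds sqrt(2) * S_p: posts would overlap diagonally")
  w_p <- S_p - d_p
  d_c <- sqrt(2) * S_p - d_p
  Fv <- pi * d_p^2 / (4 * S_p^2)
  ratio <- ifelse(w_p == 0, Inf, d_c / w_p)
  list(w_p = w_p, d_c = d_c, F = Fv, ratio = ratio)
}

#' Construct a square-lattice post array
#'
#' The array is an ideal infinite lattice of posts parallel to the x axis;
#' it is specified by any two of `S_p`, `d_p`, `w_p`. `d_p` is the
#' *effective* post diameter seen by the chain contour, i.e. the bare
#' diameter `D_p` used by the bead-post repulsion enlarged by one effective
#' bead width `w`: `d_p = D_p + w`.
#'
#' @param S_p post spacing; `d_p` effective post diameter; `w_p` passage
#'   width. Give exactly two (or all three, consistently).
#' @param w effective bead width added to the bare post diameter
#'   (default 0.9; the touching-bead model also admits `w = l` = 0.97).
#' @param origin yz coordinates of one post centre (length-2 numeric).
#' @return object of class `post_array`.
#' @export
post_array <- function(S_p = NULL, d_p = NULL, w_p = NULL, w = 0.9,
                       origin = c(0, 0)) {
  given <- !c(is.null(S_p), is.null(d_p), is.null(w_p))
  if (sum(given) < 2) stop("give at least two of S_p, d_p, w_p")
  if (is.null(S_p)) S_p <- d_p + w_p
  if (is.null(d_p)) d_p <- S_p - w_p
  if (!is.null(w_p) && abs((S_p - d_p) - w_p) > 1e-9)
    stop("inconsistent geometry: w_p must equal S_p - d_p")
  if (S_p <= 0) stop("S_p must be positive")
  if (d_p < 0) stop("d_p must be non-negative")
  if (d_p > sqrt(2) * S_p)
    stop("d_p exceeds sqrt(2) * S_p: posts would overlap diagonally")
  D_p <- d_p - w
  if (D_p < 0)
    stop("effective diameter d_p smaller than the bead width w: bare diameter would be negative")
  dp <- derived_params(S_p, d_p)
  structure(list(S_p = S_p, d_p = d_p, D_p = D_p, w = w,
                 w_p = dp$w_p, d_c = dp$d_c, F = dp$F, ratio = dp$ratio,
                 origin = as.numeric(origin)),
            class = "post_array")
}

#' @export
print.post_array <- function(x, ...) {
  cat(sprintf(
    "square post array: S_p = %g, d_p = %g (bare D_p = %g, w = %g)\n",
    x$S_p, x$d_p, x$D_p, x$w))
  cat(sprintf("  w_p = %g, d_c = %.3f, F = %.3f, d_c/w_p = %.3f\n",
              x$w_p, x$d_c, x$F, x$ratio))
  invisible(x)
}

#' Interstitial cell index of yz points
#'
#' The yz-plane is compartmented into space-filling squares whose vertices
#' are post centres; each square is one interstitial volume. Points on a
#' cell edge (including passage apertures) belong to the lower-index cell
#' (floor convention), so every point of the plane maps to exactly one cell.
#'
#' @param yz numeric length-2 vector or an n x 2 matrix of (y, z) points.
#' @param array a [post_array].
#' @return integer matrix with columns `i`, `j`.
#' @export
cell_index <- function(yz, array) {
  yz <- rbind(yz)
  i <- floor((yz[, 1] - array$origin[1]) / array$S_p)
  j <- floor((yz[, 2] - array$origin[2]) / array$S_p)
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Centre of an interstitial cell
#'
#' @param ij integer length-2 vector or n x 2 matrix of cell indices.
#' @param array a [post_array].
#' @return numeric matrix with columns `y`, `z`.
#' @export
cell_center <- function(ij, array) {
  ij <- rbind(ij)
  cbind(y = array$origin[1] + (ij[, 1] + 0.5) * array$S_p,
        z = array$origin[2] + (ij[, 2] + 0.5) * array$S_p)
}

#' Posts nearest to a yz point
#'
#' Returns the four posts at the vertices of the point's interstitial cell,
#' with centre distances. Whenever the passage width is non-negative these
#' four are guaranteed to include every post within the bead-post
#' interaction range; `brute = TRUE` instead scans a 5 x 5 post
#' neighbourhood and returns the four closest, which serves as an
#' independent check of the cell-vertex shortcut.
#'
#' @param yz numeric length-2 (y, z) point.
#' @param array a [post_array].
#' @param brute use the brute-force 25-post scan.
#' @return data.frame with columns `iy`, `iz` (lattice indices), `cy`, `cz`
#'   (post centre), `r` (centre distance), sorted by `r`.
#' @export
nearest_posts <- function(yz, array, brute = FALSE) {
  stopifnot(length(yz) == 2, all(is.finite(yz)))
  ij <- cell_index(yz, array)
  if (brute) {
    off <- expand.grid(a = -2:2, b = -2:2)
  } else {
    off <- expand.grid(a = 0:1, b = 0:1)
  }
  iy <- ij[1, 1] + off$a
  iz <- ij[1, 2] + off$b
  cy <- array$origin[1] + iy * array$S_p
  cz <- array$origin[2] + iz * array$S_p
  r <- sqrt((yz[1] - cy)^2 + (yz[2] - cz)^2)
  out <- data.frame(iy = iy, iz = iz, cy = cy, cz = cz, r = r)
  out <- out[order(out$r), , drop = FALSE]
  if (brute) out <- out[seq_len(4), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Geometry series studied at full scale
#'
#' The two families of array geometries used throughout: (1) constant post
#' spacing `S_p = 12` with effective post diameters 1.9-11.9, and
#' (2) constant passage width `w_p = 2` with diameters 1.9-60.9.
#'
#' @return named list of two data.frames with columns `S_p`, `d_p`.
#' @export
study_geometries <- function() {
  dp_wp2 <- c(1.9, 2.9, seq(4.9, 16.9, by = 2), 20.9, 30.9, 40.9, 50.9, 60.9)
  list(
    constant_Sp = data.frame(S_p = 12,
                             d_p = c(seq(1.9, 10.9, by = 1), 11.4, 11.9)),
    constant_wp = data.frame(S_p = dp_wp2 + 2, d_p = dp_wp2)
  )
}

#' Tabulate derived geometry parameters
#'
#' Computes `w_p`, `d_c`, `F` and `d_c/w_p` for a set of geometries; with no
#' arguments, both canonical series from [study_geometries()] are tabulated.
#'
#' @param geoms data.frame with columns `S_p`, `d_p`, or `NULL` for both
#'   canonical series.
#' @param file optional path; when given the table is also written as CSV.
#' @return data.frame with columns `series` (if canonical), `S_p`, `d_p`,
#'   `w_p`, `d_c`, `F`, `ratio`.
#' @export
geometry_table <- function(geoms = NULL, file = NULL) {
  if (is.null(geoms)) {
    gs <- study_geometries()
    geoms <- rbind(
      cbind(series = "constant_Sp", gs$constant_Sp[, c("S_p", "d_p")]),
      cbind(series = "constant_wp", gs$constant_wp[, c("S_p", "d_p")]))
  }
  dp <- derived_params(geoms$S_p, geoms$d_p)
  out <- cbind(geoms,
               w_p = dp$w_p, d_c = dp$d_c, F = dp$F, ratio = dp$ratio)
  rownames(out) <- NULL
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
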