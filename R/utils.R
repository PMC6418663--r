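#' Block-averaged mean and standard error
#'
#' Splits a (possibly autocorrelated) series into `n_blocks` contiguous
#' blocks and estimates the standard error of the mean from the scatter of
#' the block means. With ten or more blocks this is a robust, nearly
#' assumption-free error estimate for stationary MD time series.
#'
#' @param x numeric vector (a per-frame time series).
#' @param n_blocks number of contiguous blocks (default 10).
#' @return list with `mean`, `se`, `n_blocks`.
#' @export
block_stats <- function(x, n_blocks = 10) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < n_blocks) n_blocks <- max(1L, n)
  idx <- cut(seq_len(n), breaks = n_blocks, labels = FALSE)
  bm <- tapply(x, idx, mean)
  se <- if (n_blocks > 1) stats::sd(bm) / sqrt(n_blocks) else NA_real_
  list(mean = mean(x), se = as.numeric(se), n_blocks = n_blocks)
}

# sin(x)/x with the removable singularity filled in
sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

# Normalise any accepted frame container to a plain list of N x 3 matrices.
as_frames <- function(x) {
  if (inherits(x, "np_traj")) return(x$frames)
  if (inherits(x, "chain_state")) return(list(x$positions))
  if (is.matrix(x)) return(list(x))
  if (is.list(x)) {
    stopifnot(all(vapply(x, is.matrix, logical(1))))
    return(x)
  }
  stop("cannot interpret 'x' as a frame, chain_state, trajectory or list of frames")
}

# Bond vectors of one frame under the given topology (rows = bonds).
bond_vectors <- function(frame, circular = FALSE) {
  n <- nrow(frame)
  if (circular) {
    frame[c(seq(2, n), 1), , drop = FALSE] - frame
  } else {
    frame[-1, , drop = FALSE] - frame[-n, , drop = FALSE]
  }
}

unit_rows <- function(m) m / sqrt(rowSums(m^2))
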