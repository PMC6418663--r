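# Reference values for the two canonical geometry series (printed to three
# decimals): columns d_p, w_p, d_c, F, ratio for S_p = 12, and
# d_p, S_p, d_c, F, ratio for w_p = 2.
table_Sp12 <- function() {
  m <- matrix(c(
    1.9, 10.1, 15.071, 0.020, 1.492,
    2.9,  9.1, 14.071, 0.046, 1.546,
    3.9,  8.1, 13.071, 0.083, 1.614,
    4.9,  7.1, 12.071, 0.131, 1.700,
    5.9,  6.1, 11.071, 0.190, 1.815,
    6.9,  5.1, 10.071, 0.260, 1.975,
    7.9,  4.1,  9.071, 0.340, 2.212,
    8.9,  3.1,  8.071, 0.432, 2.603,
    9.9,  2.1,  7.071, 0.535, 3.367,
   10.9,  1.1,  6.071, 0.648, 5.519,
   11.4,  0.6,  5.571, 0.709, 9.284,
   11.9,  0.1,  5.071, 0.772, 50.706), ncol = 5, byrow = TRUE)
  colnames(m) <- c("d_p", "w_p", "d_c", "F", "ratio")
  as.data.frame(m)
}

table_wp2 <- function() {
  m <- matrix(c(
    1.9,  3.9,  3.615, 0.186,  1.808,
    2.9,  4.9,  4.030, 0.275,  2.015,
    4.9,  6.9,  4.858, 0.396,  2.429,
    6.9,  8.9,  5.687, 0.472,  2.843,
    8.9, 10.9,  6.515, 0.524,  3.257,
   10.9, 12.9,  7.343, 0.561,  3.672,
   12.9, 14.9,  8.172, 0.589,  4.086,
   14.9, 16.9,  9.000, 0.611,  4.500,
   16.9, 18.9,  9.829, 0.628,  4.914,
   20.9, 22.9, 11.485, 0.654,  5.743,
   30.9, 32.9, 15.628, 0.693,  7.814,
   40.9, 42.9, 19.770, 0.714,  9.885,
   50.9, 52.9, 23.912, 0.727, 11.956,
   60.9, 62.9, 28.054, 0.736, 14.027), ncol = 5, byrow = TRUE)
  colnames(m) <- c("d_p", "S_p", "d_c", "F", "ratio")
  as.data.frame(m)
}

# Central finite-difference forces for a configuration, the oracle against
# which the analytic forces are checked.
fd_forces <- function(positions, topology, ff, array = NULL, h = 1e-6) {
  N <- nrow(positions)
  fd <- matrix(0, N, 3)
  for (i in seq_len(N)) {
    for (k in 1:3) {
      pp <- positions; pp[i, k] <- pp[i, k] + h
      pm <- positions; pm[i, k] <- pm[i, k] - h
      ep <- chain_energy(chain_state(pp, topology), ff, array)$total
      em <- chain_energy(chain_state(pm, topology), ff, array)$total
      fd[i, k] <- -(ep - em) / (2 * h)
    }
  }
  fd
}

# A compact random self-avoiding-ish open chain that keeps all bonds legal.
random_chain <- function(N, seed, jitter = 0.05) {
  set.seed(seed)
  pos <- cbind((seq_len(N) - 1) * 0.95, 0, 0) +
    matrix(rnorm(3 * N, sd = jitter), ncol = 3)
  pos
}
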