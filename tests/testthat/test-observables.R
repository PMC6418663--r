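test_that("span measures the per-frame extent along the requested axis", {
  rod <- generate_fixture("rod", N = 100, l = 0.97)
  expect_equal(span(rod), 99 * 0.97)
  rod_y <- generate_fixture("rod", N = 100, l = 0.97, axis = 2)
  expect_equal(span(rod_y), 0)
  expect_equal(span(rod_y, axis = 2), 99 * 0.97)
  # series mean over frames
  two <- list(rod$positions, 0.5 * rod$positions)
  expect_equal(mean(span(two)), (99 * 0.97 + 49.5 * 0.97) / 2)
  # for a stretched open chain the span approaches the end-to-end distance
  ee <- sqrt(sum((rod$positions[100, ] - rod$positions[1, ])^2))
  expect_equal(span(rod), ee)
})

test_that("gyration components satisfy the decomposition identity", {
  # three collinear beads at x = -1, 0, 1: R_g^2 = 2/3, no lateral extent
  tri <- matrix(c(-1, 0, 0, 0, 0, 0, 1, 0, 0), ncol = 3, byrow = TRUE)
  g <- gyration_components(tri)
  expect_equal(g$R_g^2, 2 / 3)
  expect_equal(g$R_gx^2, 2 / 3)
  expect_equal(g$R_gyz, 0)

  # decomposition R_gx^2 + 2 R_gyz^2 = R_g^2 on arbitrary frames
  set.seed(4)
  for (k in 1:5) {
    f <- matrix(rnorm(60), ncol = 3)
    g <- gyration_components(f)
    expect_equal(g$R_gx^2 + 2 * g$R_gyz^2, g$R_g^2)
  }

  # isotropic cloud: both components near R_g / sqrt(3)
  set.seed(5)
  cloud <- matrix(rnorm(3 * 20000), ncol = 3)
  g <- gyration_components(cloud)
  expect_equal(g$R_gx, g$R_g / sqrt(3), tolerance = 0.02)
  expect_equal(g$R_gyz, g$R_g / sqrt(3), tolerance = 0.02)
})

test_that("occupation number counts distinct planted cells", {
  arr <- post_array(S_p = 12, d_p = 4.9)
  one <- generate_fixture("planted_cells", cells = rbind(c(0, 0), c(0, 0), c(0, 0)),
                          array = arr)
  expect_equal(occupation_number(one, arr), 1L)
  two <- generate_fixture("planted_cells", cells = rbind(c(0, 0), c(1, 0)),
                          array = arr)
  expect_equal(occupation_number(two, arr), 2L)
  block <- generate_fixture("planted_cells",
                            cells = as.matrix(expand.grid(0:1, 0:1)),
                            array = arr)
  expect_equal(occupation_number(block, arr), 4L)

  # invariant under bead relabelling and whole-lattice translation
  set.seed(6)
  cells <- cbind(sample(-3:3, 12, TRUE), sample(-3:3, 12, TRUE))
  ch <- generate_fixture("planted_cells", cells = cells, array = arr)
  perm <- ch$positions[sample(nrow(cells)), ]
  expect_equal(occupation_number(perm, arr), occupation_number(ch, arr))
  shifted <- ch$positions
  shifted[, 2] <- shifted[, 2] + 3 * arr$S_p
  shifted[, 3] <- shifted[, 3] - 2 * arr$S_p
  expect_equal(occupation_number(shifted, arr), occupation_number(ch, arr))

  # a bead sitting in a passage aperture still counts toward the cell it
  # geometrically lies in (here the aperture between posts (0,0) and (0,12))
  pos <- cbind(0, 6, 0.3)
  expect_equal(occupation_number(pos, arr), 1L)
  expect_equal(unname(cell_index(c(6, 0.3), arr)[1, ]), c(0L, 0L))
})

test_that("structure factor normalises to 1 at small q and matches the two-bead closed form", {
  pair <- generate_fixture("two_bead", r = 2.5)
  q <- c(1e-8, pi / 2.5, seq(0.1, 3, length.out = 20))
  sf <- structure_factor(pair, q = q)
  expect_equal(sf$S[1], 1, tolerance = 1e-10)
  # q r = pi: sinc = 0, S = 1/2
  expect_equal(sf$S[2], 0.5, tolerance = 1e-12)
  expect_equal(sf$S, (1 + nanopost:::sinc(q * 2.5)) / 2, tolerance = 1e-12)
  expect_true(all(sf$S > 0 & sf$S <= 1 + 1e-12))
})

test_that("histogram structure factor agrees with the direct double sum", {
  set.seed(8)
  frame <- matrix(cumsum(rnorm(60, sd = 0.6)), ncol = 3)
  q <- exp(seq(log(0.05), log(8), length.out = 60))
  direct <- structure_factor(frame, q = q, method = "direct")
  hist <- structure_factor(frame, q = q, method = "histogram", bin_width = 0.005)
  expect_lt(max(abs(direct$S - hist$S)), 1e-3)
})

test_that("orientation correlations reproduce rod, polygon-ring and inversion symmetry", {
  rod <- generate_fixture("rod", N = 20)
  cr <- orientation_correlation(rod)
  expect_equal(cr$C, rep(1, 19))

  # regular N-gon: C(n_s) = cos(2 pi n_s / N)
  for (N in c(4, 7, 12)) {
    ring <- generate_fixture("regular_polygon_ring", N = N)
    cc <- orientation_correlation(ring)
    expect_equal(cc$C, cos(2 * pi * (0:N) / N))
  }

  # inversion symmetry C(n_s) = C(N - n_s) for any ring conformation
  set.seed(9)
  ring <- build_chain(30, "circular")
  pos <- ring$positions + matrix(rnorm(90, sd = 0.05), ncol = 3)
  cc <- orientation_correlation(chain_state(pos, "circular"))
  expect_equal(cc$C, rev(cc$C))
  expect_equal(cc$C[1], 1)
  expect_true(all(abs(cc$C) <= 1 + 1e-12))
})

test_that("persistence length is recovered exactly from an exponential profile", {
  ns <- 0:40
  corr <- data.frame(n_s = ns, C = exp(-0.97 * ns / 19.7))
  est <- estimate_persistence_length(corr, l = 0.97)
  expect_equal(est$P, 19.7, tolerance = 1e-10)
  expect_lt(est$se, 1e-8)
  # too-short usable window errors out
  bad <- data.frame(n_s = 0:5, C = c(1, 0.2, 0.1, 0.05, 0.02, 0.01))
  expect_error(estimate_persistence_length(bad), "window")
})

test_that("persistence length is recovered from ideal worm-like-chain samples", {
  frames <- generate_fixture("ideal_wlc", N = 400, P = 10, seed = 42,
                             n_frames = 200)
  est <- estimate_persistence_length(orientation_correlation(frames))
  expect_equal(est$P, 10, tolerance = 0.05)

  # stiffness-parameterised variant: b = 10 gives P = -l / log(coth(10) - 1/10)
  frames_b <- generate_fixture("ideal_wlc", N = 400, b = 10, seed = 43,
                               n_frames = 200)
  P_exact <- -0.97 / log(1 / tanh(10) - 1 / 10)
  est_b <- estimate_persistence_length(orientation_correlation(frames_b))
  expect_equal(est_b$P, P_exact, tolerance = 0.05 * P_exact)
})

test_that("mean bond length matches construction on fixtures", {
  rod <- generate_fixture("rod", N = 50, l = 0.97)
  expect_equal(mean_bond_length(rod), 0.97)
  ring <- generate_fixture("regular_polygon_ring", N = 16, l = 0.8)
  expect_equal(mean_bond_length(ring, circular = TRUE), 0.8)
})
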