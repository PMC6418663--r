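test_that("built chains have the documented geometry and are energetically valid", {
  lin <- build_chain(100, "linear")
  expect_equal(sqrt(sum((lin$positions[100, ] - lin$positions[1, ])^2)),
               99 * 0.97)
  ring <- build_chain(100, "circular")
  expect_equal(span(ring), 49 * 0.97)
  # two parallel strands one bond length apart
  expect_equal(sort(unique(round(ring$positions[, 2], 9))),
               c(-0.485, 0.485))
  for (ch in list(lin, ring)) {
    circ <- ch$topology == "circular"
    bl <- sqrt(rowSums(nanopost:::bond_vectors(ch$positions, circ)^2))
    expect_true(all(bl < 1.5))
    expect_true(is.finite(chain_energy(ch, forcefield(20))$total))
  }
  expect_error(build_chain(99, "circular"), "even")
})

test_that("in-array placement clears the posts or fails loudly", {
  arr <- post_array(S_p = 12, d_p = 4.9)
  par <- build_chain(60, "linear", array = arr)
  e <- chain_energy(par, forcefield(0), arr)
  expect_true(is.finite(e$total))
  # parallel placement keeps all beads on the cell axis, far from posts
  d <- vapply(seq_len(60), function(i)
    min(nearest_posts(par$positions[i, 2:3], arr)$r), numeric(1))
  expect_true(all(d > arr$D_p / 2 + arr$w / 2))

  # perpendicular orientation through passage apertures
  perp <- build_chain(20, "linear", orientation = "perpendicular", array = arr)
  expect_gt(max(perp$positions[, 2]) - min(perp$positions[, 2]), 10)
  expect_true(is.finite(chain_energy(perp, forcefield(0), arr)$total))

  # an impassably narrow passage rejects a long perpendicular chain
  tight <- post_array(S_p = 12, d_p = 11.9)
  expect_error(build_chain(60, "linear", orientation = "perpendicular",
                           array = tight), "placement")
})

test_that("NVE integration conserves energy and momentum", {
  ff <- forcefield(0)
  ch <- build_chain(50, "linear")
  warm <- run_md(ch, ff, sim_params(n_steps = 2e4, sample_every = 2e4, seed = 3))
  st <- warm$chain
  nve <- run_md(st, ff, sim_params(thermostat = "none", n_steps = 1e4,
                                   sample_every = 10, seed = 3))
  E <- nve$potential + nve$kinetic
  n <- length(E)
  # secular drift: difference of first and last tenth-block means
  drift <- abs(mean(E[seq(n - n / 10, n)]) - mean(E[seq_len(n / 10)])) /
    abs(mean(E[seq_len(n / 10)]))
  expect_lt(drift, 1e-4)

  # energy fluctuation amplitude scales as dt^2 (second-order integrator)
  nve2 <- run_md(st, ff, sim_params(dt = 0.0025, thermostat = "none",
                                    n_steps = 2e4, sample_every = 20, seed = 3))
  E2 <- nve2$potential + nve2$kinetic
  ratio <- sd(E - mean(E)) / sd(E2 - mean(E2))
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 6.5)

  # no external x-forces: total x-momentum conserved to round-off
  expect_lt(abs(sum(nve$chain$velocities[, 1]) - sum(st$velocities[, 1])),
            1e-9)
})

test_that("thermostatted runs hold the kinetic temperature at the target", {
  ch <- build_chain(60, "linear")
  for (thermo in c("nose_hoover", "langevin")) {
    tr <- run_md(ch, forcefield(0),
                 sim_params(thermostat = thermo, n_steps = 2e5,
                            sample_every = 100, seed = 17))
    Ts <- tr$temperature[-(1:200)]     # discard the transient
    bs <- block_stats(Ts, 10)
    expect_lt(abs(bs$mean - 1), max(3 * bs$se, 0.02))
  }
})

test_that("trajectories are deterministic given the seed", {
  ch <- build_chain(30, "linear")
  for (thermo in c("nose_hoover", "langevin")) {
    a <- run_md(ch, forcefield(0),
                sim_params(thermostat = thermo, n_steps = 5e3,
                           sample_every = 500, seed = 5))
    b <- run_md(ch, forcefield(0),
                sim_params(thermostat = thermo, n_steps = 5e3,
                           sample_every = 500, seed = 5))
    expect_identical(a$frames, b$frames)
    c <- run_md(ch, forcefield(0),
                sim_params(thermostat = thermo, n_steps = 5e3,
                           sample_every = 500, seed = 6))
    expect_false(identical(a$frames, c$frames))
  }
})

test_that("hard repulsion keeps every bead outside the post cores", {
  arr <- post_array(S_p = 8, d_p = 2.9)
  ch <- build_chain(40, "linear", array = arr)
  tr <- run_md(ch, forcefield(0), sim_params(n_steps = 5e4, sample_every = 100,
                                             seed = 23), arr)
  min_clear <- min(vapply(tr$frames, function(f) {
    min(vapply(seq_len(nrow(f)), function(i)
      min(nearest_posts(f[i, 2:3], arr)$r), numeric(1)))
  }, numeric(1)))
  expect_gt(min_clear, arr$D_p / 2)
})

test_that("integration failures carry the step and cause", {
  # two beads far beyond R_o cannot even initialise
  bad <- chain_state(rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)), "linear")
  expect_error(run_md(bad, forcefield(0), sim_params(n_steps = 10)),
               "FENE length")
  # a bead planted inside a post core is reported
  arr <- post_array(S_p = 12, d_p = 4.9)
  inside <- chain_state(cbind(c(0, 0.97, 1.94), 0.1, 0.1), "linear")
  expect_error(run_md(inside, forcefield(0), sim_params(n_steps = 10),
                      array = arr), "post core")
})

test_that("equilibrate_and_sample reports block-averaged observables", {
  res <- equilibrate_and_sample(N = 40, b = 0, n_equil = 2e4, n_prod = 1e5,
                                sample_every = 500, seed = 19,
                                thermostat = "langevin")
  s <- res$summary
  expect_true(all(c("bond_length", "R_s", "R_g", "R_gx", "R_gyz") %in%
                    s$observable))
  expect_true(all(is.finite(s$mean)))
  expect_true(all(s$se > 0))
  bl <- s$mean[s$observable == "bond_length"]
  expect_equal(bl, 0.97, tolerance = 0.01)
  # decomposition holds for the series means too (per-frame identity)
  id_err <- max(abs(res$series$R_gx^2 + 2 * res$series$R_gyz^2 -
                      res$series$R_g^2))
  expect_lt(id_err, 1e-9)
})
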