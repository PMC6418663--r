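#' Simulation parameters
#'
#' Integration and thermostat settings for the leap-frog dynamics, in
#' reduced units (time unit tau = sigma sqrt(m/epsilon), bead mass 1).
#'
#' @param dt timestep (0.005 tau).
#' @param temperature target temperature (1 epsilon/k_B).
#' @param thermostat `"nose_hoover"` (default), `"langevin"`, or `"none"`
#'   for NVE validation runs.
#' @param relaxation Nose-Hoover relaxation time (0.1 tau).
#' @param friction Langevin friction (tau^-1).
#' @param n_steps number of integration steps.
#' @param sample_every sampling cadence in steps.
#' @param seed integer seed controlling all randomness of the run.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(dt = 0.005, temperature = 1,
                       thermostat = c("nose_hoover", "langevin", "none"),
                       relaxation = 0.1, friction = 0.5,
                       n_steps = 1e5, sample_every = 1000, seed = 1) {
  thermostat <- match.arg(thermostat)
  stopifnot(dt > 0, temperature > 0, relaxation > 0, friction > 0,
            n_steps >= 1, sample_every >= 1)
  structure(list(dt = dt, temperature = temperature, thermostat = thermostat,
                 relaxation = relaxation, friction = friction,
                 n_steps = as.integer(n_steps),
                 sample_every = as.integer(sample_every),
                 seed = as.integer(seed)),
            class = "sim_params")
}

thermo_code <- function(x) switch(x, none = 0L, nose_hoover = 1L, langevin = 2L)

#' Integrate the equations of motion
#'
#' Advances the chain with the leap-frog algorithm under the selected
#' thermostat, sampling frames and energies every `sample_every` steps.
#' The run is deterministic given the seed (initial velocities are drawn
#' from R's RNG, the Langevin noise from a seeded generator in compiled
#' code). Integration aborts with an informative error if a bond reaches
#' the maximal FENE extension, a bead penetrates a post core, or the energy
#' turns non-finite.
#'
#' @param chain a [chain_state]; if it has no velocities, Maxwell-Boltzmann
#'   velocities at the target temperature are drawn.
#' @param ff a [forcefield].
#' @param sim a [sim_params].
#' @param array optional [post_array].
#' @return object of class `np_traj`: list with `frames` (list of N x 3
#'   matrices), `steps`, `potential`, `kinetic`, `temperature` (per-sample
#'   series), `chain` (final state with velocities), `chi` (thermostat
#'   variable), and the run parameters.
#' @export
run_md <- function(chain, ff = forcefield(), sim = sim_params(),
                   array = NULL) {
  stopifnot(inherits(chain, "chain_state"))
  if (is.null(chain$velocities)) {
    set.seed(sim$seed)
    chain$velocities <- maxwell_velocities(chain$N, sim$temperature)
  }
  has_array <- !is.null(array)
  res <- np_md_run(chain$positions, chain$velocities,
                   chain$topology == "circular",
                   ff$epsilon, ff$sigma, ff$kappa, ff$R_o,
                   ff$b * ff$epsilon,
                   has_array,
                   if (has_array) array$S_p else 0,
                   if (has_array) array$D_p else 0,
                   if (has_array) array$origin[1] else 0,
                   if (has_array) array$origin[2] else 0,
                   sim$dt, sim$n_steps, sim$sample_every,
                   thermo_code(sim$thermostat), sim$temperature,
                   sim$relaxation, sim$friction, sim$seed,
                   0.3 * ff$sigma, attr(chain, "chi") %||% 0)
  nsamp <- dim(res$frames)[3]
  frames <- lapply(seq_len(nsamp), function(k) res$frames[, , k])
  final <- chain_state(res$positions, chain$topology, res$velocities)
  attr(final, "chi") <- res$chi
  structure(list(frames = frames, steps = res$steps,
                 potential = res$potential, kinetic = res$kinetic,
                 temperature = res$temperature,
                 chain = final, chi = res$chi,
                 ff = ff, sim = sim, array = array),
            class = "np_traj")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.np_traj <- function(x, ...) {
  cat(sprintf("np_traj: %d frames of %d beads (%s), %d steps, dt = %g\n",
              length(x$frames), x$chain$N, x$chain$topology,
              x$sim$n_steps, x$sim$dt))
  invisible(x)
}

#' Equilibrate a chain and sample its structural observables
#'
#' Runs an equilibration phase, checks stationarity (block means of the
#' potential energy and radius of gyration over the last two equilibration
#' blocks must agree within three combined standard errors), then a
#' production phase, and returns block-averaged means with standard errors
#' for the mean bond length, span along x, gyration components and (with an
#' array) the occupation number.
#'
#' @param N bead count; `topology`, `b`, `array`, `orientation` as in
#'   [build_chain()] and [forcefield()].
#' @param topology chain topology.
#' @param b bending stiffness.
#' @param array optional [post_array].
#' @param orientation initial principal-axis orientation.
#' @param n_equil,n_prod step counts for the two phases.
#' @param sample_every sampling cadence (steps).
#' @param dt,temperature,thermostat,relaxation,friction,seed see
#'   [sim_params()].
#' @param n_blocks blocks for the error estimate.
#' @param keep_frames return the production frames (memory permitting).
#' @return list with `summary` (data.frame: observable, mean, se),
#'   `converged` flag, the per-frame `series`, and optionally `frames`.
#' @export
equilibrate_and_sample <- function(N, topology = "linear", b = 0,
                                   array = NULL,
                                   orientation = "parallel",
                                   n_equil = 2e5, n_prod = 1e6,
                                   sample_every = 1000,
                                   dt = 0.005, temperature = 1,
                                   thermostat = "nose_hoover",
                                   relaxation = 0.1, friction = 0.5,
                                   seed = 1, n_blocks = 10,
                                   keep_frames = TRUE) {
  ff <- forcefield(b = b)
  chain <- build_chain(N, topology, l = ff$l, orientation = orientation,
                       array = array)
  sim_eq <- sim_params(dt = dt, temperature = temperature,
                       thermostat = thermostat, relaxation = relaxation,
                       friction = friction, n_steps = n_equil,
                       sample_every = max(1, n_equil %/% 200), seed = seed)
  eq <- run_md(chain, ff, sim_eq, array)

  # stationarity: last two fifths of the equilibration phase
  converged <- TRUE
  rg_eq <- gyration_components(eq)$R_g
  for (series in list(eq$potential, rg_eq)) {
    n <- length(series)
    if (n >= 10) {
      a <- series[seq(floor(0.6 * n) + 1, floor(0.8 * n))]
      bb <- series[seq(floor(0.8 * n) + 1, n)]
      sa <- block_stats(a, 5); sb <- block_stats(bb, 5)
      if (is.finite(sa$se) && is.finite(sb$se) &&
          abs(sa$mean - sb$mean) > 3 * sqrt(sa$se^2 + sb$se^2))
        converged <- FALSE
    }
  }
  if (!converged)
    warning("equilibration stationarity check failed; results are flagged")

  sim_pr <- sim_params(dt = dt, temperature = temperature,
                       thermostat = thermostat, relaxation = relaxation,
                       friction = friction, n_steps = n_prod,
                       sample_every = sample_every, seed = seed + 1L)
  pr <- run_md(eq$chain, ff, sim_pr, array)

  circ <- topology == "circular"
  bl <- vapply(pr$frames, function(f) {
    mean(sqrt(rowSums(bond_vectors(f, circ)^2)))
  }, numeric(1))
  series <- list(bond_length = bl,
                 R_s = span(pr),
                 R_g = gyration_components(pr)$R_g,
                 R_gx = gyration_components(pr)$R_gx,
                 R_gyz = gyration_components(pr)$R_gyz)
  if (!is.null(array)) series$n_occ <- occupation_number(pr, array)

  summ <- do.call(rbind, lapply(names(series), function(nm) {
    bs <- block_stats(series[[nm]], n_blocks)
    data.frame(observable = nm, mean = bs$mean, se = bs$se)
  }))
  out <- list(summary = summ, converged = converged, series = series,
              trajectory = if (keep_frames) pr else NULL)
  out
}
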