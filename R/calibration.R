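#' Free-chain calibration of the effective bond length
#'
#' Simulates a free flexible chain (the combined FENE + WCA bond at
#' temperature T = 1) and returns the block-averaged mean bond length,
#' which calibrates the effective bond length l of the model (nominally
#' 0.97 sigma).
#'
#' @param N bead count (default 100).
#' @param n_equil,n_prod equilibration and production steps.
#' @param sample_every sampling cadence.
#' @param thermostat thermostat kind.
#' @param seed integer seed.
#' @return list with `l` (mean bond length), `se`, and the
#'   [equilibrate_and_sample()] result under `details`.
#' @export
calibrate_bond_length <- function(N = 100, n_equil = 2e5, n_prod = 1e6,
                                  sample_every = 1000,
                                  thermostat = "nose_hoover", seed = 1) {
  res <- equilibrate_and_sample(N = N, b = 0, n_equil = n_equil,
                                n_prod = n_prod,
                                sample_every = sample_every,
                                thermostat = thermostat, seed = seed,
                                keep_frames = FALSE)
  row <- res$summary[res$summary$observable == "bond_length", ]
  list(l = row$mean, se = row$se, details = res)
}

#' Free-chain calibration of the persistence length
#'
#' Measures the persistence length of a free semiflexible chain from the
#' short-range exponential decay of its tangent correlations,
#' `C(n_s) = exp(-n_s l / P)`. Global conformational modes of a
#' semiflexible chain relax over times far beyond a desk-scale run and
#' leak into `C` at separations approaching one persistence length, so the
#' protocol averages over several independent replicas, each starting from
#' an overlap-free ideal worm-like-chain draw at the nominal stiffness
#' (equilibrium-like global statistics from step one) and relaxed under a
#' Langevin thermostat before production. The fit window is the short
#' scale `C >= exp(-1/2)` (about half a persistence length), where the
#' decay is exponential and insensitive to excluded-volume swelling and to
#' residual global-mode bias; the replica-to-replica scatter provides the
#' sampling uncertainty.
#'
#' @param N bead count (200-300 recommended).
#' @param b bending stiffness (20 for the semiflexible chain).
#' @param n_replicas number of independent replicas.
#' @param n_relax,n_prod relaxation and production steps per replica.
#' @param sample_every sampling cadence.
#' @param friction Langevin friction.
#' @param seed integer master seed; replica seeds are derived from it.
#' @param window_threshold smallest correlation included in the fit.
#' @return list with `P` (pooled estimate), `se` (combined fit +
#'   replica-scatter standard error), `per_replica` (data.frame),
#'   `correlation` (pooled C(n_s)), `window`.
#' @export
calibrate_persistence_length <- function(N = 250, b = 20, n_replicas = 6,
                                         n_relax = 5e5, n_prod = 1.5e6,
                                         sample_every = 500, friction = 1,
                                         seed = 1,
                                         window_threshold = exp(-1 / 2)) {
  ff <- forcefield(b = b)
  P_nominal <- b * ff$l
  corrs <- vector("list", n_replicas)
  P_rep <- numeric(n_replicas)
  for (r in seq_len(n_replicas)) {
    rs <- seed + 1000L * r
    ch <- wlc_start(N, P_nominal, rs)
    relax <- run_md(ch, ff,
                    sim_params(thermostat = "langevin", friction = friction,
                               n_steps = n_relax, sample_every = n_relax,
                               seed = rs))
    prod <- run_md(relax$chain, ff,
                   sim_params(thermostat = "langevin", friction = friction,
                              n_steps = n_prod,
                              sample_every = sample_every,
                              seed = rs + 1L))
    corrs[[r]] <- orientation_correlation(prod)
    fit_r <- estimate_persistence_length(corrs[[r]], l = ff$l,
                                         threshold = window_threshold)
    P_rep[r] <- fit_r$P
  }
  pooled <- corrs[[1]]
  pooled$C <- rowMeans(vapply(corrs, function(d) d$C,
                              numeric(nrow(pooled))))
  fit <- estimate_persistence_length(pooled, l = ff$l,
                                     threshold = window_threshold)
  se_rep <- if (n_replicas > 1) stats::sd(P_rep) / sqrt(n_replicas) else 0
  list(P = fit$P,
       se = sqrt(fit$se^2 + se_rep^2),
       per_replica = data.frame(replica = seq_len(n_replicas), P = P_rep),
       correlation = pooled,
       window = fit$window)
}

# Overlap-free ideal worm-like-chain starting conformation: redraw until no
# bead pair is deep inside the WCA core.
wlc_start <- function(N, P, seed, min_dist = 0.85, max_tries = 50) {
  for (s in seed + seq_len(max_tries) - 1L) {
    ch <- generate_fixture("ideal_wlc", N = N, P = P, seed = s)
    if (min(stats::dist(ch$positions)) > min_dist) return(ch)
  }
  stop("could not draw an overlap-free worm-like-chain start")
}
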