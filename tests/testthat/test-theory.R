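test_that("occupancy threshold ratio follows 2^(1/m)", {
  expect_equal(occupancy_threshold_ratio(), 2^(3 / 5))
  expect_equal(round(occupancy_threshold_ratio(5 / 3), 2), 1.52)
  expect_equal(occupancy_threshold_ratio(1), 2)
  expect_equal(occupancy_threshold_ratio(1e9), 1, tolerance = 1e-8)
  expect_error(occupancy_threshold_ratio(0), "positive")
})

test_that("Odijk extension interpolates between L and the A-reduced value", {
  expect_equal(odijk_extension(100, D = 1e-12, P = 20), 100, tolerance = 1e-6)
  expect_equal(suppressWarnings(odijk_extension(100, D = 20, P = 20)),
               100 * (1 - 0.1701))
  # circular chains use half the contour
  expect_equal(odijk_extension(100, D = 5, P = 20, circular = TRUE),
               odijk_extension(100, D = 5, P = 20) / 2)
  # monotone decreasing and continuous in D within the regime
  D <- seq(0.1, 19, length.out = 100)
  R <- odijk_extension(100, D, P = 20)
  expect_true(all(diff(R) < 0))
  expect_warning(odijk_extension(100, D = 30, P = 20), "D < P")
})

test_that("de Gennes extension has exact -2/3 log-log slope in D", {
  expect_equal(suppressWarnings(degennes_extension(100, D = sqrt(0.97 * 19.7),
                                                   P = 19.7, w = 0.97)), 100)
  R1 <- degennes_extension(100, D = 30, P = 19.7, w = 0.97)
  R2 <- degennes_extension(100, D = 60, P = 19.7, w = 0.97)
  expect_equal(R2 / R1, 2^(-2 / 3))
  D <- exp(seq(log(25), log(400), length.out = 50))
  slope <- diff(log(degennes_extension(100, D, P = 19.7, w = 0.97))) / diff(log(D))
  expect_equal(slope, rep(-2 / 3, 49))
  expect_warning(degennes_extension(100, D = 5, P = 19.7, w = 0.97), "D > P")
})

test_that("deflection length scales as (P D^2)^(1/3)", {
  expect_equal(deflection_length(P = 7, D = 7), 7)
  expect_equal(round(deflection_length(P = 19.7, D = 5.07), 2), 7.97)
  expect_equal(deflection_length(P = 10, D = 8) / deflection_length(P = 10, D = 4),
               2^(2 / 3))
  expect_equal(deflection_length(P = 10, D = 4, c = 0.5),
               0.5 * deflection_length(P = 10, D = 4))
})

test_that("damped orientation profile has the analytic endpoints and a first minimum", {
  l <- 0.97; P <- 19.61; lam <- deflection_length(P, 5.07, c = 0.51)
  # n_s = 0: sin(-pi/4) = -sqrt(2)/2, so C(0) = 1 + (sqrt(2)-1) lambda / (2P)
  expect_equal(damped_orientation_profile(0, l, P, lam),
               1 + (sqrt(2) - 1) * lam / (2 * P))
  # long-separation plateau
  expect_equal(damped_orientation_profile(1e4, l, P, lam), 1 - lam / (2 * P))
  # first minimum located where the continuous profile is minimal
  fmin <- optimize(function(s) damped_orientation_profile(s, l, P, lam),
                   c(0, 5 * lam / l))
  expect_gt(fmin$minimum, 0)
  expect_lt(fmin$objective, 1 - lam / (2 * P))
  # stationarity of exp(-x) sin(x - pi/4) puts the first minimum at
  # n_s l = (pi/2) lambda
  expect_equal(fmin$minimum * l / lam, pi / 2, tolerance = 1e-4)
  expect_warning(damped_orientation_profile(1, l, P = 1, lambda = 4), "dips")
})

test_that("profile fit recovers planted parameters exactly without noise", {
  l <- 0.97; D <- 5.07
  lam <- deflection_length(19.61, D, c = 0.51)
  ns <- 0:60
  dat <- data.frame(n_s = ns,
                    C = damped_orientation_profile(ns, l, 19.61, lam))
  fit <- fit_orientation_profile(dat, l = l, D = D)
  expect_equal(fit$P, 19.61, tolerance = 1e-6)
  expect_equal(fit$c, 0.51, tolerance = 1e-6)
  expect_equal(fit$lambda, lam, tolerance = 1e-5)
})

test_that("profile fit recovers parameters within 5% under 1% noise", {
  l <- 0.97; D <- 5.07
  lam <- deflection_length(19.61, D, c = 0.51)
  ns <- 0:60
  clean <- damped_orientation_profile(ns, l, 19.61, lam)
  set.seed(123)
  P_hat <- c_hat <- numeric(100)
  for (k in 1:100) {
    noisy <- data.frame(n_s = ns, C = clean + rnorm(length(ns), sd = 0.01))
    fit <- fit_orientation_profile(noisy, l = l, D = D)
    P_hat[k] <- fit$P; c_hat[k] <- fit$c
  }
  expect_lt(abs(mean(P_hat) - 19.61) / 19.61, 0.05)
  expect_lt(abs(mean(c_hat) - 0.51) / 0.51, 0.05)
})

test_that("regime classification splits at P and P^2/w with ties to the stiffer regime", {
  expect_equal(classify_regime(19.7, 0.97, 5)$regime, "odijk")
  expect_equal(classify_regime(19.7, 0.97, 19.7)$regime, "odijk")   # tie
  expect_equal(classify_regime(19.7, 0.97, 100)$regime, "extended_degennes")
  expect_gt(classify_regime(19.7, 0.97, 100)$boundaries[["P2_over_w"]], 100)
  expect_equal(classify_regime(19.7, 0.97, 500)$regime, "classic_degennes")
  expect_equal(classify_regime(1, 0.97, 10)$regime, "classic_degennes")
  # slope schedules carry the expected blob statistics
  expect_equal(classify_regime(19.7, 0.97, 100)$sq_slopes[["blob"]], -2)
  expect_equal(classify_regime(19.7, 0.97, 500)$sq_slopes[["blob"]], -5 / 3)
  expect_equal(classify_regime(19.7, 0.97, 5)$sq_slopes[["rod"]], -1)
})
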