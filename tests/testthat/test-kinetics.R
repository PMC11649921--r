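test_that("the rate-equation integrator matches closed forms", {
  set.seed(21)
  n0 <- runif(101)
  # k*t = 0 is the identity
  expect_equal(ode_evolve(n0, k = 2, t_grid = c(0, 0))[2, ], n0)

  # a delta at 60 relaxes to a shifted (truncated) Poisson pattern
  delta <- rep(0, 101)
  delta[61] <- 1
  out <- ode_evolve(delta, k = 1, t_grid = c(0, 1))[2, ]
  i <- 0:60
  expect_equal(out[i + 1], exp(-1) / factorial(60 - i), tolerance = 1e-8)

  # mass above zero never increases (the zero bin drains out)
  tg <- seq(0, 10, by = 2)
  traj <- ode_evolve(n0, k = 1, t_grid = tg)
  mass <- rowSums(traj[, -1])
  expect_true(all(diff(mass) <= 1e-10))

  expect_error(ode_evolve(n0, k = -1, t_grid = c(0, 1)), "non-negative")
})

test_that("analytic evolution equals the ODE oracle and forms a semigroup", {
  set.seed(22)
  for (rep in 1:3) {
    n0 <- runif(251)^2
    for (a in c(0.5, 2, 5)) {
      xo <- ode_evolve(n0, k = 1, t_grid = c(0, a))[2, ]
      xa <- analytic_evolve(n0, a)
      expect_lt(max(abs(xo - xa)), 1e-8)
    }
    # semigroup: alpha1 then alpha2 equals alpha1 + alpha2
    s2 <- analytic_evolve(analytic_evolve(n0, 1.3), 2.2)
    expect_lt(max(abs(s2 - analytic_evolve(n0, 3.5))), 1e-8)
  }
  expect_equal(analytic_evolve(1:10, 0), as.numeric(1:10))
  expect_error(analytic_evolve(1:10, -1), "non-negative")
})

test_that("decapping protection attenuates short tails only", {
  n0 <- modgamma_profile(modgamma_params(3.7, 0.1))
  plain <- analytic_evolve(n0, 4)
  prot <- analytic_evolve(n0, 4, protected = TRUE)
  low <- 2:11  # bins 1..10
  expect_true(all(prot[low] < plain[low]))
  hi <- 61:81  # bins 60..80: protection factor within 1e-4 of 1
  expect_true(all(abs(prot[hi] / plain[hi] - 1) < 1e-4))
  # fixed-exponent variant decouples protection from elapsed time
  fixed <- analytic_evolve(n0, 4, protected = TRUE, protection_exponent = 2)
  expect_equal(fixed, plain * tanh(0.096 * (0:250))^2)
})

test_that("decay adjustment restores the absolute scale", {
  mk <- function(dens, t) structure(
    list(support = seq_along(dens) - 1L, counts = round(dens * 1e4),
         density = dens / sum(dens), n_reads = 1e4, label = "x",
         time_min = t), class = "tail_distribution")
  dens <- modgamma_profile(modgamma_params(3.7, 0.1))
  tps <- c(0, 4, 8)
  lam <- 0.15
  ser <- chase_series(tps, lapply(tps, mk, dens = dens),
                      recovery_coeff = exp(-lam * tps))
  adj <- adjust_for_decay(ser)
  tot <- vapply(adj$abs_levels, sum, numeric(1))
  expect_equal(tot, exp(-lam * tps), tolerance = 1e-6)
  # all-ones coefficients leave the series unchanged
  adj1 <- adjust_for_decay(chase_series(tps, lapply(tps, mk, dens = dens)))
  expect_equal(adj1$abs_levels[[2]], adj1$distributions[[2]]$density)
  # halving one coefficient halves that snapshot's levels
  half <- chase_series(tps, lapply(tps, mk, dens = dens),
                       recovery_coeff = c(1, 1, 0.5))
  expect_equal(adjust_for_decay(half)$abs_levels[[3]],
               adjust_for_decay(half)$abs_levels[[1]] * 0.5)
})

test_that("position half-lives recover the apparent rate and scale with k", {
  # noiseless constructed series: arm bins decay at exactly k*(1-e^-gamma)
  p <- modgamma_profile(modgamma_params(3.7, 0.1))
  mk <- function(x, t) structure(
    list(support = 0:250, counts = round(x * 1e6), density = x / sum(x),
         n_reads = 1e6, label = "x", time_min = t),
    class = "tail_distribution")
  series_for <- function(k) {
    tps <- c(0, 2, 4, 6, 8)
    evo <- lapply(tps, function(t) analytic_evolve(p, k * t,
                                                   protected = TRUE))
    ser <- chase_series(tps, Map(mk, evo, tps),
                        recovery_coeff = pmin(vapply(evo, sum, 1), 1))
    adjust_for_decay(ser)
  }
  k1 <- 10.9
  phl1 <- position_half_lives(series_for(k1), boot = 200, seed = 3)
  expect_equal(phl1$asymptote$rate_per_min, k1 * (1 - exp(-0.1)),
               tolerance = 0.02)
  phl2 <- position_half_lives(series_for(2 * k1), boot = 200, seed = 3)
  expect_equal(phl2$asymptote$half_life_s / phl1$asymptote$half_life_s, 0.5,
               tolerance = 0.05)
  expect_error(position_half_lives(series_for(k1)$distributions),
               "decay-adjusted")
})

test_that("the control's position on the depletion time axis is recovered", {
  dens <- modgamma_profile(modgamma_params(3.7, 0.1))
  mk <- function(t) structure(
    list(support = 0:250, counts = round(dens * 1e6), density = dens,
         n_reads = 1e6, label = "x", time_min = t),
    class = "tail_distribution")
  tps <- c(0, 3, 6, 9, 12, 15)
  lam <- 1.0
  eff <- ifelse(tps == 0, 2.67, tps)  # control sits on the trend at +2.67
  ser <- adjust_for_decay(chase_series(tps, lapply(tps, mk),
                                       recovery_coeff = pmin(exp(-lam * eff) /
                                                               max(exp(-lam * eff)),
                                                             1.5)))
  sh <- estimate_time_shift(ser)
  expect_equal(sh$shift_min, 2.67, tolerance = 0.02)
  expect_false(sh$boundary)

  # control identical to the t = 0 trend point: zero shift, boundary flagged
  ser0 <- adjust_for_decay(chase_series(tps, lapply(tps, mk),
                                        recovery_coeff = exp(-lam *
                                                               pmin(tps, 1.5)) /
                                          1))
  ser0$abs_levels <- lapply(tps, function(t) dens * exp(-lam * t))
  sh0 <- estimate_time_shift(ser0)
  expect_equal(sh0$shift_min, 0, tolerance = 1e-6)
  expect_true(sh0$boundary)
})

test_that("apparent-to-microscopic conversion follows the mass-ratio law", {
  expect_equal(apparent_to_microscopic(1.09, 0.1,
                                       small_gamma_approx = TRUE)$microscopic_rate,
               10.9)
  expect_equal(apparent_to_microscopic(1, log(2))$microscopic_rate, 2)
  expect_equal(apparent_to_microscopic(1, 20)$microscopic_rate, 1,
               tolerance = 1e-8)
  expect_error(apparent_to_microscopic(1, 0), "gamma_rate")

  # monotone decreasing in gamma_rate at fixed apparent rate
  ks <- vapply(c(0.05, 0.1, 0.2, 0.5),
               function(g) apparent_to_microscopic(1, g)$microscopic_rate,
               numeric(1))
  expect_true(all(diff(ks) < 0))

  # exact half-life / rate duality
  r <- apparent_to_microscopic(1.7, 0.1)
  expect_equal(r$adenosine_half_life_s * r$apparent_rate, 60 * log(2))
})

test_that("alpha matching identifies evolution rounds and the rate", {
  n0 <- modgamma_profile(modgamma_params(3.7, 0.1))
  k <- 10
  tps <- c(0, 0.2, 0.4, 0.6, 0.8)
  mk <- function(x, t) structure(
    list(support = 0:250, counts = round(x * 1e6), density = x / sum(x),
         n_reads = 1e6, label = "x", time_min = t),
    class = "tail_distribution")
  dists <- lapply(tps, function(t) {
    x <- analytic_evolve(n0, k * t, protected = TRUE)
    mk(x, t)
  })
  ser <- chase_series(tps, dists)
  am <- alpha_match(n0, ser, alpha_grid = seq(0, 15, by = 0.05))
  expect_equal(am$per_timepoint$alpha_best[1], 0)
  expect_gt(am$pearson_r, 0.99)
  expect_equal(am$slope_k, k, tolerance = 0.05)

  # identical duplicated snapshot: tie broken toward the smaller alpha
  ser2 <- chase_series(c(0, 1, 2), list(dists[[2]], dists[[2]], dists[[2]]))
  am2 <- alpha_match(n0, ser2, alpha_grid = seq(0, 15, by = 0.05),
                     refine = FALSE)
  expect_equal(am2$per_timepoint$alpha_best[2],
               am2$per_timepoint$alpha_best[3])
  expect_error(alpha_match(n0, ser, alpha_grid = numeric(0)), "empty")
})
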