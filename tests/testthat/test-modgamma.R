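test_that("the modified gamma density normalises and behaves at its limits", {
  for (par in list(c(3.7, 0.10), c(0.5, 0.02), c(10, 0.3), c(0, 0.1))) {
    p <- modgamma_params(par[1], par[2])
    expect_equal(sum(modgamma_profile(p)), 1, tolerance = 1e-9)
  }
  p <- modgamma_params(3.7, 0.1)
  expect_equal(modgamma_density(0, p), 0)
  expect_error(modgamma_density(251, p), "support")

  # shape 0 collapses to a discrete geometric profile
  g <- modgamma_params(0, 0.1)
  prof <- modgamma_profile(g)
  expect_equal(prof[2] / prof[1], exp(-0.1), tolerance = 1e-12)

  # right-arm geometric ratio e^-gamma_rate beyond one Pab1 footprint
  prof2 <- modgamma_profile(p)
  i <- 40:99
  ratios <- prof2[i + 2] / prof2[i + 1]
  expect_true(all(abs(ratios - exp(-0.1)) < 1e-3))
})

test_that("Pab1 protection saturates at one footprint", {
  expect_equal(round(pab1_protection(20), 2), 0.96)
  expect_true(all(pab1_protection(20:250) >= 0.95))
  expect_error(pab1_protection(-1), "non-negative")
})

test_that("fitting recovers generating parameters and flags bad input", {
  p <- modgamma_params(3.7, 0.10)
  set.seed(101)
  len <- rmodgamma(50000, p)
  d <- build_distribution(tail_table(data.frame(transcript_id = "X",
                                                tail_length = len)))
  fit <- fit_modgamma(d)
  expect_true(fit$fit$converged)
  expect_lt(abs(fit$gamma_shape - 3.7) / 3.7, 0.05)
  expect_lt(abs(fit$gamma_rate - 0.10) / 0.10, 0.05)

  # degenerate geometric family
  set.seed(102)
  leng <- rmodgamma(50000, modgamma_params(1e-9, 0.1))
  dg <- build_distribution(tail_table(data.frame(transcript_id = "X",
                                                 tail_length = leng)))
  fg <- fit_modgamma(dg)
  expect_lte(fg$gamma_shape, 0.1)

  one_bin <- build_distribution(tail_table(
    data.frame(transcript_id = "X", tail_length = rep(30, 100))))
  expect_error(fit_modgamma(one_bin), "support")
  few <- build_distribution(tail_table(
    data.frame(transcript_id = "X", tail_length = 1:20)))
  expect_error(fit_modgamma(few), "minimum reads")
})

test_that("refitting the model to its own density is idempotent", {
  p <- modgamma_params(2.8, 0.07)
  d <- structure(list(support = 0:250,
                      counts = round(modgamma_profile(p) * 1e6),
                      density = modgamma_profile(p), n_reads = 1e6,
                      label = "model", time_min = 0),
                 class = "tail_distribution")
  fit <- fit_modgamma(d, start = c(3.7, 0.1))
  expect_equal(fit$gamma_shape, 2.8, tolerance = 1e-3)
  expect_equal(fit$gamma_rate, 0.07, tolerance = 1e-4)
})

test_that("moments match the classical gamma limit and move as expected", {
  # classical gamma arises as beta -> 0 (tanh(beta*i) ~ beta*i)
  st <- distribution_stats(modgamma_params(3, 0.05, beta = 1e-4))
  expect_equal(st$mean, (3 + 1) / 0.05, tolerance = 0.02)

  m1 <- distribution_stats(modgamma_params(3.7, 0.05))$mean
  m2 <- distribution_stats(modgamma_params(3.7, 0.10))$mean
  expect_lt(m2, m1)

  p <- modgamma_params(3.7, 0.1)
  set.seed(103)
  len <- rmodgamma(20000, p)
  st2 <- distribution_stats(p)
  expect_equal(st2$mean, mean(len), tolerance = 0.02)
  expect_equal(st2$variance, stats::var(len), tolerance = 0.05)
})

test_that("log density of the right arm is affine with slope -gamma_rate", {
  p <- modgamma_params(3.7, 0.1)
  d <- structure(list(support = 0:250, counts = rep(1L, 251),
                      density = modgamma_profile(p), n_reads = 251,
                      label = "model", time_min = 0),
                 class = "tail_distribution")
  arm <- right_arm_slope(d, range = c(60, 90))
  expect_equal(arm$gamma_rate, 0.1, tolerance = 1e-3)
})

test_that("new-synthesis decomposition recovers the 40-60 A component", {
  p <- modgamma_params(3.7, 0.1)
  i <- 0:250
  peak <- stats::dnorm(log2(pmax(i, 1)), log2(50), 0.15) / pmax(i, 1)
  peak[1] <- 0
  peak <- peak / sum(peak)
  mix <- 0.8 * modgamma_profile(p) + 0.2 * peak
  d <- structure(list(support = i, counts = round(mix * 1e6), density = mix,
                      n_reads = 1e6, label = "ctrl", time_min = 0),
                 class = "tail_distribution")
  ns <- new_synthesis_residual(d, fit_modgamma(d))
  expect_equal(ns$fraction_new, 0.20, tolerance = 0.03)
  expect_gt(ns$mode, 40)
  expect_lt(ns$mode, 60)
  expect_equal(sum(ns$fitted_new_mrna), ns$fraction_new, tolerance = 1e-9)

  # the exact model leaves no component
  dm <- structure(list(support = i, counts = round(modgamma_profile(p) * 1e6),
                       density = modgamma_profile(p), n_reads = 1e6,
                       label = "m", time_min = 0),
                  class = "tail_distribution")
  ns0 <- new_synthesis_residual(dm, p)
  expect_equal(ns0$fraction_new, 0)

  # sampled data without new synthesis stays near zero
  spec0 <- chase_preset("mex67_chase", seed = 9, n_transcripts = 5,
                        abundance_top_n = 2, reads_per_transcript = 5000,
                        new_syn_fraction = 0)
  ctrl <- gen_transcriptome(spec0)
  d0 <- build_distribution(ctrl$table, label = "ctrl")
  ns1 <- new_synthesis_residual(d0, fit_modgamma(d0))
  expect_lte(ns1$fraction_new, 0.02)
})

test_that("parameter time trends are recovered and guarded", {
  const <- data.frame(time_min = c(0, 5, 10), gamma_shape = 3.7,
                      gamma_rate = 0.1)
  tr <- fit_param_trend(const)
  expect_equal(tr$gamma_shape$slope, 0)
  expect_equal(tr$gamma_rate$intercept, 0.1)
  p5 <- predict(tr, 5)
  expect_equal(p5$gamma_shape, 3.7)
  expect_false(attr(p5, "extrapolated"))
  expect_true(attr(predict(tr, 50), "extrapolated"))

  set.seed(104)
  tt <- seq(0, 15, by = 3)
  noisy <- data.frame(time_min = tt,
                      gamma_shape = 3.7 - 0.05 * tt + rnorm(6, sd = 0.05),
                      gamma_rate = 0.1 + 0.004 * tt + rnorm(6, sd = 0.003))
  tr2 <- fit_param_trend(noisy)
  expect_lt(abs(tr2$gamma_shape$slope - (-0.05)),
            2 * tr2$gamma_shape$se_slope + 1e-12)
  expect_lt(abs(tr2$gamma_rate$slope - 0.004),
            2 * tr2$gamma_rate$se_slope + 1e-12)

  expect_error(fit_param_trend(const[1:2, ]), ">= 3")
})
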