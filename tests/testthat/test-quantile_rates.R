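test_that("quantiles use linear interpolation and the minimum-read rule", {
  q <- compute_quantiles(seq(10, 100, by = 10), levels = 50)
  expect_equal(q$q50, 55)

  q9 <- compute_quantiles(1:9, levels = c(50, 95))
  expect_true(is.na(q9$q50) && is.na(q9$q95))
  expect_equal(q9$flag, "low_reads")

  set.seed(31)
  p <- modgamma_params(3.7, 0.1)
  len <- rmodgamma(10000, p)
  q95 <- compute_quantiles(len, levels = 95)$q95
  cdf <- cumsum(modgamma_profile(p))
  q95_true <- which(cdf >= 0.95)[1] - 1
  expect_lt(abs(q95 - q95_true), 1)

  # monotone in level
  qs <- compute_quantiles(len)
  vals <- as.numeric(qs[1, paste0("q", c(5, 10, 15, 50, 75, 80, 85, 90, 95))])
  expect_true(all(diff(vals) >= 0))

  expect_error(compute_quantiles(len, levels = c(0, 50)), "\\(0, 100\\)")
})

test_that("quantile deadenylation rates follow the pairwise log formula", {
  # value halves every minute at every level: relative coefficient ln 2
  tps <- 0:3
  series <- do.call(rbind, lapply(c(75, 80, 85, 90, 95), function(lv)
    data.frame(time_min = tps, level = lv, value = 64 * 2^(-tps),
               n_reads = 100)))
  dr <- quantile_deadenylation_rate(series)
  expect_equal(dr$rel_coeff_per_min, log(2), tolerance = 1e-12)
  # per-adenosine rate = coeff * geometric-mean length of each interval
  expect_equal(dr$terminal_adenosine_half_life_s * dr$deadenylation_coeff,
               60 * log(2))

  # constant values: zero coefficient, half-life unreportable
  const <- do.call(rbind, lapply(c(75, 95), function(lv)
    data.frame(time_min = tps, level = lv, value = 50, n_reads = 100)))
  dc <- quantile_deadenylation_rate(const, upper_levels = c(75, 95))
  expect_equal(dc$deadenylation_coeff, 0)
  expect_true(is.na(dc$terminal_adenosine_half_life_s))
  expect_equal(dc$flag, "nonpositive_rate")

  # values above the control are removed before pairing
  s <- data.frame(time_min = c(0, 1, 2, 3), level = 95,
                  value = c(50, 60, 40, 32), n_reads = 100)
  dr2 <- quantile_deadenylation_rate(s, upper_levels = 95)
  # intervals used: 0->2 and 2->3 (the t=1 rise above 50 is dropped)
  expect_equal(dr2$n_intervals, 2L)
  expect_equal(dr2$rel_coeff_per_min,
               mean(c(log(50 / 40) / 2, log(40 / 32) / 1)))
})

test_that("decay rates respect the control shift and reference filter", {
  ab <- data.frame(time_min = c(0, 10, 20), level = c(100, 50, 25))
  d <- decay_rate(ab)
  expect_equal(d$mrna_half_life_min, 10)
  expect_equal(d$decay_coeff * d$mrna_half_life_min, log(2))

  # an above-control excursion contributes no interval
  ab2 <- data.frame(time_min = c(0, 10, 20, 30),
                    level = c(100, 120, 50, 25))
  d2 <- decay_rate(ab2)
  expect_equal(d2$n_intervals, 2L)  # 0->20, 20->30

  # forward control shift shortens the first interval
  pol <- filter_policy(control_time_shift_min = 2.67)
  d3 <- decay_rate(ab, policy = pol)
  expect_equal(d3$decay_coeff,
               mean(c(log(2) / (10 - 2.67), log(2) / 10)))
  expect_error(decay_rate(data.frame(time_min = c(0, 2), level = c(2, 1)),
                          policy = pol), "not smaller")
})

test_that("decay estimates are accurate across seeded replicates", {
  lam <- 0.0693
  tps <- c(0, 5, 10, 15, 20)
  set.seed(32)
  hl <- replicate(50, {
    counts <- rpois(length(tps), 5000 * exp(-lam * tps))
    decay_rate(data.frame(time_min = tps,
                          level = pmax(counts, 0.01)))$mrna_half_life_min
  })
  expect_equal(mean(hl), 10, tolerance = 0.05)
  expect_true(all(abs(hl - 10) < 1.5))
})

test_that("the rate table averages replicates and honours the filters", {
  small <- small_chase_fixture()
  ch <- small$chase
  reps <- lapply(ch$replicates, function(rep) {
    ab <- normalize_abundance(
      stats::setNames(rep$counts,
                      vapply(rep$tables, attr, "", "sample_id")),
      scale_mode = "none",
      time_min = vapply(rep$tables, attr, numeric(1), "time_min"))
    ab$level <- ab$norm_level
    list(tables = rep$tables, abundance = ab)
  })
  rates <- transcript_rate_table(reps)
  expect_s3_class(rates, "transcript_rates")
  expect_equal(rates$transcript_id, sort(rates$transcript_id))
  # ln 2 duality wherever both members are reported
  ok <- is.finite(rates$deadenylation_coeff) &
    is.finite(rates$terminal_adenosine_half_life_s)
  expect_equal(rates$terminal_adenosine_half_life_s[ok] *
                 rates$deadenylation_coeff[ok],
               rep(60 * log(2), sum(ok)))
  okd <- is.finite(rates$decay_coeff) & is.finite(rates$mrna_half_life_min)
  expect_equal(rates$mrna_half_life_min[okd] * rates$decay_coeff[okd],
               rep(log(2), sum(okd)))

  # restricting to a membership list drops everything else
  pol <- filter_policy(down_regulated_only = rates$transcript_id[1:2])
  r2 <- transcript_rate_table(reps, policy = pol)
  expect_equal(r2$transcript_id, rates$transcript_id[1:2])
})

test_that("no rate is computed from reads below the minimum-count filter", {
  # one transcript stays below 10 reads at every timepoint
  tps <- c(0, 5, 10)
  mk_rep <- function(seed) {
    set.seed(seed)
    tabs <- lapply(tps, function(t) {
      big <- data.frame(transcript_id = "BIG",
                        tail_length = rmodgamma(200,
                                                modgamma_params(3.7, 0.1)))
      tiny <- data.frame(transcript_id = "TINY",
                         tail_length = runif(9, 20, 60))
      tail_table(rbind(big, tiny), sample_id = sprintf("t%g", t),
                 time_min = t)
    })
    ab <- data.frame(time_min = rep(tps, each = 2),
                     transcript_id = rep(c("BIG", "TINY"), 3),
                     level = rep(c(200, 9), 3))
    list(tables = tabs, abundance = ab)
  }
  rates <- transcript_rate_table(list(rep1 = mk_rep(33)))
  tiny <- rates[rates$transcript_id == "TINY", ]
  expect_true(is.na(tiny$deadenylation_coeff))
  expect_true(grepl("no_usable_intervals", tiny$flags))
  expect_equal(tiny$n_reps_deadenylation, 0L)
})

test_that("group summaries report medians and rank correlations", {
  rates <- data.frame(transcript_id = sprintf("T%02d", 1:20),
                      deadenylation_coeff = (1:20) / 10,
                      rel_coeff_per_min = (1:20) / 100,
                      terminal_adenosine_half_life_s = 60 * log(2) /
                        ((1:20) / 10),
                      decay_coeff = (1:20) / 10,
                      mrna_half_life_min = log(2) / ((1:20) / 10),
                      stringsAsFactors = FALSE)
  gs <- group_summary(rates, groups = list(low = sprintf("T%02d", 1:5),
                                           single = "T10"))
  expect_equal(gs$correlation$rho, 1)
  expect_equal(gs$groups$flag[gs$groups$group == "single"],
               "single_transcript")
  expect_equal(gs$groups$median_deadenylation_coeff[gs$groups$group == "low"],
               0.3)
  expect_warning(group_summary(rates, groups = list(none = "ZZZ")),
                 "matched no transcripts")

  # decay = deadenylation + noise: rho near its construction value
  set.seed(34)
  x <- rlnorm(150)
  y <- x * exp(rnorm(150, sd = 0.3))
  r0 <- cor(x, y, method = "spearman")
  rates2 <- data.frame(transcript_id = sprintf("S%03d", 1:150),
                       deadenylation_coeff = x, decay_coeff = y)
  gs2 <- group_summary(rates2)
  expect_equal(gs2$correlation$rho, r0, tolerance = 1e-9)
  expect_lt(gs2$correlation$p_value, 1e-6)
})
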