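#' Bundle a chase time series of tail-length distributions
#'
#' @param timepoints strictly increasing chase times, minutes (control = 0).
#' @param distributions list of `tail_distribution`, one per timepoint.
#' @param recovery_coeff per-timepoint fraction of polyadenylated RNA
#'   recovered relative to control (dimensionless, in (0, 1.5]); the handle by
#'   which internally-normalised snapshots are put back on an absolute,
#'   decay-aware scale.
#' @param replicate_id replicate label.
#' @return A `chase_series` object.
#' @export
chase_series <- function(timepoints, distributions,
                         recovery_coeff = rep(1, length(timepoints)),
                         replicate_id = "rep1") {
  stopifnot(length(timepoints) == length(distributions),
            length(timepoints) == length(recovery_coeff))
  if (any(diff(timepoints) <= 0))
    stop_tc("timepoints must be strictly increasing")
  if (any(!is.finite(recovery_coeff) | recovery_coeff <= 0 |
            recovery_coeff > 1.5))
    stop_tc("recovery_coeff must lie in (0, 1.5]")
  lens <- vapply(distributions, function(d) length(d$support), integer(1))
  if (length(unique(lens)) != 1) stop_tc("distributions on mismatched supports")
  structure(list(timepoints = timepoints, distributions = distributions,
                 recovery_coeff = recovery_coeff,
                 replicate_id = replicate_id),
            class = "chase_series")
}

#' Numerically integrate the coupled deadenylation rate equations
#'
#' The population `x_i` of tails of length `i` obeys
#' `dx_i/dt = -k*x_i + k*x_{i+1}` with `x_{N+1} = 0`: each length loses mass
#' to the next shorter length at the microscopic rate `k`, and the zero-length
#' bin drains out of the system (shortened-to-nothing RNAs are degraded, so no
#' short-tail pile-up). Serves as the brute-force oracle for
#' [analytic_evolve()].
#'
#' @param n0 initial populations: numeric vector over lengths `0..N` or a
#'   `tail_distribution` (its counts are used).
#' @param k microscopic deadenylation rate, adenosines/min; must be positive.
#' @param t_grid times (minutes) at which to report, starting at 0.
#' @param rtol,atol integrator tolerances.
#' @return Matrix with one row per time in `t_grid`, columns = lengths 0..N.
#' @export
ode_evolve <- function(n0, k, t_grid, rtol = 1e-12, atol = 1e-14) {
  x0 <- as_level_vector(n0)
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k < 0)
    stop_tc("'k' must be a single non-negative rate")
  rhs <- function(t, x, parms) {
    list(-k * x + k * c(x[-1], 0))
  }
  sol <- deSolve::ode(y = x0, times = t_grid, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  out <- unname(sol[, -1, drop = FALSE])
  colnames(out) <- NULL
  out
}

# binning kernel of multiplicative log-normal measurement noise: column i
# holds the probability that a true length i is recorded (after half-up
# rounding) in each observed bin
#' @noRd
noise_blur_matrix <- function(n_max, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  i <- 0:n_max
  K <- matrix(0, n_max + 1L, n_max + 1L)
  for (src in seq_len(n_max)) {
    ub <- stats::pnorm((log((i + 0.5) / src) + sdlog^2 / 2) / sdlog)
    lb <- stats::pnorm((log(pmax(i - 0.5, 0) / src) + sdlog^2 / 2) / sdlog)
    lb[1] <- 0
    K[, src + 1L] <- ub - lb
    K[n_max + 1L, src + 1L] <- K[n_max + 1L, src + 1L] +
      (1 - ub[n_max + 1L])  # clamp at the support edge
  }
  K[1, 1] <- 1
  K
}

#' @noRd
as_level_vector <- function(n0) {
  if (inherits(n0, "tail_distribution")) as.numeric(n0$counts) else
    as.numeric(n0)
}

#' Closed-form Poisson-convolution evolution of a tail distribution
#'
#' Analytic solution of the coupled rate equations: after `alpha = k*t`
#' rounds of virtual deadenylation,
#' `x_i = e^-alpha * sum_j n_j * alpha^(j-i) / (j-i)!`.
#' With `protected = TRUE`, short tails are additionally attenuated by the
#' Pab1-protection factor `tanh(beta*i)^alpha`, representing accelerated
#' decapping-decay of tails that have lost their last Pab1.
#'
#' @param n0 initial populations (numeric vector over `0..N` or a
#'   `tail_distribution`).
#' @param alpha dimensionless number of deadenylation rounds, `k*t`; >= 0.
#' @param protected apply the decapping-protection prefactor.
#' @param beta Pab1 interaction strength.
#' @param protection_exponent exponent on the protection factor; default
#'   `"alpha"` follows the closed form verbatim, a fixed number decouples
#'   protection strength from elapsed time.
#' @return Numeric vector of evolved populations on the same scale as `n0`
#'   (total mass is not conserved: shortened-out and decapped RNA leaves).
#' @export
analytic_evolve <- function(n0, alpha, protected = FALSE, beta = 0.096,
                            protection_exponent = "alpha") {
  x <- as_level_vector(n0)
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) ||
        alpha < 0)
    stop_tc("'alpha' must be a single non-negative number")
  N <- length(x) - 1L
  if (alpha == 0) {
    out <- x
  } else {
    pm <- stats::dpois(0:N, alpha)
    out <- numeric(N + 1L)
    for (m in 0:N) {
      if (pm[m + 1L] == 0) next
      idx <- 1:(N + 1L - m)
      out[idx] <- out[idx] + pm[m + 1L] * x[idx + m]
    }
  }
  if (protected) {
    expo <- if (identical(protection_exponent, "alpha")) alpha else
      assert_scalar_num(protection_exponent, "protection_exponent", lower = 0)
    if (expo > 0) out <- out * tanh(beta * (0:N))^expo
  }
  out
}

#' Put chase snapshots on an absolute, decay-aware scale
#'
#' Tail-length profiles are internally normalised within each snapshot and so
#' carry no information about the shrinking size of the polyadenylated pool.
#' Multiplying each snapshot's profile by its recovery coefficient restores an
#' absolute scale on which per-position exponential decay can be fitted.
#'
#' @param series a `chase_series` with recovery coefficients.
#' @return The series with an `abs_levels` element: one numeric vector per
#'   timepoint, `density * recovery_coeff`. Densities are left untouched.
#' @export
adjust_for_decay <- function(series) {
  stopifnot(inherits(series, "chase_series"))
  if (length(series$recovery_coeff) != length(series$timepoints) ||
        any(is.na(series$recovery_coeff)))
    stop_tc("missing recovery coefficient")
  series$abs_levels <- Map(function(d, r) d$density * r,
                           series$distributions, series$recovery_coeff)
  series
}

#' Per-position adenosine half-lives and their asymptote
#'
#' For each adenosine rank `i` the decay-adjusted level `x_i(t)` is fitted by
#' log-linear least squares over the chase; the per-position half-life falls
#' with position and converges, over the window where resupply from longer
#' tails is minimal, to an asymptote: the transcriptomic terminal-adenosine
#' half-life. An exponential-plus-asymptote curve is fitted across positions
#' and a bootstrap over window positions gives the CI.
#'
#' @param series a decay-adjusted `chase_series` (see [adjust_for_decay()]).
#' @param positions adenosine ranks to fit (default 1..80).
#' @param window inclusive position range whose half-lives define the
#'   asymptote (default 40..80).
#' @param include_control include the t = 0 snapshot in the per-position
#'   fits. Off by default: the control is off-trend both through its
#'   newly-synthesised tail component and through the depletion-onset lag
#'   (see [estimate_time_shift()]), so the exponential trends are fitted on
#'   depletion timepoints only.
#' @param min_points minimum usable timepoints per position.
#' @param boot bootstrap resamples over window positions for the CI.
#' @param seed RNG seed for the bootstrap.
#' @return A `position_half_lives` object: data.frame `per_position`
#'   (`position`, `rate_per_min`, `half_life_s`, `se_log_rate`, `n_t`),
#'   `asymptote` list (`half_life_s`, `rate_per_min`, `ci_low_s`, `ci_high_s`),
#'   and the exponential-curve fit when it converged.
#' @export
position_half_lives <- function(series, positions = 1:80,
                                window = c(40, 80), include_control = FALSE,
                                min_points = 3, boot = 1000, seed = 1) {
  if (is.null(series$abs_levels))
    stop_tc("series is not decay-adjusted; call adjust_for_decay() first")
  tt <- series$timepoints
  lev <- do.call(cbind, series$abs_levels)  # bins x timepoints
  if (!include_control && sum(tt > 0) >= 3) {
    keep_t <- tt > 0
    lev <- lev[, keep_t, drop = FALSE]
    tt <- tt[keep_t]
  }
  if (length(tt) < 3) stop_tc("need >= 3 timepoints")
  per <- lapply(positions, function(p) {
    y <- lev[p + 1L, ]
    ok <- is.finite(y) & y > 0
    if (sum(ok) < min_points) return(NULL)
    fit <- stats::lm(log(y[ok]) ~ tt[ok])
    co <- summary(fit)$coefficients
    rate <- -unname(co[2, 1])
    if (!is.finite(rate) || rate <= 0) return(NULL)
    data.frame(position = p, rate_per_min = rate,
               half_life_s = 60 * log(2) / rate,
               se_log_rate = unname(co[2, 2]), n_t = sum(ok))
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0)
    stop_tc("no position had enough positive levels to fit")
  inwin <- per$position >= window[1] & per$position <= window[2]
  if (!any(inwin)) stop_tc("no fitted positions inside the window")
  hw <- per$half_life_s[inwin]
  # Descriptive exponential approach to an asymptote across positions
  # (amplitude sign free: resupply-dominated data approach from above,
  # protection-eroded data from below). The reported asymptote is the mean
  # over the window, where resupply from longer tails is minimal.
  curve_fit <- tryCatch({
    fn <- function(par) par[1] + par[2] * exp(-per$position / par[3]) -
      per$half_life_s
    f <- minpack.lm::nls.lm(par = c(mean(hw),
                                    per$half_life_s[1] - mean(hw), 10),
                            lower = c(0, -Inf, 0.5),
                            upper = c(Inf, Inf, 200), fn = fn)
    if (f$info %in% 1:4) list(asymptote_s = f$par[1], amplitude_s = f$par[2],
                              scale_pos = f$par[3]) else NULL
  }, error = function(e) NULL)
  asym_s <- mean(hw)
  ci <- with_seed(seed, {
    bs <- vapply(seq_len(boot), function(b)
      mean(hw[sample.int(length(hw), replace = TRUE)]), numeric(1))
    stats::quantile(bs, c(0.025, 0.975), names = FALSE)
  })
  structure(list(per_position = per,
                 asymptote = list(half_life_s = asym_s,
                                  rate_per_min = 60 * log(2) / asym_s,
                                  window_mean_s = mean(hw),
                                  ci_low_s = ci[1], ci_high_s = ci[2]),
                 curve = curve_fit, window = window),
            class = "position_half_lives")
}

#' @export
print.position_half_lives <- function(x, ...) {
  cat(sprintf(paste0("<position_half_lives> %d positions; asymptote %.1f s ",
                     "(95%% CI %.1f-%.1f), apparent rate %.3f /min\n"),
              nrow(x$per_position), x$asymptote$half_life_s,
              x$asymptote$ci_low_s, x$asymptote$ci_high_s,
              x$asymptote$rate_per_min))
  invisible(x)
}

#' Position of the control sample on the depletion time axis
#'
#' Depletion phenotypes take a finite time to establish, so the control sample
#' sits not at the depletion clock's zero but some way along the fitted decay
#' trend. Per-position exponential trends are fitted on the depletion
#' timepoints only (t > 0); the returned shift is the forward offset `s >= 0`
#' minimising the squared log-residuals of the control levels against those
#' trends, i.e. the control's effective position on the depletion time scale.
#'
#' @param series a decay-adjusted `chase_series` whose first timepoint (t = 0)
#'   is the control.
#' @param positions adenosine ranks used.
#' @param grid candidate shifts, minutes.
#' @return List: `shift_min`, `sse`, `boundary` (TRUE when the optimum sits on
#'   the grid edge, a diagnostic for an ill-covered grid).
#' @export
estimate_time_shift <- function(series, positions = 40:80,
                                grid = seq(0, 10, by = 0.01)) {
  if (is.null(series$abs_levels)) stop_tc("series is not decay-adjusted")
  tt <- series$timepoints
  dep <- which(tt > 0)
  if (length(dep) < 2) stop_tc("need >= 2 depletion timepoints")
  ctrl <- which(tt == 0)
  if (length(ctrl) != 1) stop_tc("exactly one control (t = 0) expected")
  lev <- do.call(cbind, series$abs_levels)
  trends <- lapply(positions, function(p) {
    y <- lev[p + 1L, dep]
    ok <- is.finite(y) & y > 0
    if (sum(ok) < 2) return(NULL)
    fit <- stats::lm(log(y[ok]) ~ tt[dep][ok])
    c(a = unname(stats::coef(fit)[1]), lam = -unname(stats::coef(fit)[2]),
      c0 = lev[p + 1L, ctrl])
  })
  trends <- do.call(rbind, trends)
  trends <- trends[is.finite(trends[, "c0"]) & trends[, "c0"] > 0 &
                     trends[, "lam"] > 0, , drop = FALSE]
  if (is.null(trends) || nrow(trends) == 0)
    stop_tc("no overlap window: no usable positions")
  sse <- vapply(grid, function(s)
    sum((log(trends[, "c0"]) - (trends[, "a"] - trends[, "lam"] * s))^2),
    numeric(1))
  ibest <- which.min(sse)
  # parabolic refinement inside the grid
  shift <- grid[ibest]
  if (ibest > 1 && ibest < length(grid)) {
    o <- stats::optimize(function(s)
      sum((log(trends[, "c0"]) - (trends[, "a"] - trends[, "lam"] * s))^2),
      interval = grid[c(ibest - 1, ibest + 1)])
    shift <- o$minimum
  }
  list(shift_min = shift, sse = min(sse),
       boundary = ibest %in% c(1L, length(grid)))
}

#' Convert an apparent deadenylation rate to the microscopic enzymatic rate
#'
#' In a mixed population the loss of tails of length `i` is partly refilled by
#' deadenylation of tails one adenosine longer, so a population-level fit sees
#' only `R_app = R * (1 - e^-gamma_rate)` where `e^-gamma_rate` is the
#' abundance ratio of adjacent tail lengths on the distribution's right arm.
#' Inverting this gives the microscopic rate; with the small-rate
#' approximation `1 - e^-gamma ~ gamma` the correction is a plain division by
#' `gamma_rate` (at `gamma_rate = 0.1`, a ~10-fold increase).
#'
#' @param R_app apparent rate, adenosines/min; > 0.
#' @param gamma_rate right-arm geometric parameter; > 0.
#' @param small_gamma_approx use `1 - e^-gamma ~ gamma`.
#' @param ci optional `c(low, high)` CI on `R_app`, scaled multiplicatively.
#' @return A `rate_estimate` list: `apparent_rate`, `microscopic_rate`,
#'   `gamma_rate_used`, `adenosine_half_life_s` (= 60 ln2 / apparent rate),
#'   `ci_low`, `ci_high` (microscopic scale), `small_gamma_approx`.
#' @export
apparent_to_microscopic <- function(R_app, gamma_rate,
                                    small_gamma_approx = FALSE, ci = NULL) {
  assert_scalar_num(R_app, "R_app", lower = 0, allow_equal = FALSE)
  if (!is.numeric(gamma_rate) || length(gamma_rate) != 1 ||
        !is.finite(gamma_rate) || gamma_rate <= 0)
    stop_tc("'gamma_rate' must be > 0 (zero mass ratio is degenerate)")
  fac <- if (small_gamma_approx) 1 / gamma_rate else
    1 / (1 - exp(-gamma_rate))
  out <- list(apparent_rate = R_app, microscopic_rate = R_app * fac,
              gamma_rate_used = gamma_rate,
              adenosine_half_life_s = 60 * log(2) / R_app,
              ci_low = if (!is.null(ci)) ci[1] * fac else NA_real_,
              ci_high = if (!is.null(ci)) ci[2] * fac else NA_real_,
              small_gamma_approx = small_gamma_approx)
  class(out) <- "rate_estimate"
  out
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf(paste0("<rate_estimate> apparent %.3f A/min (half-life %.1f s),",
                     " microscopic %.2f A/min (gamma_rate %.4f%s)\n"),
              x$apparent_rate, x$adenosine_half_life_s, x$microscopic_rate,
              x$gamma_rate_used,
              if (x$small_gamma_approx) ", small-gamma approx" else ""))
  invisible(x)
}

#' Match observed chase snapshots to virtual deadenylation rounds
#'
#' Each observed timepoint is compared with the initial distribution evolved
#' over a grid of `alpha` values (virtual deadenylation rounds, `alpha = k*t`);
#' the best-matching `alpha` per timepoint, regressed on chase time, estimates
#' the microscopic rate `k` as its slope, and the Pearson correlation of
#' `alpha_best` with time measures how well a constant rate explains the data.
#'
#' @param initial_dist initial profile (numeric density vector, a
#'   `tail_distribution`, or `modgamma_params`).
#' @param observed_series a `chase_series` (densities are compared).
#' @param alpha_grid candidate alpha values; may be coarse, see `refine`.
#' @param metric `"sse"` (default; minimal summed squared density difference)
#'   or `"pearson"` (maximal correlation of densities).
#' @param protected evolve with the decapping-protection prefactor.
#' @param refine continuously refine `alpha_best` inside the bracketing grid
#'   interval (recommended for coarse grids).
#' @param noise_cv coefficient of variation of the multiplicative tail-length
#'   measurement noise; when positive, candidate profiles are convolved with
#'   the corresponding log-normal binning kernel before comparison, so that a
#'   sharp model feature (the protection-erosion edge) is not matched against
#'   blurred observations. 0 disables the convolution.
#' @param include_t0 match the t = 0 snapshot too (its alpha is ~0 by
#'   construction when the series starts from `initial_dist`).
#' @return An `alpha_match` object: data.frame `per_timepoint`
#'   (`time_min`, `alpha_best`, `score`, `boundary`, `tied`), `slope_k`
#'   (adenosines/min), `pearson_r`, plus the settings used.
#' @export
alpha_match <- function(initial_dist, observed_series,
                        alpha_grid = seq(0, 15, by = 0.05),
                        metric = c("sse", "pearson"), protected = TRUE,
                        refine = TRUE, noise_cv = 0, include_t0 = TRUE) {
  metric <- match.arg(metric)
  if (!length(alpha_grid)) stop_tc("empty alpha grid")
  alpha_grid <- sort(unique(alpha_grid))
  n0 <- if (inherits(initial_dist, "modgamma_params"))
    modgamma_profile(initial_dist) else as_level_vector(initial_dist)
  n0 <- n0 / sum(n0)
  blur <- if (noise_cv > 0) noise_blur_matrix(length(n0) - 1L, noise_cv)
  tt <- observed_series$timepoints
  keep <- if (include_t0) seq_along(tt) else which(tt > 0)
  score_one <- function(alpha, y) {
    x <- analytic_evolve(n0, alpha, protected = protected)
    if (!is.null(blur)) x <- as.vector(blur %*% x)
    x <- x / sum(x)
    if (metric == "sse") sum((x - y)^2) else -suppressWarnings(
      stats::cor(x, y))
  }
  rows <- lapply(keep, function(j) {
    y <- observed_series$distributions[[j]]$density
    sc <- vapply(alpha_grid, score_one, numeric(1), y = y)
    ib <- which(sc == min(sc))
    tied <- length(ib) > 1
    ib <- ib[1]  # ties broken toward the smaller alpha
    ab <- alpha_grid[ib]
    if (refine && ib > 1 && ib < length(alpha_grid)) {
      o <- stats::optimize(score_one, y = y,
                           interval = alpha_grid[c(ib - 1, ib + 1)])
      if (o$objective < sc[ib]) ab <- o$minimum
    }
    data.frame(time_min = tt[j], alpha_best = ab,
               score = min(sc), boundary = ib %in% c(1L, length(alpha_grid)) &&
                 tt[j] > 0 && ib == length(alpha_grid),
               tied = tied)
  })
  per <- do.call(rbind, rows)
  slope <- pearson <- NA_real_
  if (sum(per$time_min > 0) >= 2) {
    fit <- stats::lm(alpha_best ~ time_min, data = per)
    slope <- unname(stats::coef(fit)[2])
    pearson <- suppressWarnings(stats::cor(per$time_min, per$alpha_best))
  }
  structure(list(per_timepoint = per, slope_k = slope, pearson_r = pearson,
                 metric = metric, protected = protected),
            class = "alpha_match")
}

#' @export
print.alpha_match <- function(x, ...) {
  cat(sprintf("<alpha_match> %d timepoints; slope k = %.2f A/min, Pearson r = %.3f\n",
              nrow(x$per_timepoint), x$slope_k, x$pearson_r))
  invisible(x)
}
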