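# Workflow entry points tying the modules into the three analysis paths
# (profile fitting, population kinetics, per-transcript rates) plus the
# synthetic-data writer. Each run validates its configuration up front,
# writes a machine-readable provenance block next to its outputs, and is
# deterministic given inputs and seed. The same functions back the
# `inst/cli/tailchase` command-line wrapper.

run_config_keys <- c("run_dir", "out_dir", "seed", "preset", "min_reads",
                     "beta", "support_max", "quantiles", "shift_min",
                     "alpha_max", "alpha_step", "arm_range", "noise_cv",
                     "abundance_scale", "qc_policy", "dry_run",
                     "groups", "down_regulated_only", "timepoints",
                     "n_transcripts", "reads_per_transcript", "verbose")

#' Build and validate a workflow configuration
#'
#' @param ... configuration fields; unknown keys are rejected. Recognised:
#'   `run_dir` (chase run directory), `out_dir`, `seed`, `preset`,
#'   `min_reads`, `beta`, `support_max`, `quantiles`, `shift_min`,
#'   `alpha_max`, `alpha_step`, `qc_policy`, `dry_run`, `groups`,
#'   `down_regulated_only`, `timepoints`, `n_transcripts`,
#'   `reads_per_transcript`, `verbose`.
#' @return A validated `run_config` list with defaults filled in.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1 && is.list(cfg[[1]]) && is.null(names(cfg)))
    cfg <- cfg[[1]]
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stop_tc("unknown config key(s): %s", paste(unknown, collapse = ", "))
  defaults <- list(out_dir = ".", seed = 1L, min_reads = 10, beta = 0.096,
                   support_max = 250, quantiles = default_quantile_levels,
                   shift_min = 0, alpha_max = 15, alpha_step = 0.05,
                   qc_policy = "PASS", dry_run = FALSE, verbose = TRUE)
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  assert_scalar_num(cfg$min_reads, "min_reads", lower = 1)
  assert_scalar_num(cfg$beta, "beta", lower = 0, allow_equal = FALSE)
  assert_scalar_num(cfg$support_max, "support_max", lower = 1)
  assert_scalar_num(cfg$shift_min, "shift_min", lower = 0)
  structure(cfg, class = "run_config")
}

#' @noRd
msg <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(fmt, ...))
}

#' @noRd
write_provenance <- function(cfg, out_dir, what) {
  pv <- list(tool = "tailchase", what = what,
             version = as.character(utils::packageVersion("tailchase")),
             r_version = as.character(getRversion()),
             seed = cfg$seed, config = unclass(cfg))
  jsonlite::write_json(pv, file.path(out_dir, paste0(what, ".provenance.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' @noRd
dry_run_echo <- function(cfg, what) {
  cat(sprintf("[dry-run] %s\n", what))
  utils::str(unclass(cfg))
  invisible(NULL)
}

#' Generate and write a synthetic chase run
#'
#' @param cfg a [run_config()] with `preset` (and optional overrides
#'   `timepoints`, `n_transcripts`, `reads_per_transcript`), `out_dir`,
#'   `seed`.
#' @return The run directory, invisibly (`NULL` on dry-run).
#' @export
run_synth <- function(cfg) {
  cfg <- as_run_config(cfg)
  if (isTRUE(cfg$dry_run)) return(dry_run_echo(cfg, "synth"))
  over <- list()
  for (nm in c("timepoints", "n_transcripts", "reads_per_transcript"))
    if (!is.null(cfg[[nm]])) over[[nm]] <- cfg[[nm]]
  spec <- do.call(chase_preset,
                  c(list(name = cfg$preset %||% "mex67_chase",
                         seed = cfg$seed), over))
  chase <- gen_chase(spec)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_chase(chase, cfg$out_dir)
  write_provenance(cfg, cfg$out_dir, "synth")
  msg(cfg, "synth: %d transcripts, k median %.2f A/min, gamma_rate %.3f, %s",
      spec$n_transcripts, stats::median(spec$transcripts$k),
      spec$gamma_rate, cfg$out_dir)
  invisible(cfg$out_dir)
}

#' @noRd
as_run_config <- function(cfg) {
  if (inherits(cfg, "run_config")) cfg else run_config(cfg)
}

#' @noRd
load_run <- function(cfg) {
  if (is.null(cfg$run_dir)) stop_tc("config needs 'run_dir'")
  if (!dir.exists(cfg$run_dir)) stop_tc("run directory not found: %s",
                                        cfg$run_dir)
  read_chase(cfg$run_dir, qc_policy = cfg$qc_policy)
}

#' Fit modified gamma profiles across a chase and their time trends
#'
#' Pools reads per replicate and timepoint into whole-transcriptome
#' distributions, fits the tail-profile law to each, fits linear time trends
#' of the parameters, and writes parameter, trend and reconstructed-density
#' tables.
#'
#' @param cfg a [run_config()] with `run_dir` and `out_dir`.
#' @return Invisibly, a list with `params` (data.frame) and `trend`.
#' @export
run_fit_gamma <- function(cfg) {
  cfg <- as_run_config(cfg)
  if (isTRUE(cfg$dry_run)) return(dry_run_echo(cfg, "fit_gamma"))
  run <- load_run(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (r in names(run$replicates)) {
    rep <- run$replicates[[r]]
    for (j in seq_along(rep$tables)) {
      d <- build_distribution(rep$tables[[j]], n_max = cfg$support_max,
                              label = "transcriptome")
      fit <- fit_modgamma(d, beta_fixed = cfg$beta)
      rows[[paste(r, j)]] <- data.frame(
        replicate = r, time_min = d$time_min,
        gamma_shape = fit$gamma_shape, gamma_rate = fit$gamma_rate,
        se_shape = fit$fit$se_shape, se_rate = fit$fit$se_rate,
        sse = fit$fit$sse, n_reads = d$n_reads,
        converged = fit$fit$converged)
    }
  }
  params <- do.call(rbind, rows)
  rownames(params) <- NULL
  utils::write.table(params, file.path(cfg$out_dir, "modgamma_params.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  trend <- fit_param_trend(params[params$converged, ])
  trend_df <- data.frame(
    parameter = c("gamma_shape", "gamma_rate"),
    intercept = c(trend$gamma_shape$intercept, trend$gamma_rate$intercept),
    slope = c(trend$gamma_shape$slope, trend$gamma_rate$slope),
    se_slope = c(trend$gamma_shape$se_slope, trend$gamma_rate$se_slope))
  utils::write.table(trend_df, file.path(cfg$out_dir, "param_trend.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pred <- lapply(sort(unique(params$time_min)), function(t) {
    p <- predict(trend, t)
    data.frame(time_min = t, tail_length = 0:p$n_max,
               density = modgamma_profile(p))
  })
  utils::write.table(do.call(rbind, pred),
                     file.path(cfg$out_dir, "predicted_densities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(cfg, cfg$out_dir, "fit_gamma")
  msg(cfg, "fit_gamma: %d fits, trend slopes %.4g (shape) %.4g (rate) per min",
      nrow(params), trend$gamma_shape$slope, trend$gamma_rate$slope)
  invisible(list(params = params, trend = trend))
}

#' Population deadenylation kinetics of a chase run
#'
#' Merges replicates per timepoint, restores the absolute scale with the
#' recovery coefficients, fits per-position adenosine half-lives and their
#' asymptote, converts the apparent rate to the microscopic enzymatic rate
#' via the right-arm correction, and cross-checks the rate by matching
#' observed snapshots to virtual deadenylation rounds. Requires a control
#' plus at least three depletion timepoints.
#'
#' @param cfg a [run_config()] with `run_dir`, `out_dir` and optionally
#'   `alpha_max`/`alpha_step` for the matching grid.
#' @return Invisibly, the report list (also written as `kinetics_report.json`).
#' @export
run_kinetics <- function(cfg) {
  cfg <- as_run_config(cfg)
  if (isTRUE(cfg$dry_run)) return(dry_run_echo(cfg, "kinetics"))
  run <- load_run(cfg)
  tps <- run$timepoints
  if (sum(tps > 0) < 3)
    stop_tc("insufficient depletion timepoints: need control + >= 3, got %d",
            sum(tps > 0))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  merged <- lapply(seq_along(tps), function(j)
    merge_replicates(lapply(run$replicates, function(rep)
      build_distribution(rep$tables[[j]], n_max = cfg$support_max,
                         label = "transcriptome"))))
  recov <- rowMeans(vapply(run$replicates, `[[`, numeric(length(tps)),
                           "recovery"))
  series <- chase_series(tps, merged, recovery_coeff = recov,
                         replicate_id = "merged")
  series <- adjust_for_decay(series)
  phl <- position_half_lives(series, seed = cfg$seed)
  # Right-arm rate parameter from the first depletion snapshot (no
  # new-synthesis component there). The window sits above both the
  # Pab1-protection zone and the early-time protection-erosion frontier,
  # where log density is cleanly affine in tail length.
  arm <- right_arm_slope(merged[[which(tps > 0)[1]]],
                         range = cfg$arm_range %||% c(40, 70))
  rate <- apparent_to_microscopic(phl$asymptote$rate_per_min,
                                  arm$gamma_rate,
                                  ci = 60 * log(2) /
                                    c(phl$asymptote$ci_high_s,
                                      phl$asymptote$ci_low_s))
  shift <- tryCatch(estimate_time_shift(series), error = function(e) NULL)
  ctrl_fit <- fit_modgamma(merged[[1]], beta_fixed = cfg$beta)
  ns <- new_synthesis_residual(merged[[1]], ctrl_fit)
  # the chase-start pool: the refitted base law when the joint decomposition
  # succeeded, else the new-synthesis-subtracted empirical profile
  init <- if (!is.null(ns$base_params)) modgamma_profile(ns$base_params) else
    pmax(merged[[1]]$density - ns$fitted_new_mrna, 0)
  noise_cv <- cfg$noise_cv %||% run$manifest$spec$noise_cv %||% 0
  am <- alpha_match(init / sum(init), series,
                    alpha_grid = seq(0, cfg$alpha_max, by = cfg$alpha_step),
                    noise_cv = noise_cv)
  report <- list(
    apparent_rate_per_min = rate$apparent_rate,
    adenosine_half_life_s = rate$adenosine_half_life_s,
    half_life_ci_s = c(phl$asymptote$ci_low_s, phl$asymptote$ci_high_s),
    gamma_rate_used = rate$gamma_rate_used,
    microscopic_rate_per_min = rate$microscopic_rate,
    microscopic_rate_ci = c(rate$ci_low, rate$ci_high),
    alpha_match_slope_k = am$slope_k,
    alpha_match_pearson_r = am$pearson_r,
    control_shift_min = if (!is.null(shift)) shift$shift_min else NA,
    control_fraction_new = ns$fraction_new,
    n_positions = nrow(phl$per_position))
  utils::write.table(phl$per_position,
                     file.path(cfg$out_dir, "position_half_lives.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(am$per_timepoint,
                     file.path(cfg$out_dir, "alpha_best.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(cfg$out_dir, "kinetics_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(cfg, cfg$out_dir, "kinetics")
  msg(cfg, paste0("kinetics: apparent %.3f A/min (half-life %.1f s), ",
                  "microscopic %.2f A/min, alpha slope %.2f (r = %.3f)"),
      rate$apparent_rate, rate$adenosine_half_life_s, rate$microscopic_rate,
      am$slope_k, am$pearson_r)
  invisible(report)
}

#' Per-transcript quantile deadenylation and decay rates of a chase run
#'
#' @param cfg a [run_config()] with `run_dir`, `out_dir`, filter fields
#'   (`min_reads`, `shift_min`, `down_regulated_only`) and optional `groups`
#'   (named list of transcript-id vectors for group summaries).
#' @return Invisibly, a list with `rates` and `summary`.
#' @export
run_quantile_rates <- function(cfg) {
  cfg <- as_run_config(cfg)
  if (isTRUE(cfg$dry_run)) return(dry_run_echo(cfg, "quantile_rates"))
  run <- load_run(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  policy <- filter_policy(min_reads = cfg$min_reads,
                          control_time_shift_min = cfg$shift_min,
                          down_regulated_only = cfg$down_regulated_only)
  reps <- lapply(run$replicates, function(rep) {
    ab <- normalize_abundance(
      stats::setNames(rep$counts,
                      vapply(rep$tables, attr, "", "sample_id")),
      scale_mode = cfg$abundance_scale %||% "cpm",
      time_min = vapply(rep$tables, attr, numeric(1), "time_min"))
    ab$level <- ab$norm_level
    list(tables = rep$tables, abundance = ab)
  })
  rates <- transcript_rate_table(reps, policy = policy)
  utils::write.table(rates, file.path(cfg$out_dir, "transcript_rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- group_summary(rates, groups = cfg$groups %||% list())
  if (!is.null(summ$groups))
    utils::write.table(summ$groups,
                       file.path(cfg$out_dir, "group_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summ$correlation,
                       file.path(cfg$out_dir, "rate_correlation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(cfg, cfg$out_dir, "quantile_rates")
  msg(cfg, "quantile_rates: %d transcripts, Spearman rho %.3f (n = %d)",
      nrow(rates), summ$correlation$rho, summ$correlation$n)
  invisible(list(rates = rates, summary = summ))
}
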