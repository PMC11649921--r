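#' Ground-truth specification for a synthetic chase dataset
#'
#' Defines every parameter of a synthetic direct-RNA-sequencing chase:
#' transcript abundances (heavy-tailed, with a configurable top share of
#' reads), per-transcript tail-profile parameters, microscopic deadenylation
#' rate(s), mRNA decay constants, the newly-synthesised tail component present
#' in control samples, the tail-length measurement noise, and the evolution
#' mode. A fixed seed makes the generated dataset byte-identical.
#'
#' Two evolution modes are provided. `"analytic"` evolves each transcript's
#' expected profile by the closed-form Poisson convolution with the
#' decapping-protection prefactor ([analytic_evolve()] with
#' `protected = TRUE`) - the exact functional form the population estimators
#' assume. `"molecule"` simulates each read as a molecule whose tail loses a
#' Poisson number of adenosines and that risks decapping (hazard
#' `decap_hazard` per minute) for the time its tail spends below
#' `decap_threshold`, with birth tails bounded by `birth_cap` (nuclear
#' polyadenylation does not run on forever); this mode produces the declining
#' per-transcript quantile trajectories seen in real chases and is used for
#' per-transcript rate benchmarking.
#'
#' @param n_transcripts number of transcripts.
#' @param reads_per_transcript expected control reads per transcript (total
#'   control depth = `n_transcripts * reads_per_transcript`, split by the
#'   abundance weights).
#' @param abundance_top_n,abundance_top_share the top `abundance_top_n`
#'   transcripts carry `abundance_top_share` of the reads (within each block
#'   weights fall off as a Zipf law with exponent `abundance_zipf`).
#' @param abundance_zipf Zipf exponent of the within-block falloff.
#' @param gamma_shape_range per-transcript shape drawn uniformly from this
#'   range (the empirically observed 3.5-4 window by default).
#' @param gamma_rate right-arm rate parameter (common to all transcripts).
#' @param k microscopic deadenylation rate, adenosines/min; either a scalar
#'   (global) or the median of a per-transcript log-normal when
#'   `k_sdlog > 0`.
#' @param k_sdlog log-sd of the per-transcript rate spread (0 = global rate).
#' @param lambda_median,lambda_sdlog per-transcript mRNA decay constants,
#'   1/min, log-normal.
#' @param k_lambda_rank_corr target Spearman correlation between k and lambda
#'   across transcripts (Gaussian copula; 0 = independent).
#' @param new_syn_fraction fraction of control reads from newly made mRNA.
#' @param new_syn_log2_mean,new_syn_log2_sd the new-tail component is
#'   Gaussian in log2(length); defaults put its mode near 50 adenosines
#'   (the 40-60 A window of fresh nuclear tails).
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   tail-length measurement noise (0 disables it).
#' @param non_pass_rate fraction of reads emitted with a non-PASS QC tag.
#' @param timepoints chase times, minutes, starting at 0 (the control).
#' @param n_replicates biological replicates.
#' @param mode `"analytic"` or `"molecule"` (see above).
#' @param birth_cap maximal tail length at synthesis (molecule mode),
#'   adenosines.
#' @param decap_threshold tail length below which decapping is licensed
#'   (loss of the last Pab1), adenosines.
#' @param decap_hazard decapping-decay hazard below the threshold, 1/min.
#' @param beta Pab1 interaction strength of the tail-profile law.
#' @param n_max support upper bound, adenosines.
#' @param burst_center,burst_sd when non-NULL, replace the modified-gamma
#'   initial profile by a narrow Gaussian (transcription-burst scenario).
#' @param seed integer seed; all randomness derives from it.
#' @return A `truth_spec` object including the realised per-transcript
#'   parameter table `$transcripts`.
#' @export
truth_spec <- function(n_transcripts = 50,
                       reads_per_transcript = 2000,
                       abundance_top_n = max(1, round(n_transcripts * 0.2)),
                       abundance_top_share = 0.6,
                       abundance_zipf = 0.8,
                       gamma_shape_range = c(3.5, 4),
                       gamma_rate = 0.1,
                       k = 10.9,
                       k_sdlog = 0,
                       lambda_median = log(2) / 9.7,
                       lambda_sdlog = 0.5,
                       k_lambda_rank_corr = 0,
                       new_syn_fraction = 0.2,
                       new_syn_log2_mean = log2(50),
                       new_syn_log2_sd = 0.15,
                       noise_cv = 0.1,
                       non_pass_rate = 0.05,
                       timepoints = c(0, 3, 6, 9, 12, 15),
                       n_replicates = 3,
                       mode = c("analytic", "molecule"),
                       birth_cap = 90,
                       decap_threshold = 20,
                       decap_hazard = 3,
                       beta = 0.096,
                       n_max = 250,
                       burst_center = NULL,
                       burst_sd = 1,
                       seed = 20240601) {
  mode <- match.arg(mode)
  for (nm in c("n_transcripts", "reads_per_transcript", "gamma_rate",
               "lambda_median", "new_syn_fraction", "noise_cv",
               "non_pass_rate", "n_replicates", "beta", "n_max"))
    assert_scalar_num(get(nm), nm, lower = 0)
  if (n_transcripts < 1) stop_tc("invalid field 'n_transcripts': must be >= 1")
  if (gamma_rate <= 0) stop_tc("invalid field 'gamma_rate': must be > 0")
  if (any(k <= 0)) stop_tc("invalid field 'k': rates must be positive")
  if (timepoints[1] != 0 || any(diff(timepoints) <= 0))
    stop_tc("invalid field 'timepoints': must increase from 0")
  if (new_syn_fraction >= 1)
    stop_tc("invalid field 'new_syn_fraction': must be < 1")
  if (abundance_top_n > n_transcripts)
    stop_tc("invalid field 'abundance_top_n': exceeds n_transcripts")
  spec <- list(n_transcripts = n_transcripts,
               reads_per_transcript = reads_per_transcript,
               abundance_top_n = abundance_top_n,
               abundance_top_share = abundance_top_share,
               abundance_zipf = abundance_zipf,
               gamma_shape_range = gamma_shape_range,
               gamma_rate = gamma_rate, k = k, k_sdlog = k_sdlog,
               lambda_median = lambda_median, lambda_sdlog = lambda_sdlog,
               k_lambda_rank_corr = k_lambda_rank_corr,
               new_syn_fraction = new_syn_fraction,
               new_syn_log2_mean = new_syn_log2_mean,
               new_syn_log2_sd = new_syn_log2_sd,
               noise_cv = noise_cv, non_pass_rate = non_pass_rate,
               timepoints = timepoints, n_replicates = n_replicates,
               mode = mode, birth_cap = birth_cap,
               decap_threshold = decap_threshold,
               decap_hazard = decap_hazard, beta = beta, n_max = n_max,
               burst_center = burst_center, burst_sd = burst_sd,
               seed = as.integer(seed))
  spec$transcripts <- draw_transcript_truth(spec)
  class(spec) <- "truth_spec"
  spec
}

# abundance weights: top block carries exactly `share` of the mass, Zipf
# falloff within blocks (emulates the strong enrichment of the most abundant
# mRNAs in DRS libraries)
#' @noRd
abundance_weights <- function(n, top_n, share, zipf) {
  w <- (1:n)^(-zipf)
  if (top_n >= n) return(w / sum(w))
  top <- w[1:top_n] / sum(w[1:top_n]) * share
  rest <- w[(top_n + 1):n] / sum(w[(top_n + 1):n]) * (1 - share)
  c(top, rest)
}

#' @noRd
draw_transcript_truth <- function(spec) {
  n <- spec$n_transcripts
  with_seed(child_seed(spec$seed, 101), {
    shapes <- stats::runif(n, spec$gamma_shape_range[1],
                           spec$gamma_shape_range[2])
    # Gaussian copula between log k and log lambda at the requested rank
    # correlation (Pearson-on-normals r = 2 sin(pi * rho_s / 6))
    r <- 2 * sin(pi * spec$k_lambda_rank_corr / 6)
    z1 <- stats::rnorm(n)
    z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
    kk <- if (spec$k_sdlog > 0) exp(log(spec$k) + spec$k_sdlog * z1) else
      rep(spec$k, n)
    ll <- exp(log(spec$lambda_median) + spec$lambda_sdlog * z2)
    data.frame(transcript_id = sprintf("TX%04d", 1:n),
               weight = abundance_weights(n, spec$abundance_top_n,
                                          spec$abundance_top_share,
                                          spec$abundance_zipf),
               gamma_shape = shapes,
               gamma_rate = rep(spec$gamma_rate, n),
               k = kk, lambda = ll, stringsAsFactors = FALSE)
  })
}

#' Named presets reproducing the package's reference study conditions
#'
#' \describe{
#'   \item{`mex67_chase`}{Whole-transcriptome export-block chase: global
#'     microscopic rate 10.9 A/min, right-arm rate parameter 0.1, shapes in
#'     3.5-4, median mRNA half-life 9.7 min, 50 transcripts x 2000 reads,
#'     control + five test timepoints (3-min spacing), 3 replicates, analytic
#'     (closed-form) evolution. The preset behind the population-level
#'     kinetics benchmarks.}
#'   \item{`transcript_panel`}{200-transcript panel with per-transcript rates
#'     (k log-normal around 10.9 A/min, decay constants rank-correlated 0.7
#'     with k), per-molecule evolution with birth tails bounded at 90 A and
#'     decapping below 20 A. The preset behind per-transcript rate-recovery
#'     benchmarks.}
#'   \item{`burst`}{Single transcript, near-delta initial tail distribution at
#'     60 A (transcription-burst scenario), analytic evolution.}
#' }
#'
#' @param name preset name.
#' @param seed seed override.
#' @param ... fields overriding the preset's defaults.
#' @return A `truth_spec`.
#' @export
chase_preset <- function(name = c("mex67_chase", "transcript_panel", "burst"),
                         seed = 20240601, ...) {
  name <- match.arg(name)
  args <- switch(name,
    mex67_chase = list(),
    transcript_panel = list(n_transcripts = 200, abundance_top_n = 40,
                            abundance_top_share = 0.4, abundance_zipf = 0.3,
                            k_sdlog = 0.5, k_lambda_rank_corr = 0.7,
                            mode = "molecule",
                            timepoints = c(0, 4, 8, 12, 16, 20)),
    burst = list(n_transcripts = 1, burst_center = 60, burst_sd = 1,
                 new_syn_fraction = 0, noise_cv = 0)
  )
  over <- list(...)
  args[names(over)] <- over
  args$seed <- seed
  spec <- do.call(truth_spec, args)
  attr(spec, "preset") <- name
  spec
}

# initial (steady, chase-start) tail profile of one transcript, without the
# new-synthesis component; density over 0..n_max
#' @noRd
initial_profile <- function(spec, g) {
  i <- 0:spec$n_max
  if (!is.null(spec$burst_center)) {
    p <- stats::dnorm(i, spec$burst_center, spec$burst_sd)
  } else {
    p <- modgamma_kernel(i, spec$transcripts$gamma_shape[g],
                         spec$transcripts$gamma_rate[g], spec$beta)
    if (spec$mode == "molecule") p[i > spec$birth_cap] <- 0
  }
  p / sum(p)
}

#' @noRd
draw_new_syn_lengths <- function(n, spec) {
  2^stats::rnorm(n, spec$new_syn_log2_mean, spec$new_syn_log2_sd)
}

#' @noRd
apply_read_noise <- function(len, spec) {
  if (spec$noise_cv <= 0) return(len)
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  len * exp(stats::rnorm(length(len), -sdlog^2 / 2, sdlog))
}

#' @noRd
draw_qc_tags <- function(n, spec) {
  tags <- rep("PASS", n)
  bad <- stats::runif(n) < spec$non_pass_rate
  tags[bad] <- sample(c("FAIL", "SUFFCLIP", "ADAPTER", "NOREGION"),
                      sum(bad), replace = TRUE)
  tags
}

# Molecule-mode survivor law of one transcript at chase time t, in closed
# form: tails shorten by Poisson(k*t); a tail observed at length L spent
# min((threshold - L)/k, t) minutes below the decapping threshold (shortening
# is monotone, so the dwell time depends on L only) and survived the decap
# hazard over that dwell. Shortened-to-zero molecules are gone.
#' @noRd
molecule_survivor_profile <- function(p0, spec, k, t) {
  if (t == 0) return(list(profile = p0, survival = 1))
  x <- analytic_evolve(p0, k * t, protected = FALSE)
  i <- seq_along(p0) - 1L
  tau <- pmin(pmax(spec$decap_threshold - i, 0) / k, t)
  w <- exp(-spec$decap_hazard * tau)
  w[i == 0] <- 0
  xs <- x * w
  s <- sum(xs)
  list(profile = if (s > 0) xs / s else xs, survival = s)
}

#' @noRd
sample_molecule_tails <- function(n, p0, spec, k, t,
                                  extinction_floor = 1e-6) {
  sp <- molecule_survivor_profile(p0, spec, k, t)
  if (sp$survival < extinction_floor)  # pool effectively degraded
    return(list(tails = numeric(0), survival = sp$survival))
  idx <- sample.int(length(sp$profile), n, replace = TRUE,
                    prob = sp$profile) - 1L
  list(tails = as.numeric(idx), survival = sp$survival)
}

#' Generate the control (t = 0) sample of a synthetic chase
#'
#' Per-transcript read counts follow the heavy-tailed abundance weights; each
#' read's tail is drawn from the transcript's modified-gamma profile, mixed
#' with the newly-synthesised 40-60 A component, then multiplicative
#' measurement noise and QC tags are applied.
#'
#' @param spec a `truth_spec`.
#' @param replicate replicate index (only changes the derived seed).
#' @return List: `table` (a `tail_table`), `counts` (named per-transcript read
#'   counts).
#' @export
gen_transcriptome <- function(spec, replicate = 1) {
  stopifnot(inherits(spec, "truth_spec"))
  gen_sample(spec, replicate = replicate, timepoint_index = 1)
}

#' @noRd
gen_sample <- function(spec, replicate, timepoint_index) {
  t <- spec$timepoints[timepoint_index]
  tx <- spec$transcripts
  with_seed(child_seed(spec$seed, replicate, timepoint_index), {
    expect <- spec$n_transcripts * spec$reads_per_transcript * tx$weight *
      exp(-tx$lambda * t)
    n_reads <- stats::rpois(nrow(tx), expect)
    out_len <- vector("list", nrow(tx))
    out_id <- vector("list", nrow(tx))
    surv <- numeric(nrow(tx))
    for (g in seq_len(nrow(tx))) {
      n <- n_reads[g]
      p0 <- initial_profile(spec, g)
      if (n == 0) { surv[g] <- NA_real_; next }
      if (t == 0) {
        n_new <- stats::rbinom(1, n, spec$new_syn_fraction)
        base <- sample.int(length(p0), n - n_new, replace = TRUE,
                           prob = p0) - 1L
        len <- c(as.numeric(base), draw_new_syn_lengths(n_new, spec))
        surv[g] <- 1
      } else if (spec$mode == "analytic") {
        xd <- analytic_evolve(p0, tx$k[g] * t, protected = TRUE,
                              beta = spec$beta)
        surv[g] <- sum(xd)
        xd <- xd / sum(xd)
        len <- as.numeric(sample.int(length(xd), n, replace = TRUE,
                                     prob = xd) - 1L)
      } else {
        # tail measurements exist only while the transcript's tail pool
        # survives; the abundance bookkeeping (counts) follows the decay
        # constants independently
        sm <- sample_molecule_tails(n, p0, spec, tx$k[g], t)
        len <- sm$tails
        surv[g] <- sm$survival
        n <- length(len)
      }
      out_len[[g]] <- len
      out_id[[g]] <- rep(tx$transcript_id[g], n)
    }
    len <- apply_read_noise(unlist(out_len), spec)
    ids <- unlist(out_id)
    ord <- sample.int(length(len))  # shuffle read order as in a real run
    sample_id <- sprintf("t%02d_rep%d", timepoint_index - 1L, replicate)
    tab <- tail_table(data.frame(
      read_id = sprintf("%s_read%07d", sample_id, seq_along(len)),
      transcript_id = ids[ord],
      tail_length = round(len[ord], 2),
      qc_tag = draw_qc_tags(length(len), spec),
      stringsAsFactors = FALSE
    ), sample_id = sample_id, time_min = t)
    counts <- stats::setNames(as.numeric(n_reads), tx$transcript_id)
    # mass surviving the tail kinetics, abundance-weighted at t = 0 weights
    mass_ratio <- sum(tx$weight * ifelse(is.na(surv), 0, surv)) /
      sum(tx$weight)
    list(table = tab, counts = counts, mass_ratio = mass_ratio)
  })
}

#' Generate a full synthetic chase experiment
#'
#' At each timepoint the expected tail distribution of a transcript is its
#' chase-start profile (control minus the new-synthesis component) evolved to
#' `alpha = k*t` - in closed form (`mode = "analytic"`) or per molecule
#' (`mode = "molecule"`) - and expected read counts decay as
#' `abundance * exp(-lambda*t)`. The per-timepoint recovery coefficient is
#' recorded as the realised ratio of surviving absolute tail mass; read-count
#' decay (the mRNA decay constants) is deliberately not folded into it, since
#' sequencing depth is normalised away exactly as for real libraries.
#'
#' @param spec a `truth_spec`.
#' @param timepoints optional override of `spec$timepoints` (must not extend
#'   beyond the configured horizon, the last spec timepoint).
#' @return A `synthetic_chase`: list with `spec`, `timepoints`, and
#'   `replicates` - each replicate holding `tables` (list of `tail_table`),
#'   `counts` (named vectors), `recovery` (per-timepoint coefficients).
#' @export
gen_chase <- function(spec, timepoints = NULL) {
  stopifnot(inherits(spec, "truth_spec"))
  if (!is.null(timepoints)) {
    if (max(timepoints) > max(spec$timepoints))
      stop_tc("timepoint %g beyond configured horizon %g",
              max(timepoints), max(spec$timepoints))
    spec$timepoints <- timepoints
  }
  reps <- lapply(seq_len(spec$n_replicates), function(r) {
    samples <- lapply(seq_along(spec$timepoints), function(j)
      gen_sample(spec, replicate = r, timepoint_index = j))
    list(tables = lapply(samples, `[[`, "table"),
         counts = lapply(samples, `[[`, "counts"),
         recovery = vapply(samples, `[[`, numeric(1), "mass_ratio"))
  })
  names(reps) <- sprintf("rep%d", seq_len(spec$n_replicates))
  structure(list(spec = spec, timepoints = spec$timepoints,
                 replicates = reps),
            class = "synthetic_chase")
}

#' @export
print.synthetic_chase <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_chase> %d transcripts, %d replicates, ",
                     "timepoints {%s} min, mode '%s'\n"),
              x$spec$n_transcripts, length(x$replicates),
              paste(x$timepoints, collapse = ", "), x$spec$mode))
  invisible(x)
}

#' Write a synthetic chase as tail-caller-dialect files plus a manifest
#'
#' One TSV per sample in the nanopore tail-caller column layout (readname,
#' contig, ..., polya_length, qc_tag), one abundance TSV per sample, and a
#' JSON manifest holding the design, the full ground truth and the seed, so
#' the run can be regenerated byte-identically.
#'
#' @param chase a `synthetic_chase`.
#' @param out_dir output directory (created).
#' @return `out_dir`, invisibly.
#' @export
write_chase <- function(chase, out_dir) {
  stopifnot(inherits(chase, "synthetic_chase"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_tc("cannot create directory %s", out_dir)
  files <- list()
  for (r in seq_along(chase$replicates)) {
    rep <- chase$replicates[[r]]
    for (j in seq_along(chase$timepoints)) {
      tab <- rep$tables[[j]]
      sid <- attr(tab, "sample_id")
      df <- data.frame(readname = tab$read_id, contig = tab$transcript_id,
                       position = 0L, leader_start = 0L, adapter_start = 0L,
                       polya_start = 0L, transcript_start = 0L,
                       read_rate = 70, polya_length = tab$tail_length,
                       qc_tag = tab$qc_tag, stringsAsFactors = FALSE)
      f <- file.path(out_dir, paste0(sid, ".polya.tsv"))
      utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
      fa <- file.path(out_dir, paste0(sid, ".counts.tsv"))
      utils::write.table(
        data.frame(transcript_id = names(rep$counts[[j]]),
                   count = unname(rep$counts[[j]])),
        fa, sep = "\t", quote = FALSE, row.names = FALSE)
      files[[sid]] <- list(polya = basename(f), counts = basename(fa),
                           time_min = chase$timepoints[j],
                           replicate = names(chase$replicates)[r],
                           recovery_coeff = rep$recovery[j])
    }
  }
  spec <- chase$spec
  truth <- spec$transcripts
  spec$transcripts <- NULL
  manifest <- list(generator = "tailchase::write_chase",
                   seed = spec$seed, spec = unclass(spec),
                   preset = attr(chase$spec, "preset"),
                   transcripts = truth, samples = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read back a chase run directory written by [write_chase()]
#'
#' @param dir run directory containing `manifest.json`.
#' @param qc_policy QC policy passed to [read_polya_table()].
#' @return List: `manifest`, `replicates` (same layout as in
#'   `synthetic_chase`, tables filtered by `qc_policy`), `timepoints`.
#' @export
read_chase <- function(dir, qc_policy = "PASS") {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  sm <- mf$samples
  reps <- unique(vapply(sm, `[[`, character(1), "replicate"))
  out <- lapply(reps, function(r) {
    sel <- Filter(function(s) s$replicate == r, sm)
    sel <- sel[order(vapply(sel, `[[`, numeric(1), "time_min"))]
    tabs <- lapply(sel, function(s)
      read_polya_table(file.path(dir, s$polya), qc_policy = qc_policy,
                       time_min = s$time_min))
    cts <- lapply(sel, function(s) {
      df <- utils::read.delim(file.path(dir, s$counts))
      stats::setNames(df$count, df$transcript_id)
    })
    list(tables = tabs, counts = cts,
         recovery = unname(vapply(sel, `[[`, numeric(1), "recovery_coeff")))
  })
  names(out) <- reps
  list(manifest = mf, replicates = out,
       timepoints = sort(unique(vapply(sm, `[[`, numeric(1), "time_min"))))
}
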