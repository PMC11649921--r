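#' Filtering policy for rate estimation
#'
#' Encodes the data-quality rules applied before any rate is computed:
#' quantile estimates from fewer than `min_reads` reads are discarded; values
#' greater than the reference (control) value are removed (yeast has no
#' cytoplasmic adenylase, so increases are artefactual); and, in export-block
#' chases, the control time is moved `control_time_shift_min` minutes forward
#' on the depletion time axis before decay fitting (the time the depletion
#' phenotype needs to establish).
#'
#' @param min_reads minimum reads behind a quantile estimate (default 10).
#' @param drop_above_reference drop values exceeding the control value.
#' @param control_time_shift_min forward shift of the control timepoint,
#'   minutes; applied to decay-rate fitting only.
#' @param down_regulated_only optional character vector of transcript ids to
#'   which rate estimation is restricted (stress-chase rule).
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(min_reads = 10, drop_above_reference = TRUE,
                          control_time_shift_min = 0,
                          down_regulated_only = NULL) {
  assert_scalar_num(min_reads, "min_reads", lower = 1)
  assert_scalar_num(control_time_shift_min, "control_time_shift_min",
                    lower = 0)
  structure(list(min_reads = as.integer(min_reads),
                 drop_above_reference = isTRUE(drop_above_reference),
                 control_time_shift_min = control_time_shift_min,
                 down_regulated_only = down_regulated_only),
            class = "filter_policy")
}

default_quantile_levels <- c(5, 10, 15, 50, 75, 80, 85, 90, 95)
upper_quantile_levels <- c(75, 80, 85, 90, 95)

#' Empirical quantiles of read-level tail lengths
#'
#' Linear-interpolation quantile estimator on the raw (unbinned) tail lengths.
#' When fewer than `policy$min_reads` reads are available every level is
#' reported absent - low-count quantile estimates are unusable, and absence
#' (not an error) is the contract downstream filters rely on.
#'
#' @param lengths numeric vector of tail lengths, or a `tail_table` whose
#'   `tail_length` column is used.
#' @param levels quantile levels in percent, strictly inside (0, 100).
#' @param policy a [filter_policy()].
#' @return One-row data.frame: `n_reads`, `flag`, and one `q<level>` column
#'   per level (NA when filtered).
#' @export
compute_quantiles <- function(lengths, levels = default_quantile_levels,
                              policy = filter_policy()) {
  if (inherits(lengths, "tail_table")) lengths <- lengths$tail_length
  if (any(levels <= 0 | levels >= 100)) stop_tc("levels must be in (0, 100)")
  n <- length(lengths)
  vals <- if (n >= policy$min_reads)
    stats::quantile(lengths, probs = levels / 100, type = 7, names = FALSE)
  else rep(NA_real_, length(levels))
  out <- as.data.frame(as.list(stats::setNames(vals,
                                               paste0("q", levels))))
  cbind(data.frame(n_reads = n,
                   flag = if (n < policy$min_reads) "low_reads" else ""),
        out)
}

#' Quantile tail-length trajectories over a chase
#'
#' @param tables list of `tail_table` objects (one per timepoint, `time_min`
#'   attributes set).
#' @param transcript optional transcript id; reads are restricted to it
#'   (default: all reads pooled, the whole-transcriptome trajectory).
#' @param levels quantile levels in percent.
#' @param policy a [filter_policy()].
#' @return A long data.frame: `time_min`, `level`, `value`, `n_reads`.
#' @export
quantile_series <- function(tables, transcript = NULL,
                            levels = default_quantile_levels,
                            policy = filter_policy()) {
  rows <- lapply(tables, function(tab) {
    len <- if (is.null(transcript)) tab$tail_length else
      tab$tail_length[tab$transcript_id == transcript]
    q <- compute_quantiles(len, levels, policy)
    data.frame(time_min = attr(tab, "time_min"), level = levels,
               value = as.numeric(q[1, paste0("q", levels)]),
               n_reads = q$n_reads[1])
  })
  out <- do.call(rbind, rows)
  out[order(out$time_min, out$level), , drop = FALSE]
}

# shared pairwise exponential-coefficient engine.
# values: series over time; reference = first (control) value. Returns the
# per-interval relative coefficients c = ln(v1/v2)/dt over consecutive usable
# pairs, plus per-adenosine rates c * geometric-mean(value pair) when
# per_unit = TRUE.
#' @noRd
pairwise_coeffs <- function(time, value, drop_above_reference, per_unit) {
  ok <- is.finite(value) & value > 0 & is.finite(time)
  time <- time[ok]; value <- value[ok]
  if (length(value) < 2) return(NULL)
  o <- order(time)
  time <- time[o]; value <- value[o]
  ref <- value[1]
  if (drop_above_reference) {
    keep <- c(TRUE, value[-1] <= ref)
    time <- time[keep]; value <- value[keep]
  }
  if (length(value) < 2) return(NULL)
  v1 <- value[-length(value)]; v2 <- value[-1]
  dt <- diff(time)
  cc <- log(v1 / v2) / dt
  data.frame(t1 = time[-length(time)], t2 = time[-1], v1 = v1, v2 = v2,
             coeff = cc,
             rate = if (per_unit) cc * geo_mean2(v1, v2) else cc)
}

#' Upper-quantile deadenylation rate of a chase
#'
#' For each upper quantile level the trajectory of the quantile tail length is
#' treated as an exponential decline: each consecutive usable timepoint pair
#' yields a relative coefficient `ln(L_prev/L_next)/dt` (per minute), and its
#' per-adenosine shortening rate `coeff * sqrt(L_prev*L_next)` (adenosines per
#' minute). Values above the control value are removed first; negative
#' pairwise coefficients that survive the filter (transient increases) are
#' kept, not clamped. Coefficients are averaged over intervals within a level,
#' then over the upper levels; the terminal adenosine half-life is
#' `60*ln(2)` over the per-adenosine rate.
#'
#' @param series a quantile trajectory from [quantile_series()].
#' @param upper_levels levels averaged (default 75/80/85/90/95).
#' @param policy a [filter_policy()].
#' @return List: `deadenylation_coeff` (adenosines/min),
#'   `rel_coeff_per_min` (bare exponential coefficient, 1/min),
#'   `terminal_adenosine_half_life_s`, `per_level` data.frame, `n_intervals`,
#'   `flag` (`"no_usable_intervals"` when nothing survived filtering).
#' @export
quantile_deadenylation_rate <- function(series,
                                        upper_levels = upper_quantile_levels,
                                        policy = filter_policy()) {
  per_level <- lapply(upper_levels, function(lv) {
    s <- series[series$level == lv, , drop = FALSE]
    pw <- pairwise_coeffs(s$time_min, s$value,
                          policy$drop_above_reference, per_unit = TRUE)
    if (is.null(pw)) return(data.frame(level = lv, coeff = NA_real_,
                                       rate = NA_real_, n_intervals = 0L))
    data.frame(level = lv, coeff = mean(pw$coeff), rate = mean(pw$rate),
               n_intervals = nrow(pw))
  })
  per_level <- do.call(rbind, per_level)
  usable <- per_level$n_intervals > 0
  if (!any(usable)) {
    return(list(deadenylation_coeff = NA_real_, rel_coeff_per_min = NA_real_,
                terminal_adenosine_half_life_s = NA_real_,
                per_level = per_level, n_intervals = 0L,
                flag = "no_usable_intervals"))
  }
  rate <- mean(per_level$rate[usable])
  coeff <- mean(per_level$coeff[usable])
  hl <- if (is.finite(rate) && rate > 0) 60 * log(2) / rate else NA_real_
  flag <- if (!is.finite(rate) || rate <= 0) "nonpositive_rate" else ""
  list(deadenylation_coeff = rate, rel_coeff_per_min = coeff,
       terminal_adenosine_half_life_s = hl, per_level = per_level,
       n_intervals = sum(per_level$n_intervals), flag = flag)
}

#' Exponential mRNA decay rate from a normalised abundance series
#'
#' Pairwise decay constants `ln(A_prev/A_next)/dt` over consecutive usable
#' timepoints, after removing values above the control level and moving the
#' control `control_time_shift_min` minutes forward on the depletion time
#' axis. The half-life is `ln(2)` over the averaged constant.
#'
#' @param abundance_series data.frame with `time_min` and `level`
#'   (library-normalised abundance) for one transcript.
#' @param policy a [filter_policy()].
#' @return List: `decay_coeff` (1/min), `mrna_half_life_min`, `n_intervals`,
#'   `flag`.
#' @export
decay_rate <- function(abundance_series, policy = filter_policy()) {
  tt <- abundance_series$time_min
  if (policy$control_time_shift_min > 0) {
    dep <- tt[tt > 0]
    if (length(dep) && policy$control_time_shift_min >= min(dep))
      stop_tc("control shift %.2f min not smaller than first test time %g",
              policy$control_time_shift_min, min(dep))
    tt[tt == 0] <- policy$control_time_shift_min
  }
  pw <- pairwise_coeffs(tt, abundance_series$level,
                        policy$drop_above_reference, per_unit = FALSE)
  if (is.null(pw))
    return(list(decay_coeff = NA_real_, mrna_half_life_min = NA_real_,
                n_intervals = 0L, flag = "no_usable_intervals"))
  coeff <- mean(pw$coeff)
  hl <- if (is.finite(coeff) && coeff > 0) log(2) / coeff else NA_real_
  list(decay_coeff = coeff, mrna_half_life_min = hl, n_intervals = nrow(pw),
       flag = if (!is.finite(coeff) || coeff <= 0) "nonpositive_rate" else "")
}

#' Per-transcript deadenylation and decay rate table for a chase design
#'
#' Rates are computed independently within each replicate and averaged across
#' replicates (the mean-of-means convention); half-lives are recomputed from
#' the averaged constants so the `ln 2` duality holds in the output.
#' Transcripts failing every filter appear with flags rather than being
#' silently dropped.
#'
#' @param replicates named list of replicates; each element is a list with
#'   `tables` (list of `tail_table`, one per timepoint) and `abundance` (an
#'   `abundance_table` covering the same samples).
#' @param policy a [filter_policy()]; when `down_regulated_only` is set, only
#'   those transcripts are processed.
#' @param levels,upper_levels quantile levels computed / averaged.
#' @return A `transcript_rates` data.frame sorted by transcript id:
#'   `transcript_id`, `deadenylation_coeff` (A/min), `rel_coeff_per_min`,
#'   `terminal_adenosine_half_life_s`, `decay_coeff` (1/min),
#'   `mrna_half_life_min`, `n_reads_control`, `n_reps_deadenylation`,
#'   `n_reps_decay`, `flags`.
#' @export
transcript_rate_table <- function(replicates, policy = filter_policy(),
                                  levels = default_quantile_levels,
                                  upper_levels = upper_quantile_levels) {
  stopifnot(length(replicates) >= 1)
  tx <- sort(unique(unlist(lapply(replicates, function(r)
    unlist(lapply(r$tables, function(tab) unique(tab$transcript_id)))))))
  if (!is.null(policy$down_regulated_only))
    tx <- intersect(tx, policy$down_regulated_only)
  rows <- vector("list", length(tx))
  # pre-split read lengths per replicate/timepoint for speed
  split_reps <- lapply(replicates, function(r) {
    lapply(r$tables, function(tab)
      list(time_min = attr(tab, "time_min"),
           by_tx = split(tab$tail_length, tab$transcript_id)))
  })
  for (g in seq_along(tx)) {
    id <- tx[g]
    dead <- c(); relc <- c(); dec <- c(); nctrl <- 0L; flags <- character(0)
    for (r in seq_along(replicates)) {
      sp <- split_reps[[r]]
      qrows <- lapply(sp, function(tp) {
        len <- tp$by_tx[[id]] %||% numeric(0)
        q <- compute_quantiles(len, upper_levels, policy)
        data.frame(time_min = tp$time_min, level = upper_levels,
                   value = as.numeric(q[1, paste0("q", upper_levels)]),
                   n_reads = q$n_reads[1])
      })
      qs <- do.call(rbind, qrows)
      nctrl <- max(nctrl, qs$n_reads[qs$time_min == min(qs$time_min)][1])
      dr <- quantile_deadenylation_rate(qs, upper_levels, policy)
      if (is.finite(dr$deadenylation_coeff)) {
        dead <- c(dead, dr$deadenylation_coeff)
        relc <- c(relc, dr$rel_coeff_per_min)
      } else flags <- c(flags, dr$flag)
      ab <- replicates[[r]]$abundance
      abg <- ab[ab$transcript_id == id, , drop = FALSE]
      if (is.null(abg$level)) abg$level <- abg$norm_level
      if (nrow(abg) >= 2) {
        de <- decay_rate(abg, policy)
        if (is.finite(de$decay_coeff)) dec <- c(dec, de$decay_coeff) else
          flags <- c(flags, de$flag)
      }
    }
    mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
    dcoef <- mean_or_na(dead)
    decoef <- mean_or_na(dec)
    if (length(dead) > 0 && length(dead) < length(replicates))
      flags <- c(flags, "low_replicate_support")
    rows[[g]] <- data.frame(
      transcript_id = id,
      deadenylation_coeff = dcoef,
      rel_coeff_per_min = mean_or_na(relc),
      terminal_adenosine_half_life_s =
        if (is.finite(dcoef) && dcoef > 0) 60 * log(2) / dcoef else NA_real_,
      decay_coeff = decoef,
      mrna_half_life_min =
        if (is.finite(decoef) && decoef > 0) log(2) / decoef else NA_real_,
      n_reads_control = nctrl,
      n_reps_deadenylation = length(dead),
      n_reps_decay = length(dec),
      flags = paste(unique(flags[nzchar(flags)]), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("transcript_rates", "data.frame")
  out
}

#' Group medians and rank correlation of per-transcript rates
#'
#' @param rates a `transcript_rates` table.
#' @param groups named list of transcript-id vectors (e.g. RPG membership,
#'   top-abundance sets). Empty groups are skipped with a warning; groups of
#'   one transcript are flagged.
#' @param cor_columns two rate columns whose Spearman rank correlation (with
#'   p-value) is reported over all finite pairs.
#' @return List: `groups` data.frame (per-group n and medians), `correlation`
#'   list (`rho`, `p_value`, `n`).
#' @export
group_summary <- function(rates, groups = list(),
                          cor_columns = c("deadenylation_coeff",
                                          "decay_coeff")) {
  gs <- lapply(names(groups), function(nm) {
    sub <- rates[rates$transcript_id %in% groups[[nm]], , drop = FALSE]
    if (nrow(sub) == 0) {
      warning(sprintf("group '%s' matched no transcripts; skipped", nm))
      return(NULL)
    }
    data.frame(group = nm, n = nrow(sub),
               median_deadenylation_coeff =
                 stats::median(sub$deadenylation_coeff, na.rm = TRUE),
               median_terminal_adenosine_half_life_s =
                 stats::median(sub$terminal_adenosine_half_life_s,
                               na.rm = TRUE),
               median_decay_coeff = stats::median(sub$decay_coeff,
                                                  na.rm = TRUE),
               median_mrna_half_life_min =
                 stats::median(sub$mrna_half_life_min, na.rm = TRUE),
               flag = if (nrow(sub) == 1) "single_transcript" else "",
               stringsAsFactors = FALSE)
  })
  x <- rates[[cor_columns[1]]]
  y <- rates[[cor_columns[2]]]
  ok <- is.finite(x) & is.finite(y)
  corr <- if (sum(ok) >= 3) {
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman"))
    list(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
  } else list(rho = NA_real_, p_value = NA_real_, n = sum(ok))
  list(groups = do.call(rbind, gs), correlation = corr)
}
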