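#' Read a per-read poly(A)-tail length table
#'
#' Parses the tab-separated per-read output dialect of nanopore tail callers
#' (one row per read with at least a read id, a transcript/contig id, an
#' estimated tail length in adenosines, and a QC tag). Only reads whose QC tag
#' is in `qc_policy` are retained; tag values outside the known vocabulary
#' (`PASS`, `FAIL`, `SUFFCLIP`, `ADAPTER`, `NOREGION`) are mapped to `"other"`,
#' which the default policy excludes. Gzip-compressed files are accepted.
#'
#' @param path path to a plain or gzipped TSV with a header row.
#' @param qc_policy character vector of QC tags to keep. Default `"PASS"`,
#'   the usual quality filter for downstream modelling.
#' @param columns named character vector mapping the required roles
#'   (`read_id`, `transcript_id`, `tail_length`, `qc_tag`) to header names.
#' @param sample_id sample label attached to the table; defaults to the file
#'   name without extension.
#' @param time_min nominal chase time of the sample, minutes (control = 0).
#'
#' @return A `tail_table`: a data.frame with columns `read_id`,
#'   `transcript_id`, `tail_length`, `qc_tag` (row order as in the file) and
#'   attributes `sample_id` and `time_min`.
#' @export
read_polya_table <- function(path,
                             qc_policy = "PASS",
                             columns = c(read_id = "readname",
                                         transcript_id = "contig",
                                         tail_length = "polya_length",
                                         qc_tag = "qc_tag"),
                             sample_id = NULL,
                             time_min = 0) {
  if (!file.exists(path)) stop_tc("file not found: %s", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  need <- c("read_id", "transcript_id", "tail_length", "qc_tag")
  if (!all(need %in% names(columns)))
    stop_tc("'columns' must name all of: %s", paste(need, collapse = ", "))
  miss <- setdiff(unname(columns[need]), names(raw))
  if (length(miss))
    stop_tc("required column(s) missing from %s: %s", path,
            paste(miss, collapse = ", "))
  len_chr <- raw[[columns[["tail_length"]]]]
  len <- suppressWarnings(as.numeric(len_chr))
  bad <- which(is.na(len) & !is.na(len_chr) & nzchar(len_chr) &
                 toupper(len_chr) != "NA")
  if (length(bad))
    stop_tc("unparsable tail length at data row %d of %s: '%s'",
            bad[1], path, len_chr[bad[1]])
  tab <- data.frame(
    read_id = raw[[columns[["read_id"]]]],
    transcript_id = raw[[columns[["transcript_id"]]]],
    tail_length = len,
    qc_tag = normalize_qc_tag(raw[[columns[["qc_tag"]]]]),
    stringsAsFactors = FALSE
  )
  keep <- tab$qc_tag %in% qc_policy & !is.na(tab$tail_length) &
    tab$tail_length >= 0
  new_tail_table(tab[keep, , drop = FALSE],
                 sample_id = sample_id %||%
                   sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path)),
                 time_min = time_min)
}

qc_vocabulary <- c("PASS", "FAIL", "SUFFCLIP", "ADAPTER", "NOREGION")

#' @noRd
normalize_qc_tag <- function(x) {
  x <- toupper(trimws(x))
  ifelse(x %in% qc_vocabulary, x, "other")
}

#' Construct a tail table from in-memory records
#'
#' @param records data.frame with columns `read_id`, `transcript_id`,
#'   `tail_length`, `qc_tag` (missing `qc_tag` defaults to `PASS`).
#' @param sample_id,time_min sample label and nominal chase time (minutes).
#' @return A `tail_table` data.frame.
#' @export
tail_table <- function(records, sample_id = "sample", time_min = 0) {
  if (is.null(records$qc_tag)) records$qc_tag <- rep("PASS", nrow(records))
  if (is.null(records$read_id))
    records$read_id <- sprintf("read_%06d", seq_len(nrow(records)))
  stopifnot(all(c("transcript_id", "tail_length") %in% names(records)))
  if (any(records$tail_length < 0, na.rm = TRUE))
    stop_tc("tail lengths must be non-negative")
  records$qc_tag <- normalize_qc_tag(records$qc_tag)
  new_tail_table(records[c("read_id", "transcript_id", "tail_length",
                           "qc_tag")],
                 sample_id = sample_id, time_min = time_min)
}

#' @noRd
new_tail_table <- function(df, sample_id, time_min) {
  assert_scalar_num(time_min, "time_min", lower = 0)
  rownames(df) <- NULL
  structure(df, sample_id = sample_id, time_min = time_min,
            class = c("tail_table", "data.frame"))
}

#' @export
print.tail_table <- function(x, ...) {
  cat(sprintf("<tail_table> sample '%s', t = %g min, %d reads, %d transcripts\n",
              attr(x, "sample_id"), attr(x, "time_min"), nrow(x),
              length(unique(x$transcript_id))))
  invisible(x)
}

#' Bin per-read tail lengths into an integer-resolution distribution
#'
#' Tail-caller estimates are real-valued; the kinetic model operates on integer
#' adenosine counts, so lengths are rounded half-up to the nearest integer and
#' clamped to `[0, n_max]`.
#'
#' @param table a `tail_table` (optionally pre-filtered to one transcript).
#' @param n_max upper bound of the support, adenosines (default 250).
#' @param label distribution label; defaults to the transcript id when the
#'   table holds a single transcript, else the sample id.
#' @param allow_empty return an all-zero distribution instead of erroring on an
#'   empty table.
#' @return A `tail_distribution`: list with `support` (0..n_max), integer
#'   `counts`, `density` summing to 1, `n_reads`, `label`, `time_min`.
#' @export
build_distribution <- function(table, n_max = 250, label = NULL,
                               allow_empty = FALSE) {
  assert_scalar_num(n_max, "n_max", lower = 1)
  n_max <- as.integer(n_max)
  if (nrow(table) == 0 && !allow_empty) stop_tc("no reads in table")
  # half-up rounding at 1-adenosine resolution
  v <- pmin(pmax(floor(table$tail_length + 0.5), 0), n_max)
  counts <- tabulate(v + 1L, nbins = n_max + 1L)
  if (is.null(label)) {
    tx <- unique(table$transcript_id)
    label <- if (length(tx) == 1L) tx else attr(table, "sample_id") %||% "all"
  }
  new_tail_distribution(counts, n_max = n_max, label = label,
                        time_min = attr(table, "time_min") %||% 0)
}

#' @noRd
new_tail_distribution <- function(counts, n_max, label, time_min,
                                  density = NULL) {
  n_reads <- sum(counts)
  if (is.null(density))
    density <- if (n_reads > 0) counts / n_reads else counts * 0
  structure(list(support = 0:n_max, counts = counts, density = density,
                 n_reads = n_reads, label = label, time_min = time_min),
            class = "tail_distribution")
}

#' @export
print.tail_distribution <- function(x, ...) {
  cat(sprintf("<tail_distribution> '%s', t = %g min, %d reads on 0..%d\n",
              x$label, x$time_min, x$n_reads, max(x$support)))
  invisible(x)
}

#' Merge replicate tail-length distributions
#'
#' Counts are summed and the density renormalised. All inputs must share the
#' same label, support and (within `tol` minutes) timepoint.
#'
#' @param distributions list of `tail_distribution` objects.
#' @param tol tolerance on `time_min` agreement, minutes.
#' @return A merged `tail_distribution`.
#' @export
merge_replicates <- function(distributions, tol = 1e-6) {
  stopifnot(length(distributions) >= 1)
  ref <- distributions[[1]]
  for (d in distributions[-1]) {
    if (!identical(d$label, ref$label))
      stop_tc("cannot merge distributions with labels '%s' and '%s'",
              ref$label, d$label)
    if (length(d$support) != length(ref$support))
      stop_tc("mismatched supports")
    if (abs(d$time_min - ref$time_min) > tol)
      stop_tc("mismatched timepoints: %g vs %g", ref$time_min, d$time_min)
  }
  counts <- Reduce(`+`, lapply(distributions, `[[`, "counts"))
  new_tail_distribution(counts, n_max = max(ref$support), label = ref$label,
                        time_min = ref$time_min)
}

#' Library-size normalisation of per-transcript read counts
#'
#' Excluded transcripts (by default the spike-in-contaminated ENO2) are removed
#' before the library size is computed; transcripts absent from a sample are
#' assigned `na_substitute` (default 0.01 reads) so that downstream log-ratio
#' decay fits remain defined; each sample is then scaled to counts per
#' `scale` (per million by default) of its post-exclusion library.
#'
#' @param counts named list: `sample_id -> named numeric vector` of raw read
#'   counts per transcript (e.g. from [transcript_counts()]).
#' @param excluded_ids transcript ids removed entirely (default `"ENO2"`).
#' @param na_substitute value substituted for transcripts missing from a
#'   sample, in raw-count units, before scaling.
#' @param scale common library scale (1e6 = counts per million).
#' @param scale_mode `"cpm"` (default) divides each sample by its
#'   post-exclusion library size - the right correction when sequencing depth
#'   varies technically between runs, but note that it also removes any decay
#'   component shared by the whole library. `"none"` keeps raw counts (after
#'   exclusion and NA substitution) - appropriate when depth is directly
#'   proportional to the surviving RNA pool, so counts are already on a
#'   common absolute scale.
#' @param time_min optional numeric vector of chase times, one per sample.
#' @return An `abundance_table` data.frame with columns `sample_id`,
#'   `time_min`, `transcript_id`, `raw_count`, `norm_level`.
#' @export
normalize_abundance <- function(counts, excluded_ids = "ENO2",
                                na_substitute = 0.01, scale = 1e6,
                                scale_mode = c("cpm", "none"),
                                time_min = NULL) {
  scale_mode <- match.arg(scale_mode)
  stopifnot(is.list(counts), length(counts) >= 1)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop_tc("'counts' must be a named list of per-sample count vectors")
  if (is.null(time_min)) time_min <- rep(NA_real_, length(counts))
  stopifnot(length(time_min) == length(counts))
  time_min <- unname(time_min)
  counts <- lapply(counts, function(v) v[!(names(v) %in% excluded_ids)])
  all_tx <- sort(unique(unname(unlist(lapply(counts, names)))))
  if (!length(all_tx)) stop_tc("no transcripts left after exclusion")
  out <- vector("list", length(counts))
  for (i in seq_along(counts)) {
    v <- counts[[i]]
    lib <- sum(v)
    if (lib <= 0) stop_tc("all-zero library in sample '%s'", names(counts)[i])
    raw <- v[all_tx]
    names(raw) <- all_tx
    filled <- ifelse(is.na(raw) | raw == 0, na_substitute, raw)
    lev <- if (scale_mode == "cpm") filled / lib * scale else filled
    out[[i]] <- data.frame(
      sample_id = names(counts)[i],
      time_min = time_min[i],
      transcript_id = all_tx,
      raw_count = unname(ifelse(is.na(raw), NA_real_, raw)),
      norm_level = unname(lev),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("abundance_table", "data.frame")
  res
}

#' Per-transcript read counts of a tail table
#'
#' @param table a `tail_table`.
#' @return Named numeric vector of read counts by transcript id.
#' @export
transcript_counts <- function(table) {
  tab <- table(table$transcript_id)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Write tail-length distributions as a tidy TSV histogram
#'
#' @param distributions list of `tail_distribution` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distribution_tsv <- function(distributions, path) {
  if (inherits(distributions, "tail_distribution"))
    distributions <- list(distributions)
  rows <- lapply(distributions, function(d) {
    data.frame(label = d$label, time_min = d$time_min,
               tail_length = d$support, count = d$counts,
               density = d$density, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
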