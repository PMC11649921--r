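# Shared fixtures, generated once per test run and cached. All seeds fixed.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# full-size reference chase for the population-kinetics benchmarks
mex67_chase_fixture <- function() {
  fixture("mex67", function() {
    spec <- chase_preset("mex67_chase", seed = 42)
    list(spec = spec, chase = gen_chase(spec))
  })
}

# 200-transcript correlated panel for per-transcript rate benchmarks
panel_fixture <- function() {
  fixture("panel", function() {
    spec <- chase_preset("transcript_panel", seed = 42)
    list(spec = spec, chase = gen_chase(spec))
  })
}

# small, fast chase for plumbing tests
small_chase_fixture <- function() {
  fixture("small", function() {
    spec <- chase_preset("mex67_chase", seed = 7, n_transcripts = 5,
                         abundance_top_n = 2, reads_per_transcript = 300,
                         n_replicates = 2, timepoints = c(0, 3, 6, 9))
    list(spec = spec, chase = gen_chase(spec))
  })
}

# merged whole-transcriptome distributions of a chase
merged_distributions <- function(chase, n_max = 250) {
  lapply(seq_along(chase$timepoints), function(j)
    merge_replicates(lapply(chase$replicates, function(rep)
      build_distribution(rep$tables[[j]], n_max = n_max,
                         label = "transcriptome"))))
}

mean_recovery <- function(chase) {
  rowMeans(vapply(chase$replicates, `[[`,
                  numeric(length(chase$timepoints)), "recovery"))
}

# write a minimal tail-caller TSV and return its path
write_polya_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

polya_rows <- function(lengths, tags = rep("PASS", length(lengths)),
                       contig = "TX0001") {
  n <- length(lengths)
  data.frame(readname = sprintf("r%03d", seq_len(n)),
             contig = rep(contig, n), position = rep(0, n),
             leader_start = rep(0, n), adapter_start = rep(0, n),
             polya_start = rep(0, n), transcript_start = rep(0, n),
             read_rate = rep(70, n), polya_length = lengths,
             qc_tag = tags, stringsAsFactors = FALSE)
}
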