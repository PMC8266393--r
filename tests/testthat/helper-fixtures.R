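# Shared fixtures: tiny deterministic tracks, gene tables and configs.

# A small simulation config tuned for fast tests; any field can be
# overridden.
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_genes = 40, n_replicates = 2,
                                 seed = 42L), list(...))
  do.call(simulation_config, args)
}

# Coverage track with one chromosome from a plain numeric vector.
track_from_vector <- function(values, chrom = "chrT", norm_state = "raw") {
  coverage_track(stats::setNames(list(values), chrom),
                 norm_state = norm_state)
}

# Dense per-base brute-force window sum (the independent oracle for
# window_signal and the normalization formulas).
dense_window_sum <- function(values, start, end) {
  n <- length(values)
  s <- max(0L, start); e <- min(n, end)
  if (e <= s) return(0)
  sum(values[(s + 1L):e])
}

# Minimal gene table for window/TR tests (boundary coordinate convention
# for minus-strand genes).
toy_genes <- function(chrom = "chrT") {
  data.frame(
    gene_id = c("gPlus", "gMinus"),
    chrom = chrom,
    strand = c("+", "-"),
    start = c(1000L, 3000L), end = c(2000L, 4000L),
    cds_start = c(1100L, 3900L),
    tss = c(1000L, 4000L), pas = c(2000L, 3000L),
    class = c("TFIID", "CR"), biotype = "verified",
    stringsAsFactors = FALSE)
}

# Reverse complement on plain character strings (independent of Biostrings).
rc_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
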