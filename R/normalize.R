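#' Spike-in normalization of ChEC-seq coverage
#'
#' Converts raw per-base read coverage into spike-in normalized signal:
#' every value is divided by the number of D. melanogaster spike-in reads
#' mapped for the sample and multiplied by a fixed scale factor.
#'
#' @param x A raw [coverage_track].
#' @param spike_reads Number of spike-in (D. melanogaster) reads mapped for
#'   this sample; must be positive.
#' @param scale Scale factor applied after division (default 10000).
#' @param sample_id Optional sample name used in error messages.
#' @return A `coverage_track` with `norm_state = "chec_normalized"`.
#' @export
normalize_chec <- function(x, spike_reads, scale = 10000,
                           sample_id = "sample") {
  if (x$norm_state != "raw")
    stop("track is already normalized (state: ", x$norm_state, ")")
  if (!is.finite(spike_reads) || spike_reads <= 0)
    stop("spike-in read total must be > 0 for sample '", sample_id, "'")
  scale_track(x, scale / spike_reads, norm_state = "chec_normalized")
}

#' Input-corrected spike-in normalization of ChIP-seq coverage
#'
#' Every per-base value is divided by the number of S. pombe spike-in reads
#' mapped in the IP sample, multiplied by the ratio of S. pombe to
#' S. cerevisiae reads in the corresponding input sample, and multiplied by a
#' fixed scale factor. With a unit input ratio this reduces to the ChEC
#' formula.
#'
#' @param x A raw [coverage_track] for the IP sample.
#' @param pombe_ip S. pombe read total of the IP sample (> 0).
#' @param pombe_input,cerevisiae_input S. pombe and S. cerevisiae read totals
#'   of the paired input sample (> 0).
#' @param scale Scale factor (default 10000).
#' @param sample_id Optional sample name used in error messages.
#' @return A `coverage_track` with `norm_state = "chip_normalized"`.
#' @export
normalize_chip <- function(x, pombe_ip, pombe_input, cerevisiae_input,
                           scale = 10000, sample_id = "sample") {
  if (x$norm_state != "raw")
    stop("track is already normalized (state: ", x$norm_state, ")")
  if (!is.finite(pombe_ip) || pombe_ip <= 0)
    stop("IP spike-in read total must be > 0 for sample '", sample_id, "'")
  if (!is.finite(pombe_input) || pombe_input <= 0 ||
      !is.finite(cerevisiae_input) || cerevisiae_input <= 0)
    stop("input sample read totals must be > 0 for sample '", sample_id, "'")
  factor <- (scale / pombe_ip) * (pombe_input / cerevisiae_input)
  scale_track(x, factor, norm_state = "chip_normalized")
}

#' Reads-per-million normalization
#'
#' Simple depth normalization used for re-analyzed public datasets that carry
#' no spike-in: values are scaled so the track total equals `scale` per
#' million raw reads.
#'
#' @param x A raw [coverage_track].
#' @param total_reads Total mapped reads of the sample; defaults to the track
#'   total.
#' @return A `coverage_track` with `norm_state = "rpm_normalized"`.
#' @export
normalize_rpm <- function(x, total_reads = track_total(x)) {
  if (x$norm_state != "raw")
    stop("track is already normalized (state: ", x$norm_state, ")")
  if (!is.finite(total_reads) || total_reads <= 0)
    stop("total read count must be > 0")
  scale_track(x, 1e6 / total_reads, norm_state = "rpm_normalized")
}

#' Per-gene ratio of two signal tables
#'
#' Divides one per-gene signal vector by another over the shared gene
#' universe (inner join on gene id). Genes with zero denominator are excluded
#' and counted. Used for, e.g., H4K12ac normalized to H3 at the TSS, or
#' phospho-CTD and kinase signals normalized to total Rpb1.
#'
#' @param numerator,denominator Named numeric vectors (names are gene ids).
#' @return A data.frame with `gene_id`, `numerator`, `denominator`, `ratio`;
#'   attribute `"n_zero_denominator"` counts excluded genes.
#' @export
signal_ratio <- function(numerator, denominator) {
  shared <- intersect(names(numerator), names(denominator))
  if (length(shared) == 0)
    stop("numerator and denominator share no genes")
  num <- numerator[shared]; den <- denominator[shared]
  zero <- !is.na(den) & den == 0
  keep <- !zero & !is.na(num) & !is.na(den)
  out <- data.frame(gene_id = shared[keep],
                    numerator = unname(num[keep]),
                    denominator = unname(den[keep]),
                    ratio = unname(num[keep] / den[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "n_zero_denominator") <- sum(zero)
  out
}
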