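#' Per-base coverage track with a normalization state
#'
#' A `coverage_track` stores nonnegative per-base signal for one or more
#' chromosomes as run-length encoded vectors ([S4Vectors::Rle]), together with
#' a flag recording whether the values are raw read counts or spike-in
#' normalized signal. All coordinates handled by the package are 0-based,
#' half-open, matching the bedGraph convention.
#'
#' @param cov Named list of numeric [S4Vectors::Rle] vectors (or plain numeric
#'   vectors, which are converted), one per chromosome. Names are chromosome
#'   names; the length of each vector is the chromosome length.
#' @param norm_state One of `"raw"`, `"chec_normalized"`, `"chip_normalized"`,
#'   `"rpm_normalized"`.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(cov, norm_state = "raw") {
  norm_state <- match.arg(norm_state,
                          c("raw", "chec_normalized", "chip_normalized",
                            "rpm_normalized"))
  if (is.null(names(cov)) || anyNA(names(cov)) || any(names(cov) == ""))
    stop("'cov' must be a named list (one element per chromosome)")
  cov <- lapply(cov, function(x) {
    x <- if (inherits(x, "Rle")) x else S4Vectors::Rle(as.numeric(x))
    if (any(S4Vectors::runValue(x) < 0))
      stop("coverage values must be nonnegative")
    x
  })
  structure(list(cov = cov, norm_state = norm_state),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track [", x$norm_state, "]\n", sep = "")
  for (chrom in names(x$cov)) {
    v <- x$cov[[chrom]]
    cat(sprintf("  %s: length %d, total %.4g\n", chrom, length(v),
                sum(as.numeric(S4Vectors::runValue(v)) *
                    S4Vectors::runLength(v))))
  }
  invisible(x)
}

#' @rdname coverage_track
#' @param x A `coverage_track`.
#' @export
track_chroms <- function(x) names(x$cov)

#' Total signal of a coverage track
#'
#' @param x A `coverage_track`.
#' @return Sum of per-base values over all chromosomes.
#' @export
track_total <- function(x) {
  sum(vapply(x$cov, function(v)
    sum(as.numeric(S4Vectors::runValue(v)) * S4Vectors::runLength(v)),
    numeric(1)))
}

## Internal: multiply every value by a scalar, keeping run-length form.
scale_track <- function(x, factor, norm_state = x$norm_state) {
  cov <- lapply(x$cov, function(v) v * factor)
  coverage_track(cov, norm_state = norm_state)
}

#' Read a bedGraph file into a coverage_track
#'
#' bedGraph intervals are 0-based, half-open; bases not covered by any
#' interval get value 0. Track definition lines (`track ...`) and comments are
#' ignored.
#'
#' @param path Path to a bedGraph file.
#' @param seqlengths Optional named integer vector of chromosome lengths. When
#'   omitted, each chromosome is sized to the largest end coordinate seen.
#' @param norm_state Normalization state to record on the returned track.
#' @return A [coverage_track].
#' @export
read_bedgraph <- function(path, seqlengths = NULL, norm_state = "raw") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  covs <- GenomicRanges::coverage(gr, weight = "score")
  coverage_track(as.list(covs), norm_state = norm_state)
}

#' Write a coverage_track to a bedGraph file
#'
#' Zero-valued runs are omitted (bedGraph semantics: uncovered means 0).
#' Output is plain text with deterministic formatting, so identical tracks
#' produce byte-identical files.
#'
#' @param x A [coverage_track].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (chrom in names(x$cov)) {
    v <- x$cov[[chrom]]
    ends <- cumsum(S4Vectors::runLength(v))
    starts <- c(0L, ends[-length(ends)])
    vals <- as.numeric(S4Vectors::runValue(v))
    keep <- vals != 0
    if (any(keep)) {
      lines <- sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                       format(vals[keep], trim = TRUE, scientific = FALSE,
                              digits = 10))
      writeLines(lines, con)
    }
  }
  invisible(path)
}

#' Summed signal over a genomic window
#'
#' Sums per-base values over a half-open, 0-based interval. Intervals
#' extending past a chromosome edge are clipped; whether clipping occurred is
#' available via the `"clipped"` attribute.
#'
#' @param x A [coverage_track].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval bounds (`start <= end`).
#' @return Numeric scalar; attribute `"clipped"` is `TRUE` if the interval was
#'   truncated at a chromosome edge.
#' @export
window_signal <- function(x, chrom, start, end) {
  if (!chrom %in% names(x$cov))
    stop("unknown chromosome: ", chrom)
  if (end < start) stop("'end' must be >= 'start'")
  v <- x$cov[[chrom]]
  s <- max(0L, as.integer(start))
  e <- min(length(v), as.integer(end))
  clipped <- (s != start) || (e != end)
  val <- if (e <= s) 0 else
    sum(as.numeric(S4Vectors::window(v, start = s + 1L, end = e)))
  structure(val, clipped = clipped)
}

#' Summed signal over many windows at once
#'
#' Vectorized form of [window_signal()]; windows are clipped at chromosome
#' edges.
#'
#' @param x A [coverage_track].
#' @param chrom Character vector of chromosome names (recycled if length 1).
#' @param start,end Integer vectors of 0-based half-open bounds.
#' @return Numeric vector of window sums.
#' @export
window_signal_many <- function(x, chrom, start, end) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n)
  end <- rep_len(end, n)
  out <- numeric(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (!ch %in% names(x$cov)) stop("unknown chromosome: ", ch)
    v <- x$cov[[ch]]
    s <- pmax(0L, as.integer(start[idx]))
    e <- pmin(length(v), as.integer(end[idx]))
    ok <- e > s
    if (any(ok)) {
      views <- IRanges::Views(v, start = s[ok] + 1L, end = e[ok])
      out[idx[ok]] <- IRanges::viewSums(views)
    }
  }
  out
}

#' Signal over a gene's transcribed region
#'
#' Sums normalized per-base signal between TSS and PAS (half-open interval in
#' genomic coordinates; strand only affects which coordinate is the 5' end,
#' not the sum).
#'
#' @param x A [coverage_track].
#' @param gene A one-row data.frame (or list) with `chrom`, `tss`, `pas`.
#' @return Numeric scalar; `NA` with a warning if `pas` is missing.
#' @export
gene_body_signal <- function(x, gene) {
  if (is.null(gene$pas) || is.na(gene$pas)) {
    warning("gene ", gene$gene_id, " has no PAS; excluded")
    return(NA_real_)
  }
  lo <- min(gene$tss, gene$pas)
  hi <- max(gene$tss, gene$pas)
  as.numeric(window_signal(x, gene$chrom, lo, hi))
}

#' Dense per-base values over a window
#'
#' Materializes the run-length representation as a plain numeric vector for
#' one half-open window (used for summit search and metagene extraction).
#' Out-of-chromosome positions are returned as `NA`.
#'
#' @param x A [coverage_track].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open bounds.
#' @return Numeric vector of length `end - start`.
#' @export
window_values <- function(x, chrom, start, end) {
  if (!chrom %in% names(x$cov)) stop("unknown chromosome: ", chrom)
  v <- x$cov[[chrom]]
  out <- rep(NA_real_, end - start)
  s <- max(0L, as.integer(start)); e <- min(length(v), as.integer(end))
  if (e > s)
    out[(s - start + 1L):(e - start)] <-
      as.numeric(S4Vectors::window(v, start = s + 1L, end = e))
  out
}
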