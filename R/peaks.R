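#' Call enrichment peaks against a control track
#'
#' Sliding-window scan implementing the published calling criteria: a window
#' is a candidate peak only if enriched at least `fold_control`-fold over the
#' (depth-scaled) control and `fold_local`-fold over the local background,
#' and significant at the given FDR. Significance is a Poisson tail
#' probability of the IP window signal given the larger of the control-scaled
#' and local-background expectations, computed on a fixed pseudo-depth scale
#' (`effective_reads`) so that calls are invariant to any rescaling of the
#' input tracks; Benjamini-Hochberg correction is applied across all windows.
#' Overlapping passing windows are merged and the summit of each merged peak
#' is the mid-range of its borders.
#'
#' @param ip,control [coverage_track]s normalized the same way (a free-MNase
#'   track for ChEC, an input track for ChIP). A control with zero total
#'   signal is an error.
#' @param window Candidate window width in bp (default 200).
#' @param step Scan step in bp (default `window / 2`).
#' @param local_span Span of the local-background window in bp (default
#'   10000).
#' @param fold_control,fold_local Minimum enrichment over control and local
#'   background (defaults 2).
#' @param fdr Benjamini-Hochberg false discovery rate (default 0.001).
#' @param effective_reads Pseudo-depth the IP track is rescaled to before
#'   Poisson scoring (default 1e6).
#' @return Data.frame of peaks: `chrom`, `start`, `end`, `summit`,
#'   `fold_vs_control`, `fold_vs_local`, `p_value`.
#' @export
call_peaks <- function(ip, control, window = 200L, step = window %/% 2L,
                       local_span = 10000L, fold_control = 2,
                       fold_local = 2, fdr = 0.001,
                       effective_reads = 1e6) {
  if (ip$norm_state != control$norm_state)
    stop("IP and control tracks must be normalized identically")
  ip_total <- track_total(ip)
  ctrl_total <- track_total(control)
  if (ctrl_total <= 0)
    stop("control track has zero total signal; a control is required")
  if (ip_total <= 0) return(empty_peaks())
  f <- effective_reads / ip_total
  ctrl_scale <- ip_total / ctrl_total

  cand <- list()
  for (chrom in names(ip$cov)) {
    L <- length(ip$cov[[chrom]])
    if (L < window) next
    starts <- seq.int(0L, L - window, by = step)
    ends <- starts + window
    ip_sum <- window_signal_many(ip, chrom, starts, ends)
    ctrl_sum <- if (chrom %in% names(control$cov))
      window_signal_many(control, chrom, starts, ends) else numeric(length(starts))
    centers <- starts + window %/% 2L
    loc_sum <- window_signal_many(ip, chrom,
                                  centers - local_span %/% 2L,
                                  centers + local_span %/% 2L)
    # local expectation per window, excluding the window itself
    loc_exp <- pmax(loc_sum - ip_sum, 0) / pmax(local_span - window, 1L) *
      window
    ctrl_exp <- ctrl_sum * ctrl_scale
    fc_ctrl <- ifelse(ctrl_exp > 0, ip_sum / ctrl_exp, Inf)
    fc_loc <- ifelse(loc_exp > 0, ip_sum / loc_exp, Inf)
    lambda <- pmax(ctrl_exp, loc_exp) * f
    obs <- ip_sum * f
    # continuous Poisson upper tail: P[X >= obs] for X ~ Pois(lambda)
    p <- ifelse(obs > 0,
                stats::pgamma(lambda, shape = obs, lower.tail = TRUE), 1)
    p[lambda <= 0 & obs > 0] <- 0
    cand[[chrom]] <- data.frame(chrom = chrom, start = starts, end = ends,
                                fold_vs_control = fc_ctrl,
                                fold_vs_local = fc_loc, p_value = p,
                                signal = ip_sum, stringsAsFactors = FALSE)
  }
  if (!length(cand)) return(empty_peaks())
  cand <- do.call(rbind, cand)
  cand$q_value <- stats::p.adjust(cand$p_value, method = "BH")
  pass <- cand$signal > 0 & cand$q_value <= fdr &
    cand$fold_vs_control >= fold_control & cand$fold_vs_local >= fold_local
  cand <- cand[pass, , drop = FALSE]
  if (!nrow(cand)) return(empty_peaks())

  out <- list()
  for (chrom in unique(cand$chrom)) {
    cc <- cand[cand$chrom == chrom, , drop = FALSE]
    ir <- IRanges::IRanges(start = cc$start + 1L, end = cc$end)
    red <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(ir, red)
    grp <- S4Vectors::subjectHits(ov)
    agg <- function(v, fun) as.numeric(tapply(v, grp, fun))
    ps <- BiocGenerics::start(red) - 1L
    pe <- BiocGenerics::end(red)
    out[[chrom]] <- data.frame(
      chrom = chrom, start = ps, end = pe,
      summit = peak_summit(ps, pe),
      fold_vs_control = agg(cc$fold_vs_control, max),
      fold_vs_local = agg(cc$fold_vs_local, max),
      p_value = agg(cc$p_value, min),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             summit = integer(), fold_vs_control = numeric(),
             fold_vs_local = numeric(), p_value = numeric(),
             stringsAsFactors = FALSE)
}

#' Peak summit as the mid-range of the borders
#'
#' @param start,end Half-open peak borders (`start < end`); vectorized.
#' @return Integer summit position(s), `floor((start + end) / 2)`.
#' @export
peak_summit <- function(start, end) {
  if (any(end <= start)) stop("peak must satisfy start < end")
  as.integer((as.numeric(start) + as.numeric(end)) %/% 2)
}

#' Assign peaks to promoters by summit position
#'
#' A peak is assigned to a promoter if its summit lies inside the promoter
#' window (by default -300..+100 bp around the TSS, strand-aware). When more
#' than one peak falls in a window, the peak whose summit is closest to the
#' TSS wins; an exact distance tie is broken in favor of the upstream peak
#' (transcription direction), then by peak order, so assignment is
#' deterministic.
#'
#' @param peaks Peak data.frame from [call_peaks()].
#' @param promoters Promoter windows from [promoter_windows()] (must carry
#'   `gene_id`, `chrom`, `strand`, `tss`, `start`, `end`).
#' @return Data.frame with one row per assigned promoter: `gene_id`,
#'   `summit`, `distance` (|summit - tss|), `peak_row` (row index into
#'   `peaks`). Attribute `"unassigned_peaks"` holds row indices of peaks not
#'   assigned to any promoter.
#' @export
assign_peaks_to_promoters <- function(peaks, promoters) {
  if (!nrow(peaks)) {
    out <- data.frame(gene_id = character(), summit = integer(),
                      distance = integer(), peak_row = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "unassigned_peaks") <- integer()
    return(out)
  }
  assigned <- rep(FALSE, nrow(peaks))
  rows <- vector("list", nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    pr <- promoters[i, ]
    hit <- which(peaks$chrom == pr$chrom & peaks$summit >= pr$start &
                 peaks$summit < pr$end)
    if (!length(hit)) next
    d <- abs(peaks$summit[hit] - pr$tss)
    upstream <- if (pr$strand == "+") peaks$summit[hit] < pr$tss
                else peaks$summit[hit] > pr$tss
    ord <- order(d, !upstream, hit)
    best <- hit[ord[1]]
    assigned[hit] <- TRUE
    rows[[i]] <- data.frame(gene_id = pr$gene_id,
                            summit = peaks$summit[best],
                            distance = d[ord[1]], peak_row = best,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(gene_id = character(), summit = integer(),
                      distance = integer(), peak_row = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "unassigned_peaks") <- which(!assigned)
  out
}

#' Replicate consensus of promoter binding
#'
#' A promoter is consensus-bound when it is bound in at least `k` of the `n`
#' replicate experiments (the published presets are 4 of 6 for ChEC-seq and
#' 1 of 2 for ChIP-seq).
#'
#' @param bound Logical matrix, promoters in rows (rownames = gene ids),
#'   replicates in columns.
#' @param k Minimum number of replicates calling the promoter bound.
#' @return Data.frame `gene_id`, `n_bound`, `consensus_bound`.
#' @export
consensus_bound <- function(bound, k) {
  bound <- as.matrix(bound)
  n <- ncol(bound)
  if (k > n) stop("k (", k, ") cannot exceed the number of replicates (",
                  n, ")")
  nb <- rowSums(bound)
  data.frame(gene_id = rownames(bound), n_bound = as.integer(nb),
             consensus_bound = nb >= k, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Promoter occupancy around a peak summit
#'
#' Signal per promoter is the sum of normalized per-base values in a window
#' (default 200 bp) centered on the promoter's peak summit. Promoters with
#' no assigned peak fall back to the position of the strongest signal inside
#' the promoter window: the per-base signal is smoothed with a centered
#' running mean (default 21 bp) and the argmax is used, ties resolved in
#' favor of the position closest to the TSS (then upstream). Promoter windows
#' fully off-chromosome are excluded.
#'
#' @param track A normalized [coverage_track].
#' @param promoters Promoter windows from [promoter_windows()].
#' @param summits Optional named integer vector of peak summits (names =
#'   gene ids), e.g., built from [assign_peaks_to_promoters()]; promoters
#'   absent from it use the fallback.
#' @param width Occupancy window width in bp (default 200).
#' @param smooth_bp Running-mean width for the fallback summit search
#'   (default 21).
#' @return Data.frame `gene_id`, `summit`, `summit_source`
#'   (`"peak"`/`"fallback_max"`), `signal`.
#' @export
promoter_occupancy <- function(track, promoters, summits = NULL,
                               width = 200L, smooth_bp = 21L) {
  half <- width %/% 2L
  rows <- vector("list", nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    pr <- promoters[i, ]
    L <- length(track$cov[[pr$chrom]])
    if (is.null(L) || pr$start >= L || pr$end <= 0) next
    s <- if (!is.null(summits)) summits[pr$gene_id] else NA_integer_
    if (!is.null(summits) && !is.na(s)) {
      source <- "peak"
    } else {
      vals <- window_values(track, pr$chrom, pr$start, pr$end)
      vals[is.na(vals)] <- 0
      sm <- running_mean(vals, smooth_bp)
      pos <- pr$start + seq_along(sm) - 1L
      best <- which(sm == max(sm))
      # within a smoothed plateau, prefer the raw maximum, then the position
      # closest to the TSS, then the upstream one
      d <- abs(pos[best] - pr$tss)
      upstream <- if (pr$strand == "+") pos[best] < pr$tss
                  else pos[best] > pr$tss
      s <- pos[best[order(-vals[best], d, !upstream)[1]]]
      source <- "fallback_max"
    }
    sig <- as.numeric(window_signal(track, pr$chrom, s - half, s + half))
    rows[[i]] <- data.frame(gene_id = pr$gene_id, summit = as.integer(s),
                            summit_source = source, signal = sig,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(gene_id = character(), summit = integer(),
                      summit_source = character(), signal = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## Centered running mean with shrinking edge windows.
running_mean <- function(x, width) {
  n <- length(x)
  h <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Mean log2 occupancy change over paired replicates
#'
#' For each promoter, computes log2(IAA / DMSO) within each replicate pair
#' (pairing by column name / replicate index) and averages the per-pair
#' log2 values. If any occupancy is zero, a pseudocount of half the smallest
#' positive occupancy in the experiment is added to every value (scale-aware,
#' avoids infinities); otherwise no pseudocount is used.
#'
#' @param occ_iaa,occ_dmso Numeric matrices, promoters in rows (rownames =
#'   gene ids), replicate pairs in columns. Columns are paired positionally
#'   and must agree in number.
#' @return Named numeric vector of mean log2 occupancy changes.
#' @export
occupancy_log2_change <- function(occ_iaa, occ_dmso) {
  occ_iaa <- as.matrix(occ_iaa); occ_dmso <- as.matrix(occ_dmso)
  if (ncol(occ_iaa) != ncol(occ_dmso))
    stop("unpaired replicates: ", ncol(occ_iaa), " IAA vs ",
         ncol(occ_dmso), " DMSO columns")
  if (!identical(rownames(occ_iaa), rownames(occ_dmso)))
    stop("IAA and DMSO matrices must cover the same promoters in order")
  vals <- c(occ_iaa, occ_dmso)
  p <- 0
  if (any(vals == 0)) {
    pos <- vals[vals > 0]
    if (!length(pos)) stop("all occupancies are zero")
    p <- min(pos) / 2
  }
  lfc <- log2((occ_iaa + p) / (occ_dmso + p))
  rowMeans(lfc)
}
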