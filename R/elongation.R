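#' Pol II traveling ratio
#'
#' Ratio of polymerase occupancy in a 100-bp window at the beginning of the
#' transcribed region to occupancy in a 100-bp window at its end,
#' strand-resolved: the 5' window is `[tss, tss + 100)` and the 3' window
#' `[pas - 100, pas)` in the transcription direction. Genes shorter than the
#' minimum length (default 300 bp) are excluded by contract; a zero 3' signal
#' makes the ratio undefined (`NA`).
#'
#' @param track A normalized [coverage_track].
#' @param genes Gene model data.frame with `tss` and `pas` assigned.
#' @param window_bp Width of the two anchor windows (default 100).
#' @param min_length Minimum transcribed-region length in bp (default 300).
#' @return Data.frame `gene_id`, `signal_5p`, `signal_3p`, `tr`; genes that
#'   fail the length/annotation contract are absent, and the number of genes
#'   with undefined TR is in attribute `"n_undefined"`.
#' @export
traveling_ratio <- function(track, genes, window_bp = 100L,
                            min_length = 300L) {
  ok <- !is.na(genes$tss) & !is.na(genes$pas) &
    abs(genes$pas - genes$tss) > min_length
  g <- genes[ok, , drop = FALSE]
  fwd <- g$strand == "+"
  s5 <- ifelse(fwd, g$tss, g$tss - window_bp)
  e5 <- ifelse(fwd, g$tss + window_bp, g$tss)
  s3 <- ifelse(fwd, g$pas - window_bp, g$pas)
  e3 <- ifelse(fwd, g$pas, g$pas + window_bp)
  sig5 <- window_signal_many(track, g$chrom, s5, e5)
  sig3 <- window_signal_many(track, g$chrom, s3, e3)
  tr <- ifelse(sig3 > 0, sig5 / sig3, NA_real_)
  out <- data.frame(gene_id = g$gene_id, signal_5p = sig5, signal_3p = sig3,
                    tr = tr, stringsAsFactors = FALSE)
  attr(out, "n_undefined") <- sum(is.na(tr))
  out
}

#' Traveling-ratio change and its relation to transcription change
#'
#' Per gene, computes log2(TR_IAA / TR_DMSO) over genes with a defined TR in
#' both conditions, the Spearman correlation of that change with the
#' transcriptional log2 fold change, and quintile medians of the TR change
#' (quintiles from [quintile_groups()] on the transcription change).
#'
#' @param tr_dmso,tr_iaa Data.frames from [traveling_ratio()] for the two
#'   conditions.
#' @param log2fc Named numeric vector of transcription log2 fold changes.
#' @return List with `per_gene` (gene_id, tr_dmso, tr_iaa, log2_tr_change,
#'   log2fc, quintile), `spearman_r` (NA when undefined), and
#'   `quintile_medians`.
#' @export
tr_change_summary <- function(tr_dmso, tr_iaa, log2fc) {
  shared <- intersect(intersect(tr_dmso$gene_id, tr_iaa$gene_id),
                      names(log2fc))
  if (!length(shared)) stop("no genes shared between TR tables and log2fc")
  d <- tr_dmso$tr[match(shared, tr_dmso$gene_id)]
  i <- tr_iaa$tr[match(shared, tr_iaa$gene_id)]
  keep <- !is.na(d) & !is.na(i) & d > 0 & i > 0
  shared <- shared[keep]; d <- d[keep]; i <- i[keep]
  ltc <- log2(i / d)
  fc <- log2fc[shared]
  r <- if (length(shared) >= 3 && stats::sd(ltc) > 0 && stats::sd(fc) > 0)
    spearman_cor(fc, ltc) else NA_real_
  q <- if (length(fc) >= 5) quintile_groups(fc)
       else rep(NA_character_, length(fc))
  per_gene <- data.frame(gene_id = shared, tr_dmso = d, tr_iaa = i,
                         log2_tr_change = ltc, log2fc = unname(fc),
                         quintile = q, stringsAsFactors = FALSE)
  med <- if (all(is.na(q))) stats::setNames(numeric(0), character(0))
         else tapply(ltc, q, stats::median)
  list(per_gene = per_gene, spearman_r = r,
       quintile_medians = med[order(names(med))])
}

#' Quintile groups by degron dependence
#'
#' Splits genes into five groups of equal size (±1) by their transcriptional
#' log2 fold change. Orientation: Q5 holds the most depletion-dependent genes
#' (most negative log2 change) and Q1 the least dependent. Ties are broken by
#' stable gene order.
#'
#' @param log2fc Named (or plain) numeric vector of finite values, length
#'   >= 5.
#' @return Character vector of labels `"Q1"`..`"Q5"` parallel to `log2fc`.
#' @export
quintile_groups <- function(log2fc) {
  n <- length(log2fc)
  if (n < 5) stop("need at least 5 genes to form quintiles")
  if (any(!is.finite(log2fc))) stop("log2fc must be finite")
  ord <- order(log2fc)                      # stable sort, ascending
  grp <- ceiling(seq_len(n) * 5 / n)        # 1 = most negative ... 5
  labels <- paste0("Q", 6 - grp)            # most negative -> Q5
  out <- character(n)
  out[ord] <- labels
  if (!is.null(names(log2fc))) names(out) <- names(log2fc)
  out
}

#' TSS-anchored metagene profile of log2 occupancy change
#'
#' For each gene group, averages per-base normalized coverage across genes at
#' each offset relative to the TSS (strand-resolved; default -200 to +1000
#' bp), separately for the two conditions, then reports the log2 ratio of the
#' group means (IAA over DMSO). Using log2 of group means (rather than the
#' mean of per-gene log2 values) tolerates per-gene zeros; a per-gene mode is
#' available for sensitivity analysis.
#'
#' @param track_dmso,track_iaa Normalized [coverage_track]s (replicate
#'   averages).
#' @param genes Gene model data.frame with `tss`/`pas`; genes shorter than
#'   `min_length` or missing annotation are dropped.
#' @param groups Named character vector of group labels (names = gene ids);
#'   genes without a label are dropped. Groups with zero genes are omitted
#'   with a warning.
#' @param from,to Offsets relative to TSS in bp (defaults -200 and 1000).
#' @param min_length Minimum transcribed length in bp (default 1000).
#' @param per_gene If `TRUE`, average per-gene log2 ratios (a small
#'   pseudocount of half the smallest positive per-base mean is applied)
#'   instead of taking log2 of group means.
#' @return Data.frame `offset`, `group`, `mean_dmso`, `mean_iaa`,
#'   `log2_change`, `n_genes`.
#' @export
metagene_log2_profile <- function(track_dmso, track_iaa, genes, groups,
                                  from = -200L, to = 1000L,
                                  min_length = 1000L, per_gene = FALSE) {
  ok <- !is.na(genes$tss) & !is.na(genes$pas) &
    abs(genes$pas - genes$tss) >= min_length &
    genes$gene_id %in% names(groups)
  g <- genes[ok, , drop = FALSE]
  lab <- groups[g$gene_id]
  offsets <- seq.int(from, to - 1L)
  empty <- setdiff(unique(groups), unique(lab))
  if (length(empty))
    warning("group(s) with zero usable genes omitted: ",
            paste(empty, collapse = ", "))
  rows <- list()
  for (grp in sort(unique(lab))) {
    idx <- which(lab == grp)
    acc_d <- matrix(0, nrow = length(idx), ncol = length(offsets))
    acc_i <- acc_d
    for (j in seq_along(idx)) {
      gg <- g[idx[j], ]
      if (gg$strand == "+") {
        v_d <- window_values(track_dmso, gg$chrom, gg$tss + from, gg$tss + to)
        v_i <- window_values(track_iaa, gg$chrom, gg$tss + from, gg$tss + to)
      } else {
        v_d <- rev(window_values(track_dmso, gg$chrom, gg$tss - to,
                                 gg$tss - from))
        v_i <- rev(window_values(track_iaa, gg$chrom, gg$tss - to,
                                 gg$tss - from))
      }
      acc_d[j, ] <- v_d; acc_i[j, ] <- v_i
    }
    if (per_gene) {
      pos <- c(acc_d[acc_d > 0], acc_i[acc_i > 0])
      p <- if (length(pos)) min(pos, na.rm = TRUE) / 2 else 1
      lratio <- log2((acc_i + p) / (acc_d + p))
      lc <- colMeans(lratio, na.rm = TRUE)
      md <- colMeans(acc_d, na.rm = TRUE); mi <- colMeans(acc_i, na.rm = TRUE)
    } else {
      md <- colMeans(acc_d, na.rm = TRUE); mi <- colMeans(acc_i, na.rm = TRUE)
      lc <- log2(mi / md)
    }
    rows[[grp]] <- data.frame(offset = offsets, group = grp, mean_dmso = md,
                              mean_iaa = mi, log2_change = lc,
                              n_genes = length(idx),
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Change in phosphorylation (or factor) status normalized to Rpb1
#'
#' Per gene: `log2[(P_IAA / R_IAA) / (P_DMSO / R_DMSO)]`, where P is the
#' gene-body signal of a phospho-CTD mark (or elongation factor/kinase) and R
#' the matching total Rpb1 signal. Genes with zero Rpb1 signal in either
#' condition are excluded and counted. Because the statistic is a ratio of
#' ratios, any per-condition global scaling cancels exactly.
#'
#' @param phospho_dmso,phospho_iaa,rpb1_dmso,rpb1_iaa Named numeric vectors
#'   of gene-body signals (names = gene ids).
#' @return Named numeric vector of log2 ratio changes over the shared gene
#'   set; attribute `"n_excluded"` counts genes dropped for zero Rpb1 or
#'   zero phospho signal.
#' @export
phospho_status_change <- function(phospho_dmso, phospho_iaa,
                                  rpb1_dmso, rpb1_iaa) {
  shared <- Reduce(intersect, list(names(phospho_dmso), names(phospho_iaa),
                                   names(rpb1_dmso), names(rpb1_iaa)))
  if (!length(shared)) stop("inputs share no genes")
  pd <- phospho_dmso[shared]; pi_ <- phospho_iaa[shared]
  rd <- rpb1_dmso[shared]; ri <- rpb1_iaa[shared]
  keep <- rd > 0 & ri > 0 & pd > 0 & pi_ > 0
  out <- log2((pi_[keep] / ri[keep]) / (pd[keep] / rd[keep]))
  attr(out, "n_excluded") <- sum(!keep)
  out
}
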