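#' Gene-by-sample expression table with a processing state
#'
#' Thin wrapper around a numeric matrix that records whether the values are
#' raw counts, spike-in normalized signal, or per-condition replicate
#' averages. State moves only forward (raw -> normalized -> averaged), which
#' catches accidental double normalization.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param state One of `"raw"`, `"normalized"`, `"averaged"`.
#' @return An `expression_table`.
#' @export
expression_table <- function(values, state = "raw") {
  state <- match.arg(state, c("raw", "normalized", "averaged"))
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE))
    stop("expression values must be nonnegative")
  if (is.null(rownames(values)))
    stop("'values' must have gene ids as rownames")
  structure(list(values = values, state = state),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table [%s]: %d genes x %d samples\n",
              x$state, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Build a sample sheet
#'
#' @param sample_id Character vector of unique sample names (these match
#'   count-table columns and track names).
#' @param assay `"rnaseq"`, `"chec"` or `"chip"`.
#' @param condition `"DMSO"` or `"IAA"`.
#' @param replicate Integer replicate index; (condition, replicate) pairs
#'   must be unique within an experiment.
#' @param spike_reads Spike-in read totals (S. pombe for RNA-seq/ChIP,
#'   D. melanogaster for ChEC).
#' @param experimental_reads Experimental-genome read totals.
#' @param input_link For ChIP samples, the `sample_id` of the paired input.
#' @return A data.frame sample sheet.
#' @export
sample_sheet <- function(sample_id, assay, condition, replicate,
                         spike_reads, experimental_reads = NA_real_,
                         input_link = NA_character_) {
  if (anyDuplicated(sample_id)) stop("sample ids must be unique")
  meta <- data.frame(sample_id = sample_id, assay = assay,
                     condition = condition, replicate = replicate,
                     spike_reads = spike_reads,
                     experimental_reads = experimental_reads,
                     input_link = input_link, stringsAsFactors = FALSE)
  if (!all(meta$condition %in% c("DMSO", "IAA")))
    stop("condition must be 'DMSO' or 'IAA'")
  if (anyDuplicated(meta[, c("assay", "condition", "replicate")]))
    stop("(condition, replicate) pairs must be unique within an assay")
  meta
}

#' Spike-in normalization of per-gene counts
#'
#' Each sample's counts are divided by that sample's spike-in read total and
#' multiplied by a fixed scale factor.
#'
#' @param x An `expression_table` in state `"raw"`.
#' @param meta Sample sheet with `sample_id` and `spike_reads` covering all
#'   columns of `x`.
#' @param scale Scale factor (default 10000).
#' @return An `expression_table` in state `"normalized"`.
#' @export
normalize_counts <- function(x, meta, scale = 10000) {
  if (x$state != "raw") stop("table is already ", x$state)
  idx <- match(colnames(x$values), meta$sample_id)
  if (anyNA(idx))
    stop("samples missing from sheet: ",
         paste(colnames(x$values)[is.na(idx)], collapse = ", "))
  spikes <- meta$spike_reads[idx]
  bad <- !is.finite(spikes) | spikes <= 0
  if (any(bad))
    stop("spike-in read total must be > 0; offending sample(s): ",
         paste(colnames(x$values)[bad], collapse = ", "))
  values <- sweep(x$values, 2, scale / spikes, `*`)
  expression_table(values, state = "normalized")
}

#' Average biological replicates within each condition
#'
#' @param x An `expression_table` in state `"normalized"` (raw tables are
#'   refused so averaging never precedes normalization).
#' @param meta Sample sheet covering all columns of `x`.
#' @return An `expression_table` in state `"averaged"` with one column per
#'   condition.
#' @export
average_replicates <- function(x, meta) {
  if (x$state != "normalized")
    stop("replicates are averaged after normalization (state: ", x$state, ")")
  idx <- match(colnames(x$values), meta$sample_id)
  if (anyNA(idx)) stop("samples missing from sheet")
  cond <- meta$condition[idx]
  out <- vapply(unique(cond), function(cn)
    rowMeans(x$values[, cond == cn, drop = FALSE]),
    numeric(nrow(x$values)))
  out <- matrix(out, nrow = nrow(x$values),
                dimnames = list(rownames(x$values), unique(cond)))
  expression_table(out, state = "averaged")
}

#' Per-gene log2 change between conditions
#'
#' `log2((iaa + p) / (dmso + p))`. The default pseudocount is 0 because the
#' detectability filter guarantees positive signal; a zero denominator with
#' `pseudocount = 0` is an error that points at the filter.
#'
#' @param iaa,dmso Named numeric vectors (or single columns of an averaged
#'   table) over the same gene set.
#' @param pseudocount Added to both numerator and denominator (default 0).
#' @return Named numeric vector of log2 fold changes.
#' @export
log2_change <- function(iaa, dmso, pseudocount = 0) {
  if (length(iaa) != length(dmso))
    stop("'iaa' and 'dmso' must cover the same gene set")
  if (!is.null(names(iaa)) && !is.null(names(dmso)) &&
      !identical(names(iaa), names(dmso)))
    stop("'iaa' and 'dmso' must be in the same gene order")
  if (pseudocount == 0 && any(dmso == 0 | iaa == 0))
    stop("zero signal with pseudocount 0; apply filter_detectable() first ",
         "or set a positive pseudocount")
  log2((iaa + pseudocount) / (dmso + pseudocount))
}

#' Replicate coefficient of variation
#'
#' Per gene and condition, CV = sample standard deviation / mean across
#' replicates (n - 1 denominator). Genes with zero mean have undefined CV;
#' they are excluded from the summary and counted.
#'
#' @param x An `expression_table` in state `"normalized"`.
#' @param meta Sample sheet covering all columns of `x`; each condition needs
#'   at least 2 replicates.
#' @return List with `per_gene` (data.frame gene_id, condition, cv),
#'   `median_cv` (over all defined CVs), and `n_undefined`.
#' @export
replicate_cv <- function(x, meta) {
  if (x$state != "normalized")
    stop("CV is computed on normalized replicate columns")
  idx <- match(colnames(x$values), meta$sample_id)
  cond <- meta$condition[idx]
  recs <- lapply(unique(cond), function(cn) {
    m <- x$values[, cond == cn, drop = FALSE]
    if (ncol(m) < 2)
      stop("condition ", cn, " has fewer than 2 replicates")
    mu <- rowMeans(m)
    sds <- apply(m, 1, stats::sd)
    data.frame(gene_id = rownames(m), condition = cn,
               cv = ifelse(mu > 0, sds / mu, NA_real_),
               stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, recs)
  list(per_gene = per_gene,
       median_cv = stats::median(per_gene$cv, na.rm = TRUE),
       n_undefined = sum(is.na(per_gene$cv)))
}

#' Per-class summary of log2 fold changes
#'
#' Summarizes per-gene log2 changes within gene classes (e.g.,
#' TFIID-dependent vs coactivator-redundant). The median fold decrease is
#' `2^(-median log2fc)`; because the median commutes with monotone
#' transforms, this equals the median of the per-gene linear fold decreases.
#' Empty classes are omitted rather than reported as zero.
#'
#' @param log2fc Named numeric vector of per-gene log2 fold changes.
#' @param classes Character vector of class labels, parallel to `log2fc` (or
#'   named, in which case it is matched by gene id).
#' @return Data.frame with `class`, `n`, `median_log2fc`,
#'   `median_fold_decrease`.
#' @export
class_summary <- function(log2fc, classes) {
  if (!is.null(names(classes)) && !is.null(names(log2fc)))
    classes <- classes[names(log2fc)]
  if (length(classes) != length(log2fc))
    stop("'classes' must label every gene in 'log2fc'")
  keep <- !is.na(classes) & !is.na(log2fc)
  sp <- split(log2fc[keep], classes[keep])
  sp <- sp[vapply(sp, length, integer(1)) > 0]
  data.frame(class = names(sp),
             n = vapply(sp, length, integer(1)),
             median_log2fc = vapply(sp, stats::median, numeric(1)),
             median_fold_decrease =
               vapply(sp, function(v) 2^(-stats::median(v)), numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-call nascent RNA-seq fold-change pipeline
#'
#' Runs the canonical order of operations -- spike normalization, the
#' every-sample detectability filter, replicate averaging, and per-gene log2
#' change (IAA over DMSO) -- on a raw count matrix.
#'
#' @param counts Integer matrix of raw counts (rownames = gene ids, colnames
#'   = sample ids).
#' @param meta Sample sheet covering all columns, with DMSO and IAA
#'   conditions.
#' @param scale Spike normalization scale factor (default 10000).
#' @param reference Optional reference gene list intersected with the
#'   detectable set.
#' @return Named numeric vector of per-gene log2 fold changes over the
#'   retained gene set.
#' @export
rnaseq_log2fc <- function(counts, meta, scale = 10000, reference = NULL) {
  keep <- filter_detectable(counts, reference = reference)
  norm <- normalize_counts(expression_table(counts[keep, , drop = FALSE]),
                           meta, scale = scale)
  avg <- average_replicates(norm, meta)
  log2_change(avg$values[, "IAA"], avg$values[, "DMSO"])
}
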