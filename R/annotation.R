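#' Load gene models from a TSV or GFF3 annotation
#'
#' Reads gene annotation and drops biotypes that are excluded from all
#' downstream analysis (dubious ORFs, pseudogenes, transposable elements;
#' matching is case-insensitive). Genes are returned sorted by
#' (chrom, start). All coordinates are converted to the package-internal
#' 0-based half-open convention; GFF3 input is read as 1-based inclusive.
#'
#' The TSV dialect has columns `gene_id`, `chrom`, `strand`, `start`, `end`,
#' `cds_start`, and optionally `tss`, `pas`, `class`, `biotype`. GFF3 input
#' uses records of type `gene` and reads the same fields from the attribute
#' column (`ID` for gene_id; attribute keys configurable).
#'
#' @param path Annotation file (`.tsv`/`.txt` or `.gff`/`.gff3`).
#' @param exclude_biotypes Character vector of biotypes to remove.
#' @param gff_attr Named list mapping internal field names to GFF3 attribute
#'   keys.
#' @return A data.frame of gene models with columns `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `cds_start`, `tss`, `pas`, `class`, `biotype`;
#'   attribute `"n_excluded"` records how many genes were dropped by the
#'   biotype filter.
#' @export
load_genes <- function(path,
                       exclude_biotypes = c("dubious", "pseudogene",
                                            "transposable_element"),
                       gff_attr = list(gene_id = "ID", biotype = "biotype",
                                       tss = "tss", pas = "pas",
                                       class = "gene_class",
                                       cds_start = "cds_start")) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    md <- S4Vectors::mcols(gr)
    pick <- function(key, default = NA) {
      if (!is.null(key) && key %in% colnames(md)) {
        v <- md[[key]]
        if (methods::is(v, "List")) v <- vapply(v, function(e)
          if (length(e)) as.character(e[[1]]) else NA_character_,
          character(1))
        as.character(v)
      } else rep(default, length(gr))
    }
    genes <- data.frame(
      gene_id = pick(gff_attr$gene_id),
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      strand = as.character(BiocGenerics::strand(gr)),
      start = BiocGenerics::start(gr) - 1L,  # to 0-based half-open
      end = BiocGenerics::end(gr),
      cds_start = suppressWarnings(as.integer(pick(gff_attr$cds_start))),
      tss = suppressWarnings(as.integer(pick(gff_attr$tss))),
      pas = suppressWarnings(as.integer(pick(gff_attr$pas))),
      class = pick(gff_attr$class, default = "unassigned"),
      biotype = pick(gff_attr$biotype, default = "verified"),
      stringsAsFactors = FALSE)
  } else {
    genes <- utils::read.delim(path, stringsAsFactors = FALSE)
    required <- c("gene_id", "chrom", "strand", "start", "end", "cds_start")
    missing <- setdiff(required, names(genes))
    if (length(missing))
      stop("annotation TSV lacks columns: ", paste(missing, collapse = ", "))
    for (col in c("tss", "pas"))
      if (!col %in% names(genes)) genes[[col]] <- NA_integer_
    if (!"class" %in% names(genes)) genes$class <- "unassigned"
    if (!"biotype" %in% names(genes)) genes$biotype <- "verified"
  }
  bad <- !is.finite(genes$start) | !is.finite(genes$end) |
    genes$start < 0 | genes$end <= genes$start
  if (any(bad))
    stop("malformed coordinates in annotation record(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  keep <- !(tolower(genes$biotype) %in% tolower(exclude_biotypes))
  n_excluded <- sum(!keep)
  genes <- genes[keep, , drop = FALSE]
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  attr(genes, "n_excluded") <- n_excluded
  genes
}

#' Write gene models to TSV or GFF3
#'
#' Inverse of [load_genes()]; GFF3 output stores TSS/PAS/class/biotype as
#' attributes so that the two formats round-trip to identical gene models.
#'
#' @param genes Gene model data.frame.
#' @param path Output path.
#' @param format `"tsv"` or `"gff3"`.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(genes, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = genes$chrom,
      ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
      strand = genes$strand)
    gr$type <- "gene"
    gr$ID <- genes$gene_id
    gr$cds_start <- genes$cds_start
    gr$tss <- genes$tss
    gr$pas <- genes$pas
    gr$gene_class <- genes$class
    gr$biotype <- genes$biotype
    rtracklayer::export(gr, path, format = "gff3")
  }
  invisible(path)
}

#' Fill in missing TSS annotations
#'
#' Merges an external TSS/PAS table into the gene models. Genes without a
#' table entry get a fallback TSS placed 100 bp upstream of the start codon
#' in the transcription direction (`cds_start - 100` on the plus strand,
#' `cds_start + 100` on the minus strand). A table TSS that lies on the wrong
#' chromosome is rejected with a warning and the fallback is applied. Each
#' gene records whether its TSS came from the table or the fallback.
#'
#' @param genes Gene model data.frame from [load_genes()].
#' @param tss_table Optional data.frame with `gene_id`, `tss`, and optionally
#'   `pas` and `chrom` (chrom, when present, is validated).
#' @param offset Fallback distance upstream of the start codon (default 100).
#' @return `genes` with `tss`, `pas` filled and a `tss_source` column
#'   (`"table"` or `"fallback"`).
#' @export
assign_tss <- function(genes, tss_table = NULL, offset = 100L) {
  genes$tss_source <- ifelse(is.na(genes$tss), NA_character_, "table")
  if (!is.null(tss_table)) {
    idx <- match(genes$gene_id, tss_table$gene_id)
    hit <- !is.na(idx)
    ok <- hit
    if ("chrom" %in% names(tss_table)) {
      wrong <- hit & tss_table$chrom[idx] != genes$chrom &
        !is.na(tss_table$tss[idx])
      if (any(wrong)) {
        warning(sum(wrong), " table TSS entr(ies) on the wrong chromosome; ",
                "fallback applied")
        ok <- hit & !wrong
      }
    }
    take <- ok & !is.na(tss_table$tss[idx])
    genes$tss[take] <- as.integer(tss_table$tss[idx[take]])
    genes$tss_source[take] <- "table"
    if ("pas" %in% names(tss_table)) {
      take_pas <- ok & !is.na(tss_table$pas[idx])
      genes$pas[take_pas] <- as.integer(tss_table$pas[idx[take_pas]])
    }
  }
  miss <- is.na(genes$tss)
  fwd <- genes$strand == "+"
  genes$tss[miss & fwd] <- genes$cds_start[miss & fwd] - as.integer(offset)
  genes$tss[miss & !fwd] <- genes$cds_start[miss & !fwd] + as.integer(offset)
  genes$tss_source[miss] <- "fallback"
  genes
}

#' Strand-aware promoter window around a TSS
#'
#' Builds the half-open genomic interval covering `upstream` bp upstream to
#' `downstream` bp downstream of the TSS, in the transcription direction
#' (default -300..+100). Windows are clipped at chromosome edges when a
#' chromosome length is supplied; clipping is recorded.
#'
#' @param gene One-row data.frame (or list) with `gene_id`, `chrom`,
#'   `strand`, `tss`.
#' @param upstream,downstream Window extents in bp (defaults 300 and 100).
#' @param chrom_length Optional chromosome length used to clip the right
#'   edge.
#' @return A one-row data.frame `gene_id`, `chrom`, `start`, `end`,
#'   `clipped`.
#' @export
promoter_window <- function(gene, upstream = 300L, downstream = 100L,
                            chrom_length = NULL) {
  if (is.null(gene$tss) || is.na(gene$tss))
    stop("gene ", gene$gene_id, " has no TSS; run assign_tss() first")
  if (gene$strand == "+") {
    start <- gene$tss - upstream; end <- gene$tss + downstream
  } else {
    start <- gene$tss - downstream; end <- gene$tss + upstream
  }
  clipped <- FALSE
  if (start < 0) { start <- 0L; clipped <- TRUE }
  if (!is.null(chrom_length) && end > chrom_length) {
    end <- chrom_length; clipped <- TRUE
  }
  data.frame(gene_id = gene$gene_id, chrom = gene$chrom,
             start = as.integer(start), end = as.integer(end),
             clipped = clipped, stringsAsFactors = FALSE)
}

#' Promoter windows for a whole gene table
#'
#' @param genes Gene model data.frame with `tss` assigned.
#' @param upstream,downstream Window extents in bp.
#' @param seqlengths Optional named vector of chromosome lengths for
#'   clipping.
#' @return Data.frame with one window per gene (same order as `genes`).
#' @export
promoter_windows <- function(genes, upstream = 300L, downstream = 100L,
                             seqlengths = NULL) {
  if (anyNA(genes$tss)) stop("all genes need a TSS; run assign_tss() first")
  fwd <- genes$strand == "+"
  start <- ifelse(fwd, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(fwd, genes$tss + downstream, genes$tss + upstream)
  clipped <- start < 0
  start <- pmax(start, 0L)
  if (!is.null(seqlengths)) {
    lim <- seqlengths[genes$chrom]
    over <- !is.na(lim) & end > lim
    clipped <- clipped | over
    end[over] <- lim[over]
  }
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             strand = genes$strand, tss = genes$tss,
             start = as.integer(start), end = as.integer(end),
             clipped = clipped, stringsAsFactors = FALSE)
}

#' Classify promoters by TATA-box consensus
#'
#' Scans the sense strand of each promoter for the TATA consensus TATAWAW
#' (W = A or T) inside a window upstream of the TSS (default -200..TSS in the
#' transcription direction). Ambiguous bases (N) in the genome never match.
#'
#' @param genes Gene model data.frame with `tss` assigned.
#' @param genome A [Biostrings::DNAStringSet] (or path to a FASTA file)
#'   covering all scan windows.
#' @param upstream,downstream Scan window extents relative to the TSS
#'   (defaults 200 and 0).
#' @param motif Consensus to scan for (IUPAC codes allowed; default
#'   `"TATAWAW"`).
#' @return Logical vector, one flag per gene (`TRUE` = TATA-containing).
#' @export
classify_tata <- function(genes, genome, upstream = 200L, downstream = 0L,
                          motif = "TATAWAW") {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (!all(genes$chrom %in% names(genome)))
    stop("genome is missing chromosome(s): ",
         paste(setdiff(genes$chrom, names(genome)), collapse = ", "))
  fwd <- genes$strand == "+"
  start <- ifelse(fwd, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(fwd, genes$tss + downstream, genes$tss + upstream)
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  start <- pmax(start, 0L)
  end <- pmin(end, lens[genes$chrom])
  flags <- logical(nrow(genes))
  nonempty <- end > start
  if (any(nonempty)) {
    seqs <- Biostrings::DNAStringSet(lapply(which(nonempty), function(i) {
      s <- Biostrings::subseq(genome[[genes$chrom[i]]],
                              start = start[i] + 1L, end = end[i])
      if (!fwd[i]) s <- Biostrings::reverseComplement(s)
      s
    }))
    hits <- Biostrings::vcountPattern(motif, seqs, fixed = "subject")
    flags[nonempty] <- hits > 0
  }
  flags
}

#' Keep genes with measurable signal in every sample
#'
#' A gene is retained only if its raw count is greater than zero in all
#' samples. Optionally intersects the result with an externally supplied
#' reference gene list (e.g., a previously published high-reproducibility
#' set).
#'
#' @param counts Numeric matrix of raw counts, rownames = gene ids.
#' @param genes Optional gene model data.frame; counts rows absent from it
#'   are dropped with a warning.
#' @param reference Optional character vector of gene ids to intersect with.
#' @return Character vector of retained gene ids (in `counts` row order).
#' @export
filter_detectable <- function(counts, genes = NULL, reference = NULL) {
  ids <- rownames(counts)
  if (is.null(ids)) stop("'counts' must have gene ids as rownames")
  if (!is.null(genes)) {
    unknown <- setdiff(ids, genes$gene_id)
    if (length(unknown)) {
      warning(length(unknown),
              " gene(s) in counts absent from annotation; dropped")
      counts <- counts[ids %in% genes$gene_id, , drop = FALSE]
      ids <- rownames(counts)
    }
  }
  keep <- apply(counts > 0, 1, all)
  retained <- ids[keep]
  if (!is.null(reference)) retained <- retained[retained %in% reference]
  retained
}
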