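make_ann_tsv <- function(genes, path = tempfile(fileext = ".tsv")) {
  write_genes(genes, path, format = "tsv")
  path
}

test_that("load_genes drops excluded biotypes and sorts by position", {
  g <- toy_genes()
  g <- rbind(g, within(g[1, ], {
    gene_id <- "gDubious"; biotype <- "Dubious"; start <- 500L; end <- 900L
    tss <- 500L; pas <- 900L; cds_start <- 600L
  }))
  path <- make_ann_tsv(g)
  loaded <- load_genes(path)
  expect_equal(nrow(loaded), 2)
  expect_false("gDubious" %in% loaded$gene_id)
  expect_equal(attr(loaded, "n_excluded"), 1)
  expect_equal(loaded$start, sort(loaded$start))
})

test_that("load_genes handles empty tables and malformed coordinates", {
  empty <- toy_genes()[0, ]
  expect_equal(nrow(load_genes(make_ann_tsv(empty))), 0)
  bad <- toy_genes()
  bad$end[1] <- bad$start[1]          # zero-length gene
  expect_error(load_genes(make_ann_tsv(bad)), "malformed coordinates")
})

test_that("TSV and GFF3 readers yield identical gene models", {
  cfg <- tiny_config()
  ann <- simulate_annotation(cfg)
  genes <- ann$genes[1:10, ]
  tsv <- tempfile(fileext = ".tsv"); gff <- tempfile(fileext = ".gff3")
  write_genes(genes, tsv, "tsv")
  write_genes(genes, gff, "gff3")
  a <- load_genes(tsv); b <- load_genes(gff)
  for (col in c("gene_id", "chrom", "strand", "start", "end", "cds_start",
                "tss", "pas", "class", "biotype"))
    expect_equal(a[[col]], b[[col]], info = col)
})

test_that("assign_tss applies the -100 bp start-codon fallback per strand", {
  g <- data.frame(gene_id = c("gp", "gm", "gt"), chrom = "chrT",
                  strand = c("+", "-", "+"),
                  start = c(900L, 900L, 900L), end = c(2000L, 2000L, 2000L),
                  cds_start = c(1000L, 1000L, 1000L),
                  tss = NA_integer_, pas = NA_integer_,
                  stringsAsFactors = FALSE)
  tbl <- data.frame(gene_id = "gt", tss = 850L)
  out <- assign_tss(g, tbl)
  expect_equal(out$tss[out$gene_id == "gp"], 900)   # cds_start - 100
  expect_equal(out$tss[out$gene_id == "gm"], 1100)  # strand mirror
  expect_equal(out$tss[out$gene_id == "gt"], 850)
  expect_equal(out$tss_source, c("fallback", "fallback", "table"))
})

test_that("assign_tss rejects table TSS on the wrong chromosome", {
  g <- data.frame(gene_id = "g1", chrom = "chrT", strand = "+",
                  start = 900L, end = 2000L, cds_start = 1000L,
                  tss = NA_integer_, pas = NA_integer_,
                  stringsAsFactors = FALSE)
  tbl <- data.frame(gene_id = "g1", chrom = "chrZ", tss = 850L)
  expect_warning(out <- assign_tss(g, tbl), "wrong chromosome")
  expect_equal(out$tss, 900)
  expect_equal(out$tss_source, "fallback")
})

test_that("promoter windows are strand-mirrored -300..+100 intervals", {
  gp <- list(gene_id = "gp", chrom = "chrT", strand = "+", tss = 5000L)
  gm <- list(gene_id = "gm", chrom = "chrT", strand = "-", tss = 5000L)
  wp <- promoter_window(gp); wm <- promoter_window(gm)
  expect_equal(c(wp$start, wp$end), c(4700, 5100))
  expect_equal(c(wm$start, wm$end), c(4900, 5300))
  expect_equal(wp$end - wp$start, wm$end - wm$start)
  # clipping at the chromosome start
  edge <- promoter_window(list(gene_id = "e", chrom = "chrT",
                               strand = "+", tss = 100L))
  expect_equal(c(edge$start, edge$end), c(0, 200))
  expect_true(edge$clipped)
  expect_error(promoter_window(list(gene_id = "x", chrom = "chrT",
                                    strand = "+", tss = NA)), "no TSS")
  # vectorized form agrees with the scalar form
  g <- toy_genes()
  pw <- promoter_windows(g)
  expect_equal(pw$start, c(promoter_window(g[1, ])$start,
                           promoter_window(g[2, ])$start))
})

test_that("classify_tata agrees with an independent regex scan", {
  cfg <- tiny_config(tata_fraction_per_class = c(TFIID = 0.5, CR = 0.5))
  ann <- simulate_annotation(cfg)
  flags <- classify_tata(ann$genes, ann$genome)
  # independent oracle: character-level extraction + regex
  seq_str <- as.character(ann$genome[["chrS"]])
  oracle <- vapply(seq_len(nrow(ann$genes)), function(i) {
    g <- ann$genes[i, ]
    win <- if (g$strand == "+")
      substr(seq_str, g$tss - 200 + 1, g$tss)
    else rc_chr(substr(seq_str, g$tss + 1, g$tss + 200))
    grepl("TATA[AT]A[AT]", win)
  }, logical(1))
  expect_equal(flags, oracle)
  expect_equal(flags, ann$genes$tata)  # planted flags are exact truth
})

test_that("classify_tata sees the consensus and only the scan window", {
  base <- strrep("GC", 400)
  genome <- Biostrings::DNAStringSet(c(chrT = paste0(base, strrep("C", 200))))
  g <- data.frame(gene_id = c("hit", "miss"), chrom = "chrT",
                  strand = "+", tss = c(600L, 600L),
                  stringsAsFactors = FALSE)
  # plant TATATAA inside the scan window of gene 'hit' only
  s <- as.character(genome[[1]])
  substr(s, 450, 456) <- "TATATAA"
  genome_hit <- Biostrings::DNAStringSet(c(chrT = s))
  expect_equal(classify_tata(g, genome_hit), c(TRUE, TRUE))
  expect_equal(classify_tata(g, genome), c(FALSE, FALSE))
  # sequence outside the window does not matter
  s2 <- as.character(genome[[1]])
  substr(s2, 650, 656) <- "TATATAA"  # downstream of the TSS
  expect_equal(classify_tata(g, Biostrings::DNAStringSet(c(chrT = s2))),
               c(FALSE, FALSE))
})

test_that("filter_detectable keeps genes positive in every sample", {
  m <- matrix(c(5, 3, 2, 1,
                4, 0, 7, 2,
                9, 8, 1, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  expect_equal(filter_detectable(m), c("g1", "g3"))
  all_pos <- matrix(1:12, nrow = 3,
                    dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(filter_detectable(all_pos), paste0("g", 1:3))
  # brute-force oracle on a random matrix
  set.seed(5)
  r <- matrix(rpois(1000, 2), nrow = 100,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:10)))
  expect_equal(filter_detectable(r),
               rownames(r)[vapply(seq_len(100), function(i)
                 all(r[i, ] > 0), logical(1))])
  # reference-list intersection
  expect_equal(filter_detectable(m, reference = c("g3", "g9")), "g3")
  # counts genes absent from annotation are dropped with a warning
  genes <- data.frame(gene_id = c("g1", "g2"))
  expect_warning(out <- filter_detectable(m, genes = genes),
                 "absent from annotation")
  expect_equal(out, "g1")
})
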