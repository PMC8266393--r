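test_that("configuration invariants are enforced", {
  expect_error(simulation_config(n_genes = -1), "n_genes")
  expect_error(simulation_config(class_fractions = c(TFIID = 0.5, CR = 0.4)),
               "sum to 1")
  expect_error(simulation_config(
    tata_fraction_per_class = c(TFIID = 1.2, CR = 0)), "\\[0, 1\\]")
  expect_error(simulation_config(spike_ratio = 0), "spike_ratio")
})

test_that("n_genes = 0 gives an empty annotation", {
  ann <- simulate_annotation(simulation_config(n_genes = 0, seed = 1))
  expect_equal(nrow(ann$genes), 0)
  expect_s4_class(ann$genome, "DNAStringSet")
})

test_that("an undersized chromosome is a sizing error", {
  expect_error(simulate_annotation(tiny_config(chrom_length = 1000)),
               "too small")
})

test_that("same config and seed reproduce annotation, counts and tracks", {
  cfg <- tiny_config()
  a1 <- simulate_annotation(cfg); a2 <- simulate_annotation(cfg)
  expect_identical(a1$genes, a2$genes)
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  c1 <- simulate_counts(cfg, a1); c2 <- simulate_counts(cfg, a2)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$meta, c2$meta)
  t1 <- simulate_tracks(cfg, a1, "chec")
  t2 <- simulate_tracks(cfg, a2, "chec")
  expect_identical(t1$meta, t2$meta)
  expect_identical(as.numeric(t1$tracks[[1]]$cov[[1]]),
                   as.numeric(t2$tracks[[1]]$cov[[1]]))
  # written outputs are byte-identical
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(a1, d1, counts = c1)
  write_simulation(a2, d2, counts = c2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})

test_that("genes are laid out without overlap and truth is consistent", {
  ann <- simulate_annotation(tiny_config())
  g <- ann$genes
  expect_true(all(g$start[-1] >= g$end[-nrow(g)]))   # non-overlapping
  expect_true(all(g$end <= ann$chrom_length))
  # TSS/PAS orientation per strand (boundary convention)
  fwd <- g$strand == "+"
  expect_true(all(g$tss[fwd] < g$pas[fwd]))
  expect_true(all(g$tss[!fwd] > g$pas[!fwd]))
  expect_true(all(c("+", "-") %in% g$strand))
})

test_that("tata_fraction = 1 plants a TATAWAW in every promoter scan window", {
  cfg <- tiny_config(tata_fraction_per_class = c(TFIID = 1, CR = 1))
  ann <- simulate_annotation(cfg)
  seq_str <- as.character(ann$genome[["chrS"]])
  hits <- vapply(seq_len(nrow(ann$genes)), function(i) {
    g <- ann$genes[i, ]
    win <- if (g$strand == "+") substr(seq_str, g$tss - 199, g$tss)
           else rc_chr(substr(seq_str, g$tss + 1, g$tss + 200))
    grepl("TATA[AT]A[AT]", win)
  }, logical(1))
  expect_true(all(hits))
})

test_that("counts obey the zero-noise limit and refuse zero replicates", {
  cfg <- tiny_config(replicate_cv = 0)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  expect_identical(sim$counts[, "rnaseq_DMSO_rep1"],
                   sim$counts[, "rnaseq_DMSO_rep2"])
  expect_identical(sim$counts[, "rnaseq_IAA_rep1"],
                   sim$counts[, "rnaseq_IAA_rep2"])
  cfg0 <- tiny_config(n_replicates = 0)
  expect_error(simulate_counts(cfg0, ann), "n_replicates")
})

test_that("null effect simulations center per-class medians at fold 1", {
  cfg <- simulation_config(
    n_genes = 2000, n_replicates = 2, seed = 7,
    effect_spec = list(TFIID = list(median_log2fc = 0, sd = 0.3),
                       CR = list(median_log2fc = 0, sd = 0.3)))
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  est <- rnaseq_log2fc(sim$counts, sim$meta)
  cs <- class_summary(est, stats::setNames(ann$genes$class,
                                           ann$genes$gene_id))
  expect_true(all(abs(cs$median_log2fc) < 0.1))
})

test_that("injected class fold changes are recovered by the full pipeline", {
  cfg <- simulation_config(n_genes = 2000, n_replicates = 3, seed = 11)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  est <- rnaseq_log2fc(sim$counts, sim$meta)
  cs <- class_summary(est, stats::setNames(ann$genes$class,
                                           ann$genes$gene_id))
  tfiid <- cs$median_fold_decrease[cs$class == "TFIID"]
  cr <- cs$median_fold_decrease[cs$class == "CR"]
  expect_gt(tfiid, 3.6); expect_lt(tfiid, 4.4)
  expect_gt(cr, 1.3 * 0.9); expect_lt(cr, 1.3 * 1.1)
  # estimated per-gene changes track the truth
  expect_gt(cor(est, sim$truth$true_log2fc[names(est)]), 0.8)
})

test_that("replicate CV near the configured level is recovered", {
  cfg <- simulation_config(n_genes = 1000, n_replicates = 3,
                           replicate_cv = 0.2, seed = 13)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  norm <- normalize_counts(expression_table(sim$counts), sim$meta)
  out <- replicate_cv(norm, sim$meta)
  expect_gt(out$median_cv, 0.12); expect_lt(out$median_cv, 0.3)
})

test_that("depth scaling leaves normalized quantities unchanged in expectation", {
  cfg <- simulation_config(n_genes = 1500, n_replicates = 2, seed = 17,
                           replicate_cv = 0.1)
  ann <- simulate_annotation(cfg)
  base <- simulate_counts(cfg, ann)
  est1 <- rnaseq_log2fc(base$counts, base$meta)
  # doubling every sample's counts and spikes changes nothing downstream
  meta2 <- base$meta; meta2$spike_reads <- meta2$spike_reads * 2
  est2 <- rnaseq_log2fc(base$counts * 2, meta2)
  expect_equal(est1, est2)
})

test_that("chec tracks place recoverable peaks with truthful summits", {
  cfg <- simulation_config(n_genes = 60, n_replicates = 1, seed = 19,
                           peak_spec = list(height = 8, sigma = 75,
                                            bound_fraction = 0.5,
                                            background = 0.4,
                                            occ_log2fc = 0))
  ann <- simulate_annotation(cfg)
  sim <- simulate_tracks(cfg, ann, "chec")
  pw <- promoter_windows(ann$genes)
  pw <- pw[match(names(sim$truth$true_summits), pw$gene_id), ]
  expect_true(all(sim$truth$true_summits >= pw$start &
                  sim$truth$true_summits < pw$end))
  expect_setequal(names(sim$tracks),
                  c("ip_DMSO_rep1", "control_DMSO_rep1",
                    "ip_IAA_rep1", "control_IAA_rep1"))
})

test_that("zero peak height makes IP and control indistinguishable", {
  cfg <- simulation_config(n_genes = 40, n_replicates = 1, seed = 23,
                           peak_spec = list(height = 1, sigma = 75,
                                            bound_fraction = 0.5,
                                            background = 0.4,
                                            occ_log2fc = 0))
  ann <- simulate_annotation(cfg)
  sim <- simulate_tracks(cfg, ann, "chec")
  peaks <- call_peaks(sim$tracks$ip_DMSO_rep1, sim$tracks$control_DMSO_rep1)
  expect_equal(nrow(peaks), 0)
})

test_that("5' accumulation raises the TR of shifted genes", {
  cfg <- simulation_config(n_genes = 120, n_replicates = 1, seed = 29,
                           replicate_cv = 0,
                           elongation_spec = list(base_accum = 1,
                                                  five_prime_strength = 3,
                                                  decay_length = 130))
  ann <- simulate_annotation(cfg)
  sim <- simulate_tracks(cfg, ann, "polii")
  trd <- traveling_ratio(sim$tracks$rpb1_DMSO_rep1, ann$genes)
  tri <- traveling_ratio(sim$tracks$rpb1_IAA_rep1, ann$genes)
  shared <- intersect(trd$gene_id, tri$gene_id)
  shift <- log2(tri$tr[match(shared, tri$gene_id)] /
                trd$tr[match(shared, trd$gene_id)])
  w <- sim$truth$dependence_weight[match(shared, ann$genes$gene_id)]
  shifted <- w > 0.75; unshifted <- w < 0.25
  expect_gt(mean(shift[shifted], na.rm = TRUE),
            mean(shift[unshifted], na.rm = TRUE))
  # truth says shifted genes move their TR up
  expect_true(all(sim$truth$true_tr_shift[match(shared[shifted],
    names(sim$truth$true_tr_shift))] > 0))
})
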