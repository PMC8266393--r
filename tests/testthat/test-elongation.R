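test_that("traveling ratio is 1 on a uniform track and matches window sums", {
  g <- toy_genes()
  uni <- track_from_vector(rep(1.5, 5000))
  tr <- traveling_ratio(uni, g)
  expect_equal(tr$tr, c(1, 1))
  # constructed 5' sum 200 vs 3' sum 50 -> TR 4
  vals <- rep(0, 5000); vals[1001:1100] <- 2; vals[1901:2000] <- 0.5
  tr4 <- traveling_ratio(track_from_vector(vals), g[1, ])
  expect_equal(tr4$signal_5p, 200)
  expect_equal(tr4$signal_3p, 50)
  expect_equal(tr4$tr, 4)
})

test_that("traveling ratio is strand-symmetric under track mirroring", {
  set.seed(29)
  vals <- rpois(5000, 1) + 0.2
  tr_plus <- traveling_ratio(track_from_vector(vals), toy_genes()[1, ])
  mirror <- track_from_vector(rev(vals))
  gm <- data.frame(gene_id = "gm", chrom = "chrT", strand = "-",
                   start = 3000L, end = 4000L, cds_start = 3900L,
                   tss = 4000L, pas = 3000L, stringsAsFactors = FALSE)
  tr_minus <- traveling_ratio(mirror, gm)
  expect_equal(tr_minus$tr, tr_plus$tr)
  expect_equal(tr_minus$signal_5p, tr_plus$signal_5p)
})

test_that("short genes and zero 3' signal are excluded from TR", {
  short <- data.frame(gene_id = "s", chrom = "chrT", strand = "+",
                      start = 100L, end = 350L, cds_start = 200L,
                      tss = 100L, pas = 350L, stringsAsFactors = FALSE)
  uni <- track_from_vector(rep(1, 1000))
  expect_equal(nrow(traveling_ratio(uni, short)), 0)
  dead <- track_from_vector(c(rep(1, 500), rep(0, 500)))
  g <- data.frame(gene_id = "g", chrom = "chrT", strand = "+",
                  start = 100L, end = 900L, cds_start = 200L,
                  tss = 100L, pas = 900L, stringsAsFactors = FALSE)
  out <- traveling_ratio(dead, g)
  expect_true(is.na(out$tr))
  expect_equal(attr(out, "n_undefined"), 1)
})

test_that("TR is scale-invariant and its change ignores per-condition scaling", {
  set.seed(31)
  vals <- rpois(5000, 2) + 0.1
  g <- toy_genes()
  a <- traveling_ratio(track_from_vector(vals), g)
  b <- traveling_ratio(track_from_vector(vals * 37), g)
  expect_equal(a$tr, b$tr)
})

test_that("quintile groups split evenly with Q5 = most dependent", {
  lfc <- stats::setNames(c(-5, -4, -3, -2, -1, 0, 1, 2, 3, 4),
                         paste0("g", 1:10))
  q <- quintile_groups(lfc)
  expect_equal(as.integer(table(q)), rep(2L, 5))
  expect_equal(unname(q[c("g1", "g2")]), c("Q5", "Q5"))  # most negative
  expect_equal(unname(q[c("g9", "g10")]), c("Q1", "Q1"))
  # all-equal values: stable order, sizes 2,2,2,2,2
  tied <- stats::setNames(rep(0, 10), paste0("g", 1:10))
  qt <- quintile_groups(tied)
  expect_equal(as.integer(table(qt)), rep(2L, 5))
  expect_equal(unname(qt[1:2]), c("Q5", "Q5"))
  expect_error(quintile_groups(rep(0, 4)), "at least 5")
  # boundaries equal a brute-force sorted split
  set.seed(37)
  v <- rnorm(503)
  q2 <- quintile_groups(v)
  ord <- order(v)
  sizes <- unname(table(factor(q2, levels = paste0("Q", 5:1))[ord]))
  expect_true(max(sizes) - min(sizes) <= 1)
  expect_true(all(diff(match(q2[ord], paste0("Q", 5:1))) >= 0))
})

test_that("tr_change_summary recovers sign structure and nulls", {
  g <- toy_genes()
  uni <- track_from_vector(rep(1, 5000))
  trd <- traveling_ratio(uni, g)
  lfc <- stats::setNames(c(-2, -1), g$gene_id)
  expect_error(tr_change_summary(trd[0, ], trd[0, ], lfc), "no genes")
  # identical conditions: all TR changes 0, correlation undefined
  out <- tr_change_summary(trd, trd, lfc)
  expect_equal(out$per_gene$log2_tr_change, c(0, 0))
  expect_true(is.na(out$spearman_r))
})

test_that("random permutation gives near-zero TR-change correlation", {
  set.seed(41)
  n <- 2000
  ids <- sprintf("g%04d", 1:n)
  trd <- data.frame(gene_id = ids, signal_5p = 1, signal_3p = 1,
                    tr = runif(n, 0.5, 2), stringsAsFactors = FALSE)
  tri <- trd; tri$tr <- trd$tr * runif(n, 0.8, 1.25)
  lfc <- stats::setNames(sample(rnorm(n)), ids)   # independent of TR change
  out <- tr_change_summary(trd, tri, lfc)
  expect_lt(abs(out$spearman_r), 0.1)
})

test_that("metagene profile is 0 for identical conditions, -1 for halving", {
  set.seed(43)
  vals <- rpois(20000, 2) + 1
  tr <- track_from_vector(vals)
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chrT",
                      strand = c("+", "-"),
                      start = c(2000L, 10000L), end = c(4000L, 12000L),
                      cds_start = c(2100L, 11900L),
                      tss = c(2000L, 12000L), pas = c(4000L, 10000L),
                      stringsAsFactors = FALSE)
  groups <- stats::setNames(c("A", "A"), genes$gene_id)
  p0 <- metagene_log2_profile(tr, tr, genes, groups)
  expect_true(all(p0$log2_change == 0))
  half <- track_from_vector(vals * 0.5)
  p1 <- metagene_log2_profile(tr, half, genes, groups)
  expect_true(all(abs(p1$log2_change + 1) < 1e-12))
  expect_equal(sort(unique(p0$offset)), seq(-200L, 999L))
})

test_that("metagene offsets are strand-resolved", {
  # impulse at TSS+10 for a minus-strand gene must appear at offset +10
  vals <- rep(1, 20000)
  vals[12000 - 10] <- 101   # 0-based base 11989 = offset +10 for tss = 12000
  tr <- track_from_vector(vals)
  gm <- data.frame(gene_id = "gm", chrom = "chrT", strand = "-",
                   start = 10000L, end = 12000L, cds_start = 11900L,
                   tss = 12000L, pas = 10000L, stringsAsFactors = FALSE)
  p <- metagene_log2_profile(tr, track_from_vector(vals * 2), gm,
                             stats::setNames("A", "gm"))
  expect_equal(p$mean_dmso[p$offset == 10], 101)
  expect_true(all(p$mean_dmso[p$offset != 10] == 1))
})

test_that("phospho status change is a ratio of ratios", {
  ids <- paste0("g", 1:4)
  p_d <- stats::setNames(c(4, 4, 4, 4), ids)
  r_d <- stats::setNames(c(2, 2, 2, 2), ids)
  # joint scaling of phospho and Rpb1 cancels exactly
  expect_equal(unname(phospho_status_change(p_d, p_d * 0.3, r_d, r_d * 0.3)),
               rep(0, 4), ignore_attr = TRUE)
  # phospho halved, Rpb1 unchanged -> -1
  expect_equal(unname(phospho_status_change(p_d, p_d / 2, r_d, r_d)),
               rep(-1, 4), ignore_attr = TRUE)
  # brute-force composed ratio on random tables
  set.seed(47)
  pi_ <- stats::setNames(runif(4, 1, 9), ids)
  ri <- stats::setNames(runif(4, 1, 9), ids)
  out <- phospho_status_change(p_d, pi_, r_d, ri)
  expect_equal(unname(out),
               unname(log2((pi_ / ri) / (p_d / r_d))), ignore_attr = TRUE)
  # genes with zero Rpb1 are excluded and counted
  ri2 <- ri; ri2[2] <- 0
  out2 <- phospho_status_change(p_d, pi_, r_d, ri2)
  expect_equal(attr(out2, "n_excluded"), 1)
  expect_equal(length(out2), 3)
})
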