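#' Configuration for the synthetic spike-in experiment generator
#'
#' Bundles every knob of the simulator with defaults chosen to emulate the
#' study design the package quantifies: an 8:1 experimental:spike cell mix,
#' two gene classes (TFIID-dependent and coactivator-redundant) with
#' class-specific transcriptional responses to depletion, replicate noise
#' below a 30% coefficient of variation, negative-binomial count noise, and
#' promoter-peaked MNase-style coverage.
#'
#' For minus-strand genes, `tss` and `pas` are stored as half-open interval
#' boundaries (the mirror image of plus-strand coordinates), so every
#' windowed operation is an exact reflection of its plus-strand counterpart.
#'
#' @param n_genes Number of simulated genes.
#' @param chrom_length Length of the single simulated chromosome in bp;
#'   `NULL` sizes it automatically to the gene layout.
#' @param class_fractions Named proportions of the gene classes (must sum
#'   to 1).
#' @param effect_spec Per-class true transcriptional response: a named list
#'   of `list(median_log2fc, sd)`. Defaults inject a 4-fold median decrease
#'   for the TFIID class and 1.3-fold for the CR class.
#' @param tata_fraction_per_class Named per-class probability that a promoter
#'   carries a planted TATAWAW element.
#' @param n_replicates Biological replicates per condition.
#' @param replicate_cv Coefficient of variation of the per-replicate depth
#'   factor (0 = deterministic depths and counts).
#' @param spike_ratio Expected spike:experimental read ratio (default 1/8,
#'   matching an 8:1 experimental:spike cell mix).
#' @param dispersion Negative-binomial gene-level dispersion (default 0.05).
#' @param peak_spec Promoter-peak shape: `height` (fold enrichment over
#'   background at the peak center), `sigma` (Gaussian width in bp),
#'   `bound_fraction` (fraction of promoters carrying a peak), `background`
#'   (expected control reads per bp), `occ_log2fc` (true log2 occupancy
#'   change at bound promoters under depletion; default a 1.7-fold drop).
#' @param elongation_spec Pol II gene-body profile: `base_accum` (5'
#'   accumulation amplitude shared by both conditions), `five_prime_strength`
#'   (extra 5' accumulation under depletion, weighted by gene dependence),
#'   `decay_length` (bp scale over which 5' accumulation decays; default 130,
#'   so the excess is spent by ~400 bp).
#' @param seed Integer seed; the same configuration and seed reproduce every
#'   output bit-for-bit.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              chrom_length = NULL,
                              class_fractions = c(TFIID = 0.73, CR = 0.27),
                              effect_spec = list(
                                TFIID = list(median_log2fc = -2, sd = 0.4),
                                CR = list(median_log2fc = -log2(1.3),
                                          sd = 0.3)),
                              tata_fraction_per_class = c(TFIID = 0.1,
                                                          CR = 0.6),
                              n_replicates = 3,
                              replicate_cv = 0.2,
                              spike_ratio = 1 / 8,
                              dispersion = 0.05,
                              peak_spec = list(height = 8, sigma = 75,
                                               bound_fraction = 0.7,
                                               background = 0.2,
                                               occ_log2fc = -log2(1.7)),
                              elongation_spec = list(
                                base_accum = 1,
                                five_prime_strength = 0,
                                decay_length = 130),
                              seed = 1L) {
  if (n_genes < 0) stop("n_genes must be >= 0")
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop("class_fractions must sum to 1")
  fr <- c(class_fractions, tata_fraction_per_class,
          peak_spec$bound_fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (replicate_cv < 0) stop("replicate_cv must be >= 0")
  if (spike_ratio <= 0) stop("spike_ratio must be > 0")
  if (!setequal(names(class_fractions), names(effect_spec)) ||
      !setequal(names(class_fractions), names(tata_fraction_per_class)))
    stop("class names must agree across class_fractions, effect_spec and ",
         "tata_fraction_per_class")
  structure(list(n_genes = as.integer(n_genes),
                 chrom_length = chrom_length,
                 class_fractions = class_fractions,
                 effect_spec = effect_spec,
                 tata_fraction_per_class = tata_fraction_per_class,
                 n_replicates = as.integer(n_replicates),
                 replicate_cv = replicate_cv, spike_ratio = spike_ratio,
                 dispersion = dispersion, peak_spec = peak_spec,
                 elongation_spec = elongation_spec,
                 seed = as.integer(seed)),
            class = "sim_config")
}

SIM_CHROM <- "chrS"
TATA_SCAN <- 200L  # planted motifs live in the -200..TSS sense-strand window

#' Simulate gene annotation and a matching genome
#'
#' Lays out non-overlapping genes on both strands of a single chromosome,
#' assigns TSS/PAS and class labels, and emits a random genome in which every
#' TATA-flagged promoter carries at least one planted TATAWAW element inside
#' the -200..TSS sense-strand scan window, while TATA-negative promoters are
#' scrubbed of chance matches (so the flags are exact ground truth).
#'
#' @param cfg A [simulation_config()].
#' @return List with `genes` (gene model data.frame including the truth
#'   columns `class` and `tata`), `genome` (a
#'   [Biostrings::DNAStringSet]), and `chrom_length`.
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  if (n == 0) {
    L <- if (is.null(cfg$chrom_length)) 2000L else cfg$chrom_length
    genome <- Biostrings::DNAStringSet(stats::setNames(
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), SIM_CHROM))
    return(list(genes = empty_gene_table(), genome = genome,
                chrom_length = L))
  }
  lens <- sample(500:2500, n, replace = TRUE)
  gaps <- sample(600:1000, n, replace = TRUE)
  starts <- 1000L + cumsum(c(0L, (lens + gaps)[-n]))
  ends <- starts + lens
  needed <- ends[n] + 1000L
  L <- cfg$chrom_length
  if (is.null(L)) L <- needed
  if (L < needed)
    stop("chrom_length (", L, ") too small for ", n,
         " genes; need at least ", needed)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  fwd <- strand == "+"
  tss <- ifelse(fwd, starts, ends)
  pas <- ifelse(fwd, ends, starts)
  cds_start <- ifelse(fwd, tss + 100L, tss - 100L)
  classes <- sample(names(cfg$class_fractions), n, replace = TRUE,
                    prob = cfg$class_fractions)
  tata <- stats::runif(n) < cfg$tata_fraction_per_class[classes]
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n)),
    chrom = SIM_CHROM, strand = strand, start = starts, end = ends,
    cds_start = as.integer(cds_start), tss = as.integer(tss),
    pas = as.integer(pas), class = classes, biotype = "verified",
    tata = tata, stringsAsFactors = FALSE)

  seq_chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                      prob = c(0.31, 0.19, 0.19, 0.31))
  for (i in seq_len(n)) {
    w <- tata_window_chars(genes[i, ])       # genomic 1-based indices, 5'->3'
    sense <- sense_bases(seq_chars, w, genes$strand[i])
    if (genes$tata[i]) {
      motif <- c("T", "A", "T", "A", sample(c("A", "T"), 1), "A",
                 sample(c("A", "T"), 1))
      off <- sample(seq_len(length(sense) - 7L), 1)
      sense[off:(off + 6L)] <- motif
    } else {
      repeat {
        m <- gregexpr("TATA[AT]A[AT]", paste(sense, collapse = ""))[[1]]
        if (m[1] == -1) break
        sense[m + 2L] <- "C"                  # break every match
      }
    }
    seq_chars <- unsense_bases(seq_chars, w, genes$strand[i], sense)
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(
    paste(seq_chars, collapse = ""), SIM_CHROM))
  list(genes = genes, genome = genome, chrom_length = L)
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), chrom = character(),
             strand = character(), start = integer(), end = integer(),
             cds_start = integer(), tss = integer(), pas = integer(),
             class = character(), biotype = character(), tata = logical(),
             stringsAsFactors = FALSE)
}

## 1-based genomic indices of the -TATA_SCAN..TSS scan window, 5'->3'.
tata_window_chars <- function(gene) {
  if (gene$strand == "+") (gene$tss - TATA_SCAN + 1L):gene$tss
  else (gene$tss + TATA_SCAN):(gene$tss + 1L)
}

COMP <- c(A = "T", C = "G", G = "C", T = "A")

sense_bases <- function(seq_chars, idx, strand) {
  if (strand == "+") seq_chars[idx] else unname(COMP[seq_chars[idx]])
}

unsense_bases <- function(seq_chars, idx, strand, sense) {
  seq_chars[idx] <- if (strand == "+") sense else unname(COMP[sense])
  seq_chars
}

## Per-sample depth factors with CV = cv (lognormal, mean 1); cv = 0 gives 1.
depth_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate spike-in nascent RNA-seq count tables
#'
#' Draws per-gene counts from a negative-binomial model: DMSO means are
#' lognormal across genes; IAA means are the DMSO means scaled by
#' `2^true_log2fc`, with the true log2 fold change drawn per gene from its
#' class's effect specification. Each sample gets a depth factor with the
#' configured replicate CV, and spike-in read totals are drawn binomially
#' from the sample's total sequencing depth so spike counts co-vary with
#' depth as in a true cell-mix spike-in. With `replicate_cv = 0` the
#' zero-noise limit is returned (counts equal their rounded means), which
#' makes degenerate-case tests exact.
#'
#' @param cfg A [simulation_config()].
#' @param ann Result of [simulate_annotation()] (or any list with a `genes`
#'   table carrying `gene_id` and `class`).
#' @return List with `counts` (integer matrix genes x samples), `meta` (a
#'   [sample_sheet()]), and `truth` (list with `true_log2fc`).
#' @export
simulate_counts <- function(cfg, ann) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_replicates < 1)
    stop("n_replicates must be >= 1 to simulate an experiment")
  set.seed(cfg$seed + 1L)
  genes <- ann$genes
  n <- nrow(genes)
  mu <- stats::rlnorm(n, meanlog = log(200), sdlog = 1)
  lfc <- numeric(n)
  for (cl in names(cfg$effect_spec)) {
    idx <- genes$class == cl
    es <- cfg$effect_spec[[cl]]
    lfc[idx] <- stats::rnorm(sum(idx), es$median_log2fc, es$sd)
  }
  mu_cond <- list(DMSO = mu, IAA = mu * 2^lfc)
  conds <- rep(c("DMSO", "IAA"), each = cfg$n_replicates)
  reps <- rep(seq_len(cfg$n_replicates), times = 2)
  ids <- sprintf("rnaseq_%s_rep%d", conds, reps)
  d <- depth_factors(length(ids), cfg$replicate_cv)
  spike_base <- cfg$spike_ratio * sum(mu_cond$DMSO)
  counts <- matrix(0L, nrow = n, ncol = length(ids),
                   dimnames = list(genes$gene_id, ids))
  spike <- numeric(length(ids))
  total <- numeric(length(ids))
  for (j in seq_along(ids)) {
    m <- mu_cond[[conds[j]]] * d[j]
    counts[, j] <- if (cfg$replicate_cv == 0) as.integer(round(m))
      else if (cfg$dispersion > 0)
        stats::rnbinom(n, mu = m, size = 1 / cfg$dispersion)
      else stats::rpois(n, m)
    exp_spike <- spike_base * d[j]
    tot <- round(sum(counts[, j]) + exp_spike)
    frac <- exp_spike / (sum(m) + exp_spike)
    spike[j] <- if (cfg$replicate_cv == 0) round(exp_spike)
      else stats::rbinom(1, tot, frac)
    total[j] <- tot
  }
  meta <- sample_sheet(sample_id = ids, assay = "rnaseq", condition = conds,
                       replicate = reps, spike_reads = spike,
                       experimental_reads = total - spike)
  list(counts = counts, meta = meta,
       truth = list(true_log2fc = stats::setNames(lfc, genes$gene_id)))
}

#' Simulate spike-in coverage tracks
#'
#' Two track families share the configuration:
#' \describe{
#'   \item{`kind = "chec"`}{Promoter-peaked IP tracks plus free-MNase-style
#'     controls. A configured fraction of promoters is truly bound; each
#'     bound promoter gets a discretized Gaussian fragment pileup centered on
#'     its true summit, on top of a uniform Poisson background. Under IAA the
#'     pileup amplitude is scaled by `2^peak_spec$occ_log2fc`.}
#'   \item{`kind = "polii"`}{Polymerase-style tracks spanning TSS to PAS with
#'     a 5' accumulation that decays exponentially into the gene body. Under
#'     IAA the gene-body rate is scaled by the gene's true transcriptional
#'     fold change and, when `elongation_spec$five_prime_strength > 0`, the
#'     5' accumulation grows in proportion to the gene's dependence rank
#'     (a 5' shift of Pol II at the most depletion-sensitive genes).}
#' }
#' Spike-in totals are drawn binomially from each sample's total depth, as
#' for the count simulator.
#'
#' @param cfg A [simulation_config()].
#' @param ann Result of [simulate_annotation()].
#' @param kind `"chec"` or `"polii"`.
#' @return List with `tracks` (named list of raw [coverage_track]s; names
#'   like `ip_DMSO_rep1` / `control_DMSO_rep1` or `rpb1_IAA_rep2`), `meta`
#'   (a [sample_sheet()] covering the IP/polymerase samples), and `truth`
#'   (ground truth: bound promoters and summits for `"chec"`; per-gene true
#'   log2 fold change, 5' accumulation amplitudes per condition, and the
#'   true log2 TR shift for `"polii"`).
#' @export
simulate_tracks <- function(cfg, ann, kind = c("chec", "polii")) {
  kind <- match.arg(kind)
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_replicates < 1)
    stop("n_replicates must be >= 1 to simulate an experiment")
  set.seed(cfg$seed + 2L)
  genes <- ann$genes
  L <- ann$chrom_length
  n <- nrow(genes)
  conds <- rep(c("DMSO", "IAA"), each = cfg$n_replicates)
  reps <- rep(seq_len(cfg$n_replicates), times = 2)

  if (kind == "chec") {
    ps <- cfg$peak_spec
    bound <- sort(sample(n, round(ps$bound_fraction * n)))
    offset <- pmin(pmax(round(stats::rnorm(length(bound), -100, 50)),
                        -250L), 40L)
    fwd <- genes$strand[bound] == "+"
    summit <- ifelse(fwd, genes$tss[bound] + offset,
                     genes$tss[bound] - 1L - offset)
    rate_of <- function(cond) {
      rate <- rep(ps$background, L)
      amp <- ps$background * (ps$height - 1)
      if (cond == "IAA") amp <- amp * 2^ps$occ_log2fc
      for (k in seq_along(bound)) {
        lo <- max(1L, summit[k] - 4L * ps$sigma)
        hi <- min(L, summit[k] + 4L * ps$sigma)
        x <- lo:hi
        rate[x] <- rate[x] + amp * exp(-((x - summit[k])^2) /
                                         (2 * ps$sigma^2))
      }
      rate
    }
    rates <- list(DMSO = rate_of("DMSO"), IAA = rate_of("IAA"))
    ids <- sprintf("ip_%s_rep%d", conds, reps)
    d <- depth_factors(length(ids), cfg$replicate_cv)
    tracks <- list(); spike <- numeric(length(ids))
    total <- numeric(length(ids))
    for (j in seq_along(ids)) {
      rate <- rates[[conds[j]]] * d[j]
      cov <- stats::rpois(L, rate)
      tracks[[ids[j]]] <- coverage_track(
        stats::setNames(list(S4Vectors::Rle(as.numeric(cov))), SIM_CHROM))
      ctrl <- stats::rpois(L, ps$background * d[j])
      tracks[[sprintf("control_%s_rep%d", conds[j], reps[j])]] <-
        coverage_track(
          stats::setNames(list(S4Vectors::Rle(as.numeric(ctrl))), SIM_CHROM))
      exp_spike <- cfg$spike_ratio * sum(rates[[conds[j]]]) * d[j]
      tot <- round(sum(cov) + exp_spike)
      spike[j] <- if (cfg$replicate_cv == 0) round(exp_spike)
        else stats::rbinom(1, tot, exp_spike / (sum(rate) + exp_spike))
      total[j] <- tot
    }
    meta <- sample_sheet(sample_id = ids, assay = "chec", condition = conds,
                         replicate = reps, spike_reads = spike,
                         experimental_reads = total - spike)
    truth <- list(
      true_bound = genes$gene_id[bound],
      true_summits = stats::setNames(as.integer(summit),
                                     genes$gene_id[bound]),
      occ_log2fc = ps$occ_log2fc)
    return(list(tracks = tracks, meta = meta, truth = truth))
  }

  ## kind == "polii"
  es <- cfg$elongation_spec
  base_expr <- stats::rlnorm(n, log(0.5), 0.6)   # expected reads per bp
  lfc <- numeric(n)
  for (cl in names(cfg$effect_spec)) {
    idx <- genes$class == cl
    sp <- cfg$effect_spec[[cl]]
    lfc[idx] <- stats::rnorm(sum(idx), sp$median_log2fc, sp$sd)
  }
  dep_rank <- rank(-lfc, ties.method = "first")   # 1 = least dependent
  w <- if (n > 1) (dep_rank - 1) / (n - 1) else rep(1, n)
  a_dmso <- rep(es$base_accum, n)
  a_iaa <- es$base_accum + es$five_prime_strength * w
  rate_of <- function(cond) {
    rate <- rep(1e-3, L)                          # trace background
    a <- if (cond == "DMSO") a_dmso else a_iaa
    scale <- if (cond == "DMSO") rep(1, n) else 2^lfc
    for (i in seq_len(n)) {
      lo <- min(genes$tss[i], genes$pas[i]); hi <- max(genes$tss[i],
                                                       genes$pas[i])
      pos <- (lo + 1L):hi                         # 1-based bases of the body
      x <- if (genes$strand[i] == "+") pos - 1L - genes$tss[i]
           else genes$tss[i] - pos                # distance from the 5' end
      rate[pos] <- rate[pos] + base_expr[i] * scale[i] *
        (1 + a[i] * exp(-x / es$decay_length))
    }
    rate
  }
  rates <- list(DMSO = rate_of("DMSO"), IAA = rate_of("IAA"))
  ids <- sprintf("rpb1_%s_rep%d", conds, reps)
  d <- depth_factors(length(ids), cfg$replicate_cv)
  tracks <- list(); spike <- numeric(length(ids)); total <- numeric(length(ids))
  for (j in seq_along(ids)) {
    rate <- rates[[conds[j]]] * d[j]
    cov <- stats::rpois(L, rate)
    tracks[[ids[j]]] <- coverage_track(
      stats::setNames(list(S4Vectors::Rle(as.numeric(cov))), SIM_CHROM))
    exp_spike <- cfg$spike_ratio * sum(rates[[conds[j]]]) * d[j]
    tot <- round(sum(cov) + exp_spike)
    spike[j] <- if (cfg$replicate_cv == 0) round(exp_spike)
      else stats::rbinom(1, tot, exp_spike / (sum(rate) + exp_spike))
    total[j] <- tot
  }
  meta <- sample_sheet(sample_id = ids, assay = "chip", condition = conds,
                       replicate = reps, spike_reads = spike,
                       experimental_reads = total - spike)
  ## exact expected TR shift from the noiseless rate model
  tr_expected <- function(a) {
    x5 <- 0:99; x3 <- function(len) (len - 100):(len - 1)
    vapply(seq_len(n), function(i) {
      len <- abs(genes$pas[i] - genes$tss[i])
      s5 <- sum(1 + a[i] * exp(-x5 / es$decay_length))
      s3 <- sum(1 + a[i] * exp(-x3(len) / es$decay_length))
      s5 / s3
    }, numeric(1))
  }
  truth <- list(
    true_log2fc = stats::setNames(lfc, genes$gene_id),
    a5_dmso = a_dmso, a5_iaa = a_iaa, dependence_weight = w,
    true_tr_shift = stats::setNames(
      log2(tr_expected(a_iaa) / tr_expected(a_dmso)), genes$gene_id))
  list(tracks = tracks, meta = meta, truth = truth)
}

#' Write a simulated experiment to disk
#'
#' Emits the genome FASTA, gene table TSV, count table TSV, sample sheet
#' TSV, one bedGraph per coverage track, and the ground truth as JSON. All
#' writers are deterministic.
#'
#' @param ann Result of [simulate_annotation()].
#' @param dir Output directory (created if needed).
#' @param counts Optional result of [simulate_counts()].
#' @param tracks Optional result of [simulate_tracks()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(ann, dir, counts = NULL, tracks = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(ann$genome, file.path(dir, "genome.fa"))
  write_genes(ann$genes, file.path(dir, "genes.tsv"))
  truth <- list()
  if (!is.null(counts)) {
    utils::write.table(data.frame(gene_id = rownames(counts$counts),
                                  counts$counts, check.names = FALSE),
                       file.path(dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(counts$meta, file.path(dir, "samples_rnaseq.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth$rnaseq <- counts$truth
  }
  if (!is.null(tracks)) {
    for (nm in names(tracks$tracks))
      write_bedgraph(tracks$tracks[[nm]],
                     file.path(dir, paste0(nm, ".bedgraph")))
    utils::write.table(tracks$meta, file.path(dir, "samples_tracks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    truth$tracks <- tracks$truth
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
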