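#' Significance stars for a p-value
#'
#' Cutoffs: p <= 0.0001 -> `****`, <= 0.001 -> `***`, <= 0.01 -> `**`,
#' <= 0.05 -> `*`, otherwise `ns`.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  ifelse(p <= 1e-4, "****",
    ifelse(p <= 1e-3, "***",
      ifelse(p <= 1e-2, "**",
        ifelse(p <= 0.05, "*", "ns"))))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. Returns `NA` with a warning
#' when either vector is constant (the correlation is undefined).
#'
#' @param x,y Equal-length finite numeric vectors, n >= 3.
#' @return Correlation coefficient in \[-1, 1\], or `NA`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. When both samples have zero variance and equal
#' means the test is degenerate and p = 1 is reported by convention.
#'
#' @param x,y Numeric samples, each with n >= 2.
#' @return List of class `test_result`: `statistic`, `df`, `p_value`,
#'   `stars`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("both samples need at least 2 observations")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(test_result(statistic = 0, df = NA_real_, p_value = 1))
    return(test_result(statistic = Inf * sign(mean(x) - mean(y)),
                       df = NA_real_, p_value = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  test_result(statistic = unname(ht$statistic), df = unname(ht$parameter),
              p_value = ht$p.value)
}

#' Hypergeometric test of set overlap
#'
#' One-sided over-representation tail P\[X >= |A intersect B|\] for
#' X ~ Hypergeometric(|U|, |A|, |B|): the probability of an overlap at least
#' as large as observed when B is drawn uniformly from the universe.
#'
#' @param set_a,set_b Character vectors (subsets of `universe`).
#' @param universe Character vector, the promoter/gene universe.
#' @return A `test_result` with fields `overlap`, `statistic` (= overlap),
#'   `p_value`, `stars`; `degenerate = TRUE` is flagged when the overlap
#'   cannot be anything but maximal.
#' @export
hypergeom_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("both sets must be subsets of the universe")
  n_u <- length(universe); n_a <- length(set_a); n_b <- length(set_b)
  ov <- length(intersect(set_a, set_b))
  # P[X >= ov], X ~ Hyper(m = n_a, n = n_u - n_a, k = n_b)
  p <- stats::phyper(ov - 1, m = n_a, n = n_u - n_a, k = n_b,
                     lower.tail = FALSE)
  res <- test_result(statistic = ov, df = NA_real_, p_value = p)
  res$overlap <- ov
  res$degenerate <- ov == max(0, n_a + n_b - n_u) && ov == min(n_a, n_b)
  res
}

test_result <- function(statistic, df, p_value) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 stars = p_stars(p_value)), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("statistic = %.4g, df = %s, p = %.4g [%s]\n", x$statistic,
              ifelse(is.na(x$df), "-", format(x$df, digits = 4)),
              x$p_value, x$stars))
  invisible(x)
}

#' Per-class bound-promoter percentages
#'
#' For each factor's bound set, the percentage of promoters in each class
#' that the factor binds: `100 * |bound intersect class| / |class|`. Empty
#' classes yield no row.
#'
#' @param bound_sets Named list of character vectors (bound promoter ids per
#'   factor).
#' @param class_labels Named character vector: class per promoter (names =
#'   promoter/gene ids); its names define the universe.
#' @return Data.frame `factor`, `class`, `n_class`, `n_bound`,
#'   `percent_bound`.
#' @export
class_composition <- function(bound_sets, class_labels) {
  universe <- names(class_labels)
  if (is.null(universe)) stop("'class_labels' must be named by promoter id")
  rows <- list()
  for (fac in names(bound_sets)) {
    bound <- intersect(bound_sets[[fac]], universe)
    for (cl in sort(unique(class_labels))) {
      members <- universe[class_labels == cl]
      if (!length(members)) next
      nb <- length(intersect(bound, members))
      rows[[paste(fac, cl)]] <- data.frame(
        factor = fac, class = cl, n_class = length(members), n_bound = nb,
        percent_bound = 100 * nb / length(members),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
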