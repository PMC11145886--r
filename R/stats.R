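#' Two-sample t-test
#'
#' Two-sided independent two-sample t-test, pooled-variance (Student) by
#' default with Welch behind a flag. Degenerate zero-variance inputs follow
#' a documented convention: equal means give p = 1, unequal means p = 0.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal logical; pooled-variance Student test (default) or Welch.
#' @return \code{list(statistic, p_value)}.
#' @examples
#' twoSampleTTest(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
twoSampleTTest <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("non-finite values")
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0, p_value = 1))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Log2 fold change between group means
#'
#' Difference of log2 group means, disease minus control: positive values
#' mean the protein is higher in the disease group.
#'
#' @param log2_disease,log2_control numeric vectors on the log2 scale.
#' @return The fold change in log2 units.
#' @export
log2FoldChange <- function(log2_disease, log2_control) {
  if (!length(log2_disease) || !length(log2_control)) stop("empty group")
  mean(log2_disease) - mean(log2_control)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; returns adjusted values in the
#' original order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-feature volcano table
#'
#' One row per feature with group means, log2 fold change (disease minus
#' control), raw and BH-adjusted t-test p-values and a significance flag at
#' adjusted p < \code{alpha}.
#'
#' @param m a log2-scale \linkS4class{QuantMatrix}.
#' @param info sample metadata with exactly two groups.
#' @param case disease-class label (log2FC is case minus control); defaults
#'   to the first group encountered in \code{info}.
#' @param alpha adjusted-p significance threshold, default 0.01.
#' @param var_equal passed to \code{\link{twoSampleTTest}}.
#' @return data.frame with columns feature_id, mean_case, mean_control,
#'   log2fc, t_stat, p_raw, p_adj, neg_log10_p_adj, significant.
#' @export
volcanoTable <- function(m, info, case = NULL, alpha = 0.01,
                         var_equal = TRUE) {
  stopifnot(is(m, "QuantMatrix"))
  if (quantScale(m) != "log2") stop("volcano table expects log2 scale")
  v <- quantValues(m)
  grp <- setNames(as.character(info$group), info$sample_id)[sampleIds(m)]
  lv <- unique(grp)
  if (length(lv) != 2L) stop("exactly two groups required")
  if (is.null(case)) case <- lv[1]
  control <- setdiff(lv, case)
  if (min(table(grp)) < 2L) stop("each group needs at least 2 samples")
  if (nrow(v) == 0L)
    return(data.frame(feature_id = character(), mean_case = numeric(),
                      mean_control = numeric(), log2fc = numeric(),
                      t_stat = numeric(), p_raw = numeric(),
                      p_adj = numeric(), neg_log10_p_adj = numeric(),
                      significant = logical()))
  ia <- grp == case
  res <- t(apply(v, 1, function(x) {
    tt <- twoSampleTTest(x[ia], x[!ia], var_equal = var_equal)
    c(mean(x[ia]), mean(x[!ia]), tt$statistic, tt$p_value)
  }))
  p_adj <- bhAdjust(res[, 4])
  data.frame(
    feature_id = rownames(v),
    mean_case = res[, 1], mean_control = res[, 2],
    log2fc = res[, 1] - res[, 2],
    t_stat = res[, 3], p_raw = res[, 4], p_adj = p_adj,
    neg_log10_p_adj = -log10(p_adj),
    significant = p_adj < alpha,
    row.names = NULL, stringsAsFactors = FALSE)
}

# log multivariate hypergeometric probability of an r x 2 table given margins
logTableProb <- function(a, rows, n1, N) {
  sum(lchoose(rows, a)) - lchoose(N, n1)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value: the sum of hypergeometric probabilities of all
#' tables with the observed margins whose probability does not exceed the
#' observed table's (relative tolerance 1e-12). A zero margin gives p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return The exact two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(46, 29, 36, 26), 2, 2))
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("2x2 table required")
  checkCounts(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Freeman-Halton exact test for an r x 2 table
#'
#' Exact generalization of Fisher's test to r rows and two columns by full
#' enumeration of all tables sharing the observed margins, summing the
#' multivariate hypergeometric probabilities not exceeding the observed
#' table's (relative tolerance 1e-12). Rows with a zero margin are dropped
#' (the test on the reduced table is identical). If the number of
#' margin-fixed tables exceeds \code{max_tables} a seeded Monte Carlo
#' estimate over \code{mc_samples} margin-conditioned tables is used when
#' \code{monte_carlo = TRUE}, otherwise an error advises it.
#'
#' @param tab r x 2 matrix of non-negative integer counts.
#' @param max_tables enumeration cap, default 1e7.
#' @param monte_carlo logical, allow the Monte Carlo fallback.
#' @param mc_samples Monte Carlo sample size.
#' @param seed seed for the Monte Carlo fallback.
#' @return The exact (or Monte Carlo) two-sided p-value.
#' @examples
#' eth <- matrix(c(37, 24, 13, 1, 0, 41, 12, 7, 0, 2), ncol = 2)
#' fisherFreemanHalton(eth)
#' @export
fisherFreemanHalton <- function(tab, max_tables = 1e7, monte_carlo = FALSE,
                                mc_samples = 1e5, seed = 1L) {
  tab <- as.matrix(tab)
  if (ncol(tab) != 2L) stop("r x 2 table required")
  checkCounts(tab)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L || any(colSums(tab) == 0)) return(1)
  rows <- rowSums(tab); n1 <- sum(tab[, 1]); N <- sum(tab)
  r <- length(rows)

  # count margin-fixed tables by dynamic programming before enumerating
  counts <- rep(0, n1 + 1); counts[1] <- 1
  for (i in seq_len(r)) {
    new <- rep(0, n1 + 1)
    for (s in 0:n1) if (counts[s + 1] > 0)
      for (a in 0:min(rows[i], n1 - s))
        new[s + a + 1] <- new[s + a + 1] + counts[s + 1]
    counts <- new
  }
  n_tables <- counts[n1 + 1]
  if (n_tables > max_tables) {
    if (!monte_carlo)
      stop(sprintf(
        "%.3g margin-fixed tables exceeds cap %.3g; use monte_carlo = TRUE",
        n_tables, max_tables))
    return(ffhMonteCarlo(tab, mc_samples, seed))
  }

  lp_obs <- logTableProb(tab[, 1], rows, n1, N)
  tol <- lp_obs + log1p(1e-12)
  # depth-first enumeration of first-column counts per row
  total <- 0
  recurse <- function(i, remaining, lp) {
    if (i == r) {
      if (remaining <= rows[r]) {
        lpt <- lp + lchoose(rows[r], remaining) - lchoose(N, n1)
        if (lpt <= tol) total <<- total + exp(lpt)
      }
      return(invisible())
    }
    lo <- max(0, remaining - sum(rows[(i + 1):r]))
    hi <- min(rows[i], remaining)
    for (a in lo:hi)
      recurse(i + 1L, remaining - a, lp + lchoose(rows[i], a))
  }
  recurse(1L, n1, 0)
  min(1, total)
}

# Monte Carlo tail estimate under the margin-conditioned null via r2dtable
ffhMonteCarlo <- function(tab, mc_samples, seed) {
  rows <- rowSums(tab); cols <- colSums(tab); N <- sum(tab)
  lp_obs <- logTableProb(tab[, 1], rows, cols[1], N)
  tol <- lp_obs + log1p(1e-12)
  set.seed(seed)
  sims <- stats::r2dtable(mc_samples, rows, cols)
  lps <- vapply(sims, function(t) logTableProb(t[, 1], rows, cols[1], N), 0)
  (sum(lps <= tol) + 1) / (mc_samples + 1)
}

checkCounts <- function(tab) {
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  invisible(TRUE)
}

#' Wilcoxon rank-sum test
#'
#' Two-sided test: exact enumeration when the combined sample size is at
#' most 10 and there are no ties, otherwise the normal approximation with
#' tie and continuity corrections.
#'
#' @param a,b numeric vectors, each non-empty.
#' @return The two-sided p-value.
#' @export
wilcoxonRankSum <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 10) && !ties
  suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
}

#' Train-only statistical feature selection
#'
#' Selects features whose BH-adjusted two-sample t-test p-value on the
#' training partition is below \code{alpha}. The returned id list is meant
#' to be applied to the held-out partition without recomputation, avoiding
#' selection leakage.
#'
#' @param m_train log2-scale \linkS4class{QuantMatrix}, training samples only.
#' @param info_train matching metadata.
#' @param alpha adjusted-p threshold in (0, 1]; \code{alpha = 1} keeps all.
#' @param case passed to \code{\link{volcanoTable}}.
#' @return Character vector of selected feature ids.
#' @export
trainOnlyStatFilter <- function(m_train, info_train, alpha = 0.01,
                                case = NULL) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  vt <- volcanoTable(m_train, info_train, case = case, alpha = alpha)
  if (alpha >= 1) return(vt$feature_id)
  vt$feature_id[vt$p_adj < alpha]
}
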