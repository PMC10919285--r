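# Paired statistical comparison of two models' per-label metric scores:
# normality check of the paired differences (Kolmogorov-Smirnov against a
# fitted normal), then a paired two-sided Wilcoxon signed-rank test.

#' Compare two models' paired metric scores
#'
#' Takes two vectors of the same metric measured on the same items (e.g. DSC
#' per evaluated label) and tests whether the paired differences are centred
#' at zero. The differences are first checked for normality with a
#' Kolmogorov-Smirnov test against a normal with the sample mean and SD; the
#' location test is a two-sided paired Wilcoxon signed-rank test, computed
#' exactly (full enumeration of the 2^n sign assignments) whenever the sample
#' is small enough and free of zeros and ties, and by the usual normal
#' approximation with continuity correction otherwise. No multiple-testing
#' correction is applied.
#'
#' @param scores_a,scores_b numeric vectors of equal length, paired by
#'   position.
#' @param alpha significance level (default 0.05).
#' @param exact_max largest n for which the exact Wilcoxon distribution is
#'   requested (default 25).
#' @return list with `n`, `differences`, `mean_difference`,
#'   `ks_statistic`, `ks_p_value`, `normal` (KS p > alpha),
#'   `wilcoxon_statistic`, `wilcoxon_p_value`, `wilcoxon_exact`,
#'   `significant` (Wilcoxon p < alpha), `alpha`, `degenerate` (TRUE when all
#'   differences are zero, in which case the models are identical on this
#'   metric and the Wilcoxon p is reported as 1).
#' @export
compare_models <- function(scores_a, scores_b, alpha = 0.05, exact_max = 25) {
  scores_a <- as.numeric(scores_a)
  scores_b <- as.numeric(scores_b)
  if (length(scores_a) != length(scores_b))
    stop("paired score vectors must have equal length")
  if (length(scores_a) < 2) stop("need at least 2 paired scores")
  if (anyNA(scores_a) || anyNA(scores_b))
    stop("paired scores must not contain NA")
  d <- scores_a - scores_b
  n <- length(d)

  if (all(d == 0)) {
    return(list(n = n, differences = d, mean_difference = 0,
                ks_statistic = NA_real_, ks_p_value = NA_real_,
                normal = NA, wilcoxon_statistic = NA_real_,
                wilcoxon_p_value = 1, wilcoxon_exact = TRUE,
                significant = FALSE, alpha = alpha, degenerate = TRUE))
  }

  # KS against a normal fitted to the differences. With zero spread the
  # fitted normal is degenerate and the data are trivially non-normal.
  if (stats::sd(d) > 0) {
    ks <- suppressWarnings(stats::ks.test(d, "pnorm", mean(d), stats::sd(d)))
    ks_stat <- unname(ks$statistic)
    ks_p <- ks$p.value
  } else {
    ks_stat <- 1
    ks_p <- 0
  }

  nz <- d[d != 0]
  use_exact <- length(nz) <= exact_max && !anyDuplicated(abs(nz)) &&
    length(nz) == n
  wt <- suppressWarnings(
    stats::wilcox.test(scores_a, scores_b, paired = TRUE,
                       exact = use_exact, correct = TRUE))

  list(n = n, differences = d, mean_difference = mean(d),
       ks_statistic = ks_stat, ks_p_value = ks_p,
       normal = isTRUE(ks_p > alpha),
       wilcoxon_statistic = unname(wt$statistic),
       wilcoxon_p_value = wt$p.value,
       wilcoxon_exact = use_exact,
       significant = wt$p.value < alpha,
       alpha = alpha, degenerate = FALSE)
}

#' Exact paired Wilcoxon p-value by full sign-flip enumeration
#'
#' Reference implementation of the two-sided exact signed-rank p-value: all
#' 2^n assignments of signs to the ranked absolute differences are
#' enumerated and the p-value is the fraction of assignments whose V
#' statistic is at least as extreme as the observed one. Requires no zero
#' differences and no ties in the absolute differences. Intended as an
#' independent cross-check of [compare_models()]; cost grows as 2^n.
#'
#' @param differences numeric vector of non-zero paired differences (n <= 20).
#' @return list with `statistic` (V, the positive-rank sum) and `p_value`.
#' @export
wilcoxon_exact_enum <- function(differences) {
  d <- as.numeric(differences)
  n <- length(d)
  if (n < 1 || n > 20) stop("enumeration supports 1 <= n <= 20")
  if (any(d == 0)) stop("exact enumeration requires non-zero differences")
  r <- rank(abs(d))
  if (anyDuplicated(r)) stop("exact enumeration requires untied |differences|")
  v_obs <- sum(r[d > 0])
  total <- sum(r)
  # distribution of V under random sign flips
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  # two-sided: V and its mirror total - V are equally extreme
  lo <- min(v_obs, total - v_obs)
  p <- mean(vs <= lo | vs >= total - lo)
  list(statistic = v_obs, p_value = min(1, p))
}
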