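# Cycle-averaged group statistics: Wilcoxon rank-sum, Pearson correlation
# with t-based p, Fisher r-to-z comparison of two independent correlations.

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided Mann-Whitney U with midrank ties.  The exact null
#' distribution is enumerated when the pooled sample size is at most 12
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity corrections is used.  Appropriate for independent samples
#' with unequal group sizes.
#'
#' @param x,y numeric samples (each non-empty).
#' @return list with `statistic` (U, pairs where x exceeds y) and `p`
#'   (two-sided).
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p = wt$p.value, exact = use_exact)
}

#' Two-sided p-value for a Pearson correlation
#'
#' p from \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on n-2 degrees of freedom.
#'
#' @param r correlation coefficient (|r| < 1).
#' @param n sample size (>= 3).
#' @return two-sided p-value.
#' @export
pearson_p_from_r <- function(r, n) {
  if (n < 3) stop("need n >= 3")
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric samples of equal length n >= 3, each with nonzero
#'   variance.
#' @return list with `r`, `p` (two-sided, from the t distribution on n-2
#'   degrees of freedom) and `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined")
  }
  r <- stats::cor(x, y)
  list(r = r, p = pearson_p_from_r(r, n), n = n)
}

#' Fisher r-to-z comparison of two independent correlations
#'
#' \deqn{ z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'            {\sqrt{1/(n_1-3) + 1/(n_2-3)}} }
#' with a two-sided standard-normal p-value.
#'
#' @param r1,r2 correlation coefficients (|r| < 1).
#' @param n1,n2 sample sizes (>= 4 each).
#' @return list with `z` and `p`.
#' @export
fisher_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in each group")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = normal_two_sided_p(z))
}

#' Two-sided standard-normal p-value
#'
#' \eqn{2(1 - \Phi(|z|))}.
#'
#' @param z a finite normal deviate.
#' @return probability in [0, 1].
#' @export
normal_two_sided_p <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  2 * stats::pnorm(-abs(z))
}

#' Full scalar group comparison
#'
#' Assembles, for two lists of per-subject cycle-averaged summaries, the
#' group means/SDs and Wilcoxon rank-sum tests for each metric (ellipsoid
#' volume, AP/ML/VT directional SDs, total variability), the within-group
#' Pearson correlations between ellipsoid volume and total variability,
#' and the Fisher r-to-z comparison of the two correlations.
#'
#' @param summariesA,summariesB lists of [subject_summary()] objects
#'   (>= 4 subjects per group).
#' @param alpha significance level for the `significant` flags.
#' @return object of class `group_comparison` with `metrics` (data.frame),
#'   `correlations` (per-group r/p/n), `fisher` (z, p) and `alpha`.
#' @export
compare_groups <- function(summariesA, summariesB, alpha = 0.05) {
  if (length(summariesA) < 4 || length(summariesB) < 4) {
    stop("need at least 4 subjects per group")
  }
  fields <- c("mean_ellipsoid_volume", "var_ap", "var_ml", "var_vt",
              "total_variability")
  getv <- function(lst, f) vapply(lst, function(s) s[[f]], numeric(1))
  metrics <- do.call(rbind, lapply(fields, function(f) {
    a <- getv(summariesA, f); b <- getv(summariesB, f)
    rs <- rank_sum_test(a, b)
    data.frame(metric = f,
               mean_A = mean(a), sd_A = stats::sd(a),
               mean_B = mean(b), sd_B = stats::sd(b),
               statistic = rs$statistic, p = rs$p,
               significant = rs$p < alpha,
               stringsAsFactors = FALSE)
  }))
  corr <- lapply(list(A = summariesA, B = summariesB), function(lst) {
    pearson_with_p(getv(lst, "mean_ellipsoid_volume"),
                   getv(lst, "total_variability"))
  })
  fish <- fisher_compare(corr$A$r, corr$A$n, corr$B$r, corr$B$n)
  structure(list(metrics = metrics, correlations = corr, fisher = fish,
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-22s A %.4g (SD %.3g) vs B %.4g (SD %.3g), p = %.4g%s\n",
                m$metric[i], m$mean_A[i], m$sd_A[i], m$mean_B[i], m$sd_B[i],
                m$p[i], if (m$significant[i]) " *" else ""))
  }
  cat(sprintf("  volume~total r: A %.3f (p %.4g, n %d) vs B %.3f (p %.4g, n %d)\n",
              x$correlations$A$r, x$correlations$A$p, x$correlations$A$n,
              x$correlations$B$r, x$correlations$B$p, x$correlations$B$n))
  cat(sprintf("  Fisher r-to-z: z = %.3f, p = %.4g\n", x$fisher$z, x$fisher$p))
  invisible(x)
}
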