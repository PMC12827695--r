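# Group statistics: pooled two-sample t, Cohen's d with 95% CI, Pearson
# chi-square, Benjamini-Hochberg FDR, and Spearman rank correlation.

#' Pooled-variance two-sample t test
#'
#' Student (equal-variance) t test of group A minus group B with
#' df = n_A + n_B - 2 and two-sided p value, plus Cohen's d and its 95% CI
#' via [cohens_d_ci()].
#'
#' @param values_a,values_b Numeric vectors (at least 2 each).
#' @param metric_name Optional label carried into the result.
#' @return Object of class `group_comparison`: `metric_name`,
#'   `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`, `t_statistic`,
#'   `df`, `p_value`, `cohens_d`, `ci95` (length-2).
#' @examples
#' two_sample_t(rnorm(20, 1), rnorm(20))
#' @export
two_sample_t <- function(values_a, values_b, metric_name = "metric") {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop_edgedyn("need at least 2 observations per group")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop_edgedyn("zero pooled variance")
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2L
  d <- cohens_d_ci(mean(a), stats::sd(a), na, mean(b), stats::sd(b), nb)
  structure(list(metric_name = metric_name,
                 mean_a = mean(a), sd_a = stats::sd(a), n_a = na,
                 mean_b = mean(b), sd_b = stats::sd(b), n_b = nb,
                 t_statistic = tstat, df = df,
                 p_value = 2 * stats::pt(-abs(tstat), df),
                 cohens_d = d$d, ci95 = d$ci95),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.4g (n=%d) vs %.4g +/- %.4g (n=%d); t(%d) = %.3f, p = %.4g, d = %.3f (%.3f, %.3f)\n",
              x$metric_name, x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b,
              x$df, x$t_statistic, x$p_value, x$cohens_d, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Cohen's d with normal-approximation 95% CI from summary statistics
#'
#' d = (mean_A - mean_B) / s_pooled with
#' s_pooled = sqrt(((n_A-1) sd_A^2 + (n_B-1) sd_B^2) / (n_A+n_B-2)), and
#' CI = d +/- 1.96 * sqrt((n_A+n_B)/(n_A n_B) + d^2 / (2 (n_A+n_B))).
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summary statistics.
#' @return List with `d` and `ci95` (length-2 vector, low then high).
#' @examples
#' cohens_d_ci(5.96, 0.55, 211, 4.95, 0.42, 210)
#' @export
cohens_d_ci <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  n_a <- check_count(n_a, "n_a", 2L); n_b <- check_count(n_b, "n_b", 2L)
  if (!is.finite(sd_a) || !is.finite(sd_b) || sd_a < 0 || sd_b < 0 ||
      (sd_a == 0 && sd_b == 0))
    stop_edgedyn("invalid standard deviations")
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  d <- (mean_a - mean_b) / sp
  se <- sqrt((n_a + n_b) / (n_a * n_b) + d^2 / (2 * (n_a + n_b)))
  list(d = d, ci95 = c(d - 1.96 * se, d + 1.96 * se))
}

#' Pearson chi-square test of independence
#'
#' Classical Pearson chi-square without continuity correction,
#' df = (r-1)(c-1). Errors on any zero row or column marginal.
#'
#' @param contingency Matrix of non-negative integer counts, at least 2x2.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @examples
#' chi_square_test(matrix(c(78, 91, 133, 119), 2))
#' @export
chi_square_test <- function(contingency) {
  o <- as.matrix(contingency)
  if (nrow(o) < 2L || ncol(o) < 2L) stop_edgedyn("need at least a 2x2 table")
  if (any(o < 0) || any(o != round(o))) stop_edgedyn("counts must be non-negative integers")
  rs <- rowSums(o); cs <- colSums(o)
  if (any(rs == 0) || any(cs == 0)) stop_edgedyn("zero row or column marginal")
  e <- outer(rs, cs) / sum(o)
  stat <- sum((o - e)^2 / e)
  df <- (nrow(o) - 1L) * (ncol(o) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), expected = e)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjustment: adjusted p for the k-th smallest raw p is
#' min over j >= k of p_(j) * m / j, capped at 1; rejections are raw
#' p_(k) <= k * alpha / m for k up to the largest such index.
#'
#' @param p_values Raw p values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return List with `adjusted` (same order as input) and `reject`
#'   (logical mask).
#' @examples
#' fdr_bh(c(0.005, 0.03, 0.04))
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_edgedyn("p values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  adj_sorted <- p[ord] * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  adj <- numeric(m)
  adj[ord] <- pmin(adj_sorted, 1)
  thresh <- which(p[ord] <= seq_len(m) * alpha / m)
  reject <- logical(m)
  if (length(thresh)) reject[ord[seq_len(max(thresh))]] <- TRUE
  list(adjusted = adj, reject = reject)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive mean rank), with a
#' two-sided p value from the t approximation
#' t = rho sqrt((n-2)/(1-rho^2)) on n-2 df.
#'
#' @param x,y Paired numeric vectors; pairs with missing values dropped.
#' @param labels Optional length-2 character vector naming the pair.
#' @return Object of class `correlation_result`: `variable_pair`, `rho`,
#'   `p_value`, `n`.
#' @examples
#' spearman_cor(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
#' @export
spearman_cor <- function(x, y, labels = c("x", "y")) {
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x)[ok]; y <- as.numeric(y)[ok]
  n <- length(x)
  if (n < 3L) stop_edgedyn("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_edgedyn("constant vector: rank correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0
       else 2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2)
  structure(list(variable_pair = labels, rho = rho, p_value = p, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman %s ~ %s: rho = %.3f, p = %.4g, n = %d\n",
              x$variable_pair[1], x$variable_pair[2], x$rho, x$p_value, x$n))
  invisible(x)
}

#' Group comparison table over metric columns
#'
#' Runs [two_sample_t()] for each metric column between two groups, with
#' optional ComBat harmonization across sites first and BH-FDR adjustment
#' of the p values.
#'
#' @param metrics data.frame of numeric metric columns.
#' @param group Factor/vector with exactly two levels; the first level is
#'   group A.
#' @param site Optional site labels; when given, metrics are harmonized
#'   with [combat_fit_apply()] retaining the group effect.
#' @param fdr Apply BH adjustment across metrics (default TRUE).
#' @param alpha FDR level.
#' @return data.frame, one row per metric: group means/SDs/n, t, df, p,
#'   Cohen's d, CI bounds, and `p_fdr`/`significant` when `fdr`.
#' @export
group_comparison_table <- function(metrics, group, site = NULL, fdr = TRUE,
                                   alpha = 0.05) {
  metrics <- as.data.frame(metrics)
  group <- factor(group)
  if (nlevels(group) != 2L) stop_edgedyn("'group' must have exactly 2 levels")
  keep <- stats::complete.cases(metrics)
  metrics <- metrics[keep, , drop = FALSE]
  group <- group[keep]
  nonconst <- vapply(metrics, function(v) stats::var(v) > 0, logical(1))
  metrics <- metrics[, nonconst, drop = FALSE]
  if (!is.null(site)) {
    site <- factor(site[keep])
    if (nlevels(site) > 1L) {
      gind <- as.numeric(group == levels(group)[1L])
      metrics <- as.data.frame(
        combat_fit_apply(metrics, site, covariates = cbind(group = gind))$harmonized)
    }
  }
  rows <- lapply(names(metrics), function(m) {
    cmp <- tryCatch(
      two_sample_t(metrics[[m]][group == levels(group)[1L]],
                   metrics[[m]][group == levels(group)[2L]],
                   metric_name = m),
      edgedyn_error = function(e) NULL)  # constant metric: skip
    if (is.null(cmp)) return(NULL)
    data.frame(metric = m, mean_a = cmp$mean_a, sd_a = cmp$sd_a, n_a = cmp$n_a,
               mean_b = cmp$mean_b, sd_b = cmp$sd_b, n_b = cmp$n_b,
               t = cmp$t_statistic, df = cmp$df, p = cmp$p_value,
               cohens_d = cmp$cohens_d,
               ci_low = cmp$ci95[1L], ci_high = cmp$ci95[2L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (fdr) {
    f <- fdr_bh(out$p, alpha)
    out$p_fdr <- f$adjusted
    out$significant <- f$reject
  }
  out
}
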