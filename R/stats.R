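#' One-sided Mann-Whitney U test
#'
#' Two-sample rank test with the contract used throughout the reports: the
#' exact null distribution is used when `min(n, m) <= 8` and the pooled
#' sample is tie-free; otherwise the normal approximation with tie
#' correction (and continuity correction) is used. Computation delegates to
#' [stats::wilcox.test()].
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"less"` if `x` is hypothesised stochastically smaller
#'   than `y`, `"greater"` if larger.
#' @param group_labels Length-2 character vector naming the groups.
#' @return list of class `group_comparison`: group labels, per-group `n`,
#'   `mean`, `sd`, the U statistic (number of (x, y) pairs with x > y) and
#'   the one-sided `p`, plus whether the exact path was used.
#' @export
mann_whitney_one_sided <- function(x, y, alternative = c("less", "greater"),
                                   group_labels = c("x", "y")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stopf("both samples must be non-empty")
  exact <- min(length(x), length(y)) <= 8L && !anyDuplicated(c(x, y))
  ht <- stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                           correct = TRUE)
  structure(list(
    groups = group_labels,
    n = c(length(x), length(y)),
    mean = c(mean(x), mean(y)),
    sd = c(stats::sd(x), stats::sd(y)),
    U = unname(ht$statistic),
    p = ht$p.value,
    alternative = alternative,
    exact = exact
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: n=%d, mean=%.2f, sd=%.2f\n", x$groups[1L], x$n[1L], x$mean[1L], x$sd[1L]))
  cat(sprintf("%s: n=%d, mean=%.2f, sd=%.2f\n", x$groups[2L], x$n[2L], x$mean[2L], x$sd[2L]))
  cat(sprintf("one-sided Mann-Whitney U = %g (%s, %s), p %s\n",
              x$U, x$alternative, if (x$exact) "exact" else "normal approximation",
              format_p(x$p)))
  invisible(x)
}

# Underflowed p-values are reported as bounds, never as 0.
format_p <- function(p) {
  if (p < 1e-300) "< 1e-300" else sprintf("= %.4g", p)
}

#' Squared correlation coefficient
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, non-constant.
#' @param method `"pearson"` or `"spearman"` (Pearson on mid-ranks).
#' @return The squared correlation coefficient.
#' @export
correlation_r2 <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3L) stopf("need n >= 3 for a correlation")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("correlation undefined for constant input")
  }
  stats::cor(x, y, method = method)^2
}
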