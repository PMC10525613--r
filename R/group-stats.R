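# Nonparametric statistics for cohort-level analysis: Mann-Whitney
# contrasts, Spearman correlations, median-split grouping, bootstrap ROC
# curves, and median/IQR summaries.

#' Mann-Whitney U test
#'
#' The statistic is the number of (x, y) pairs with \eqn{x > y}, counting
#' ties one half.  The two-sided p-value is exact (full enumeration of the
#' null distribution) when the smaller sample has at most 8 observations
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity corrections is used.
#'
#' @param x,y Numeric samples, each non-empty.
#' @return A \code{mw_test} list: \code{statistic} (U), \code{n_x},
#'   \code{n_y}, \code{p_two_sided}, \code{method} (\code{"exact"} or
#'   \code{"normal-approx"}).
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x[is.finite(x)]); y <- as.numeric(y[is.finite(y)])
  nx <- length(x); ny <- length(y)
  if (nx == 0L || ny == 0L) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- min(nx, ny) <= 8L && !ties
  if (stats::var(c(x, y)) == 0) {
    p <- 1
    method <- "normal-approx"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    p <- min(1, wt$p.value)
    method <- if (exact) "exact" else "normal-approx"
  }
  structure(list(statistic = U, n_x = nx, n_y = ny, p_two_sided = p,
                 method = method), class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("<Mann-Whitney U = %g (n = %d vs %d), p = %.4g [%s]>\n",
              x$statistic, x$n_x, x$n_y, x$p_two_sided, x$method))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with a
#' two-sided p-value from the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}}.  A perfect monotone relation
#' (\eqn{\rho = \pm 1}) is reported at the permutation bound \eqn{2/n!}.
#'
#' @param x,y Paired numeric vectors of equal length, \eqn{n \ge 3};
#'   incomplete pairs are dropped.
#' @return A \code{spearman_result} list: \code{rho}, \code{n},
#'   \code{p_two_sided}.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: constant input")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1 - 1e-12) {
    p <- min(1, 2 * exp(-lfactorial(n)))
  } else {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  structure(list(rho = rho, n = n, p_two_sided = p),
            class = "spearman_result")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("<Spearman rho = %.3f (n = %d), p = %.4g>\n",
              x$rho, x$n, x$p_two_sided))
  invisible(x)
}

# Rank-formula AUC: probability that a positive outranks a negative,
# ties counted one half.
auc_rank <- function(scores, positive) {
  r <- rank(scores)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve and AUC with bootstrap confidence interval
#'
#' AUC by the rank (pair-counting) formula with ties counted one half,
#' identical to \eqn{U / (n_{pos} n_{neg})} for the Mann-Whitney U of the
#' positive-class scores.  The confidence interval is a class-stratified
#' percentile bootstrap over subjects.
#'
#' @param scores Numeric feature values.
#' @param labels Class labels (two classes present).
#' @param positive_label The label treated as positive.
#' @param direction \code{"higher"} if larger scores indicate the positive
#'   class, \code{"lower"} if smaller scores do (the score is negated
#'   internally; the reported AUC refers to the oriented score).
#' @param n_boot Bootstrap resamples for the CI (default 2000).
#' @param seed Optional seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return A \code{roc_result}: \code{auc}, \code{ci_low}, \code{ci_high},
#'   \code{positive_label}, \code{direction}, \code{n_pos}, \code{n_neg},
#'   and \code{curve} (data frame of FPR/TPR from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels, positive_label,
                    direction = c("higher", "lower"),
                    n_boot = 2000L, seed = NULL, conf = 0.95) {
  direction <- match.arg(direction)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  positive <- labels == positive_label
  if (!any(positive) || all(positive))
    stop("both classes must be present in `labels`")
  s <- if (direction == "lower") -scores else scores

  auc <- auc_rank(s, positive)

  ord <- order(s, decreasing = TRUE)
  lab_o <- positive[ord]; s_o <- s[ord]
  tp <- cumsum(lab_o); fp <- cumsum(!lab_o)
  last_of_tie <- c(diff(s_o) != 0, TRUE)
  curve <- data.frame(
    fpr = c(0, fp[last_of_tie] / sum(!positive)),
    tpr = c(0, tp[last_of_tie] / sum(positive)))

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    pos_idx <- which(positive); neg_idx <- which(!positive)
    aucs <- with_seed_local(seed, {
      vapply(seq_len(n_boot), function(b) {
        pi <- sample(pos_idx, length(pos_idx), replace = TRUE)
        ni <- sample(neg_idx, length(neg_idx), replace = TRUE)
        idx <- c(pi, ni)
        auc_rank(s[idx], c(rep(TRUE, length(pi)), rep(FALSE, length(ni))))
      }, numeric(1))
    })
    alpha <- (1 - conf) / 2
    ci <- as.numeric(stats::quantile(aucs, c(alpha, 1 - alpha),
                                     names = FALSE))
    ci[1L] <- min(ci[1L], auc); ci[2L] <- max(ci[2L], auc)
  }
  structure(list(auc = auc, ci_low = ci[1L], ci_high = ci[2L],
                 positive_label = positive_label, direction = direction,
                 n_pos = sum(positive), n_neg = sum(!positive),
                 curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<ROC: AUC = %.3f (CI %.3f-%.3f), positive = %s, %d vs %d>\n",
              x$auc, x$ci_low, x$ci_high, x$positive_label,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Median-split grouping
#'
#' Splits values at the midpoint-interpolated sample median; values at or
#' above the median form the high group (by the tie convention used for
#' UMN-burden grouping, a score exactly at the cut goes high).  When all
#' values are equal every subject is "high" -- a documented degenerate
#' outcome.
#'
#' @param scores Numeric vector, length at least 2.
#' @return A factor with levels \code{c("low", "high")}.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 values")
  med <- stats::median(scores)
  factor(ifelse(scores >= med, "high", "low"), levels = c("low", "high"))
}

#' Median and interquartile range summary
#'
#' @param values Numeric vector, non-empty; NA dropped.
#' @return A \code{group_summary}: \code{median}, \code{q1}, \code{q3}
#'   (linear interpolation between order statistics), \code{n}.
#' @export
summarize_values <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("empty input")
  qs <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(median = qs[2L], q1 = qs[1L], q3 = qs[3L],
                 n = length(values)), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<median %.3g (IQR %.3g-%.3g), n = %d>\n",
              x$median, x$q1, x$q3, x$n))
  invisible(x)
}
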