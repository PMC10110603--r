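#' Discrimination index for novel object recognition
#'
#' `DI = (N_N - N_F) / (N_N + N_F)`, where `N_N` and `N_F` are the numbers
#' of explorations of the novel and familiar object.  Ranges over
#' `[-1, 1]`; 0 means no preference.
#'
#' @param novel,familiar Non-negative exploration counts.
#' @return DI in `[-1, 1]`.
#' @examples
#' discrimination_index(8, 4)  # 1/3
#' @export
discrimination_index <- function(novel, familiar) {
  if (any(novel < 0) || any(familiar < 0)) stop("counts must be non-negative")
  if (any(novel + familiar == 0)) {
    stop("DI undefined: no explorations of either object")
  }
  (novel - familiar) / (novel + familiar)
}

#' F test for equality of variances
#'
#' `F` is the ratio of the larger to the smaller sample variance, with
#' numerator/denominator degrees of freedom matched to that ordering; the
#' two-sided p-value is twice the upper-tail F probability at the observed
#' ratio (capped at 1).  A summary-statistic mode accepts a precomputed
#' `(F, df)` pair so printed values can be checked without raw data.
#'
#' @param x,y Numeric samples (each n >= 2), or `NULL` in summary mode.
#' @param f,df Summary mode: observed ratio (larger/smaller) and
#'   `c(df_num, df_den)`.
#' @param alternative `"two.sided"` (default) or `"greater"` (one-tailed).
#' @return An object of class `"variance_test"`: list with `F`, `df_num`,
#'   `df_den`, `p`, `alternative`.
#' @examples
#' variance_ratio_test(f = 3.128, df = c(25, 26))$p  # ~0.0051
#' @export
variance_ratio_test <- function(x = NULL, y = NULL, f = NULL, df = NULL,
                                alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (is.null(f)) {
    if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
    vx <- stats::var(x)
    vy <- stats::var(y)
    if (vx == 0 || vy == 0) stop("zero variance in a sample; F test undefined")
    if (vx >= vy) {
      f <- vx / vy; df <- c(length(x) - 1L, length(y) - 1L)
    } else {
      f <- vy / vx; df <- c(length(y) - 1L, length(x) - 1L)
    }
  } else {
    if (is.null(df) || length(df) != 2) {
      stop("summary mode needs df = c(df_num, df_den)")
    }
    if (f < 1) stop("summary-mode F must use the larger/smaller convention (F >= 1)")
  }
  tail <- stats::pf(f, df[1], df[2], lower.tail = FALSE)
  p <- if (alternative == "two.sided") min(1, 2 * tail) else tail
  structure(list(F = f, df_num = df[1], df_den = df[2], p = p,
                 alternative = alternative),
            class = "variance_test")
}

#' @export
print.variance_test <- function(x, ...) {
  cat(sprintf("F test for equality of variance: F = %.4g, df = (%d, %d), %s p = %.4g\n",
              x$F, x$df_num, x$df_den,
              if (x$alternative == "two.sided") "two-sided" else "one-sided",
              x$p))
  invisible(x)
}

#' Variance-conditional two-sample t test
#'
#' The comparison policy used for group differences: an F test for equality
#' of variances decides the t test flavor — Welch's unequal-variance
#' correction when the F test is significant at `alpha_variance`, the
#' pooled-variance Student t test otherwise.  Two-sided.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param alpha_variance Significance level of the variance pre-test
#'   (default 0.05).
#' @return An object of class `"welch_conditional_t"`: list with `t`, `df`,
#'   `p`, `welch_applied`, `variance_test`, and the underlying `htest`.
#' @export
welch_conditional_ttest <- function(x, y, alpha_variance = 0.05) {
  vt <- variance_ratio_test(x, y)
  welch <- vt$p < alpha_variance
  tt <- stats::t.test(x, y, var.equal = !welch)
  structure(list(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, welch_applied = welch,
                 variance_test = vt, htest = tt),
            class = "welch_conditional_t")
}

#' @export
print.welch_conditional_t <- function(x, ...) {
  cat(sprintf("%s t test: t = %.4g, df = %.4g, p = %.4g\n",
              if (x$welch_applied) "Welch (unequal-variance)" else "pooled",
              x$t, x$df, x$p))
  cat(sprintf("  variance pre-test: F = %.4g, p = %.4g -> Welch %s\n",
              x$variance_test$F, x$variance_test$p,
              if (x$welch_applied) "applied" else "not applied"))
  invisible(x)
}
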