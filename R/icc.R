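#' Single-measure two-way random absolute-agreement ICC
#'
#' Intraclass correlation for a complete subjects-by-raters table under the
#' two-way random-effects model with absolute agreement, single measure --
#' ICC(2,1) in the Shrout--Fleiss numbering, ICC(A,1) in McGraw--Wong.
#' From the two-way ANOVA mean squares (rows/subjects MSR, columns/raters
#' MSC, residual MSE):
#'
#' \deqn{ICC = \frac{MSR - MSE}{MSR + (k-1)MSE + \frac{k}{n}(MSC - MSE)}}
#'
#' The confidence interval is the F-based interval of McGraw and Wong for
#' the absolute-agreement single-measure case. Because absolute agreement
#' is assessed, a constant shift between raters lowers the estimate even
#' when the rank order is preserved.
#'
#' @param data An n-subjects by k-raters numeric matrix or data frame of
#'   measurements; no missing cells allowed, n >= 2, k >= 2.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `bst_icc` with elements `estimate`,
#'   `conf.low`, `conf.high`, `n_subjects`, `n_raters`, `interpretation`
#'   and the mean squares. Use [tidy.bst_icc()] for a tibble.
#' @examples
#' ratings <- cbind(r1 = c(9, 6, 8, 7, 10), r2 = c(9, 5, 9, 8, 10))
#' icc_2_1(ratings)
#' @export
icc_2_1 <- function(data, conf_level = 0.95) {
  m <- as.matrix(data)
  storage.mode(m) <- "double"
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop_validation("ICC needs at least 2 subjects and 2 raters")
  }
  if (anyNA(m)) {
    stop_validation("ICC requires a complete table: missing cells found")
  }
  if (stats::var(as.vector(m)) == 0) {
    stop_validation("all measurements are identical: ICC is undefined")
  }
  grand <- mean(m)
  rm_ <- rowMeans(m)
  cm_ <- colMeans(m)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  mse <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand)^2) /
    ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf_level
  if (mse <= .Machine$double.eps * msr) {
    # perfect agreement: the F interval degenerates
    ci <- c(est, est)
  } else {
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(min(lower, est), max(upper, est))
  }
  structure(
    list(estimate = est, conf.low = ci[1], conf.high = ci[2],
         n_subjects = n, n_raters = k, conf_level = conf_level,
         interpretation = interpret_icc(est),
         ms = c(msr = msr, msc = msc, mse = mse)),
    class = "bst_icc"
  )
}

#' Interpret an ICC estimate
#'
#' Agreement bands: below 0.5 poor, 0.5 to 0.75 moderate, 0.75 to 0.9
#' good, 0.9 to 1 excellent. Band endpoints belong to the higher band.
#'
#' @param estimate ICC estimate(s), each at most 1.
#' @return Character vector in `poor`, `moderate`, `good`, `excellent`.
#' @examples
#' interpret_icc(c(0.3, 0.6, 0.8, 0.92))
#' @export
interpret_icc <- function(estimate) {
  if (any(estimate > 1 + 1e-8)) {
    stop_validation("ICC estimates cannot exceed 1")
  }
  dplyr::case_when(
    estimate < 0.5 ~ "poor",
    estimate < 0.75 ~ "moderate",
    estimate < 0.9 ~ "good",
    .default = "excellent"
  )
}

#' @export
print.bst_icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) absolute agreement, single measure: %.3f (%g%% CI %.3f–%.3f)\n",
              x$estimate, 100 * x$conf_level, x$conf.low, x$conf.high))
  cat(sprintf("  %d subjects x %d raters; interpretation: %s\n",
              x$n_subjects, x$n_raters, x$interpretation))
  invisible(x)
}

#' Tidy an ICC result
#'
#' @param x A [icc_2_1()] result.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.bst_icc <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate, conf.low = x$conf.low, conf.high = x$conf.high,
    n_subjects = x$n_subjects, n_raters = x$n_raters,
    interpretation = x$interpretation
  )
}
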