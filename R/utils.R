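# Internal helpers: error classes, small vector algebra, summary formatting.

stop_validation <- function(message, ...) {
  rlang::abort(message, class = "bstmap_validation_error", ...)
}

stop_usage <- function(message, ...) {
  rlang::abort(message, class = "bstmap_usage_error", ...)
}

stop_io <- function(message, ...) {
  rlang::abort(message, class = "bstmap_io_error", ...)
}

unit_vector <- function(v, what = "vector") {
  v <- as.numeric(v)
  if (length(v) != 3L || anyNA(v) || any(!is.finite(v))) {
    stop_validation(sprintf("%s must be a finite 3D vector", what))
  }
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop_validation(sprintf("%s has zero length", what))
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# mean +/- SD, as printed in clinical summary tables
format_mean_sd <- function(x, digits = 1) {
  sprintf("%.*f ± %.*f", digits, mean(x), digits, stats::sd(x))
}

# median [IQR] for non-normally distributed variables
format_median_iqr <- function(x, digits = 1) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  sprintf("%.*f [%.*f–%.*f]", digits, stats::median(x),
          digits, q[1], digits, q[2])
}
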