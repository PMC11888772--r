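safe_shapiro_p <- function(x) {
  if (length(x) < 3L || length(unique(x)) == 1L) return(0)
  if (length(x) > 5000L) x <- sample(x, 5000L)
  tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
}

#' Normality-gated two-group comparison
#'
#' Compares a continuous variable between two groups the way clinical
#' reliability studies report it: each group is tested for normality with
#' the Shapiro--Wilk test; if both pass at `alpha_normality` the
#' independent-samples (Welch) t-test is used and groups are summarised as
#' mean ± SD, otherwise the Mann--Whitney U test is used with median
#' \[IQR\] summaries. Groups smaller than 3 cannot be normality-tested and
#' fall back to the Mann--Whitney U test with a warning.
#'
#' @param data A data frame.
#' @param value Column holding the measurements (bare name).
#' @param group Column holding the two-level group labels (bare name).
#' @param alpha_normality Shapiro--Wilk gate level (default 0.05).
#' @return A one-row tibble: group labels and sizes, the normality
#'   decision, chosen `test`, `statistic`, `p.value`, and formatted
#'   `summary_1` / `summary_2` strings matching the decision.
#' @examples
#' d <- data.frame(tsa = c(rnorm(20, 94, 2), rnorm(20, 87, 2)),
#'                 grp = rep(c("valgus", "varus"), each = 20))
#' compare_groups(d, tsa, grp)
#' @export
compare_groups <- function(data, value, group, alpha_normality = 0.05) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  lev <- levels(droplevels(g))
  if (length(lev) != 2L) {
    stop_validation("`group` must have exactly two non-empty levels")
  }
  x1 <- v[g == lev[1]]
  x2 <- v[g == lev[2]]
  small <- length(x1) < 3L || length(x2) < 3L
  if (small) {
    rlang::warn(paste0("a group has fewer than 3 observations; ",
                       "falling back to the Mann–Whitney U test"))
    normal <- FALSE
  } else {
    normal <- safe_shapiro_p(x1) > alpha_normality &&
      safe_shapiro_p(x2) > alpha_normality
  }
  if (normal) {
    ht <- stats::t.test(x1, x2)
    test <- "Welch t-test"
    s1 <- format_mean_sd(x1)
    s2 <- format_mean_sd(x2)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x1, x2, exact = FALSE))
    test <- "Mann-Whitney U"
    s1 <- format_median_iqr(x1)
    s2 <- format_median_iqr(x2)
  }
  tibble::tibble(
    group_1 = lev[1], group_2 = lev[2],
    n_1 = length(x1), n_2 = length(x2),
    normal = normal, test = test,
    statistic = unname(ht$statistic),
    p.value = ht$p.value,
    summary_1 = s1, summary_2 = s2
  )
}

#' Normality-gated correlation of two paired variables
#'
#' Pearson's correlation when both variables pass the Shapiro--Wilk
#' normality test, Spearman's rank correlation otherwise. Correlations are
#' flagged significant at the stringent `sig_level` of 0.001 used for
#' correlation reporting.
#'
#' @param data A data frame.
#' @param x,y Paired numeric columns (bare names).
#' @param alpha_normality Shapiro--Wilk gate level (default 0.05).
#' @param sig_level Significance threshold for the `significant` flag
#'   (default 0.001).
#' @return A one-row tibble with `pair`, `method`, `estimate`, `p.value`,
#'   `n`, `significant`.
#' @export
correlate_pair <- function(data, x, y, alpha_normality = 0.05,
                           sig_level = 0.001) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  xname <- rlang::as_name(rlang::enquo(x))
  yname <- rlang::as_name(rlang::enquo(y))
  ok <- stats::complete.cases(xv, yv)
  xv <- xv[ok]
  yv <- yv[ok]
  if (length(xv) < 4L) stop_validation("correlation needs at least 4 complete pairs")
  if (stats::var(xv) == 0 || stats::var(yv) == 0) {
    stop_validation("correlation is undefined for a constant variable")
  }
  normal <- safe_shapiro_p(xv) > alpha_normality &&
    safe_shapiro_p(yv) > alpha_normality
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(xv, yv, method = method, exact = FALSE))
  tibble::tibble(
    pair = paste(xname, "vs", yname),
    method = if (normal) "Pearson" else "Spearman",
    estimate = unname(ct$estimate),
    p.value = ct$p.value,
    n = length(xv),
    significant = ct$p.value < sig_level
  )
}

#' Group comparisons and correlations for a scored cohort
#'
#' Reproduces the structure of a clinical summary: the coronal alignment
#' measures (alpha angle, tibiotalar surface angle, hindfoot alignment
#' angle, talocalcaneal angle, talar tilt) are compared between the varus
#' and valgus contact-pattern groups and correlated with TWSx; the
#' sagittal measures (beta angle, tibiotalar ratio) are compared between
#' the anterior and posterior groups and correlated with TWSy. Tests and
#' summaries are normality-gated as in [compare_groups()] and
#' [correlate_pair()]. Comparisons whose groups have fewer than 2 patients
#' are skipped with a warning rather than failing.
#'
#' @param cohort A data frame with columns `tws_x`, `tws_y`, the angle
#'   columns `alpha_deg`, `tsa_deg`, `hfa_deg`, `talocalcaneal_deg`,
#'   `tt_deg`, `beta_deg`, `ttr_mm` (missing angle columns are skipped),
#'   and optionally `coronal_class` / `sagittal_class` (derived from the
#'   TWS values when absent).
#' @param zero_tol,digits Passed to [classify_contact()] when classes are
#'   derived.
#' @return An object of class `bst_cohort_report`: a list with tibbles
#'   `comparisons` and `correlations` plus the group `counts`. Use
#'   [tidy.bst_cohort_report()] to extract either table.
#' @export
cohort_analysis <- function(cohort, zero_tol = 0, digits = 3) {
  if (!all(c("tws_x", "tws_y") %in% names(cohort))) {
    stop_validation("`cohort` must have tws_x and tws_y columns")
  }
  if (!all(c("coronal_class", "sagittal_class") %in% names(cohort))) {
    cls <- classify_contact(cohort$tws_x, cohort$tws_y,
                            zero_tol = zero_tol, digits = digits)
    cohort$coronal_class <- cls$coronal_class
    cohort$sagittal_class <- cls$sagittal_class
  }
  coronal_vars <- c("alpha_deg", "tsa_deg", "hfa_deg", "talocalcaneal_deg", "tt_deg")
  sagittal_vars <- c("beta_deg", "ttr_mm")

  run_comparisons <- function(vars, class_col, levels_wanted, plane) {
    purrr::map_dfr(intersect(vars, names(cohort)), function(var) {
      sub <- cohort[cohort[[class_col]] %in% levels_wanted, , drop = FALSE]
      counts <- table(factor(sub[[class_col]], levels = levels_wanted))
      if (any(counts < 2L)) {
        rlang::warn(sprintf("skipping %s comparison of %s: group with fewer than 2 patients",
                            plane, var))
        return(tibble::tibble())
      }
      sub[[class_col]] <- factor(sub[[class_col]], levels = levels_wanted)
      res <- compare_groups(sub, !!rlang::sym(var), !!rlang::sym(class_col))
      dplyr::bind_cols(tibble::tibble(variable = var, plane = plane), res)
    })
  }
  run_correlations <- function(vars, tws_col, plane) {
    purrr::map_dfr(intersect(vars, names(cohort)), function(var) {
      res <- correlate_pair(cohort, !!rlang::sym(tws_col), !!rlang::sym(var))
      dplyr::bind_cols(tibble::tibble(plane = plane), res)
    })
  }

  comparison_template <- tibble::tibble(
    variable = character(), plane = character(), group_1 = character(),
    group_2 = character(), n_1 = integer(), n_2 = integer(),
    normal = logical(), test = character(), statistic = numeric(),
    p.value = numeric(), summary_1 = character(), summary_2 = character()
  )
  comparisons <- dplyr::bind_rows(
    comparison_template,
    run_comparisons(coronal_vars, "coronal_class", c("valgus", "varus"), "coronal"),
    run_comparisons(sagittal_vars, "sagittal_class", c("anterior", "posterior"), "sagittal")
  )
  correlations <- dplyr::bind_rows(
    run_correlations(coronal_vars, "tws_x", "coronal"),
    run_correlations(sagittal_vars, "tws_y", "sagittal")
  )
  counts <- dplyr::count(
    tidyr::pivot_longer(cohort[, c("coronal_class", "sagittal_class")],
                        dplyr::everything(),
                        names_to = "plane", values_to = "class"),
    .data$plane, .data$class
  )
  structure(list(comparisons = comparisons, correlations = correlations,
                 counts = counts, n = nrow(cohort)),
            class = "bst_cohort_report")
}

#' @export
print.bst_cohort_report <- function(x, ...) {
  cat(sprintf("Cohort contact-pattern report (%d patients)\n", x$n))
  cat("\nGroup counts:\n")
  print(as.data.frame(x$counts), row.names = FALSE)
  cat("\nGroup comparisons:\n")
  print(as.data.frame(x$comparisons[, c("variable", "plane", "summary_1",
                                        "summary_2", "test", "p.value")]),
        row.names = FALSE)
  cat("\nCorrelations:\n")
  print(as.data.frame(x$correlations[, c("pair", "method", "estimate",
                                         "p.value", "significant")]),
        row.names = FALSE)
  invisible(x)
}

#' Tidy a cohort report
#'
#' @param x A [cohort_analysis()] result.
#' @param type `"comparisons"` (default), `"correlations"` or `"counts"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.bst_cohort_report <- function(x, type = c("comparisons", "correlations",
                                               "counts"), ...) {
  type <- match.arg(type)
  x[[type]]
}

#' One-row summary of a cohort report
#'
#' @param x A [cohort_analysis()] result.
#' @param ... Unused.
#' @return A one-row tibble with patient and test counts.
#' @export
glance.bst_cohort_report <- function(x, ...) {
  tibble::tibble(
    n_patients = x$n,
    n_comparisons = nrow(x$comparisons),
    n_correlations = nrow(x$correlations),
    n_significant_correlations = sum(x$correlations$significant)
  )
}
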