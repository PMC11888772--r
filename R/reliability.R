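#' Intra- and inter-rater reliability of weighted-sum ratings
#'
#' Computes the four agreement entries of a two-rater, two-reading design:
#' intra-rater agreement for each rater (their two readings as columns)
#' and inter-rater agreement for each reading (the raters as columns),
#' each as a single-measure two-way random absolute-agreement ICC via
#' [icc_2_1()], for each requested measure. With `pool = TRUE` a pooled
#' row per entry (the mean of the per-measure estimates) is appended,
#' since reliability is sometimes reported as one agreement number for
#' the weighted-sum point.
#'
#' @param ratings A data frame with columns `patient_id`, `rater_id`,
#'   `reading` and the measure columns (default `tws_x`, `tws_y`). Every
#'   patient must have every rater-by-reading cell.
#' @param measures Character vector of measure columns.
#' @param conf_level Confidence level for the ICC intervals.
#' @param pool Append pooled (mean across measures) rows.
#' @return A tibble with one row per measure, agreement type
#'   (`intra-rater` / `inter-rater`) and stratum (the rater or reading),
#'   holding the ICC `estimate`, its interval, the interpretation band and
#'   the design counts.
#' @export
reliability_report <- function(ratings, measures = c("tws_x", "tws_y"),
                               conf_level = 0.95, pool = FALSE) {
  needed <- c("patient_id", "rater_id", "reading", measures)
  missing_cols <- setdiff(needed, names(ratings))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf("ratings table lacks columns: %s",
                            paste(missing_cols, collapse = ", ")))
  }
  patients <- unique(ratings$patient_id)
  raters <- sort(unique(ratings$rater_id))
  readings <- sort(unique(ratings$reading))
  if (length(raters) < 2L || length(readings) < 2L) {
    stop_validation("ratings need at least two raters and two readings")
  }
  expected <- tidyr::expand_grid(patient_id = patients, rater_id = raters,
                                 reading = readings)
  have <- dplyr::distinct(ratings[, c("patient_id", "rater_id", "reading")])
  if (nrow(have) < nrow(ratings[, c("patient_id", "rater_id", "reading")])) {
    stop_validation("duplicate (patient, rater, reading) cells in ratings table")
  }
  miss <- dplyr::anti_join(expected, have,
                           by = c("patient_id", "rater_id", "reading"))
  if (nrow(miss) > 0L) {
    keys <- sprintf("patient %s / rater %s / reading %s",
                    miss$patient_id, miss$rater_id, miss$reading)
    stop_validation(paste0("incomplete ratings design; missing cells: ",
                           paste(head(keys, 5L), collapse = "; ")))
  }

  icc_of <- function(sub, measure, unit_col) {
    wide <- tidyr::pivot_wider(sub[, c("patient_id", unit_col, measure)],
                               names_from = dplyr::all_of(unit_col),
                               values_from = dplyr::all_of(measure))
    icc_2_1(as.matrix(wide[, -1, drop = FALSE]), conf_level = conf_level)
  }
  entries <- tidyr::expand_grid(
    measure = measures,
    dplyr::bind_rows(
      tibble::tibble(type = "intra-rater", stratum = paste("rater", raters),
                     unit = "reading", filter_col = "rater_id",
                     filter_val = as.character(raters)),
      tibble::tibble(type = "inter-rater", stratum = paste("reading", readings),
                     unit = "rater_id", filter_col = "reading",
                     filter_val = as.character(readings))
    )
  )
  out <- purrr::pmap_dfr(entries, function(measure, type, stratum, unit,
                                           filter_col, filter_val) {
    sub <- ratings[as.character(ratings[[filter_col]]) == filter_val, , drop = FALSE]
    fit <- icc_of(sub, measure, unit)
    dplyr::bind_cols(
      tibble::tibble(measure = measure, type = type, stratum = stratum),
      tidy(fit)
    )
  })
  if (pool) {
    pooled <- dplyr::summarise(
      dplyr::group_by(out, .data$type, .data$stratum),
      measure = "pooled",
      estimate = mean(.data$estimate),
      conf.low = mean(.data$conf.low),
      conf.high = mean(.data$conf.high),
      n_subjects = .data$n_subjects[1],
      n_raters = .data$n_raters[1],
      .groups = "drop"
    )
    pooled$interpretation <- interpret_icc(pooled$estimate)
    out <- dplyr::bind_rows(out, pooled[, names(out)])
  }
  out
}
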