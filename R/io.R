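# Tabular interchange formats. All CSV files are comma-separated UTF-8
# with "." decimals and a header row.

grid_value_cols <- function() {
  sq <- grid_square_centers()
  sprintf("d_r%dc%d", sq$row, sq$col)
}

grid_cyst_cols <- function() sub("^d_", "cyst_", grid_value_cols())

#' Convert a 16-square field table to one wide grid-table row
#'
#' @param field A [generate_grid_field()] tibble (row-major order).
#' @param patient_id,rater_id,reading,side Identifying columns of the row.
#' @return A one-row tibble in the grid CSV schema: `patient_id`,
#'   `rater_id`, `reading`, `side`, 16 mean-distance columns
#'   `d_r0c0..d_r3c3` (mm, rows posterior to anterior, columns medial to
#'   lateral) and 16 cyst flags `cyst_r0c0..cyst_r3c3` (0/1).
#' @export
grid_table_row <- function(field, patient_id = "P001", rater_id = 1L,
                           reading = 1L, side = "right") {
  vals <- as.list(field$mean_distance_mm)
  names(vals) <- grid_value_cols()
  cysts <- as.list(as.integer(field$cyst))
  names(cysts) <- grid_cyst_cols()
  tibble::tibble(patient_id = patient_id, rater_id = rater_id,
                 reading = reading, side = side,
                 !!!vals, !!!cysts)
}

#' Read / write a 16-square grid table
#'
#' The mesh-free input format: one row per patient-rater-reading with the
#' 32 per-square columns described in [grid_table_row()].
#'
#' @param path CSV path.
#' @return `read_grid_table()` returns the validated tibble.
#' @export
read_grid_table <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read grid table '%s': no such file", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("patient_id", "rater_id", "reading", "side",
              grid_value_cols(), grid_cyst_cols())
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf("grid table '%s' lacks columns: %s", path,
                            paste(head(missing_cols, 6L), collapse = ", ")))
  }
  df
}

#' @param data A grid table as returned by [read_grid_table()] or built
#'   from [grid_table_row()] rows.
#' @rdname read_grid_table
#' @export
write_grid_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Score every row of a grid table
#'
#' @param data A grid table (see [read_grid_table()]).
#' @param ... Passed to [bst_from_grid()].
#' @return A tibble with the identifying columns plus the
#'   [glance.bst_result()] summary of each row.
#' @export
score_grid_table <- function(data, ...) {
  purrr::map_dfr(seq_len(nrow(data)), function(i) {
    row <- data[i, ]
    res <- bst_from_grid(as.numeric(row[1, grid_value_cols()]),
                         cyst = as.logical(as.numeric(row[1, grid_cyst_cols()])),
                         side = row$side, ...)
    dplyr::bind_cols(row[, c("patient_id", "rater_id", "reading")], glance(res))
  })
}

#' Read / write a ratings table
#'
#' Schema: `patient_id`, `rater_id`, `reading`, `tws_x`, `tws_y`.
#'
#' @param path CSV path.
#' @return `read_ratings()` returns the validated tibble.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read ratings '%s': no such file", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("patient_id", "rater_id", "reading", "tws_x", "tws_y")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf("ratings table '%s' lacks columns: %s", path,
                            paste(missing_cols, collapse = ", ")))
  }
  df
}

#' @param data A ratings tibble.
#' @rdname read_ratings
#' @export
write_ratings <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read / write a cohort table
#'
#' Schema: `patient_id`, `tws_x`, `tws_y` plus any of the alignment
#' columns `alpha_deg`, `tsa_deg`, `hfa_deg`, `talocalcaneal_deg`,
#' `tt_deg`, `beta_deg`, `ttr_mm` (angles are consumed as inputs; their
#' computation from images is out of scope).
#'
#' @param path CSV path.
#' @return `read_cohort()` returns the validated tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cannot read cohort '%s': no such file", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) stop_validation(sprintf("cohort table '%s' is empty", path))
  needed <- c("patient_id", "tws_x", "tws_y")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop_validation(sprintf("cohort table '%s' lacks columns: %s", path,
                            paste(missing_cols, collapse = ", ")))
  }
  df
}

#' @param data A cohort tibble.
#' @rdname read_cohort
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Export a Battleship-technique result as JSON or CSV
#'
#' @param result A `bst_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bst_json <- function(result, path) {
  stopifnot(inherits(result, "bst_result"))
  payload <- list(
    tws_x = result$tws_x, tws_y = result$tws_y,
    coronal_class = result$coronal_class,
    sagittal_class = result$sagittal_class,
    side = result$side,
    squares = result$squares[, c("row", "col", "quadrant", "cx", "cy",
                                 "cyst_fraction", "mean_distance",
                                 "flag_empty", "dmc", "wsq_x", "wsq_y")]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_bst_json
#' @export
write_bst_csv <- function(result, path) {
  stopifnot(inherits(result, "bst_result"))
  readr::write_csv(dplyr::bind_cols(glance(result)[rep(1, 16), ],
                                    tidy(result)),
                   path, progress = FALSE)
  invisible(path)
}

#' Export a cohort report as JSON or Markdown
#'
#' @param report A [cohort_analysis()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "bst_cohort_report"))
  jsonlite::write_json(
    list(n_patients = report$n, counts = report$counts,
         comparisons = report$comparisons, correlations = report$correlations),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

md_table <- function(df) {
  fmt <- function(x) {
    if (is.numeric(x)) sprintf("%.4g", x) else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, rule, rows)
}

#' @rdname write_report_json
#' @export
write_report_md <- function(report, path) {
  stopifnot(inherits(report, "bst_cohort_report"))
  lines <- c(
    sprintf("# Cohort contact-pattern report (%d patients)", report$n),
    "", "## Group counts", "", md_table(report$counts),
    "", "## Group comparisons", "",
    md_table(report$comparisons[, c("variable", "plane", "summary_1",
                                    "summary_2", "test", "p.value")]),
    "", "## Correlations", "",
    md_table(report$correlations[, c("pair", "method", "estimate",
                                     "p.value", "significant")])
  )
  writeLines(lines, path)
  invisible(path)
}
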