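#' Find the anatomical centre of a projected talar dome
#'
#' The anatomical centre is the intersection of the mediolateral and
#' anteroposterior mid-extents of the articular surface: the midpoint of
#' the min/max x extent and of the min/max y extent over all non-excluded
#' samples (extra-articular osteophytes are excluded by flag upstream).
#'
#' @param pm A [project_axial()] result.
#' @return Named numeric vector `c(x = , y = )` in mm.
#' @export
find_anatomical_center <- function(pm) {
  keep <- pm$flag != "excluded"
  if (!any(keep)) stop_validation("projected map has no non-excluded samples")
  x <- pm$x[keep]
  y <- pm$y[keep]
  c(x = (min(x) + max(x)) / 2, y = (min(y) + max(y)) / 2)
}

#' Build the 16-square dome grid
#'
#' Draws the bounding rectangle of the non-excluded samples, places the
#' x/y axes through the anatomical centre, and splits the rectangle into a
#' 4x4 grid of equal squares. Each square carries its centre in normalized
#' rectangle units (the rectangle mapped to \[-0.5, +0.5\] in each
#' direction), so centres lie at ±0.125 and ±0.375, and a quadrant label
#' (AL, AM, PL, PM) determined by the side of the axes on which the square
#' centre falls.
#'
#' @param pm A [project_axial()] result.
#' @param center Optional anatomical centre `c(x, y)` in mm; defaults to
#'   [find_anatomical_center()]. The squares remain equal subdivisions of
#'   the bounding rectangle; the centre only moves the axes used for
#'   quadrant labels.
#' @return An object of class `bst_dome_grid`: a list with `center`,
#'   `xlim`, `ylim`, `half_width_x`, `half_width_y` and a 16-row `squares`
#'   tibble (`row` 0-3 posterior to anterior, `col` 0-3 medial to lateral,
#'   `quadrant`, normalized centres `cx`, `cy`, and mm bounds).
#' @export
build_grid <- function(pm, center = NULL) {
  keep <- pm$flag != "excluded"
  if (!any(keep)) stop_validation("projected map has no non-excluded samples")
  xlim <- range(pm$x[keep])
  ylim <- range(pm$y[keep])
  if (diff(xlim) <= 0 || diff(ylim) <= 0) {
    stop_validation("bounding rectangle of the projected map has zero area")
  }
  if (is.null(center)) {
    center <- find_anatomical_center(pm)
  } else {
    center <- c(x = as.numeric(center[1]), y = as.numeric(center[2]))
    if (center["x"] < xlim[1] || center["x"] > xlim[2] ||
        center["y"] < ylim[1] || center["y"] > ylim[2]) {
      stop_validation("`center` must lie inside the sample extents")
    }
  }
  wx <- diff(xlim)
  wy <- diff(ylim)
  squares <- tidyr::expand_grid(row = 0:3, col = 0:3)
  squares <- dplyr::mutate(
    squares,
    cx = -0.375 + 0.25 * .data$col,
    cy = -0.375 + 0.25 * .data$row,
    xmin = xlim[1] + .data$col * wx / 4,
    xmax = xlim[1] + (.data$col + 1) * wx / 4,
    ymin = ylim[1] + .data$row * wy / 4,
    ymax = ylim[1] + (.data$row + 1) * wy / 4,
    quadrant = paste0(
      ifelse((.data$ymin + .data$ymax) / 2 > center["y"], "A", "P"),
      ifelse((.data$xmin + .data$xmax) / 2 > center["x"], "L", "M")
    )
  )
  structure(
    list(center = center, xlim = xlim, ylim = ylim,
         half_width_x = wx / 2, half_width_y = wy / 2,
         squares = squares),
    class = "bst_dome_grid"
  )
}

#' @export
print.bst_dome_grid <- function(x, ...) {
  cat(sprintf(
    "<bst_dome_grid: centre (%.2f, %.2f) mm, rectangle %.1f x %.1f mm, 16 squares>\n",
    x$center["x"], x$center["y"], 2 * x$half_width_x, 2 * x$half_width_y))
  invisible(x)
}

#' Per-square sample statistics of a projected distance map
#'
#' Assigns every non-excluded sample to exactly one grid square by its
#' (x, y) position (half-open square bounds; the last row and column are
#' closed so boundary samples on the rectangle edge are kept). Cyst
#' samples contribute a distance of 0 mm to the square mean -- a fully
#' cystic square therefore reaches the maximum distance-mapping
#' coefficient of 1 -- and are tallied in `cyst_fraction`. Squares with no
#' samples are flagged empty rather than failing.
#'
#' @param pm A [project_axial()] result.
#' @param grid A [build_grid()] result in the same coordinate frame.
#' @return A 16-row tibble with `row`, `col`, `quadrant`, `cx`, `cy`,
#'   `n_samples`, `cyst_fraction`, `mean_distance`, `flag_empty`.
#' @export
square_stats <- function(pm, grid) {
  stopifnot(inherits(grid, "bst_dome_grid"))
  keep <- pm$flag %in% c("valid", "cyst")
  x <- pm$x[keep]
  y <- pm$y[keep]
  wx <- 2 * grid$half_width_x
  wy <- 2 * grid$half_width_y
  col <- pmax(pmin(floor((x - grid$xlim[1]) / wx * 4), 3L), 0L)
  row <- pmax(pmin(floor((y - grid$ylim[1]) / wy * 4), 3L), 0L)
  d <- ifelse(pm$flag[keep] == "cyst", 0, pm$distance[keep])
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(row = as.integer(row), col = as.integer(col),
                                   d = d, cyst = pm$flag[keep] == "cyst"),
                    .data$row, .data$col),
    n_samples = dplyr::n(),
    cyst_fraction = mean(.data$cyst),
    mean_distance = mean(.data$d),
    .groups = "drop"
  )
  out <- dplyr::left_join(grid$squares[, c("row", "col", "quadrant", "cx", "cy")],
                          agg, by = c("row", "col"))
  dplyr::mutate(
    out,
    n_samples = dplyr::coalesce(.data$n_samples, 0L),
    cyst_fraction = dplyr::coalesce(.data$cyst_fraction, 0),
    flag_empty = .data$n_samples == 0L
  )
}
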