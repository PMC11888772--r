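#' Distance-mapping coefficient of a grid square
#'
#' The distance-mapping coefficient (DMC) is one minus the square's mean
#' intraarticular distance in millimetres. Cyst samples have already
#' contributed a distance of 0 mm to the mean, so a fully cystic square
#' reaches exactly 1, the maximum possible DMC. The formula extends below
#' zero for squares whose mean distance exceeds 1 mm. Empty squares yield
#' `NA` and carry zero weight downstream.
#'
#' @param mean_distance Mean intraarticular distance per square (mm).
#' @param cyst_fraction Fraction of the square's samples that are cystic.
#' @param flag_empty Logical; `TRUE` for squares without samples.
#' @return Numeric DMC values (dimensionless, always <= 1).
#' @examples
#' compute_dmc(0.3)                    # 0.7
#' compute_dmc(0, cyst_fraction = 1)   # fully cystic square: 1
#' compute_dmc(2.5)                    # -1.5
#' @export
compute_dmc <- function(mean_distance, cyst_fraction = 0, flag_empty = FALSE) {
  n <- max(length(mean_distance), length(cyst_fraction), length(flag_empty))
  mean_distance <- rep_len(mean_distance, n)
  flag_empty <- rep_len(flag_empty, n)
  if (any(!flag_empty & !is.na(mean_distance) & mean_distance < 0)) {
    stop_validation("mean distances must be non-negative")
  }
  dmc <- 1 - mean_distance
  dmc[flag_empty] <- NA_real_
  dmc
}

#' Total weighted sums over the 16-square grid
#'
#' Each square's weighted sums are its DMC multiplied by its normalized
#' centre coordinates, `wsq_x = dmc * cx` and `wsq_y = dmc * cy`. The total
#' weighted sums divide the column sums by the fixed total of 16 squares;
#' empty squares contribute zero but do not shrink the divisor.
#'
#' @param stats A 16-row data frame with columns `dmc`, `cx`, `cy` and
#'   optionally `flag_empty`.
#' @return A one-row tibble with `tws_x` and `tws_y`.
#' @export
compute_weighted_sums <- function(stats) {
  if (nrow(stats) != 16L) {
    stop_validation("`stats` must describe exactly 16 grid squares")
  }
  empty <- if ("flag_empty" %in% names(stats)) stats$flag_empty else is.na(stats$dmc)
  wx <- ifelse(empty | is.na(stats$dmc), 0, stats$dmc * stats$cx)
  wy <- ifelse(empty | is.na(stats$dmc), 0, stats$dmc * stats$cy)
  tibble::tibble(tws_x = sum(wx) / 16, tws_y = sum(wy) / 16)
}

#' Classify the contact pattern from the weighted-sum point
#'
#' With +x lateral and +y anterior, a weighted-sum point on the medial side
#' (TWSx < 0, the AM/PM quadrants) marks a varus contact pattern and a
#' lateral point (TWSx > 0, AL/PL) a valgus pattern; an anterior point
#' (TWSy > 0, AM/AL) marks anterior contact and a posterior point (TWSy <
#' 0) posterior contact. Values are rounded to `digits` decimals first and
#' a value of exactly zero (within `zero_tol`) is neutral.
#'
#' @param tws_x,tws_y Total weighted sums (dimensionless).
#' @param zero_tol Non-negative half-width of the neutral band (default 0,
#'   applied after rounding).
#' @param digits Decimals to round to before classification (default 3).
#' @return A tibble with `coronal_class` (`varus`/`valgus`/`neutral`) and
#'   `sagittal_class` (`anterior`/`posterior`/`neutral`).
#' @examples
#' classify_contact(-0.10, 0.05)  # varus, anterior
#' classify_contact(0, 0)         # neutral, neutral
#' @export
classify_contact <- function(tws_x, tws_y, zero_tol = 0, digits = 3) {
  if (zero_tol < 0) stop_validation("`zero_tol` must be non-negative")
  rx <- round(tws_x, digits)
  ry <- round(tws_y, digits)
  tibble::tibble(
    coronal_class = dplyr::case_when(
      rx < -zero_tol ~ "varus",
      rx > zero_tol ~ "valgus",
      .default = "neutral"
    ),
    sagittal_class = dplyr::case_when(
      ry > zero_tol ~ "anterior",
      ry < -zero_tol ~ "posterior",
      .default = "neutral"
    )
  )
}

new_bst_result <- function(tws_x, tws_y, coronal_class, sagittal_class,
                           side, squares, zero_tol, digits) {
  structure(
    list(tws_x = tws_x, tws_y = tws_y,
         coronal_class = coronal_class, sagittal_class = sagittal_class,
         side = side, squares = squares,
         zero_tol = zero_tol, digits = digits),
    class = "bst_result"
  )
}

# canonical 16-square reference grid in row-major order
# (rows posterior -> anterior, columns medial -> lateral)
grid_square_centers <- function() {
  squares <- tidyr::expand_grid(row = 0:3, col = 0:3)
  dplyr::mutate(
    squares,
    cx = -0.375 + 0.25 * .data$col,
    cy = -0.375 + 0.25 * .data$row,
    quadrant = paste0(ifelse(.data$cy > 0, "A", "P"),
                      ifelse(.data$cx > 0, "L", "M"))
  )
}

#' Battleship-technique score from a 16-square distance table
#'
#' Mesh-free entry point: scores a table of per-square mean intraarticular
#' distances (mm) and cyst flags, in row-major order with rows running
#' posterior to anterior and columns medial to lateral. The column order is
#' anatomical for both feet, so a left foot with the same
#' medial-to-lateral distance pattern scores identically to a right foot
#' (`columns = "image"` instead mirrors the columns of left feet whose
#' table was recorded in the unmirrored image frame).
#'
#' @param data Either a numeric vector of 16 mean distances (mm) or a data
#'   frame with columns `mean_distance_mm` and `cyst` (e.g. from
#'   [generate_grid_field()]), in row-major order.
#' @param cyst Logical vector of 16 cyst flags when `data` is a vector.
#' @param side `"right"` or `"left"`.
#' @param columns `"anatomical"` (default: columns are medial to lateral
#'   for both sides) or `"image"` (left-foot columns are mirrored first).
#' @param zero_tol,digits Passed to [classify_contact()].
#' @return A `bst_result`: see [glance.bst_result()] and
#'   [tidy.bst_result()].
#' @examples
#' # closer medial contact on a right foot: varus pattern
#' d <- rep(c(0.2, 0.2, 0.8, 0.8), 4)
#' bst_from_grid(d)
#' @export
bst_from_grid <- function(data, cyst = NULL, side = c("right", "left"),
                          columns = c("anatomical", "image"),
                          zero_tol = 0, digits = 3) {
  side <- match.arg(side)
  columns <- match.arg(columns)
  if (is.data.frame(data)) {
    if (!"mean_distance_mm" %in% names(data)) {
      stop_validation("`data` must have a `mean_distance_mm` column")
    }
    mean_distance <- as.numeric(data$mean_distance_mm)
    cyst <- if ("cyst" %in% names(data)) as.logical(data$cyst) else NULL
  } else {
    mean_distance <- as.numeric(data)
  }
  if (is.null(cyst)) cyst <- rep(FALSE, length(mean_distance))
  if (length(mean_distance) != 16L || length(cyst) != 16L) {
    stop_validation("grid tables must have exactly 16 squares")
  }
  if (anyNA(mean_distance[!cyst]) || any(mean_distance[!cyst] < 0)) {
    stop_validation("mean distances must be non-negative and non-missing")
  }
  if (columns == "image" && side == "left") {
    # reverse the columns within each row-major row
    mirror <- rep(seq(0L, 12L, by = 4L), each = 4L) + rep(4:1, 4)
    mean_distance <- mean_distance[mirror]
    cyst <- cyst[mirror]
  }
  stats <- grid_square_centers()
  stats$n_samples <- NA_integer_
  stats$cyst_fraction <- as.numeric(cyst)
  stats$mean_distance <- ifelse(cyst, 0, mean_distance)
  stats$flag_empty <- FALSE
  score_square_stats(stats, side = side, zero_tol = zero_tol, digits = digits)
}

score_square_stats <- function(stats, side, zero_tol, digits) {
  stats$dmc <- compute_dmc(stats$mean_distance, stats$cyst_fraction, stats$flag_empty)
  stats$wsq_x <- ifelse(stats$flag_empty, 0, stats$dmc * stats$cx)
  stats$wsq_y <- ifelse(stats$flag_empty, 0, stats$dmc * stats$cy)
  tws <- compute_weighted_sums(stats)
  cls <- classify_contact(tws$tws_x, tws$tws_y, zero_tol = zero_tol, digits = digits)
  new_bst_result(tws$tws_x, tws$tws_y, cls$coronal_class, cls$sagittal_class,
                 side, stats, zero_tol, digits)
}

#' Battleship-technique score from a projected distance map
#'
#' Builds the 16-square grid on the projected talar dome, computes per-
#' square statistics and distance-mapping coefficients, and reduces them
#' to the distance-map weighted-sum point and its classification.
#'
#' @param pm A [project_axial()] result.
#' @param center Optional anatomical centre, see [build_grid()].
#' @param side Foot side; defaults to the side recorded on `pm`.
#' @param zero_tol,digits Passed to [classify_contact()].
#' @return A `bst_result`.
#' @export
bst_score <- function(pm, center = NULL, side = NULL, zero_tol = 0, digits = 3) {
  side <- side %||% attr(pm, "side") %||% "right"
  grid <- build_grid(pm, center = center)
  stats <- square_stats(pm, grid)
  res <- score_square_stats(stats, side = side, zero_tol = zero_tol, digits = digits)
  res$grid <- grid
  res
}

#' Battleship-technique score straight from bone surface meshes
#'
#' Convenience pipeline composing [compute_distance_map()],
#' [project_axial()] and [bst_score()].
#'
#' @param talus,tibia [surface_mesh()] objects (talar dome, tibial
#'   plafond).
#' @param side `"right"` or `"left"`.
#' @param axis,ap_direction Projection frame, see [project_axial()].
#' @param subdivide Midpoint-subdivision rounds for the talar mesh.
#' @param zero_tol,digits Passed to [classify_contact()].
#' @return A `bst_result`.
#' @export
bst_from_meshes <- function(talus, tibia, side = c("right", "left"),
                            axis = c(0, 0, 1), ap_direction = c(0, 1, 0),
                            subdivide = 0L, zero_tol = 0, digits = 3) {
  side <- match.arg(side)
  dm <- compute_distance_map(talus, tibia, subdivide = subdivide)
  pm <- project_axial(dm, axis = axis, ap_direction = ap_direction, side = side)
  bst_score(pm, zero_tol = zero_tol, digits = digits)
}

#' @export
print.bst_result <- function(x, ...) {
  cat("Battleship-technique distance-map weighted sum\n")
  cat(sprintf("  side: %s\n", x$side))
  cat(sprintf("  TWSx: %+.5f  ->  %s\n", x$tws_x, x$coronal_class))
  cat(sprintf("  TWSy: %+.5f  ->  %s\n", x$tws_y, x$sagittal_class))
  n_cyst <- sum(x$squares$cyst_fraction > 0)
  n_empty <- sum(x$squares$flag_empty)
  if (n_cyst > 0) cat(sprintf("  squares with cyst samples: %d\n", n_cyst))
  if (n_empty > 0) cat(sprintf("  empty squares: %d\n", n_empty))
  invisible(x)
}

#' Tidy the per-square table of a Battleship-technique result
#'
#' @param x A `bst_result`.
#' @param ... Unused.
#' @return A 16-row tibble with square positions, quadrant labels, mean
#'   distances, DMC and per-square weighted sums.
#' @export
tidy.bst_result <- function(x, ...) {
  tibble::as_tibble(x$squares)
}

#' One-row summary of a Battleship-technique result
#'
#' @param x A `bst_result`.
#' @param ... Unused.
#' @return A one-row tibble with `tws_x`, `tws_y`, the coronal and
#'   sagittal classes, the side and bookkeeping counts.
#' @export
glance.bst_result <- function(x, ...) {
  tibble::tibble(
    tws_x = x$tws_x, tws_y = x$tws_y,
    coronal_class = x$coronal_class, sagittal_class = x$sagittal_class,
    side = x$side,
    n_cyst_squares = sum(x$squares$cyst_fraction >= 1),
    n_empty_squares = sum(x$squares$flag_empty)
  )
}
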