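#' Compute the inter-surface distance map of an articular surface
#'
#' For every articular vertex of `source` (the talar dome) the minimum
#' Euclidean distance to the `target` surface (the tibial plafond) is
#' computed as the nearest point on any target triangle, not merely the
#' nearest target vertex. Vertices labelled `cyst` are carried through with
#' flag `"cyst"` and no distance (downstream scoring assigns them the
#' maximum distance-mapping coefficient); vertices labelled `osteophyte`
#' are flagged `"excluded"` and take no part in any later step.
#'
#' @param source Talar-dome [surface_mesh()]; its vertices are the sampling
#'   points of the map.
#' @param target Tibial-plafond [surface_mesh()].
#' @param subdivide Number of midpoint-subdivision rounds applied to
#'   `source` before sampling (default 0; use for very coarse meshes).
#' @return A tibble of class `bst_distance_map` with columns `x`, `y`, `z`
#'   (mm, sample position on the source surface), `distance` (mm, `NA` for
#'   cyst/excluded samples) and `flag` (`"valid"`, `"cyst"`, `"excluded"`).
#' @examples
#' talus <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
#'                       rbind(c(1, 2, 3), c(1, 3, 4)))
#' tibia <- surface_mesh(rbind(c(0, 0, 2), c(1, 0, 2), c(1, 1, 2), c(0, 1, 2)),
#'                       rbind(c(1, 2, 3), c(1, 3, 4)))
#' compute_distance_map(talus, tibia)  # every distance is 2 mm
#' @export
compute_distance_map <- function(source, target, subdivide = 0L) {
  if (!inherits(source, "bst_surface_mesh") || !inherits(target, "bst_surface_mesh")) {
    stop_validation("`source` and `target` must be surface meshes")
  }
  if (nrow(target$faces) < 1L) {
    stop_validation("target mesh has no faces")
  }
  if (subdivide > 0L) source <- subdivide_mesh(source, subdivide)
  flag <- c(articular = "valid", cyst = "cyst", osteophyte = "excluded")[source$labels]
  distance <- rep(NA_real_, nrow(source$vertices))
  valid <- flag == "valid"
  distance[valid] <- cpp_point_mesh_distance(
    source$vertices[valid, , drop = FALSE],
    target$vertices,
    target$faces - 1L
  )
  if (!any(flag %in% c("valid", "cyst"))) {
    stop_validation("distance map has no valid or cyst samples")
  }
  dm <- tibble::tibble(
    x = source$vertices[, 1],
    y = source$vertices[, 2],
    z = source$vertices[, 3],
    distance = distance,
    flag = unname(flag)
  )
  class(dm) <- c("bst_distance_map", class(dm))
  dm
}

#' Project a distance map onto the axial plane
#'
#' Projects every non-excluded sample onto the plane normal to `axis`,
#' expressed in an in-plane frame with +y along the anteroposterior
#' direction and +x completing a right-handed frame. Left-side maps are
#' mirrored so that +x is always the lateral direction; all downstream
#' grid scoring and varus/valgus rules assume this anatomical frame.
#' Distances and flags are carried through unchanged.
#'
#' @param dm A [compute_distance_map()] result (any data frame with columns
#'   `x`, `y`, `z`, `distance`, `flag` works).
#' @param axis Projection axis (superior direction), default the world z
#'   axis used by the synthetic generator.
#' @param ap_direction Anterior direction, non-parallel to `axis`.
#' @param side `"right"` or `"left"` foot.
#' @return A tibble of class `bst_projected_map` with columns `x` (mm,
#'   + = lateral), `y` (mm, + = anterior), `distance`, `flag`, and
#'   attributes `side` and `axis`.
#' @export
project_axial <- function(dm, axis = c(0, 0, 1), ap_direction = c(0, 1, 0),
                          side = c("right", "left")) {
  side <- match.arg(side)
  axis <- unit_vector(axis, "`axis`")
  ap <- unit_vector(ap_direction, "`ap_direction`")
  if (sqrt(sum(cross3(axis, ap)^2)) < 1e-8) {
    stop_validation("`axis` and `ap_direction` must not be parallel")
  }
  # Gram-Schmidt: +y along the anterior direction within the plane,
  # +x = y x axis so that (x, y, axis) is right-handed
  yhat <- ap - sum(ap * axis) * axis
  yhat <- yhat / sqrt(sum(yhat^2))
  xhat <- cross3(yhat, axis)
  keep <- dm$flag != "excluded"
  p <- cbind(dm$x, dm$y, dm$z)[keep, , drop = FALSE]
  px <- as.numeric(p %*% xhat)
  py <- as.numeric(p %*% yhat)
  if (side == "left") px <- -px
  pm <- tibble::tibble(x = px, y = py,
                       distance = dm$distance[keep],
                       flag = dm$flag[keep])
  attr(pm, "side") <- side
  attr(pm, "axis") <- axis
  class(pm) <- c("bst_projected_map", class(pm))
  pm
}

#' Export a distance map to CSV
#'
#' @param dm A [compute_distance_map()] result.
#' @param path Output CSV path (columns `x_mm`, `y_mm`, `z_mm`,
#'   `distance_mm`, `flag`).
#' @return `path`, invisibly.
#' @export
write_distance_map_csv <- function(dm, path) {
  readr::write_csv(
    tibble::tibble(x_mm = dm$x, y_mm = dm$y, z_mm = dm$z,
                   distance_mm = dm$distance, flag = dm$flag),
    path, progress = FALSE
  )
  invisible(path)
}
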