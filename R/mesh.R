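#' Construct a triangulated articular surface mesh
#'
#' A `bst_surface_mesh` holds a triangulated bone surface (talar dome or
#' tibial plafond) as a vertex matrix in millimetres, a 1-based triangle
#' index matrix, and a per-vertex region label. Labels mark which vertices
#' take part in distance-map scoring: `articular` vertices are measured,
#' `cyst` vertices mark subchondral cyst holes (scored at the maximum
#' distance-mapping coefficient downstream), and `osteophyte` vertices are
#' extra-articular outgrowths excluded from the analysis.
#'
#' @param vertices Numeric matrix or data frame with three columns (x, y, z
#'   in mm), one row per vertex.
#' @param faces Integer matrix with three columns of 1-based vertex indices,
#'   one row per triangle.
#' @param labels Optional character vector, one per vertex, with values in
#'   `"articular"`, `"osteophyte"`, `"cyst"`. Defaults to all-articular.
#' @return An object of class `bst_surface_mesh`: a list with elements
#'   `vertices`, `faces`, `labels`.
#' @examples
#' # unit square as two triangles
#' m <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
#'                   rbind(c(1, 2, 3), c(1, 3, 4)))
#' m
#' @export
surface_mesh <- function(vertices, faces, labels = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L || nrow(vertices) < 3L) {
    stop_validation("`vertices` must be an n x 3 matrix with n >= 3")
  }
  if (any(!is.finite(vertices))) {
    stop_validation("mesh vertex coordinates must be finite")
  }
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L || nrow(faces) < 1L) {
    stop_validation("`faces` must be an m x 3 index matrix with at least one triangle")
  }
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    stop_validation("face indices must reference existing vertices")
  }
  if (is.null(labels)) {
    labels <- rep("articular", nrow(vertices))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(vertices)) {
    stop_validation("`labels` must have one entry per vertex")
  }
  bad <- setdiff(unique(labels), c("articular", "osteophyte", "cyst"))
  if (length(bad) > 0L) {
    stop_validation(sprintf("unknown vertex labels: %s", paste(bad, collapse = ", ")))
  }
  if (!any(labels == "articular")) {
    stop_validation("mesh must contain at least one articular vertex")
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces, labels = labels),
            class = "bst_surface_mesh")
}

#' @export
print.bst_surface_mesh <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<bst_surface_mesh: %d vertices, %d faces (%s)>\n",
              nrow(x$vertices), nrow(x$faces),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read a triangulated surface mesh from PLY, STL or OBJ
#'
#' Reads ASCII PLY, STL or OBJ files. If a sidecar label file
#' `<path>.labels.csv` exists (columns `vertex_index` (1-based), `label`),
#' or one is supplied via `labels_path`, per-vertex region labels are
#' attached; otherwise all vertices are labelled `articular`.
#'
#' @param path Path to the mesh file.
#' @param format One of `"auto"` (from the file extension), `"ply"`,
#'   `"stl"`, `"obj"`.
#' @param labels_path Optional path to a label CSV.
#' @return A [surface_mesh()].
#' @export
read_surface <- function(path, format = c("auto", "ply", "stl", "obj"),
                         labels_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_io(sprintf("cannot read mesh file '%s': no such file", path))
  }
  if (format == "auto") {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("ply", "stl", "obj")) {
      stop_validation(sprintf("cannot infer mesh format from '%s'", path))
    }
  }
  parsed <- switch(format,
    ply = parse_ply(path),
    stl = parse_stl(path),
    obj = parse_obj(path)
  )
  labels <- NULL
  if (is.null(labels_path)) {
    candidate <- paste0(path, ".labels.csv")
    if (file.exists(candidate)) labels_path <- candidate
  }
  if (!is.null(labels_path)) {
    labels <- read_surface_labels(labels_path, n_vertices = nrow(parsed$vertices))
  }
  surface_mesh(parsed$vertices, parsed$faces, labels = labels)
}

read_surface_labels <- function(path, n_vertices) {
  if (!file.exists(path)) {
    stop_io(sprintf("cannot read label file '%s': no such file", path))
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("vertex_index", "label") %in% names(df))) {
    stop_validation(sprintf("label file '%s' must have columns vertex_index,label", path))
  }
  idx <- as.integer(df$vertex_index)
  if (any(idx < 1L) || any(idx > n_vertices)) {
    stop_validation(sprintf("label file '%s' references vertices outside 1..%d",
                            path, n_vertices))
  }
  labels <- rep("articular", n_vertices)
  labels[idx] <- as.character(df$label)
  labels
}

parse_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply") {
    stop_validation(sprintf("'%s' is not an ASCII PLY file", path))
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop_validation(sprintf("'%s': missing end_header", path))
  header <- trimws(lines[seq_len(end)])
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", header, value = TRUE)[1]))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", header, value = TRUE)[1]))
  if (is.na(nv) || nv < 1L) stop_validation(sprintf("'%s': no vertex element", path))
  if (is.na(nf)) nf <- 0L
  if (nf < 1L) stop_validation(sprintf("'%s': mesh has no faces", path))
  body <- lines[(end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop_validation(sprintf("'%s': truncated PLY body", path))
  vt <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"), function(p) {
    as.numeric(p[1:3])
  }))
  ft <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"), function(p) {
    p <- as.integer(p)
    if (p[1] != 3L) stop_validation(sprintf("'%s': only triangular faces are supported", path))
    p[2:4] + 1L
  }))
  list(vertices = vt, faces = ft)
}

parse_stl <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vlines <- grep("^vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L) {
    stop_validation(sprintf("'%s' is not a valid ASCII STL file", path))
  }
  coords <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(p) as.numeric(p[2:4])))
  # weld coincident corners back into shared vertices
  key <- apply(round(coords, 9), 1L, paste, collapse = ",")
  uniq <- !duplicated(key)
  vid <- match(key, key[uniq])
  vertices <- coords[uniq, , drop = FALSE]
  faces <- matrix(vid, ncol = 3L, byrow = TRUE)
  list(vertices = vertices, faces = faces)
}

parse_obj <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vlines <- grep("^v\\s", lines, value = TRUE)
  flines <- grep("^f\\s", lines, value = TRUE)
  if (length(vlines) == 0L) stop_validation(sprintf("'%s': no vertices", path))
  if (length(flines) == 0L) stop_validation(sprintf("'%s': mesh has no faces", path))
  vertices <- do.call(rbind, lapply(strsplit(vlines, "\\s+"), function(p) as.numeric(p[2:4])))
  faces <- do.call(rbind, lapply(strsplit(flines, "\\s+"), function(p) {
    idx <- vapply(p[-1], function(tok) as.integer(strsplit(tok, "/")[[1]][1]), integer(1))
    if (length(idx) != 3L) stop_validation(sprintf("'%s': only triangular faces are supported", path))
    unname(idx)
  }))
  list(vertices = vertices, faces = faces)
}

#' Write a surface mesh as ASCII PLY (with optional label sidecar)
#'
#' Non-articular vertex labels, if any, are written to the sidecar file
#' `<path>.labels.csv` so that [read_surface()] round-trips them.
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path (`.ply`).
#' @return `path`, invisibly.
#' @export
write_surface_ply <- function(mesh, path) {
  stopifnot(inherits(mesh, "bst_surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d",
                     mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  if (any(mesh$labels != "articular")) {
    idx <- which(mesh$labels != "articular")
    readr::write_csv(tibble::tibble(vertex_index = idx, label = mesh$labels[idx]),
                     paste0(path, ".labels.csv"), progress = FALSE)
  }
  invisible(path)
}

#' Midpoint-subdivide a surface mesh
#'
#' Splits every triangle into four by inserting edge midpoints. Useful to
#' densify a coarse articular surface before distance-map sampling. Midpoint
#' labels are inherited when both edge endpoints agree, else `articular`.
#'
#' @param mesh A [surface_mesh()].
#' @param times Number of subdivision rounds (each quadruples the face count).
#' @return A [surface_mesh()].
#' @export
subdivide_mesh <- function(mesh, times = 1L) {
  stopifnot(inherits(mesh, "bst_surface_mesh"))
  times <- as.integer(times)
  for (round in seq_len(times)) {
    v <- mesh$vertices
    f <- mesh$faces
    lab <- mesh$labels
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    edges <- t(apply(edges, 1L, sort))
    key <- paste(edges[, 1], edges[, 2], sep = "-")
    uniq <- !duplicated(key)
    eu <- edges[uniq, , drop = FALSE]
    mid_id <- nrow(v) + match(key, key[uniq])
    mids <- (v[eu[, 1], , drop = FALSE] + v[eu[, 2], , drop = FALSE]) / 2
    mid_lab <- ifelse(lab[eu[, 1]] == lab[eu[, 2]], lab[eu[, 1]], "articular")
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m13 <- mid_id[2L * nf + seq_len(nf)]
    newf <- rbind(cbind(f[, 1], m12, m13),
                  cbind(m12, f[, 2], m23),
                  cbind(m13, m23, f[, 3]),
                  cbind(m12, m23, m13))
    mesh <- surface_mesh(rbind(v, mids), newf, labels = c(lab, mid_lab))
  }
  mesh
}
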