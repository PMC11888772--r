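# Independent oracles and fixture builders, deliberately implemented with
# different algorithms than the package code they check.

# Closest distance from point p to triangle (a, b, c) via the candidate-set
# method: the in-plane projection (if its barycentric coordinates are
# admissible), the clamped projections onto the three edges, and the three
# vertices. Different route than the Voronoi-region walk in the package.
oracle_point_tri_dist <- function(p, a, b, c) {
  cands <- list(a, b, c)
  e1 <- b - a
  e2 <- c - a
  nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
  n2 <- sum(nrm^2)
  if (n2 > 1e-20) {
    q <- p - sum((p - a) * nrm) / n2 * nrm
    g <- rbind(c(sum(e1 * e1), sum(e1 * e2)), c(sum(e1 * e2), sum(e2 * e2)))
    st <- solve(g, c(sum((q - a) * e1), sum((q - a) * e2)))
    if (st[1] >= 0 && st[2] >= 0 && sum(st) <= 1) cands <- c(cands, list(q))
  }
  for (edge in list(list(a, b), list(b, c), list(a, c))) {
    u <- edge[[1]]
    v <- edge[[2]]
    L2 <- sum((v - u)^2)
    if (L2 > 0) {
      t <- min(max(sum((p - u) * (v - u)) / L2, 0), 1)
      cands <- c(cands, list(u + t * (v - u)))
    }
  }
  sqrt(min(vapply(cands, function(q) sum((p - q)^2), numeric(1))))
}

oracle_mesh_distance <- function(points, mesh) {
  apply(points, 1L, function(p) {
    min(apply(mesh$faces, 1L, function(f) {
      oracle_point_tri_dist(p, mesh$vertices[f[1], ], mesh$vertices[f[2], ],
                            mesh$vertices[f[3], ])
    }))
  })
}

# ICC(2,1) via R's own two-way ANOVA decomposition (stats::aov), as an
# independent source of the mean squares.
oracle_icc_2_1 <- function(m) {
  df <- data.frame(
    y = as.vector(m),
    subj = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  tab <- anova(stats::aov(y ~ subj + rater, data = df))
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  n <- nrow(m)
  k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Brute-force re-summation of the 16 weighted-sum terms with explicit loops.
oracle_tws <- function(dmc, cx, cy) {
  sx <- 0
  sy <- 0
  for (i in 1:16) {
    if (!is.na(dmc[i])) {
      sx <- sx + dmc[i] * cx[i]
      sy <- sy + dmc[i] * cy[i]
    }
  }
  c(tws_x = sx / 16, tws_y = sy / 16)
}

# Planar rectangular mesh patch at height z, independent of the package's
# synthetic generator.
make_plate <- function(z = 0, n = 5, xlim = c(0, 10), ylim = c(0, 10),
                       z_of = NULL, labels = NULL) {
  g <- expand.grid(x = seq(xlim[1], xlim[2], length.out = n),
                   y = seq(ylim[1], ylim[2], length.out = n))
  zs <- if (is.null(z_of)) rep(z, nrow(g)) else z_of(g$x, g$y)
  v <- cbind(g$x, g$y, zs)
  faces <- NULL
  for (j in seq_len(n - 1)) {
    for (i in seq_len(n - 1)) {
      v00 <- (j - 1) * n + i
      faces <- rbind(faces, c(v00, v00 + 1, v00 + n + 1),
                     c(v00, v00 + n + 1, v00 + n))
    }
  }
  surface_mesh(v, faces, labels = labels)
}

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_res)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

transform_mesh <- function(mesh, rot, shift) {
  surface_mesh(sweep(mesh$vertices %*% t(rot), 2, shift, "+"), mesh$faces,
               labels = mesh$labels)
}

# A projected-map tibble without going through mesh code.
make_pm <- function(x, y, distance, flag = NULL, side = "right") {
  pm <- tibble::tibble(x = x, y = y, distance = distance,
                       flag = flag %||% rep("valid", length(x)))
  attr(pm, "side") <- side
  pm
}

# reverse the four columns within each row of a row-major 16-square table
mirror_grid_table <- function(d) {
  d[rep(seq(0, 12, by = 4), each = 4) + rep(4:1, 4)]
}
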