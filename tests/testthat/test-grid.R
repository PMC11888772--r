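test_that("the anatomical centre is the midpoint of the articular extents", {
  pm <- make_pm(x = c(-10, 10, 0, 5), y = c(-15, 15, 2, -3),
                distance = rep(0.5, 4))
  expect_equal(find_anatomical_center(pm), c(x = 0, y = 0))

  pm2 <- make_pm(x = c(0, 30, 12), y = c(10, 20, 17), distance = rep(0.4, 3))
  expect_equal(find_anatomical_center(pm2), c(x = 15, y = 15))

  # an osteophyte outlier does not move the centre
  pm3 <- make_pm(x = c(-10, 10, 80), y = c(-15, 15, 0),
                 distance = c(0.5, 0.5, NA),
                 flag = c("valid", "valid", "excluded"))
  expect_equal(find_anatomical_center(pm3), c(x = 0, y = 0))
  expect_error(find_anatomical_center(make_pm(1, 1, 0.1, flag = "excluded")),
               class = "bstmap_validation_error")
})

test_that("the grid is 16 equal squares with the expected normalized centres", {
  withr::local_seed(3)
  pm <- make_pm(x = runif(200, -10, 10), y = runif(200, -15, 15),
                distance = runif(200))
  grid <- build_grid(pm)
  sq <- grid$squares
  expect_equal(nrow(sq), 16L)
  expect_setequal(unique(sq$cx), c(-0.375, -0.125, 0.125, 0.375))
  expect_setequal(unique(sq$cy), c(-0.375, -0.125, 0.125, 0.375))
  expect_equal(as.integer(table(sq$quadrant)), rep(4L, 4))
  # anterolateral corner square
  al <- sq[sq$row == 3 & sq$col == 3, ]
  expect_equal(c(al$cx, al$cy), c(0.375, 0.375))
  expect_equal(al$quadrant, "AL")
  # quadrant labels match the sign pattern of the centres
  expect_true(all(sq$quadrant == paste0(ifelse(sq$cy > 0, "A", "P"),
                                        ifelse(sq$cx > 0, "L", "M"))))
  # equal subdivision of the bounding rectangle
  expect_equal(sq$xmax - sq$xmin, rep(diff(grid$xlim) / 4, 16))
})

test_that("an off-midpoint centre moves quadrant labels but not the squares", {
  pm <- make_pm(x = rep(seq(0, 8, by = 2), 5), y = rep(seq(0, 8, by = 2), each = 5),
                distance = runif(25))
  g_mid <- build_grid(pm)
  g_off <- build_grid(pm, center = c(1.2, 1.2))
  expect_equal(g_off$squares[, c("xmin", "xmax", "ymin", "ymax", "cx", "cy")],
               g_mid$squares[, c("xmin", "xmax", "ymin", "ymax", "cx", "cy")])
  # with the axes pushed toward the posteromedial corner, most squares
  # now lie anterolateral of the centre
  expect_gt(sum(g_off$squares$quadrant == "AL"),
            sum(g_mid$squares$quadrant == "AL"))
  expect_error(build_grid(pm, center = c(50, 0)),
               class = "bstmap_validation_error")
})

test_that("samples are binned half-open with the last row and column closed", {
  # 5x5 lattice on [0,4]^2: interior boundaries at 1, 2, 3
  xs <- rep(0:4, 5)
  ys <- rep(0:4, each = 5)
  pm <- make_pm(xs, ys, distance = rep(0.1, 25))
  grid <- build_grid(pm)
  st <- square_stats(pm, grid)
  expect_equal(sum(st$n_samples), 25L)
  # x = 1 sits on the col0/col1 boundary -> positive side (col 1);
  # x = 4 is the closed rectangle edge -> col 3
  expect_equal(st$n_samples[st$row == 0 & st$col == 0], 1L)  # only (0,0)
  expect_equal(st$n_samples[st$row == 3 & st$col == 3], 4L)  # (3,3),(4,3),(3,4),(4,4)
})

test_that("square means, cyst fractions and empty squares are computed", {
  withr::local_seed(5)
  pm <- make_pm(x = runif(400, 0, 8), y = runif(400, 0, 8),
                distance = rep(0.4, 400))
  grid <- build_grid(pm)
  st <- square_stats(pm, grid)
  expect_equal(st$mean_distance, rep(0.4, 16))
  expect_equal(st$cyst_fraction, rep(0, 16))

  # a fully cystic square: distance contribution is zero
  pm2 <- make_pm(x = c(0.5, 0.6, 5, 0.5, 7), y = c(0.5, 0.7, 5, 7, 0.5),
                 distance = c(NA, NA, 0.8, 0.2, 0.6),
                 flag = c("cyst", "cyst", "valid", "valid", "valid"))
  grid2 <- build_grid(pm2)
  st2 <- square_stats(pm2, grid2)
  corner <- st2[st2$row == 0 & st2$col == 0, ]
  expect_equal(corner$mean_distance, 0)
  expect_equal(corner$cyst_fraction, 1)
  expect_true(any(st2$flag_empty))
  expect_true(all(is.na(st2$mean_distance[st2$flag_empty])))
})
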