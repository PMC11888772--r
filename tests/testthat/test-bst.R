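test_that("the distance-mapping coefficient follows 1 - mean distance", {
  expect_equal(compute_dmc(0.3), 0.7)
  expect_equal(compute_dmc(2.5), -1.5)          # extends below zero
  expect_equal(compute_dmc(0, cyst_fraction = 1), 1)  # fully cystic square
  expect_true(is.na(compute_dmc(NA, flag_empty = TRUE)))
  expect_error(compute_dmc(-0.1), class = "bstmap_validation_error")
  # bound: never above 1 for admissible distances
  expect_true(all(compute_dmc(runif(100, 0, 3)) <= 1))
})

test_that("weighted sums reproduce hand-computed reference values", {
  sq <- bstmap:::grid_square_centers()
  # identical DMC everywhere: coordinate symmetry cancels to (0, 0)
  st <- dplyr::mutate(sq, dmc = 0.63, flag_empty = FALSE)
  tws <- compute_weighted_sums(st)
  expect_equal(c(tws$tws_x, tws$tws_y), c(0, 0), tolerance = 1e-15)
  # DMC 1 in the anterolateral corner square only: 0.375/16
  st2 <- dplyr::mutate(sq, dmc = ifelse(row == 3 & col == 3, 1, 0),
                       flag_empty = FALSE)
  tws2 <- compute_weighted_sums(st2)
  expect_equal(c(tws2$tws_x, tws2$tws_y), c(0.0234375, 0.0234375))
  # noiseless coronal gradient: closed form -g * 1.25 / 16
  g <- 0.7
  st3 <- dplyr::mutate(sq, dmc = 1 - (0.5 + g * cx), flag_empty = FALSE)
  tws3 <- compute_weighted_sums(st3)
  expect_equal(tws3$tws_x, -0.078125 * g, tolerance = 1e-12)
  expect_equal(tws3$tws_y, 0, tolerance = 1e-12)
  expect_error(compute_weighted_sums(st3[1:15, ]),
               class = "bstmap_validation_error")
})

test_that("empty squares contribute zero weight but the divisor stays 16", {
  sq <- bstmap:::grid_square_centers()
  st <- dplyr::mutate(sq, dmc = ifelse(row == 3 & col == 3, 1, NA),
                      flag_empty = !(row == 3 & col == 3))
  tws <- compute_weighted_sums(st)
  expect_equal(tws$tws_x, 0.375 / 16)
})

test_that("sign rules classify the weighted-sum point into contact groups", {
  expect_equal(unlist(classify_contact(-0.10, 0.05)),
               c(coronal_class = "varus", sagittal_class = "anterior"))
  expect_equal(unlist(classify_contact(0.02, -0.03)),
               c(coronal_class = "valgus", sagittal_class = "posterior"))
  expect_equal(unlist(classify_contact(0, 0)),
               c(coronal_class = "neutral", sagittal_class = "neutral"))
  # values that round to zero at 3 decimals are neutral
  expect_equal(classify_contact(4e-4, -4e-4)$coronal_class, "neutral")
  expect_equal(classify_contact(4e-4, -4e-4, digits = 6)$coronal_class, "valgus")
  expect_error(classify_contact(0, 0, zero_tol = -1),
               class = "bstmap_validation_error")
})

test_that("grid tables score with anatomical column order on both sides", {
  # constant field: neutral on both axes
  res <- bst_from_grid(rep(0.5, 16))
  expect_equal(c(res$tws_x, res$tws_y), c(0, 0))
  expect_equal(res$coronal_class, "neutral")
  # closer medial contact (medial columns 0.2, lateral 0.8): varus
  d <- rep(c(0.2, 0.2, 0.8, 0.8), 4)
  res_r <- bst_from_grid(d, side = "right")
  expect_lt(res_r$tws_x, 0)
  expect_equal(res_r$coronal_class, "varus")
  # the same anatomical table for a left foot: medial remains medial
  res_l <- bst_from_grid(d, side = "left")
  expect_equal(res_l$tws_x, res_r$tws_x)
  expect_equal(res_l$coronal_class, "varus")
  # a left-foot table recorded in the unmirrored image frame is
  # column-mirrored first
  res_img <- bst_from_grid(mirror_grid_table(d), side = "left", columns = "image")
  expect_equal(res_img$tws_x, res_r$tws_x)
  expect_error(bst_from_grid(d[1:12]), class = "bstmap_validation_error")
  expect_error(bst_from_grid(replace(d, 3, -0.2)),
               class = "bstmap_validation_error")
})

test_that("cystic squares score at the maximum DMC through the grid path", {
  d <- rep(0.5, 16)
  cyst <- seq_len(16) == 16  # anterolateral corner
  res <- bst_from_grid(d, cyst = cyst)
  sq16 <- tidy(res)[16, ]
  expect_equal(sq16$dmc, 1)
  expect_equal(sq16$cyst_fraction, 1)
  expect_gt(res$tws_x, 0)
  expect_gt(res$tws_y, 0)
})

test_that("weighted sums match a brute-force re-summation on random tables", {
  withr::local_seed(19)
  for (rep in 1:200) {
    d <- runif(16, 0, 1.4)
    res <- bst_from_grid(d)
    sq <- tidy(res)
    expected <- oracle_tws(sq$dmc, sq$cx, sq$cy)
    expect_equal(res$tws_x, unname(expected["tws_x"]), tolerance = 1e-12)
    expect_equal(res$tws_y, unname(expected["tws_y"]), tolerance = 1e-12)
  }
})

test_that("TWS magnitudes are bounded by 0.375 times the largest DMC", {
  withr::local_seed(23)
  for (rep in 1:50) {
    d <- runif(16, 0, 2)
    res <- bst_from_grid(d)
    bound <- 0.375 * max(abs(tidy(res)$dmc))
    expect_lte(abs(res$tws_x), bound + 1e-12)
    expect_lte(abs(res$tws_y), bound + 1e-12)
  }
})

test_that("distance fields even in x give a vanishing TWSx", {
  withr::local_seed(29)
  for (rep in 1:25) {
    half <- matrix(runif(8, 0, 1), 4, 2)
    m <- cbind(half, half[, 2:1])       # f(x, y) = f(-x, y)
    res <- bst_from_grid(as.vector(t(m)))
    expect_equal(res$tws_x, 0, tolerance = 1e-12)
  }
})

test_that("scoring from a projected map matches the mesh-free grid path", {
  withr::local_seed(31)
  # dense uniform samples with a linear coronal gradient
  n <- 6000
  x <- runif(n, -15, 15)
  y <- runif(n, -20, 20)
  d <- 0.5 + 0.4 * (x / 30)
  pm <- make_pm(x, y, d)
  res <- bst_score(pm)
  expect_equal(res$tws_x, -0.078125 * 0.4, tolerance = 0.15)
  expect_equal(res$coronal_class, "varus")
  g <- glance(res)
  expect_equal(g$coronal_class, res$coronal_class)
  expect_equal(nrow(tidy(res)), 16L)
})
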