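test_that("field specs generate the stated per-square distances", {
  field <- generate_grid_field(field_spec(d0 = 0.5))
  expect_equal(field$mean_distance_mm, rep(0.5, 16))
  expect_false(any(field$cyst))
  # linear field matches d0 + gx*cx + gy*cy exactly when noise-free
  spec <- field_spec(d0 = 0.6, gx = 0.3, gy = -0.2)
  f2 <- generate_grid_field(spec)
  expect_equal(f2$mean_distance_mm, 0.6 + 0.3 * f2$cx - 0.2 * f2$cy)
  # cyst squares flagged with distance zero
  f3 <- generate_grid_field(field_spec(cyst_squares = c(4, 8)))
  expect_true(all(f3$cyst[c(4, 8)]))
  expect_equal(f3$mean_distance_mm[c(4, 8)], c(0, 0))
})

test_that("seeded generation is reproducible and clamps negative draws", {
  spec <- field_spec(noise_sd = 0.1, seed = 71)
  expect_identical(generate_grid_field(spec), generate_grid_field(spec))
  expect_warning(f <- generate_grid_field(field_spec(d0 = 0.1, gx = 0.6)),
                 "clamped")
  expect_true(all(f$mean_distance_mm >= 0))
})

test_that("noiseless grid fields recover the closed-form weighted sums", {
  for (g in c(-0.5, 0.2, 0.4)) {
    res <- bst_from_grid(generate_grid_field(field_spec(gx = g, gy = -g / 2)))
    expect_equal(res$tws_x, -0.078125 * g, tolerance = 1e-12)
    expect_equal(res$tws_y, 0.078125 * g / 2, tolerance = 1e-12)
  }
})

test_that("parallel synthetic joints score as neutral through the full pipeline", {
  meshes <- generate_joint_meshes(field_spec(d0 = 0.5), resolution = 24)
  res <- bst_from_meshes(meshes$talus, meshes$tibia)
  expect_equal(c(res$tws_x, res$tws_y), c(0, 0), tolerance = 1e-6)
  expect_equal(res$coronal_class, "neutral")
})

test_that("mesh-level gradients agree with the grid-level closed form", {
  spec <- field_spec(d0 = 0.5, gx = 0.4)
  meshes <- generate_joint_meshes(spec, resolution = 32)
  res <- bst_from_meshes(meshes$talus, meshes$tibia)
  expect_equal(res$tws_x, -0.03125, tolerance = 0.05)
  expect_equal(res$tws_y, 0, tolerance = 1e-4)
  expect_equal(res$coronal_class, "varus")
})

test_that("left-side mesh generation scores identically after mirroring", {
  spec <- field_spec(d0 = 0.5, gx = 0.3, gy = -0.2)
  right <- generate_joint_meshes(spec, resolution = 24, side = "right")
  left <- generate_joint_meshes(spec, resolution = 24, side = "left")
  res_r <- bst_from_meshes(right$talus, right$tibia, side = "right")
  res_l <- bst_from_meshes(left$talus, left$tibia, side = "left")
  expect_equal(res_l$tws_x, res_r$tws_x, tolerance = 1e-9)
  expect_equal(res_l$tws_y, res_r$tws_y, tolerance = 1e-9)
  expect_equal(res_l$coronal_class, res_r$coronal_class)
})

test_that("cyst squares become labelled talus vertices and raise the DMC", {
  spec <- field_spec(d0 = 0.5, cyst_squares = 16)
  meshes <- generate_joint_meshes(spec, resolution = 24)
  expect_true(any(meshes$talus$labels == "cyst"))
  res <- bst_from_meshes(meshes$talus, meshes$tibia)
  sq16 <- tidy(res)[16, ]
  expect_gt(sq16$cyst_fraction, 0.9)
  expect_gt(sq16$dmc, 0.9)
  expect_error(generate_joint_meshes(field_spec(d0 = 0.1, gx = 0.6)),
               class = "bstmap_validation_error")
})

test_that("synthetic cohorts honour their coupling and noise settings", {
  sim <- generate_cohort(cohort_spec(n_patients = 40, seed = 81))
  expect_equal(nrow(sim$cohort), 40L)
  expect_equal(nrow(sim$ratings), 160L)
  # true weighted sums follow the closed form of the drawn deformity
  expect_equal(sim$cohort$tws_x, -tws_gain() * sim$cohort$gx)
  # classification concordance: sign of the generating gradient is
  # reproduced for every patient whose TWS does not round to zero
  vis <- abs(round(sim$cohort$tws_x, 3)) > 0
  expect_true(all(sim$cohort$coronal_class[vis] ==
                    ifelse(sim$cohort$gx[vis] > 0, "varus", "valgus")))
})

test_that("null angle coupling yields correlations centred on zero", {
  model <- default_angle_model()
  model$slope <- 0
  sim <- generate_cohort(cohort_spec(n_patients = 40, angle_model = model,
                                     seed = 82))
  report <- cohort_analysis(sim$cohort)
  corr <- tidy(report, "correlations")
  expect_false(any(corr$significant))
  expect_lt(max(abs(corr$estimate)), 0.5)
})

test_that("the excellent-agreement rater regime reproduces high ICCs", {
  # rater noise a tenth of the between-patient TWS spread (~0.02)
  hits <- vapply(1:40, function(s) {
    sim <- generate_cohort(cohort_spec(n_patients = 40, rater_sd = 0.002,
                                       seed = 100 + s))
    wide <- tidyr::pivot_wider(
      sim$ratings[sim$ratings$reading == 1, c("patient_id", "rater_id", "tws_x")],
      names_from = "rater_id", values_from = "tws_x")
    icc_2_1(as.matrix(wide[, -1]))$estimate
  }, numeric(1))
  expect_gte(mean(hits >= 0.9), 0.95)
})
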