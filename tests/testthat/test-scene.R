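test_that("an empty scene has no emitters and no membership", {
  truth <- simulate_scene(scene_params(n_clusters = 0, seed = 1))
  expect_identical(nrow(truth$emitters), 0L)
  expect_identical(nrow(truth$centers), 0L)
})

test_that("opposite-band cluster centers lie inside the two edge strips", {
  # strip geometry: |projected offset| within band_halfwidth of the edge
  truth <- simulate_scene(scene_params("opposite_bands",
                                       tubule_radius_nm = 150,
                                       band_halfwidth_nm = 50,
                                       n_clusters = 200, seed = 42))
  off <- truth$centers$y_offset_nm
  expect_length(off, 200L)
  for (o in off) {
    expect_gte(abs(o), 100)
    expect_lte(abs(o), 150)
  }
  expect_gt(sum(off > 0), 0)  # both strips populated
  expect_gt(sum(off < 0), 0)
})

test_that("stripe-pattern cluster centers sit on the periodic rings", {
  p <- scene_params("stripe_pattern", stripe_period_nm = 150,
                    n_clusters = 50, seed = 5)
  truth <- simulate_scene(p)
  rings <- seq(150 / 2, p$tubule_length_um * 1000, by = 150)
  expect_true(all(truth$centers$x_nm %in% rings))
})

test_that("extended assemblies produce contiguous arcs of the declared span", {
  p <- scene_params("extended_assemblies", n_clusters = 3,
                    assembly_arc_deg = 120, seed = 9)
  truth <- simulate_scene(p)
  # every arc has many emitters and a projected transverse spread far
  # beyond a punctate cluster's
  for (id in unique(truth$emitters$cluster_id)) {
    e <- truth$emitters[truth$emitters$cluster_id == id, ]
    expect_gt(nrow(e), 20)
  }
})

test_that("every emitter lies inside the tubule footprint and image bounds", {
  for (model in c("scattered_puncta", "stripe_pattern",
                  "opposite_bands", "extended_assemblies")) {
    for (seed in 1:5) {
      p <- scene_params(model, n_clusters = 15, seed = seed)
      truth <- simulate_scene(p)
      m <- truth$margin_nm
      L <- p$tubule_length_um * 1000
      r <- p$tubule_radius_nm
      expect_true(all(truth$emitters$x_nm >= m - 1e-9 &
                        truth$emitters$x_nm <= m + L + 1e-9),
                  label = paste(model, seed, "axial footprint"))
      expect_true(all(abs(truth$emitters$y_nm - (r + m)) <= r + 1e-9),
                  label = paste(model, seed, "transverse footprint"))
      expect_true(all(truth$emitters$x_nm >= 0 &
                        truth$emitters$x_nm <= truth$image_nm[["width_nm"]] &
                        truth$emitters$y_nm >= 0 &
                        truth$emitters$y_nm <= truth$image_nm[["height_nm"]]),
                  label = paste(model, seed, "image bounds"))
      expect_true(all(truth$emitters$cluster_id %in% truth$centers$cluster_id))
    }
  }
})

test_that("identical parameters and seed reproduce the ground truth exactly", {
  p <- scene_params("scattered_puncta", seed = 123)
  expect_identical(simulate_scene(p), simulate_scene(p))
  p2 <- scene_params("scattered_puncta", seed = 124)
  expect_false(identical(simulate_scene(p)$emitters,
                         simulate_scene(p2)$emitters))
})

test_that("model-specific parameter errors are raised", {
  expect_error(scene_params(tubule_length_um = -1), "positive")
  p <- scene_params("extended_assemblies")
  p$assembly_arc_deg <- 0
  expect_error(simulate_scene(p), "assembly_arc_deg")
  p <- scene_params("stripe_pattern")
  p$stripe_period_nm <- -5
  expect_error(simulate_scene(p), "stripe_period_nm")
  expect_error(scene_params(pixel_size_nm = 60), "\\[5, 50\\]")
  expect_error(scene_params(psf_fwhm_nm = 10, pixel_size_nm = 20),
               "at least one pixel")
})
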