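test_that("the clustered fraction reproduces forced arithmetic", {
  # pixel size 100 nm -> 0.01 um^2 per pixel: areas {0.01, 0.01, 0.08}
  seg <- manual_segmentation(c(1L, 1L, 8L), pixel_size_nm = 100)
  res <- clustered_fraction(seg, cutoff_um2 = 0.0225)
  expect_equal(res$clustered_fraction, 0.2)
  expect_identical(res$n_single_clusters, 2L)
  expect_equal(res$area_single_um2, 0.02)
  expect_equal(res$area_total_um2, 0.10)
})

test_that("all segments below the cutoff give fraction one, none give zero", {
  seg <- manual_segmentation(c(1L, 2L, 1L), pixel_size_nm = 100)
  expect_equal(clustered_fraction(seg, 0.0225)$clustered_fraction, 1.0)
  seg <- manual_segmentation(c(3L, 4L), pixel_size_nm = 100)
  expect_equal(clustered_fraction(seg, 0.0225)$clustered_fraction, 0.0)
})

test_that("a segment at exactly the cutoff is not a single cluster", {
  # one pixel of 150 nm has an area of exactly 0.0225 um^2
  seg <- manual_segmentation(1L, pixel_size_nm = 150)
  expect_identical(unname(seg$segment_areas_um2), 0.0225)
  res <- clustered_fraction(seg, cutoff_um2 = 0.0225)
  expect_identical(res$n_single_clusters, 0L)
  expect_equal(res$clustered_fraction, 0.0)
})

test_that("an empty segmentation is flagged undefined, not zero", {
  seg <- segment_clusters(image2d(matrix(0, 12, 12), pixel_size_nm = 20))
  res <- clustered_fraction(seg)
  expect_true(res$undefined)
  expect_true(is.na(res$clustered_fraction))
})

test_that("merging single clusters past the cutoff never raises the fraction", {
  # two single segments (1 px each at 100 nm) vs the merged segment (26 px
  # > 0.0225 um^2 once combined with padding to exceed the cutoff)
  for (counts in list(c(1L, 1L, 8L), c(2L, 2L, 5L), c(1L, 2L))) {
    seg_split <- manual_segmentation(counts, pixel_size_nm = 100)
    merged <- c(sum(counts[1:2]) + 2L, counts[-(1:2)])  # merged exceeds cutoff
    seg_merged <- manual_segmentation(merged, pixel_size_nm = 100)
    f1 <- clustered_fraction(seg_split, 0.0225)$clustered_fraction
    f2 <- clustered_fraction(seg_merged, 0.0225)$clustered_fraction
    expect_lte(f2, f1)
  }
})

test_that("the metric is invariant to positive intensity rescaling", {
  img <- render_image(simulate_scene(scene_params(seed = 13)))
  base <- cluster_metric(img)
  for (c0 in c(0.25, 3, 117.5)) {
    scaled <- image2d(as.matrix(unclass(img)) * c0,
                      pixel_size_nm = pixel_size_nm(img))
    res <- cluster_metric(scaled)
    expect_identical(attr(res, "segmentation")$label_map,
                     attr(base, "segmentation")$label_map)
    expect_equal(res$clustered_fraction, base$clustered_fraction,
                 tolerance = 1e-12)
  }
})

test_that("a mask restricts the analysis region", {
  img <- render_image(simulate_scene(scene_params(seed = 14)))
  mask <- matrix(FALSE, nrow(img), ncol(img))
  mask[, seq_len(ncol(img) %/% 2)] <- TRUE
  res <- cluster_metric(img, mask = mask)
  seg <- attr(res, "segmentation")
  expect_true(all(seg$label_map[, (ncol(img) %/% 2 + 1):ncol(img)] == 0L))
})

test_that("scattered puncta score a higher clustered fraction than assemblies", {
  fr <- function(model, n_clusters, seed) {
    res <- cluster_metric(render_image(simulate_scene(
      scene_params(model, n_clusters = n_clusters, seed = seed))))
    res$clustered_fraction
  }
  f_punct <- vapply(1:8, function(s) fr("scattered_puncta", 30, s), 0)
  f_ext <- vapply(1:8, function(s) fr("extended_assemblies", 6, s), 0)
  expect_gt(mean(f_punct), mean(f_ext))
})

test_that("group comparison delegates to the one-way ANOVA", {
  # same values in both groups: no between-group variance, F = 0
  res <- compare_clustered_fractions(list(a = c(0.2, 0.5, 0.8),
                                          b = c(0.2, 0.5, 0.8)))
  expect_equal(res$f_stat, 0)
  res <- compare_clustered_fractions(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$f_stat, 13.5)
  expect_identical(c(res$df_between, res$df_within), c(1L, 4L))
  # permutation of group order leaves F unchanged
  res2 <- compare_clustered_fractions(list(b = c(4, 5, 6), a = c(1, 2, 3)))
  expect_equal(res2$f_stat, res$f_stat)
  expect_error(compare_clustered_fractions(list(a = c(1, 2), b = 3)),
               ">= 2")
})
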