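test_that("denoising strengths behave as specified", {
  spec <- two_region_spec(image_shape = c(16, 16))
  lab <- make_phantom_labels(spec)
  d <- simulate_dataset(spec, lab, "control", seed = 2)
  pm <- extract_peak_matrix(d, phantom_reference_list(spec))
  expect_identical(denoise_feature_images(pm, "off"), pm)

  # constant on-tissue image: unchanged in the tissue interior
  pm_const <- pm
  pm_const[attr(pm, "on_tissue"), ] <- 5
  for (s in c("weak", "strong")) {
    den <- denoise_feature_images(pm_const, s)
    interior <- attr(pm, "on_tissue") &
      apply(attr(pm, "coords"), 1, function(rc)
        all(rc >= 4 & rc <= 11))
    expect_true(all(den[interior, ] == 5))
    expect_true(all(den >= 0))
    # the on-tissue pixel set never changes
    expect_identical(attr(den, "on_tissue"), attr(pm, "on_tissue"))
  }
})

test_that("a single-pixel impulse is removed by weak denoising", {
  coords <- expand.grid(col = 0:7, row = 0:7)[, 2:1]
  x <- matrix(0, 64, 1)
  x[28, 1] <- 100  # an isolated hotspot on a zero image
  pm <- structure(x, coords = coords, ref_mz = 500,
                  shape = c(8L, 8L), on_tissue = rep(TRUE, 64),
                  tolerance = 0.25,
                  class = c("peak_matrix", "matrix", "array"))
  den <- denoise_feature_images(pm, "weak")
  expect_true(all(den == 0))
  # oracle: direct 3x3 median of the image
  img <- matrix(0, 8, 8); img[cbind(coords$row + 1, coords$col + 1)] <- x
  expect_true(all(brute_median2d(img, 3) == 0))
})

test_that("k-means recovers a noiseless two-region phantom exactly", {
  skip_if_not_installed("mclust")
  spec <- two_region_spec(image_shape = c(32, 32))
  lab <- make_phantom_labels(spec)
  d <- simulate_dataset(spec, lab, "control", seed = 3)
  pm <- preprocess_dataset(d, phantom_reference_list(spec))
  seg <- segment_spatial(pm, k = 2, seed = 42)
  on <- attr(pm, "on_tissue")
  truth <- pixel_regions(lab, attr(pm, "coords"))[on]
  ari <- mclust::adjustedRandIndex(seg$pixel_cluster[on], truth)
  expect_equal(ari, 1.0)
})

test_that("segmentation is deterministic and validates k", {
  spec <- two_region_spec(image_shape = c(16, 16), noise_sd = 3)
  lab <- make_phantom_labels(spec)
  d <- simulate_dataset(spec, lab, "control", seed = 5)
  pm <- preprocess_dataset(d, phantom_reference_list(spec))
  s1 <- segment_spatial(pm, k = 2, seed = 7)
  s2 <- segment_spatial(pm, k = 2, seed = 7)
  expect_identical(s1$cluster_map, s2$cluster_map)
  expect_error(segment_spatial(pm, k = 1), "k must be >= 2")
})

test_that("cluster naming follows the white-matter markers", {
  skip_if_not_installed("mclust")
  # white-matter species (refs 1-4) are exclusive to the white band
  spec <- two_region_spec(image_shape = c(32, 32), noise_sd = 1)
  lab <- make_phantom_labels(spec)
  d <- simulate_dataset(spec, lab, "control", seed = 11)
  pm <- preprocess_dataset(d, phantom_reference_list(spec))
  seg <- map_clusters(segment_spatial(pm, k = 2, seed = 42),
                      marker_refs = 1:4)
  on <- attr(pm, "on_tissue")
  truth <- pixel_regions(lab, attr(pm, "coords"))[on]
  named <- seg$assignment[as.character(seg$pixel_cluster[on])]
  # the cluster carrying the marker species is the white-matter region
  expect_gt(mean(named == truth), 0.99)
})

test_that("marker ties break deterministically with a warning", {
  spec <- two_region_spec(image_shape = c(16, 16))
  lab <- make_phantom_labels(spec)
  d <- simulate_dataset(spec, lab, "control", seed = 2)
  pm <- preprocess_dataset(d, phantom_reference_list(spec))
  seg <- segment_spatial(pm, k = 2, seed = 42)
  seg$cluster_profiles[] <- 1  # identical marker means everywhere
  expect_warning(res <- map_clusters(seg, marker_refs = 1:2), "tie")
  expect_identical(unname(res$assignment[1]), "white_matter")
  expect_error(map_clusters(seg, integer(0)), "non-empty")
})
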