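test_that("subfields layout yields all six labels, deterministically", {
  spec <- phantom_spec(image_shape = c(64, 64), species = mini_species())
  lab <- make_phantom_labels(spec)
  expect_identical(sort(unique(as.vector(lab$raster))), 0:5)
  expect_setequal(unname(lab$legend),
                  c("background", "white_matter", "CA1", "CA2/3", "CA4", "DG"))
  lab2 <- make_phantom_labels(spec)
  expect_identical(lab$raster, lab2$raster)
})

test_that("every named region has at least 16 pixels at 32x32", {
  lab <- make_phantom_labels(
    phantom_spec(image_shape = c(32, 32), species = mini_species()))
  counts <- table(as.vector(lab$raster))
  named <- setdiff(names(lab$legend), "0")
  for (l in named)
    expect_gte(unname(counts[l]), 16L)
})

test_that("a layout that starves a region errors with the region's name", {
  expect_error(
    make_phantom_labels(phantom_spec(image_shape = c(8, 8),
                                     species = mini_species())),
    "DG")
})

test_that("species m/z outside the axis is a configuration error", {
  expect_error(
    phantom_spec(species = mini_species(mz = c(300, 560, 600)),
                 mz_range = c(400, 2000)),
    "outside mz_range")
})

test_that("noise-free control and case agree except for the planted fold", {
  sp <- mini_species(fold_region = "CA1", fold = 1.75)
  spec <- tiny_spec(sp, noise_sd = 0, tic_cv = 0, baseline_amplitude = 0)
  lab <- make_phantom_labels(spec)
  ctrl <- simulate_dataset(spec, lab, "control", seed = 1)
  case <- simulate_dataset(spec, lab, "case", seed = 2)
  regions <- pixel_regions(lab, ctrl$coords)
  apex_ch <- which.min(abs(ctrl$mz - 520.0))
  in_ca1 <- regions == "CA1"
  other <- !(regions %in% c("CA1", "background"))
  # unchanged regions: case pixels identical to control pixels
  expect_equal(case$intensities[, other], ctrl$intensities[, other])
  # planted region: apex exactly 1.75x
  expect_equal(case$intensities[apex_ch, in_ca1],
               1.75 * ctrl$intensities[apex_ch, in_ca1])
  # no noise: spectra constant across pixels within a region
  ca1 <- ctrl$intensities[, in_ca1]
  expect_true(all(ca1 == ca1[, 1]))
})

test_that("with noise on, the region-mean apex ratio recovers the fold", {
  sp <- mini_species(fold_region = "CA1", fold = 1.75)
  # no baseline: the raw apex then carries only the species signal, so the
  # region-mean apex ratio estimates the fold directly
  spec <- tiny_spec(sp, image_shape = c(48, 48), baseline_amplitude = 0)
  lab <- make_phantom_labels(spec)
  ctrl <- simulate_dataset(spec, lab, "control", seed = 31)
  case <- simulate_dataset(spec, lab, "case", seed = 32)
  in_ca1 <- which(pixel_regions(lab, ctrl$coords) == "CA1")
  expect_gte(length(in_ca1), 200)
  apex_ch <- which.min(abs(ctrl$mz - 520.0))
  a0 <- ctrl$intensities[apex_ch, in_ca1]
  a1 <- case$intensities[apex_ch, in_ca1]
  ratio <- mean(a1) / mean(a0)
  se <- ratio * sqrt(sd(a1)^2 / mean(a1)^2 + sd(a0)^2 / mean(a0)^2) /
    sqrt(length(in_ca1))
  expect_lt(abs(ratio - 1.75), 3 * se)
})

test_that("all simulated intensities are non-negative", {
  spec <- tiny_spec(noise_sd = 20)  # strong noise to exercise clipping
  lab <- make_phantom_labels(spec)
  d <- simulate_dataset(spec, lab, "control", seed = 5)
  expect_true(all(d$intensities >= 0))
})

test_that("paired study layout, ground truth and determinism", {
  sp <- mini_species(fold_region = "DG", fold = 1.5)
  spec <- tiny_spec(sp)
  study <- simulate_paired_study(spec, n_pairs = 3, seed = 9)
  expect_length(study$pairs, 3)
  expect_s3_class(study$pairs[[1]]$control, "msi_dataset")
  expect_s3_class(study$pairs[[1]]$case, "msi_dataset")
  # ground truth rows = number of (species, region) cells with fold != 1
  expect_identical(nrow(study$ground_truth), sum(sp$fold != 1))
  expect_identical(study$ground_truth$direction, "up")

  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_ground_truth(simulate_paired_study(spec, 3, seed = 9)$ground_truth, f1)
  write_ground_truth(simulate_paired_study(spec, 3, seed = 9)$ground_truth, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("paired study shares the pair scale factor within a pair", {
  spec <- tiny_spec(mini_species())
  study <- simulate_paired_study(spec, n_pairs = 2, seed = 4)
  for (p in study$pairs)
    expect_identical(p$control$metadata$scale, p$case$metadata$scale)
})
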