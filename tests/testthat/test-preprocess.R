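one_pixel_dataset <- function(mz, spectrum) {
  msi_dataset(mz, matrix(spectrum, ncol = 1), data.frame(row = 0, col = 0))
}

test_that("top-hat annihilates flat spectra and matches the sliding oracle", {
  mz <- seq(400, 420, by = 0.1)
  zero <- one_pixel_dataset(mz, rep(0, length(mz)))
  expect_true(all(tophat_baseline(zero)$intensities == 0))

  const <- one_pixel_dataset(mz, rep(7.5, length(mz)))
  expect_true(all(tophat_baseline(const)$intensities == 0))

  # ramp baseline + narrow Gaussian: apex preserved, ramp removed
  ramp <- 5 + 0.8 * (mz - 400)
  peak <- 100 * exp(-(mz - 410)^2 / (2 * 0.08^2))
  d <- one_pixel_dataset(mz, ramp + peak)
  corrected <- tophat_baseline(d, window = 1.5)$intensities[, 1]
  oracle <- (ramp + peak) - brute_opening(ramp + peak, h = 7)  # 15 channels
  expect_equal(corrected, oracle, tolerance = 1e-12)
  apex <- which.min(abs(mz - 410))
  expect_lt(abs(corrected[apex] - peak[apex]) / peak[apex], 0.02)
  # off-peak and away from the axis boundary (partial windows there)
  off <- abs(mz - 410) > 2 & mz > 401 & mz < 419
  expect_lt(max(corrected[off]), 0.01 * max(ramp))
})

test_that("top-hat is idempotent on baseline-plus-peaks spectra", {
  mz <- seq(500, 560, by = 0.1)
  set.seed(42)
  for (i in 1:5) {
    base <- runif(1, 10, 200) * exp(-runif(1, 0.001, 0.02) * (mz - 500))
    spec <- base
    for (centre in c(510, 525, 543))
      spec <- spec + runif(1, 50, 500) * exp(-(mz - centre)^2 / (2 * 0.08^2))
    d <- one_pixel_dataset(mz, spec)
    once <- tophat_baseline(d)
    twice <- tophat_baseline(once)
    expect_equal(twice$intensities, once$intensities, tolerance = 1e-9)
  }
})

test_that("window smaller than 3 channels is rejected", {
  d <- one_pixel_dataset(seq(400, 500, by = 1), rep(1, 101))
  expect_error(tophat_baseline(d, window = 1), "3 channels")
})

test_that("TIC normalization equalizes pixels to the mean TIC", {
  mz <- seq(400, 409, by = 1)
  ints <- cbind(rep(1, 10), rep(3, 10))  # TICs 10 and 30
  d <- msi_dataset(mz, ints, data.frame(row = c(0, 0), col = c(0, 1)))
  n <- tic_normalize(d)
  expect_equal(pixel_tic(n), c(20, 20))

  # idempotence and off-tissue pixels untouched
  ints3 <- cbind(ints, rep(0, 10))
  d3 <- msi_dataset(mz, ints3, data.frame(row = 0, col = 0:2))
  n3 <- tic_normalize(tic_normalize(d3))
  expect_equal(pixel_tic(n3), c(20, 20, 0))
  expect_equal(tic_normalize(n3)$intensities, n3$intensities)
})

test_that("TIC variance after normalization is numerically zero", {
  spec <- tiny_spec(mini_species())
  d <- simulate_dataset(spec, make_phantom_labels(spec), "control", seed = 8)
  n <- tic_normalize(d)
  tic <- pixel_tic(n)[on_tissue(n)]
  expect_lt(var(tic), 1e-10 * mean(tic)^2)
})

test_that("alignment assigns apices inside the window only", {
  mz <- seq(695, 705, by = 0.1)
  make_peak <- function(centre) 100 * exp(-(mz - centre)^2 / (2 * 0.08^2))
  ref <- ref_mz_list(data.frame(mz = 700.0))
  inside <- align_to_reference(one_pixel_dataset(mz, make_peak(700.1)),
                               ref, tolerance = 0.3)
  expect_true(inside$present)
  expect_equal(mz[inside$center], 700.1)
  outside <- align_to_reference(one_pixel_dataset(mz, make_peak(700.5)),
                                ref, tolerance = 0.3)
  expect_false(outside$present)
})

test_that("overlapping reference windows split at the midpoint", {
  mz <- seq(790, 800, by = 0.1)
  spec <- 100 * exp(-(mz - 794.6)^2 / (2 * 0.08^2)) +
    80 * exp(-(mz - 795.7)^2 / (2 * 0.08^2))
  ref <- ref_mz_list(data.frame(mz = c(794.6, 795.7)))
  al <- align_to_reference(one_pixel_dataset(mz, spec), ref, tolerance = 0.6)
  midpoint <- (794.6 + 795.7) / 2  # 795.15
  expect_lte(mz[al$hi[1]], midpoint)
  expect_gte(mz[al$lo[2]], midpoint)
  expect_lt(al$hi[1], al$lo[2])  # disjoint windows
  expect_true(all(al$present))
})

test_that("references outside the axis are absent, not errors", {
  mz <- seq(400, 500, by = 0.1)
  al <- align_to_reference(one_pixel_dataset(mz, rep(1, length(mz))),
                           ref_mz_list(data.frame(mz = c(450, 900))), 0.25)
  expect_identical(al$present, c(TRUE, FALSE))
})

test_that("windowed extraction matches the numeric Gaussian integral", {
  mz <- seq(500, 520, by = 0.1)
  amp <- 250; sigma <- 0.08
  spec <- amp * exp(-(mz - 510)^2 / (2 * sigma^2))
  d <- one_pixel_dataset(mz, spec)
  ref <- ref_mz_list(data.frame(mz = 510))
  pm <- extract_peak_matrix(d, ref, tolerance = 0.25)
  oracle <- amp * sigma * sqrt(2 * pi) / 0.1  # analytic integral / step
  expect_lt(abs(pm[1, 1] - oracle) / oracle, 0.02)

  # linearity: doubling the spectrum doubles the row
  d2 <- one_pixel_dataset(mz, 2 * spec)
  expect_equal(extract_peak_matrix(d2, ref, 0.25)[1, 1], 2 * pm[1, 1])

  # absent reference: zero column
  pm2 <- extract_peak_matrix(d, ref_mz_list(data.frame(mz = c(510, 900))), 0.25)
  expect_true(all(pm2[, 2] == 0))
})

test_that("extraction commutes with pixel permutation", {
  spec <- tiny_spec(mini_species())
  d <- simulate_dataset(spec, make_phantom_labels(spec), "control", seed = 13)
  ref <- phantom_reference_list(spec)
  set.seed(2)
  perm <- sample(ncol(d$intensities))
  dp <- msi_dataset(d$mz, d$intensities[, perm], d$coords[perm, ])
  pm <- extract_peak_matrix(d, ref)
  pmp <- extract_peak_matrix(dp, ref)
  strip <- function(x) matrix(as.numeric(x), nrow(x))
  # row i of the permuted extraction is row perm[i] of the original
  expect_equal(strip(pmp), strip(pm)[perm, ])
})

test_that("peak detection finds planted species and respects SNR limits", {
  sp <- mini_species(mz = c(520, 560, 600), fold_region = NULL)
  # case lacks the first species: drive its abundance to ~zero via fold
  fold <- sp$abundance * 0 + 1
  fold[1, ] <- 1e-9
  sp_case <- species_set(sp$mz, sp$peak_sigma, sp$abundance, fold)
  spec <- tiny_spec(sp, noise_sd = 0, tic_cv = 0)
  spec_case <- tiny_spec(sp_case, noise_sd = 0, tic_cv = 0)
  lab <- make_phantom_labels(spec)
  ref <- phantom_reference_list(spec)
  ctrl <- tophat_baseline(simulate_dataset(spec, lab, "control", seed = 1))
  case <- tophat_baseline(simulate_dataset(spec_case, lab, "case", seed = 1))
  det_ctrl <- detect_peaks(ctrl, ref)
  det_case <- detect_peaks(case, ref)
  expect_identical(det_ctrl, 1:3)             # noiseless: all planted found
  expect_identical(intersect(det_ctrl, det_case), 2:3)
  expect_length(detect_peaks(ctrl, ref, snr_threshold = 1e300), 0)
})

test_that("the canonical preprocessing order is pinned", {
  spec <- tiny_spec(mini_species())
  d <- simulate_dataset(spec, make_phantom_labels(spec), "control", seed = 21)
  ref <- phantom_reference_list(spec)
  canonical <- preprocess_dataset(d, ref)
  manual <- extract_peak_matrix(
    tic_normalize(tophat_baseline(d, 1.5)), ref, 0.25,
    alignment = align_to_reference(d, ref, 0.25))
  expect_equal(unclass(canonical), unclass(manual))
  # swapping normalization before baseline removal changes the result
  swapped <- extract_peak_matrix(
    tophat_baseline(tic_normalize(d), 1.5), ref, 0.25,
    alignment = align_to_reference(d, ref, 0.25))
  expect_gt(max(abs(unclass(swapped) - unclass(canonical))), 1e-6)
})
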