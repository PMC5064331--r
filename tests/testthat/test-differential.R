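test_that("roc_auc handles ties, separation and the enumerated example", {
  expect_equal(roc_auc(c(5, 5, 5), c(5, 5)), 0.5)        # all ties
  expect_equal(roc_auc(c(0, 1), c(2, 3)), 1.0)           # perfect separation
  expect_equal(roc_auc(c(2, 3), c(1, 2, 4)),
               brute_auc(c(2, 3), c(1, 2, 4)))           # wins + half ties
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("roc_auc equals brute-force enumeration on random tied samples", {
  set.seed(99)
  for (i in 1:50) {
    n0 <- sample(1:30, 1); n1 <- sample(1:30, 1)
    ctrl <- sample(0:8, n0, replace = TRUE) + sample(c(0, 0.5), n0, TRUE)
    case <- sample(0:8, n1, replace = TRUE) + sample(c(0, 0.5), n1, TRUE)
    expect_equal(roc_auc(ctrl, case), brute_auc(ctrl, case),
                 tolerance = 1e-12)
    expect_identical(roc_auc(ctrl, case) + roc_auc(case, ctrl), 1)
    expect_equal(roc_auc(3 * ctrl, 3 * case), roc_auc(ctrl, case))
  }
})

test_that("pairwise ROC separates planted from null species", {
  sp <- mini_species(mz = c(520, 560, 600), abundance = 1500,
                     fold_region = "CA1", fold = 1.75)
  spec <- tiny_spec(sp, image_shape = c(32, 32))
  study <- simulate_paired_study(spec, n_pairs = 2, seed = 14)
  mats <- study_peak_matrices(study, phantom_reference_list(spec))
  rec <- pairwise_roc(mats, regions = c("CA1", "DG"))
  planted <- rec[rec$ref_index == 1 & rec$region == "CA1", ]
  expect_true(all(planted$auc > 0.9))
  expect_true(all(planted$direction == "up"))
  null_rec <- rec[rec$ref_index != 1 | rec$region != "CA1", ]
  expect_true(all(null_rec$auc > 0.1 & null_rec$auc < 0.9))
})

test_that("regions below the pixel floor are skipped with a warning", {
  sp <- mini_species()
  spec <- tiny_spec(sp, image_shape = c(24, 24))
  study <- simulate_paired_study(spec, n_pairs = 1, seed = 3)
  mats <- study_peak_matrices(study, phantom_reference_list(spec))
  expect_warning(rec <- pairwise_roc(mats, regions = c("DG", "CA1"),
                                     min_pixels = 40L), "DG")
  expect_false("DG" %in% rec$region)
  expect_true("CA1" %in% rec$region)
})

test_that("consistency filter implements the all-pairs rule exactly", {
  all_up <- fake_records(rep("up", 6))
  kept <- consistency_filter(all_up, 6)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$direction, "up")

  five_up <- fake_records(c(rep("up", 5), "none"))
  expect_identical(nrow(consistency_filter(five_up, 6)), 0L)

  mixed <- fake_records(c(rep("up", 3), rep("down", 3)))
  expect_identical(nrow(consistency_filter(mixed, 6)), 0L)

  missing_pair <- fake_records(rep("down", 5))  # only 5 of 6 records exist
  expect_identical(nrow(consistency_filter(missing_pair, 6)), 0L)
})

test_that("consistency is monotone: more pairs can only shrink the set", {
  # anything retained over all six pairs is retained over any four of them
  recs_up <- fake_records(rep("up", 6))
  expect_identical(nrow(consistency_filter(recs_up, 6)), 1L)
  expect_identical(nrow(consistency_filter(recs_up[1:4, ], 4)), 1L)
  set.seed(7)
  retained_full <- 0L
  for (i in 1:40) {
    dirs <- sample(c("up", "down", "none"), 6, replace = TRUE,
                   prob = c(0.45, 0.45, 0.1))
    recs <- fake_records(dirs)
    full <- consistency_filter(recs, 6)
    sub <- consistency_filter(recs[1:4, ], 4)
    if (nrow(full) == 1L) {
      retained_full <- retained_full + 1L
      expect_identical(nrow(sub), 1L)
      expect_identical(sub$direction, full$direction)
    }
  }
  expect_gte(retained_full, 1L)  # the random sweep exercised the property
})

test_that("percent change is the mean over per-pair relative differences", {
  pairs <- lapply(1:3, function(i)
    fake_pair(sprintf("pair%02d", i), mean_control = c(10, 4),
              mean_case = c(17.5, 4)))
  pc <- percent_change(pairs, ref_index = 1, region = "CA1")
  expect_equal(pc$mean_percent_change, 75.0)
  expect_equal(unname(pc$per_pair), rep(75.0, 3))
  null_pc <- percent_change(pairs, ref_index = 2, region = "CA1")
  expect_equal(null_pc$mean_percent_change, 0)

  # zero control mean: undefined, reported as missing
  degenerate <- list(fake_pair("pair01", c(0, 1), c(5, 1)))
  expect_true(is.na(percent_change(degenerate, 1, "CA1")$mean_percent_change))
})

test_that("planted decreases are recovered within 3 SE", {
  sp <- mini_species(mz = c(520, 560, 600), abundance = 2000,
                     fold_region = "CA1", fold = 0.8)
  spec <- tiny_spec(sp, image_shape = c(32, 32))
  study <- simulate_paired_study(spec, n_pairs = 4, seed = 23)
  mats <- study_peak_matrices(study, phantom_reference_list(spec))
  pc <- percent_change(mats, ref_index = 1, region = "CA1")
  expect_lt(abs(pc$mean_percent_change - (-20)), 3 * pc$se_percent_change)
  # a null species stays within 3 SE of zero
  pc_null <- percent_change(mats, ref_index = 2, region = "CA1")
  expect_lt(abs(pc_null$mean_percent_change), 3 * pc_null$se_percent_change)
})

test_that("the change report joins filter, quantification and annotation", {
  pairs <- lapply(1:2, function(i)
    fake_pair(sprintf("pair%02d", i), mean_control = c(10, 5),
              mean_case = c(14, 5), ref_mz = c(885.6, 739.2)))
  changes <- consistency_filter(
    fake_records(rep("up", 2), ref_index = 1L, mz = 885.6), 2)
  ann <- annotate_mz(ref_mz_list(data.frame(mz = c(739.2, 885.6))),
                     lipid_assignments())
  rep_tab <- build_change_report(pairs, changes, annotation = ann)
  expect_identical(rep_tab$lipid_assignment, "PI 38:4-H-")
  expect_equal(rep_tab$mean_percent_change, 40.0)
  expect_identical(rep_tab$n_pairs_consistent, 2L)
})
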