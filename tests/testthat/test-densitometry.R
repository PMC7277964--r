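test_that("histogram building counts masked voxels into 1-HU bins", {
  vol <- row_volume(c(-1000, -900, -800, -500, -100))
  mask <- seg_mask(array(TRUE, dim(vol$voxels)), vol)
  h <- build_histogram(vol, mask)
  expect_equal(sum(h$counts), 5)
  expect_equal(h$counts[c(-1000, -900, -800, -500, -100) + 1025],
               rep(1, 5))

  all_air <- row_volume(rep(-1024, 4))
  h2 <- build_histogram(all_air, seg_mask(array(TRUE, c(1, 1, 4)), all_air))
  expect_equal(h2$counts[1], 4)
  expect_equal(sum(h2$counts[-1]), 0)

  expect_error(build_histogram(vol, seg_mask(array(FALSE, dim(vol$voxels)))),
               "empty mask")
})

test_that("lung volume restriction follows the upper threshold", {
  h <- toy_hist(c(-1000, -900, -800, -500, -100))
  expect_equal(lung_volume_at(h, 0)$voxels, 5)
  expect_equal(lung_volume_at(h, -200)$voxels, 4)  # -100 excluded
  expect_equal(lung_volume_at(h, 200)$ml, 5 * h$voxel_volume_ml)
})

test_that("band fractions are exact on hand-enumerated histograms", {
  h <- toy_hist(c(-1000, -900, -800, -500, -100))
  expect_equal(band_fraction(h, c(-950, -701), 0), 40)       # 2 of 5
  expect_equal(band_fraction(h, c(-950, -701), -200), 50)    # 2 of 4
  expect_equal(band_fraction(h, c(-199, 200), -200), 0)      # disjoint band
  expect_equal(band_fraction(h, c(-1024, 0), 0), 100)        # normalization
})

test_that("feature percentages match manual fractions on toy data", {
  h <- toy_hist(c(-1000, -900, -800, -500, -100))
  fs <- compute_features(h, 0)
  expect_equal(fs$nl_pct, 40)                  # -900, -800
  expect_equal(fs$laa_pct, 20)                 # -1000 (<= -961)
  expect_equal(fs$nonfibrotic_pct, 60)         # -1000, -900, -800
  expect_equal(fs$pff_pct, 40)                 # complement
  expect_equal(fs$haa_pct, 20)                 # -100 (>= -199)
  expect_equal(fs$haa_a_pct, 20)               # -500 in [-600, -250]
  expect_equal(fs$lung_volume_ml, 5)
})

test_that("moments behave on a symmetric two-point histogram", {
  h <- toy_hist(c(-900, -700), counts = c(10, 10))
  fs <- compute_features(h, 0)
  expect_equal(fs$skewness, 0)
  expect_equal(fs$mld, -800)
  expect_equal(fs$variance_hu2, 10000)
  expect_equal(fs$kurtosis, -2)  # two-point distribution

  single <- toy_hist(-800, counts = 5)
  expect_error(compute_features(single, 0), "kurtosis and skewness")
})

test_that("histogram moments agree with direct voxel-list statistics", {
  set.seed(31)
  hu <- rnorm(20000, -650, 120)
  hu <- hu[hu >= -1020 & hu <= 195]
  vol <- ct_volume(array(hu[1:8000], c(20, 20, 20)))
  mask <- seg_mask(array(TRUE, c(20, 20, 20)), vol)
  fs <- compute_features(build_histogram(vol, mask), 200)
  raw <- vol$voxels
  expect_lt(abs(fs$mld - mean(raw)), 0.5)
  expect_lt(abs(fs$median_hu - median(raw)), 1)
  expect_equal(fs$variance_hu2, mean((raw - mean(raw))^2), tolerance = 0.01)
  expect_lt(abs(fs$kurtosis - excess_kurtosis(raw)), 0.01)
})

test_that("excess kurtosis matches closed-form values for known shapes", {
  set.seed(32)
  g <- rnorm(2e5, -800, 60)
  expect_lt(abs(excess_kurtosis(g)), 0.05)
  u <- runif(2e5, -900, -500)
  expect_equal(excess_kurtosis(u), -1.2, tolerance = 0.02)
  # histogram path with the Gaussian fully inside [-1024, 200]
  vol <- ct_volume(array(g[1:125000], c(50, 50, 50)))
  mask <- seg_mask(array(TRUE, c(50, 50, 50)), vol)
  fs <- compute_features(build_histogram(vol, mask), 200)
  expect_lt(abs(fs$kurtosis), 0.05)
})

test_that("band fractions over an exhaustive partition sum to 100", {
  set.seed(33)
  h <- attenuation_histogram(rpois(1225, 4))
  for (upper in c(-200, 0, 200)) {
    cuts <- c(-1024, sort(sample(seq(-1000, upper - 1), 6)), upper)
    tot <- 0
    for (i in seq_len(length(cuts) - 1)) {
      lo <- if (i == 1) cuts[1] else cuts[i] + 1
      tot <- tot + band_fraction(h, c(lo, cuts[i + 1]), upper)
    }
    expect_equal(tot, 100, tolerance = 1e-9)
  }
})

test_that("NL decreases and PFF increases with the upper threshold", {
  set.seed(34)
  for (r in 1:5) {
    h <- attenuation_histogram(runif(1225))
    fs <- compute_all_thresholds(h)
    expect_true(fs[["-200"]]$nl_pct >= fs[["0"]]$nl_pct)
    expect_true(fs[["0"]]$nl_pct >= fs[["200"]]$nl_pct)
    expect_true(fs[["-200"]]$pff_pct <= fs[["0"]]$pff_pct)
    expect_true(fs[["0"]]$pff_pct <= fs[["200"]]$pff_pct)
    expect_equal(fs[["-200"]]$haa_pct, 0)
  }
})

test_that("with no mass above -200 HU all three feature sets coincide", {
  h <- toy_hist(c(-950, -800, -650, -400), counts = c(3, 5, 2, 1))
  fs <- compute_all_thresholds(h)
  for (f in c("nl_pct", "pff_pct", "laa_pct", "haa_a_pct", "kurtosis",
              "mld", "variance_hu2")) {
    expect_equal(fs[["-200"]][[f]], fs[["0"]][[f]])
    expect_equal(fs[["0"]][[f]], fs[["200"]][[f]])
  }
})

test_that("the feature table exports tidily", {
  h <- toy_hist(c(-1000, -900, -800, -500, -100))
  tab <- features_to_table(list(P1 = compute_all_thresholds(h)))
  expect_equal(sort(unique(tab$threshold_hu)), c(-200, 0, 200))
  expect_true(all(c("patient_id", "threshold_hu", "feature", "value") %in%
                    names(tab)))
  expect_equal(nrow(tab), 3 * 12)
})
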