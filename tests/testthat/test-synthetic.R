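test_that("pure-tissue mixtures match Gaussian closed forms", {
  # all normal lung: NL band mass = Phi difference of Normal(-850, 60),
  # evaluated at the half-integer bin edges used by the 1-HU binning
  tf0 <- mixture_true_features(0, 0, thresholds = 200L)[["200"]]
  want_nl <- 100 * (pnorm(-700.5, -850, 60) - pnorm(-950.5, -850, 60))
  expect_equal(tf0$nl_pct, want_nl, tolerance = 1e-10)

  # all fibrotic: Normal(-300, 150) truncated at +200; little NL-band mass
  tf1 <- mixture_true_features(1, 0, thresholds = 200L)[["200"]]
  z <- pnorm(200, -300, 150)
  want_nl1 <- 100 * (pnorm(-700.5, -300, 150) - pnorm(-950.5, -300, 150)) / z
  expect_equal(tf1$nl_pct, want_nl1, tolerance = 1e-10)
  expect_lt(tf1$nl_pct, 1)
})

test_that("phantom generation is deterministic under a fixed seed", {
  a <- generate_phantom(small_phantom_spec(seed = 61))
  b <- generate_phantom(small_phantom_spec(seed = 61))
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$lung_mask$flags, b$lung_mask$flags)
  c <- generate_phantom(small_phantom_spec(seed = 62))
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("phantom lung histogram totals match the ground-truth mask", {
  ph <- generate_phantom(small_phantom_spec(seed = 63))
  h <- build_histogram(ph$volume, ph$lung_mask)
  expect_equal(sum(h$counts), ph$lung_mask$voxel_count)
})

test_that("phantom spec validation rejects impossible mixtures", {
  expect_error(phantom_spec(fibrosis_fraction = 0.8,
                            emphysema_fraction = 0.4), "sum <= 1")
  expect_error(phantom_spec(grid_shape = c(16, 96, 64)), "at least 32")
})

test_that("fibrosis monotonically erodes the normal-lung percentage", {
  nl <- vapply(seq(0, 0.5, by = 0.1), function(f)
    mixture_true_features(f, 0, thresholds = 200L)[["200"]]$nl_pct,
    numeric(1))
  expect_true(all(diff(nl) < 0))
})

test_that("a fibrosis-free phantom has near-zero lung kurtosis at +200 HU", {
  ph <- generate_phantom(small_phantom_spec(seed = 64, f = 0, e = 0))
  fs <- compute_features(build_histogram(ph$volume, ph$lung_mask), 200)
  expect_lt(abs(fs$kurtosis), 0.15)
})

test_that("pipeline features recover phantom ground truth within 1.5%", {
  ph <- generate_phantom(phantom_spec(seed = 65, fibrosis_fraction = 0.3,
                                      emphysema_fraction = 0.05))
  mask <- segment_lungs(ph$volume)
  fs <- compute_all_thresholds(build_histogram(ph$volume, mask))
  for (th in names(fs)) {
    for (f in c("nl_pct", "laa_pct", "haa_a_pct")) {
      expect_lt(abs(fs[[th]][[f]] - ph$true_features[[th]][[f]]), 1.5)
    }
  }
})

test_that("the HAA_A band captures the fibrotic mixture mass", {
  # fibrosis weight 0.30: the mixture mass in [-600, -250] is dominated by
  # the fibrotic component; the phantom estimate recovers it within 1%
  ph <- generate_phantom(phantom_spec(seed = 66, fibrosis_fraction = 0.3,
                                      emphysema_fraction = 0))
  fs <- compute_features(build_histogram(ph$volume, ph$lung_mask), 200)
  expect_lt(abs(fs$haa_a_pct - ph$true_features[["200"]]$haa_a_pct), 1)
})

test_that("cohort generation is deterministic and respects its links", {
  co1 <- generate_cohort(cohort_spec(seed = 67))
  co2 <- generate_cohort(cohort_spec(seed = 67))
  expect_identical(co1$clinical, co2$clinical)
  expect_identical(co1$features, co2$features)
  expect_equal(nrow(co1$clinical), 32)
  expect_equal(nrow(co1$features), 32 * 3)
  expect_true(all(co1$clinical$fvc_pct_pred > 0))
  expect_true(all(co1$clinical$dlco_pct_pred > 0))
  expect_true(all(co1$features$haa_pct[co1$features$threshold_hu == -200] == 0))
})

test_that("a zero lung-function link decouples NL from FVC", {
  spec0 <- cohort_spec(n_patients = 400L,
                       fvc_link = c(a = log(89), b = 0, shape = 25),
                       seed = 68)
  co <- generate_cohort(spec0)
  nl <- co$features$nl_pct[co$features$threshold_hu == -200]
  expect_lt(abs(cor(nl, co$clinical$fvc_pct_pred)), 0.12)
})

test_that("a positive link yields positive NL-FVC rank correlation", {
  hits <- 0
  for (r in 1:20) {
    co <- generate_cohort(cohort_spec(seed = 700 + r))
    nl <- co$features$nl_pct[co$features$threshold_hu == -200]
    if (cor(nl, co$clinical$fvc_pct_pred, method = "spearman") > 0)
      hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("cohort marginals land near their specified means", {
  co <- generate_cohort(cohort_spec(n_patients = 1000L, seed = 69))
  expect_equal(mean(co$clinical$age_years), 68.3, tolerance = 0.02)
  expect_equal(mean(co$clinical$sex == "male"), 26 / 32, tolerance = 0.05)
  # FVC mean implied by the link at the realized NL values
  nl <- co$features$nl_pct[co$features$threshold_hu == -200]
  want <- mean(exp(3.8386 + 0.010 * nl))
  expect_equal(mean(co$clinical$fvc_pct_pred), want, tolerance = 0.03)
})

test_that("simulated GAP cohorts are reproducible and Poisson-driven", {
  s1 <- simulate_gap_cohort(n = 32, seed = 70)
  s2 <- simulate_gap_cohort(n = 32, seed = 70)
  expect_identical(s1, s2)
  expect_true(all(s1$gap_points >= 0))
  expect_true(all(s1$gap_points == round(s1$gap_points)))
  big <- simulate_gap_cohort(n = 3000, a = 3.7, b = -0.04, seed = 71)
  expect_equal(mean(big$gap_points), mean(exp(3.7 - 0.04 * big$nl_true)),
               tolerance = 0.03)
})
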