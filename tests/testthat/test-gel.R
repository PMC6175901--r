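test_that("ladder calibration demands at least two monotone points", {
  cal <- calibrate_ladder(cbind(c(10, 50), c(250, 10)))
  expect_s3_class(cal, "ladder_calibration")
  expect_error(calibrate_ladder(cbind(10, 250)), class = "abv_error_calibration")
  expect_error(calibrate_ladder(cbind(c(10, 10), c(250, 10))),
               class = "abv_error_calibration")
  expect_error(calibrate_ladder(cbind(c(10, 20, 30), c(250, 300, 10))),
               class = "abv_error_calibration")
})

test_that("apparent MW is log-linear between knots and exact at knots", {
  cal <- calibrate_ladder(cbind(c(10, 30), c(100, 10)))
  # midpoint in migration -> midpoint in log10 MW: 10^1.5
  expect_equal(apparent_mw(cal, 20), 10^1.5, tolerance = 1e-12)
  expect_equal(apparent_mw(cal, c(10, 30)), c(100, 10), tolerance = 1e-12)
  expect_error(apparent_mw(cal, 31), class = "abv_error_range")
  # slope -0.05 log10/mm extended 10 mm past the last knot
  expect_equal(apparent_mw(cal, 40, allow_extrapolation = TRUE), 10^0.5,
               tolerance = 1e-9)
})

test_that("apparent MW strictly decreases in migration on random ladders", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    mig <- sort(runif(n, 5, 60))
    mw <- sort(runif(n, 5, 300), decreasing = TRUE)
    cal <- calibrate_ladder(cbind(mig, mw))
    xs <- seq(min(mig), max(mig), length.out = 60)
    ys <- apparent_mw(cal, xs)
    expect_true(all(diff(ys) < 0))
  }
})

test_that("theoretical MW matches frozen average-mass reference values", {
  # reference masses computed with an independent protein-MW calculator
  expect_equal(theoretical_mw("G"), 0.0750666, tolerance = 2e-5)
  expect_equal(theoretical_mw("PEPTIDE"), 0.7998226, tolerance = 1e-4)
  expect_equal(theoretical_mw("ACDEFGHIKLMNPQRSTVWY"), 2.3957134,
               tolerance = 1e-4)
  expect_equal(theoretical_mw("MKV"), 0.3765146, tolerance = 1e-4)
  expect_error(theoretical_mw(""), class = "abv_error_sequence")
  expect_error(theoretical_mw("ACDX"), class = "abv_error_sequence")
})

test_that("theoretical MW is additive up to one water mass", {
  set.seed(7)
  for (i in 1:20) {
    s1 <- random_protein_sequence(sample(5:80, 1), seed = i)
    s2 <- random_protein_sequence(sample(5:80, 1), seed = 1000 + i)
    expect_equal(theoretical_mw(paste0(s1, s2)),
                 theoretical_mw(s1) + theoretical_mw(s2) - 18.01528 / 1000,
                 tolerance = 1e-9)
  }
})

test_that("a 450-residue chain of human-like composition weighs about 50 kDa", {
  mws <- vapply(1:20, function(i)
    theoretical_mw(random_protein_sequence(450, seed = i)), numeric(1))
  expect_true(all(mws > 44 & mws < 56))
  expect_equal(mean(mws), 50, tolerance = 0.05)
})

test_that("MW histograms conserve counts overall and per class", {
  h <- mw_histogram(c(50, 50, 50), n_bins = 1)
  expect_equal(sum(h$counts), 3)
  set.seed(1)
  mws <- exp(rnorm(1000, log(50), 0.8))
  labels <- sample(c("intracellular", "secreted_or_membrane"), 1000, TRUE)
  h2 <- mw_histogram(mws, labels, n_bins = 25)
  expect_equal(sum(h2$counts), 1000)
  expect_equal(colSums(h2$by_class), h2$counts, ignore_attr = TRUE)
  expect_error(mw_histogram(c(50, -1)), class = "abv_error_value")
})

test_that("dominant band selection applies the clear-separation criteria", {
  d <- dominant_band(make_lane(c(60, 30), c(1000, 100)))
  expect_equal(d$band$apparent_mw_kda, 60)
  expect_true(d$clearly_separated)

  d2 <- dominant_band(make_lane(c(60, 58), c(1000, 900)))
  expect_equal(d2$band$apparent_mw_kda, 60)
  expect_false(d2$clearly_separated)

  d3 <- dominant_band(make_lane(50, 123))
  expect_true(d3$clearly_separated)

  d4 <- dominant_band(make_lane(c(60, 30), c(500, 500)))
  expect_false(d4$clearly_separated)
  expect_match(d4$note, "tie")

  expect_error(dominant_band(lane_profile("a", "s")),
               class = "abv_error_empty_lane")
})

test_that("virtual Westerns sum replicates and locate the modal slice", {
  ss <- toy_slice_set(list(P1 = c(0, 0, 5, 9, 2, 0, 0, 0, 0, 0),
                           P2 = rep(0L, 10),
                           P3 = rbind(c(1, 0, 2, rep(0, 7)),
                                      c(0, 1, 2, rep(0, 7)))))
  vw <- build_virtual_western(ss, "P1")
  expect_equal(vw$modal_slice, 4L)
  expect_true(vw$detected)

  expect_false(build_virtual_western(ss, "P2")$detected)
  expect_equal(build_virtual_western(ss, "P3")$profile,
               c(1, 1, 4, rep(0, 7)))
  # tie breaks toward the lower index (higher MW)
  tie <- toy_slice_set(list(T = c(0, 3, 0, 3, rep(0, 6))))
  expect_equal(build_virtual_western(tie, "T")$modal_slice, 2L)
  expect_error(build_virtual_western(ss, "NOPE"),
               class = "abv_error_not_covered")
})

test_that("capture-MS concordance scores offsets against the slice window", {
  ss <- toy_slice_set(list(P = c(0, 0, 0, 12, 3, 0, 0, 0, 0, 0)))
  # modal slice 4 spans 70-80 kDa in the toy geometry
  cfg <- pillar_config(mw_tolerance_slices = 1)
  hit <- capture_ms_match(75, ss, "P", cfg)
  expect_equal(hit$status, "enhanced")
  expect_equal(hit$metrics$mw_offset_slices, 0)
  expect_equal(hit$metrics$crowding_flag, 0)

  # enumerate every slice center against modal slice 4, tolerance 1:
  # offset <= 1 enhanced, offset 2 uncertain, offset >= 3 not validated
  centers <- (ss$slices$mw_low_kda + ss$slices$mw_high_kda) / 2
  for (j in 1:10) {
    res <- capture_ms_match(centers[j], ss, "P", cfg)
    off <- abs(j - 4)
    expect_equal(res$metrics$mw_offset_slices, off)
    expect_equal(res$status,
                 if (off <= 1) "enhanced" else if (off <= 2) "uncertain"
                 else "not_validated")
  }

  zero <- capture_ms_match(75, toy_slice_set(list(P = rep(0L, 10))), "P", cfg)
  expect_equal(zero$status, "uncertain")

  crowd <- capture_ms_match(45, ss, "P", cfg)
  expect_equal(crowd$metrics$crowding_flag, 1)

  expect_error(capture_ms_match(500, ss, "P", cfg), class = "abv_error_range")
})

test_that("capture-MS honors the one-line-suffices default across cell lines", {
  good <- toy_slice_set(list(P = c(0, 0, 0, 12, 3, 0, 0, 0, 0, 0)), "RT4")
  empty <- toy_slice_set(list(P = rep(0L, 10)), "U-251")
  res <- capture_ms_match(75, list(good, empty), "P")
  expect_equal(res$status, "enhanced")
  res_all <- capture_ms_match(75, list(good, empty), "P",
                              require_all_lines = TRUE)
  expect_equal(res_all$status, "enhanced")  # undetected lines are not offsets
})
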