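test_that("pearson_r matches hand cases and rejects degenerate series", {
  expect_equal(pearson_r(1:4, 1:4), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6)),
               pearson_bruteforce(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 6)),
               tolerance = 1e-12)
  expect_error(pearson_r(c(1, 2), c(1, 2)), class = "abv_error_degenerate")
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)),
               class = "abv_error_degenerate")
})

test_that("fold change uses the pseudocount-stabilized max/min ratio", {
  expect_equal(fold_change(c(2, 10)), 5.0)
  expect_equal(fold_change(c(7, 7, 7)), 1.0)
  expect_equal(fold_change(c(0, 9), pseudocount = 1), 10.0)
  expect_error(fold_change(c(0, 0), pseudocount = 0),
               class = "abv_error_degenerate")
})

test_that("orthogonal validation gates on fold change before correlating", {
  cfg <- pillar_config(pseudocount = 0)
  samples <- paste0("S", 1:8)

  # band tracking the orthogonal series: validated
  orth <- c(1, 2, 4, 8, 16, 32, 64, 128)
  good <- series_pair(orth * 3, orth, samples)
  expect_equal(orthogonal_validate(good, cfg)$status, "enhanced")

  # same band sizes but uncorrelated: not validated
  bad <- series_pair(rev(orth), orth, samples)
  res_bad <- orthogonal_validate(bad, cfg)
  expect_equal(res_bad$status, "not_validated")
  expect_lt(res_bad$metrics$pearson_r, 0.5)

  # low-variability orthogonal series: uncertain no matter the bands
  flat <- series_pair(c(5, 1, 9), c(10, 11, 12), paste0("S", 1:3))
  res_flat <- orthogonal_validate(flat, cfg)
  expect_equal(res_flat$status, "uncertain")
  expect_lt(res_flat$metrics$fold_change, 5)

  # degenerate band series: uncertain, never an error
  flatband <- series_pair(c(2, 2, 2), c(1, 10, 100), paste0("S", 1:3))
  expect_equal(orthogonal_validate(flatband, cfg)$status, "uncertain")

  # missing lanes are dropped pairwise; < 3 survivors -> uncertain
  holey <- series_pair(c(1, NA, 3, NA, 5, NA, 7, NA),
                       c(1, 2, 3, 4, 5, 6, 7, 8), samples)
  expect_equal(orthogonal_validate(holey, cfg)$status, "enhanced")
  holey2 <- series_pair(c(1, NA, 3, NA, NA, NA, NA, NA),
                        c(1, 2, 3, 4, 5, 6, 7, 8), samples)
  expect_equal(orthogonal_validate(holey2, cfg)$status, "uncertain")
})

test_that("correlation threshold is strict at r_min", {
  cfg <- pillar_config(pseudocount = 0)
  # band series built to have an exact Pearson r with the orthogonal
  # series, using a basis vector orthogonal to x
  stub <- function(r) {
    x <- c(0, 1, 2, 3); e <- c(0.5, -1.5, 1.5, -0.5)
    y <- r * scale(x)[, 1] + sqrt(1 - r^2) * scale(e)[, 1]
    series_pair(y - min(y), x * 40 + 1, paste0("S", 1:4))
  }
  for (r in c(0.49, 0.5, 0.51))
    expect_equal(orthogonal_validate(stub(r), cfg)$metrics$pearson_r, r,
                 tolerance = 1e-12)
  expect_equal(orthogonal_validate(stub(0.51), cfg)$status, "enhanced")
  expect_equal(orthogonal_validate(stub(0.50), cfg)$status, "not_validated")
  expect_equal(orthogonal_validate(stub(0.49), cfg)$status, "not_validated")
})

test_that("two-line validation follows fold, trend and size support rules", {
  cfg <- pillar_config(pseudocount = 0)
  pr <- function(rna, bands) series_pair(bands, rna, c("RT4", "U-251"))

  expect_equal(two_line_validate(pr(c(100, 10), c(0.9, 0.1)), FALSE, cfg)$status,
               "enhanced")
  expect_equal(two_line_validate(pr(c(30, 10), c(0.9, 0.1)), TRUE, cfg)$status,
               "enhanced")
  expect_equal(two_line_validate(pr(c(30, 10), c(0.9, 0.1)), FALSE, cfg)$status,
               "uncertain")
  expect_equal(two_line_validate(pr(c(100, 10), c(0.1, 0.9)), FALSE, cfg)$status,
               "not_validated")
  expect_equal(two_line_validate(pr(c(100, 10), c(0, 0)), TRUE, cfg)$status,
               "uncertain")
  # fold exactly at the threshold counts as sufficient (>= fold_min)
  expect_equal(two_line_validate(pr(c(50, 10), c(2, 1)), FALSE, cfg)$status,
               "enhanced")
  expect_error(two_line_validate(series_pair(1:3, 1:3, paste0("S", 1:3))),
               class = "abv_error_usage")
})

test_that("independent-antibody validation compares dominant bands across the panel", {
  panel <- c("RT4", "U-251", "plasma", "liver", "tonsil")
  ints <- c(10, 50, 5, 100, 20)
  lanes_a <- lapply(seq_along(panel), function(i)
    make_lane(55, ints[i], ab = "ab1", sample = panel[i]))
  lanes_b <- lapply(seq_along(panel), function(i)
    make_lane(55, ints[i] * 2.5, ab = "ab2", sample = panel[i]))
  ab1 <- antibody_record("ab1", "AASS", epitope_interval = c(10, 50))
  ab2 <- antibody_record("ab2", "AASS", epitope_interval = c(100, 150))

  res <- independent_validate(lanes_a, lanes_b, ab1, ab2)
  expect_equal(res$status, "enhanced")
  expect_gt(res$metrics$pearson_r, 0.99)

  # overlapping epitopes are not independent
  ab2o <- antibody_record("ab2", "AASS", epitope_interval = c(40, 80))
  expect_equal(independent_validate(lanes_a, lanes_b, ab1, ab2o)$status,
               "uncertain")

  # partner band 20 kDa off in liver: discordant, scored uncertain
  lanes_b2 <- lanes_b
  lanes_b2[[4]] <- make_lane(75, 250, ab = "ab2", sample = "liver")
  res2 <- independent_validate(lanes_a, lanes_b2, ab1, ab2)
  expect_equal(res2$status, "uncertain")
  expect_equal(res2$metrics$discordant_partner, 1)

  # different targets are a usage error
  expect_error(independent_validate(lanes_a, lanes_b, ab1,
                                    antibody_record("ab2", "HNMT",
                                                    epitope_interval = c(100, 150))),
               class = "abv_error_usage")

  # two shared detections: ordering agreement suffices
  res3 <- independent_validate(lanes_a[1:2], lanes_b[1:2], ab1, ab2)
  expect_equal(res3$status, "enhanced")

  # no shared detection anywhere
  empty_b <- lapply(panel, function(s) lane_profile("ab2", s))
  expect_equal(independent_validate(lanes_a, empty_b, ab1, ab2)$status,
               "uncertain")
})

test_that("genetic validation requires strictly more than the knockdown fraction", {
  expect_equal(genetic_validate(1.0, c(0.70, 0.95))$status, "enhanced")
  expect_equal(genetic_validate(1.0, c(0.70, 0.95))$metrics$kd_fraction, 0.30)
  expect_equal(genetic_validate(1.0, c(0.80, 0.85))$status, "uncertain")
  expect_equal(genetic_validate(1.0, 0.75)$status, "uncertain")  # exactly 25%
  expect_equal(genetic_validate(1.0, 0.75, kd_verified = TRUE)$status,
               "not_validated")
  expect_error(genetic_validate(0, 0.5), class = "abv_error_value")
  expect_error(genetic_validate(1, c(0.1, 0.2, 0.3)),
               class = "abv_error_usage")
})

test_that("recombinant validation compares overexpression and control bands", {
  oe <- make_lane(50, 1000, sample = "oe")
  ctrl_none <- lane_profile("ab1", "ctrl")
  expect_equal(recombinant_validate(ctrl_none, oe)$status, "enhanced")

  expect_equal(recombinant_validate(ctrl_none, oe, expressed = FALSE)$status,
               "uncertain")
  expect_equal(recombinant_validate(make_lane(50, 100, sample = "ctrl"),
                                    make_lane(50, 100, sample = "oe"))$status,
               "not_validated")
  expect_equal(recombinant_validate(make_lane(50, 100, sample = "ctrl"),
                                    make_lane(50, 600, sample = "oe"))$status,
               "enhanced")
  expect_equal(recombinant_validate(make_lane(50, 100, sample = "ctrl"),
                                    make_lane(50, 300, sample = "oe"))$status,
               "uncertain")
  expect_equal(recombinant_validate(make_lane(50, 100, sample = "ctrl"),
                                    ctrl_none)$status, "not_validated")
})

test_that("cohort summaries count tails consistently with a brute-force recount", {
  r1 <- validation_report("a", list(pillar_result("orthogonal", "enhanced")))
  r2 <- validation_report("b", list(pillar_result("orthogonal", "enhanced"),
                                    pillar_result("genetic", "enhanced")))
  r3 <- validation_report("c", list(pillar_result("orthogonal", "enhanced"),
                                    pillar_result("genetic", "enhanced"),
                                    pillar_result("capture_ms", "enhanced")))
  s <- summarize_cohort(list(r1, r2, r3))
  expect_equal(unname(s$validated_by_at_least), c(3, 2, 1, 0, 0))

  expect_equal(unname(summarize_cohort(list())$validated_by_at_least),
               rep(0, 5))

  # random cohort vs independent recount
  set.seed(99)
  reports <- lapply(1:40, function(i) {
    picked <- sample(c("orthogonal", "capture_ms", "independent", "genetic",
                       "recombinant"), sample(0:5, 1))
    validation_report(paste0("ab", i), lapply(picked, function(p)
      pillar_result(p, sample(c("enhanced", "uncertain", "not_validated"), 1))))
  })
  s2 <- summarize_cohort(reports)
  recount <- vapply(1:5, function(k)
    sum(vapply(reports, function(r)
      sum(vapply(r$pillar_results, function(p)
        p$status == "enhanced", logical(1))) >= k, logical(1))), numeric(1))
  expect_equal(unname(s2$validated_by_at_least), recount)
  expect_true(all(diff(s2$validated_by_at_least) <= 0))
  expect_equal(sum(s2$per_pillar_enhanced),
               sum(vapply(reports, `[[`, numeric(1), "n_enhanced")))
})

test_that("threshold monotonicity: stricter r_min never upgrades, looser fold_min never downgrades", {
  set.seed(5)
  rank_status <- function(s)
    match(s, c("not_validated", "uncertain", "enhanced"))
  for (i in 1:30) {
    orth <- 2^runif(8, 0, 7)
    bands <- orth * exp(rnorm(8, 0, 0.6))
    pair <- series_pair(bands, orth, paste0("S", 1:8))
    s_loose <- orthogonal_validate(pair, pillar_config(r_min = 0.3))$status
    s_tight <- orthogonal_validate(pair, pillar_config(r_min = 0.7))$status
    if (s_tight == "enhanced") expect_equal(s_loose, "enhanced")
    if (s_loose == "not_validated") expect_equal(s_tight, "not_validated")
    s_lofold <- orthogonal_validate(pair, pillar_config(fold_min = 2))$status
    s_hifold <- orthogonal_validate(pair, pillar_config(fold_min = 50))$status
    if (s_hifold != "uncertain") expect_equal(s_lofold, s_hifold)
  }
})

test_that("orthogonal status is invariant under positive rescaling of either series", {
  set.seed(11)
  cfg <- pillar_config(pseudocount = 0)
  for (i in 1:25) {
    orth <- 2^runif(8, 0, 7)
    bands <- orth * exp(rnorm(8, 0, 0.4))
    base <- orthogonal_validate(series_pair(bands, orth, paste0("S", 1:8)), cfg)
    for (k in c(0.01, 3, 1000)) {
      expect_equal(orthogonal_validate(
        series_pair(bands * k, orth, paste0("S", 1:8)), cfg)$status,
        base$status)
      expect_equal(orthogonal_validate(
        series_pair(bands, orth * k, paste0("S", 1:8)), cfg)$status,
        base$status)
    }
  }
})

test_that("pillar rules return enum statuses, not errors, on degenerate biology", {
  cfg <- pillar_config()
  degenerate <- list(
    orthogonal_validate(series_pair(c(0, 0, 0), c(1, 50, 100),
                                    paste0("S", 1:3)), cfg),
    orthogonal_validate(series_pair(c(1, 2, 3), c(2, 2, 2),
                                    paste0("S", 1:3)), cfg),
    two_line_validate(series_pair(c(0, 0), c(10, 100), c("RT4", "U-251")),
                      config = cfg),
    genetic_validate(1, 1, cfg),
    capture_ms_match(75, toy_slice_set(list(P = rep(0L, 10))), "P", cfg))
  for (res in degenerate)
    expect_true(res$status %in% c("enhanced", "not_validated", "uncertain",
                                  "not_done"))
})
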