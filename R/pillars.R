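# Decision rules for the five validation pillars and their aggregation.

#' Paired antibody/orthogonal abundance series
#'
#' Aligns the dominant-band intensity series for one antibody with an
#' antibody-independent abundance series (TPM, PRM ratio or TMT intensity)
#' over the same samples. Panel mode needs at least 3 samples; the two-line
#' mode exactly 2.
#'
#' @param antibody_band_series nonnegative band intensities per sample
#'   (loading-control normalized where controls exist); NA marks a missing
#'   lane.
#' @param orthogonal_series nonnegative orthogonal abundances per sample.
#' @param sample_ids aligned sample identifiers.
#' @return an object of class `series_pair`.
#' @export
series_pair <- function(antibody_band_series, orthogonal_series, sample_ids) {
  n <- length(sample_ids)
  if (length(antibody_band_series) != n || length(orthogonal_series) != n)
    abv_error("abv_error_format", "series and sample_ids must have equal length")
  if (n < 2)
    abv_error("abv_error_format", "a series pair needs at least 2 samples")
  if (any(antibody_band_series < 0, na.rm = TRUE) ||
      any(orthogonal_series < 0, na.rm = TRUE))
    abv_error("abv_error_value", "series values must be nonnegative")
  structure(list(antibody_band_series = as.numeric(antibody_band_series),
                 orthogonal_series = as.numeric(orthogonal_series),
                 sample_ids = as.character(sample_ids)),
            class = "series_pair")
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r; invariant under positive affine transforms of either
#' series. Series of fewer than 3 points or zero variance raise a
#' degenerate-series error, which the pillar rules map to `uncertain`.
#'
#' @param x,y equal-length numeric series, length >= 3.
#' @return r in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    abv_error("abv_error_degenerate", "need equal-length series of at least 3 points")
  if (anyNA(x) || anyNA(y))
    abv_error("abv_error_degenerate", "series contain missing values")
  if (sd(x) == 0 || sd(y) == 0)
    abv_error("abv_error_degenerate", "zero-variance series")
  cor(x, y, method = "pearson")
}

#' Max/min fold change of a series
#'
#' `(max + pseudocount) / (min + pseudocount)`; scale-invariant when
#' `pseudocount = 0`.
#'
#' @param values nonnegative numeric series (NAs dropped).
#' @param pseudocount nonnegative stabilizer.
#' @return fold change >= 1.
#' @export
fold_change <- function(values, pseudocount = 0) {
  values <- values[!is.na(values)]
  if (!length(values))
    abv_error("abv_error_degenerate", "empty series")
  if (max(values) + pseudocount == 0)
    abv_error("abv_error_degenerate", "all-zero series with zero pseudocount")
  (max(values) + pseudocount) / (min(values) + pseudocount)
}

maybe_log <- function(v, config) {
  if (config$log_transform) log2(v + config$pseudocount) else v
}

#' Orthogonal validation over a cell-line panel
#'
#' Correlates the antibody's dominant-band intensities with an
#' antibody-independent abundance series across a panel of samples. When
#' the orthogonal series varies by less than `fold_min` the correlation is
#' uninformative (low variability forces a low r regardless of antibody
#' specificity) and the pillar is `uncertain`; otherwise the antibody is
#' `enhanced` when r exceeds `r_min` and `not_validated` when it does not.
#'
#' @param pair a [series_pair()] with >= 3 samples; sample pairs with a
#'   missing value in either series are dropped before correlation, and
#'   fewer than 3 surviving pairs yields `uncertain`.
#' @param config a [pillar_config()].
#' @return a [pillar_result()] with pillar `"orthogonal"`; metrics carry
#'   `pearson_r`, `fold_change` and `n_samples`.
#' @export
orthogonal_validate <- function(pair, config = pillar_config()) {
  stopifnot(inherits(pair, "series_pair"))
  keep <- !is.na(pair$antibody_band_series) & !is.na(pair$orthogonal_series)
  x <- pair$antibody_band_series[keep]
  y <- pair$orthogonal_series[keep]
  if (length(x) < 3)
    return(pillar_result("orthogonal", "uncertain",
                         metrics = list(n_samples = length(x)),
                         note = "fewer than 3 samples with paired measurements"))
  fc <- tryCatch(fold_change(y, config$pseudocount),
                 abv_error_degenerate = function(e) NA_real_)
  if (is.na(fc))
    return(pillar_result("orthogonal", "uncertain",
                         metrics = list(n_samples = length(x)),
                         note = "degenerate orthogonal series"))
  if (fc < config$fold_min)
    return(pillar_result("orthogonal", "uncertain",
                         metrics = list(fold_change = fc, n_samples = length(x)),
                         note = "insufficient variability in orthogonal series"))
  r <- tryCatch(pearson_r(maybe_log(x, config), maybe_log(y, config)),
                abv_error_degenerate = function(e) NA_real_)
  if (is.na(r))
    return(pillar_result("orthogonal", "uncertain",
                         metrics = list(fold_change = fc, n_samples = length(x)),
                         note = "degenerate band series"))
  status <- if (r > config$r_min) "enhanced" else "not_validated"
  pillar_result("orthogonal", status,
                metrics = list(pearson_r = r, fold_change = fc,
                               n_samples = length(x)))
}

#' Orthogonal validation in the standardized two-cell-line assay
#'
#' The standardized assay compares exactly two cell lines (an RT4/U-251
#' style pair). With at least a `fold_min` difference in the orthogonal
#' (RNA) levels and band intensities ordered the same way, the antibody is
#' `enhanced`. Below `fold_min` the trend may still validate if the band
#' ordering agrees and the band size is independently supported
#' (`size_supported`, e.g. by theoretical MW or capture MS). Contradictory
#' ordering is `not_validated`; anything else `uncertain`.
#'
#' @param pair a [series_pair()] with exactly 2 samples.
#' @param size_supported logical: the band size is confirmed by theoretical
#'   MW or capture MS.
#' @param config a [pillar_config()].
#' @return a [pillar_result()] with pillar `"orthogonal"`.
#' @export
two_line_validate <- function(pair, size_supported = FALSE,
                              config = pillar_config()) {
  stopifnot(inherits(pair, "series_pair"))
  if (length(pair$sample_ids) != 2)
    abv_error("abv_error_usage", "two-line mode needs exactly 2 samples")
  b <- pair$antibody_band_series; o <- pair$orthogonal_series
  if (all(is.na(b) | b == 0))
    return(pillar_result("orthogonal", "uncertain",
                         note = "no band detected in either sample"))
  if (anyNA(b) || anyNA(o))
    return(pillar_result("orthogonal", "uncertain",
                         note = "missing measurement in one sample"))
  fc <- fold_change(o, config$pseudocount)
  ord_o <- sign(o[1] - o[2]); ord_b <- sign(b[1] - b[2])
  metrics <- list(fold_change = fc)
  if (ord_o == 0 || ord_b == 0)
    return(pillar_result("orthogonal", "uncertain", metrics = metrics,
                         note = "tied values give no trend"))
  if (ord_o != ord_b)
    return(pillar_result("orthogonal", "not_validated", metrics = metrics,
                         note = "band ordering contradicts orthogonal levels"))
  if (fc >= config$fold_min)
    return(pillar_result("orthogonal", "enhanced", metrics = metrics))
  if (size_supported)
    return(pillar_result("orthogonal", "enhanced", metrics = metrics,
                         note = "trend concordant and band size supported"))
  pillar_result("orthogonal", "uncertain", metrics = metrics,
                note = "concordant trend but fold below threshold and size unsupported")
}

#' Independent-antibody validation
#'
#' Compares the staining pattern of two antibodies against the same target
#' across a standard sample panel (typically two cell lines, plasma, and
#' two tissue extracts). The antibodies must have non-overlapping epitopes
#' to count as independent. The pair is `enhanced` when, in every sample
#' where both detect a band, the dominant-band MWs agree within
#' `mw_gap_log10` and the across-sample intensity profiles agree (Pearson
#' r above `r_min` with >= 3 shared detections, or matching ordering with
#' exactly 2). Discordant dominant-band sizes mark non-specific staining of
#' the partner and score `uncertain` with a `discordant_partner` flag.
#'
#' @param lanes_a,lanes_b lists of [lane_profile()] for the two antibodies
#'   over the same samples.
#' @param ab_a,ab_b [antibody_record()]s sharing `target_gene`.
#' @param config a [pillar_config()].
#' @return a [pillar_result()] with pillar `"independent"`.
#' @export
independent_validate <- function(lanes_a, lanes_b, ab_a, ab_b,
                                 config = pillar_config()) {
  if (ab_a$target_gene != ab_b$target_gene)
    abv_error("abv_error_usage", "antibodies target different genes")
  ea <- ab_a$epitope_interval; eb <- ab_b$epitope_interval
  if (!is.null(ea) && !is.null(eb) && ea[1] <= eb[2] && eb[1] <= ea[2])
    return(pillar_result("independent", "uncertain",
                         note = "overlapping epitopes: antibodies are not independent"))
  norm_int <- function(lane, d) {
    i <- d$band$intensity
    if (!is.null(lane$loading_control_intensity))
      i <- i / lane$loading_control_intensity
    i
  }
  ids_a <- vapply(lanes_a, `[[`, character(1), "sample_id")
  ids_b <- vapply(lanes_b, `[[`, character(1), "sample_id")
  shared <- intersect(ids_a, ids_b)
  mw_a <- mw_b <- int_a <- int_b <- numeric(0)
  for (s in shared) {
    la <- lanes_a[[match(s, ids_a)]]; lb <- lanes_b[[match(s, ids_b)]]
    if (!length(la$bands) || !length(lb$bands)) next
    da <- dominant_band(la, config); db <- dominant_band(lb, config)
    mw_a <- c(mw_a, da$band$apparent_mw_kda)
    mw_b <- c(mw_b, db$band$apparent_mw_kda)
    int_a <- c(int_a, norm_int(la, da)); int_b <- c(int_b, norm_int(lb, db))
  }
  n <- length(mw_a)
  if (n == 0)
    return(pillar_result("independent", "uncertain",
                         note = "no sample where both antibodies detect a band"))
  mw_ok <- abs(log10(mw_a) - log10(mw_b)) <= config$mw_gap_log10
  max_gap <- max(abs(log10(mw_a) - log10(mw_b)))
  if (!all(mw_ok))
    return(pillar_result("independent", "uncertain",
                         metrics = list(discordant_partner = 1,
                                        n_shared = n, max_mw_gap_log10 = max_gap),
                         note = "non-specific staining of the paired antibody (dominant-band size disagrees)"))
  if (n >= 3) {
    r <- tryCatch(pearson_r(int_a, int_b),
                  abv_error_degenerate = function(e) NA_real_)
    if (!is.na(r) && r > config$r_min)
      return(pillar_result("independent", "enhanced",
                           metrics = list(pearson_r = r, n_shared = n)))
    return(pillar_result("independent", "uncertain",
                         metrics = list(pearson_r = r, n_shared = n),
                         note = "staining profiles weakly correlated"))
  }
  if (n == 2) {
    if (sign(int_a[1] - int_a[2]) != 0 &&
        sign(int_a[1] - int_a[2]) == sign(int_b[1] - int_b[2]))
      return(pillar_result("independent", "enhanced",
                           metrics = list(n_shared = n)))
    return(pillar_result("independent", "uncertain",
                         metrics = list(n_shared = n),
                         note = "intensity ordering disagrees or is tied"))
  }
  pillar_result("independent", "uncertain",
                metrics = list(n_shared = n),
                note = "single shared detection: size agrees but profile untestable")
}

#' Genetic (siRNA knockdown) validation
#'
#' Compares loading-control-normalized dominant-band intensity before and
#' after knockdown with up to two siRNA reagents. At least one reagent must
#' reduce the band by strictly more than `kd_min_fraction` (default 25%).
#' Failure maps to `uncertain` because an unresponsive band is usually a
#' failed knockdown rather than a non-specific antibody; set
#' `kd_verified = TRUE` when knockdown efficacy was independently confirmed
#' to remap failure to `not_validated`.
#'
#' @param control_intensity band intensity before knockdown (positive).
#' @param kd_intensities 1-2 nonnegative band intensities after knockdown.
#' @param config a [pillar_config()].
#' @param kd_verified independent evidence that the knockdown worked.
#' @return a [pillar_result()] with pillar `"genetic"`; metric
#'   `kd_fraction` is the best (largest) reduction fraction.
#' @export
genetic_validate <- function(control_intensity, kd_intensities,
                             config = pillar_config(), kd_verified = FALSE) {
  if (is.na(control_intensity) || control_intensity <= 0)
    abv_error("abv_error_value", "control intensity must be positive")
  if (!length(kd_intensities) || length(kd_intensities) > 2)
    abv_error("abv_error_usage", "provide 1 or 2 knockdown intensities")
  if (any(kd_intensities < 0))
    abv_error("abv_error_value", "knockdown intensities must be nonnegative")
  reduction <- 1 - min(kd_intensities) / control_intensity
  if (reduction > config$kd_min_fraction)
    return(pillar_result("genetic", "enhanced",
                         metrics = list(kd_fraction = reduction)))
  pillar_result("genetic",
                if (kd_verified) "not_validated" else "uncertain",
                metrics = list(kd_fraction = reduction),
                note = if (kd_verified)
                  "band unresponsive despite verified knockdown"
                else
                  "band reduction below threshold; siRNA efficacy unverified")
}

#' Recombinant-overexpression validation
#'
#' Compares matched lanes with and without recombinant expression of the
#' target. When the recombinant line failed to express, the result is
#' `uncertain`. Otherwise the antibody is `enhanced` when the dominant
#' overexpression band is at least `oe_min_ratio` times the corresponding
#' control band (an absent control band contributes only the pseudocount),
#' and `not_validated` when the control band is as strong as or stronger
#' than the overexpression band.
#'
#' @param control_lane,oe_lane [lane_profile()]s from matched samples.
#' @param expressed logical: the recombinant line expressed the target.
#' @param config a [pillar_config()].
#' @return a [pillar_result()] with pillar `"recombinant"`; metric
#'   `oe_ratio`.
#' @export
recombinant_validate <- function(control_lane, oe_lane, expressed = TRUE,
                                 config = pillar_config()) {
  if (!expressed)
    return(pillar_result("recombinant", "uncertain",
                         note = "no expression in the recombinant cell line"))
  if (!length(oe_lane$bands))
    return(pillar_result("recombinant", "not_validated",
                         note = "no band despite recombinant expression"))
  d_oe <- dominant_band(oe_lane, config)
  oe_int <- d_oe$band$intensity
  oe_mw <- d_oe$band$apparent_mw_kda
  ctrl_int <- config$pseudocount
  if (length(control_lane$bands)) {
    mws <- vapply(control_lane$bands, `[[`, numeric(1), "apparent_mw_kda")
    near <- which(abs(log10(mws) - log10(oe_mw)) <= config$mw_gap_log10)
    if (length(near))
      ctrl_int <- max(vapply(control_lane$bands[near], `[[`, numeric(1),
                             "intensity"))
  }
  ratio <- oe_int / max(ctrl_int, config$pseudocount, .Machine$double.eps)
  if (ctrl_int >= oe_int)
    return(pillar_result("recombinant", "not_validated",
                         metrics = list(oe_ratio = ratio),
                         note = "control band as strong as overexpression band"))
  if (oe_int >= config$oe_min_ratio * ctrl_int)
    return(pillar_result("recombinant", "enhanced",
                         metrics = list(oe_ratio = ratio)))
  pillar_result("recombinant", "uncertain",
                metrics = list(oe_ratio = ratio),
                note = "overexpression enrichment below threshold")
}

#' Aggregate pillar results into a per-antibody report
#'
#' Missing pillars are scored `not_done`; `n_enhanced` counts pillars with
#' status `enhanced` (0-5).
#'
#' @param antibody_id identifier.
#' @param results list of [pillar_result()], at most one per pillar.
#' @return a [validation_report()].
#' @export
aggregate_pillars <- function(antibody_id, results = list()) {
  validation_report(antibody_id, results)
}

#' Cohort-level summary of validation reports
#'
#' @param reports list of [validation_report()].
#' @return list with `n_antibodies`, `validated_by_at_least` (named vector
#'   for k = 1..5, antibodies with `n_enhanced >= k`), and
#'   `per_pillar_enhanced` (named vector of per-pillar enhanced counts).
#' @export
summarize_cohort <- function(reports) {
  n_enh <- vapply(reports, `[[`, numeric(1), "n_enhanced")
  at_least <- vapply(1:5, function(k) sum(n_enh >= k), numeric(1))
  names(at_least) <- paste0(">=", 1:5)
  per_pillar <- vapply(PILLARS, function(p)
    sum(vapply(reports, function(r)
      r$pillar_results[[p]]$status == "enhanced", logical(1))), numeric(1))
  list(n_antibodies = length(reports),
       validated_by_at_least = at_least,
       per_pillar_enhanced = per_pillar)
}
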