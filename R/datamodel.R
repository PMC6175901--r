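#' @importFrom stats cor sd rnorm runif rpois setNames approx quantile
#' @importFrom utils read.delim write.table head
NULL

PILLARS  <- c("orthogonal", "capture_ms", "independent", "genetic", "recombinant")
STATUSES <- c("enhanced", "not_validated", "uncertain", "not_done")
SAMPLE_KINDS <- c("cell_line", "tissue", "plasma")
MEASUREMENT_KINDS <- c("tpm", "prm_ratio", "tmt_intensity", "band_intensity")

#' Abundance panel (genes x samples)
#'
#' A quantification matrix holding one measurement kind: RNA-seq TPM, PRM
#' ratio-to-standard, TMT median intensity, or Western band intensity.
#' Gene identifiers are treated as opaque strings; no identifier mapping is
#' performed.
#'
#' @param values numeric matrix, genes in rows, samples in columns; all
#'   values must be nonnegative. Row names are gene identifiers, column
#'   names sample identifiers (both may instead be given via `genes` /
#'   `samples`).
#' @param measurement_kind one of `"tpm"`, `"prm_ratio"`, `"tmt_intensity"`,
#'   `"band_intensity"`.
#' @param genes optional character vector of gene identifiers.
#' @param samples optional data.frame with columns `sample_id` and `kind`
#'   (`cell_line`, `tissue` or `plasma`), or a character vector of sample
#'   identifiers (kind defaults to `cell_line`).
#' @param replicate_sd optional matrix of replicate standard deviations,
#'   same shape as `values`.
#' @return an object of class `abundance_panel`.
#' @export
abundance_panel <- function(values, measurement_kind,
                            genes = rownames(values),
                            samples = colnames(values),
                            replicate_sd = NULL) {
  measurement_kind <- match.arg(measurement_kind, MEASUREMENT_KINDS)
  values <- as.matrix(values)
  if (is.null(genes)) abv_error("abv_error_format", "gene identifiers are required")
  genes <- as.character(genes)
  if (is.character(samples) || is.null(samples)) {
    if (is.null(samples)) samples <- paste0("S", seq_len(ncol(values)))
    samples <- data.frame(sample_id = as.character(samples),
                          kind = "cell_line", stringsAsFactors = FALSE)
  }
  if (!all(c("sample_id", "kind") %in% names(samples)))
    abv_error("abv_error_format", "samples must have columns sample_id and kind")
  if (any(!nzchar(samples$sample_id)) || anyDuplicated(samples$sample_id))
    abv_error("abv_error_format", "sample ids must be nonempty and unique")
  if (!all(samples$kind %in% SAMPLE_KINDS))
    stopf("abv_error_format", "unknown sample kind: %s",
          paste(setdiff(samples$kind, SAMPLE_KINDS), collapse = ", "))
  if (length(genes) != nrow(values) || nrow(samples) != ncol(values))
    abv_error("abv_error_format", "matrix dimensions inconsistent with gene/sample lists")
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stopf("abv_error_duplicate_key", "duplicate gene identifier(s): %s",
          paste(unique(dup), collapse = ", "))
  if (!is.numeric(values) || anyNA(values))
    abv_error("abv_error_value", "abundance values must be numeric and non-missing")
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1, ]
    stopf("abv_error_value", "negative value at gene '%s', sample '%s'",
          genes[idx[1]], samples$sample_id[idx[2]])
  }
  if (!is.null(replicate_sd)) {
    replicate_sd <- as.matrix(replicate_sd)
    if (!identical(dim(replicate_sd), dim(values)))
      abv_error("abv_error_format", "replicate_sd must match the shape of values")
  }
  dimnames(values) <- list(genes, samples$sample_id)
  structure(list(values = values, measurement_kind = measurement_kind,
                 samples = samples, replicate_sd = replicate_sd),
            class = "abundance_panel")
}

#' @export
print.abundance_panel <- function(x, ...) {
  cat(sprintf("Abundance panel [%s]: %d genes x %d samples\n",
              x$measurement_kind, nrow(x$values), ncol(x$values)))
  cat("  samples:", paste(x$samples$sample_id, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_panel <- function(x) dim(x$values)

#' A single Western blot band
#'
#' Exactly one of `apparent_mw_kda` or `migration` must be given at load
#' time; migration distances are resolved to apparent molecular weight
#' through a [ladder_calibration()].
#'
#' @param apparent_mw_kda apparent molecular weight in kDa (positive).
#' @param migration migration distance in the gel's units (positive).
#' @param intensity nonnegative densitometry intensity (arbitrary units).
#' @return an object of class `band`.
#' @export
band <- function(apparent_mw_kda = NULL, migration = NULL, intensity) {
  has_mw  <- !is.null(apparent_mw_kda) && !is.na(apparent_mw_kda)
  has_mig <- !is.null(migration) && !is.na(migration)
  if (has_mw && has_mig)
    abv_error("abv_error_format", "a band may carry either apparent MW or migration, not both")
  if (!has_mw && !has_mig)
    abv_error("abv_error_format", "a band needs either apparent MW or migration")
  if (has_mw && apparent_mw_kda <= 0)
    abv_error("abv_error_value", "apparent_mw_kda must be positive")
  if (has_mig && migration <= 0)
    abv_error("abv_error_value", "migration must be positive")
  if (is.na(intensity) || intensity < 0)
    abv_error("abv_error_value", "band intensity must be nonnegative")
  structure(list(apparent_mw_kda = if (has_mw) as.numeric(apparent_mw_kda) else NA_real_,
                 migration = if (has_mig) as.numeric(migration) else NA_real_,
                 intensity = as.numeric(intensity)),
            class = "band")
}

#' One antibody's lane over one sample
#'
#' Bands are stored sorted by descending apparent molecular weight (top of
#' the gel first). The optional loading-control intensity (e.g.
#' alpha-tubulin or PSMA1) is used to normalize band intensities before
#' cross-sample comparison.
#'
#' @param antibody_id,sample_id identifiers.
#' @param bands list of [band()] objects with resolved apparent MW.
#' @param loading_control_intensity optional positive real.
#' @return an object of class `lane_profile`.
#' @export
lane_profile <- function(antibody_id, sample_id, bands = list(),
                         loading_control_intensity = NULL) {
  stopifnot(is.character(antibody_id), is.character(sample_id))
  if (!all(vapply(bands, inherits, logical(1), "band")))
    abv_error("abv_error_format", "bands must be a list of band objects")
  mws <- vapply(bands, `[[`, numeric(1), "apparent_mw_kda")
  if (anyNA(mws))
    abv_error("abv_error_configuration",
              "all bands must have apparent MW resolved before building a lane")
  bands <- bands[order(-mws)]
  if (!is.null(loading_control_intensity) &&
      (is.na(loading_control_intensity) || loading_control_intensity <= 0))
    abv_error("abv_error_value", "loading_control_intensity must be positive")
  structure(list(antibody_id = antibody_id, sample_id = sample_id,
                 bands = bands,
                 loading_control_intensity = loading_control_intensity),
            class = "lane_profile")
}

#' @export
print.lane_profile <- function(x, ...) {
  cat(sprintf("Lane %s / %s: %d band(s)\n", x$antibody_id, x$sample_id,
              length(x$bands)))
  for (b in x$bands)
    cat(sprintf("  %7.2f kDa  intensity %g\n", b$apparent_mw_kda, b$intensity))
  invisible(x)
}

#' Antibody metadata
#'
#' @param antibody_id identifier.
#' @param target_gene gene identifier (opaque string, HGNC symbol in the
#'   bundled fixtures).
#' @param epitope_interval optional integer pair `c(start_aa, end_aa)`,
#'   1-based inclusive amino-acid positions.
#' @param application free-text application tag (default `"western_blot"`).
#' @return an object of class `antibody_record`.
#' @export
antibody_record <- function(antibody_id, target_gene, epitope_interval = NULL,
                            application = "western_blot") {
  if (!is.null(epitope_interval)) {
    if (length(epitope_interval) != 2 || any(epitope_interval < 1) ||
        epitope_interval[1] > epitope_interval[2])
      abv_error("abv_error_value",
                "epitope_interval must be c(start_aa, end_aa) with start <= end, 1-based")
    epitope_interval <- as.integer(epitope_interval)
  }
  structure(list(antibody_id = antibody_id, target_gene = target_gene,
                 epitope_interval = epitope_interval, application = application),
            class = "antibody_record")
}

#' Decision thresholds for the five validation pillars
#'
#' Defaults follow the published decision rules: Pearson correlation above
#' 0.5, at least a fivefold spread in the orthogonal series, knockdown of
#' more than 25 percent, a fivefold overexpression ratio. The remaining
#' knobs parameterize steps the procedure leaves open.
#'
#' @param r_min Pearson correlation threshold (strict `>`), in (0, 1).
#' @param fold_min minimum max/min fold-change of the orthogonal series
#'   required for an unambiguous correlation call; below it the pillar is
#'   `uncertain` (insufficient variability).
#' @param kd_min_fraction knockdown fraction that must be exceeded
#'   (strict `>`), in (0, 1).
#' @param dominance_ratio the dominant band must be at least this many times
#'   the second-strongest band to count as clearly separated.
#' @param mw_tolerance_slices capture-MS concordance window: band slice may
#'   be at most this many slices from the modal peptide slice.
#' @param oe_min_ratio overexpressed band must be at least this many times
#'   the control band.
#' @param pseudocount added to numerator and denominator of fold changes
#'   (and inside the optional log transform) to tame zeros.
#' @param log_transform correlate on log2(value + pseudocount) instead of
#'   the linear scale.
#' @param mw_gap_log10 log10-MW gap used both as the separation requirement
#'   between the dominant and nearest other band, and as the tolerance for
#'   calling two antibodies' dominant bands "the same size".
#' @return an object of class `pillar_config`.
#' @export
pillar_config <- function(r_min = 0.5, fold_min = 5.0, kd_min_fraction = 0.25,
                          dominance_ratio = 2.0, mw_tolerance_slices = 1L,
                          oe_min_ratio = 5.0, pseudocount = 0.1,
                          log_transform = FALSE, mw_gap_log10 = 0.05) {
  if (r_min <= 0 || r_min >= 1)
    abv_error("abv_error_value", "r_min must lie in (0, 1)")
  if (fold_min <= 1)
    abv_error("abv_error_value", "fold_min must exceed 1")
  if (kd_min_fraction <= 0 || kd_min_fraction >= 1)
    abv_error("abv_error_value", "kd_min_fraction must lie in (0, 1)")
  if (pseudocount < 0)
    abv_error("abv_error_value", "pseudocount must be nonnegative")
  if (mw_tolerance_slices < 0)
    abv_error("abv_error_value", "mw_tolerance_slices must be nonnegative")
  structure(list(r_min = r_min, fold_min = fold_min,
                 kd_min_fraction = kd_min_fraction,
                 dominance_ratio = dominance_ratio,
                 mw_tolerance_slices = as.integer(mw_tolerance_slices),
                 oe_min_ratio = oe_min_ratio, pseudocount = pseudocount,
                 log_transform = isTRUE(log_transform),
                 mw_gap_log10 = mw_gap_log10),
            class = "pillar_config")
}

#' @export
print.pillar_config <- function(x, ...) {
  cat("Pillar configuration:\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' One pillar's validation outcome
#'
#' @param pillar one of `"orthogonal"`, `"capture_ms"`, `"independent"`,
#'   `"genetic"`, `"recombinant"`.
#' @param status one of `"enhanced"`, `"not_validated"`, `"uncertain"`,
#'   `"not_done"`.
#' @param metrics named list of reals produced by the decision (e.g.
#'   `pearson_r`, `fold_change`, `kd_fraction`, `mw_offset_slices`).
#' @param note free text explaining the call.
#' @return an object of class `pillar_result`.
#' @export
pillar_result <- function(pillar, status, metrics = list(), note = "") {
  pillar <- match.arg(pillar, PILLARS)
  status <- match.arg(status, STATUSES)
  structure(list(pillar = pillar, status = status,
                 metrics = metrics, note = note),
            class = "pillar_result")
}

#' @export
print.pillar_result <- function(x, ...) {
  cat(sprintf("[%s] %s", x$pillar, x$status))
  if (length(x$metrics)) {
    m <- vapply(x$metrics, function(v) format(v, digits = 4), character(1))
    cat("  (", paste(names(m), m, sep = "=", collapse = ", "), ")", sep = "")
  }
  if (nzchar(x$note)) cat("  --", x$note)
  cat("\n")
  invisible(x)
}

#' Per-antibody validation report across the five pillars
#'
#' @param antibody_id identifier.
#' @param pillar_results list of [pillar_result()], at most one per pillar;
#'   missing pillars are recorded as `not_done`.
#' @return an object of class `validation_report` with slots for all five
#'   pillars and `n_enhanced`, the count of pillars scored `enhanced`.
#' @export
validation_report <- function(antibody_id, pillar_results = list()) {
  if (inherits(pillar_results, "pillar_result"))
    pillar_results <- list(pillar_results)
  got <- vapply(pillar_results, `[[`, character(1), "pillar")
  if (anyDuplicated(got))
    stopf("abv_error_usage", "duplicate pillar result(s): %s",
          paste(unique(got[duplicated(got)]), collapse = ", "))
  slots <- setNames(vector("list", length(PILLARS)), PILLARS)
  for (p in PILLARS) slots[[p]] <- pillar_result(p, "not_done")
  for (r in pillar_results) slots[[r$pillar]] <- r
  n_enh <- sum(vapply(slots, function(r) r$status == "enhanced", logical(1)))
  structure(list(antibody_id = antibody_id, pillar_results = slots,
                 n_enhanced = n_enh),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report for %s (%d/5 pillars enhanced)\n",
              x$antibody_id, x$n_enhanced))
  for (r in x$pillar_results) print(r)
  invisible(x)
}

#' @export
summary.validation_report <- function(object, ...) {
  st <- vapply(object$pillar_results, `[[`, character(1), "status")
  out <- data.frame(antibody_id = object$antibody_id,
                    t(st), n_enhanced = object$n_enhanced,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}
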