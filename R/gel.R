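# SDS-PAGE surrogate: ladder calibration, molecular weights, dominant-band
# analysis, virtual Westerns and the capture-MS concordance pillar.

# Average (not monoisotopic) residue masses in Da; gel-scale physics works
# with average masses. One water is added per chain.
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01528

# Approximate human proteome amino-acid frequencies, used by the synthetic
# generators to draw sequences of realistic average composition.
AA_FREQ_HUMAN <- c(
  A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023, E = 0.071,
  Q = 0.048, G = 0.066, H = 0.026, I = 0.043, L = 0.100, K = 0.057,
  M = 0.021, F = 0.037, P = 0.063, S = 0.083, T = 0.054, W = 0.012,
  Y = 0.027, V = 0.060)

#' Calibrate a molecular-weight ladder
#'
#' Fits the standard SDS-PAGE migration model: apparent molecular weight is
#' log10-linear in migration distance, interpolated piecewise between ladder
#' knots. Migration must strictly increase while MW strictly decreases
#' (smaller proteins run further).
#'
#' @param points two-column matrix or data.frame `(migration, mw_kda)` with
#'   at least two rows.
#' @return an object of class `ladder_calibration`.
#' @export
calibrate_ladder <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2)
    abv_error("abv_error_calibration", "a ladder needs at least two points")
  o <- order(points[, 1])
  mig <- points[o, 1]; mw <- points[o, 2]
  if (any(mig <= 0) || any(mw <= 0))
    abv_error("abv_error_calibration", "migration and MW must be positive")
  if (any(diff(mig) <= 0) || any(diff(mw) >= 0))
    abv_error("abv_error_calibration",
              "ladder must have strictly increasing migration and strictly decreasing MW")
  structure(list(migration = mig, log10_mw = log10(mw)),
            class = "ladder_calibration")
}

#' Apparent molecular weight from migration distance
#'
#' @param calibration a [calibrate_ladder()] result.
#' @param migration migration distance(s); must lie within the calibrated
#'   range unless `allow_extrapolation = TRUE`.
#' @param allow_extrapolation extend the flanking segments linearly in
#'   log10 MW beyond the ladder (off by default).
#' @return apparent MW in kDa, strictly decreasing in migration.
#' @export
apparent_mw <- function(calibration, migration, allow_extrapolation = FALSE) {
  stopifnot(inherits(calibration, "ladder_calibration"))
  rng <- range(calibration$migration)
  if (!allow_extrapolation && any(migration < rng[1] | migration > rng[2]))
    stopf("abv_error_range",
          "migration outside calibrated range [%g, %g]", rng[1], rng[2])
  lg <- approx(calibration$migration, calibration$log10_mw, xout = migration,
               rule = if (allow_extrapolation) 2 else 1)$y
  if (allow_extrapolation) {
    # rule = 2 clamps; extend the end segments instead
    below <- migration < rng[1]; above <- migration > rng[2]
    if (any(below)) {
      s <- diff(calibration$log10_mw[1:2]) / diff(calibration$migration[1:2])
      lg[below] <- calibration$log10_mw[1] + s * (migration[below] - rng[1])
    }
    if (any(above)) {
      n <- length(calibration$migration)
      s <- diff(calibration$log10_mw[(n - 1):n]) /
        diff(calibration$migration[(n - 1):n])
      lg[above] <- calibration$log10_mw[n] + s * (migration[above] - rng[2])
    }
  }
  10^lg
}

#' Theoretical molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water, in kDa; no post-
#' translational modifications are considered.
#'
#' @param sequence character vector of amino-acid strings over the 20
#'   standard one-letter codes.
#' @return numeric vector of molecular weights in kDa.
#' @export
theoretical_mw <- function(sequence) {
  vapply(sequence, function(s) {
    if (is.na(s) || !nzchar(s))
      abv_error("abv_error_sequence", "empty protein sequence")
    aa <- strsplit(toupper(s), "")[[1]]
    bad <- setdiff(aa, names(AA_AVG_MASS))
    if (length(bad))
      stopf("abv_error_sequence", "unknown amino-acid letter(s): %s",
            paste(unique(bad), collapse = ", "))
    (sum(AA_AVG_MASS[aa]) + WATER_MASS) / 1000
  }, numeric(1), USE.NAMES = !is.null(names(sequence)))
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper around `Biostrings::readAAStringSet`; returns plain
#' character sequences named by the first token of each FASTA header.
#' Choosing which isoform (e.g. the largest transcript) to supply is the
#' caller's responsibility.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1)
  seqs
}

#' Histogram of molecular weights on the log2 scale
#'
#' Bins `log2(mw)` into `n_bins` equal-width bins spanning the observed
#' range; counts are conserved exactly. When per-protein class labels are
#' given (e.g. intracellular vs secreted/membrane), per-class counts over
#' the same bins are returned as well.
#'
#' @param mws positive molecular weights in kDa.
#' @param labels optional character vector of class labels, same length.
#' @param n_bins number of bins.
#' @return an object of class `mw_histogram` with `breaks` (log2 kDa),
#'   `counts`, and optionally `by_class` (matrix classes x bins).
#' @export
mw_histogram <- function(mws, labels = NULL, n_bins = 30) {
  if (any(mws <= 0) || anyNA(mws))
    abv_error("abv_error_value", "molecular weights must be positive")
  lg <- log2(mws)
  rng <- range(lg)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(lg, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  by_class <- NULL
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(mws))
    cls <- sort(unique(labels))
    by_class <- t(vapply(cls, function(cl)
      tabulate(bin[labels == cl], nbins = n_bins), integer(n_bins)))
    rownames(by_class) <- cls
  }
  structure(list(breaks = breaks, counts = counts, by_class = by_class),
            class = "mw_histogram")
}

#' @export
plot.mw_histogram <- function(x, main = "Molecular weight distribution", ...) {
  mids <- (head(x$breaks, -1) + x$breaks[-1]) / 2
  if (is.null(x$by_class)) {
    graphics::barplot(x$counts, names.arg = round(mids, 1),
                      xlab = "log2 MW (kDa)", ylab = "proteins", main = main, ...)
  } else {
    graphics::barplot(x$by_class, names.arg = round(mids, 1), beside = FALSE,
                      legend.text = rownames(x$by_class),
                      xlab = "log2 MW (kDa)", ylab = "proteins", main = main, ...)
  }
  invisible(x)
}

#' Dominant band of a lane and its separation call
#'
#' Only the strongest stained band in a lane is eligible for validation,
#' and it must be clearly separated from any weaker bands: its intensity at
#' least `dominance_ratio` times the second strongest, and its log10-MW gap
#' to the nearest other band at least `mw_gap_log10`. A tie in maximum
#' intensity yields `clearly_separated = FALSE` with a tie note.
#'
#' @param lane a [lane_profile()] with at least one band.
#' @param config a [pillar_config()].
#' @return list with `band` (the max-intensity [band()]),
#'   `clearly_separated` (logical) and `note`.
#' @export
dominant_band <- function(lane, config = pillar_config()) {
  stopifnot(inherits(lane, "lane_profile"))
  if (!length(lane$bands))
    abv_error("abv_error_empty_lane", "lane has no bands")
  ints <- vapply(lane$bands, `[[`, numeric(1), "intensity")
  mws  <- vapply(lane$bands, `[[`, numeric(1), "apparent_mw_kda")
  i <- which.max(ints)
  if (length(ints) == 1L)
    return(list(band = lane$bands[[i]], clearly_separated = TRUE, note = ""))
  if (sum(ints == ints[i]) > 1L)
    return(list(band = lane$bands[[i]], clearly_separated = FALSE,
                note = "tie in maximum intensity"))
  second <- max(ints[-i])
  gap <- min(abs(log10(mws[i]) - log10(mws[-i])))
  sep <- ints[i] >= config$dominance_ratio * second && gap >= config$mw_gap_log10
  list(band = lane$bands[[i]], clearly_separated = sep,
       note = if (sep) "" else "dominant band not clearly separated")
}

#' Gel slice set from a capture-MS experiment
#'
#' An ordered set of gel slices (slice 1 at the top of the gel, highest MW)
#' with explicit per-slice MW ranges, and per-protein peptide counts,
#' optionally per replicate.
#'
#' @param cell_line sample identifier the lane was cut from.
#' @param slices data.frame with columns `index`, `mw_low_kda`,
#'   `mw_high_kda`; ranges must be non-overlapping and ordered high to low.
#' @param counts named list: protein -> integer matrix (replicates x
#'   slices) or vector (one replicate) of nonnegative peptide counts.
#' @return an object of class `slice_set`.
#' @export
slice_set <- function(cell_line, slices, counts) {
  slices <- as.data.frame(slices)
  stopifnot(all(c("index", "mw_low_kda", "mw_high_kda") %in% names(slices)))
  slices <- slices[order(slices$index), , drop = FALSE]
  n <- nrow(slices)
  if (!identical(as.integer(slices$index), seq_len(n)))
    abv_error("abv_error_format", "slice indices must be 1..N")
  if (any(slices$mw_low_kda >= slices$mw_high_kda))
    abv_error("abv_error_format", "each slice needs mw_low < mw_high")
  if (n > 1 && any(slices$mw_high_kda[-1] > slices$mw_low_kda[-n] + 1e-9))
    abv_error("abv_error_format",
              "slice MW ranges must be non-overlapping and ordered high to low")
  counts <- lapply(counts, function(x) {
    m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
    if (ncol(m) != n)
      abv_error("abv_error_format", "counts length must equal the number of slices")
    if (any(m < 0) || anyNA(m))
      abv_error("abv_error_value", "peptide counts must be nonnegative")
    m
  })
  structure(list(cell_line = cell_line, slices = slices, counts = counts),
            class = "slice_set")
}

#' @export
print.slice_set <- function(x, ...) {
  cat(sprintf("Slice set [%s]: %d slices (%.1f-%.1f kDa), %d proteins\n",
              x$cell_line, nrow(x$slices), max(x$slices$mw_high_kda),
              min(x$slices$mw_low_kda), length(x$counts)))
  invisible(x)
}

# Index of the slice whose MW range contains mw, or NA. Top slice includes
# its upper boundary; each slice is (low, high].
slice_of_mw <- function(slice_set, mw) {
  lo <- slice_set$slices$mw_low_kda; hi <- slice_set$slices$mw_high_kda
  hit <- which(mw > lo - 1e-12 & (mw <= hi + 1e-12))
  if (!length(hit)) return(NA_integer_)
  hit[1]
}

#' Virtual Western profile for one protein
#'
#' Sums peptide counts over replicates per gel slice and locates the modal
#' slice (the argmax; ties break toward the lower index, i.e. higher MW).
#' A protein absent from the slice set raises a not-covered error, distinct
#' from a covered protein with all-zero counts (`detected = FALSE`).
#'
#' @param slice_set a [slice_set()].
#' @param protein gene/protein identifier.
#' @return an object of class `virtual_western`: `profile` (per-slice
#'   summed counts), `modal_slice`, `detected`, plus the slice table.
#' @export
build_virtual_western <- function(slice_set, protein) {
  stopifnot(inherits(slice_set, "slice_set"))
  if (!protein %in% names(slice_set$counts))
    stopf("abv_error_not_covered",
          "protein '%s' is not covered by this slice set", protein)
  prof <- colSums(slice_set$counts[[protein]])
  detected <- any(prof > 0)
  structure(list(protein = protein, cell_line = slice_set$cell_line,
                 profile = prof,
                 modal_slice = if (detected) which.max(prof) else NA_integer_,
                 detected = detected, slices = slice_set$slices),
            class = "virtual_western")
}

#' @export
print.virtual_western <- function(x, ...) {
  cat(sprintf("Virtual Western: %s in %s -- %s\n", x$protein, x$cell_line,
              if (x$detected)
                sprintf("modal slice %d (%.1f-%.1f kDa), %d peptides total",
                        x$modal_slice, x$slices$mw_low_kda[x$modal_slice],
                        x$slices$mw_high_kda[x$modal_slice], sum(x$profile))
              else "not detected"))
  invisible(x)
}

#' @export
plot.virtual_western <- function(x, band_mw = NULL, ...) {
  mids <- sqrt(x$slices$mw_low_kda * x$slices$mw_high_kda)
  graphics::barplot(x$profile, names.arg = round(mids, 0),
                    xlab = "slice mid MW (kDa)", ylab = "peptides",
                    main = sprintf("%s (%s)", x$protein, x$cell_line), ...)
  invisible(x)
}

#' Capture-MS concordance between a Western band and the virtual Western
#'
#' The pillar is `enhanced` when the protein is detected (at least one
#' peptide in at least one replicate of at least one required cell line)
#' and the band falls within `mw_tolerance_slices` slices of the modal
#' peptide slice; `uncertain` when the protein is not detected at all or
#' the band lies just outside the window (within twice the tolerance),
#' mirroring bands that fall just outside the expected boundaries;
#' `not_validated` otherwise. Because many proteins co-migrate in the
#' mid-MW region, a `crowding_flag` metric marks bands between 30 and
#' 70 kDa where this pillar is least reliable.
#'
#' @param band_mw apparent MW of the (dominant) Western band, kDa; must lie
#'   within the gel's overall MW range.
#' @param slice_sets a [slice_set()] or list of them (one per cell line).
#' @param protein target identifier.
#' @param config a [pillar_config()].
#' @param require_all_lines demand concordance in every cell line instead
#'   of at least one.
#' @return a [pillar_result()] with pillar `"capture_ms"`; metrics include
#'   `mw_offset_slices` and `crowding_flag`.
#' @export
capture_ms_match <- function(band_mw, slice_sets, protein,
                             config = pillar_config(),
                             require_all_lines = FALSE) {
  if (inherits(slice_sets, "slice_set")) slice_sets <- list(slice_sets)
  crowding <- as.numeric(band_mw >= 30 && band_mw <= 70)
  offsets <- rep(NA_real_, length(slice_sets))
  detected_any <- FALSE
  for (i in seq_along(slice_sets)) {
    ss <- slice_sets[[i]]
    rng <- c(min(ss$slices$mw_low_kda), max(ss$slices$mw_high_kda))
    if (band_mw < rng[1] || band_mw > rng[2])
      stopf("abv_error_range", "band MW %.1f kDa outside gel range [%.1f, %.1f]",
            band_mw, rng[1], rng[2])
    vw <- tryCatch(build_virtual_western(ss, protein),
                   abv_error_not_covered = function(e) NULL)
    if (is.null(vw) || !vw$detected) next
    detected_any <- TRUE
    offsets[i] <- abs(slice_of_mw(ss, band_mw) - vw$modal_slice)
  }
  tol <- config$mw_tolerance_slices
  if (!detected_any)
    return(pillar_result("capture_ms", "uncertain",
                         metrics = list(crowding_flag = crowding),
                         note = "target protein not detected in any gel slice"))
  off <- if (require_all_lines) max(offsets, na.rm = TRUE) else min(offsets, na.rm = TRUE)
  status <- if (off <= tol) "enhanced"
            else if (off <= 2 * tol) "uncertain"
            else "not_validated"
  note <- if (status == "uncertain") "band just outside expected slice window" else ""
  pillar_result("capture_ms", status,
                metrics = list(mw_offset_slices = off, crowding_flag = crowding),
                note = note)
}
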