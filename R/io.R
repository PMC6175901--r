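# Readers and writers for the tabular interchange formats. Dialect is
# auto-detected from the extension (.csv comma, anything else tab);
# decimal point only, UTF-8.

sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_checked <- function(path) {
  if (!file.exists(path))
    stopf("abv_error_io", "file not found: %s", path)
  df <- utils::read.table(path, sep = sep_for(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (!ncol(df))
    abv_error("abv_error_format", "missing header row")
  df
}

#' Read an abundance matrix from TSV/CSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; the body must be nonnegative numbers. Duplicate genes and
#' negative or non-numeric cells are rejected with named errors.
#'
#' @param path TSV or CSV file.
#' @param measurement_kind one of `"tpm"`, `"prm_ratio"`, `"tmt_intensity"`,
#'   `"band_intensity"`.
#' @return an [abundance_panel()].
#' @export
read_abundance_panel <- function(path, measurement_kind) {
  df <- read_table_checked(path)
  if (ncol(df) < 2)
    abv_error("abv_error_format", "need a gene column plus at least one sample column")
  genes <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num) && !anyNA(v))
        stopf("abv_error_value", "non-numeric cell in column '%s'", names(body)[j])
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- genes
  abundance_panel(m, measurement_kind)
}

#' Write an abundance panel to TSV/CSV
#'
#' @param panel an [abundance_panel()].
#' @param path output file; dialect from extension.
#' @param gene_col name for the gene-identifier column.
#' @export
write_abundance_panel <- function(panel, path, gene_col = "gene") {
  df <- data.frame(rownames(panel$values), panel$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- gene_col
  utils::write.table(df, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read Western-blot lane tables
#'
#' Expects columns `antibody_id`, `sample_id`, a band position (`mw_kda`
#' or `migration`, exactly one non-missing per row), `intensity`, and
#' optionally `loading_control`. Rows are grouped into one
#' [lane_profile()] per (antibody, sample); bands carrying only a
#' migration distance are resolved through `calibration`.
#'
#' @param path CSV/TSV file.
#' @param calibration optional [calibrate_ladder()] result; required when
#'   any row gives only a migration distance.
#' @return named list of [lane_profile()], names `antibody_id.sample_id`.
#' @export
read_lane_table <- function(path, calibration = NULL) {
  df <- read_table_checked(path)
  need <- c("antibody_id", "sample_id", "intensity")
  if (!all(need %in% names(df)))
    stopf("abv_error_format", "lane table must have columns: %s",
          paste(need, collapse = ", "))
  has_mw <- "mw_kda" %in% names(df)
  has_mig <- "migration" %in% names(df)
  if (!has_mw && !has_mig)
    abv_error("abv_error_format", "lane table needs an mw_kda or migration column")
  key <- paste(df$antibody_id, df$sample_id, sep = ".")
  out <- list()
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    bands <- lapply(seq_len(nrow(rows)), function(i) {
      mw  <- if (has_mw) rows$mw_kda[i] else NA
      mig <- if (has_mig) rows$migration[i] else NA
      if (!is.na(mw) && !is.na(mig))
        abv_error("abv_error_format",
                  "a row may give mw_kda or migration, not both")
      if (is.na(mw)) {
        if (is.na(mig))
          abv_error("abv_error_format", "row gives neither mw_kda nor migration")
        if (is.null(calibration))
          abv_error("abv_error_configuration",
                    "migration given but no ladder calibration supplied")
        mw <- apparent_mw(calibration, mig)
      }
      band(apparent_mw_kda = mw, intensity = rows$intensity[i])
    })
    lc <- NULL
    if ("loading_control" %in% names(rows)) {
      v <- rows$loading_control[!is.na(rows$loading_control)]
      if (length(v)) lc <- v[1]
    }
    out[[k]] <- lane_profile(rows$antibody_id[1], rows$sample_id[1],
                             bands, loading_control_intensity = lc)
  }
  out
}

#' Write lane profiles back to a lane table
#'
#' @param lanes list of [lane_profile()].
#' @param path output CSV/TSV.
#' @export
write_lane_table <- function(lanes, path) {
  rows <- do.call(rbind, lapply(lanes, function(l) {
    if (!length(l$bands)) return(NULL)
    data.frame(antibody_id = l$antibody_id, sample_id = l$sample_id,
               mw_kda = vapply(l$bands, `[[`, numeric(1), "apparent_mw_kda"),
               intensity = vapply(l$bands, `[[`, numeric(1), "intensity"),
               loading_control = if (is.null(l$loading_control_intensity))
                 NA_real_ else l$loading_control_intensity,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gel slice set from TSV
#'
#' Long format with columns `cell_line`, `replicate`, `slice_index`,
#' `mw_low`, `mw_high`, `protein`, `peptide_count`; one [slice_set()] per
#' cell line.
#'
#' @param path TSV/CSV file.
#' @return named list of [slice_set()] keyed by cell line.
#' @export
read_slice_sets <- function(path) {
  df <- read_table_checked(path)
  need <- c("cell_line", "replicate", "slice_index", "mw_low", "mw_high",
            "protein", "peptide_count")
  if (!all(need %in% names(df)))
    stopf("abv_error_format", "slice table must have columns: %s",
          paste(need, collapse = ", "))
  out <- list()
  for (cl in unique(df$cell_line)) {
    sub <- df[df$cell_line == cl, , drop = FALSE]
    sl <- unique(sub[, c("slice_index", "mw_low", "mw_high")])
    sl <- sl[order(sl$slice_index), ]
    slices <- data.frame(index = sl$slice_index, mw_low_kda = sl$mw_low,
                         mw_high_kda = sl$mw_high)
    counts <- list()
    for (p in unique(sub$protein)) {
      ps <- sub[sub$protein == p, , drop = FALSE]
      reps <- sort(unique(ps$replicate))
      m <- matrix(0L, nrow = length(reps), ncol = nrow(slices))
      for (i in seq_len(nrow(ps)))
        m[match(ps$replicate[i], reps), ps$slice_index[i]] <- ps$peptide_count[i]
      counts[[p]] <- m
    }
    out[[cl]] <- slice_set(cl, slices, counts)
  }
  out
}

#' Write slice sets to TSV
#'
#' @param slice_sets a [slice_set()] or named list of them.
#' @param path output TSV.
#' @export
write_slice_sets <- function(slice_sets, path) {
  if (inherits(slice_sets, "slice_set")) slice_sets <- list(slice_sets)
  rows <- do.call(rbind, lapply(slice_sets, function(ss) {
    do.call(rbind, lapply(names(ss$counts), function(p) {
      m <- ss$counts[[p]]
      do.call(rbind, lapply(seq_len(nrow(m)), function(r)
        data.frame(cell_line = ss$cell_line, replicate = r,
                   slice_index = ss$slices$index,
                   mw_low = ss$slices$mw_low_kda,
                   mw_high = ss$slices$mw_high_kda,
                   protein = p, peptide_count = m[r, ],
                   stringsAsFactors = FALSE)))
    }))
  }))
  # keep every slice's geometry at least once per cell line, drop other
  # zero-count rows to keep files small
  keep_key <- paste(rows$cell_line, rows$slice_index)
  rows <- rows[rows$peptide_count > 0 | !duplicated(keep_key), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

report_to_list <- function(r) {
  list(antibody_id = r$antibody_id,
       n_enhanced = r$n_enhanced,
       pillars = lapply(r$pillar_results, function(p)
         list(status = p$status, metrics = p$metrics, note = p$note)))
}

#' Write validation reports to JSON (and a TSV summary)
#'
#' The JSON document holds one object per antibody with per-pillar status,
#' metrics and notes; the TSV summary has one row per antibody with the
#' five pillar statuses and `n_enhanced`. `read_report()` round-trips the
#' JSON losslessly.
#'
#' @param reports list of [validation_report()].
#' @param path JSON output path; the TSV summary is written next to it
#'   with extension `.tsv` (or pass `tsv_path`).
#' @param tsv_path optional explicit TSV path.
#' @return invisibly, the JSON path.
#' @export
write_report <- function(reports, path, tsv_path = NULL) {
  if (inherits(reports, "validation_report")) reports <- list(reports)
  payload <- lapply(reports, report_to_list)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (is.null(tsv_path)) tsv_path <- sub("\\.json$", ".tsv", path)
  if (length(reports)) {
    summ <- do.call(rbind, lapply(reports, summary))
  } else {
    summ <- data.frame(antibody_id = character(0))
    for (p in PILLARS) summ[[p]] <- character(0)
    summ$n_enhanced <- integer(0)
  }
  utils::write.table(summ, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read validation reports back from JSON
#'
#' @param path JSON file written by [write_report()].
#' @return list of [validation_report()].
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(obj) {
    results <- list()
    for (p in names(obj$pillars)) {
      pr <- obj$pillars[[p]]
      if (pr$status == "not_done") next
      results[[length(results) + 1L]] <-
        pillar_result(p, pr$status,
                      metrics = lapply(pr$metrics, as.numeric),
                      note = if (is.null(pr$note)) "" else pr$note)
    }
    validation_report(obj$antibody_id, results)
  })
}

#' Read a pillar configuration from YAML or JSON
#'
#' Unknown keys are rejected; omitted keys keep their defaults.
#'
#' @param path `.yaml`/`.yml` or `.json` file mirroring [pillar_config()].
#' @return a [pillar_config()].
#' @export
read_pillar_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pillar_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stopf("abv_error_configuration", "unknown config key(s): %s",
          paste(bad, collapse = ", "))
  do.call(pillar_config, vals)
}

#' Write a pillar configuration to YAML
#'
#' @param config a [pillar_config()].
#' @param path output `.yaml` path.
#' @export
write_pillar_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
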