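# Cohort reproduction: recompute the orthogonal-validation tallies from
# user-supplied abundance and band-intensity tables. This stage only runs
# when the tables are present; without them it reports "data unavailable"
# so the package remains self-contained.

#' Orthogonal-validation tallies over an antibody cohort
#'
#' For each antibody, builds a series pair between its band-intensity
#' series and (a) its assigned proteomics panel (PRM or TMT) and (b) the
#' RNA panel, then tallies how many antibodies pass the Pearson cutoff on
#' each route, how many fail despite sufficient RNA fold-change, and how
#' many sit below the fold-change gate. A per-antibody audit table is
#' returned so the tallies can be recounted independently.
#'
#' @param wb_panel [abundance_panel()] of kind `band_intensity`
#'   (antibodies x samples).
#' @param orth_panels named list of [abundance_panel()]s (e.g. `prm`,
#'   `tmt`), genes x samples.
#' @param rna_panel [abundance_panel()] of kind `tpm`.
#' @param antibodies data.frame with columns `antibody_id`, `target_gene`,
#'   `platform` (a name of `orth_panels`).
#' @param config a [pillar_config()].
#' @return an object of class `cohort_result`: counts
#'   (`n_total_antibodies`, `n_pass_proteomics`, `n_below_r_min`,
#'   `n_pass_rna`, `n_fail_despite_fold`, `n_low_fold`), the `audit`
#'   data.frame and an `exclusions` vector of antibodies that could not be
#'   matched to a panel.
#' @export
reproduce_orthogonal_counts <- function(wb_panel, orth_panels, rna_panel,
                                        antibodies,
                                        config = pillar_config()) {
  stopifnot(all(c("antibody_id", "target_gene", "platform") %in%
                  names(antibodies)))
  audit <- NULL
  exclusions <- character(0)
  safe_r <- function(x, y) tryCatch(
    pearson_r(maybe_log(x, config), maybe_log(y, config)),
    abv_error_degenerate = function(e) NA_real_)
  for (i in seq_len(nrow(antibodies))) {
    ab <- antibodies$antibody_id[i]
    gene <- antibodies$target_gene[i]
    plat <- antibodies$platform[i]
    if (!ab %in% rownames(wb_panel$values) ||
        !plat %in% names(orth_panels) ||
        !gene %in% rownames(orth_panels[[plat]]$values)) {
      exclusions <- c(exclusions, ab)
      next
    }
    op <- orth_panels[[plat]]
    shared <- intersect(colnames(wb_panel$values), colnames(op$values))
    wb <- wb_panel$values[ab, shared]
    prot <- op$values[gene, shared]
    r_prot <- safe_r(wb, prot)
    rna_r <- rna_fc <- NA_real_
    if (gene %in% rownames(rna_panel$values)) {
      shared_rna <- intersect(colnames(wb_panel$values),
                              colnames(rna_panel$values))
      rna <- rna_panel$values[gene, shared_rna]
      rna_r <- safe_r(wb_panel$values[ab, shared_rna], rna)
      rna_fc <- fold_change(rna, config$pseudocount)
    }
    audit <- rbind(audit, data.frame(
      antibody_id = ab, target_gene = gene, platform = plat,
      r_proteomics = r_prot, r_rna = rna_r, rna_fold_change = rna_fc,
      stringsAsFactors = FALSE))
  }
  if (is.null(audit)) audit <- data.frame()
  counts <- list(
    n_total_antibodies = nrow(audit),
    n_pass_proteomics = sum(audit$r_proteomics > config$r_min, na.rm = TRUE),
    n_below_r_min = sum(audit$r_proteomics <= config$r_min, na.rm = TRUE),
    n_pass_rna = sum(audit$r_rna > config$r_min, na.rm = TRUE),
    n_fail_despite_fold = sum(audit$r_rna <= config$r_min &
                                audit$rna_fold_change >= config$fold_min,
                              na.rm = TRUE),
    n_low_fold = sum(audit$rna_fold_change < config$fold_min, na.rm = TRUE))
  structure(c(counts, list(audit = audit, exclusions = exclusions)),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("Orthogonal-validation cohort tallies:\n")
  cat(sprintf("  antibodies analyzed        %d\n", x$n_total_antibodies))
  cat(sprintf("  pass by proteomics (r > cutoff)   %d\n", x$n_pass_proteomics))
  cat(sprintf("  below cutoff by proteomics        %d\n", x$n_below_r_min))
  cat(sprintf("  pass by RNA                        %d\n", x$n_pass_rna))
  cat(sprintf("  fail despite sufficient RNA fold   %d\n", x$n_fail_despite_fold))
  cat(sprintf("  RNA fold below gate                %d\n", x$n_low_fold))
  if (length(x$exclusions))
    cat("  excluded (no panel match):", paste(x$exclusions, collapse = ", "), "\n")
  invisible(x)
}

#' Count genes expressed above a TPM threshold
#'
#' A gene counts as expressed when its maximum TPM across the panel's
#' samples strictly exceeds the threshold.
#'
#' @param rna either an [abundance_panel()] or a genes x samples matrix.
#' @param tpm_threshold strict threshold (default 10).
#' @return integer count.
#' @export
count_expressed_genes <- function(rna, tpm_threshold = 10) {
  m <- if (inherits(rna, "abundance_panel")) rna$values else as.matrix(rna)
  if (!nrow(m)) return(0L)
  sum(apply(m, 1, max) > tpm_threshold)
}

#' Reproduce cohort tallies from a data directory
#'
#' Looks for `wb.tsv`, `prm.tsv`, `tmt.tsv`, `rna.tsv` and
#' `antibodies.tsv` in `data_dir`. When the files are absent the stage is
#' skipped with status `"data unavailable"`. When present, the tallies are
#' computed for both correlation scales (linear and log2), since the
#' published procedure does not state which was used.
#'
#' @param data_dir directory holding the tables.
#' @param config a [pillar_config()].
#' @return list with `status` (`"ok"` or `"data unavailable"`) and, when
#'   run, `linear` and `log2` [reproduce_orthogonal_counts()] results plus
#'   `n_genes_tpm_gt10`.
#' @export
reproduce_cohort <- function(data_dir, config = pillar_config()) {
  files <- file.path(data_dir, c(wb = "wb.tsv", rna = "rna.tsv",
                                 antibodies = "antibodies.tsv"))
  names(files) <- c("wb", "rna", "antibodies")
  if (!dir.exists(data_dir) || !all(file.exists(files)))
    return(list(status = "data unavailable",
                missing = files[!file.exists(files)]))
  wb <- read_abundance_panel(files[["wb"]], "band_intensity")
  rna <- read_abundance_panel(files[["rna"]], "tpm")
  orth <- list()
  for (p in c("prm", "tmt")) {
    f <- file.path(data_dir, paste0(p, ".tsv"))
    if (file.exists(f))
      orth[[p]] <- read_abundance_panel(
        f, if (p == "prm") "prm_ratio" else "tmt_intensity")
  }
  antibodies <- utils::read.delim(files[["antibodies"]],
                                  stringsAsFactors = FALSE)
  cfg_log <- do.call(pillar_config,
                     modifyList(unclass(config), list(log_transform = TRUE)))
  cfg_lin <- do.call(pillar_config,
                     modifyList(unclass(config), list(log_transform = FALSE)))
  list(status = "ok",
       linear = reproduce_orthogonal_counts(wb, orth, rna, antibodies, cfg_lin),
       log2 = reproduce_orthogonal_counts(wb, orth, rna, antibodies, cfg_log),
       n_genes_tpm_gt10 = count_expressed_genes(rna))
}
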