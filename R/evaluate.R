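# End-to-end evaluation: run a synthetic scenario through the generators
# and the pillar decision rules, recovering the known ground truth.

#' Random protein sequence of human-like composition
#'
#' Draws residues i.i.d. from approximate human proteome amino-acid
#' frequencies; a 450-residue draw has a theoretical MW close to 50 kDa,
#' the mode of the human proteome's size distribution.
#'
#' @param n_residues chain length.
#' @param seed RNG seed.
#' @return a single amino-acid string.
#' @export
random_protein_sequence <- function(n_residues, seed = 1L) {
  with_seed(seed, paste(sample(names(AA_FREQ_HUMAN), n_residues,
                               replace = TRUE, prob = AA_FREQ_HUMAN),
                        collapse = ""))
}

eval_one_orthogonal <- function(label, seed, config) {
  sc <- scenario(label, target_gene = "TARGET", seed = seed,
                 decoy_gene = if (label == "off_target") "DECOY" else NULL)
  panels <- gen_expression_panel(2, sc)
  sim <- gen_lanes(sc, panels)
  bands <- vapply(sim$lanes, function(l)
    dominant_band(l, config)$band$intensity, numeric(1))
  orth <- panels$protein$values[sc$target_gene, names(sim$lanes)]
  pair <- series_pair(bands, orth, names(sim$lanes))
  orthogonal_validate(pair, config)$status
}

eval_one_capture <- function(label, seed, config, shift_slices = 3L) {
  mw <- with_seed(seed + 3L, 2^runif(1, log2(15), log2(200)))
  gs <- gen_slice_set(c(TARGET = mw), seed = seed)
  ss <- gs$slice_set
  home <- gs$truth[["TARGET"]]
  if (label == "mw_shifted") {
    j <- home + if (home + shift_slices <= nrow(ss$slices)) shift_slices else -shift_slices
    band_mw <- sqrt(ss$slices$mw_low_kda[j] * ss$slices$mw_high_kda[j])
  } else {
    band_mw <- mw
  }
  capture_ms_match(band_mw, ss, "TARGET", config)$status
}

#' Classification recovery of a pillar on a synthetic cohort
#'
#' Generates `n_antibodies` independent antibodies under one scenario
#' label, runs the named pillar end-to-end (generator -> dominant band ->
#' decision rule), and tabulates the resulting statuses against the
#' scenario's expected call.
#'
#' @param label a [scenario()] label.
#' @param n_antibodies cohort size.
#' @param seed base RNG seed; antibody i uses a seed derived from it.
#' @param config a [pillar_config()].
#' @param pillar `"orthogonal"` or `"capture_ms"` (the pillars whose
#'   outcome is statistical rather than deterministic arithmetic).
#' @param shift_slices displacement, in slices, of the band for the
#'   `mw_shifted` capture-MS scenario.
#' @return an object of class `scenario_recovery`: the status table, the
#'   per-status fractions, and the run's parameters.
#' @export
evaluate_scenario <- function(label, n_antibodies = 200, seed = 1L,
                              config = pillar_config(),
                              pillar = c("orthogonal", "capture_ms"),
                              shift_slices = 3L) {
  pillar <- match.arg(pillar)
  seeds <- seed + 31L * seq_len(n_antibodies)
  statuses <- vapply(seeds, function(s) {
    if (pillar == "orthogonal") eval_one_orthogonal(label, s, config)
    else eval_one_capture(label, s, config, shift_slices)
  }, character(1))
  tab <- table(factor(statuses, levels = STATUSES))
  structure(list(label = label, pillar = pillar, n = n_antibodies,
                 statuses = statuses, counts = tab,
                 fractions = as.numeric(tab) / n_antibodies,
                 status_levels = STATUSES, seed = seed),
            class = "scenario_recovery")
}

#' Fraction of a cohort assigned a given status
#'
#' @param x a [evaluate_scenario()] result.
#' @param status one of the four status values.
#' @return fraction in \[0, 1\].
#' @export
recovery_fraction <- function(x, status) {
  stopifnot(inherits(x, "scenario_recovery"))
  as.numeric(x$counts[[match.arg(status, STATUSES)]]) / x$n
}

#' @export
print.scenario_recovery <- function(x, ...) {
  cat(sprintf("Scenario '%s' through the %s pillar (n = %d, seed = %d):\n",
              x$label, x$pillar, x$n, x$seed))
  for (s in names(x$counts))
    if (x$counts[[s]] > 0)
      cat(sprintf("  %-14s %4d  (%.1f%%)\n", s, x$counts[[s]],
                  100 * x$counts[[s]] / x$n))
  invisible(x)
}
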