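# Seeded generators for synthetic panels, lanes, gel slice sets and
# perturbation experiments, each emitting ground-truth labels so every
# pillar can be exercised end-to-end without external data.

SCENARIO_LABELS <- c("specific", "off_target", "mw_shifted", "multi_band",
                     "low_variability")

# The standard eight-cell-line panel used for PRM-style validation.
PANEL_CELL_LINES <- c("A431", "A549", "HEK 293", "HeLa", "Hep G2", "RT4",
                      "SH-SY5Y", "U-2 OS")

# Evaluate expr with a private, seeded RNG stream; the caller's RNG state
# is untouched. Bit-reproducible for a fixed seed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation scenario for one antibody
#'
#' Describes how an antibody behaves in the synthetic experiments:
#' `specific` (band tracks the target), `off_target` (band tracks a decoy
#' gene of similar size), `mw_shifted` (band displaced from the target's
#' theoretical MW), `multi_band` (a dominant target band plus weaker
#' off-size bands), or `low_variability` (a specific antibody whose target
#' barely varies across the panel, defeating correlation-based
#' validation).
#'
#' @param label one of the scenario labels above.
#' @param target_gene,decoy_gene gene identifiers; `decoy_gene` is
#'   required for `off_target`.
#' @param target_mw_kda the target's theoretical MW (kDa).
#' @param mw_shift_kda band displacement for `mw_shifted`.
#' @param noise_sd_log SD of multiplicative lognormal noise (natural log)
#'   on band intensities and perturbation readouts.
#' @param rna_protein_rho latent RNA-protein correlation in \[-1, 1\].
#' @param n_samples panel size (8 emulates the standard cell-line panel).
#' @param fold_range_log2 width (log2) of the uniform spread of per-sample
#'   expression; `low_variability` defaults to 2 (max fourfold).
#' @param seed RNG seed; every generator consuming the scenario is
#'   bit-reproducible given it.
#' @return an object of class `scenario`.
#' @export
scenario <- function(label, target_gene = "TARGET1", decoy_gene = NULL,
                     target_mw_kda = 50, mw_shift_kda = 15,
                     noise_sd_log = 0.2, rna_protein_rho = 0.9,
                     n_samples = 8,
                     fold_range_log2 = if (label == "low_variability") 2 else 6,
                     seed = 1L) {
  label <- match.arg(label, SCENARIO_LABELS)
  if (label == "off_target") {
    if (is.null(decoy_gene) || identical(decoy_gene, target_gene))
      abv_error("abv_error_parameter",
                "off_target requires a decoy_gene different from target_gene")
  }
  if (abs(rna_protein_rho) > 1)
    abv_error("abv_error_parameter", "rna_protein_rho must lie in [-1, 1]")
  if (noise_sd_log < 0 || fold_range_log2 < 0)
    abv_error("abv_error_parameter", "noise parameters must be nonnegative")
  structure(list(label = label, target_gene = target_gene,
                 decoy_gene = decoy_gene, target_mw_kda = target_mw_kda,
                 mw_shift_kda = mw_shift_kda, noise_sd_log = noise_sd_log,
                 rna_protein_rho = rna_protein_rho,
                 n_samples = as.integer(n_samples),
                 fold_range_log2 = fold_range_log2,
                 seed = as.integer(seed)),
            class = "scenario")
}

scenario_samples <- function(sc) {
  if (sc$n_samples == length(PANEL_CELL_LINES)) PANEL_CELL_LINES
  else paste0("S", seq_len(sc$n_samples))
}

#' Generate a correlated RNA/protein expression panel
#'
#' Per gene, per-sample log2 expression means are drawn uniformly over a
#' window of width `fold_range_log2`; protein log-abundance is built from
#' the standardized RNA values with latent correlation `rna_protein_rho`
#' plus Gaussian noise, then back-transformed. The first genes are named
#' after the scenario's target (and decoy, when present).
#'
#' @param n_genes number of genes (>= 1).
#' @param sc a [scenario()].
#' @return list with `rna` (an [abundance_panel()] of kind `tpm`) and
#'   `protein` (kind `prm_ratio`).
#' @export
gen_expression_panel <- function(n_genes, sc) {
  stopifnot(n_genes >= 1)
  genes <- paste0("GENE", sprintf("%04d", seq_len(n_genes)))
  genes[1] <- sc$target_gene
  if (!is.null(sc$decoy_gene)) {
    if (n_genes < 2)
      abv_error("abv_error_parameter", "need n_genes >= 2 for a decoy gene")
    genes[2] <- sc$decoy_gene
  }
  n <- sc$n_samples
  rho <- sc$rna_protein_rho
  with_seed(sc$seed, {
    rna <- prot <- matrix(0, n_genes, n)
    for (g in seq_len(n_genes)) {
      base <- runif(1, 2, 6)
      rna_log2 <- base + runif(n, 0, sc$fold_range_log2)
      s <- sd(rna_log2)
      z <- if (s > 0) (rna_log2 - mean(rna_log2)) / s else rep(0, n)
      prot_z <- rho * z + sqrt(1 - rho^2) * rnorm(n)
      # confine protein log-abundance to the gene's expression window so a
      # low-variability gene is low-variability at the protein level too
      prot_log2 <- pmin(pmax(mean(rna_log2) + s * prot_z, base),
                        base + sc$fold_range_log2)
      rna[g, ] <- 2^rna_log2
      prot[g, ] <- 2^(prot_log2 - base)  # ratio-to-standard scale
    }
    samples <- scenario_samples(sc)
    dimnames(rna) <- dimnames(prot) <- list(genes, samples)
    list(rna = abundance_panel(rna, "tpm"),
         protein = abundance_panel(prot, "prm_ratio"))
  })
}

#' Generate Western-blot lanes for an antibody under a scenario
#'
#' One lane per panel sample. A `specific` antibody shows one band at the
#' target's theoretical MW with intensity proportional to the target's
#' protein abundance times multiplicative lognormal noise; `off_target`
#' intensities track the decoy instead (at a similar band size);
#' `mw_shifted` displaces the band by `mw_shift_kda`; `multi_band` adds
#' weaker bands at other sizes around a dominant target band.
#'
#' @param sc a [scenario()].
#' @param panels output of [gen_expression_panel()] containing the target
#'   (and decoy, when needed).
#' @param antibody_id identifier stamped on the lanes.
#' @return list with `lanes` (named list of [lane_profile()], one per
#'   sample) and `truth` (scenario label, driver gene, band MW).
#' @export
gen_lanes <- function(sc, panels, antibody_id = paste0("ab_", sc$target_gene)) {
  prot <- panels$protein$values
  if (!sc$target_gene %in% rownames(prot))
    abv_error("abv_error_parameter", "target gene missing from panel")
  driver <- sc$target_gene
  if (sc$label == "off_target") {
    if (is.null(sc$decoy_gene) || !sc$decoy_gene %in% rownames(prot))
      abv_error("abv_error_parameter", "decoy gene missing from panel")
    driver <- sc$decoy_gene
  }
  band_mw <- sc$target_mw_kda +
    if (sc$label == "mw_shifted") sc$mw_shift_kda else 0
  samples <- colnames(prot)
  with_seed(sc$seed + 7L, {
    lanes <- lapply(samples, function(s) {
      noise <- exp(rnorm(1, 0, sc$noise_sd_log))
      main <- band(apparent_mw_kda = band_mw,
                   intensity = prot[driver, s] * noise)
      bands <- list(main)
      if (sc$label == "multi_band") {
        bands <- c(bands, list(
          band(apparent_mw_kda = band_mw * 1.6,
               intensity = main$intensity * 0.2),
          band(apparent_mw_kda = band_mw / 1.6,
               intensity = main$intensity * 0.15)))
      }
      lane_profile(antibody_id, s, bands)
    })
    names(lanes) <- samples
    list(lanes = lanes,
         truth = list(label = sc$label, driver_gene = driver,
                      band_mw_kda = band_mw))
  })
}

#' Uniform-in-log2 gel slice geometry
#'
#' @param n_slices number of slices (slice 1 at the top, highest MW).
#' @param mw_range overall gel MW range in kDa.
#' @return slice data.frame for [slice_set()].
#' @export
gel_slice_table <- function(n_slices = 50, mw_range = c(10, 250)) {
  br <- 2^seq(log2(mw_range[2]), log2(mw_range[1]), length.out = n_slices + 1)
  data.frame(index = seq_len(n_slices), mw_low_kda = br[-1],
             mw_high_kda = br[-(n_slices + 1)])
}

#' Generate a capture-MS slice set with known modal slices
#'
#' Each protein's expected peptide count is concentrated in the slice
#' containing its (theoretical) MW, decaying geometrically into
#' neighboring slices with factor `spillover`; observed counts are Poisson
#' draws split over replicates. Proteins with abundance below
#' `detection_floor` yield all-zero counts, exercising the missing-data
#' path.
#'
#' @param protein_mws named numeric vector of protein MWs (kDa), each
#'   within `mw_range`.
#' @param abundance named relative abundances (default 1 for all).
#' @param n_slices,mw_range gel geometry (50 slices by default).
#' @param spillover geometric decay per slice of the expected count.
#' @param base_lambda expected total peptide count in the home slice of a
#'   protein at abundance 1.
#' @param detection_floor abundance below which a protein is undetectable.
#' @param n_replicates technical replicates.
#' @param cell_line sample identifier.
#' @param seed RNG seed.
#' @return list with `slice_set` (a [slice_set()]) and `truth` (named
#'   vector of true home-slice indices; NA for undetectable proteins).
#' @export
gen_slice_set <- function(protein_mws, abundance = NULL, n_slices = 50,
                          mw_range = c(10, 250), spillover = 0.25,
                          base_lambda = 20, detection_floor = 0.05,
                          n_replicates = 3, cell_line = "RT4", seed = 1L) {
  if (is.null(names(protein_mws)))
    abv_error("abv_error_parameter", "protein_mws must be named")
  if (any(protein_mws < mw_range[1] | protein_mws > mw_range[2]))
    abv_error("abv_error_range", "protein MW outside gel range")
  if (spillover < 0 || spillover >= 1)
    abv_error("abv_error_parameter", "spillover must lie in [0, 1)")
  if (is.null(abundance))
    abundance <- setNames(rep(1, length(protein_mws)), names(protein_mws))
  slices <- gel_slice_table(n_slices, mw_range)
  ss0 <- slice_set(cell_line, slices,
                   setNames(list(rep(0L, n_slices)), names(protein_mws)[1]))
  home <- vapply(protein_mws, function(m) slice_of_mw(ss0, m), integer(1))
  with_seed(seed, {
    counts <- lapply(names(protein_mws), function(p) {
      m <- matrix(0L, n_replicates, n_slices)
      if (abundance[[p]] >= detection_floor) {
        d <- abs(seq_len(n_slices) - home[[p]])
        decay <- if (spillover == 0) as.numeric(d == 0) else spillover^d
        lam <- base_lambda * abundance[[p]] * decay
        lam[lam < 1e-6] <- 0
        for (r in seq_len(n_replicates))
          m[r, ] <- rpois(n_slices, lam / n_replicates)
      }
      m
    })
    names(counts) <- names(protein_mws)
    truth <- home
    truth[abundance[names(protein_mws)] < detection_floor] <- NA_integer_
    list(slice_set = slice_set(cell_line, slices, counts), truth = truth)
  })
}

#' Generate a knockdown experiment
#'
#' For a specific antibody the post-knockdown band intensity is
#' `control * (1 - efficiency)` times lognormal noise; an off-target band
#' does not respond to the knockdown.
#'
#' @param sc a [scenario()].
#' @param efficiencies 1-2 siRNA knockdown efficiencies in \[0, 1\].
#' @param control_intensity baseline band intensity.
#' @param seed RNG seed (defaults to the scenario's).
#' @return list with `control`, `kd` (vector of post-knockdown
#'   intensities) and `truth`.
#' @export
gen_knockdown <- function(sc, efficiencies = c(0.6, 0.4),
                          control_intensity = 1.0, seed = sc$seed) {
  if (any(efficiencies < 0 | efficiencies > 1))
    abv_error("abv_error_parameter", "efficiencies must lie in [0, 1]")
  responds <- sc$label != "off_target"
  with_seed(seed + 11L, {
    kd <- vapply(efficiencies, function(e) {
      eff <- if (responds) e else 0
      control_intensity * (1 - eff) * exp(rnorm(1, 0, sc$noise_sd_log))
    }, numeric(1))
    list(control = control_intensity, kd = kd,
         truth = list(label = sc$label, responds = responds,
                      efficiencies = efficiencies))
  })
}

#' Generate a recombinant-overexpression experiment
#'
#' A specific antibody's band scales with the induced expression
#' (`induction_fold`); an off-target band stays at the control level.
#'
#' @param sc a [scenario()].
#' @param induction_fold overexpression factor (>= 1).
#' @param control_present is the target endogenously expressed in the
#'   control line (if not, the control lane has no band).
#' @param base_intensity band intensity unit.
#' @param seed RNG seed (defaults to the scenario's).
#' @return list with `control_lane`, `oe_lane` ([lane_profile()]s),
#'   `expressed` (TRUE) and `truth`.
#' @export
gen_overexpression <- function(sc, induction_fold = 20,
                               control_present = TRUE,
                               base_intensity = 100, seed = sc$seed) {
  if (induction_fold < 1)
    abv_error("abv_error_parameter", "induction_fold must be >= 1")
  responds <- sc$label != "off_target"
  ab <- paste0("ab_", sc$target_gene)
  with_seed(seed + 13L, {
    noise <- exp(rnorm(2, 0, sc$noise_sd_log))
    ctrl_bands <- if (control_present)
      list(band(apparent_mw_kda = sc$target_mw_kda,
                intensity = base_intensity * noise[1]))
    else list()
    oe_int <- if (responds)
      base_intensity * induction_fold * noise[2]
    else if (control_present) base_intensity * noise[2] else 0
    oe_bands <- if (oe_int > 0)
      list(band(apparent_mw_kda = sc$target_mw_kda, intensity = oe_int))
    else list()
    list(control_lane = lane_profile(ab, "HEK293_ctrl", ctrl_bands),
         oe_lane = lane_profile(ab, "HEK293_oe", oe_bands),
         expressed = TRUE,
         truth = list(label = sc$label, responds = responds,
                      induction_fold = induction_fold))
  })
}
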