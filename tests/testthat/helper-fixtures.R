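# Shared fixtures and independent oracles, built in code.

# Independent sum-of-products Pearson formula (oracle; deliberately not
# calling cor()).
pearson_bruteforce <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

make_lane <- function(mws, intensities, ab = "ab1", sample = "RT4", lc = NULL) {
  lane_profile(ab, sample,
               mapply(function(m, i) band(apparent_mw_kda = m, intensity = i),
                      mws, intensities, SIMPLIFY = FALSE),
               loading_control_intensity = lc)
}

# Ten uniform slices spanning 10-110 kDa (slice 1 = 100-110 kDa).
toy_slice_set <- function(counts_list, cell_line = "RT4") {
  slices <- data.frame(index = 1:10,
                       mw_low_kda = seq(100, 10, by = -10),
                       mw_high_kda = seq(110, 20, by = -10))
  slice_set(cell_line, slices, counts_list)
}

tmpfile <- function(ext) tempfile(fileext = ext)

# A synthetic stand-in cohort with statuses known by construction:
# 3 antibodies pass proteomics, 1 fails; on the RNA route 2 pass, 1 fails
# despite sufficient fold-change, 1 sits below the fold gate.
make_standin_cohort <- function() {
  samples <- paste0("S", 1:6)
  up <- c(1, 2, 4, 8, 16, 32)
  flat <- c(10, 11, 12, 11, 10, 12)
  prm <- abundance_panel(rbind(G1 = up, G2 = up, G3 = up, G4 = up),
                         "prm_ratio", samples = samples)
  rna <- abundance_panel(rbind(G1 = up, G2 = up, G3 = flat, G4 = up),
                         "tpm", samples = samples)
  wb <- abundance_panel(rbind(ab1 = up * 2,       # tracks: passes both
                              ab2 = up * 5,       # tracks: passes both
                              ab3 = up * 3,       # tracks prot; RNA flat
                              ab4 = rev(up)),     # anti-tracks: fails both
                        "band_intensity", samples = samples)
  antibodies <- data.frame(
    antibody_id = paste0("ab", 1:4),
    target_gene = paste0("G", 1:4),
    platform = rep("prm", 4),
    stringsAsFactors = FALSE)
  list(wb = wb, orth = list(prm = prm), rna = rna, antibodies = antibodies)
}
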