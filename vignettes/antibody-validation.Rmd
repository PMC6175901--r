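---
title: "Five-pillar enhanced validation of Western blot antibodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Five-pillar enhanced validation of Western blot antibodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abvalidate)
```

## The problem

A Western blot band of "the expected size" is weak evidence that an
antibody binds its intended target: thousands of proteins comigrate at any
given apparent molecular weight, and conversely a specific antibody can be
wrongly rejected when its target runs off-size because of processing or
modification. `abvalidate` scores each antibody with up to five
independent strategies and aggregates the per-pillar outcomes
(`enhanced`, `not_validated`, `uncertain`, `not_done`) into a
per-antibody report. The package's scope is the decision layer: it
consumes quantification matrices (RNA-seq TPM, PRM ratio-to-standard, TMT
median intensities), lane tables of band positions and densitometry
intensities, and gel-slice peptide-count tables — never raw spectra,
reads, or blot images.

## The decision rules

**Orthogonal (panel mode).** Let $b_s$ be the dominant-band intensity in
sample $s$ (divided by the loading-control intensity when one was
recorded) and $a_s$ the orthogonal abundance. The pillar computes Pearson
$r(b, a)$ over the panel and the fold-change
$\mathrm{FC}(a) = (\max a + c)/(\min a + c)$ with pseudocount $c$
(default 0.1). The decision is:

* $\mathrm{FC}(a) < 5$ → `uncertain`: when the target barely varies
  across the panel, a low $r$ is expected even for a perfectly specific
  antibody, so the assay is inconclusive rather than failed;
* otherwise $r > 0.5$ → `enhanced`, else `not_validated`.

Both thresholds are strict inequalities on the side the rule names: the
correlation rule is "*r* above 0.5", so $r = 0.5$ exactly does **not**
validate, while the variability gate rejects only "fold below 5", so a
fold-change of exactly 5 proceeds to the correlation. Degenerate inputs
(zero-variance series, fewer than three samples after pairwise deletion
of missing lanes) map to `uncertain`, never to an error: they are
biology, not bugs. Correlation is computed on the linear scale by
default; `log_transform = TRUE` correlates $\log_2(v + c)$ instead. We
default to linear because relative band intensities are compared
per-antibody and the statistic is already invariant to the (arbitrary,
scanner-dependent) intensity scale; the option exists because nothing in
the procedure pins the scale down.

**Orthogonal (two-line standardized assay).** With exactly two samples a
correlation is meaningless, so the rule becomes: fold-change ≥ 5 *and*
matching ordering of bands and orthogonal levels → `enhanced`; ordering
matches but fold < 5 → `enhanced` only if the band size is independently
supported (theoretical MW or capture MS), else `uncertain`; contradictory
ordering → `not_validated`. "Trend" is strict ordering agreement; ties
give no trend and score `uncertain`.

**Capture MS (virtual Western).** The gel lane is cut into ordered slices
(slice 1 at the top, each with an explicit MW range, so non-uniform slice
widths are representable); per-slice peptide counts, summed over
replicates, form the protein's migration profile. The modal slice is the
argmax, ties broken toward the lower index (higher MW) for determinism.
The band is `enhanced` when the protein is detected (≥ 1 peptide in ≥ 1
replicate — identification, not quantification, is what this pillar uses)
and the band's slice is within $k$ slices of the modal slice
(`mw_tolerance_slices`, default 1); within $2k$ it is `uncertain`,
reflecting bands that fall just outside the expected window through
gel-cutting imprecision; beyond that, `not_validated`. An undetected
protein is `uncertain` (absence of MS evidence is not evidence of
non-specificity). When several cell lines were sliced, support in one
line suffices by default (`require_all_lines = TRUE` demands all). A
`crowding_flag` marks bands between 30 and 70 kDa, where comigration
makes this — the weakest — pillar least reliable. The $k$/$2k$ window is
our quantification of a criterion that lab practice states only
narratively ("the band matched the peptide profile"); it is the
deliberately simplest rule with one knob.

**Independent antibody.** Two antibodies on the same target qualify only
with non-overlapping epitope intervals (1-based inclusive amino-acid
coordinates); overlap → `uncertain`. Across the shared samples where both
detect a band, dominant-band MWs must agree within `mw_gap_log10`
(default 0.05 in log10 MW, ≈ 12%, about one ladder interval) and the
intensity profiles must agree ($r > 0.5$ with ≥ 3 shared detections,
ordering agreement with 2). Size disagreement in any shared sample is
scored `uncertain` with a `discordant_partner` metric — the discordance
indicts the *partner's* specificity, not necessarily the antibody under
test.

**Genetic.** With control band intensity $I_0$ and post-knockdown
intensities $I_j$, the best reduction is $1 - \min_j I_j / I_0$; strictly
more than `kd_min_fraction` (0.25) → `enhanced`. Failure is `uncertain`
by default because an unresponsive band is most often a failed siRNA, a
technical fault of the method; `kd_verified = TRUE` (independent evidence
the knockdown worked) remaps failure to `not_validated`.

**Recombinant.** Overexpression lane vs matched control lane: no
expression in the recombinant line → `uncertain`; dominant
overexpression band ≥ `oe_min_ratio` (5) × the control band at the same
size (absent control band contributes only the pseudocount) →
`enhanced`; control band at least as strong → `not_validated`; ratios in
between → `uncertain`.

**Aggregation.** A report holds all five pillar slots (missing pillars
`not_done`) and `n_enhanced` ∈ 0–5; cohort summaries tabulate
"validated by ≥ k pillars", which is non-increasing in k by construction.

## The gel model

Ladder calibration interpolates linearly in (migration, log10 MW)
between knots — the standard SDS-PAGE working model — with strict
monotonicity enforced and extrapolation refused by default (the flanking
segments can be extended explicitly). Theoretical MW is the sum of
*average* (not monoisotopic) residue masses plus one water; gel-scale
physics sees average masses, and no PTMs are applied. Proteome MW
distributions are binned on the log2 scale with exact count conservation;
the intracellular vs secreted/membrane split is an input label, not a
prediction.

## The synthetic-data generators

Every generator is seeded and bit-reproducible, and emits ground-truth
labels sufficient to score every pillar. Defaults mirror the standard
study design: an 8-cell-line panel (A431, A549, HEK 293, HeLa, Hep G2,
RT4, SH-SY5Y, U-2 OS), per-gene log2 expression spread uniformly over a
6-log2 window (`fold_range_log2 = 6`), latent RNA–protein correlation
`rna_protein_rho = 0.9`, multiplicative lognormal noise with
`noise_sd_log = 0.2` on band intensities — lognormal abundance and
multiplicative densitometry noise being the standard models for such
data. Protein log-abundance is built from the standardized RNA values
with correlation ρ plus Gaussian noise, then confined to the gene's
expression window, so a low-variability gene is low-variability at the
protein level too; the `low_variability` scenario uses
`fold_range_log2 = 2` (at most fourfold), which makes the variability
gate deterministic. Gel slice sets use 50 slices uniform in log2 MW over
10–250 kDa; a protein's expected peptide count is `base_lambda` (20) in
its home slice, decaying geometrically with `spillover = 0.25` per slice,
with Poisson counts split over 3 replicates — peptide totals of a few
dozen per protein, the scale typical of shotgun slice data. An abundance
floor (`detection_floor`) yields all-zero counts for low-abundance
proteins, exercising the missing-data paths. Scenario failure modes:
`off_target` bands track a decoy gene at a similar size, `mw_shifted`
displaces the band, `multi_band` adds weaker off-size bands around a
dominant target band.

What the generators do *not* emulate — and hence what passing tests do
not show about real blots: saturation and background of densitometry,
correlated noise across lanes of one membrane, isoform mixtures and
proteolytic fragments, epitope masking, partial knockdown off-target
effects, or non-Poisson peptide sampling. Recovery rates on synthetic
cohorts certify the decision logic, not field performance of any real
antibody.

## Problem sizes and numerical choices

The test suite and the acceptance script run 200 antibodies per scenario
(a size at which the binomial noise on a recovery rate is ≈ 2–3
percentage points), 1,000 random series for the correlation oracle, and
30 sequence draws for the 450-residue size check; the whole suite runs in
well under a minute. Slice-boundary containment uses a 1e-12 kDa
tolerance so a band exactly on a boundary lands in the higher-MW slice
deterministically. Fold-change with a positive pseudocount is only
asymptotically scale-invariant, which is why the scale-invariance
property is stated (and tested) at `pseudocount = 0`.

## Cohort reproduction

`reproduce_cohort()` recomputes orthogonal-validation tallies (pass
counts by proteomics and by RNA, failures despite sufficient fold-change,
low-fold cases, genes with max TPM > 10) from tables in a data directory
(`wb.tsv`, `prm.tsv`/`tmt.tsv`, `rna.tsv`, `antibodies.tsv`). No cohort
tables are bundled; without them the stage reports `"data unavailable"`
and the machinery is exercised on a synthetic stand-in cohort with
tallies known by construction. Because band-intensity correlations can
reasonably be computed on the linear or the log2 scale, the stage
reports both variants.

## Known limitations

The independent-antibody MW tolerance and the capture-MS slice window are
package choices where the field's practice is qualitative; both are
configurable and all decisions carry their metrics so any cohort can be
re-scored under different thresholds. Isoform-aware peptide mapping,
FDR control and identifier mapping are out of scope — inputs are assumed
to be gene-level and already quality-controlled.
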