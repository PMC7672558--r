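---
title: "Bioenergetic and transcriptomic analysis of hypoxic cell cultures with hypoflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bioenergetic and transcriptomic analysis of hypoxic cell cultures with hypoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoflux)
```

## The experimental design this package analyses

`hypoflux` implements the computational analysis of a two-condition
cell-culture experiment in which cultures (the motivating system is
human astrocytes) are held under normoxia or hypoxia and profiled on
three platforms:

1. **Extracellular flux** ("Seahorse"-type) plates measuring oxygen
   consumption rate (OCR, pmol O~2~/min) and extracellular acidification
   rate (ECAR, mpH/min) per well through a five-phase injection series:
   glucose-free baseline, then glucose, oligomycin, FCCP, and
   rotenone/antimycin A.
2. **Expression microarrays** yielding a log2 RMA-normalized
   probeset-by-sample matrix (normalization itself is upstream of this
   package; we consume the normalized matrix).
3. **qPCR validation** of candidate genes with a housekeeping
   reference, quantified by the ΔΔCt method.

Every analysis stage can be exercised without any external data through
the seeded generators `simulate_flux_plates()`, `simulate_expression()`
and `simulate_qpcr()`, which are first-class, tested components, not
test fixtures.

## Flux corrections

**Low-oxygen rate correction.** Under low ambient oxygen the instrument
registers an apparent plate-wide OCR offset. Wells injected with sodium
sulphite — a chemical oxygen scavenger with zero biological respiration
— read that artifact directly. Vendor software performs this correction
by an undocumented proprietary algorithm; `correct_hypoxia_rates()`
implements a transparent stand-in: at each measurement cycle the median
OCR over sulphite reference wells is subtracted from every non-blank
well. The median (rather than mean) resists a single misbehaving
reference well; with the recommended two reference wells it equals the
mean. ECAR is left untouched because sulphite scavenges oxygen without
acidifying the medium; whether the original analysis corrected ECAR is
not documented, and we deliberately do not.

**Cell-number normalization.** Per-well DNA-binding fluorescence
(CyQUANT-type) proxies cell number. `normalize_to_cell_count()`
subtracts the mean blank-well fluorescence as background, then
multiplies each sample well's rates by `M / (F_w - background)`, with
`M` the mean background-subtracted sample fluorescence of the plate.
Dividing by relative rather than absolute fluorescence keeps rates in
instrument units at the plate's average cell density. Note the exact
invariant of this convention: the *fluorescence-weighted* plate mean of
normalized rates equals the unweighted raw mean (the unweighted mean is
not preserved — a low-fluorescence well is scaled up more than a
high-fluorescence well is scaled down).

## Derived bioenergetic metrics

With per-phase OCR/ECAR summaries (`summarize_phases()`, mean of the
cycles in a phase by default; `last_cycle` is available because some
labs prefer the reading closest to post-injection steady state):

| metric | definition |
|---|---|
| MR (mitochondrial respiration) | OCR~glucose~ − OCR~rot/AA~ |
| PL (proton leak) | OCR~oligomycin~ − OCR~rot/AA~ |
| CR (coupled respiration) | MR − PL = OCR~glucose~ − OCR~oligomycin~ |
| SRC (spare respiratory capacity) | OCR~FCCP~ − MR |
| NG-ECAR (non-glycolytic) | ECAR~pre-glucose~ |
| glycolytic ECAR | ECAR~glucose~ − ECAR~pre-glucose~ |
| glycolytic capacity | ECAR~oligomycin~ − ECAR~glucose~ |
| glycolytic reserve | ECAR~oligomycin~ − glycolytic ECAR |

Two definitional choices deserve comment.

* **Coupled respiration.** A literal reading of the originating
  protocol ("remove OCR in the presence of oligomycin from
  mitochondrial respiration", i.e. CR = MR − OCR~oligo~) is
  inconsistent with reporting CR and PL as complementary percentages of
  MR (84.3% + 15.7% = 100%). We default to the self-consistent reading
  CR = MR − PL, under which CR% + PL% is exactly 100; the literal
  variant is available via `cr_method = "literal"`.
* **Glycolytic reserve.** The definition implemented (reserve =
  ECAR~oligo~ − glycolytic ECAR = capacity + NG-ECAR) is *wider* than
  the common convention (capacity − glycolytic ECAR). It is the
  protocol's literal formula and is kept; users comparing against other
  software should be aware of the difference.

Numerically, the identities MR = CR + PL, reserve = capacity + NG-ECAR
and CR% + PL% = 100 are computed *by construction* (e.g. MR is stored
as CR + PL) so they hold bit-exactly; leaving each to independent
floating-point subtractions breaks exact equality on a few percent of
random inputs. Wells with MR = 0 yield `NA` percentages with an
explicit `pct_undefined` flag, and OCR/ECAR equilibrium ratios
(`ratio_PrG`, `ratio_PsG`, `ratio_FCCP`; higher = more aerobic) are
likewise flagged when the phase ECAR is zero, so degenerate wells never
propagate silent NaNs.

## The statistical layer

`compare_groups()` reproduces the gated testing procedure used for flux
metrics:

1. **Transform.** Percentage-of-MR metrics are transformed
   `Y -> 1/Y -> logit(1/Y)` (equivalently −ln(Y−1)) before testing; the
   registry in `compare_profiles()` enforces this for `CR_pct_MR`,
   `PL_pct_MR` and `SRC_pct_MR`. The composite requires Y > 1 on the
   percent scale and values at or below 1 raise a domain error rather
   than being clamped.
2. **Normality gate.** Kolmogorov–Smirnov (Lilliefors-corrected, the
   form Prism computes), D'Agostino–Pearson (implemented here:
   skewness/kurtosis z statistics combined into K² against χ²₂, since
   no installed R package provides the omnibus test; it matches
   scipy's reference values to 10 decimal places) and Shapiro–Wilk, on
   both groups. Tests whose preconditions fail (D'Agostino–Pearson
   needs n ≥ 8, Lilliefors n ≥ 5, any test a non-constant sample) are
   recorded as *not applicable* rather than failing the gate; with no
   applicable test the gate conservatively chooses the non-parametric
   branch.
3. **Decision rule.** The default requires *every applicable* test to
   pass (p > 0.05) in both groups before the parametric branch —
   deliberately conservative. Because up to six tests can each trip at
   the 5% level, Normal data take the parametric branch in only ~82% of
   cases at n = 50 (floor 0.95⁶ ≈ 0.74 under independence);
   `rule = "majority"` restores a ≥ 95% parametric rate where that
   matters more than conservatism.
4. **Test.** Welch's t (unpaired) or paired t on the parametric branch;
   Mann–Whitney or Wilcoxon signed-rank otherwise. The full procedure's
   type-I error on Normal nulls is 0.0485 at α = 0.05 (10,000
   simulations in `scripts/acceptance.R`).

Effect sizes are reported as `percent_change()` — 100·(mean~hyp~ −
mean~norm~)/mean~norm~, negative for reductions — always on the raw
scale even when testing happened on the transformed scale.
`percent_change_se()` provides a delta-method standard error treating
the group means as independent.

**The analysis unit is the plate.** The sulphite correction subtracts
one shared reference series from all wells of a hypoxia plate, so wells
within a plate are positively correlated; treating 27 pooled wells as
independent understates the sampling error of ratio metrics (measured:
~2.2× for SRC%). Downstream inference therefore aggregates wells to
plate means — mirroring the laboratory practice of averaging the 9–10
wells of each biological replicate — before testing or
standard-error computation.

## Differential expression and enrichment

`differential_expression()` computes, per probeset, the mean log2
difference (hypoxia − normoxia), a two-sample t p-value, and the signed
linear fold change (d ≥ 0 → 2^d, d < 0 → −2^−d, so −2.5 means 2.5-fold
down and |FC| ≥ 1 always). Two reporting stringencies are flagged:
strict (|FC| ≥ 2, p ≤ 0.05) and relaxed (|FC| > 1.2, p ≤ 0.05), the
latter used for immune-family surveys. The default statistic is the
pooled (Student) t: at the n = 3/group designs typical here it is
exactly calibrated (empirical type-I 0.0495 on 10,000 null probesets),
whereas Welch's t is conservative below about n = 5 (~0.037 measured at
n = 3); `var_equal = FALSE` selects Welch. Filtering follows the raw
p ≤ 0.05 convention of the motivating analysis — no multiple-testing
correction by default, with an optional Benjamini–Hochberg column —
and all counting is probeset-level, with gene-level counts emitted
alongside when an annotation maps probesets to symbols.

`ora()` implements the over-representation test behind
DAVID-style pathway reports: the exact hypergeometric upper tail of the
overlap between the DE list and each gene set against the array
background, plus the conservative EASE variant (overlap decremented by
one). `pca_qc()` projects samples onto the first two principal
components of the probeset-centered matrix and flags samples more than
3 pooled within-group SDs from their group centroid.

## ΔΔCt quantification

`delta_delta_ct()` normalizes target Ct to the housekeeping gene per
sample, contrasts paired hypoxia/normoxia samples, and reports both
RQ = 2^−ΔΔCt and −ΔΔCt (the log2 effect), since relative-expression
axes are reported in both conventions. Amplification efficiency is
fixed at the doubling assumption; efficiency-corrected variants are out
of scope. `qpcr_test()` is the paired Student t on per-pair ΔCt, with
an explicit undefined flag when pair differences have zero variance.
Pairing must be supplied (`pair_id`): which runs constitute a pair is
an experimental fact the data file must state.

## What the generators emulate — and what they do not

`simulate_flux_plates()` draws, per sample well, a multiplicative level
L~w~ ~ lognormal(0, `well_cv`) — multiplicative because rates are
positive and scale with seeded cell number — and adds independent
per-cycle Gaussian noise. On the hypoxia plate a constant apparent-OCR
offset is added to every non-blank well and read directly by the
sulphite wells, giving the correction real signal to remove. Cell
fluorescence is drawn independently of L~w~; real fluorescence
correlates with the metabolic level of the well, so the simulated
normalization step adds variance rather than removing it — a
conservative choice for power assessment.

The default phase means are documented constants chosen so the true
condition contrasts have the direction and, where the metric
definitions permit, the approximate magnitude seen in hypoxic
astrocytes: MR −80.7%, pre-glucose OCR −82.6%, post-glucose −72%,
CR% 84.3 → 66.7, SRC% 135.5 → 92.2, glycolytic ECAR +38%, capacity
−52%. Two published magnitudes cannot be reproduced as stated: a
90.7% reserve reduction is arithmetically unreachable under the
literal reserve = capacity + NG-ECAR definition when capacity falls
52% and NG-ECAR mildly, so the preset reproduces the direction
(~−41%); and the hypoxia PL% (28.2 with CR% 66.7, summing to 94.9)
cannot hold under the exact percentage split, so PL% is 33.3. Defaults:
9 sample wells, 2 sulphite wells, 1 blank per 24-well plate, 3 cycles
per phase (instrument convention; the protocol does not state cycle
counts), `well_cv` 0.1, cycle noise SD 0.5 rate units.

`simulate_expression()` spikes a configurable fraction of probesets up
and down by a fixed log2 effect on Normal(baseline, 0.35) backgrounds
(0.35 log2 units is a typical within-group residual SD on
RMA-normalized arrays); 3 samples per group by default, the smallest
testable design. It does not emulate probe-level effects,
intensity-dependent variance, or correlation between probesets of one
gene — so passing recovery tests demonstrate correctness of the
filtering arithmetic and calibration of the test under the stated
model, not robustness to array artifacts. `simulate_qpcr()` adds a
pair-level Ct shift shared by both conditions of a pair (inducing the
correlation that motivates paired testing; it cancels exactly in ΔΔCt)
plus independent technical Ct noise.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise: conservation
identities on 10,000 randomized viable wells; oracle equivalence on
1,000 random profiles, brute-force DE counts, and exact ORA tail
enumeration for all margins ≤ 30; parameter recovery over 500
replicates of the full study-scale design (6 plate-pairs × 9 wells);
and calibration on 10,000 gate+test simulations and 10,000 null
probesets. These sizes give binomial standard errors well inside the
asserted bands while keeping a full run to a few minutes.

## Known limitations

* The sulphite correction is a documented stand-in, not the vendor
  algorithm; on real exported data the two can differ.
* ECAR is not buffering-power corrected to proton efflux, and ATP
  production rates are not modeled.
* The expression arm consumes an already-normalized matrix; RMA,
  present/absent calls and probe remapping are upstream.
* `ora()` tests user-supplied gene sets; it ships no pathway database.
* Percentage metrics at or below 1% are outside the reciprocal-logit
  domain and are rejected, not clamped.
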