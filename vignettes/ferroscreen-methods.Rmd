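---
title: "Methods and design notes for the ferroscreen pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for the ferroscreen pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferroscreen)
```

ferroscreen implements four analysis stages used to characterize
ferroptosis sensitivity in cancer cell panels — a pooled CRISPR resistance
screen, lipidomic differential analysis, dose-response quantification, and
drug-sensitivity selectivity testing — together with synthetic-data
generators that plant known ground truth. This vignette documents the
models, the parameters that matter, the numerical choices, and the places
where the design was genuinely open and we had to pick a convention.

## CRISPR resistance screen

A resistance (suppressor) screen selects cells under a lethal compound;
sgRNAs that disable genes required for killing become enriched relative to
the vehicle arm. The analysis is:

1. **RPM normalization** (`rpmNormalize`): each sample is scaled to a total
   of 10^6 reads, removing depth differences between conditions.
2. **Per-sgRNA enrichment** (`sgrnaEnrichment`):
   `log2FC = log2((RPM_trt + c) / (RPM_ctrl + c))` with pseudocount
   `c = 1` RPM on both sides to stabilize low counts.
3. **Empirical-null p-values**: the screen has one sample per condition, so
   no replicate-based test exists. We standardize the per-condition log2FC
   vector with a robust z-score, `z = (x − median) / (1.4826 · MAD)`, and
   take normal-tail p-values. The median/MAD null assumes the large
   majority of sgRNAs are unaffected by treatment, which holds in a
   genome-wide library where true resistance genes are rare. A one-sided
   (enrichment-only) option exists; the default is two-sided, which is the
   more conservative reading of an unspecified "p < 0.05" rule. If the MAD
   degenerates to zero the code falls back to a standard-deviation z.
4. **Gene-level hit rule** (`callGeneHits`): genes with 3–10 sgRNAs are
   eligible; an sgRNA passes when `log2FC ≥ log2(2)` **and** `p < 0.05`; a
   gene scores in a condition with ≥ 2 passing sgRNAs; the final call
   intersects the treated conditions (day-4/6/8 exposures), with a union
   mode available. "2-fold enrichment" is interpreted on the RPM ratio,
   not raw counts.

`coverageCheck` implements the library-representation arithmetic
(`cells × infection rate / library size`) used to confirm that a screen
maintains > 500 cells per sgRNA.

**Interpretation caveat.** The per-sgRNA p-value definition is an
interpretation: with only the printed rule ("at least 2 sgRNAs with at
least 2-fold enrichment and p < 0.05") and no replicates, an empirical
null is the self-contained choice. Hit lists from replicate-based or
rank-aggregation tools (MAGeCK-style) will differ in borderline calls.

## Lipidomics

LC-MS lipid identities are *summed compositions*: class plus total acyl
carbons and total double bonds (e.g. `PE C38:4`), with no chain-level
resolution. `parseLipidAnnotation` accepts `<CLASS> C<carbons>:<db>` in
either token order, case-insensitive, across 15 classes (CE, Cer, MAG,
DAG, TAG, LPC, LPE, PC, PE, ePC, ePE, PI, PS, SM, FFA); the chain count
(1, 2 or 3) follows from the class.

**PUFA classification** (`classifyPufa`). Whether a summed composition must
contain a polyunsaturated chain (≥ 2 double bonds on one chain) is a
pigeonhole question: with `k` chains and `DB` total double bonds, every
split of `DB` forces some chain to ≥ 2 exactly when `DB ≥ k + 1`. This is
the weakest class-aware rule that *guarantees* a PUFA chain, and it
reproduces the canonical examples (PE C38:4 and arachidonic FFA C20:4 are
PUFA; TAG C50:1 is not). Stricter conventions can be set per class via
`LipidClassConfig(pufaMinDbOverride = ...)`. We do not subtract the
vinyl-ether double bond of plasmalogens (ePC/ePE) before classification,
because whether source tables count it is annotation-dependent; an override
for those classes is the escape hatch.

**Normalization and testing.** `medianNormalize` equalizes per-sample
medians (the between-sample normalization for LC-MS loading differences).
`differentialAbundance` computes `log2(mean_test / mean_reference)` per
species, a two-tailed equal-variance Student t-test on log2 abundances
(log transformation stabilizes the multiplicative noise of intensity
data), and BH adjustment across species. Species with any zero abundance
are flagged "nd" (not detectable) and excluded from testing rather than
imputed.

**Compositional caveat.** Median normalization assumes most species are
unchanged. When a large fraction of the lipidome truly shifts (as with the
planted PUFA depletion affecting roughly half the simulated species),
normalizing by sample medians absorbs part of the real signal. The
differential stage is therefore applied to tables that are already on a
comparable scale — the synthetic generator emulates such a table directly —
and `medianNormalize` is reserved for raw intensity tables where the
assumption holds.

## Dose-response

`makeDilutionSeries(max, n, fold)` builds the geometric plate series
`max, max/fold, …` (e.g. 11-point 2-fold from 20 µM reaches 0.01953 µM).
`normalizeViability` divides by the vehicle-well mean; values above 1
(apparent stimulation) are preserved, negatives floored at 0.

`fitSigmoid` fits the 4-parameter logistic
`v(c) = bottom + (top−bottom)/(1 + (c/EC50)^h)` by Levenberg–Marquardt
(minpack.lm). Initialization: top = max observed, bottom = min observed,
EC50 = geometric midpoint of the series, h = 1; EC50 is box-bounded to
`[min/4, 4·max]` of the assayed range (an EC50 far outside the series is
not identifiable). Constant data short-circuit to the degenerate
`top = bottom` fit with zero residual; non-convergence returns the best
iterate flagged `converged = FALSE`.

`normalizedAUC` uses the trapezoid over the **log-concentration axis**.
Because the series is geometric, equal log spacing reduces it to
`(v₁/2 + v₂ + … + v_{n−1} + v_n/2)/(n−1)`, which is exactly 1 for a flat
curve at viability 1 — the "normalized to 1" convention for AUC
sensitivity scores. Whether public AUC resources use the identical
trapezoid is not derivable from their documentation; this is our stated
convention, not a claim of numerical equivalence with CTRP.

`compareCurves` quantifies "significantly shifted" sensitivity curves, a
phrase with no printed definition: we compute one AUC per replicate
(replicate j takes the j-th well at every concentration), report the mean
AUC difference, and test with the Student t-test across replicates; BH is
applied by the caller across a candidate panel. This assumes replicate
wells are exchangeable across concentrations (true for plate replicates
seeded from one suspension).

## Selectivity

`applyInclusionFilters` applies the two coverage rules — compounds profiled
in ≥ 2/3 of lines, then lines profiled with ≥ 50% of *retained* compounds —
in one pass each. The printed criteria do not fix an order or iteration;
one-pass compounds-then-lines is deterministic and idempotent, which is why
we chose it. `compoundSelectivity` runs a two-sided Mann–Whitney test per
compound (histotype group vs all other lines; missing values dropped
pairwise), reports the difference of group means as effect size (the
volcano-plot x-axis convention; a median-difference variant would be
trivial to add), and BH-adjusts across compounds. `lineageRanking` orders
lineages (> 5 lines) by mean AUC, most sensitive first.

## Statistical primitives

* `studentTTest`: equal-variance two-sample t (the named test is Student's,
  not Welch's; Welch behind `welch = TRUE`). Zero-variance input is handled
  explicitly (equal means → p = 1).
* `mannWhitneyU`: exact p by full null enumeration when `n1 + n2 ≤ 12` and
  the data are tie-free — small enough that exactness is free, large enough
  to cover the small-group comparisons here — otherwise the normal
  approximation with tie and continuity corrections. Ties always route to
  the approximation. Two-sided p-values are doubled and capped at 1.
* `bhAdjust`: BH step-up, validated against an O(m²) suffix-minimum oracle
  in the tests.
* `robustZ`: median/MAD z-scores; errors on zero MAD so the caller makes an
  explicit fallback decision.

## Synthetic-data generators

The generators define the study conditions for every recovery test; their
defaults are fixed and not tuned per analysis.

* **Screen** (`simulateScreenCounts`): negative-binomial counts with
  variance `m + α·m²` (default α = 0.05, a typical pooled-screen
  overdispersion), per-sgRNA baselines log-normal (sdlog 0.5) to mimic
  library skew, 4 sgRNAs/gene, one control plus three treated conditions.
  Planted genes carry the effect on 75% of their guides (3 of 4) so the
  ≥ 2-passing-sgRNA rule is genuinely exercised, with an 8-fold default
  enrichment; expected sample totals are held at the configured depth
  (default 500 reads/sgRNA), since sequencing depth is fixed by the
  instrument and enrichment reshapes the composition. What it does *not*
  emulate: guide-specific efficiency, PCR jackpotting, multi-infection, or
  depletion (essentiality) signal — so passing recovery tests show the hit
  rule works under the stated count model, not that it matches any
  replicate-free real screen's noise.
* **Lipidome** (`simulateLipidome`): ~150 species across all 15 classes
  (about the size of a routinely annotated panel), log-normal baselines,
  log2-scale Gaussian noise (default sd 0.25), 3 samples/group (the
  standard LC-MS replicate design), and a −2 log2 depletion applied to
  every PUFA-classified species in non-reference groups. Real lipidomes
  have correlated species and class-level batch structure; the generator
  does not.
* **Viability** (`simulateViability`): 4PL plus homoscedastic Gaussian
  noise truncated at 0 (no published noise model; plate replicates at 2%
  of signal is a realistic CellTiter-Glo figure), 7-point 2-fold series
  from 5 µM, 4 replicates.
* **Sensitivity matrix** (`simulateSensitivityMatrix`): 110 lines over 5
  lineages, 50 compounds, per-compound baseline AUC ~ U(0.6, 0.95), line
  noise sd 0.08, one planted compound shifted by −0.4 in the 10-line
  target lineage, 5% missingness, AUC clipped to [0, 1]. This is a
  deliberate scale-down of a public sensitivity resource (hundreds of
  lines and compounds) that keeps the 10-vs-100 group-size geometry.

All generators take a single integer seed, restore the caller's RNG state,
and are byte-reproducible given the seed. `tumorVolume` implements the
caliper formula `V = L·W²/2`.

## Problem sizes and runtime

The test suite and the acceptance script run at desk scale by design:
1000-gene screens (4000 sgRNAs, 4 samples), 150-species lipidomes,
100-seed dose-response recovery loops, 200-table brute-force hit-caller
comparisons, and 110 × 50 sensitivity matrices. The full suite completes
in well under a minute on one CPU.

## Known limitations

* The per-sgRNA p-value and the curve-shift test are interpretations of
  underspecified published rules (documented above); hit lists are faithful
  to the stated thresholds but not guaranteed to match any specific
  published gene list.
* The PUFA rule classifies summed compositions only; chain-resolved
  (sn-position) identities are out of scope.
* AUC conventions differ between resources; compare AUCs produced by this
  package only with each other.
* No plate-effect correction, imputation, or batch modeling anywhere:
  inputs are assumed pre-cleaned to that level.
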