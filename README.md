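# ferroscreen

Tools for the computational analyses that establish lineage-selective
ferroptosis sensitivity in clear-cell carcinomas: pooled CRISPR
resistance-screen hit calling, lipidomics differential analysis with
polyunsaturated-lipid (PUFA) classification, dose-response fitting with
normalized area-under-curve (AUC) statistics, and CTRP-style drug-sensitivity
selectivity testing. Every stage comes with a synthetic-data generator that
plants known ground truth, so the whole pipeline is testable end to end
without any deposited dataset.

The package is written for computational biologists analysing GPX4-inhibitor
(e.g. ML210, RSL3) experiments in cancer cell panels, and for anyone who
needs a self-contained, oracle-tested implementation of these four analysis
stages.

## Methods at a glance

**CRISPR resistance screen.** Read counts are scaled to reads per million
(RPM) per sample. Per sgRNA and treated condition,
`log2FC = log2((RPM_trt + c)/(RPM_ctrl + c))` with pseudocount `c = 1`; a
robust z-score over all sgRNAs (median/MAD empirical null) yields a normal
p-value. A gene with 3–10 sgRNAs is a hit in a condition when at least 2
sgRNAs show ≥ 2-fold enrichment with p < 0.05, and a final hit when it
scores in every treated condition (day-4/6/8 drug exposures).

**Lipidomics.** Summed-composition annotations (`PE C38:4` = class, total
acyl carbons : total double bonds) are parsed and classified: a species must
contain a polyunsaturated chain exactly when `DB ≥ n_chains + 1`
(pigeonhole over the chains). Differential abundance per species is
`log2(mean_test/mean_WT)` with a two-tailed Student t-test on log2
abundances and Benjamini–Hochberg adjustment; class-level PUFA ratios
(e.g. PUFA-PE/ePE over total PE/ePE) summarize each sample.

**Dose-response.** Two-fold dilution series; viability normalized to the
vehicle (DMSO) mean; four-parameter logistic fit
`v(c) = bottom + (top−bottom)/(1+(c/EC50)^h)` by Levenberg–Marquardt; AUC is
the trapezoid over the log-concentration axis normalized so a flat curve at
viability 1 scores 1. Curve shifts (cDNA re-sensitization readout) are
tested on replicate-level AUCs.

**Selectivity.** A cell line × compound normalized-AUC matrix is filtered
(compounds profiled in ≥ 2/3 of lines, then lines profiled with ≥ 50% of
retained compounds); each compound is tested for histotype selectivity with
a two-sided Mann–Whitney U (group vs all other lines), BH-adjusted across
compounds; lineages with > 5 lines are ranked by mean AUC.

## Worked example

```r
library(ferroscreen)

## a 1000-gene screen with 20 planted resistance genes (8-fold enrichment,
## 3 of 4 sgRNAs active), sequenced at 500 reads per sgRNA
sim <- simulateScreenCounts(ScreenSimConfig(nGenes = 1000L, nPlanted = 20L,
                                            seed = 1L))
res <- screenHits(sim$counts, controlLabel = "DMSO")
hits <- res$geneHits[res$geneHits$hit, ]
head(hits[, c("gene_id", "n_sgrnas", "passing_d4", "passing_d6",
              "passing_d8", "hit")], 4)
#>       gene_id  n_sgrnas passing_d4 passing_d6 passing_d8       hit
#> 1    gene0129         4          3          3          3      TRUE
#> 2    gene0187         4          3          3          3      TRUE
#> 3    gene0270         4          3          3          3      TRUE
#> 4    gene0277         4          3          3          3      TRUE
sum(sim$truth$plantedGenes %in% hits$gene_id)   # 20 of 20 planted recovered
```

Each hit gene has 3 of its 4 sgRNAs passing the 2-fold / p < 0.05 rule in
all three treated conditions — exactly the planted design (75% of guides
active). With this seed all 20 planted genes are recovered with 0 false
positives among the remaining 980 genes.

```r
makeDilutionSeries(5, 7, 2)
#> DoseSeries: 7-point, 2-fold from 5 uM (min 0.07812 uM)

## planted -2 log2 PUFA depletion, 3 samples/group, log2 noise sd 0.25
lsim <- simulateLipidome(LipidomeSimConfig(seed = 7L))
d <- differentialAbundance(lsim$lipidome)
head(as.data.frame(d[order(d$adj_p),
                     c("annotation", "pufa", "log2fc", "adj_p")]), 4)
#>           annotation pufa    log2fc        adj_p
#> LPC C22:8  LPC C22:8 TRUE -2.232840 0.0006517138
#> TAG C60:5  TAG C60:5 TRUE -1.817969 0.0006531250
#> TAG C40:6  TAG C40:6 TRUE -2.206236 0.0006531250
#> TAG C52:4  TAG C52:4 TRUE -2.189594 0.0006531250

round(classPufaRatio(lsim$lipidome, c("PE", "ePE")), 3)
#>  WT_1  WT_2  WT_3  KO_1  KO_2  KO_3
#> 0.686 0.613 0.633 0.308 0.329 0.311
```

The top differential species are PUFA-classified with fitted log2 fold
changes near the planted −2, and the PUFA-PE/ePE fraction drops from ~0.64
in the reference group to ~0.32 in the depleted group.

A command-line front-end over the same functions lives at
`inst/scripts/ferroscreen.R`
(`Rscript inst/scripts/ferroscreen.R simulate --out out/ --seed 1`, then
`screen`, `lipids`, `dose`, `select`, or `run --config run.yaml`).

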