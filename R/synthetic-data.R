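# Synthetic-data generators with planted ground truth. Each generator
# emulates the statistical structure one analysis stage assumes (negative-
# binomial pooled-screen counts, log-normal lipid abundances with planted
# PUFA-selective depletion, 4PL viability curves, AUC matrices with one
# lineage-selective compound), so recovery against known truth is testable.

## Evaluate expr under a private seed, restoring the caller's random state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

# ---------------------------------------------------------------------------
# Screen simulation
# ---------------------------------------------------------------------------

#' Pooled-screen simulation configuration
#'
#' Parameters of the negative-binomial sgRNA count generator. Counts have
#' mean `m` and variance `m + dispersion * m^2`; per-sgRNA baseline
#' abundances are log-normal to mimic library skew. Planted resistance genes
#' have `fractionActive` of their sgRNAs drawn with mean multiplied by
#' `enrichmentFold` in every treated condition; expected sample totals are
#' held at `depth` (sequencing depth is fixed by the instrument, so
#' enrichment reshapes the composition rather than adding reads).
#'
#' @slot nGenes genes in the library.
#' @slot sgrnasPerGene guides per gene (default 4, within the eligible 3-10).
#' @slot nPlanted number of planted resistance genes.
#' @slot enrichmentFold treated/control expected ratio for active planted
#'   sgRNAs (1 = null).
#' @slot fractionActive fraction of a planted gene's sgRNAs that carry the
#'   effect, in `(0, 1]` (default 0.75 so the >=2-sgRNA rule is exercised).
#' @slot depth expected reads per sample.
#' @slot dispersion negative-binomial dispersion (> 0).
#' @slot conditions treated-condition labels (default d4/d6/d8 exposures).
#' @slot controlLabel the control condition label.
#' @slot seed integer generator seed.
#' @export
setClass("ScreenSimConfig",
  representation(nGenes = "integer", sgrnasPerGene = "integer",
                 nPlanted = "integer", enrichmentFold = "numeric",
                 fractionActive = "numeric", depth = "numeric",
                 dispersion = "numeric", conditions = "character",
                 controlLabel = "character", seed = "integer"))

setValidity("ScreenSimConfig", function(object) {
  msg <- character()
  if (object@nPlanted > object@nGenes)
    msg <- c(msg, "nPlanted must be <= nGenes")
  if (object@depth <= 0) msg <- c(msg, "depth must be > 0")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (object@enrichmentFold <= 0) msg <- c(msg, "enrichmentFold must be > 0")
  if (object@fractionActive <= 0 || object@fractionActive > 1)
    msg <- c(msg, "fractionActive must be in (0, 1]")
  if (!length(object@conditions)) msg <- c(msg, "need >= 1 treated condition")
  if (length(msg)) msg else TRUE
})

#' @param nGenes,sgrnasPerGene,nPlanted,enrichmentFold,fractionActive,depth,dispersion,conditions,controlLabel,seed
#'   see the class slots.
#' @rdname ScreenSimConfig-class
#' @export
ScreenSimConfig <- function(nGenes = 1000L, sgrnasPerGene = 4L,
                            nPlanted = 20L, enrichmentFold = 8,
                            fractionActive = 0.75,
                            depth = 500 * nGenes * sgrnasPerGene,
                            dispersion = 0.05,
                            conditions = c("d4", "d6", "d8"),
                            controlLabel = "DMSO", seed = 1L) {
  new("ScreenSimConfig", nGenes = as.integer(nGenes),
      sgrnasPerGene = as.integer(sgrnasPerGene),
      nPlanted = as.integer(nPlanted), enrichmentFold = enrichmentFold,
      fractionActive = fractionActive, depth = depth,
      dispersion = dispersion, conditions = conditions,
      controlLabel = controlLabel, seed = as.integer(seed))
}

#' Simulate a pooled resistance screen with planted hits
#'
#' @param config a [ScreenSimConfig-class].
#' @return list with `counts` (a [ScreenCounts-class]; one control sample
#'   plus one sample per treated condition) and `truth` (list:
#'   `plantedGenes`, `activeSgrnas`).
#' @export
simulateScreenCounts <- function(config) {
  stopifnot(is(config, "ScreenSimConfig"))
  validObject(config)
  .withSeed(config@seed, {
    nSg <- config@nGenes * config@sgrnasPerGene
    genes <- sprintf("gene%04d", seq_len(config@nGenes))
    geneOf <- rep(genes, each = config@sgrnasPerGene)
    sgIds <- paste0(geneOf, "_sg", seq_len(config@sgrnasPerGene))
    planted <- sort(sample(genes, config@nPlanted))
    nActive <- max(1L, round(config@fractionActive * config@sgrnasPerGene))
    activeSg <- unlist(lapply(planted, function(g)
      sample(sgIds[geneOf == g], nActive)))
    baseline <- rlnorm(nSg, meanlog = 0, sdlog = 0.5)
    samples <- c(config@controlLabel, config@conditions)
    cts <- matrix(0L, nSg, length(samples),
                  dimnames = list(sgIds, samples))
    for (s in samples) {
      w <- baseline
      if (s != config@controlLabel)
        w[sgIds %in% activeSg] <- w[sgIds %in% activeSg] * config@enrichmentFold
      mu <- config@depth * w / sum(w)
      cts[, s] <- rnbinom(nSg, mu = mu, size = 1 / config@dispersion)
    }
    sc <- ScreenCounts(cts, geneIds = geneOf, condition = samples)
    list(counts = sc,
         truth = list(plantedGenes = planted, activeSgrnas = sort(activeSg)))
  })
}

# ---------------------------------------------------------------------------
# Lipidome simulation
# ---------------------------------------------------------------------------

#' Lipidome simulation configuration
#'
#' Log-normal lipid abundances spanning the supported classes, with
#' PUFA-classified species depleted (or enriched) by a fixed log2 fold
#' change in every non-reference group — the structure of a
#' transcription-factor-knockout lipidomic comparison. Defaults: 3 samples
#' per group (the replicate design of LC-MS lipid profiling here), a -2
#' log2 depletion of PUFA species, and 0.25 log2-scale measurement noise.
#'
#' @slot classes named integer vector: species to simulate per lipid class.
#' @slot nSamplesPerGroup samples per group (>= 3).
#' @slot groups group labels, reference first (>= 2 groups).
#' @slot pufaDepletionLog2fc log2 fold change applied to PUFA species in
#'   non-reference groups.
#' @slot noiseSd log2-scale s.d. of measurement noise.
#' @slot seed integer generator seed.
#' @export
setClass("LipidomeSimConfig",
  representation(classes = "integer", nSamplesPerGroup = "integer",
                 groups = "character", pufaDepletionLog2fc = "numeric",
                 noiseSd = "numeric", seed = "integer"))

setValidity("LipidomeSimConfig", function(object) {
  msg <- character()
  if (length(object@groups) < 2) msg <- c(msg, "need at least 2 groups")
  if (object@nSamplesPerGroup < 3)
    msg <- c(msg, "need at least 3 samples per group")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  bad <- setdiff(names(object@classes), names(.LIPID_CHAIN_COUNTS))
  if (length(bad))
    msg <- c(msg, paste0("unknown lipid class: ", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @param classes,nSamplesPerGroup,groups,pufaDepletionLog2fc,noiseSd,seed
#'   see the class slots.
#' @rdname LipidomeSimConfig-class
#' @export
LipidomeSimConfig <- function(
    classes = c(TAG = 40L, PE = 15L, ePE = 10L, PC = 15L, ePC = 8L,
                PI = 6L, PS = 6L, LPC = 5L, LPE = 5L, DAG = 8L, MAG = 4L,
                CE = 6L, Cer = 6L, SM = 8L, FFA = 8L),
    nSamplesPerGroup = 3L, groups = c("WT", "KO"),
    pufaDepletionLog2fc = -2, noiseSd = 0.25, seed = 7L) {
  new("LipidomeSimConfig", classes = setNames(as.integer(classes),
                                              names(classes)),
      nSamplesPerGroup = as.integer(nSamplesPerGroup), groups = groups,
      pufaDepletionLog2fc = pufaDepletionLog2fc, noiseSd = noiseSd,
      seed = as.integer(seed))
}

## carbon/double-bond grids per chain count, roughly matching what C8 LC-MS
## lipid panels report
.lipidGrid <- function(nChains) {
  carbons <- switch(nChains, `1` = seq(14L, 26L, 2L),
                    `2` = seq(30L, 44L, 2L), `3` = seq(40L, 60L, 2L))
  expand.grid(carbons = carbons, db = 0:8)
}

#' Simulate a lipid abundance table with planted PUFA depletion
#'
#' @param config a [LipidomeSimConfig-class].
#' @return list with `lipidome` (a [LipidomeExperiment-class]) and `truth`
#'   (data.frame: `annotation`, `pufa`, `plantedLog2fc`).
#' @export
simulateLipidome <- function(config) {
  stopifnot(is(config, "LipidomeSimConfig"))
  validObject(config)
  .withSeed(config@seed, {
    anns <- unlist(lapply(names(config@classes), function(cls) {
      k <- .LIPID_CHAIN_COUNTS[[cls]]
      grid <- .lipidGrid(as.character(k))
      n <- config@classes[[cls]]
      if (n > nrow(grid))
        stop("class ", cls, " supports at most ", nrow(grid), " species")
      pick <- grid[sample(nrow(grid), n), ]
      sprintf("%s C%d:%d", cls, pick$carbons, pick$db)
    }))
    species <- parseLipidAnnotation(anns)
    pufa <- classifyPufa(species)
    nSp <- length(anns)
    baseline <- rlnorm(nSp, meanlog = log(1e6), sdlog = 1)
    groups <- rep(config@groups, each = config@nSamplesPerGroup)
    sampleNames <- paste0(groups, "_", seq_len(config@nSamplesPerGroup))
    ab <- matrix(0, nSp, length(groups),
                 dimnames = list(anns, sampleNames))
    for (j in seq_along(groups)) {
      shift <- if (groups[j] == config@groups[1]) 0 else
        ifelse(pufa, config@pufaDepletionLog2fc, 0)
      noise <- if (config@noiseSd > 0)
        rnorm(nSp, 0, config@noiseSd) else 0
      ab[, j] <- baseline * 2^(shift + noise)
    }
    truth <- data.frame(
      annotation = anns, pufa = pufa,
      plantedLog2fc = ifelse(pufa, config@pufaDepletionLog2fc, 0))
    list(lipidome = LipidomeExperiment(ab, group = groups,
                                       reference = config@groups[1]),
         truth = truth)
  })
}

# ---------------------------------------------------------------------------
# Viability simulation
# ---------------------------------------------------------------------------

#' Viability-curve simulation configuration
#'
#' Replicate viabilities are the four-parameter logistic evaluated at the
#' dilution-series concentrations plus homoscedastic Gaussian noise,
#' truncated below at 0. Defaults mirror a 384-well GPX4-inhibitor assay:
#' a 7-point 2-fold series from 5 uM with 4 replicates.
#'
#' @slot top,bottom asymptotes in `[0, 1.5]`, `bottom <= top`.
#' @slot ec50 half-maximal concentration, uM.
#' @slot hill Hill slope (> 0).
#' @slot series a [DoseSeries-class].
#' @slot nReplicates replicate wells per concentration.
#' @slot noiseSd Gaussian noise s.d. on the viability scale.
#' @slot seed integer generator seed.
#' @export
setClass("ViabilitySimConfig",
  representation(top = "numeric", bottom = "numeric", ec50 = "numeric",
                 hill = "numeric", series = "DoseSeries",
                 nReplicates = "integer", noiseSd = "numeric",
                 seed = "integer"))

setValidity("ViabilitySimConfig", function(object) {
  msg <- character()
  if (object@bottom > object@top) msg <- c(msg, "bottom must be <= top")
  if (any(c(object@top, object@bottom) < 0) ||
      any(c(object@top, object@bottom) > 1.5))
    msg <- c(msg, "top/bottom must lie in [0, 1.5]")
  if (object@ec50 <= 0) msg <- c(msg, "ec50 must be > 0")
  if (object@hill <= 0) msg <- c(msg, "hill must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param top,bottom,ec50,hill,series,nReplicates,noiseSd,seed see slots.
#' @rdname ViabilitySimConfig-class
#' @export
ViabilitySimConfig <- function(top = 1, bottom = 0, ec50 = 0.5, hill = 1,
                               series = makeDilutionSeries(5, 7, 2),
                               nReplicates = 4L, noiseSd = 0.02, seed = 1L) {
  new("ViabilitySimConfig", top = top, bottom = bottom, ec50 = ec50,
      hill = hill, series = series, nReplicates = as.integer(nReplicates),
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' Simulate replicate viability measurements
#'
#' @param config a [ViabilitySimConfig-class].
#' @return a normalized [ViabilityCurves-class].
#' @export
simulateViability <- function(config) {
  stopifnot(is(config, "ViabilitySimConfig"))
  validObject(config)
  .withSeed(config@seed, {
    conc <- concentrations(config@series)
    mu <- .fourPL(conc, config@top, config@bottom, config@ec50, config@hill)
    v <- matrix(rep(mu, config@nReplicates), ncol = config@nReplicates)
    if (config@noiseSd > 0)
      v <- v + matrix(rnorm(length(v), 0, config@noiseSd), nrow = nrow(v))
    ViabilityCurves(config@series, pmax(v, 0), normalized = TRUE)
  })
}

# ---------------------------------------------------------------------------
# Sensitivity-matrix simulation
# ---------------------------------------------------------------------------

#' Sensitivity-matrix simulation configuration
#'
#' Cell line x compound normalized-AUC matrix with exactly one planted
#' lineage-selective compound: its mean AUC in the target lineage is shifted
#' by `effect` (negative = more sensitive, as for a ferroptosis inducer in
#' clear-cell lines). Default panel: 10 target lines against 100 others
#' spread over 5 lineages.
#'
#' @slot nCellLines named integer vector, lineage -> line count.
#' @slot targetLineage the lineage carrying the planted effect.
#' @slot nCompounds compounds in the panel.
#' @slot effect mean AUC shift in the target lineage (negative lowers AUC).
#' @slot missingFraction fraction of entries set missing, in `[0, 1)`.
#' @slot seed integer generator seed.
#' @export
setClass("SensitivitySimConfig",
  representation(nCellLines = "integer", targetLineage = "character",
                 nCompounds = "integer", effect = "numeric",
                 missingFraction = "numeric", seed = "integer"))

setValidity("SensitivitySimConfig", function(object) {
  msg <- character()
  if (!object@targetLineage %in% names(object@nCellLines))
    msg <- c(msg, "targetLineage must be one of the simulated lineages")
  if (object@effect > 0)
    msg <- c(msg, "effect must be <= 0 (lowers AUC in the sensitive lineage)")
  if (object@missingFraction < 0 || object@missingFraction >= 1)
    msg <- c(msg, "missingFraction must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' @param nCellLines,targetLineage,nCompounds,effect,missingFraction,seed
#'   see slots.
#' @rdname SensitivitySimConfig-class
#' @export
SensitivitySimConfig <- function(
    nCellLines = c(CCC = 10L, lung = 25L, breast = 25L, colon = 25L,
                   skin = 25L),
    targetLineage = "CCC", nCompounds = 50L, effect = -0.4,
    missingFraction = 0.05, seed = 1L) {
  new("SensitivitySimConfig",
      nCellLines = setNames(as.integer(nCellLines), names(nCellLines)),
      targetLineage = targetLineage, nCompounds = as.integer(nCompounds),
      effect = effect, missingFraction = missingFraction,
      seed = as.integer(seed))
}

#' Simulate an AUC sensitivity matrix with one selective compound
#'
#' @param config a [SensitivitySimConfig-class].
#' @return list with `matrix` (a [SensitivityMatrix-class]) and `truth`
#'   (list: `selectiveCompound`, `targetLineage`).
#' @export
simulateSensitivityMatrix <- function(config) {
  stopifnot(is(config, "SensitivitySimConfig"))
  validObject(config)
  .withSeed(config@seed, {
    lineage <- rep(names(config@nCellLines), times = config@nCellLines)
    nLines <- length(lineage)
    lines <- sprintf("%s_%02d", lineage, unlist(lapply(config@nCellLines,
                                                       seq_len)))
    cpds <- sprintf("cpd%03d", seq_len(config@nCompounds))
    baseMean <- runif(config@nCompounds, 0.6, 0.95)
    auc <- matrix(rnorm(nLines * config@nCompounds,
                        mean = rep(baseMean, each = nLines), sd = 0.08),
                  nrow = nLines, dimnames = list(lines, cpds))
    planted <- sample(cpds, 1)
    tgt <- lineage == config@targetLineage
    auc[tgt, planted] <- auc[tgt, planted] + config@effect
    auc <- pmin(pmax(auc, 0), 1)
    if (config@missingFraction > 0) {
      drop <- runif(length(auc)) < config@missingFraction
      auc[drop] <- NA_real_
    }
    sm <- SensitivityMatrix(auc, lineage = lineage, isTarget = tgt)
    list(matrix = sm, truth = list(selectiveCompound = planted,
                                   targetLineage = config@targetLineage))
  })
}

# ---------------------------------------------------------------------------
# Xenograft volume
# ---------------------------------------------------------------------------

#' Caliper tumor volume
#'
#' Ellipsoid approximation from caliper length and width:
#' `V = L * W * W / 2` (mm^3).
#'
#' @param lengthL tumor length in mm (longest axis).
#' @param widthW tumor width in mm; must satisfy `lengthL >= widthW > 0`.
#' @return volume in mm^3.
#' @examples
#' tumorVolume(10, 6)  # 180
#' @export
tumorVolume <- function(lengthL, widthW) {
  if (any(widthW <= 0) || any(lengthL <= 0))
    stop("length and width must be positive")
  if (any(lengthL < widthW))
    stop("length must be >= width (caliper convention)")
  lengthL * widthW * widthW / 2
}
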