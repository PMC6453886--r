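#' @import methods
#' @importFrom stats median mad sd var setNames rnorm rlnorm rnbinom runif
#'   pnorm p.adjust t.test wilcox.test complete.cases prcomp
#' @importFrom utils read.delim write.table head modifyList
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData assay<-
NULL

## Lipid classes supported by the annotation grammar, with the number of acyl
## chains each class carries (summed-composition nomenclature).
.LIPID_CHAIN_COUNTS <- c(
  CE = 1L, MAG = 1L, LPC = 1L, LPE = 1L, FFA = 1L,
  Cer = 2L, DAG = 2L, PC = 2L, PE = 2L, ePC = 2L, ePE = 2L,
  PI = 2L, PS = 2L, SM = 2L,
  TAG = 3L
)

# ---------------------------------------------------------------------------
# Screen container
# ---------------------------------------------------------------------------

#' Pooled CRISPR screen count container
#'
#' `ScreenCounts` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds an sgRNA x sample matrix of sequencing read counts in the `"counts"`
#' assay. Each sgRNA (row) maps to exactly one gene (`rowData(x)$gene_id`);
#' each sample (column) carries a `condition` label in `colData` (one control
#' condition, e.g. `"DMSO"`, and one or more treated conditions, e.g. day-4 /
#' day-6 / day-8 drug exposures). [rpmNormalize()] adds an `"rpm"` assay with
#' per-sample reads-per-million scaling.
#'
#' @seealso [ScreenCounts()], [rpmNormalize()], [sgrnaEnrichment()],
#'   [callGeneHits()]
#' @export
setClass("ScreenCounts", contains = "SummarizedExperiment")

setValidity("ScreenCounts", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (any(!is.finite(cts)) || any(cts < 0) || any(cts != round(cts)))
      msg <- c(msg, "'counts' must be non-negative integers")
  }
  if (!"gene_id" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain 'gene_id'")
  if (!"condition" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'condition'")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "rownames (sgRNA ids) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct a ScreenCounts object
#'
#' @param counts integer matrix, sgRNAs in rows (rownames = sgRNA ids),
#'   samples in columns.
#' @param geneIds character vector, one gene id per sgRNA.
#' @param condition character vector, one condition label per sample.
#' @param timepoint optional per-sample time-point labels.
#' @return A [ScreenCounts-class] object.
#' @examples
#' cts <- matrix(rpois(12, 50), nrow = 4,
#'               dimnames = list(paste0("sg", 1:4), paste0("s", 1:3)))
#' sc <- ScreenCounts(cts, geneIds = c("A", "A", "B", "B"),
#'                    condition = c("DMSO", "d4", "d6"))
#' @export
ScreenCounts <- function(counts, geneIds, condition, timepoint = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("sg", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  if (length(geneIds) != nrow(counts))
    stop("'geneIds' must have one entry per sgRNA row")
  if (length(condition) != ncol(counts))
    stop("'condition' must have one entry per sample column")
  cd <- DataFrame(condition = as.character(condition),
                  row.names = colnames(counts))
  if (!is.null(timepoint)) cd$timepoint <- as.character(timepoint)
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(gene_id = as.character(geneIds),
                        row.names = rownames(counts)),
    colData = cd
  )
  new("ScreenCounts", se)
}

# ---------------------------------------------------------------------------
# Lipidome container
# ---------------------------------------------------------------------------

#' Lipid abundance container
#'
#' `LipidomeExperiment` extends [SummarizedExperiment::SummarizedExperiment]
#' with a species x sample `"abundance"` assay of non-negative lipid
#' abundances. Rows are summed-composition lipid species; `rowData` carries
#' the parsed identity (`annotation`, `lipidClass`, `nCarbons`,
#' `nDoubleBonds`, `nChains`, `pufa`). Columns carry a `group` label with one
#' reference group (stored in `metadata(x)$reference`).
#'
#' @seealso [LipidomeExperiment()], [medianNormalize()],
#'   [differentialAbundance()], [classPufaRatio()]
#' @export
setClass("LipidomeExperiment", contains = "SummarizedExperiment")

setValidity("LipidomeExperiment", function(object) {
  msg <- character()
  if (!"abundance" %in% assayNames(object))
    msg <- c(msg, "assay 'abundance' is required")
  else if (any(assay(object, "abundance") < 0, na.rm = TRUE))
    msg <- c(msg, "abundances must be non-negative")
  need <- c("annotation", "lipidClass", "nCarbons", "nDoubleBonds",
            "nChains", "pufa")
  miss <- setdiff(need, colnames(rowData(object)))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks: ", paste(miss, collapse = ", ")))
  if (!"group" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'group'")
  ref <- metadata(object)$reference
  if (is.null(ref) || !ref %in% colData(object)$group)
    msg <- c(msg, "metadata(x)$reference must name a non-empty group")
  if (length(msg)) msg else TRUE
})

#' Construct a LipidomeExperiment
#'
#' Parses the annotation strings, classifies each species as PUFA-containing
#' or SFA/MUFA-only, and assembles the container.
#'
#' @param abundance numeric matrix, species x sample; rownames are
#'   summed-composition annotations such as `"TAG C54:6"` or `"C38:4 PE"`.
#' @param group character vector of per-sample group labels.
#' @param reference label of the reference group (default: first group).
#' @param classConfig a [LipidClassConfig-class]; controls chain counts and
#'   any per-class PUFA overrides.
#' @return A [LipidomeExperiment-class].
#' @export
LipidomeExperiment <- function(abundance, group,
                               reference = group[1],
                               classConfig = LipidClassConfig()) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)))
    stop("rownames of 'abundance' must be lipid annotations")
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("sample", seq_len(ncol(abundance)))
  if (length(group) != ncol(abundance))
    stop("'group' must have one entry per sample")
  group <- as.character(group)
  if (!reference %in% group)
    stop("reference group '", reference, "' has no samples")
  species <- parseLipidAnnotation(rownames(abundance), classConfig)
  species$pufa <- classifyPufa(species, classConfig)
  se <- SummarizedExperiment(
    assays = list(abundance = abundance),
    rowData = species,
    colData = DataFrame(group = group, row.names = colnames(abundance))
  )
  metadata(se)$reference <- reference
  new("LipidomeExperiment", se)
}

# ---------------------------------------------------------------------------
# Dose-response value classes
# ---------------------------------------------------------------------------

#' Geometric dilution series
#'
#' Descending concentration series `max, max/fold, ..., max/fold^(n-1)`,
#' the layout of plate-based viability assays (e.g. a 7-point, 2-fold
#' series).
#'
#' @slot maxConcentration top concentration, in micromolar.
#' @slot nPoints number of concentrations.
#' @slot fold dilution factor between adjacent points (> 1).
#' @slot concentrations the descending series, micromolar.
#' @seealso [makeDilutionSeries()]
#' @export
setClass("DoseSeries",
  representation(maxConcentration = "numeric", nPoints = "integer",
                 fold = "numeric", concentrations = "numeric"))

setValidity("DoseSeries", function(object) {
  msg <- character()
  if (object@maxConcentration <= 0) msg <- c(msg, "max concentration must be > 0")
  if (object@fold <= 1) msg <- c(msg, "fold must be > 1")
  if (object@nPoints < 1L) msg <- c(msg, "nPoints must be >= 1")
  expect <- object@maxConcentration / object@fold^(seq_len(object@nPoints) - 1)
  if (length(object@concentrations) != object@nPoints ||
      any(abs(object@concentrations - expect) >
          1e-12 * pmax(1, expect)))
    msg <- c(msg, "concentrations must equal max/fold^k, k = 0..n-1")
  if (length(msg)) msg else TRUE
})

#' Replicated viability measurements over a dilution series
#'
#' @slot series the [DoseSeries-class] assayed.
#' @slot viability matrix, concentrations x replicates, of (relative)
#'   viabilities; equal replicate count at every concentration.
#' @slot normalized whether values are relative to the vehicle control.
#' @slot label free-text identifier (cell line, cDNA, compound).
#' @seealso [normalizeViability()], [fitSigmoid()], [normalizedAUC()]
#' @export
setClass("ViabilityCurves",
  representation(series = "DoseSeries", viability = "matrix",
                 normalized = "logical", label = "character"))

setValidity("ViabilityCurves", function(object) {
  msg <- character()
  if (nrow(object@viability) != object@series@nPoints)
    msg <- c(msg, "viability must have one row per concentration")
  if (isTRUE(object@normalized) && any(object@viability < 0))
    msg <- c(msg, "normalized viabilities must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Bundle viabilities with their dose series
#'
#' @param series a [DoseSeries-class].
#' @param viability numeric matrix (concentrations x replicates) or vector.
#' @param normalized are values already relative to vehicle?
#' @param label optional identifier.
#' @return A [ViabilityCurves-class].
#' @export
ViabilityCurves <- function(series, viability, normalized = TRUE,
                            label = NA_character_) {
  if (is.vector(viability)) viability <- matrix(viability, ncol = 1)
  new("ViabilityCurves", series = series, viability = as.matrix(viability),
      normalized = isTRUE(normalized), label = as.character(label))
}

#' Four-parameter logistic fit
#'
#' Parameters of `v(c) = bottom + (top - bottom) / (1 + (c/ec50)^hill)`,
#' the standard sigmoidal dose-response model for viability data.
#'
#' @slot top,bottom asymptotic viabilities (`bottom <= top`).
#' @slot ec50 half-maximal concentration, micromolar (> 0).
#' @slot hill Hill slope (> 0 for a decreasing viability curve).
#' @slot residualSS residual sum of squares of the fit.
#' @slot converged whether the optimizer reported convergence.
#' @export
setClass("SigmoidFit",
  representation(top = "numeric", bottom = "numeric", ec50 = "numeric",
                 hill = "numeric", residualSS = "numeric",
                 converged = "logical"))

setValidity("SigmoidFit", function(object) {
  msg <- character()
  if (object@bottom > object@top + 1e-9) msg <- c(msg, "bottom must be <= top")
  if (object@ec50 <= 0) msg <- c(msg, "ec50 must be > 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Sensitivity matrix
# ---------------------------------------------------------------------------

#' Cell line x compound sensitivity matrix
#'
#' Normalized area-under-curve (AUC) drug-sensitivity values for a panel of
#' cell lines (rows) against a panel of compounds (columns), with per-line
#' lineage labels and a logical histotype flag marking the group of interest
#' (e.g. clear-cell carcinoma lines). `NA` entries mark compound/line pairs
#' that were not profiled. Lower AUC = more sensitive; a completely
#' insensitive line scores 1.
#'
#' @slot auc numeric matrix, cell lines x compounds, values in `[0, 1]`
#'   where present, `NA` allowed.
#' @slot lineage character, lineage per cell line.
#' @slot isTarget logical, histotype flag per cell line.
#' @seealso [applyInclusionFilters()], [compoundSelectivity()],
#'   [lineageRanking()]
#' @export
setClass("SensitivityMatrix",
  representation(auc = "matrix", lineage = "character",
                 isTarget = "logical"))

setValidity("SensitivityMatrix", function(object) {
  msg <- character()
  if (length(object@lineage) != nrow(object@auc))
    msg <- c(msg, "one lineage label per cell line required")
  if (length(object@isTarget) != nrow(object@auc))
    msg <- c(msg, "one isTarget flag per cell line required")
  vals <- object@auc[!is.na(object@auc)]
  if (any(!is.finite(vals)))
    msg <- c(msg, "non-missing AUCs must be finite")
  if (is.null(rownames(object@auc)) || is.null(colnames(object@auc)))
    msg <- c(msg, "auc matrix needs cell-line rownames and compound colnames")
  if (length(msg)) msg else TRUE
})

#' @param auc numeric matrix, cell lines x compounds (NA = not profiled).
#' @param lineage character vector of lineage labels per line.
#' @param isTarget logical histotype flag per line.
#' @return A [SensitivityMatrix-class].
#' @rdname SensitivityMatrix-class
#' @export
SensitivityMatrix <- function(auc, lineage, isTarget) {
  auc <- as.matrix(auc)
  if (is.null(rownames(auc))) rownames(auc) <- paste0("line", seq_len(nrow(auc)))
  if (is.null(colnames(auc))) colnames(auc) <- paste0("cpd", seq_len(ncol(auc)))
  new("SensitivityMatrix", auc = auc, lineage = as.character(lineage),
      isTarget = as.logical(isTarget))
}

# ---------------------------------------------------------------------------
# Configuration classes
# ---------------------------------------------------------------------------

#' Gene-level hit-calling configuration
#'
#' Encodes the resistance-screen hit rule: genes represented by
#' `minSgrnas`–`maxSgrnas` guides are eligible; an sgRNA passes in a treated
#' condition when its enrichment is at least `foldThreshold`-fold with
#' p < `pThreshold`; a gene scores in a condition when at least
#' `minPassingSgrnas` of its guides pass; the final call combines treated
#' conditions by `combineMode`.
#'
#' @slot foldThreshold minimum fold enrichment (default 2).
#' @slot pThreshold per-sgRNA p-value cut-off (default 0.05).
#' @slot minSgrnas,maxSgrnas eligible guides-per-gene range (default 3–10).
#' @slot minPassingSgrnas guides that must pass per condition (default 2).
#' @slot combineMode `"intersection"` (scored in every treated condition) or
#'   `"union"`.
#' @slot pseudocount RPM added to numerator and denominator of the fold
#'   change (default 1).
#' @export
setClass("HitCallConfig",
  representation(foldThreshold = "numeric", pThreshold = "numeric",
                 minSgrnas = "integer", maxSgrnas = "integer",
                 minPassingSgrnas = "integer", combineMode = "character",
                 pseudocount = "numeric"))

setValidity("HitCallConfig", function(object) {
  msg <- character()
  if (object@minSgrnas > object@maxSgrnas)
    msg <- c(msg, "minSgrnas must be <= maxSgrnas")
  if (object@foldThreshold <= 0 || object@pThreshold <= 0)
    msg <- c(msg, "thresholds must be positive")
  if (!object@combineMode %in% c("intersection", "union"))
    msg <- c(msg, "combineMode must be 'intersection' or 'union'")
  if (object@pseudocount < 0) msg <- c(msg, "pseudocount must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param foldThreshold,pThreshold,minSgrnas,maxSgrnas,minPassingSgrnas,combineMode,pseudocount
#'   see the class slots.
#' @rdname HitCallConfig-class
#' @export
HitCallConfig <- function(foldThreshold = 2, pThreshold = 0.05,
                          minSgrnas = 3L, maxSgrnas = 10L,
                          minPassingSgrnas = 2L,
                          combineMode = c("intersection", "union"),
                          pseudocount = 1) {
  new("HitCallConfig", foldThreshold = foldThreshold, pThreshold = pThreshold,
      minSgrnas = as.integer(minSgrnas), maxSgrnas = as.integer(maxSgrnas),
      minPassingSgrnas = as.integer(minPassingSgrnas),
      combineMode = match.arg(combineMode), pseudocount = pseudocount)
}

#' Lipid class configuration
#'
#' Maps each supported lipid class to its acyl-chain count (mono-, di- or
#' tri-acyl), which drives the PUFA classification rule, and optionally
#' overrides the minimum double-bond count for specific classes.
#'
#' @slot chainCounts named integer vector, class -> chains.
#' @slot pufaMinDbOverride named numeric vector; for listed classes, the
#'   species is PUFA-containing iff its double-bond count meets the override.
#' @export
setClass("LipidClassConfig",
  representation(chainCounts = "integer", pufaMinDbOverride = "numeric"))

setValidity("LipidClassConfig", function(object) {
  if (any(object@chainCounts <= 0L)) "chain counts must be positive" else TRUE
})

#' @param chainCounts named class -> chain-count map.
#' @param pufaMinDbOverride optional named per-class minimum double-bond
#'   override.
#' @rdname LipidClassConfig-class
#' @export
LipidClassConfig <- function(chainCounts = .LIPID_CHAIN_COUNTS,
                             pufaMinDbOverride = numeric()) {
  new("LipidClassConfig",
      chainCounts = setNames(as.integer(chainCounts), names(chainCounts)),
      pufaMinDbOverride = pufaMinDbOverride)
}

#' Selectivity analysis configuration
#'
#' @slot compoundCoverageMin minimum fraction of cell lines in which a
#'   compound must be profiled (default 2/3).
#' @slot lineCoverageMin minimum fraction of retained compounds a cell line
#'   must be profiled with (default 1/2).
#' @slot minLineageSize minimum lines per lineage for the lineage ranking
#'   (default 6, i.e. more than 5).
#' @export
setClass("SelectivityConfig",
  representation(compoundCoverageMin = "numeric", lineCoverageMin = "numeric",
                 minLineageSize = "integer"))

setValidity("SelectivityConfig", function(object) {
  f <- c(object@compoundCoverageMin, object@lineCoverageMin)
  if (any(f <= 0) || any(f > 1)) "coverage fractions must be in (0, 1]" else TRUE
})

#' @param compoundCoverageMin,lineCoverageMin,minLineageSize see slots.
#' @rdname SelectivityConfig-class
#' @export
SelectivityConfig <- function(compoundCoverageMin = 2 / 3,
                              lineCoverageMin = 0.5, minLineageSize = 6L) {
  new("SelectivityConfig", compoundCoverageMin = compoundCoverageMin,
      lineCoverageMin = lineCoverageMin,
      minLineageSize = as.integer(minLineageSize))
}

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "DoseSeries", function(object) {
  cat(sprintf("DoseSeries: %d-point, %g-fold from %g uM (min %.4g uM)\n",
              object@nPoints, object@fold, object@maxConcentration,
              min(object@concentrations)))
})

setMethod("show", "SigmoidFit", function(object) {
  cat(sprintf(
    "SigmoidFit: top=%.4g bottom=%.4g ec50=%.4g uM hill=%.4g (RSS %.3g%s)\n",
    object@top, object@bottom, object@ec50, object@hill, object@residualSS,
    if (object@converged) "" else ", NOT converged"))
})

setMethod("show", "SensitivityMatrix", function(object) {
  cat(sprintf(
    "SensitivityMatrix: %d cell lines x %d compounds (%.1f%% missing), %d lineages, %d target lines\n",
    nrow(object@auc), ncol(object@auc),
    100 * mean(is.na(object@auc)), length(unique(object@lineage)),
    sum(object@isTarget)))
})

setMethod("show", "HitCallConfig", function(object) {
  cat(sprintf(
    "HitCallConfig: >=%d sgRNAs at fold >= %g & p < %g; %d-%d sgRNAs/gene; %s across conditions; pseudocount %g RPM\n",
    object@minPassingSgrnas, object@foldThreshold, object@pThreshold,
    object@minSgrnas, object@maxSgrnas, object@combineMode,
    object@pseudocount))
})

# ---------------------------------------------------------------------------
# Accessors
# ---------------------------------------------------------------------------

#' @name accessors
#' @title Accessors for ferroscreen value classes
#' @description Small typed getters used instead of direct slot access.
#' @param x object.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
concentrations <- function(x) {
  stopifnot(is(x, "DoseSeries"))
  x@concentrations
}

#' @rdname accessors
#' @export
viabilities <- function(x) {
  stopifnot(is(x, "ViabilityCurves"))
  x@viability
}

#' @rdname accessors
#' @export
doseSeries <- function(x) {
  stopifnot(is(x, "ViabilityCurves"))
  x@series
}

#' @rdname accessors
#' @export
isNormalized <- function(x) {
  stopifnot(is(x, "ViabilityCurves"))
  x@normalized
}

#' @rdname accessors
#' @export
aucMatrix <- function(x) {
  stopifnot(is(x, "SensitivityMatrix"))
  x@auc
}

#' @rdname accessors
#' @export
lineages <- function(x) {
  stopifnot(is(x, "SensitivityMatrix"))
  setNames(x@lineage, rownames(x@auc))
}

#' @rdname accessors
#' @export
targetLines <- function(x) {
  stopifnot(is(x, "SensitivityMatrix"))
  setNames(x@isTarget, rownames(x@auc))
}

#' @rdname accessors
#' @export
fitParameters <- function(x) {
  stopifnot(is(x, "SigmoidFit"))
  c(top = x@top, bottom = x@bottom, ec50 = x@ec50, hill = x@hill)
}
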