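# Lipidomics analysis on summed-composition annotations: parsing, PUFA
# classification, median normalization, differential abundance (log2
# Test/WT ratios with BH-adjusted t-tests), class-level PUFA ratios and PCA.

#' Parse summed-composition lipid annotations
#'
#' Summed-composition nomenclature denotes a species by lipid class plus the
#' total number of acyl carbons and total number of double bonds across all
#' chains, e.g. `"TAG C54:6"` (a triacylglycerol with 54 carbons and 6 double
#' bonds) or `"C38:4 PE"`. Accepted grammar: `<CLASS> C<carbons>:<db>` or
#' `C<carbons>:<db> <CLASS>`; the `C` prefix is optional and the class is
#' case-insensitive. The chain count (1 for CE/MAG/LPC/LPE/FFA, 2 for most
#' phospholipids/Cer/SM, 3 for TAG) is derived from the class.
#'
#' @param text character vector of annotation strings.
#' @param config a [LipidClassConfig-class] giving the supported classes.
#' @return [S4Vectors::DataFrame] with `annotation`, `lipidClass`,
#'   `nCarbons`, `nDoubleBonds`, `nChains`; rownames are the input strings.
#' @examples
#' parseLipidAnnotation(c("TAG C54:6", "C38:4 PE"))
#' @export
parseLipidAnnotation <- function(text, config = LipidClassConfig()) {
  stopifnot(is(config, "LipidClassConfig"))
  text <- as.character(text)
  classes <- names(config@chainCounts)
  one <- function(s) {
    toks <- strsplit(trimws(s), "\\s+")[[1]]
    if (length(toks) != 2)
      stop("malformed lipid annotation: '", s, "'")
    compRe <- "^C?([0-9]+):([0-9]+)$"
    isComp <- grepl(compRe, toks)
    if (sum(isComp) != 1)
      stop("malformed composition token in '", s, "'")
    comp <- toks[isComp]
    clsTok <- toks[!isComp]
    hit <- match(tolower(clsTok), tolower(classes))
    if (is.na(hit))
      stop("unknown lipid class '", clsTok, "' in '", s, "'")
    c(cls = classes[hit],
      carbons = sub(compRe, "\\1", comp),
      db = sub(compRe, "\\2", comp))
  }
  parts <- vapply(text, one, character(3))
  carbons <- as.integer(parts["carbons", ])
  if (any(carbons <= 0))
    stop("carbon count must be positive")
  cls <- unname(parts["cls", ])
  DataFrame(annotation = text, lipidClass = cls, nCarbons = carbons,
            nDoubleBonds = as.integer(parts["db", ]),
            nChains = unname(config@chainCounts[cls]), row.names = text)
}

#' Canonical annotation string for parsed species
#'
#' @param species table from [parseLipidAnnotation()].
#' @return character vector `"<CLASS> C<carbons>:<db>"`; re-parsing it
#'   reproduces the same species.
#' @export
formatLipidAnnotation <- function(species) {
  sprintf("%s C%d:%d", species$lipidClass, species$nCarbons,
          species$nDoubleBonds)
}

#' Classify species as PUFA-containing or SFA/MUFA-only
#'
#' A summed composition only reports the total double-bond count, so whether
#' a polyunsaturated chain (>= 2 double bonds in one chain) must be present
#' follows from a pigeonhole argument: with `k` chains and `DB` total double
#' bonds, every split of `DB` over the chains forces some chain to carry
#' >= 2 double bonds exactly when `DB >= k + 1`. E.g. PE C38:4 (2 chains,
#' 4 double bonds) is PUFA-containing, TAG C50:1 is not. A per-class
#' override in the config replaces the pigeonhole threshold.
#'
#' @param species table from [parseLipidAnnotation()] (or any data frame
#'   with `lipidClass`, `nDoubleBonds`, `nChains`).
#' @param config a [LipidClassConfig-class].
#' @return logical vector: `TRUE` = PUFA-containing.
#' @examples
#' sp <- parseLipidAnnotation(c("PE C38:4", "TAG C50:1", "FFA C20:4"))
#' classifyPufa(sp)   # TRUE FALSE TRUE
#' @export
classifyPufa <- function(species, config = LipidClassConfig()) {
  thr <- species$nChains + 1L
  ov <- config@pufaMinDbOverride
  if (length(ov)) {
    idx <- match(species$lipidClass, names(ov))
    thr <- ifelse(is.na(idx), thr, ov[idx])
  }
  unname(species$nDoubleBonds >= thr)
}

#' Median normalization across samples
#'
#' Rescales every sample so all sample medians equal the grand median of the
#' per-sample medians: sample j is multiplied by
#' `median(sampleMedians) / sampleMedian_j`. This is the between-sample
#' normalization applied to LC-MS lipid abundance tables before
#' differential analysis.
#'
#' @param x a [LipidomeExperiment-class] whose samples all have positive
#'   medians.
#' @return `x` with the `"abundance"` assay rescaled.
#' @export
medianNormalize <- function(x) {
  stopifnot(is(x, "LipidomeExperiment"))
  ab <- assay(x, "abundance")
  med <- apply(ab, 2, median)
  if (any(med <= 0)) {
    bad <- colnames(ab)[med <= 0]
    stop("sample(s) with non-positive median: ", paste(bad, collapse = ", "))
  }
  assay(x, "abundance") <- sweep(ab, 2, median(med) / med, "*")
  x
}

#' Differential lipid abundance versus the reference group
#'
#' Per species: `log2fc = log2(mean_test / mean_reference)` on the
#' (median-normalized) abundances, a two-tailed Student t-test on the
#' per-sample log2 abundances (variance stabilization), and BH adjustment
#' across all tested species. Species with a zero abundance in either group
#' are not detectable on the log scale ("nd"); they are flagged and excluded
#' from testing rather than imputed.
#'
#' @param x a [LipidomeExperiment-class] with >= 2 samples per group.
#' @param testGroup group to compare against the reference; default: the
#'   single non-reference group.
#' @param reference reference group label; default `metadata(x)$reference`.
#' @return [S4Vectors::DataFrame]: `annotation`, `lipidClass`, `pufa`,
#'   `log2fc`, `p_value`, `adj_p`, `neg_log10_adj_p`, `nd`.
#' @export
differentialAbundance <- function(x, testGroup = NULL, reference = NULL) {
  stopifnot(is(x, "LipidomeExperiment"))
  grp <- colData(x)$group
  if (is.null(reference)) reference <- metadata(x)$reference
  if (is.null(testGroup)) {
    others <- setdiff(unique(grp), reference)
    if (length(others) != 1)
      stop("several non-reference groups present; specify 'testGroup'")
    testGroup <- others
  }
  for (g in c(reference, testGroup))
    if (sum(grp == g) < 2) stop("group '", g, "' needs >= 2 samples")
  ab <- assay(x, "abundance")
  refM <- ab[, grp == reference, drop = FALSE]
  tstM <- ab[, grp == testGroup, drop = FALSE]
  nd <- apply(refM, 1, function(v) any(v <= 0) || mean(v) == 0) |
    apply(tstM, 1, function(v) any(v <= 0))
  l2fc <- log2(rowMeans(tstM) / rowMeans(refM))
  l2fc[nd] <- NA_real_
  p <- rep(NA_real_, nrow(ab))
  for (i in which(!nd))
    p[i] <- studentTTest(log2(tstM[i, ]), log2(refM[i, ]))$p.value
  adj <- rep(NA_real_, nrow(ab))
  adj[!nd] <- bhAdjust(p[!nd])
  DataFrame(annotation = rowData(x)$annotation,
            lipidClass = rowData(x)$lipidClass,
            pufa = rowData(x)$pufa,
            log2fc = unname(l2fc), p_value = p, adj_p = adj,
            neg_log10_adj_p = -log10(adj), nd = unname(nd),
            row.names = rownames(x))
}

#' Per-sample PUFA abundance ratio within lipid classes
#'
#' For the selected classes (e.g. `c("PE", "ePE")`), the per-sample ratio of
#' summed PUFA-containing species abundance to summed abundance over all
#' species in those classes — the tumor/normal comparison statistic for
#' PUFA-phospholipid enrichment.
#'
#' @param x a [LipidomeExperiment-class].
#' @param classes character vector of lipid classes present in `x`.
#' @return named numeric vector in `[0, 1]`, one value per sample.
#' @export
classPufaRatio <- function(x, classes) {
  stopifnot(is(x, "LipidomeExperiment"))
  if (!length(classes)) stop("empty class selection")
  inCls <- rowData(x)$lipidClass %in% classes
  if (!any(inCls))
    stop("none of the classes present in the table: ",
         paste(classes, collapse = ", "))
  ab <- assay(x, "abundance")
  tot <- colSums(ab[inCls, , drop = FALSE])
  puf <- colSums(ab[inCls & rowData(x)$pufa, , drop = FALSE])
  puf / tot
}

#' PCA of per-sample lipid log-ratio profiles
#'
#' Computes per-species log2 ratios of every sample to the reference-group
#' mean, median-centers each sample's log-ratio profile, then takes the
#' singular value decomposition of the species-centered matrix. Species with
#' non-positive abundances (log-ratio undefined) are dropped.
#'
#' @param x a [LipidomeExperiment-class].
#' @param reference reference group; default `metadata(x)$reference`.
#' @return list with `scores` (samples x components), `varianceFraction`
#'   (sums to 1), and `centered` (the decomposed matrix, samples x species).
#' @export
pcaScores <- function(x, reference = NULL) {
  stopifnot(is(x, "LipidomeExperiment"))
  if (is.null(reference)) reference <- metadata(x)$reference
  grp <- colData(x)$group
  ab <- assay(x, "abundance")
  if (ncol(ab) < 2 || nrow(ab) < 2) stop("need >= 2 samples and >= 2 species")
  keep <- apply(ab, 1, function(v) all(v > 0))
  ab <- ab[keep, , drop = FALSE]
  refMean <- rowMeans(ab[, grp == reference, drop = FALSE])
  lr <- log2(ab / refMean)
  lr <- sweep(lr, 2, apply(lr, 2, median))     # per-sample median centering
  m <- t(lr)                                   # samples x species
  m <- sweep(m, 2, colMeans(m))                # species centering
  if (all(abs(m) < 1e-12))
    stop("degenerate matrix: no variation across samples")
  sv <- svd(m)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- rownames(m)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores, varianceFraction = sv$d^2 / sum(sv$d^2),
       centered = m)
}
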