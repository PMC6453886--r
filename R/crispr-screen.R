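# Genome-wide CRISPR resistance-screen analysis: RPM normalization,
# per-sgRNA enrichment against an empirical (median/MAD) null, gene-level
# hit calling with the 3-10 sgRNA / >=2 passing sgRNA rule, cross-condition
# intersection, and library-representation checks.

#' Reads-per-million normalization
#'
#' Scales every sample (column) of the count matrix to a total of 10^6,
#' storing the result in the `"rpm"` assay: `rpm_ij = 1e6 * count_ij /
#' colsum_j`.
#'
#' @param x a [ScreenCounts-class].
#' @return `x` with the `"rpm"` assay filled.
#' @export
rpmNormalize <- function(x) {
  stopifnot(is(x, "ScreenCounts"))
  cts <- assay(x, "counts")
  totals <- colSums(cts)
  if (any(totals <= 0)) {
    bad <- colnames(cts)[totals <= 0]
    stop("sample(s) with zero total counts: ", paste(bad, collapse = ", "))
  }
  assay(x, "rpm") <- sweep(cts, 2, totals, "/") * 1e6
  x
}

#' Per-sgRNA enrichment of a treated condition over control
#'
#' For every sgRNA, computes `log2fc = log2((rpm_treated + pc) /
#' (rpm_control + pc))` where `pc` is the RPM pseudocount, then a robust
#' z-score of the log2 fold changes across all sgRNAs in the condition
#' (median/MAD empirical null) and a normal-tail p-value. When several
#' samples share a condition label their RPM values are averaged first.
#'
#' The per-sgRNA p-value is an empirical-null interpretation (the screen
#' has no replicate-based test); a one-sided (enrichment-only) p is
#' available with `oneSided = TRUE`, the default is two-sided.
#'
#' @param x a [ScreenCounts-class] with the `"rpm"` assay (see
#'   [rpmNormalize()]).
#' @param controlLabel,treatedLabel condition labels present in
#'   `colData(x)$condition`.
#' @param config a [HitCallConfig-class] (supplies the pseudocount).
#' @param oneSided report upper-tail (enrichment-only) p-values.
#' @return [S4Vectors::DataFrame] with `sgrna_id`, `gene_id`, `condition`,
#'   `log2fc`, `z`, `p_value`.
#' @export
sgrnaEnrichment <- function(x, controlLabel, treatedLabel,
                            config = HitCallConfig(), oneSided = FALSE) {
  stopifnot(is(x, "ScreenCounts"), is(config, "HitCallConfig"))
  if (!"rpm" %in% assayNames(x))
    stop("RPM assay missing; run rpmNormalize() first")
  cond <- colData(x)$condition
  for (lab in c(controlLabel, treatedLabel))
    if (!lab %in% cond) stop("condition label not found: ", lab)
  rpm <- assay(x, "rpm")
  ctrl <- rowMeans(rpm[, cond == controlLabel, drop = FALSE])
  trt <- rowMeans(rpm[, cond == treatedLabel, drop = FALSE])
  pc <- config@pseudocount
  l2fc <- log2((trt + pc) / (ctrl + pc))
  # median/MAD empirical null; degenerate MAD falls back to the standard
  # deviation, and a fully constant column yields z = 0 everywhere
  z <- tryCatch(robustZ(l2fc), error = function(e) {
    s <- sd(l2fc)
    if (s == 0) rep(0, length(l2fc)) else (l2fc - median(l2fc)) / s
  })
  p <- if (oneSided) pnorm(z, lower.tail = FALSE) else 2 * pnorm(-abs(z))
  DataFrame(sgrna_id = rownames(x), gene_id = rowData(x)$gene_id,
            condition = treatedLabel, log2fc = unname(l2fc),
            z = unname(z), p_value = unname(p))
}

#' Gene-level hit calling across treated conditions
#'
#' Applies the resistance-screen rule: genes represented by 3-10 sgRNAs
#' (configurable) are eligible; an sgRNA passes in a condition when
#' `log2fc >= log2(foldThreshold)` and `p < pThreshold`; a gene scores in a
#' condition when at least `minPassingSgrnas` of its sgRNAs pass; the final
#' hit requires scoring in every treated condition (`"intersection"`, the
#' default) or any (`"union"`).
#'
#' @param stats a list of per-condition enrichment tables from
#'   [sgrnaEnrichment()] (one element per treated condition), or a single
#'   such table.
#' @param config a [HitCallConfig-class].
#' @return [S4Vectors::DataFrame], one row per eligible gene: `gene_id`,
#'   `n_sgrnas`, one `passing_<condition>` count and one `hit_<condition>`
#'   flag per condition, `conditions_hit`, and the final `hit` flag.
#' @export
callGeneHits <- function(stats, config = HitCallConfig()) {
  stopifnot(is(config, "HitCallConfig"))
  if (is(stats, "DataFrame") || is.data.frame(stats)) stats <- list(stats)
  stats <- lapply(stats, as.data.frame)
  conds <- vapply(stats, function(s) s$condition[1], character(1))
  if (anyDuplicated(conds)) stop("duplicate condition tables supplied")
  names(stats) <- conds
  for (s in stats) {
    if (any(is.na(s$gene_id) | s$gene_id == "")) {
      bad <- s$sgrna_id[is.na(s$gene_id) | s$gene_id == ""]
      stop("sgRNA(s) without gene mapping: ", paste(bad, collapse = ", "))
    }
  }
  map <- stats[[1]][, c("sgrna_id", "gene_id")]
  nSg <- table(map$gene_id)
  eligible <- names(nSg)[nSg >= config@minSgrnas & nSg <= config@maxSgrnas]
  eligible <- sort(eligible)
  if (!length(eligible))
    return(DataFrame(gene_id = character(), n_sgrnas = integer(),
                     conditions_hit = character(), hit = logical()))
  lfcMin <- log2(config@foldThreshold)
  passCount <- sapply(stats, function(s) {
    pass <- s$log2fc >= lfcMin & s$p_value < config@pThreshold
    cnt <- tapply(pass, s$gene_id, sum)
    as.integer(cnt[eligible])
  })
  passCount <- matrix(passCount, nrow = length(eligible),
                      dimnames = list(eligible, conds))
  hitMat <- passCount >= config@minPassingSgrnas
  final <- if (config@combineMode == "intersection")
    rowSums(hitMat) == length(conds) else rowSums(hitMat) > 0
  out <- DataFrame(gene_id = eligible,
                   n_sgrnas = as.integer(nSg[eligible]))
  for (cd in conds) {
    out[[paste0("passing_", cd)]] <- unname(passCount[, cd])
    out[[paste0("hit_", cd)]] <- unname(hitMat[, cd])
  }
  out$conditions_hit <- unname(apply(hitMat, 1, function(h)
    paste(conds[h], collapse = ",")))
  out$hit <- unname(final)
  out
}

#' One-call screen analysis
#'
#' Convenience wrapper: RPM-normalizes, computes per-sgRNA enrichment for
#' every treated condition against the control, and calls gene-level hits.
#'
#' @param x a [ScreenCounts-class].
#' @param controlLabel the control condition (e.g. `"DMSO"`); all other
#'   condition labels are treated.
#' @param config a [HitCallConfig-class].
#' @param oneSided passed to [sgrnaEnrichment()].
#' @return list with `sgrnaStats` (list of per-condition tables) and
#'   `geneHits` (the [callGeneHits()] table).
#' @export
screenHits <- function(x, controlLabel = "DMSO", config = HitCallConfig(),
                       oneSided = FALSE) {
  x <- rpmNormalize(x)
  treated <- setdiff(unique(colData(x)$condition), controlLabel)
  if (!length(treated)) stop("no treated conditions besides the control")
  st <- lapply(treated, function(tc)
    sgrnaEnrichment(x, controlLabel, tc, config, oneSided = oneSided))
  names(st) <- treated
  list(sgrnaStats = st, geneHits = callGeneHits(st, config))
}

#' Screen library representation check
#'
#' Mean cells per sgRNA for a pooled screen: `nCells * infectionRate /
#' nSgrnas`. Pooled resistance screens aim to keep this above ~500 so that
#' guide dropout is not depth-limited (e.g. 40e6 cells over a 77,441-guide
#' library gives 516.5).
#'
#' @param nCells number of cells carried per condition.
#' @param nSgrnas library size (> 0).
#' @param infectionRate fraction of cells transduced, in `(0, 1]`.
#' @return mean cells per sgRNA.
#' @examples
#' coverageCheck(40e6, 77441)        # 516.5
#' coverageCheck(150e6, 77441, 0.3)  # 581.1
#' @export
coverageCheck <- function(nCells, nSgrnas, infectionRate = 1) {
  if (nSgrnas <= 0) stop("library size must be positive")
  if (nCells <= 0) stop("cell number must be positive")
  if (infectionRate <= 0 || infectionRate > 1)
    stop("infection rate must be in (0, 1]")
  nCells * infectionRate / nSgrnas
}
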