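# CTRP-style lineage/histotype selectivity analysis of a cell line x
# compound normalized-AUC matrix: coverage filtering, per-compound
# Mann-Whitney comparison of a histotype group against all other lines, and
# per-compound lineage ranking.

#' Coverage-based inclusion filtering
#'
#' Applies the two inclusion criteria in one pass each: first compounds
#' profiled in fewer than `compoundCoverageMin` (default 2/3) of the cell
#' lines are removed, then cell lines profiled with fewer than
#' `lineCoverageMin` (default 1/2) of the *retained* compounds are removed.
#' The operation is idempotent.
#'
#' @param x a [SensitivityMatrix-class].
#' @param config a [SelectivityConfig-class].
#' @return list with `matrix` (the filtered [SensitivityMatrix-class]) and
#'   `excluded` (data.frame of removals: `item`, `type`, `coverage`).
#' @export
applyInclusionFilters <- function(x, config = SelectivityConfig()) {
  stopifnot(is(x, "SensitivityMatrix"), is(config, "SelectivityConfig"))
  auc <- aucMatrix(x)
  cpdCov <- colMeans(!is.na(auc))
  keepCpd <- cpdCov >= config@compoundCoverageMin
  auc2 <- auc[, keepCpd, drop = FALSE]
  lineCov <- if (ncol(auc2)) rowMeans(!is.na(auc2)) else
    setNames(rep(0, nrow(auc2)), rownames(auc2))
  keepLine <- lineCov >= config@lineCoverageMin
  excluded <- rbind(
    data.frame(item = colnames(auc)[!keepCpd],
               type = rep("compound", sum(!keepCpd)),
               coverage = unname(cpdCov[!keepCpd])),
    data.frame(item = rownames(auc)[!keepLine],
               type = rep("cell_line", sum(!keepLine)),
               coverage = unname(lineCov[!keepLine])))
  if (!any(keepCpd) || !any(keepLine))
    stop("matrix is empty after coverage filtering")
  out <- new("SensitivityMatrix",
             auc = auc2[keepLine, , drop = FALSE],
             lineage = x@lineage[keepLine],
             isTarget = x@isTarget[keepLine])
  list(matrix = out, excluded = excluded)
}

#' Per-compound selectivity of a histotype group
#'
#' For each compound, compares the normalized AUC of the flagged group
#' (e.g. clear-cell carcinoma lines) against all other cell lines with a
#' two-sided Mann-Whitney test; missing AUCs are dropped pairwise, never
#' imputed. Effect size is the difference of group means (group - rest), so
#' negative = the group is more sensitive. P-values are BH-adjusted across
#' compounds. Compounds with fewer than 2 usable lines on either side are
#' skipped with a reason.
#'
#' @param x a (filtered) [SensitivityMatrix-class].
#' @param groupFlag logical per cell line; default the matrix's `isTarget`
#'   flag.
#' @return [S4Vectors::DataFrame] sorted by `adj_p`: `compound`, `effect`,
#'   `U`, `p_value`, `adj_p`, `n_group`, `n_rest`; skipped compounds are in
#'   `metadata()$skipped`.
#' @export
compoundSelectivity <- function(x, groupFlag = NULL) {
  stopifnot(is(x, "SensitivityMatrix"))
  if (is.null(groupFlag)) groupFlag <- x@isTarget
  auc <- aucMatrix(x)
  if (length(groupFlag) != nrow(auc))
    stop("groupFlag must have one entry per cell line")
  rows <- vector("list", ncol(auc))
  skipped <- character()
  for (j in seq_len(ncol(auc))) {
    a <- auc[groupFlag, j]; b <- auc[!groupFlag, j]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      skipped <- c(skipped, colnames(auc)[j])
      next
    }
    mw <- mannWhitneyU(a, b)
    rows[[j]] <- data.frame(
      compound = colnames(auc)[j], effect = mean(a) - mean(b),
      U = mw$statistic, p_value = mw$p.value,
      n_group = length(a), n_rest = length(b))
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows)) stop("no compound has >= 2 lines in both groups")
  res <- DataFrame(rows)
  res$adj_p <- bhAdjust(res$p_value)
  res <- res[order(res$adj_p, res$p_value), ]
  res <- res[, c("compound", "effect", "U", "p_value", "adj_p",
                 "n_group", "n_rest")]
  metadata(res)$skipped <- skipped
  res
}

#' Rank lineages by sensitivity to one compound
#'
#' Orders lineages by ascending mean normalized AUC (most sensitive first)
#' for the given compound, keeping only lineages with at least
#' `minLineageSize` profiled lines (default > 5), and tests each lineage
#' against all other lines (Mann-Whitney, BH across lineages).
#'
#' @param x a [SensitivityMatrix-class].
#' @param compound a compound name present in the matrix.
#' @param config a [SelectivityConfig-class].
#' @return [S4Vectors::DataFrame] ordered by `mean_auc`: `lineage`, `n`,
#'   `mean_auc`, `p_value`, `adj_p`.
#' @export
lineageRanking <- function(x, compound, config = SelectivityConfig()) {
  stopifnot(is(x, "SensitivityMatrix"))
  auc <- aucMatrix(x)
  if (!compound %in% colnames(auc)) stop("compound not found: ", compound)
  v <- auc[, compound]
  keep <- !is.na(v)
  v <- v[keep]; lin <- x@lineage[keep]
  sizes <- table(lin)
  use <- names(sizes)[sizes >= config@minLineageSize]
  if (!length(use))
    stop("no lineage has >= ", config@minLineageSize, " profiled lines")
  rows <- lapply(use, function(L) {
    p <- if (any(lin != L))
      mannWhitneyU(v[lin == L], v[lin != L])$p.value else NA_real_
    data.frame(lineage = L, n = sum(lin == L), mean_auc = mean(v[lin == L]),
               p_value = p)
  })
  res <- DataFrame(do.call(rbind, rows))
  res$adj_p <- bhAdjust(res$p_value)
  res[order(res$mean_auc), ]
}
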