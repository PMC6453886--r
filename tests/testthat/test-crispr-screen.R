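toyScreen <- function(counts, genes, condition) {
  ScreenCounts(counts, geneIds = genes, condition = condition)
}

test_that("RPM normalization scales every sample to one million", {
  cts <- matrix(c(1, 3), ncol = 1, dimnames = list(c("a", "b"), "s1"))
  sc <- toyScreen(cts, c("g1", "g1"), "DMSO")
  rpm <- SummarizedExperiment::assay(rpmNormalize(sc), "rpm")
  expect_equal(as.vector(rpm), c(250000, 750000))

  set.seed(1)
  cts2 <- matrix(rpois(40, 30), 10,
                 dimnames = list(paste0("sg", 1:10), paste0("s", 1:4)))
  sc2 <- toyScreen(cts2, rep(c("g1", "g2"), 5), c("DMSO", "d4", "d6", "d8"))
  rpm2 <- SummarizedExperiment::assay(rpmNormalize(sc2), "rpm")
  expect_equal(unname(colSums(rpm2)), rep(1e6, 4))

  cts3 <- matrix(5, 4, 1, dimnames = list(paste0("sg", 1:4), "s1"))
  rpm3 <- SummarizedExperiment::assay(
    rpmNormalize(toyScreen(cts3, rep("g", 4), "DMSO")), "rpm")
  expect_equal(as.vector(rpm3), rep(1e6 / 4, 4))

  bad <- toyScreen(matrix(c(0, 0, 1, 2), 2,
                          dimnames = list(c("a", "b"), c("s1", "s2"))),
                   c("g", "g"), c("DMSO", "d4"))
  expect_error(rpmNormalize(bad), "s1")
})

test_that("per-sgRNA enrichment computes pseudocounted log2 ratios", {
  set.seed(2)
  n <- 50
  cts <- matrix(rpois(2 * n, 100), n,
                dimnames = list(paste0("sg", 1:n), c("DMSO", "d4")))
  cts[1, ] <- c(100, 100)   # identical counts -> identical RPM only if
  cts[, 2] <- cts[, 1]      # make treated column equal to control
  sc <- rpmNormalize(toyScreen(cts, rep(paste0("g", 1:10), each = 5),
                               c("DMSO", "d4")))
  st <- sgrnaEnrichment(sc, "DMSO", "d4")
  expect_equal(st$log2fc, rep(0, n))

  # exact 4x composition ratio with pseudocount 0 (equal column totals)
  cts2 <- matrix(c(2, 248, 250, 250, 250, 8, 246, 246, 250, 250), 5,
                 dimnames = list(letters[1:5], c("DMSO", "d4")))
  sc2 <- rpmNormalize(toyScreen(cts2, rep("g1", 5), c("DMSO", "d4")))
  st2 <- sgrnaEnrichment(sc2, "DMSO", "d4",
                         config = HitCallConfig(pseudocount = 0))
  expect_equal(st2$log2fc[1], 2)
  expect_error(sgrnaEnrichment(sc2, "DMSO", "d8"), "d8")
  expect_error(sgrnaEnrichment(toyScreen(cts2, rep("g1", 5),
                                         c("DMSO", "d4")), "DMSO", "d4"),
               "rpmNormalize")
})

test_that("null screens give calibrated per-sgRNA p-values", {
  sim <- simulateScreenCounts(ScreenSimConfig(
    nGenes = 1500L, nPlanted = 0L, enrichmentFold = 1, seed = 12L))
  st <- screenHits(sim$counts, "DMSO")$sgrnaStats[["d4"]]
  fp <- mean(st$p_value < 0.05)
  expect_lt(abs(fp - 0.05), 0.01)
})

mkStats <- function(cond, ids, genes, lfc, p) {
  data.frame(sgrna_id = ids, gene_id = genes, condition = cond,
             log2fc = lfc, p_value = p)
}

test_that("gene hit rule: eligibility window, passing counts, intersection", {
  ids <- c(paste0("gA_", 1:4), paste0("gB_", 1:2), paste0("gC_", 1:4))
  genes <- c(rep("gA", 4), rep("gB", 2), rep("gC", 4))
  # gA: 3 strong sgRNAs in every condition -> hit
  # gB: only 2 sgRNAs -> excluded even though both pass
  # gC: 1 passing sgRNA everywhere -> not a hit
  lfc <- c(3.5, 3.0, 2.8, 0.1, 5, 5, 2.5, 0, 0, 0)
  p <- c(0.01, 0.01, 0.01, 0.9, 0.001, 0.001, 0.01, 0.9, 0.9, 0.9)
  stats <- lapply(c("d4", "d6", "d8"), mkStats, ids = ids, genes = genes,
                  lfc = lfc, p = p)
  hits <- callGeneHits(stats)
  expect_setequal(hits$gene_id, c("gA", "gC"))   # gB outside 3-10 window
  expect_true(hits$hit[hits$gene_id == "gA"])
  expect_equal(hits$passing_d4[hits$gene_id == "gA"], 3L)
  expect_false(hits$hit[hits$gene_id == "gC"])
  expect_equal(hits$conditions_hit[hits$gene_id == "gA"], "d4,d6,d8")
})

test_that("a gene scoring in only some conditions needs union mode", {
  ids <- paste0("gA_", 1:3)
  genes <- rep("gA", 3)
  strong <- mkStats("d4", ids, genes, c(3, 3, 3), c(0.01, 0.01, 0.01))
  weak <- mkStats("d6", ids, genes, c(0, 0, 0), c(0.9, 0.9, 0.9))
  inter <- callGeneHits(list(strong, weak))
  expect_false(inter$hit)
  uni <- callGeneHits(list(strong, weak),
                      HitCallConfig(combineMode = "union"))
  expect_true(uni$hit)
})

test_that("hit caller matches the plain-loop oracle on random tables", {
  set.seed(2024)
  for (rep in 1:200) {
    stats <- randomStatsTables(nGenes = sample(4:10, 1),
                               nConds = sample(1:3, 1))
    mode <- sample(c("intersection", "union"), 1)
    got <- callGeneHits(stats, HitCallConfig(combineMode = mode))
    want <- bruteHitCaller(stats, mode = mode)
    expect_setequal(got$gene_id, names(want))
    expect_equal(setNames(got$hit, got$gene_id)[names(want)],
                 unlist(want))
  }
})

test_that("intersection hits are a subset of union hits; thresholds monotone", {
  set.seed(77)
  for (rep in 1:20) {
    stats <- randomStatsTables(nGenes = 8, nConds = 3)
    hitsI <- callGeneHits(stats, HitCallConfig(combineMode = "intersection"))
    hitsU <- callGeneHits(stats, HitCallConfig(combineMode = "union"))
    expect_true(all(hitsI$gene_id[hitsI$hit] %in% hitsU$gene_id[hitsU$hit]))
    # stricter thresholds never add hits
    lax <- callGeneHits(stats, HitCallConfig(foldThreshold = 2,
                                             pThreshold = 0.05))
    strictFold <- callGeneHits(stats, HitCallConfig(foldThreshold = 4,
                                                    pThreshold = 0.05))
    strictP <- callGeneHits(stats, HitCallConfig(foldThreshold = 2,
                                                 pThreshold = 0.01))
    expect_true(all(strictFold$gene_id[strictFold$hit] %in%
                      lax$gene_id[lax$hit]))
    expect_true(all(strictP$gene_id[strictP$hit] %in%
                      lax$gene_id[lax$hit]))
  }
})

test_that("unmapped sgRNAs are reported by id", {
  s <- mkStats("d4", c("a", "b", "c"), c("g1", NA, "g1"),
               c(1, 1, 1), c(0.5, 0.5, 0.5))
  expect_error(callGeneHits(list(s)), "b")
})

test_that("planted resistance genes are recovered under the default rule", {
  sim <- simulateScreenCounts(ScreenSimConfig(
    nGenes = 1000L, sgrnasPerGene = 4L, nPlanted = 20L, enrichmentFold = 8,
    fractionActive = 0.75, depth = 500 * 4000, dispersion = 0.05, seed = 1L))
  res <- screenHits(sim$counts, "DMSO")
  called <- res$geneHits$gene_id[res$geneHits$hit]
  expect_gte(sum(sim$truth$plantedGenes %in% called), 18)
  expect_lte(sum(!called %in% sim$truth$plantedGenes), 2)
})

test_that("screen coverage arithmetic reproduces the library design numbers", {
  expect_equal(round(coverageCheck(40e6, 77441), 1), 516.5)
  expect_gte(coverageCheck(40e6, 77441), 500)
  expect_equal(coverageCheck(77441, 77441), 1)
  expect_equal(round(coverageCheck(150e6, 77441, 0.30), 1), 581.1)
  expect_gte(coverageCheck(150e6, 77441, 0.30), 500)
  expect_error(coverageCheck(1e6, 0), "library")
  expect_error(coverageCheck(1e6, 100, 1.5), "infection")
})
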