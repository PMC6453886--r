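test_that("summed-composition annotations parse in both token orders", {
  sp <- parseLipidAnnotation(c("TAG C54:6", "C38:4 PE", "ffa 20:4",
                               "ePE C36:5"))
  expect_equal(sp$lipidClass, c("TAG", "PE", "FFA", "ePE"))
  expect_equal(sp$nCarbons, c(54L, 38L, 20L, 36L))
  expect_equal(sp$nDoubleBonds, c(6L, 4L, 4L, 5L))
  expect_equal(sp$nChains, c(3L, 2L, 1L, 2L))
  expect_error(parseLipidAnnotation("XYZ C10:0"), "XYZ")
  expect_error(parseLipidAnnotation("PE"), "malformed")
  expect_error(parseLipidAnnotation("PE C38:4 extra"), "malformed")
})

test_that("annotation formatting round-trips through the parser", {
  anns <- c("TAG C54:6", "pe C38:4", "C20:4 FFA", "SM 34:1")
  sp <- parseLipidAnnotation(anns)
  canon <- formatLipidAnnotation(sp)
  sp2 <- parseLipidAnnotation(canon)
  expect_equal(sp2$lipidClass, sp$lipidClass)
  expect_equal(sp2$nCarbons, sp$nCarbons)
  expect_equal(sp2$nDoubleBonds, sp$nDoubleBonds)
  expect_identical(formatLipidAnnotation(sp2), canon)
})

test_that("PUFA classification equals the chain-composition oracle", {
  # named examples: PE C38:4 and FFA C20:4 contain a PUFA chain, TAG C50:1
  # cannot
  sp <- parseLipidAnnotation(c("PE C38:4", "FFA C20:4", "TAG C50:1"))
  expect_equal(classifyPufa(sp), c(TRUE, TRUE, FALSE))

  grid <- expand.grid(cls = c("FFA", "PE", "TAG"), db = 0:12,
                      stringsAsFactors = FALSE)   # chains 1, 2, 3
  sp <- parseLipidAnnotation(sprintf("%s C40:%d", grid$cls, grid$db))
  want <- mapply(brutePufa, db = grid$db,
                 nChains = c(FFA = 1, PE = 2, TAG = 3)[grid$cls])
  expect_equal(classifyPufa(sp), unname(want))
})

test_that("per-class overrides replace the pigeonhole threshold", {
  cfg <- LipidClassConfig(pufaMinDbOverride = c(TAG = 6))
  sp <- parseLipidAnnotation(c("TAG C50:4", "TAG C50:6", "PE C38:4"), cfg)
  expect_equal(classifyPufa(sp, cfg), c(FALSE, TRUE, TRUE))
})

mkLipidome <- function(ab, group, reference = "WT") {
  LipidomeExperiment(ab, group = group, reference = reference)
}

test_that("median normalization equalizes sample medians", {
  ab <- matrix(c(1, 2, 3, 2, 4, 6), 3,
               dimnames = list(c("PE C36:2", "PE C38:4", "TAG C52:2"),
                               c("WT_1", "KO_1")))
  le <- mkLipidome(ab, c("WT", "KO"))
  norm <- SummarizedExperiment::assay(medianNormalize(le), "abundance")
  expect_equal(unname(apply(norm, 2, median)), c(3, 3))   # grand median 3
  expect_equal(unname(norm[, 1]), c(1, 2, 3) * 1.5)
  expect_equal(unname(norm[, 2]), c(2, 4, 6) * 0.75)
  # already-equal medians: unchanged; rescaling a sample is absorbed
  norm2 <- SummarizedExperiment::assay(
    medianNormalize(mkLipidome(norm, c("WT", "KO"))), "abundance")
  expect_equal(norm2, norm)
  # rescaling one sample changes only the global level (the grand median
  # moves with it); the normalized table is recovered up to one constant
  ab2 <- ab; ab2[, 2] <- ab2[, 2] * 7
  norm3 <- SummarizedExperiment::assay(
    medianNormalize(mkLipidome(ab2, c("WT", "KO"))), "abundance")
  expect_equal(norm3 / norm3[1, 1], norm / norm[1, 1], tolerance = 1e-12)
  abZero <- ab; abZero[, 1] <- 0
  expect_error(medianNormalize(mkLipidome(abZero, c("WT", "KO"))), "WT_1")
})

test_that("differential abundance: identical groups and planted depletion", {
  set.seed(8)
  base <- rlnorm(10, log(100), 0.4)
  anns <- sprintf("PE C%d:%d", seq(30, 48, by = 2), 0:9)
  ab <- matrix(rep(base, 6), 10, dimnames = list(anns, paste0("s", 1:6)))
  le <- mkLipidome(ab, rep(c("WT", "KO"), each = 3))
  d <- differentialAbundance(le)
  expect_equal(d$log2fc, rep(0, 10))
  expect_equal(d$p_value, rep(1, 10))

  # noiseless planted depletion of -1 on PUFA species only
  sim <- simulateLipidome(LipidomeSimConfig(
    pufaDepletionLog2fc = -1, noiseSd = 0, seed = 4L))
  d2 <- differentialAbundance(sim$lipidome)
  pufa <- sim$truth$pufa
  expect_equal(d2$log2fc[pufa], rep(-1, sum(pufa)), tolerance = 1e-9)
  expect_equal(d2$log2fc[!pufa], rep(0, sum(!pufa)), tolerance = 1e-9)
})

test_that("differential log2fc is antisymmetric in group order", {
  sim <- simulateLipidome(LipidomeSimConfig(seed = 3L))
  fw <- differentialAbundance(sim$lipidome, testGroup = "KO",
                              reference = "WT")
  bw <- differentialAbundance(sim$lipidome, testGroup = "WT",
                              reference = "KO")
  expect_equal(fw$log2fc, -bw$log2fc, tolerance = 1e-10)
  expect_equal(fw$p_value, bw$p_value, tolerance = 1e-10)
  expect_true(all(fw$adj_p >= fw$p_value - 1e-12, na.rm = TRUE))
})

test_that("species with zero abundances are flagged nd and excluded", {
  ab <- matrix(rlnorm(20, 5), 5,
               dimnames = list(sprintf("PC C3%d:2", 2:6), paste0("s", 1:4)))
  ab[2, 1] <- 0
  le <- mkLipidome(ab, rep(c("WT", "KO"), each = 2))
  d <- differentialAbundance(le)
  expect_true(d$nd[2])
  expect_true(is.na(d$p_value[2]))
  expect_false(any(d$nd[-2]))
  # BH applied over tested species only
  expect_equal(d$adj_p[!d$nd], bhAdjust(d$p_value[!d$nd]))
})

test_that("class PUFA ratio is a within-class abundance fraction", {
  ab <- matrix(c(30, 90, 50, 10, 110, 40), 3,
               dimnames = list(c("PE C38:4", "PE C36:1", "TAG C52:6"),
                               c("WT_1", "KO_1")))
  le <- mkLipidome(ab, c("WT", "KO"))
  r <- classPufaRatio(le, c("PE", "ePE"))
  expect_equal(unname(r), c(30 / 120, 10 / 120))
  expect_equal(unname(classPufaRatio(le, "TAG")), c(1, 1))
  expect_error(classPufaRatio(le, character()), "empty")
  expect_error(classPufaRatio(le, "SM"), "SM")

  # ratio of only-SFA/MUFA table is zero
  ab0 <- ab[2, , drop = FALSE]
  expect_equal(unname(classPufaRatio(mkLipidome(ab0, c("WT", "KO")), "PE")),
               c(0, 0))

  # invariance under median normalization (within-sample scaling cancels)
  sim <- simulateLipidome(LipidomeSimConfig(seed = 9L))
  r1 <- classPufaRatio(sim$lipidome, c("PE", "ePE"))
  r2 <- classPufaRatio(medianNormalize(sim$lipidome), c("PE", "ePE"))
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("PCA scores capture single-species variation and SVD identities", {
  anns <- c("PE C36:2", "PE C38:4", "TAG C52:3", "SM C34:1")
  ab <- matrix(100, 4, 4, dimnames = list(anns, paste0("s", 1:4)))
  ab[2, ] <- c(100, 100, 400, 400)   # variation along one species only
  le <- mkLipidome(ab, rep(c("WT", "KO"), each = 2))
  pc <- pcaScores(le)
  expect_equal(pc$varianceFraction[1], 1)
  expect_equal(sum(pc$varianceFraction), 1)
  # samples 1/2 and 3/4 are duplicates -> coincide in score space
  expect_equal(pc$scores[1, ], pc$scores[2, ], tolerance = 1e-10)
  expect_equal(pc$scores[3, ], pc$scores[4, ], tolerance = 1e-10)

  sim <- simulateLipidome(LipidomeSimConfig(seed = 2L))
  pc2 <- pcaScores(sim$lipidome)
  sv <- svd(pc2$centered)
  recon <- sv$u %*% diag(sv$d) %*% t(sv$v)
  expect_lt(max(abs(recon - pc2$centered)), 1e-8)

  flat <- mkLipidome(matrix(7, 3, 4, dimnames = list(anns[1:3],
                                                     paste0("s", 1:4))),
                     rep(c("WT", "KO"), each = 2))
  expect_error(pcaScores(flat), "degenerate")
})
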