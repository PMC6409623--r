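smallCfg <- function(...) SimulationConfig(nGenes = 200, nAgents = 40,
                                           mEdges = 4, ...)

test_that("generators are pure functions of (config, seed)", {
  cfg <- smallCfg(seed = 5)
  s1 <- simulateAll(cfg, expression = TRUE, nSamples = 40)
  s2 <- simulateAll(cfg, expression = TRUE, nSamples = 40)
  expect_equal(pValues(s1$scores), pValues(s2$scores))
  expect_equal(edgeTable(s1$network), edgeTable(s2$network))
  expect_equal(geneSets(s1$reference), geneSets(s2$reference))
  expect_equal(as.data.frame(s1$drugTargets), as.data.frame(s2$drugTargets))
  expect_equal(SummarizedExperiment::assay(s1$expression),
               SummarizedExperiment::assay(s2$expression))
  # byte-identical on disk too
  d1 <- tempfile(); d2 <- tempfile()
  writeSimulatedData(s1, d1); writeSimulatedData(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # and a different seed changes the draw
  s3 <- simulateGeneScores(smallCfg(seed = 6))
  expect_false(identical(pValues(s1$scores), pValues(s3$scores)))
})

test_that("disease genes have stochastically smaller p-values", {
  truth <- simulateGeneScores(SimulationConfig(nGenes = 2000, betaA = 0.1,
                                               seed = 2))
  p <- pValues(truth$scores)
  isD <- names(p) %in% truth$diseaseGenes
  expect_lt(mean(p[isD]), mean(p[!isD]))
  expect_equal(sum(isD), round(0.05 * 2000))
  # betaA = 1 degenerates to Uniform: KS against punif rarely rejects
  rejections <- sum(vapply(1:20, function(s) {
    t1 <- simulateGeneScores(SimulationConfig(nGenes = 5000, piDisease = 0.5,
                                              betaA = 1, seed = 100 + s))
    pd <- pValues(t1$scores)[names(pValues(t1$scores)) %in% t1$diseaseGenes]
    stats::ks.test(pd, "punif")$p.value < 0.01
  }, logical(1)))
  expect_lte(rejections, 1)
})

test_that("attachment network has the stated degree structure", {
  cfg <- smallCfg(seed = 9)
  truth <- simulateGeneScores(cfg)
  net <- simulateNetwork(truth, cfg)
  dg <- outDegree(net)
  # every node beyond the first mEdges draws exactly mEdges out-neighbours
  expect_equal(sum(dg == cfg@mEdges), cfg@nGenes - cfg@mEdges)
  expect_true(all(dg <= cfg@mEdges))
  # m >= n is rejected already at config validation
  expect_error(SimulationConfig(nGenes = 200, mEdges = 200), "mEdges")
})

test_that("homophily concentrates edges inside the disease module", {
  mixFraction <- function(hom, seed) {
    cfg <- SimulationConfig(nGenes = 400, mEdges = 5, homophily = hom,
                            piDisease = 0.2, seed = seed)
    truth <- simulateGeneScores(cfg)
    et <- edgeTable(simulateNetwork(truth, cfg))
    mean(et$from %in% truth$diseaseGenes & et$to %in% truth$diseaseGenes)
  }
  fr1 <- vapply(1:10, function(s) mixFraction(1, s), numeric(1))
  fr10 <- vapply(1:10, function(s) mixFraction(10, s), numeric(1))
  # null mixing ~ piDisease^2 within 3 standard errors
  se <- sd(fr1) / sqrt(length(fr1))
  expect_lt(abs(mean(fr1) - 0.2^2), 3 * se + 1e-3)
  # paired seeds: homophily strictly increases disease-disease mixing
  expect_true(all(fr10 > fr1))
})

test_that("reference database emulates sensitivity and contamination", {
  cfg <- smallCfg(seed = 13, dbSensitivity = 1, dbFpr = 0)
  truth <- simulateGeneScores(cfg)
  ref <- simulateReferenceDb(truth, cfg)
  expect_setequal(ref[[1]], truth$diseaseGenes)
  refNone <- simulateReferenceDb(truth, smallCfg(seed = 13, dbSensitivity = 0,
                                                 dbFpr = 0))
  expect_length(geneSets(refNone), 0)
  # binomial mean at half sensitivity, within 3 SE
  cfgB <- SimulationConfig(nGenes = 4000, piDisease = 0.25, seed = 13,
                           dbSensitivity = 0.5, dbFpr = 0)
  truthB <- simulateGeneScores(cfgB)
  refB <- simulateReferenceDb(truthB, cfgB)
  nD <- length(truthB$diseaseGenes)
  expect_lt(abs(length(intersect(refB[[1]], truthB$diseaseGenes)) - 0.5 * nD),
            3 * sqrt(nD * 0.25))
})

test_that("supported agents target the disease module preferentially", {
  hitRate <- function(enrich, seed) {
    cfg <- SimulationConfig(nGenes = 500, nAgents = 120, targetsPerAgent = 3,
                            piSupported = 0.5, supportEnrichment = enrich,
                            seed = seed)
    truth <- simulateGeneScores(cfg)
    dt <- simulateDrugTargets(truth, cfg)
    df <- as.data.frame(dt)
    hits <- tapply(df$target_gene_id %in% truth$diseaseGenes,
                   df$agent_id, any)
    sup <- supportFlags(dt)[names(hits)]
    c(sup = mean(hits[sup]), unsup = mean(hits[!sup]))
  }
  paired <- vapply(1:20, function(s) hitRate(20, s), numeric(2))
  expect_gt(mean(paired["sup", ] - paired["unsup", ]), 0)
  expect_gt(mean(paired["sup", ] > paired["unsup", ]), 0.85)
  # all pairs and agent ids unique by construction
  cfg <- smallCfg(seed = 3)
  dt <- simulateDrugTargets(simulateGeneScores(cfg), cfg)
  df <- as.data.frame(dt)
  expect_false(anyDuplicated(paste(df$agent_id, df$target_gene_id)) > 0)
  expect_equal(length(agents(dt)), cfg@nAgents)
})

test_that("expression chain carries phenotype signal, null genes do not", {
  cfg <- SimulationConfig(nGenes = 30, mEdges = 3, piDisease = 0.2, seed = 17)
  truth <- simulateGeneScores(cfg)
  se <- simulateExpression(truth, cfg, nSamples = 200, effect = 3)
  chain <- S4Vectors::metadata(se)$chainGenes
  expect_length(chain, 3)
  m <- SummarizedExperiment::assay(se)
  y <- as.integer(SummarizedExperiment::colData(se)$phenotype)
  miOf <- function(g) mutualInformation(discretizeEqualFreq(m[g, ], 3), y)
  nulls <- setdiff(rownames(m), chain)
  expect_gt(miOf(chain[1]), max(vapply(nulls[1:5], miOf, numeric(1))))
  # effect = 0 leaves every gene uninformative at permutation level
  se0 <- simulateExpression(truth, cfg, nSamples = 100, effect = 0)
  y0 <- as.integer(SummarizedExperiment::colData(se0)$phenotype)
  disc0 <- t(apply(SummarizedExperiment::assay(se0)[1:10, ], 1,
                   discretizeEqualFreq, nBins = 3))
  pt <- miPermutationTest(disc0, y0, nPerm = 200, seed = 1)
  expect_lte(sum(pt$p < 0.05), 2)
  expect_error(simulateExpression(truth, cfg, nSamples = 10), "16")
})
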