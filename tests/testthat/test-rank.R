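test_that("initial scores are -log(p) with clamping", {
  gs <- GeneScoreTable(c("A", "B", "C"), c(0.01, 1, 1e-300))
  f <- initialScores(computeInitialScores(gs))
  expect_equal(unname(f), c(2, 0, 300))
  # configurable base
  f2 <- initialScores(computeInitialScores(
    GeneScoreTable("A", exp(-3)), RankConfig(logBase = exp(1))))
  expect_equal(unname(f2), 3)
})

test_that("propagation matches hand-derived fixed points", {
  # d = 0: scores equal f, one sweep
  net <- DependencyNetwork(from = c("A", "A", "B"), to = c("B", "C", "C"))
  gs <- computeInitialScores(GeneScoreTable(c("A", "B", "C"),
                                            c(0.1, 10^-0.5, 10^-0.25)))
  r0 <- geneRank(net, gs, RankConfig(d = 0))
  expect_equal(rankScores(r0), initialScores(gs))
  expect_equal(r0@nIterations, 1L)
  expect_true(converged(r0))

  # edgeless network: r = (1 - d) f
  netE <- DependencyNetwork(from = character(0), to = character(0),
                            nodes = c("A", "B"))
  gsE <- GeneScoreTable(c("A", "B"), c(1e-2, 1e-4))  # f = (2, 4)
  rE <- geneRank(netE, computeInitialScores(gsE), RankConfig(d = 0.5))
  expect_equal(unname(rankScores(rE)), c(1, 2))

  # 2-node chain A -> B, f = (1, 0), d = 0.5: hand elimination gives
  # r_A = 0.5, r_B = d * r_A = 0.25
  net2 <- DependencyNetwork(from = "A", to = "B")
  r2 <- geneRankClosedForm(net2, c(A = 1, B = 0), d = 0.5)
  expect_equal(unname(r2), c(0.5, 0.25))

  # 3-node instance against the dense-elimination oracle
  f3 <- c(A = 1.0, B = 0.5, C = 0.25)
  expected <- oracleFixedPoint(edgeTable(net), nodes(net), f3, 0.5)
  gs3 <- GeneScoreTable(c("A", "B", "C"), 10^-f3)
  it <- geneRank(net, computeInitialScores(gs3),
                 RankConfig(d = 0.5, epsilon = 1e-10))
  expect_equal(rankScores(it)[names(expected)], expected, tolerance = 1e-6)
  cf <- geneRankClosedForm(net, f3, 0.5)
  expect_equal(cf, expected, tolerance = 1e-12)
})

test_that("iterative and closed-form scores agree on random networks", {
  for (s in 1:20) {
    inst <- randomInstance(n = sample(5:60, 1), pEdge = runif(1, 0.02, 0.3),
                           seed = s)
    net <- asNetwork(inst)
    d <- runif(1, 0, 0.9)
    gs <- GeneScoreTable(inst$ids, 10^-inst$f)
    it <- rankScores(geneRank(net, computeInitialScores(gs),
                              RankConfig(d = d, epsilon = 1e-9)))
    cf <- geneRankClosedForm(net, inst$f, d)
    expect_lt(max(abs(it[inst$ids] - cf[inst$ids])), 1e-6)
    oracle <- oracleFixedPoint(inst$edges, inst$ids, inst$f, d)
    expect_lt(max(abs(cf[inst$ids] - oracle)), 1e-9)
  }
})

test_that("propagation is linear in f and its residuals shrink monotonically", {
  inst <- randomInstance(n = 40, pEdge = 0.1, seed = 99)
  net <- asNetwork(inst)
  cfg <- RankConfig(d = 0.7, epsilon = 1e-9)
  gs1 <- computeInitialScores(GeneScoreTable(inst$ids, 10^-inst$f))
  r1 <- geneRank(net, gs1, cfg)
  # scaling f by c > 0 scales r by exactly c (closed form is linear)
  c0 <- 3.7
  r2 <- geneRankClosedForm(net, c0 * inst$f, 0.7)
  expect_equal(unname(r2), unname(c0 * geneRankClosedForm(net, inst$f, 0.7)),
               tolerance = 1e-12)
  # induced ranking unchanged
  expect_equal(geneIds(rankGenes(r2)),
               geneIds(rankGenes(geneRankClosedForm(net, inst$f, 0.7))))
  # residual trace non-increasing
  expect_true(all(diff(r1@residuals) <= 1e-12))
  expect_true(converged(r1))
  expect_equal(r1@finalResidual, r1@residuals[length(r1@residuals)])
})

test_that("score mass is bounded when no dangling nodes exist", {
  # complete directed graph: every node has out-degree n - 1
  n <- 8
  ids <- sprintf("K%d", 1:n)
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  net <- DependencyNetwork(from = pairs$from, to = pairs$to)
  f <- setNames(runif(n), ids)
  r <- geneRankClosedForm(net, f, 0.5)
  expect_lte(sum(abs(r)), sum(abs(f)) + 1e-12)
})

test_that("ranking is deterministic with lexicographic tie-breaks", {
  expect_equal(geneIds(rankGenes(c(A = 2, B = 1))), c("A", "B"))
  rl <- rankGenes(c(B = 1, A = 1))
  expect_equal(geneIds(rl), c("A", "B"))      # tie -> identifier order
  expect_equal(rl@rank, 1:2)
  expect_equal(length(rankGenes(setNames(numeric(0), character(0)))), 0L)
})

test_that("top-k selection truncates and validates k", {
  rl <- rankGenes(setNames(seq(50, 1), sprintf("G%02d", 1:50)))
  expect_length(topGenes(rl, 100), 50)
  expect_length(topGenes(rl, 10), 10)
  expect_equal(topGenes(rl, 1), "G01")
  expect_error(topGenes(rl, 0), "positive")
})

test_that("the analysis universe is the score/network intersection by default", {
  net <- DependencyNetwork(from = c("A", "B"), to = c("B", "C"))
  gs <- computeInitialScores(GeneScoreTable(c("A", "B", "Z"), c(0.1, 0.2, 0.3)))
  r <- geneRank(net, gs, RankConfig(d = 0.5))
  expect_setequal(names(rankScores(r)), c("A", "B"))    # C unscored, Z absent
  rAll <- geneRank(net, gs, RankConfig(d = 0.5), keepUnscored = TRUE)
  expect_setequal(names(rankScores(rAll)), c("A", "B", "C"))
  expect_error(geneRank(net, computeInitialScores(GeneScoreTable("Q", 0.5))),
               "no genes shared")
})

test_that("transpose flips the propagation direction", {
  net <- DependencyNetwork(from = "A", to = "B")
  f <- c(A = 1, B = 0)
  fwd <- geneRankClosedForm(net, f, 0.5)
  rev <- geneRankClosedForm(net, f, 0.5, transpose = TRUE)
  expect_equal(unname(fwd), c(0.5, 0.25))
  expect_equal(unname(rev), c(0.5, 0))   # B -> A, but f_B = 0 flows nothing
})
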