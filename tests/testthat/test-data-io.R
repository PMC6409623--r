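test_that("gene-score reader parses, clamps and rejects as contracted", {
  p <- writeTempTsv(c("gene_id\tp_value", "# a comment", "G1\t0.01", "G2\t1.0"))
  gs <- readGeneScores(p)
  expect_equal(geneIds(gs), c("G1", "G2"))
  expect_equal(unname(pValues(gs)), c(0.01, 1.0))

  # p = 0 clamped up to pMin, never rejected
  gs0 <- readGeneScores(writeTempTsv(c("G1\t0")), pMin = 1e-300)
  expect_equal(unname(pValues(gs0)), 1e-300)

  expect_error(readGeneScores(writeTempTsv(c("G1\t0.1", "G1\t0.2"))),
               "duplicate gene identifier")
  expect_error(readGeneScores(writeTempTsv(c("G1\t0.1", "G2"))), "line 2")
  expect_error(readGeneScores(writeTempTsv(c("G1\t-0.5"))), "outside")
  expect_error(readGeneScores(writeTempTsv(c("G1\t1.5"))), "outside")
  # a lone non-numeric row is indistinguishable from a header-only file
  expect_error(readGeneScores(writeTempTsv(c("G1\tabc"))), "no data")
  expect_error(readGeneScores(writeTempTsv(c("G1\t0.1", "G2\tabc"))),
               "not numeric")
})

test_that("edge-list reader dedupes, drops self-loops, counts out-degrees", {
  net <- readEdgeList(writeTempTsv(c("A\tB", "A\tC", "B\tC")))
  expect_equal(length(nodes(net)), 3L)
  expect_equal(unname(outDegree(net)[c("A", "B", "C")]), c(2L, 1L, 0L))

  net2 <- readEdgeList(writeTempTsv(c("A\tB", "A\tB")))
  expect_equal(edgeCount(net2), 1L)

  expect_warning(net3 <- readEdgeList(writeTempTsv(c("A\tB", "A\tA"))),
                 "self-loop")
  expect_equal(edgeCount(net3), 1L)

  expect_error(readEdgeList(writeTempTsv(character(0))), "no edges")
  expect_error(readEdgeList(writeTempTsv(c("A\tB", "C"))), "line 2")
})

test_that("GMT reader enforces the format contract", {
  gc <- readGmt(writeTempTsv(c("S1\tdesc\tG1\tG2", "S2\tdesc\tG3")))
  expect_equal(names(gc), c("S1", "S2"))
  expect_setequal(gc[["S1"]], c("G1", "G2"))
  expect_error(readGmt(writeTempTsv(c("S1\tdesc"))), "at least one gene")
  expect_error(readGmt(writeTempTsv(c("S1\td\tG1", "S1\td\tG2"))),
               "duplicate set name")
})

test_that("drug-target reader applies the OR rule for agent support", {
  dt <- readDrugTargets(writeTempTsv(c("D1\tG1\t0", "D1\tG2\t1", "D2\tG3\t0")))
  expect_equal(agents(dt), c("D1", "D2"))
  expect_equal(unname(supportFlags(dt)[c("D1", "D2")]), c(TRUE, FALSE))
  expect_error(readDrugTargets(writeTempTsv(c("D1\tG1\t2"))), "must be 0 or 1")
  # duplicate pairs collapse, support still OR'd across all rows
  dt2 <- readDrugTargets(writeTempTsv(c("D1\tG1\t0", "D1\tG1\t1")))
  expect_equal(length(dt2@agentId), 1L)
  expect_true(supportFlags(dt2)[["D1"]])
})

test_that("every object round-trips through its writer exactly", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      n <- sample(3:40, 1)
      gs <- GeneScoreTable(sprintf("g%02d", 1:n),
                           pmax(runif(n), 1e-12))
      p <- tempfile(); writeGeneScores(gs, p)
      back <- readGeneScores(p)
      expect_equal(geneIds(back), geneIds(gs))
      expect_equal(pValues(back), pValues(gs))

      inst <- randomInstance(sample(4:20, 1), pEdge = 0.2,
                             seed = sample.int(1e6, 1))
      net <- asNetwork(inst)
      p2 <- tempfile(); writeEdgeList(net, p2)
      back2 <- readEdgeList(p2, nodes = nodes(net))
      expect_equal(nodes(back2), nodes(net))
      expect_equal(edgeTable(back2), edgeTable(net))
      expect_equal(outDegree(back2), outDegree(net))
    }
  })

  gc <- GeneSetCollection(sets = list(a = c("G1", "G2"), b = "G9"))
  p3 <- tempfile(); writeGmt(gc, p3)
  expect_equal(geneSets(readGmt(p3)), geneSets(gc))

  dt <- DrugTargetTable(c("D1", "D1", "D2"), c("G1", "G2", "G1"),
                        supported = c(1, 0, 0))
  p4 <- tempfile(); writeDrugTargets(dt, p4)
  back4 <- readDrugTargets(p4)
  expect_equal(supportFlags(back4), supportFlags(dt))
  expect_equal(as.data.frame(back4), as.data.frame(dt))

  rl <- RankedGeneList(rank = 1:3, geneId = c("B", "A", "C"),
                       score = c(2.5, 1, 1))
  p5 <- tempfile(); writeRankedGenes(rl, p5)
  expect_equal(as.data.frame(readRankedGenes(p5)), as.data.frame(rl))
})

test_that("reader outputs satisfy the class invariants", {
  # validity is enforced at construction; spot-check the key clauses
  expect_error(GeneScoreTable(c("A", "A"), c(0.1, 0.2)), "unique")
  expect_error(GeneScoreTable("A", 0), "0, 1")
  expect_error(RankedGeneList(rank = 1:2, geneId = c("A", "B"),
                              score = c(1, 2)), "non-increasing")
  expect_error(RankedGeneList(rank = c(1L, 3L), geneId = c("A", "B"),
                              score = c(2, 1)), "contiguous")
  expect_error(GeneSetCollection(sets = list(a = character(0))), "non-empty")
})
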