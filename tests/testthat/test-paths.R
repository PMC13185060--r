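test_that("thresholding collapses lags and keeps only strong edges", {
  cs <- conceptSet(c("a", "b"), rep("environment", 2))
  m <- fcmModel(cs, weights = list(rbind(c(0, 0.5), c(0.005, 0))),
                mask = matrix(TRUE, 2, 2))
  g <- thresholdGraph(m, epsilon = 0.01)
  expect_identical(nrow(graphEdges(g)), 1L)
  expect_identical(graphEdges(g)$source, "a")
  expect_equal(graphEdges(g)$weight, 0.5)

  # epsilon -> 0+ on an all-nonzero matrix gives the complete digraph
  # minus self-loops
  cs4 <- conceptSet(paste0("n", 1:4), rep("environment", 4))
  W <- matrix(0.3, 4, 4)
  m4 <- fcmModel(cs4, weights = list(W), mask = matrix(TRUE, 4, 4))
  gFull <- thresholdGraph(m4, epsilon = 1e-9)
  expect_identical(nrow(graphEdges(gFull)), 4L * 3L)

  # edge count is non-increasing in epsilon
  mR <- randomModel(cs4, seed = 14)
  eps <- c(0.01, 0.05, 0.2, 0.5, 0.9)
  counts <- vapply(eps, function(e)
    nrow(graphEdges(suppressWarnings(thresholdGraph(mR, e)))), integer(1))
  expect_true(all(diff(counts) <= 0))

  expect_warning(thresholdGraph(m, epsilon = 0.99), "empty")
})

test_that("higher-order lag collapse picks the dominant lag weight", {
  cs <- conceptSet(c("a", "b"), rep("environment", 2))
  W1 <- rbind(c(0, 0.2), c(-0.7, 0))
  W2 <- rbind(c(0, -0.6), c(0.1, 0))
  m <- fcmModel(cs, order = 2L, weights = list(W1, W2),
                mask = matrix(TRUE, 2, 2))
  expect_equal(unname(collapseLags(m, "maxabs")),
               rbind(c(0, -0.6), c(-0.7, 0)))
  expect_equal(unname(collapseLags(m, "sum")),
               rbind(c(0, -0.4), c(-0.6, 0)))
})

test_that("simple-path enumeration matches hand-countable cases", {
  cs <- conceptSet(c("A", "B", "C"), rep("environment", 3))
  pairs <- expand.grid(source = c("A", "B", "C"),
                       target = c("A", "B", "C"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  edges <- data.frame(source = pairs$source, target = pairs$target,
                      weight = 0.5)
  g <- new("SignedDigraph", concepts = cs, edges = edges, epsilon = 0.05)
  for (i in seq_len(nrow(pairs))) {
    paths <- enumerateSimplePaths(g, pairs$source[i], pairs$target[i],
                                  maxLen = 2L)
    expect_identical(nrow(paths), 2L)
  }

  e2 <- data.frame(source = c("A", "B"), target = c("B", "C"),
                   weight = c(0.5, -0.4))
  g2 <- new("SignedDigraph", concepts = cs, edges = e2, epsilon = 0.05)
  p <- enumerateSimplePaths(g2, "A", "C", maxLen = 3L)
  expect_identical(p$path, "A->B->C")
  expect_equal(p$weight, -0.2)

  expect_error(enumerateSimplePaths(g2, "A", "A", maxLen = 2L), "differ")
  expect_error(enumerateSimplePaths(g2, "A", "Z", maxLen = 2L), "unknown")
})

test_that("path enumeration agrees with a backtracking oracle", {
  for (seed in 1:30) {
    n <- 3 + seed %% 5
    g <- randomDigraph(n, pEdge = 0.45, seed = seed)
    maxLen <- 1 + seed %% 4
    labs <- conceptNames(g@concepts)
    src <- labs[1 + seed %% n]
    tgt <- labs[1 + (seed + 1) %% n]
    if (src == tgt) tgt <- labs[1 + (seed + 2) %% n]
    got <- enumerateSimplePaths(g, src, tgt, maxLen)
    expect_identical(pathsAsDescriptors(got),
                     oraclePaths(graphEdges(g), src, tgt, maxLen))
  }
})

test_that("pair metrics aggregate counts and signed weight sums", {
  cs <- conceptSet(c("A", "B", "C"), rep("environment", 3))
  e <- data.frame(source = c("A", "A", "B"), target = c("C", "B", "C"),
                  weight = c(0.7, 0.5, -0.4))
  g <- new("SignedDigraph", concepts = cs, edges = e, epsilon = 0.05)
  pm <- pairMetrics(g, "A", "C", maxLen = 3L)
  expect_identical(pm$nPaths, 2L)
  expect_equal(pm$weightSum, 0.7 + 0.5 * -0.4)

  none <- pairMetrics(g, "C", "A", maxLen = 3L)
  expect_identical(none$nPaths, 0L)
  expect_identical(none$weightSum, 0)

  # weight sums are invariant to the order edges are listed in
  gShuf <- g
  gShuf@edges <- e[c(3, 1, 2), ]
  pmS <- pairMetrics(gShuf, "A", "C", maxLen = 3L)
  expect_equal(pmS$weightSum, pm$weightSum, tolerance = 1e-15)
  expect_identical(pmS$nPaths, pm$nPaths)
})

test_that("path weights obey the product magnitude bound", {
  for (seed in 31:40) {
    g <- randomDigraph(5, pEdge = 0.5, seed = seed)
    if (nrow(graphEdges(g)) == 0) next
    wmax <- max(abs(graphEdges(g)$weight))
    labs <- conceptNames(g@concepts)
    p <- enumerateSimplePaths(g, labs[1], labs[2], maxLen = 4L)
    if (nrow(p) == 0) next
    expect_true(all(abs(p$weight) <= wmax^p$length + 1e-12))
  }
})

test_that("factor-disease table matches direct construction and oracle", {
  envNames <- paste0("F", 1:15)
  cs <- conceptSet(c(envNames, "ON"),
                   c(rep("environment", 15), "disease"))
  W <- matrix(0, 16, 16, dimnames = list(conceptNames(cs), conceptNames(cs)))
  W["F2", "ON"] <- 0.3   # a lone PM10-like direct influence
  m <- fcmModel(cs, weights = list(W))
  tb <- factorDiseaseTable(m, epsilon = 0.05, maxLen = 4L)
  expect_equal(unname(tb$weights["F2", "ON"]), 0.3)
  expect_equal(sum(tb$weights != 0), 1L)
  expect_equal(unname(tb$absMean[["ON"]]), 0.3 / 15)

  # cellwise oracle agreement on a random small model
  cs2 <- conceptSet(c(paste0("F", 1:4), "d1", "d2"),
                    c(rep("environment", 4), rep("disease", 2)))
  m2 <- randomModel(cs2, seed = 55)
  tb2 <- factorDiseaseTable(m2, epsilon = 0.05, maxLen = 3L)
  g2 <- thresholdGraph(m2, 0.05)
  for (f in paste0("F", 1:4)) for (d in c("d1", "d2")) {
    ps <- oraclePaths(graphEdges(g2), f, d, 3L)
    wsum <- sum(vapply(strsplit(ps, "|", fixed = TRUE),
                       function(x) as.numeric(x[2]), numeric(1)))
    expect_equal(unname(tb2$weights[f, d]), wsum, tolerance = 1e-9)
    expect_identical(unname(tb2$counts[f, d]), length(ps))
  }
})

test_that("disease-disease tables have zero diagonals and need >= 2 diseases", {
  cs <- conceptSet(c("E1", "d1", "d2"),
                   c("environment", "disease", "disease"))
  W <- matrix(0, 3, 3, dimnames = list(conceptNames(cs), conceptNames(cs)))
  W["d1", "d2"] <- 0.9
  m <- fcmModel(cs, weights = list(W))
  dd <- diseaseDiseaseTables(m)
  expect_equal(unname(dd$counts), rbind(c(0L, 1L), c(0L, 0L)))
  expect_equal(unname(dd$weights), rbind(c(0, 0.9), c(0, 0)))
  expect_true(all(diag(dd$counts) == 0) && all(diag(dd$weights) == 0))

  csSing <- conceptSet(c("E1", "d1"), c("environment", "disease"))
  expect_error(diseaseDiseaseTables(fcmModel(csSing)), "overall model")
})

test_that("environment intermediates break disease-disease symmetry", {
  # d1 -> E -> d2 exists; no route back from d2 to d1
  cs <- conceptSet(c("E", "d1", "d2"),
                   c("environment", "disease", "disease"))
  W <- matrix(0, 3, 3, dimnames = list(conceptNames(cs), conceptNames(cs)))
  W["d1", "E"] <- 0    # masked anyway
  W["E", "d2"] <- 0.5
  W["d1", "d2"] <- 0.4
  m <- fcmModel(cs, weights = list(W))
  dd <- diseaseDiseaseTables(m)
  expect_gt(dd$counts["d1", "d2"], dd$counts["d2", "d1"])

  ddRestricted <- diseaseDiseaseTables(m, diseaseOnlyIntermediates = TRUE)
  expect_identical(unname(ddRestricted$counts["d1", "d2"]), 1L)
})

test_that("top-k screening ranks, clamps and breaks ties by label", {
  mkTable <- function(w, counts) {
    list(weights = w, counts = counts, absMean = colMeans(abs(w)),
         meanCount = colMeans(counts))
  }
  facs <- paste0("F", 1:3)
  dis <- c("a", "b", "c")
  wOverall <- matrix(c(0.3, 0, 0, 0, 0.2, 0, 0, 0, 0.1), 3,
                     dimnames = list(facs, dis))
  cOverall <- matrix(c(5, 0, 0, 0, 3, 0, 0, 0, 1), 3,
                     dimnames = list(facs, dis))
  overall <- mkTable(wOverall, cOverall)
  singular <- lapply(stats::setNames(dis, dis), function(d) {
    w <- wOverall[, d, drop = FALSE]
    mkTable(w, cOverall[, d, drop = FALSE])
  })
  expect_warning(sc <- screenTopK(singular, overall, k = 5), "clamped")
  expect_identical(sc$k, 3L)
  expect_identical(sc$topByWeight$overall$disease, c("a", "b", "c"))
  expect_identical(sc$topByCount$singular$disease, c("a", "b", "c"))

  # all-equal metrics fall back to label order
  wTie <- matrix(0.2, 3, 3, dimnames = list(facs, dis))
  cTie <- matrix(2, 3, 3, dimnames = list(facs, dis))
  overallTie <- mkTable(wTie, cTie)
  singularTie <- lapply(stats::setNames(dis, dis), function(d)
    mkTable(wTie[, d, drop = FALSE], cTie[, d, drop = FALSE]))
  scTie <- screenTopK(singularTie, overallTie, k = 2)
  expect_identical(scTie$topByWeight$singular$disease, c("a", "b"))

  # associations are ordered by absolute weight within each disease
  aAssoc <- sc$associations[sc$associations$disease == "a", ]
  expect_identical(aAssoc$factor[1], "F1")
})

test_that("tables are pure functions of the serialized model", {
  cs <- conceptSet(c(paste0("F", 1:3), "d1", "d2"),
                   c(rep("environment", 3), rep("disease", 2)))
  m <- randomModel(cs, order = 2L, seed = 66)
  path <- withr::local_tempfile(fileext = ".json")
  writeFCMModel(m, path)
  m2 <- readFCMModel(path)
  tb <- factorDiseaseTable(m, epsilon = 0.08, maxLen = 3L)
  tb2 <- factorDiseaseTable(m2, epsilon = 0.08, maxLen = 3L)
  expect_equal(tb$weights, tb2$weights, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(tb$counts, tb2$counts, ignore_attr = TRUE)
})

test_that("graph export writes GraphML and DOT with attributes", {
  g <- randomDigraph(4, pEdge = 0.6, seed = 70)
  gml <- withr::local_tempfile(fileext = ".graphml")
  dot <- withr::local_tempfile(fileext = ".dot")
  exportGraph(g, gml, "graphml")
  exportGraph(g, dot, "dot")
  expect_true(file.size(gml) > 0)
  xml <- paste(readLines(gml, warn = FALSE), collapse = "\n")
  expect_match(xml, "weight")
  expect_match(xml, "role")
  expect_true(file.size(dot) > 0)
})
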