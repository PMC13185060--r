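test_that("DE settings load from YAML and JSON config files", {
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(popSize = 24, CR = 0.9, orders = c(1, 2),
                        seed = 11), yml)
  cfg <- deConfigFromFile(yml)
  expect_identical(cfg@popSize, 24L)
  expect_equal(cfg@CR, 0.9)
  expect_identical(cfg@orders, c(1L, 2L))
  expect_equal(cfg@F, 0.5)   # untouched default

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(maxEpochs = 10, nRestarts = 2), js,
                       auto_unbox = TRUE)
  expect_identical(deConfigFromFile(js)@maxEpochs, 10L)

  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(popsize = 10), bad)
  expect_error(deConfigFromFile(bad), "unknown DE setting")
})

test_that("genome encoding and decoding are exact inverses", {
  cs <- tinyConcepts(3, 2)
  for (ord in c(1L, 3L)) {
    m <- randomModel(cs, order = ord, seed = ord)
    g <- encodeGenome(m)
    expect_length(g, ord * sum(fcmMask(m)))
    m2 <- decodeGenome(g, fcmModel(cs, order = ord))
    expect_equal(fcmWeights(m2), fcmWeights(m), tolerance = 1e-15)
    expect_identical(encodeGenome(m2), g)
  }
  expect_error(decodeGenome(c(1, 2), fcmModel(cs, order = 1L)),
               "genome length")
})

test_that("crossover is the clipped scaled difference of donors", {
  expect_equal(deCrossover(c(0.2), c(0.8), c(0.4), F = 0.5), 0.4)
  tgt <- c(0.1, -0.5, 0.9)
  expect_identical(deCrossover(tgt, c(1, 1, 1), c(0, -1, 0.5), F = 0),
                   tgt)
  d <- c(0.3, 0.3, 0.3)
  expect_identical(deCrossover(tgt, d, d, F = 0.7), tgt)
  # clipping to the conventional weight bounds
  expect_equal(deCrossover(c(0.9), c(1), c(-1), F = 1), 1)
  expect_equal(deCrossover(c(-0.9), c(-1), c(1), F = 1), -1)
})

test_that("mutation takes the forced index and respects CR extremes", {
  orig <- seq(0.1, 1, by = 0.1)
  pert <- -orig
  withr::with_seed(1, {
    expect_identical(deMutate(orig, pert, CR = 1), pert)
    for (i in 1:20) {
      trial <- deMutate(orig, pert, CR = 0)
      expect_identical(sum(trial != orig), 1L)
    }
  })
})

test_that("mutation replacement frequency matches CR plus the forced draw", {
  L <- 10
  nTrial <- 1e4
  orig <- rep(0, L)
  pert <- rep(1, L)
  hits <- withr::with_seed(42, {
    rowSums(vapply(seq_len(nTrial),
                   function(i) deMutate(orig, pert, CR = 0.3) == 1,
                   logical(L)))
  })
  p <- 0.3 + 0.7 / L
  sigma <- sqrt(p * (1 - p) / nTrial)
  expect_true(all(abs(hits / nTrial - p) <= 3 * sigma))
})

test_that("mutation never returns the original when vectors differ everywhere", {
  withr::with_seed(9, {
    for (i in 1:50) {
      orig <- runif(6)
      trial <- deMutate(orig, orig + 0.1, CR = runif(1))
      expect_false(identical(trial, orig))
    }
  })
})

test_that("greedy selection keeps the better individual, incumbent on ties", {
  a <- list(genome = 1, loss = 1.0)
  b <- list(genome = 2, loss = 0.5)
  expect_identical(greedySelect(a, b), b)
  expect_identical(greedySelect(b, a), b)
  tie <- list(genome = 3, loss = 0.5)
  expect_identical(greedySelect(b, tie), b)
  expect_error(greedySelect(a, list(genome = 4)), "evaluated loss")
})

test_that("squared-error loss matches a naive double-loop oracle", {
  cs <- tinyConcepts(2, 2)
  template1 <- fcmModel(cs, order = 1L)
  obs <- randomNormalizedSeries(12, 4, seed = 6, names = conceptNames(cs))

  # exact-fit and closed-form cases
  zeroG <- encodeGenome(template1)
  half <- timeSeriesMatrix(matrix(0.5, 8, 4,
                                  dimnames = list(NULL, conceptNames(cs))),
                           normParams = list(min = rep(0, 4),
                                             max = rep(1, 4)))
  expect_equal(fcmLoss(zeroG, half, template1), 0)
  ones <- timeSeriesMatrix(matrix(1, 8, 4,
                                  dimnames = list(NULL, conceptNames(cs))),
                           normParams = list(min = rep(0, 4),
                                             max = rep(1, 4)))
  expect_equal(fcmLoss(zeroG, ones, template1), 0.25 * 7 * 4)

  for (seed in 1:10) {
    ord <- 1L + seed %% 3L
    template <- fcmModel(cs, order = ord)
    m <- randomModel(cs, order = ord, seed = seed + 50)
    for (mode in c("teacher_forced", "free_run")) {
      expect_equal(fcmLoss(encodeGenome(m), obs, template, mode),
                   naiveLoss(m, obs, mode), tolerance = 1e-10)
    }
  }
})

test_that("MAE evaluation matches a naive loop oracle and closed forms", {
  cs <- tinyConcepts(2, 1)
  obs <- randomNormalizedSeries(10, 3, seed = 8, names = conceptNames(cs))
  m <- randomModel(cs, order = 2L, seed = 9)
  got <- evaluateMAE(m, obs)
  want <- naiveMAE(m, obs)
  expect_equal(unname(got$perConcept), unname(want), tolerance = 1e-12)
  expect_equal(got$overall, mean(want), tolerance = 1e-12)

  truth <- recoveryTruth()
  traj <- selfTrajectory(truth, Tn = 40, burnIn = 5, seed = 12)
  expect_equal(evaluateMAE(truth, traj)$overall, 0, tolerance = 1e-12)
  expect_error(evaluateMAE(m, timeSeriesMatrix(
    matrix(0.5, 2, 3, dimnames = list(NULL, conceptNames(cs))))),
    "longer than")
})

test_that("feedback mask frees everything except disease-to-environment", {
  cs <- conceptSet(c("pm", "on"), c("environment", "disease"))
  expect_identical(unname(buildMask(cs)),
                   rbind(c(TRUE, TRUE), c(FALSE, TRUE)))
  allEnv <- conceptSet(c("a", "b", "c"), rep("environment", 3))
  expect_true(all(buildMask(allEnv)))
})

test_that("evolution is deterministic, monotone, and mask-conserving", {
  fx <- makeStudyFixture("tiny", seed = 77)
  train <- trainTestSplit(fx$data)$train
  template <- fcmModel(fx$concepts, order = 1L)
  cfg <- deConfig(popSize = 12L, maxEpochs = 40L, nRestarts = 1L,
                  orders = 1L, seed = 5L)
  r1 <- deEvolve(train, template, cfg)
  r2 <- deEvolve(train, template, cfg)
  expect_identical(fcmWeights(r1@bestModel), fcmWeights(r2@bestModel))
  expect_identical(r1@history, r2@history)
  expect_true(all(diff(r1@history) <= 0))
  W <- fcmWeights(r1@bestModel)[[1]]
  expect_true(all(W[!fcmMask(r1@bestModel)] == 0))

  cfg0 <- deConfig(popSize = 12L, maxEpochs = 0L, nRestarts = 1L,
                   orders = 1L, seed = 5L)
  r0 <- deEvolve(train, template, cfg0)
  expect_equal(r0@bestFitness, fcmLoss(r0@bestModel, train),
               tolerance = 1e-12)
  expect_gte(r0@bestFitness, r1@bestFitness)
})

test_that("multi-restart selection returns the minimum over candidates", {
  fx <- makeStudyFixture("tiny", seed = 78)
  sp <- trainTestSplit(fx$data)
  cfgSingle <- deConfig(popSize = 10L, maxEpochs = 25L, nRestarts = 1L,
                        orders = 1L, seed = 3L)
  single <- multiRestartFit(sp$train, fx$concepts, cfgSingle)
  # a 1-restart, 1-order multi fit is exactly one evolve at the sub-seed
  sub <- cfgSingle
  sub@seed <- as.integer(fcmscreen:::.subSeed(3L, 1L, 1L))
  direct <- deEvolve(sp$train, fcmModel(fx$concepts, order = 1L), sub)
  expect_identical(fcmWeights(single@bestModel), fcmWeights(direct@bestModel))
  expect_equal(single@bestFitness, direct@bestFitness)

  cfgMulti <- deConfig(popSize = 10L, maxEpochs = 25L, nRestarts = 3L,
                       orders = c(1L, 2L), seed = 3L)
  multi <- multiRestartFit(sp$train, fx$concepts, cfgMulti,
                           testData = sp$test)
  expect_identical(nrow(multi@fitnessTable), 6L)
  expect_equal(multi@bestFitness, min(multi@fitnessTable$fitness))
  expect_true(all(vapply(fcmWeights(multi@bestModel), function(W)
    all(W[!fcmMask(multi@bestModel)] == 0), logical(1))))
  expect_length(multi@testMAE$perConcept, 6L)
})

test_that("an order-2 truth is fit better by order 2 than order 1", {
  truth <- order2Truth()
  traj <- selfTrajectory(truth, Tn = 150, burnIn = 20, seed = 13)
  cs <- truth@concepts
  fit1 <- multiRestartFit(traj, cs,
                          deConfig(popSize = 30L, CR = 0.9,
                                   maxEpochs = 300L, nRestarts = 2L,
                                   orders = 1L, seed = 21L))
  fit2 <- multiRestartFit(traj, cs,
                          deConfig(popSize = 30L, CR = 0.9,
                                   maxEpochs = 300L, nRestarts = 2L,
                                   orders = 2L, seed = 21L))
  expect_lt(fit2@bestFitness, fit1@bestFitness)
})
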