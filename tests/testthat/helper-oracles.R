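# Independent oracles and small builders used across the suite. The
# oracles deliberately share no code with the package internals: plain
# double loops and recursive backtracking.

tinyConcepts <- function(nEnv = 2, nDis = 1) {
  conceptSet(c(paste0("E", seq_len(nEnv)), paste0("D", seq_len(nDis))),
             c(rep("environment", nEnv), rep("disease", nDis)))
}

# random masked model with weights uniform in [-1, 1]
randomModel <- function(concepts, order = 1L, seed = 1, lambda = 5) {
  withr::with_seed(seed, {
    n <- nConcepts(concepts)
    mask <- buildMask(concepts)
    weights <- lapply(seq_len(order), function(l) {
      W <- matrix(stats::runif(n * n, -1, 1), n)
      W[!mask] <- 0
      W
    })
    fcmModel(concepts, order = order, weights = weights, mask = mask,
             lambda = lambda)
  })
}

randomNormalizedSeries <- function(Tn, n, seed = 1, names = NULL) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(Tn * n), Tn, n)
    colnames(m) <- names %||% paste0("V", seq_len(n))
    timeSeriesMatrix(m, normParams = list(min = rep(0, n), max = rep(1, n)))
  })
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive teacher-forced/free-run squared-error loss: explicit loops over
# lags, sources, targets and time.
naiveLoss <- function(model, X, mode = "teacher_forced") {
  if (is(X, "TimeSeriesMatrix")) X <- tsValues(X)
  k <- fcmOrder(model)
  W <- fcmWeights(model)
  lam <- fcmLambda(model)
  n <- ncol(X)
  P <- X
  total <- 0
  for (t in (k + 1):nrow(X)) {
    src <- if (mode == "teacher_forced") X else P
    for (i in seq_len(n)) {
      z <- 0
      for (l in seq_len(k)) for (j in seq_len(n))
        z <- z + W[[l]][j, i] * src[t - l, j]
      P[t, i] <- 1 / (1 + exp(-lam * z))
      total <- total + (P[t, i] - X[t, i])^2
    }
  }
  unname(total)
}

naiveMAE <- function(model, X, mode = "teacher_forced") {
  if (is(X, "TimeSeriesMatrix")) X <- tsValues(X)
  k <- fcmOrder(model)
  W <- fcmWeights(model)
  lam <- fcmLambda(model)
  n <- ncol(X)
  P <- X
  err <- matrix(0, nrow(X) - k, n)
  for (t in (k + 1):nrow(X)) {
    src <- if (mode == "teacher_forced") X else P
    for (i in seq_len(n)) {
      z <- 0
      for (l in seq_len(k)) for (j in seq_len(n))
        z <- z + W[[l]][j, i] * src[t - l, j]
      P[t, i] <- 1 / (1 + exp(-lam * z))
      err[t - k, i] <- abs(P[t, i] - X[t, i])
    }
  }
  colMeans(err)
}

# Recursive-backtracking simple-path oracle on an edge data.frame.
# Returns a sorted character vector of "a->b->c|weight" descriptors.
oraclePaths <- function(edges, source, target, maxLen) {
  out <- character(0)
  recurse <- function(node, visited, weight) {
    if (length(visited) - 1L > maxLen) return()
    if (node == target && length(visited) > 1L) {
      out[[length(out) + 1L]] <<- paste0(
        paste(visited, collapse = "->"), "|",
        formatC(weight, digits = 12, format = "g"))
      return()
    }
    nxt <- edges[edges$source == node, , drop = FALSE]
    for (r in seq_len(nrow(nxt))) {
      if (nxt$target[r] %in% visited) next
      if (length(visited) > maxLen) next
      recurse(nxt$target[r], c(visited, nxt$target[r]),
              weight * nxt$weight[r])
    }
  }
  recurse(source, source, 1)
  sort(out)
}

pathsAsDescriptors <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste0(df$path, "|", formatC(df$weight, digits = 12, format = "g")))
}

randomDigraph <- function(n, pEdge, seed) {
  withr::with_seed(seed, {
    labs <- paste0("N", seq_len(n))
    pairs <- expand.grid(source = labs, target = labs,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    keep <- stats::runif(nrow(pairs)) < pEdge
    e <- pairs[keep, , drop = FALSE]
    e$weight <- stats::runif(nrow(e), -1, 1)
    e <- e[abs(e$weight) >= 0.05, , drop = FALSE]
    rownames(e) <- NULL
    cs <- conceptSet(labs, rep("environment", n))
    new("SignedDigraph", concepts = cs, edges = e, epsilon = 0.05)
  })
}

# Frozen sparse order-1 ground truth whose free-run sigmoid dynamics stay
# aperiodic, so a noise-free trajectory identifies the weights.
recoveryTruth <- function() {
  W <- rbind(c(-0.81, -0.60,  0.00,  0.00),
             c(-0.42,  0.00,  0.00,  0.50),
             c( 0.67,  0.00,  0.00,  0.00),
             c( 0.00,  0.00,  0.58, -0.74))
  cs <- conceptSet(paste0("X", 1:4), rep("environment", 4))
  fcmModel(cs, order = 1L, weights = list(W), mask = matrix(TRUE, 4, 4))
}

# Noise-free length-Tn trajectory of a model (burn-in discarded), marked
# as normalized.
selfTrajectory <- function(model, Tn = 200, burnIn = 20, seed = 5) {
  k <- fcmOrder(model)
  n <- nConcepts(model)
  withr::with_seed(seed, {
    U <- matrix(0, Tn + burnIn, n, dimnames = list(NULL, conceptNames(model)))
    for (t in seq_len(k)) U[t, ] <- stats::runif(n)
    for (t in (k + 1):(Tn + burnIn))
      U[t, ] <- fcmStep(model, lapply(seq_len(k), function(l) U[t - l, ]))
    timeSeriesMatrix(U[(burnIn + 1):(burnIn + Tn), , drop = FALSE],
                     normParams = list(min = rep(0, n), max = rep(1, n)))
  })
}

# Frozen order-2 ground truth with an aperiodic trajectory, for
# order-selection checks.
order2Truth <- function() {
  W1 <- rbind(c( 0.00,  0.95, 0.61),
              c(-0.82,  0.00, 0.00),
              c( 0.00, -0.24, 0.00))
  W2 <- rbind(c( 0.00, -0.72,  0.00),
              c( 0.00,  0.00,  0.00),
              c( 0.56,  0.00, -0.66))
  cs <- conceptSet(paste0("X", 1:3), rep("environment", 3))
  fcmModel(cs, order = 2L, weights = list(W1, W2),
           mask = matrix(TRUE, 3, 3))
}

# Study-scale DE settings used by the end-to-end tests: chosen for
# convergence quality on the tiny fixture at CI-scale runtime.
studyDE <- function(seed = 1L, nRestarts = 5L) {
  deConfig(popSize = 40L, CR = 0.9, maxEpochs = 1000L,
           nRestarts = nRestarts, orders = 1L, stallWindow = 150L,
           seed = seed)
}
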