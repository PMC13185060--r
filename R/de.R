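#' Create a DEConfig
#'
#' Differential-evolution hyperparameters with conventional defaults for
#' genomes of at most a few thousand entries: population 50, cross factor
#' F = 0.5, mutation rate CR = 0.3, 500 epochs, early stop when the best
#' loss improves by less than \code{convergenceTol} over a window of
#' \code{stallWindow} epochs. Ten independent restarts per order mirror the
#' multi-start protocol used for model selection.
#'
#' @param popSize population size (>= 4).
#' @param F cross factor in [0, 1].
#' @param CR mutation rate in [0, 1].
#' @param maxEpochs epoch cap (0 = score the random initial population only).
#' @param convergenceTol stall threshold on best-loss improvement.
#' @param stallWindow stall-window length in epochs.
#' @param seed integer master seed; every random draw in a fit derives
#'   from it.
#' @param nRestarts independent restarts per order.
#' @param orders integer subset of {1, 2, 3}.
#' @param mode prediction mode inside the loss.
#' @return a [DEConfig-class].
#' @export
deConfig <- function(popSize = 50L, F = 0.5, CR = 0.3, maxEpochs = 500L,
                     convergenceTol = 1e-8, stallWindow = 50L, seed = 1L,
                     nRestarts = 10L, orders = c(1L, 2L, 3L),
                     mode = "teacher_forced") {
  new("DEConfig", popSize = as.integer(popSize), F = as.numeric(F),
      CR = as.numeric(CR), maxEpochs = as.integer(maxEpochs),
      convergenceTol = as.numeric(convergenceTol),
      stallWindow = as.integer(stallWindow), seed = as.integer(seed),
      nRestarts = as.integer(nRestarts), orders = as.integer(orders),
      mode = as.character(mode))
}

#' @describeIn deConfig build a DEConfig from a YAML or JSON file whose
#'   top-level keys are the constructor's argument names; omitted keys
#'   keep their defaults.
#' @param path path to a .yaml/.yml or .json settings file.
#' @export
deConfigFromFile <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(spec), names(formals(deConfig)))
  if (length(unknown))
    stop("unknown DE setting(s): ", paste(unknown, collapse = ", "))
  do.call(deConfig, spec)
}

setMethod("show", "DEConfig", function(object) {
  cat("DEConfig: pop", object@popSize, ", F =", object@F, ", CR =",
      object@CR, ",", object@maxEpochs, "epochs,", object@nRestarts,
      "restarts, orders {", paste(object@orders, collapse = ","),
      "}, mode", object@mode, ", seed", object@seed, "\n")
})

# Deterministic sub-seed for restart r of order o under a master seed;
# kept strictly below 2^31 - 1.
.subSeed <- function(seed, order, restart) {
  (abs(as.numeric(seed)) * 7919 + order * 1299709 + restart * 104729) %%
    2147483647
}

#' Encode the learnable weights of a model as a genome
#'
#' The genome covers only mask-true entries, lag by lag, column-major
#' within each lag matrix. Decoding a genome back into the template is the
#' exact inverse.
#'
#' @param model an [FCMModel-class].
#' @return numeric vector of length order * sum(mask).
#' @export
encodeGenome <- function(model) {
  unlist(lapply(model@weights, function(W) W[model@mask]), use.names = FALSE)
}

#' @describeIn encodeGenome rebuild a model from a genome and a template
#'   carrying the concepts, order, mask and lambda.
#' @param genome numeric vector as produced by [encodeGenome()].
#' @param template an [FCMModel-class] supplying everything but the
#'   learnable weights.
#' @export
decodeGenome <- function(genome, template) {
  nLearn <- sum(template@mask)
  if (length(genome) != template@order * nLearn)
    stop("genome length does not match the template's mask and order")
  weights <- vector("list", template@order)
  for (l in seq_len(template@order)) {
    W <- matrix(0, nrow(template@mask), ncol(template@mask),
                dimnames = dimnames(template@mask))
    W[template@mask] <- genome[((l - 1L) * nLearn + 1L):(l * nLearn)]
    weights[[l]] <- W
  }
  new("FCMModel", concepts = template@concepts, order = template@order,
      lambda = template@lambda, weights = weights, mask = template@mask)
}

#' Training loss of a genome (sum of squared prediction errors)
#'
#' L = sum over concepts i and scored rows t of
#' (predicted_i(t) - observed_i(t))^2. Only rows with a full lag window
#' (t > k) are scored. Non-finite predictions yield an infinite loss so
#' the individual is culled by greedy selection.
#'
#' @param genome numeric genome vector (see [encodeGenome()]), or an
#'   [FCMModel-class] to score directly.
#' @param data a normalized [TimeSeriesMatrix-class].
#' @param template template [FCMModel-class] (ignored when \code{genome}
#'   is already a model).
#' @param mode prediction mode.
#' @return non-negative scalar.
#' @export
fcmLoss <- function(genome, data, template = NULL,
                    mode = c("teacher_forced", "free_run")) {
  mode <- match.arg(mode)
  model <- if (is(genome, "FCMModel")) genome else decodeGenome(genome, template)
  X <- if (is(data, "TimeSeriesMatrix")) data@values else as.matrix(data)
  k <- model@order
  P <- .forwardPass(model@weights, model@lambda, X, mode)
  scored <- (k + 1L):nrow(X)
  err <- P[scored, , drop = FALSE] - X[scored, , drop = FALSE]
  s <- sum(err * err)
  if (!is.finite(s)) Inf else s
}

#' DE crossover: scaled difference of two donors
#'
#' Produces the perturbed vector target + F * (donor1 - donor2), clipped
#' elementwise to the conventional FCM weight bounds [-1, 1]. With F = 0
#' or identical donors the target is returned unchanged.
#'
#' @param target,donor1,donor2 numeric genome vectors of equal length.
#' @param F cross factor in [0, 1].
#' @return perturbed genome vector.
#' @export
deCrossover <- function(target, donor1, donor2, F) {
  stopifnot(length(donor1) == length(target),
            length(donor2) == length(target))
  pmin(pmax(target + F * (donor1 - donor2), -1), 1)
}

#' DE mutation: elementwise recombination with a forced index
#'
#' Builds the trial vector by taking element j from \code{perturbed}
#' whenever a uniform draw is <= CR or j equals one pre-drawn forced
#' index, and from \code{original} otherwise. The forced index guarantees
#' at least one element is always taken from the perturbed vector, even
#' at CR = 0.
#'
#' @param original,perturbed numeric genome vectors of equal length.
#' @param CR mutation rate in [0, 1].
#' @return trial genome vector.
#' @export
deMutate <- function(original, perturbed, CR) {
  L <- length(original)
  stopifnot(L >= 1L, length(perturbed) == L)
  take <- stats::runif(L) <= CR
  take[sample.int(L, 1L)] <- TRUE
  ifelse(take, perturbed, original)
}

#' Greedy selection between incumbent and trial
#'
#' Returns the individual with the lower loss; ties keep the incumbent
#' (deterministic, conservative).
#'
#' @param original,trial lists with elements \code{genome} and \code{loss}.
#' @return the surviving individual.
#' @export
greedySelect <- function(original, trial) {
  if (is.null(original$loss) || is.null(trial$loss))
    stop("both individuals must carry an evaluated loss")
  if (trial$loss < original$loss) trial else original
}

# Batched teacher-forced loss: rows of G are genomes. Xlag is the
# (T-k) x (k*n) lagged design, Xs the scored observations, wIdx the
# linear indices of the learnable entries inside one stacked (k*n) x n
# weight block. One matrix product evaluates the whole population.
.batchLoss <- function(G, Xlag, Xs, wIdx, n, k, lambda) {
  np <- nrow(G)
  L <- ncol(G)
  WAll <- matrix(0, k * n, n * np)
  WAll[rep(wIdx, np) + rep((seq_len(np) - 1L) * (k * n * n), each = L)] <-
    as.vector(t(G))
  P <- 1 / (1 + exp(-lambda * (Xlag %*% WAll)))
  E <- P - Xs[, rep(seq_len(n), np), drop = FALSE]
  losses <- colSums(matrix(colSums(E * E), n, np))
  losses[!is.finite(losses)] <- Inf
  losses
}

# Precompute the lagged design and index machinery for .batchLoss.
.lossContext <- function(X, template) {
  k <- template@order
  n <- ncol(X)
  Tn <- nrow(X)
  Xlag <- matrix(0, Tn - k, k * n)
  for (l in seq_len(k))
    Xlag[, ((l - 1L) * n + 1L):(l * n)] <- X[(k + 1L - l):(Tn - l), ,
                                             drop = FALSE]
  # genome order is lag-major, column-major within each lag's mask;
  # entry (r, c) of lag l sits at row (l-1)*n + r of the stacked block
  mi <- which(template@mask, arr.ind = TRUE)
  ord <- order(mi[, 2], mi[, 1])  # column-major, matching W[mask]
  mi <- mi[ord, , drop = FALSE]
  wIdx <- unlist(lapply(seq_len(k), function(l)
    (mi[, 2] - 1L) * (k * n) + (l - 1L) * n + mi[, 1]))
  list(Xlag = Xlag, Xs = X[(k + 1L):Tn, , drop = FALSE], wIdx = wIdx,
       n = n, k = k)
}

#' Run differential evolution for a single restart and order
#'
#' Initializes a population uniformly in [-1, 1] over the learnable
#' entries, then iterates crossover ([deCrossover()]), mutation
#' ([deMutate()]) and greedy selection until \code{maxEpochs} or until the
#' best loss has improved by less than \code{convergenceTol} over the last
#' \code{stallWindow} epochs. The best-loss trace is non-increasing by
#' construction.
#'
#' @param data normalized training [TimeSeriesMatrix-class].
#' @param template [FCMModel-class] fixing concepts, order, mask, lambda.
#' @param config a [DEConfig-class]; \code{config@seed} drives all draws.
#' @return a [FitReport-class] (testMAE empty).
#' @export
deEvolve <- function(data, template, config) {
  stopifnot(is(template, "FCMModel"), is(config, "DEConfig"))
  X <- if (is(data, "TimeSeriesMatrix")) data@values else as.matrix(data)
  if (min(X) < 0 || max(X) > 1)
    stop("training data must be min-max normalized")
  L <- template@order * sum(template@mask)
  if (L < 1L) stop("template has no learnable entries")
  np <- config@popSize
  mode <- config@mode
  ctx <- if (config@mode == "teacher_forced") .lossContext(X, template)
  evalPop <- function(G) {
    if (!is.null(ctx))
      .batchLoss(G, ctx$Xlag, ctx$Xs, ctx$wIdx, ctx$n, ctx$k,
                 template@lambda)
    else apply(G, 1, fcmLoss, data = X, template = template, mode = mode)
  }
  withr::with_seed(config@seed, {
    pop <- matrix(stats::runif(np * L, -1, 1), nrow = np)
    losses <- evalPop(pop)
    best <- min(losses)
    history <- numeric(0)
    stall <- 0L
    epoch <- 0L
    while (epoch < config@maxEpochs) {
      epoch <- epoch + 1L
      trials <- pop
      for (i in seq_len(np)) {
        donors <- sample(setdiff(seq_len(np), i), 2L)
        perturbed <- deCrossover(pop[i, ], pop[donors[1L], ],
                                 pop[donors[2L], ], config@F)
        trials[i, ] <- deMutate(pop[i, ], perturbed, config@CR)
      }
      trialLosses <- evalPop(trials)
      improve <- trialLosses < losses
      pop[improve, ] <- trials[improve, , drop = FALSE]
      losses[improve] <- trialLosses[improve]
      newBest <- min(losses)
      if (best - newBest < config@convergenceTol) stall <- stall + 1L
      else stall <- 0L
      best <- newBest
      history <- c(history, best)
      if (stall >= config@stallWindow) break
    }
    ib <- which.min(losses)
    new("FitReport",
        bestModel = decodeGenome(pop[ib, ], template),
        bestFitness = losses[ib],
        fitnessTable = data.frame(order = template@order, restart = 1L,
                                  fitness = losses[ib]),
        history = if (length(history)) history else best,
        testMAE = list())
  })
}

#' Multi-restart, multi-order model selection
#'
#' Runs [deEvolve()] for every (order, restart) pair with deterministic
#' sub-seeds derived from the master seed, and returns the fit with the
#' lowest training fitness across all candidates. The full fitness table
#' is kept for reporting. When \code{testData} is supplied the selected
#' model's mean absolute error on it is attached.
#'
#' @param data normalized training [TimeSeriesMatrix-class].
#' @param concepts a [ConceptSet-class]; the feedback mask is built from
#'   its roles.
#' @param config a [DEConfig-class].
#' @param testData optional normalized test [TimeSeriesMatrix-class].
#' @param lambda sigmoid steepness passed to each candidate model.
#' @return a [FitReport-class].
#' @export
multiRestartFit <- function(data, concepts, config, testData = NULL,
                            lambda = 5) {
  stopifnot(is(concepts, "ConceptSet"), is(config, "DEConfig"))
  rows <- list()
  bestReport <- NULL
  for (ord in sort(config@orders)) {
    template <- fcmModel(concepts, order = ord, lambda = lambda)
    for (r in seq_len(config@nRestarts)) {
      sub <- config
      sub@seed <- as.integer(.subSeed(config@seed, ord, r))
      rep <- deEvolve(data, template, sub)
      rows[[length(rows) + 1L]] <- data.frame(order = ord, restart = r,
                                              fitness = rep@bestFitness)
      if (is.null(bestReport) || rep@bestFitness < bestReport@bestFitness)
        bestReport <- rep
    }
  }
  tab <- do.call(rbind, rows)
  mae <- if (!is.null(testData))
    evaluateMAE(bestReport@bestModel, testData, config@mode) else list()
  new("FitReport", bestModel = bestReport@bestModel,
      bestFitness = bestReport@bestFitness, fitnessTable = tab,
      history = bestReport@history, testMAE = mae)
}

setMethod("show", "FitReport", function(object) {
  cat("FitReport: best fitness", format(object@bestFitness, digits = 6),
      "( order", object@bestModel@order, ") over",
      nrow(object@fitnessTable), "candidate fit(s)\n")
  if (length(object@testMAE))
    cat("  overall test MAE:", format(object@testMAE$overall, digits = 6),
        "\n")
})

#' Mean absolute prediction error on held-out data
#'
#' MAE_i = mean over scored rows t of |predicted_i(t) - observed_i(t)|;
#' the overall value is the mean over concepts. The test data must be
#' normalized with the training-set bounds.
#'
#' @param model a fitted [FCMModel-class].
#' @param test normalized test [TimeSeriesMatrix-class].
#' @param mode prediction mode.
#' @return list with \code{perConcept} (named numeric vector) and
#'   \code{overall} (scalar).
#' @export
evaluateMAE <- function(model, test, mode = c("teacher_forced", "free_run")) {
  mode <- match.arg(mode)
  X <- if (is(test, "TimeSeriesMatrix")) test@values else as.matrix(test)
  k <- model@order
  if (nrow(X) <= k)
    stop("test series must be longer than the model order")
  P <- .forwardPass(model@weights, model@lambda, X, mode)
  scored <- (k + 1L):nrow(X)
  perConcept <- colMeans(abs(P[scored, , drop = FALSE] -
                               X[scored, , drop = FALSE]))
  names(perConcept) <- model@concepts@names
  list(perConcept = perConcept, overall = mean(perConcept))
}
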