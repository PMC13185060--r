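#' Create an FCMModel
#'
#' @param concepts a [ConceptSet-class].
#' @param order lag order k in {1, 2, 3}.
#' @param weights list of k numeric n x n matrices (source rows, target
#'   columns, entries in [-1, 1]); defaults to all-zero matrices.
#' @param mask logical n x n learnable-entry matrix; defaults to
#'   [buildMask()] of the concepts. Masked-out entries are forced to zero.
#' @param lambda sigmoid steepness; default 5. The steepness has little
#'   influence on the inferred structure but is kept configurable.
#'
#' @return an [FCMModel-class].
#' @export
fcmModel <- function(concepts, order = 1L, weights = NULL, mask = NULL,
                     lambda = 5) {
  stopifnot(is(concepts, "ConceptSet"))
  n <- length(concepts@names)
  order <- as.integer(order)
  if (is.null(mask)) mask <- buildMask(concepts)
  dimnames(mask) <- list(concepts@names, concepts@names)
  if (is.null(weights))
    weights <- replicate(order, matrix(0, n, n), simplify = FALSE)
  weights <- lapply(weights, function(W) {
    W <- as.matrix(W)
    dimnames(W) <- list(concepts@names, concepts@names)
    W[!mask] <- 0
    W
  })
  new("FCMModel", concepts = concepts, order = order,
      lambda = as.numeric(lambda), weights = weights, mask = mask)
}

#' @describeIn fcmModel list of per-lag weight matrices (lag 1 = t-1).
#' @param x an FCMModel.
#' @export
fcmWeights <- function(x) x@weights

#' @describeIn fcmModel the learnable-entry mask.
#' @export
fcmMask <- function(x) x@mask

#' @describeIn fcmModel the lag order.
#' @export
fcmOrder <- function(x) x@order

#' @describeIn fcmModel the sigmoid steepness.
#' @export
fcmLambda <- function(x) x@lambda

setMethod("show", "FCMModel", function(object) {
  n <- length(object@concepts@names)
  nz <- sum(vapply(object@weights, function(W) sum(W != 0), numeric(1)))
  cat("FCMModel: order", object@order, "over", n, "concepts, lambda =",
      object@lambda, "\n")
  cat("  learnable entries:", sum(object@mask), "of", n * n, "per lag;",
      nz, "nonzero weights in total\n")
})

#' Sigmoid transition kernel
#'
#' The squashing function applied to each concept's weighted input sum:
#' f(x) = 1 / (1 + exp(-lambda * x)). Strictly increasing, range (0, 1),
#' f(0) = 0.5.
#'
#' @param x numeric input (vectorized).
#' @param lambda positive steepness; default 5.
#' @return values in (0, 1).
#' @examples
#' sigmoidTransfer(0)       # 0.5
#' sigmoidTransfer(1, 5)    # 1 / (1 + exp(-5))
#' @export
sigmoidTransfer <- function(x, lambda = 5) {
  if (length(lambda) != 1L || !is.finite(lambda) || lambda <= 0)
    stop("lambda must be a single positive number")
  if (anyNA(x) || any(!is.finite(x)))
    stop("non-finite input to the transition function (corrupt state)")
  1 / (1 + exp(-lambda * x))
}

#' One transition step of an FCM
#'
#' Computes the next activation of every concept from the last k state
#' vectors: output_i = f( sum over lags l and sources j of
#' weights[[l]][j, i] * history[[l]][j] ), with f the sigmoid kernel.
#'
#' @param model an [FCMModel-class].
#' @param history list of k numeric vectors of length n; element 1 is the
#'   state at t-1, element k the state at t-k.
#' @return numeric vector of length n with entries in (0, 1).
#' @export
fcmStep <- function(model, history) {
  stopifnot(is(model, "FCMModel"))
  if (!is.list(history)) history <- list(history)
  if (length(history) != model@order)
    stop("history must hold exactly ", model@order, " state vectors")
  n <- length(model@concepts@names)
  z <- numeric(n)
  for (l in seq_len(model@order)) {
    h <- history[[l]]
    if (length(h) != n) stop("history vectors must have length n")
    z <- z + drop(h %*% model@weights[[l]])
  }
  stats::setNames(sigmoidTransfer(z, model@lambda), model@concepts@names)
}

#' Predict a concept time series with an FCM
#'
#' In \code{teacher_forced} mode each row t >= k+1 is computed by one
#' transition step from the *observed* rows t-1, ..., t-k. In
#' \code{free_run} mode the model is seeded with the first k observed rows
#' and then rolled forward on its own predictions. The first k rows of the
#' result are copied from the observations in both modes.
#'
#' @param model an [FCMModel-class].
#' @param observed a normalized [TimeSeriesMatrix-class] whose columns
#'   match the model's concepts.
#' @param mode \code{"teacher_forced"} (default) or \code{"free_run"}.
#' @return list with \code{predicted} (T x n matrix) and \code{mode}.
#' @export
predictSeries <- function(model, observed,
                          mode = c("teacher_forced", "free_run")) {
  mode <- match.arg(mode)
  stopifnot(is(model, "FCMModel"))
  X <- if (is(observed, "TimeSeriesMatrix")) observed@values else
    as.matrix(observed)
  if (min(X) < 0 || max(X) > 1)
    stop("observations must be min-max normalized to [0, 1]")
  k <- model@order
  if (nrow(X) <= k) stop("need more rows than the model order")
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), model@concepts@names))
    stop("observation columns must match the model's concepts in order")
  P <- .forwardPass(model@weights, model@lambda, X, mode)
  dimnames(P) <- dimnames(X)
  list(predicted = P, mode = mode)
}

# Shared forward dynamics. teacher_forced is fully vectorized over time;
# free_run is inherently sequential.
.forwardPass <- function(weights, lambda, X, mode) {
  k <- length(weights)
  Tn <- nrow(X)
  if (mode == "teacher_forced") {
    Z <- matrix(0, Tn - k, ncol(X))
    for (l in seq_len(k))
      Z <- Z + X[(k + 1L - l):(Tn - l), , drop = FALSE] %*% weights[[l]]
    P <- X
    P[(k + 1L):Tn, ] <- 1 / (1 + exp(-lambda * Z))
  } else {
    P <- X
    for (t in (k + 1L):Tn) {
      z <- 0
      for (l in seq_len(k)) z <- z + P[t - l, ] %*% weights[[l]]
      P[t, ] <- 1 / (1 + exp(-lambda * drop(z)))
    }
  }
  P
}

#' Serialize an FCMModel to JSON
#'
#' Writes concepts, roles, order, lambda, the lag matrices (row-major,
#' source rows first), the mask, and optional provenance (seed, fitness,
#' settings) so that every downstream table can be recomputed from the
#' file alone.
#'
#' @param model an [FCMModel-class].
#' @param path output file path.
#' @param provenance optional named list stored verbatim.
#' @return invisibly, \code{path}.
#' @export
writeFCMModel <- function(model, path, provenance = list()) {
  doc <- list(
    concepts = model@concepts@names,
    roles = model@concepts@roles,
    order = model@order,
    lambda = model@lambda,
    weights = lapply(model@weights, function(W)
      lapply(seq_len(nrow(W)), function(j) unname(W[j, ]))),
    mask = lapply(seq_len(nrow(model@mask)), function(j)
      unname(model@mask[j, ])),
    provenance = provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an FCMModel from JSON
#'
#' @param path file written by [writeFCMModel()].
#' @return an [FCMModel-class]; provenance is attached as the
#'   \code{"provenance"} attribute.
#' @export
readFCMModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cs <- conceptSet(doc$concepts, doc$roles)
  n <- length(doc$concepts)
  # jsonlite simplifies the nested weight arrays to a k x n x n array when
  # dimensions are consistent, otherwise to a list of row-lists
  wraw <- doc$weights
  weights <- lapply(seq_len(doc$order), function(l) {
    W <- if (is.array(wraw) && length(dim(wraw)) == 3L)
      wraw[l, , ] else wraw[[l]]
    if (is.list(W)) W <- do.call(rbind, lapply(W, as.numeric))
    W <- as.matrix(W)
    storage.mode(W) <- "double"
    W
  })
  mask <- doc$mask
  if (is.list(mask)) mask <- do.call(rbind, lapply(mask, as.logical))
  storage.mode(mask) <- "logical"
  m <- fcmModel(cs, order = doc$order, weights = weights, mask = mask,
                lambda = doc$lambda)
  attr(m, "provenance") <- doc$provenance
  m
}
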