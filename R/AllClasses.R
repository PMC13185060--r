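#' @import methods
NULL

#' ConceptSet: ordered, role-tagged concept labels
#'
#' An ordered set of concept (node) labels, each tagged as an
#' \code{"environment"} factor (pollutant or meteorological variable) or a
#' \code{"disease"} admission-count series. The order of the labels fixes
#' matrix indexing for every weight matrix and time-series column in the
#' package.
#'
#' @slot names character vector of unique, non-empty concept labels.
#' @slot roles character vector, same length, each \code{"environment"} or
#'   \code{"disease"}.
#'
#' @seealso [conceptSet()], [buildMask()]
#' @exportClass ConceptSet
setClass("ConceptSet",
  representation(names = "character", roles = "character"))

setValidity("ConceptSet", function(object) {
  msgs <- character()
  if (length(object@names) < 2L)
    msgs <- c(msgs, "at least 2 concepts are required")
  if (anyDuplicated(object@names))
    msgs <- c(msgs, "concept names must be unique")
  if (any(!nzchar(object@names)))
    msgs <- c(msgs, "concept names must be non-empty")
  if (length(object@roles) != length(object@names))
    msgs <- c(msgs, "roles must match names in length")
  if (!all(object@roles %in% c("environment", "disease")))
    msgs <- c(msgs, "roles must be 'environment' or 'disease'")
  if (length(msgs)) msgs else TRUE
})

#' TimeSeriesMatrix: daily multivariate observations
#'
#' A T x n matrix of daily observations, one column per concept, with an
#' ordered date index and optional min-max normalization metadata. When
#' \code{normParams} is non-empty all values lie in [0, 1] and the original
#' scale can be recovered with [denormalize()].
#'
#' @slot values numeric matrix (rows = days, columns = concepts); no missing
#'   entries.
#' @slot timestamps Date vector, strictly increasing, length \code{nrow(values)}.
#' @slot normParams list; either empty (raw scale) or with numeric vectors
#'   \code{min} and \code{max}, one entry per column.
#'
#' @seealso [timeSeriesMatrix()], [minMaxNormalize()]
#' @exportClass TimeSeriesMatrix
setClass("TimeSeriesMatrix",
  representation(values = "matrix", timestamps = "Date", normParams = "list"))

setValidity("TimeSeriesMatrix", function(object) {
  msgs <- character()
  v <- object@values
  if (!is.numeric(v)) msgs <- c(msgs, "values must be numeric")
  if (nrow(v) < 2L) msgs <- c(msgs, "at least 2 rows are required")
  if (anyNA(v) || any(!is.finite(v)))
    msgs <- c(msgs, "values must be finite with no missing entries")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msgs <- c(msgs, "values must have unique column names")
  if (length(object@timestamps) != nrow(v))
    msgs <- c(msgs, "timestamps length must equal nrow(values)")
  if (length(object@timestamps) > 1L && any(diff(object@timestamps) <= 0))
    msgs <- c(msgs, "timestamps must be strictly increasing")
  if (length(object@normParams)) {
    np <- object@normParams
    if (!all(c("min", "max") %in% names(np)) ||
        length(np$min) != ncol(v) || length(np$max) != ncol(v))
      msgs <- c(msgs, "normParams must hold per-column 'min' and 'max'")
    else if (length(msgs) == 0L && (min(v) < 0 || max(v) > 1))
      msgs <- c(msgs, "normalized values must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' FCMModel: a (possibly higher-order) fuzzy cognitive map
#'
#' A signed, weighted, directed graph over the concepts whose activations
#' evolve in discrete time. Order k means the next state depends on lags
#' t-1, ..., t-k, with one n x n weight matrix per lag. Weights are stored
#' source-major: \code{weights[[l]][j, i]} is the influence of concept j at
#' lag l on concept i at the next step. The boolean \code{mask} marks which
#' (source, target) entries are learnable; masked-out entries are exactly
#' zero in every lag matrix.
#'
#' @slot concepts a [ConceptSet-class].
#' @slot order integer lag order k in {1, 2, 3}.
#' @slot lambda positive sigmoid steepness (default 5).
#' @slot weights list of k numeric n x n matrices with entries in [-1, 1].
#' @slot mask logical n x n matrix; TRUE = learnable.
#'
#' @seealso [fcmModel()], [fcmStep()], [predictSeries()]
#' @exportClass FCMModel
setClass("FCMModel",
  representation(concepts = "ConceptSet", order = "integer",
                 lambda = "numeric", weights = "list", mask = "matrix"))

setValidity("FCMModel", function(object) {
  msgs <- character()
  n <- length(object@concepts@names)
  if (!(object@order %in% 1:3)) msgs <- c(msgs, "order must be 1, 2 or 3")
  if (length(object@lambda) != 1L || !is.finite(object@lambda) ||
      object@lambda <= 0)
    msgs <- c(msgs, "lambda must be a single positive number")
  if (length(object@weights) != object@order)
    msgs <- c(msgs, "need one weight matrix per lag")
  if (!is.logical(object@mask) || !all(dim(object@mask) == c(n, n)))
    msgs <- c(msgs, "mask must be a logical n x n matrix")
  for (W in object@weights) {
    if (!is.numeric(W) || !all(dim(W) == c(n, n))) {
      msgs <- c(msgs, "each weight matrix must be numeric n x n")
      break
    }
    if (anyNA(W) || max(abs(W)) > 1 + 1e-12) {
      msgs <- c(msgs, "weights must be finite and within [-1, 1]")
      break
    }
    if (is.logical(object@mask) && all(dim(object@mask) == c(n, n)) &&
        any(W[!object@mask] != 0)) {
      msgs <- c(msgs, "masked-out entries must be exactly 0 at every lag")
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' DEConfig: differential-evolution settings
#'
#' Hyperparameters for the differential-evolution optimizer and the
#' multi-restart, multi-order model-selection protocol. F is the cross
#' factor scaling the donor difference vector; CR is the mutation rate of
#' the elementwise recombination.
#'
#' @slot popSize integer population size (>= 4).
#' @slot F cross factor in [0, 1].
#' @slot CR mutation rate in [0, 1].
#' @slot maxEpochs integer epoch cap (0 allowed: evaluate the random
#'   initial population only).
#' @slot convergenceTol stall threshold on best-loss improvement.
#' @slot stallWindow epochs without improvement beyond the tolerance that
#'   trigger early termination.
#' @slot seed integer master seed.
#' @slot nRestarts independent restarts per order.
#' @slot orders integer subset of {1, 2, 3} to try.
#' @slot mode prediction mode used inside the loss: \code{"teacher_forced"}
#'   or \code{"free_run"}.
#'
#' @seealso [deConfig()], [deEvolve()], [multiRestartFit()]
#' @exportClass DEConfig
setClass("DEConfig",
  representation(popSize = "integer", F = "numeric", CR = "numeric",
                 maxEpochs = "integer", convergenceTol = "numeric",
                 stallWindow = "integer", seed = "integer",
                 nRestarts = "integer", orders = "integer", mode = "character"))

setValidity("DEConfig", function(object) {
  msgs <- character()
  if (object@popSize < 4L)
    msgs <- c(msgs, "popSize must be >= 4 (target + 2 distinct donors)")
  if (object@F < 0 || object@F > 1) msgs <- c(msgs, "F must lie in [0, 1]")
  if (object@CR < 0 || object@CR > 1) msgs <- c(msgs, "CR must lie in [0, 1]")
  if (object@maxEpochs < 0L) msgs <- c(msgs, "maxEpochs must be >= 0")
  if (object@convergenceTol < 0) msgs <- c(msgs, "convergenceTol must be >= 0")
  if (object@stallWindow < 1L) msgs <- c(msgs, "stallWindow must be >= 1")
  if (object@nRestarts < 1L) msgs <- c(msgs, "nRestarts must be >= 1")
  if (length(object@orders) < 1L || !all(object@orders %in% 1:3))
    msgs <- c(msgs, "orders must be a non-empty subset of {1, 2, 3}")
  if (!object@mode %in% c("teacher_forced", "free_run"))
    msgs <- c(msgs, "mode must be 'teacher_forced' or 'free_run'")
  if (length(msgs)) msgs else TRUE
})

#' FitReport: result of a differential-evolution fit
#'
#' Holds the selected model, its training fitness, the per-(order, restart)
#' fitness table used for model selection, the best-loss-per-epoch trace of
#' the winning run, and (when a test split was supplied) per-concept and
#' overall mean absolute error.
#'
#' @slot bestModel the selected [FCMModel-class].
#' @slot bestFitness training loss of the selected model.
#' @slot fitnessTable data.frame with columns order, restart, fitness.
#' @slot history numeric vector, best loss per epoch of the winning run
#'   (non-increasing).
#' @slot testMAE list with \code{perConcept} (named numeric) and
#'   \code{overall} (scalar), or empty when no test data were scored.
#'
#' @seealso [multiRestartFit()], [evaluateMAE()]
#' @exportClass FitReport
setClass("FitReport",
  representation(bestModel = "FCMModel", bestFitness = "numeric",
                 fitnessTable = "data.frame", history = "numeric",
                 testMAE = "list"))

setValidity("FitReport", function(object) {
  msgs <- character()
  if (nrow(object@fitnessTable) &&
      abs(min(object@fitnessTable$fitness) - object@bestFitness) > 1e-9)
    msgs <- c(msgs, "bestFitness must equal the minimum of fitnessTable")
  if (length(object@history) > 1L && any(diff(object@history) > 1e-12))
    msgs <- c(msgs, "best-loss history must be non-increasing")
  if (length(msgs)) msgs else TRUE
})

#' SignedDigraph: thresholded signed influence graph
#'
#' The learned weight matrix collapsed over lags and sparsified at an
#' absolute-weight threshold epsilon; the substrate for simple-path
#' enumeration. Self-loops are excluded (a simple path cannot revisit its
#' start); self-weights remain available in the model object.
#'
#' @slot concepts the [ConceptSet-class] of the originating model.
#' @slot edges data.frame with columns source, target (labels) and weight
#'   (signed, |weight| >= epsilon).
#' @slot epsilon the inclusion threshold that produced the edge set.
#'
#' @seealso [thresholdGraph()], [enumerateSimplePaths()]
#' @exportClass SignedDigraph
setClass("SignedDigraph",
  representation(concepts = "ConceptSet", edges = "data.frame",
                 epsilon = "numeric"))

setValidity("SignedDigraph", function(object) {
  msgs <- character()
  e <- object@edges
  if (!all(c("source", "target", "weight") %in% names(e)))
    msgs <- c(msgs, "edges needs columns source, target, weight")
  else {
    if (anyDuplicated(e[, c("source", "target")]))
      msgs <- c(msgs, "duplicate (source, target) pairs are not allowed")
    if (nrow(e) && min(abs(e$weight)) < object@epsilon)
      msgs <- c(msgs, "all edges must satisfy |weight| >= epsilon")
    if (nrow(e) && any(e$source == e$target))
      msgs <- c(msgs, "self-loops are excluded from the path graph")
    known <- object@concepts@names
    if (nrow(e) && !all(c(e$source, e$target) %in% known))
      msgs <- c(msgs, "edge endpoints must be known concepts")
  }
  if (object@epsilon <= 0) msgs <- c(msgs, "epsilon must be > 0")
  if (length(msgs)) msgs else TRUE
})
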