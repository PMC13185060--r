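#' Create a TimeSeriesMatrix
#'
#' @param values numeric matrix, rows = days, columns = concepts; column
#'   names required.
#' @param timestamps Date vector of length \code{nrow(values)}; defaults to
#'   consecutive days starting 2019-01-01.
#' @param normParams optional list with per-column \code{min} and
#'   \code{max}; supply only for data already on the [0, 1] scale.
#'
#' @return a [TimeSeriesMatrix-class].
#' @export
timeSeriesMatrix <- function(values, timestamps = NULL, normParams = list()) {
  values <- as.matrix(values)
  if (is.null(timestamps))
    timestamps <- seq(as.Date("2019-01-01"), by = "day",
                      length.out = nrow(values))
  new("TimeSeriesMatrix", values = values, timestamps = as.Date(timestamps),
      normParams = normParams)
}

#' @describeIn timeSeriesMatrix the observation matrix.
#' @param x a TimeSeriesMatrix.
#' @export
tsValues <- function(x) x@values

#' @describeIn timeSeriesMatrix the date index.
#' @export
tsDates <- function(x) x@timestamps

#' @describeIn timeSeriesMatrix per-column normalization bounds (empty list
#'   when the data are on the raw scale).
#' @export
normParams <- function(x) x@normParams

#' @describeIn timeSeriesMatrix TRUE when min-max normalization metadata is
#'   attached.
#' @export
isNormalized <- function(x) length(x@normParams) > 0L

setMethod("show", "TimeSeriesMatrix", function(object) {
  cat("TimeSeriesMatrix:", nrow(object@values), "days x",
      ncol(object@values), "concepts,",
      if (isNormalized(object)) "normalized [0,1]" else "raw scale", "\n")
  cat("  dates:", format(object@timestamps[1]), "to",
      format(object@timestamps[length(object@timestamps)]), "\n")
})

#' Min-max normalize a time-series matrix
#'
#' Maps every column to [0, 1] via (x - min) / (max - min) and records the
#' per-column bounds so [denormalize()] can invert the transform. When
#' \code{params} is supplied (e.g. the training-set bounds applied to a
#' test split) those bounds are used instead of the column's own, and the
#' result is clipped to [0, 1].
#'
#' @param x a raw-scale [TimeSeriesMatrix-class] or plain numeric matrix.
#' @param params optional list with \code{min} and \code{max} vectors to
#'   reuse (training-set normalization applied to held-out data).
#'
#' @return a normalized [TimeSeriesMatrix-class].
#' @export
minMaxNormalize <- function(x, params = NULL) {
  tsm <- if (is(x, "TimeSeriesMatrix")) x else timeSeriesMatrix(x)
  if (isNormalized(tsm))
    stop("input is already normalized")
  v <- tsm@values
  if (is.null(params)) {
    mins <- apply(v, 2, min)
    maxs <- apply(v, 2, max)
    degenerate <- maxs - mins <= 0
    if (any(degenerate))
      stop("constant column(s) cannot be min-max normalized: ",
           paste(colnames(v)[degenerate], collapse = ", "))
  } else {
    mins <- params$min
    maxs <- params$max
  }
  scaled <- sweep(sweep(v, 2, mins, "-"), 2, maxs - mins, "/")
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  new("TimeSeriesMatrix", values = scaled, timestamps = tsm@timestamps,
      normParams = list(min = stats::setNames(as.numeric(mins), colnames(v)),
                        max = stats::setNames(as.numeric(maxs), colnames(v))))
}

#' Invert min-max normalization
#'
#' @param x a normalized [TimeSeriesMatrix-class].
#' @return a raw-scale [TimeSeriesMatrix-class]; recovers the original
#'   values to floating tolerance.
#' @export
denormalize <- function(x) {
  stopifnot(is(x, "TimeSeriesMatrix"))
  if (!isNormalized(x)) stop("input carries no normalization metadata")
  np <- x@normParams
  raw <- sweep(sweep(x@values, 2, np$max - np$min, "*"), 2, np$min, "+")
  new("TimeSeriesMatrix", values = raw, timestamps = x@timestamps,
      normParams = list())
}

#' Chronological train/test split
#'
#' The first \code{fraction} of the rows (chronological, no shuffling) form
#' the training set, the remainder the test set. When \code{normalize} is
#' TRUE both splits are min-max normalized with the training-set bounds.
#'
#' @param x a [TimeSeriesMatrix-class].
#' @param fraction training fraction in (0, 1); default 0.75.
#' @param normalize normalize both splits with training bounds.
#' @return list with elements \code{train} and \code{test}.
#' @export
trainTestSplit <- function(x, fraction = 0.75, normalize = TRUE) {
  stopifnot(is(x, "TimeSeriesMatrix"), fraction > 0, fraction < 1)
  Tn <- nrow(x@values)
  nTrain <- floor(fraction * Tn)
  if (nTrain < 2L || Tn - nTrain < 2L)
    stop("split leaves fewer than 2 rows in one partition")
  slice <- function(idx) new("TimeSeriesMatrix",
                             values = x@values[idx, , drop = FALSE],
                             timestamps = x@timestamps[idx],
                             normParams = x@normParams)
  train <- slice(seq_len(nTrain))
  test <- slice((nTrain + 1L):Tn)
  if (normalize && !isNormalized(x)) {
    train <- minMaxNormalize(train)
    test <- minMaxNormalize(test, params = train@normParams)
  }
  list(train = train, test = test)
}

#' Read a study data set from CSV plus a roles sidecar
#'
#' The CSV must have a \code{date} column (ISO-8601) and one column per
#' concept; the sidecar (YAML or JSON) maps each concept column to its role
#' (\code{environment} or \code{disease}). Missing values are rejected:
#' daily aggregation is expected to have produced complete series.
#'
#' @param csvPath path to the data CSV.
#' @param rolesPath path to the YAML/JSON sidecar.
#' @return list with \code{data} (raw [TimeSeriesMatrix-class]) and
#'   \code{concepts} ([ConceptSet-class]).
#' @export
readStudyData <- function(csvPath, rolesPath) {
  df <- utils::read.csv(csvPath, check.names = FALSE)
  if (!"date" %in% names(df)) stop("CSV must contain a 'date' column")
  dates <- as.Date(df$date)
  mat <- as.matrix(df[, setdiff(names(df), "date"), drop = FALSE])
  storage.mode(mat) <- "double"
  if (anyNA(mat))
    stop("missing values in data CSV; ingestion performs no imputation")
  roles <- if (grepl("\\.json$", rolesPath, ignore.case = TRUE))
    jsonlite::read_json(rolesPath, simplifyVector = TRUE)
  else yaml::read_yaml(rolesPath)
  roles <- unlist(roles)
  missing <- setdiff(colnames(mat), names(roles))
  if (length(missing))
    stop("no role given for column(s): ", paste(missing, collapse = ", "))
  cs <- conceptSet(colnames(mat), roles[colnames(mat)])
  list(data = timeSeriesMatrix(mat, dates), concepts = cs)
}

#' Write a study data set as CSV plus a roles sidecar
#'
#' @param data a raw-scale [TimeSeriesMatrix-class].
#' @param concepts the matching [ConceptSet-class].
#' @param csvPath,rolesPath output paths (roles written as YAML).
#' @return invisibly, the two paths.
#' @export
writeStudyData <- function(data, concepts, csvPath, rolesPath) {
  df <- data.frame(date = format(data@timestamps), data@values,
                   check.names = FALSE)
  utils::write.csv(df, csvPath, row.names = FALSE, quote = FALSE)
  roles <- as.list(stats::setNames(concepts@roles, concepts@names))
  yaml::write_yaml(roles, rolesPath)
  invisible(c(csvPath, rolesPath))
}
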