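#' Variance inflation factors for a set of columns
#'
#' For each selected column c, VIF_c = 1 / (1 - R^2_c) where R^2_c comes
#' from the ordinary least-squares regression (with intercept) of column c
#' on the other selected columns. Computed on the raw, pre-normalization
#' scale; VIF is invariant to affine rescaling of any column, so the
#' choice of scale is a convention, not a result. Exactly collinear
#' columns are flagged infinite rather than erroring.
#'
#' @param data a [TimeSeriesMatrix-class] or numeric matrix.
#' @param columns column names (or indices) to assess; default: all
#'   columns. For study data the conventional choice is the environment
#'   columns only.
#' @return data.frame with columns \code{variable} and \code{vif}
#'   (\code{Inf} for exact collinearity); finite entries are >= 1.
#' @export
computeVIF <- function(data, columns = NULL) {
  X <- if (is(data, "TimeSeriesMatrix")) data@values else as.matrix(data)
  if (!is.null(columns)) X <- X[, columns, drop = FALSE]
  p <- ncol(X)
  if (p < 3L) stop("VIF needs at least 3 columns")
  if (nrow(X) <= p)
    stop("underdetermined: need more rows than columns")
  vif <- vapply(seq_len(p), function(j) {
    fit <- stats::lm(X[, j] ~ X[, -j, drop = FALSE])
    # an exactly collinear column yields a perfect fit; the warning from
    # summary.lm is expected there, and the VIF is reported as Inf
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(variable = colnames(X), vif = vif, stringsAsFactors = FALSE)
}

#' Tabulate fit reports for export
#'
#' A pure formatter: one row per study model echoing the values already in
#' each [FitReport-class] (order chosen, best training fitness, overall
#' test MAE); nothing is recomputed, so identical reports give
#' byte-identical output.
#'
#' @param reports named list of [FitReport-class] objects (names = model
#'   identifiers, e.g. the disease or "overall").
#' @return data.frame with columns model, order, bestFitness, testMAE
#'   (NA when no test data were scored), ordered by model identifier.
#' @export
fitSummary <- function(reports) {
  stopifnot(length(reports) >= 1L)
  ids <- names(reports)
  if (is.null(ids)) ids <- as.character(seq_along(reports))
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(model = ids[i], order = r@bestModel@order,
               bestFitness = r@bestFitness,
               testMAE = if (length(r@testMAE)) r@testMAE$overall else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$model), , drop = FALSE]
  rownames(out) <- NULL
  out
}
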