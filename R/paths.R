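#' Collapse a model's lag matrices and threshold into a signed digraph
#'
#' A learned weight matrix is dense, which would make every ordered pair
#' connected and every path count identical; screening therefore works on
#' a sparsified graph. The per-lag weights are first collapsed into a
#' single n x n matrix -- by default taking, for each (source, target)
#' pair, the lag weight of maximal absolute value (alternatively their
#' sum) -- and an edge is kept when its absolute collapsed weight reaches
#' \code{epsilon}. Self-loops are excluded: a simple path cannot revisit
#' its start node.
#'
#' @param model an [FCMModel-class].
#' @param epsilon positive inclusion threshold on |weight|; default 0.05.
#' @param collapse \code{"maxabs"} (default) or \code{"sum"}.
#' @return a [SignedDigraph-class].
#' @export
thresholdGraph <- function(model, epsilon = 0.05,
                           collapse = c("maxabs", "sum")) {
  collapse <- match.arg(collapse)
  stopifnot(is(model, "FCMModel"), epsilon > 0)
  W <- collapseLags(model, collapse)
  diag(W) <- 0
  keep <- which(abs(W) >= epsilon, arr.ind = TRUE)
  labs <- model@concepts@names
  edges <- data.frame(source = labs[keep[, 1]], target = labs[keep[, 2]],
                      weight = W[keep], stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) == 0L)
    warning("no edge reaches |weight| >= ", epsilon,
            "; the graph is empty")
  new("SignedDigraph", concepts = model@concepts, edges = edges,
      epsilon = epsilon)
}

#' @describeIn thresholdGraph collapse the per-lag matrices to one signed
#'   n x n matrix without thresholding.
#' @export
collapseLags <- function(model, collapse = c("maxabs", "sum")) {
  collapse <- match.arg(collapse)
  if (collapse == "sum") return(Reduce(`+`, model@weights))
  W <- model@weights[[1]]
  if (model@order > 1L)
    for (l in 2:model@order) {
      Wl <- model@weights[[l]]
      swap <- abs(Wl) > abs(W)
      W[swap] <- Wl[swap]
    }
  W
}

#' @describeIn thresholdGraph edge table accessor.
#' @param graph a SignedDigraph.
#' @export
graphEdges <- function(graph) graph@edges

setMethod("show", "SignedDigraph", function(object) {
  cat("SignedDigraph:", length(object@concepts@names), "nodes,",
      nrow(object@edges), "edges (|weight| >=", object@epsilon, ")\n")
})

# igraph view of a SignedDigraph; isolated concepts are kept as vertices.
.asIgraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph@edges, directed = TRUE,
    vertices = data.frame(name = graph@concepts@names,
                          role = graph@concepts@roles))
}

#' Enumerate simple directed paths between two concepts
#'
#' Returns every simple path (no repeated node) from \code{source} to
#' \code{target} with at most \code{maxLen} edges, together with its
#' weight: the product of the traversed edge weights, so sign semantics
#' compose along the path.
#'
#' @param graph a [SignedDigraph-class].
#' @param source,target distinct concept labels.
#' @param maxLen maximum number of edges per path; default 4. Unbounded
#'   enumeration is factorial in the node count, so the cap is always
#'   reported alongside results.
#' @return data.frame with columns \code{path} (node labels joined by
#'   \code{"->"}), \code{length} (edges) and \code{weight}.
#' @export
enumerateSimplePaths <- function(graph, source, target, maxLen = 4L) {
  stopifnot(is(graph, "SignedDigraph"), maxLen >= 1L)
  if (source == target) stop("source and target must differ")
  known <- graph@concepts@names
  if (!source %in% known || !target %in% known)
    stop("unknown node: ", setdiff(c(source, target), known)[1])
  g <- .asIgraph(graph)
  paths <- igraph::all_simple_paths(g, from = source, to = target,
                                    mode = "out", cutoff = maxLen)
  wlookup <- stats::setNames(graph@edges$weight,
                             paste(graph@edges$source, graph@edges$target,
                                   sep = "\r"))
  rows <- lapply(paths, function(p) {
    nodes <- names(p)
    w <- prod(wlookup[paste(nodes[-length(nodes)], nodes[-1], sep = "\r")])
    data.frame(path = paste(nodes, collapse = "->"),
               length = length(nodes) - 1L, weight = w,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(), length = integer(), weight = numeric())
  out <- out[order(out$path), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simple-path metrics for one ordered concept pair
#'
#' The two screening statistics for (source, target): the number of simple
#' paths and the signed sum of their weights (each path's weight being the
#' product of its edge weights).
#'
#' @inheritParams enumerateSimplePaths
#' @return list with \code{source}, \code{target}, \code{nPaths},
#'   \code{weightSum} and \code{weights} (per-path vector).
#' @export
pairMetrics <- function(graph, source, target, maxLen = 4L) {
  paths <- enumerateSimplePaths(graph, source, target, maxLen)
  list(source = source, target = target, nPaths = nrow(paths),
       weightSum = sum(paths$weight), weights = paths$weight)
}

#' Environment-factor x disease simple-path tables
#'
#' For every (environment factor, disease) pair, the signed sum of
#' simple-path weights and the number of simple paths from the factor to
#' the disease. The \code{"absMean"} row of the weight table is the mean
#' of |cell| over the environment factors, the per-disease summary used to
#' rank how markedly each disease is influenced.
#'
#' @param model a fitted [FCMModel-class] covering >= 1 disease.
#' @param epsilon edge-inclusion threshold (see [thresholdGraph()]).
#' @param maxLen maximum path length in edges.
#' @param collapse lag-collapse rule.
#' @return list with matrices \code{weights} (factors x diseases),
#'   \code{counts}, numeric vectors \code{absMean} and \code{meanCount}
#'   (per disease), and the \code{settings} used.
#' @export
factorDiseaseTable <- function(model, epsilon = 0.05, maxLen = 4L,
                               collapse = "maxabs") {
  graph <- thresholdGraph(model, epsilon, collapse)
  facs <- environmentConcepts(model)
  dis <- diseaseConcepts(model)
  if (length(dis) < 1L) stop("model covers no disease concept")
  weights <- matrix(0, length(facs), length(dis), dimnames = list(facs, dis))
  counts <- matrix(0L, length(facs), length(dis), dimnames = list(facs, dis))
  for (f in facs) for (d in dis) {
    pm <- pairMetrics(graph, f, d, maxLen)
    weights[f, d] <- pm$weightSum
    counts[f, d] <- pm$nPaths
  }
  list(weights = weights, counts = counts,
       absMean = colMeans(abs(weights)),
       meanCount = colMeans(counts),
       settings = list(epsilon = epsilon, maxLen = maxLen,
                       collapse = collapse))
}

#' Disease-disease simple-path count and weight tables
#'
#' For every ordered pair of distinct diseases in an overall model, the
#' number of simple paths and the signed sum of simple-path weights.
#' Environment nodes may serve as intermediates (configurable), which is
#' why the tables need not be symmetric even for symmetric direct weights.
#' Diagonals are reported as 0.
#'
#' @inheritParams factorDiseaseTable
#' @param diseaseOnlyIntermediates restrict path interiors to disease
#'   nodes; default FALSE.
#' @return list with integer matrix \code{counts}, numeric matrix
#'   \code{weights} (both diseases x diseases, zero diagonal) and
#'   \code{settings}.
#' @export
diseaseDiseaseTables <- function(model, epsilon = 0.05, maxLen = 4L,
                                 collapse = "maxabs",
                                 diseaseOnlyIntermediates = FALSE) {
  dis <- diseaseConcepts(model)
  if (length(dis) < 2L)
    stop("disease-disease tables need >= 2 diseases; ",
         "use the overall model, not a singular one")
  graph <- thresholdGraph(model, epsilon, collapse)
  if (diseaseOnlyIntermediates) {
    e <- graph@edges
    keep <- e$source %in% dis & e$target %in% dis
    graph@edges <- e[keep, , drop = FALSE]
  }
  counts <- matrix(0L, length(dis), length(dis), dimnames = list(dis, dis))
  weights <- matrix(0, length(dis), length(dis), dimnames = list(dis, dis))
  for (d1 in dis) for (d2 in dis) {
    if (d1 == d2) next
    pm <- pairMetrics(graph, d1, d2, maxLen)
    counts[d1, d2] <- pm$nPaths
    weights[d1, d2] <- pm$weightSum
  }
  list(counts = counts, weights = weights,
       settings = list(epsilon = epsilon, maxLen = maxLen,
                       collapse = collapse,
                       diseaseOnlyIntermediates = diseaseOnlyIntermediates))
}

#' Top-k comprehensive screening across singular and overall studies
#'
#' Ranks diseases within each study by (a) the mean number of simple paths
#' from the environment factors and (b) the absolute mean of simple-path
#' weights, keeps the Top-k of each ranking, and synthesizes a prioritized
#' association list: a disease is retained when it appears in any Top-k
#' list, and its associated environment factors are ordered by absolute
#' path-weight sum (singular-study weights, falling back to the overall
#' study when a disease only qualified there). Ties are broken by the
#' stable rule (metric descending, label ascending).
#'
#' @param singularTables named list (one per disease) of
#'   [factorDiseaseTable()] results from the singular models; each table
#'   carries that model's single disease column.
#' @param overallTable [factorDiseaseTable()] result from the overall model.
#' @param k list length per ranking; clamped to the number of diseases
#'   with a warning when larger.
#' @return list with \code{topByCount} and \code{topByWeight} (each with
#'   \code{singular} and \code{overall} data.frames) and
#'   \code{associations} (data.frame factor, disease, direction, weight).
#' @export
screenTopK <- function(singularTables, overallTable, k = 5L) {
  singDiseases <- names(singularTables)
  overDiseases <- colnames(overallTable$weights)
  if (!setequal(singDiseases, overDiseases))
    stop("singular and overall studies must cover the same diseases")
  kEff <- as.integer(min(k, length(singDiseases)))
  if (kEff < k) warning("k clamped to the number of diseases (", kEff, ")")

  rankTop <- function(metric) {
    ord <- order(-metric, names(metric))
    data.frame(disease = names(metric)[ord][seq_len(kEff)],
               value = unname(metric[ord][seq_len(kEff)]),
               stringsAsFactors = FALSE)
  }
  singCount <- vapply(singularTables, function(tb) tb$meanCount[[1]],
                      numeric(1))
  singWeight <- vapply(singularTables, function(tb) tb$absMean[[1]],
                       numeric(1))
  overCount <- overallTable$meanCount
  overWeight <- overallTable$absMean

  tops <- list(
    topByCount = list(singular = rankTop(singCount),
                      overall = rankTop(overCount)),
    topByWeight = list(singular = rankTop(singWeight),
                       overall = rankTop(overWeight)))

  retained <- sort(unique(c(tops$topByCount$singular$disease,
                            tops$topByCount$overall$disease,
                            tops$topByWeight$singular$disease,
                            tops$topByWeight$overall$disease)))
  assoc <- do.call(rbind, lapply(retained, function(d) {
    w <- singularTables[[d]]$weights[, 1]
    ord <- order(-abs(w), names(w))
    data.frame(disease = d, factor = names(w)[ord],
               direction = ifelse(w[ord] >= 0, "positive", "negative"),
               weight = unname(w[ord]), stringsAsFactors = FALSE)
  }))
  rownames(assoc) <- NULL
  c(tops, list(associations = assoc, k = kEff))
}

#' Export a signed digraph to GraphML or DOT
#'
#' Writes the graph with the signed weight as an edge attribute and the
#' concept role as a node attribute, for rendering in external tools.
#'
#' @param graph a [SignedDigraph-class].
#' @param path output file.
#' @param format \code{"graphml"} or \code{"dot"}.
#' @return invisibly, \code{path}.
#' @export
exportGraph <- function(graph, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(.asIgraph(graph), path, format = format)
  invisible(path)
}
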