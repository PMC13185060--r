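#' Create a ConceptSet
#'
#' @param names character vector of unique concept labels.
#' @param roles character vector of the same length, each
#'   \code{"environment"} or \code{"disease"}.
#'
#' @return a [ConceptSet-class].
#' @examples
#' cs <- conceptSet(c("PM2.5", "PM10", "cataract"),
#'                  c("environment", "environment", "disease"))
#' conceptNames(cs)
#' @export
conceptSet <- function(names, roles) {
  new("ConceptSet", names = as.character(names), roles = as.character(roles))
}

#' @describeIn conceptSet concept labels, in storage order.
#' @param x a ConceptSet (or object carrying one).
#' @export
conceptNames <- function(x) {
  if (is(x, "FCMModel")) x <- x@concepts
  x@names
}

#' @describeIn conceptSet per-concept roles, in storage order.
#' @export
conceptRoles <- function(x) {
  if (is(x, "FCMModel")) x <- x@concepts
  stats::setNames(x@roles, x@names)
}

#' @describeIn conceptSet number of concepts.
#' @export
nConcepts <- function(x) {
  if (is(x, "FCMModel")) x <- x@concepts
  length(x@names)
}

#' @describeIn conceptSet labels of the environment concepts.
#' @export
environmentConcepts <- function(x) {
  if (is(x, "FCMModel")) x <- x@concepts
  x@names[x@roles == "environment"]
}

#' @describeIn conceptSet labels of the disease concepts.
#' @export
diseaseConcepts <- function(x) {
  if (is(x, "FCMModel")) x <- x@concepts
  x@names[x@roles == "disease"]
}

setMethod("show", "ConceptSet", function(object) {
  cat("ConceptSet with", length(object@names), "concepts (",
      sum(object@roles == "environment"), "environment,",
      sum(object@roles == "disease"), "disease )\n")
  cat("  ", paste0(object@names, " [", substr(object@roles, 1, 3), "]",
                   collapse = ", "), "\n")
})

#' Build the learnable-edge mask for a concept set
#'
#' Disease incidence is not allowed to feed back on environmental factors:
#' every (source = disease, target = environment) entry is frozen at zero
#' during optimization. All other directed influences -- environment to
#' environment, environment to disease, disease to disease, and self-loops
#' -- are learnable.
#'
#' @param concepts a [ConceptSet-class].
#' @return logical n x n matrix, \code{TRUE} = learnable; rows index the
#'   source concept, columns the target.
#' @examples
#' cs <- conceptSet(c("PM10", "ON"), c("environment", "disease"))
#' buildMask(cs)
#' @export
buildMask <- function(concepts) {
  stopifnot(is(concepts, "ConceptSet"))
  n <- length(concepts@names)
  m <- matrix(TRUE, n, n, dimnames = list(concepts@names, concepts@names))
  m[concepts@roles == "disease", concepts@roles == "environment"] <- FALSE
  m
}
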