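#' Configuration of a full screening study
#'
#' Bundles everything [runStudy()] needs: the data CSV + roles sidecar,
#' the optimizer settings, the path-analysis settings, the output
#' directory and the master seed from which every model's randomness is
#' derived.
#'
#' @param dataPath path to the data CSV (date column + concept columns).
#' @param rolesPath path to the YAML/JSON roles sidecar.
#' @param de a [DEConfig-class]; its seed field is ignored in favour of
#'   \code{seed}.
#' @param epsilon edge-inclusion threshold for the path graph.
#' @param maxLen maximum simple-path length in edges.
#' @param collapse lag-collapse rule for higher-order models.
#' @param outDir output directory for all artifacts.
#' @param seed master seed for the whole study.
#' @param models which models to run: \code{"singular"} (one model per
#'   disease), \code{"overall"}, or both (default). Screening requires
#'   both.
#' @param diseases optional subset of disease labels for the singular
#'   models; default: all.
#' @param splitFraction chronological training fraction (default 0.75).
#' @param topK screening list length.
#' @return a StudyConfig (classed list).
#' @export
studyConfig <- function(dataPath, rolesPath, de = deConfig(),
                        epsilon = 0.05, maxLen = 4L, collapse = "maxabs",
                        outDir = tempfile("study"), seed = 1L,
                        models = c("singular", "overall"),
                        diseases = NULL, splitFraction = 0.75, topK = 5L) {
  stopifnot(file.exists(dataPath), file.exists(rolesPath),
            is(de, "DEConfig"), epsilon > 0, maxLen >= 1)
  structure(list(dataPath = dataPath, rolesPath = rolesPath, de = de,
                 epsilon = epsilon, maxLen = as.integer(maxLen),
                 collapse = collapse, outDir = outDir,
                 seed = as.integer(seed),
                 models = match.arg(models, several.ok = TRUE),
                 diseases = diseases,
                 splitFraction = splitFraction, topK = as.integer(topK)),
            class = "StudyConfig")
}

# Per-model seed derived from the study master seed.
.modelSeed <- function(seed, idx) {
  as.integer((abs(as.numeric(seed)) * 7919 + idx * 33301 + 17) %% 2147483647)
}

# Load, validate and split the study data once.
.loadStudy <- function(config) {
  study <- readStudyData(config$dataPath, config$rolesPath)
  v <- study$data@values
  constant <- apply(v, 2, function(x) max(x) == min(x))
  if (any(constant))
    stop("pre-flight validation failed: constant column(s): ",
         paste(colnames(v)[constant], collapse = ", "))
  dis <- diseaseConcepts(study$concepts)
  if ("singular" %in% config$models || "overall" %in% config$models) {
    want <- config$diseases %||% dis
    unknown <- setdiff(want, dis)
    if (length(unknown))
      stop("unknown disease label(s): ", paste(unknown, collapse = ", "),
           "; available: ", paste(dis, collapse = ", "))
  }
  split <- trainTestSplit(study$data, config$splitFraction)
  c(study, split = list(split))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Column subset of a normalized TimeSeriesMatrix (min-max normalization is
# per-column, so subsetting commutes with normalizing).
.subsetTSM <- function(x, cols) {
  np <- x@normParams
  new("TimeSeriesMatrix", values = x@values[, cols, drop = FALSE],
      timestamps = x@timestamps,
      normParams = if (length(np))
        list(min = np$min[cols], max = np$max[cols]) else list())
}

# Fit one study model over the given concept subset.
.fitStudyModel <- function(loaded, config, cols, roles, idx) {
  cs <- conceptSet(cols, roles)
  de <- config$de
  de@seed <- .modelSeed(config$seed, idx)
  multiRestartFit(.subsetTSM(loaded$split$train, cols), cs, de,
                  testData = .subsetTSM(loaded$split$test, cols))
}

#' Fit a singular model (all environment factors + one disease)
#'
#' @param config a [studyConfig()].
#' @param disease disease column label.
#' @return list with \code{report} ([FitReport-class]) and \code{table}
#'   (the [factorDiseaseTable()] for the model's single disease).
#' @export
runSingular <- function(config, disease) {
  loaded <- .loadStudy(config)
  dis <- diseaseConcepts(loaded$concepts)
  if (!disease %in% dis)
    stop("unknown disease label '", disease, "'; available: ",
         paste(dis, collapse = ", "))
  env <- environmentConcepts(loaded$concepts)
  idx <- match(disease, dis)
  report <- .fitStudyModel(loaded, config, c(env, disease),
                           c(rep("environment", length(env)), "disease"),
                           idx)
  list(report = report,
       table = factorDiseaseTable(report@bestModel, config$epsilon,
                                  config$maxLen, config$collapse))
}

#' Fit the overall model (all environment factors + all diseases)
#'
#' @param config a [studyConfig()].
#' @return list with \code{report}, \code{table}
#'   ([factorDiseaseTable()]) and \code{ddTables}
#'   ([diseaseDiseaseTables()]).
#' @export
runOverall <- function(config) {
  loaded <- .loadStudy(config)
  cs <- loaded$concepts
  report <- .fitStudyModel(loaded, config, conceptNames(cs),
                           conceptRoles(cs), 0L)
  list(report = report,
       table = factorDiseaseTable(report@bestModel, config$epsilon,
                                  config$maxLen, config$collapse),
       ddTables = diseaseDiseaseTables(report@bestModel, config$epsilon,
                                       config$maxLen, config$collapse))
}

.writeTable <- function(mat, path) {
  df <- data.frame(rowname = rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full screening study
#'
#' Executes the requested models (one singular model per disease and/or
#' the overall model), runs the Top-k screening when both studies are
#' available, computes diagnostics, and writes every artifact under
#' \code{config$outDir}:
#' \itemize{
#'   \item \code{models/} -- one JSON per fitted model (with provenance);
#'   \item \code{tables/} -- factor x disease weight and count tables
#'     (singular and overall), disease-disease count and weight tables,
#'     fitness and MAE tables, VIF table;
#'   \item \code{graphs/} -- GraphML and DOT exports of the thresholded
#'     overall graph;
#'   \item \code{screening.json} -- Top-k lists and prioritized
#'     associations;
#'   \item \code{manifest.json} -- seed and full settings; re-running with
#'     the same manifest settings reproduces every artifact byte for byte.
#' }
#'
#' All randomness derives from \code{config$seed}; no wall-clock
#' information enters any artifact.
#'
#' @param config a [studyConfig()].
#' @return invisibly, a list with reports, tables, screening and the
#'   manifest.
#' @export
runStudy <- function(config) {
  loaded <- .loadStudy(config)
  cs <- loaded$concepts
  env <- environmentConcepts(cs)
  dis <- config$diseases %||% diseaseConcepts(cs)
  out <- config$outDir
  for (d in c("models", "tables", "graphs"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)

  reports <- list()
  singularTables <- list()
  if ("singular" %in% config$models) {
    for (i in seq_along(dis)) {
      d <- dis[i]
      report <- .fitStudyModel(loaded, config, c(env, d),
                               c(rep("environment", length(env)),
                                 "disease"), i)
      reports[[d]] <- report
      singularTables[[d]] <- factorDiseaseTable(
        report@bestModel, config$epsilon, config$maxLen, config$collapse)
      writeFCMModel(report@bestModel,
                    file.path(out, "models", paste0("singular_", d, ".json")),
                    provenance = list(model = paste0("singular:", d),
                                      seed = .modelSeed(config$seed, i),
                                      fitness = report@bestFitness))
    }
    t1w <- do.call(cbind, lapply(singularTables, function(tb) tb$weights))
    colnames(t1w) <- names(singularTables)
    t1 <- rbind(t1w, `Absolute mean` =
                  vapply(singularTables, function(tb) tb$absMean[[1]],
                         numeric(1)))
    .writeTable(t1, file.path(out, "tables", "singular_factor_disease_weights.csv"))
    t1c <- do.call(cbind, lapply(singularTables, function(tb) tb$counts))
    colnames(t1c) <- names(singularTables)
    .writeTable(t1c, file.path(out, "tables", "singular_factor_disease_counts.csv"))
  }

  overall <- NULL
  if ("overall" %in% config$models) {
    report <- .fitStudyModel(loaded, config, conceptNames(cs),
                             conceptRoles(cs), 0L)
    reports[["overall"]] <- report
    overall <- list(
      table = factorDiseaseTable(report@bestModel, config$epsilon,
                                 config$maxLen, config$collapse),
      ddTables = diseaseDiseaseTables(report@bestModel, config$epsilon,
                                      config$maxLen, config$collapse))
    writeFCMModel(report@bestModel,
                  file.path(out, "models", "overall.json"),
                  provenance = list(model = "overall",
                                    seed = .modelSeed(config$seed, 0L),
                                    fitness = report@bestFitness))
    t2 <- rbind(overall$table$weights,
                `Absolute mean` = overall$table$absMean)
    .writeTable(t2, file.path(out, "tables", "overall_factor_disease_weights.csv"))
    .writeTable(overall$ddTables$counts,
                file.path(out, "tables", "disease_disease_counts.csv"))
    .writeTable(overall$ddTables$weights,
                file.path(out, "tables", "disease_disease_weights.csv"))
    graph <- thresholdGraph(report@bestModel, config$epsilon,
                            config$collapse)
    exportGraph(graph, file.path(out, "graphs", "overall.graphml"),
                "graphml")
    exportGraph(graph, file.path(out, "graphs", "overall.dot"), "dot")
  }

  screening <- NULL
  if (length(singularTables) >= 2L && !is.null(overall)) {
    screening <- screenTopK(singularTables, overall$table, config$topK)
    jsonlite::write_json(screening, file.path(out, "screening.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }

  vif <- computeVIF(loaded$data, env)
  utils::write.csv(vif, file.path(out, "tables", "vif.csv"),
                   row.names = FALSE, quote = FALSE)
  fits <- fitSummary(reports)
  utils::write.csv(fits, file.path(out, "tables", "fitness_mae.csv"),
                   row.names = FALSE, quote = FALSE)
  maeRows <- do.call(rbind, lapply(names(reports), function(id) {
    pc <- reports[[id]]@testMAE$perConcept
    data.frame(model = id, concept = names(pc), mae = unname(pc),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(maeRows, file.path(out, "tables", "mae_per_concept.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest <- list(
    seed = config$seed,
    dataPath = config$dataPath,
    rolesPath = config$rolesPath,
    models = config$models,
    diseases = dis,
    splitFraction = config$splitFraction,
    pathSettings = list(epsilon = config$epsilon, maxLen = config$maxLen,
                        collapse = config$collapse, topK = config$topK),
    de = list(popSize = config$de@popSize, F = config$de@F,
              CR = config$de@CR, maxEpochs = config$de@maxEpochs,
              convergenceTol = config$de@convergenceTol,
              stallWindow = config$de@stallWindow,
              nRestarts = config$de@nRestarts,
              orders = config$de@orders, mode = config$de@mode),
    package = list(name = "fcmscreen",
                   version = as.character(utils::packageVersion("fcmscreen"))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(reports = reports, singularTables = singularTables,
                 overall = overall, screening = screening, vif = vif,
                 fitSummary = fits, manifest = manifest, outDir = out))
}
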