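#' Describe a synthetic environmental-factor panel
#'
#' Each factor is a daily series: baseline + seasonal sine (period 365.25
#' days) + Gaussian noise. Collinear factors (PM10 tracking PM2.5;
#' min/max temperature, dew point and humidity tracking temperature) are
#' generated as correlated mixtures of their parent: the child is a linear
#' blend of the parent's z-scores with independent noise, so the sample
#' correlation concentrates on the requested value.
#'
#' @param nDays number of days (>= 100).
#' @param factors data.frame with columns name, baseline, amplitude,
#'   phase (days), noiseSD.
#' @param collinearity data.frame with columns parent, child, correlation
#'   in (-1, 1); child rows in \code{factors} supply the child's location
#'   and scale.
#' @return an EnvProfile (classed list).
#' @export
envProfile <- function(nDays, factors, collinearity = NULL) {
  stopifnot(nDays >= 100,
            all(c("name", "baseline", "amplitude", "phase", "noiseSD")
                %in% names(factors)))
  if (is.null(collinearity))
    collinearity <- data.frame(parent = character(), child = character(),
                               correlation = numeric())
  stopifnot(all(abs(collinearity$correlation) < 1),
            all(collinearity$parent %in% factors$name),
            all(collinearity$child %in% factors$name))
  structure(list(nDays = as.integer(nDays), factors = factors,
                 collinearity = collinearity), class = "EnvProfile")
}

#' Generate a synthetic environmental panel
#'
#' @param profile an [envProfile()].
#' @param seed integer seed; the same seed reproduces the same panel.
#' @param startDate first day of the panel.
#' @return a raw-scale [TimeSeriesMatrix-class], one column per factor.
#' @export
generateEnvironment <- function(profile, seed,
                                startDate = as.Date("2019-01-01")) {
  stopifnot(inherits(profile, "EnvProfile"))
  nd <- profile$nDays
  fs <- profile$factors
  withr::with_seed(as.integer(seed), {
    t <- seq_len(nd)
    mat <- sapply(seq_len(nrow(fs)), function(i) {
      fs$baseline[i] +
        fs$amplitude[i] * sin(2 * pi * (t + fs$phase[i]) / 365.25) +
        stats::rnorm(nd, 0, fs$noiseSD[i])
    })
    colnames(mat) <- fs$name
    # overwrite child factors with correlated mixtures of their parents
    for (i in seq_len(nrow(profile$collinearity))) {
      co <- profile$collinearity[i, ]
      parent <- mat[, co$parent]
      zp <- (parent - mean(parent)) / stats::sd(parent)
      z <- co$correlation * zp +
        sqrt(1 - co$correlation^2) * stats::rnorm(nd)
      row <- fs[fs$name == co$child, ]
      sdChild <- sqrt(row$amplitude^2 / 2 + row$noiseSD^2)
      mat[, co$child] <- row$baseline + sdChild * z
    }
  })
  timeSeriesMatrix(mat, seq(startDate, by = "day", length.out = nd))
}

#' Ground truth for synthetic admissions
#'
#' @param model an [FCMModel-class] over environment + disease concepts;
#'   its mask must forbid disease-to-environment edges.
#' @param baseRates named positive vector, mean daily admissions per
#'   disease at a neutral (0.5) latent activation.
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson; \code{Inf} = exactly Poisson); default 5.
#' @return a GroundTruth (classed list).
#' @export
groundTruth <- function(model, baseRates, dispersion = 5) {
  stopifnot(is(model, "FCMModel"), all(baseRates >= 0))
  dis <- diseaseConcepts(model)
  stopifnot(setequal(names(baseRates), dis))
  bad <- model@mask[model@concepts@roles == "disease",
                    model@concepts@roles == "environment"]
  if (any(bad))
    stop("ground-truth mask must forbid disease-to-environment edges")
  structure(list(model = model, baseRates = baseRates[dis],
                 dispersion = dispersion), class = "GroundTruth")
}

#' Generate daily admission counts from a ground-truth FCM
#'
#' The environment panel is min-max normalized and drives the ground-truth
#' model's disease concepts: disease latents start at 0.5 and evolve by
#' the sigmoid transition on the joint (environment, disease) state, so
#' disease-disease influences are honoured. The latent activation is
#' mapped linearly to a mean daily rate, mu_d(t) = baseRate_d *
#' latent_d(t) / 0.5, and counts are drawn negative-binomial with the
#' stated dispersion. Small base rates naturally yield many zero-count
#' days, mimicking rare conditions.
#'
#' @param env raw-scale environment [TimeSeriesMatrix-class]; its columns
#'   must be exactly the ground truth's environment concepts.
#' @param truth a [groundTruth()].
#' @param seed integer seed.
#' @return [TimeSeriesMatrix-class] of non-negative integer counts, one
#'   column per disease.
#' @export
generateAdmissions <- function(env, truth, seed) {
  stopifnot(inherits(truth, "GroundTruth"))
  model <- truth$model
  envNames <- environmentConcepts(model)
  dis <- diseaseConcepts(model)
  X <- env@values
  if (!identical(colnames(X), envNames))
    stop("environment columns must match the ground truth's ",
         "environment concepts in order")
  Xn <- minMaxNormalize(env)@values
  k <- model@order
  Tn <- nrow(Xn)
  labs <- model@concepts@names
  U <- matrix(0.5, Tn, length(labs), dimnames = list(NULL, labs))
  U[, envNames] <- Xn
  for (t in (k + 1L):Tn) {
    z <- 0
    for (l in seq_len(k)) z <- z + U[t - l, ] %*% model@weights[[l]]
    U[t, dis] <- sigmoidTransfer(drop(z), model@lambda)[dis]
  }
  mu <- sweep(U[, dis, drop = FALSE] / 0.5, 2, truth$baseRates, "*")
  withr::with_seed(as.integer(seed), {
    counts <- if (is.infinite(truth$dispersion))
      stats::rpois(length(mu), lambda = mu)
    else
      stats::rnbinom(length(mu), size = truth$dispersion, mu = mu)
  })
  counts <- matrix(counts, nrow = Tn, dimnames = list(NULL, dis))
  timeSeriesMatrix(counts, env@timestamps)
}

# Fixed study-shaped fixtures. `tiny` is a 4-factor, 2-disease, 300-day
# panel for fast end-to-end runs; `paper_like` mirrors the full study
# shape: 6 pollutants + 9 meteorological factors, 10 diseases, daily from
# 2019-01-01 to 2024-06-30, with strong PM2.5-PM10 and temperature-family
# collinearity and base rates graded over two orders of magnitude.
.fixtureSpec <- function(scale) {
  if (scale == "tiny") {
    factors <- data.frame(
      name = c("PM2.5", "PM10", "temperature", "wind_speed"),
      baseline = c(50, 70, 16, 3),
      amplitude = c(20, 25, 10, 1),
      phase = c(0, 0, 90, 180),
      noiseSD = c(8, 10, 2.5, 0.8))
    collinearity <- data.frame(parent = "PM2.5", child = "PM10",
                               correlation = 0.9)
    diseases <- c("D1", "D2")
    baseRates <- c(D1 = 20, D2 = 6)
    dispersion <- 20
    nDays <- 300L
    # negative self-loops keep the disease activations inside the
    # sigmoid's sensitive range so the environmental signal is not
    # squashed; self-loops never enter simple paths, so the injected
    # temperature -> D1 effect stays the only env -> D1 influence
    edges <- list(c("temperature", "D1", 0.8),
                  c("D1", "D1", -0.6),
                  c("wind_speed", "D2", -0.6),
                  c("D1", "D2", 0.3),
                  c("D2", "D2", -0.3))
  } else {
    factors <- data.frame(
      name = c("PM2.5", "PM10", "SO2", "CO", "NO2", "O3",
               "temperature", "atmospheric_pressure", "humidity",
               "wind_speed", "min_temperature", "max_temperature",
               "visibility", "dew_point", "precipitation"),
      baseline = c(50, 70, 10, 0.9, 35, 80,
                   17, 1013, 75, 3, 13, 22, 12, 11, 4),
      amplitude = c(20, 25, 4, 0.3, 10, 35,
                    11, 8, 8, 1, 11, 11, 3, 10, 3),
      phase = c(0, 0, 0, 0, 0, 180,
                90, 270, 120, 180, 90, 90, 30, 90, 120),
      noiseSD = c(8, 10, 2, 0.15, 6, 15,
                  2.5, 3, 8, 0.8, 2.5, 2.5, 3, 3, 4))
    collinearity <- data.frame(
      parent = c("PM2.5", "temperature", "temperature", "temperature",
                 "temperature"),
      child = c("PM10", "min_temperature", "max_temperature", "dew_point",
                "humidity"),
      correlation = c(0.9, 0.97, 0.97, 0.9, 0.5))
    diseases <- c("VRD", "TAO", "C", "LDD", "U", "G", "S", "DOSA", "ON",
                  "OT")
    baseRates <- c(VRD = 3.9, TAO = 0.03, C = 8.1, LDD = 0.18, U = 0.12,
                   G = 0.46, S = 0.05, DOSA = 1.3, ON = 0.03, OT = 0.25)
    dispersion <- 5
    nDays <- as.integer(as.Date("2024-06-30") - as.Date("2019-01-01")) + 1L
    edges <- list(c("PM10", "ON", 0.7),
                  c("visibility", "ON", -0.3),
                  c("O3", "OT", 0.4),
                  c("wind_speed", "OT", -0.2),
                  c("temperature", "C", 0.3),
                  c("humidity", "C", -0.15),
                  c("PM2.5", "DOSA", 0.35),
                  c("precipitation", "DOSA", -0.2),
                  c("C", "VRD", 0.25),
                  c("C", "C", 0.2),
                  c("VRD", "VRD", 0.2))
  }
  list(profile = envProfile(nDays, factors, collinearity),
       diseases = diseases, baseRates = baseRates, dispersion = dispersion,
       edges = edges)
}

#' Build a complete study fixture on disk
#'
#' Generates an environment panel and FCM-driven admission counts from a
#' fixed ground-truth model, and writes the data CSV, the roles sidecar
#' (YAML) and the ground-truth JSON to \code{dir}. \code{tiny} (4
#' environment factors, 2 diseases, 300 days) runs the whole pipeline in
#' seconds at a reduced optimizer budget; \code{paper_like} mirrors the
#' full study shape (15 environment factors, 10 diseases, ~5.5 years).
#'
#' @param scale \code{"tiny"} or \code{"paper_like"}.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the written paths, the data objects and
#'   the [groundTruth()].
#' @export
makeStudyFixture <- function(scale = c("tiny", "paper_like"), seed,
                             dir = tempfile("fixture")) {
  scale <- match.arg(scale)
  spec <- .fixtureSpec(scale)
  envNames <- spec$profile$factors$name
  cs <- conceptSet(c(envNames, spec$diseases),
                   c(rep("environment", length(envNames)),
                     rep("disease", length(spec$diseases))))
  n <- nConcepts(cs)
  W <- matrix(0, n, n, dimnames = list(conceptNames(cs), conceptNames(cs)))
  for (e in spec$edges) W[e[1], e[2]] <- as.numeric(e[3])
  truthModel <- fcmModel(cs, order = 1L, weights = list(W))
  truth <- groundTruth(truthModel, spec$baseRates, spec$dispersion)

  env <- generateEnvironment(spec$profile, seed)
  seed <- as.integer(seed)
  counts <- generateAdmissions(env, truth, seed = (seed + 5000L) %% 2147483647L)
  values <- cbind(env@values, counts@values)
  data <- timeSeriesMatrix(values, env@timestamps)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csvPath <- file.path(dir, "data.csv")
  rolesPath <- file.path(dir, "roles.yaml")
  truthPath <- file.path(dir, "ground_truth.json")
  writeStudyData(data, cs, csvPath, rolesPath)
  writeFCMModel(truthModel, truthPath,
                provenance = list(kind = "synthetic ground truth",
                                  scale = scale, seed = seed,
                                  baseRates = as.list(truth$baseRates),
                                  dispersion = truth$dispersion))
  invisible(list(csvPath = csvPath, rolesPath = rolesPath,
                 truthPath = truthPath, data = data, concepts = cs,
                 truth = truth))
}
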