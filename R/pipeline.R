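#' Run the full twin-cycle analysis pipeline
#'
#' Orchestrates preprocessing, model fitting, fit indices, the
#' variable-randomised null test and the mediation table for one cohort and
#' one or more models, from a single configuration, and writes machine- and
#' human-readable artefacts: per model an edge-estimate CSV, a mediation
#' CSV, the null chi-square values as a single-column CSV, plus a
#' correlation-matrix CSV, the residualised analysis table, optional DOT
#' diagrams, and a JSON manifest tying everything to the configuration and
#' seed. The manifest contains no timestamps, so the same configuration and
#' seed reproduce it byte for byte.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{input}{path to a participant CSV \emph{or}}
#'     \item{synthetic}{list of arguments for [syntheticCohortSpec()]
#'       (exactly one of \code{input}/\code{synthetic} must be present)}
#'     \item{columnMapping}{optional named list mapping model variable names
#'       to CSV column names}
#'     \item{models}{character vector of built-in names and/or model-spec
#'       file paths (default \code{c("TC", "TC-PA")})}
#'     \item{preprocess}{list: \code{offset} (default 0.375), \code{strata}
#'       (default \code{"sex"}; cohort-2 runs conventionally use
#'       \code{c("sex", "treatment")}), \code{covariates} (default age,
#'       centre, energy, carbohydrate, fat, protein)}
#'     \item{nullTest}{list: \code{nIter} (default 10000), \code{seed}
#'       (default 1)}
#'     \item{mediation}{list: \code{alpha} (default 0.05), \code{source}
#'       (default \code{"PA"}), \code{sinks} (default \code{c("FG","PG")}),
#'       \code{maxLength} (default Inf)}
#'     \item{outputDir}{artefact directory (created if needed)}
#'     \item{dot}{write DOT diagrams (default TRUE)}
#'   }
#' @return the manifest, invisibly (also written to
#'   \code{outputDir/manifest.json})
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (sum(c("input", "synthetic") %in% names(config)) != 1L)
    stop("config must contain exactly one of 'input' or 'synthetic'")
  outDir <- if (is.null(config$outputDir)) "twincycle-output" else
    config$outputDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  models <- if (is.null(config$models)) c("TC", "TC-PA") else config$models
  pp <- utils::modifyList(
    list(offset = 0.375, strata = "sex",
         covariates = c("age", "centre", "energy", "carbohydrate", "fat",
                        "protein")),
    if (is.null(config$preprocess)) list() else config$preprocess)
  nt <- utils::modifyList(list(nIter = 10000L, seed = 1L),
                          if (is.null(config$nullTest)) list() else
                            config$nullTest)
  md <- utils::modifyList(
    list(alpha = 0.05, source = "PA", sinks = c("FG", "PG"),
         maxLength = Inf),
    if (is.null(config$mediation)) list() else config$mediation)

  if (!is.null(config$synthetic)) {
    spec <- do.call(syntheticCohortSpec, config$synthetic)
    message("generating synthetic cohort ", spec$cohort, " (n = ", spec$n,
            ", seed ", spec$seed, ")")
    raw <- generateCohort(spec)
    if (spec$cohort == 2 && identical(pp$strata, "sex"))
      pp$strata <- c("sex", "treatment")
  } else {
    raw <- read.csv(config$input, stringsAsFactors = FALSE)
    if (!is.null(config$columnMapping)) {
      cm <- unlist(config$columnMapping)
      missing <- setdiff(unname(cm), names(raw))
      if (length(missing))
        stop("input CSV lacks mapped column(s): ",
             paste(missing, collapse = ", "))
      for (nm in names(cm)) raw[[nm]] <- raw[[cm[nm]]]
    }
  }

  manifest <- list(
    config = list(models = models, preprocess = pp,
                  nullTest = nt[c("nIter", "seed")],
                  mediation = md,
                  synthetic = config$synthetic, input = config$input),
    models = list()
  )

  for (mName in models) {
    t0 <- Sys.time()
    model <- if (file.exists(mName)) parseModelSpec(mName) else
      builtinModel(mName)
    vars <- nodeNames(model)
    missing <- setdiff(vars, names(raw))
    if (length(missing))
      stop("input lacks model variable column(s): ",
           paste(missing, collapse = ", "))
    analysis <- preprocessCohort(raw, vars, strata = pp$strata,
                                 covariates = pp$covariates,
                                 offset = pp$offset)
    ci <- covarianceInput(analysis, vars)
    key <- gsub("[^A-Za-z0-9]+", "-", mName)

    corM <- pairwiseCorrelations(analysis)
    write.csv(corM, file.path(outDir, paste0(key, "-correlations.csv")))
    write.csv(analysis, file.path(outDir, paste0(key, "-analysis-table.csv")),
              row.names = FALSE)

    fit <- fitModel(model, ci)
    edgeEstimateTable(fit, file.path(outDir, paste0(key, "-edges.csv")))
    fi <- computeFitIndices(fit)
    nulls <- randomizedNullDistribution(model, ci, nIter = nt$nIter,
                                        seed = nt$seed, observedFit = fit)
    write.csv(data.frame(chisq = nulls@chisq),
              file.path(outDir, paste0(key, "-null-chisq.csv")),
              row.names = FALSE)

    medTab <- if (md$source %in% vars)
      mediationTable(fit, source = md$source, sinks = intersect(md$sinks, vars),
                     alpha = md$alpha, maxLength = md$maxLength)
    else NULL
    if (!is.null(medTab))
      write.csv(medTab, file.path(outDir, paste0(key, "-mediation.csv")),
                row.names = FALSE)
    if (!identical(config$dot, FALSE))
      exportDOT(model, file.path(outDir, paste0(key, "-model.dot")))

    manifest$models[[mName]] <- list(
      n = sampleSize(ci), df = modelDF(fit),
      chisq = chisq(fit), fml = fit@fml, converged = fit@converged,
      cfi = fi$cfi, tli = fi$tli, rmsea = fi$rmsea,
      baselineChisq = fi$baselineChisq,
      nullMean = nulls@nullMean, empiricalP = nulls@empiricalP,
      tStat = nulls@tStat, tP = nulls@tP,
      nullConverged = nulls@convergedN, nullAttempted = nulls@attempted,
      heywood = fit@heywood,
      files = paste0(key, c("-edges.csv", "-mediation.csv",
                            "-null-chisq.csv", "-correlations.csv")))
    message(sprintf(
      "%s: chi-square %.1f (df %d) vs null mean %.1f, empirical p %.3g [%.1f s]",
      mName, chisq(fit), as.integer(modelDF(fit)), nulls@nullMean,
      nulls@empiricalP, as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Heatmap of a correlation matrix
#'
#' @param r symmetric correlation matrix, e.g. from
#'   [pairwiseCorrelations()]
#' @return a ggplot object
#' @export
plotCorrelationMatrix <- function(r) {
  df <- data.frame(
    row = factor(rep(rownames(r), ncol(r)), levels = rev(rownames(r))),
    col = factor(rep(colnames(r), each = nrow(r)), levels = colnames(r)),
    value = as.vector(r))
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", value)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r")
}
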