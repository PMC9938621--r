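## End-to-end orchestration: simulate (or load) -> normalize -> per-gene
## ANOVA -> co-expression network -> marker selection -> train/CV ->
## validation prediction -> outcome association, with a run manifest and
## seed propagation.

#' Default pipeline configuration
#'
#' Nested per-stage configuration of [runPipeline()]. Every constant of the
#' method is a named, defaulted field: the 0.05 significance levels, the
#' fold-change cutoff 2, the DEG call rule (q < 0.05), the network
#' parameters, the panel size 87, the probability threshold 0.6 and the 10
#' cross-validation folds.
#'
#' @param seed global seed propagated to every stochastic stage.
#' @param ... overrides for any nested field, e.g.
#'   `deg = list(qCut = 0.01)` or `sim = list(nGenes = 5000)`.
#' @param outDir output directory (`NULL`: nothing written).
#' @param simulate simulate the cohorts (`TRUE`) or read user data from
#'   `exprPath`/`metaPath` (log2 scale expected).
#' @return Nested configuration list.
#' @export
pipelineConfig <- function(seed = 1, ..., outDir = NULL, simulate = TRUE) {
  cfg <- list(
    seed = as.integer(seed), outDir = outDir, simulate = simulate,
    exprPath = NULL, metaPath = NULL,
    sim = list(nGenes = 3000, nDEG = 200, nPatients = 48,
               validationN = 22, nQCFail = 1),
    qc = list(minGenesDetectedFrac = 0.2),
    deg = list(qCut = 0.05, includeTreatment = FALSE),
    network = list(beta = 6, sign = "unsigned", cutHeight = 0.9,
                   minModuleSize = 30),
    markers = list(alpha = 0.05, panelSize = 87, ntree = 500),
    model = list(tau = 0.6, ntree = 500, cvFolds = 10)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Omitted fields take the [pipelineConfig()] defaults; a seed must be
#' present in the file or supplied here.
#'
#' @param path YAML file with (a subset of) the configuration fields.
#' @param seed fallback seed when the file has none.
#' @return Nested configuration list.
#' @export
readPipelineConfig <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed) && is.null(seed)) {
    stopf("configuration error: seed missing from %s", path)
  }
  do.call(pipelineConfig, c(list(seed = y$seed %||% seed),
                            y[setdiff(names(y), "seed")]))
}

#' Run the full receptivity-test pipeline
#'
#' Executes simulate (or load) -> QC -> per-gene ANOVA -> co-expression
#' modules on the stage-associated genes -> marker selection -> classifier
#' training and patient-grouped cross-validation -> validation-cohort
#' prediction with the threshold call rule -> WOI/outcome association.
#' When `outDir` is set, writes every stage artifact (`expr.tsv`,
#' `meta.tsv`, `genestats.tsv`, `modules.json`, `panel.tsv`,
#' `predictions.tsv`, `cv.json`, `assoc.json`) plus `manifest.json` holding
#' the seed, the configuration and a content hash of the outputs; reruns
#' with identical configuration and seed are byte-identical.
#'
#' @param config a [pipelineConfig()].
#' @return List with `dataset`, `genestats`, `degGenes`, `modules`,
#'   `panel`, `model`, `cv`, `validation` (dataset, predictions, qc),
#'   `assoc`, `truth` (simulation only), `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  out <- list()
  if (isTRUE(config$simulate)) {
    simcfg <- do.call(simulationConfig,
                      c(config$sim[setdiff(names(config$sim), "nQCFail")],
                        list(seed = config$seed)))
    tr <- simulateTrainingCohort(simcfg)
    va <- simulateValidationCohort(simcfg, tr$truth,
                                   nQCFail = config$sim$nQCFail %||% 0)
    dataset <- tr$dataset
    out$truth <- va$truth
    valData <- va$dataset
  } else {
    if (is.null(config$exprPath) || is.null(config$metaPath)) {
      stopf("configuration error: exprPath/metaPath required when simulate = FALSE")
    }
    dataset <- readDataset(config$exprPath, config$metaPath, "log2")
    valData <- NULL
  }

  gs <- geneANOVA(dataset,
                  includeTreatment = isTRUE(config$deg$includeTreatment))
  deg <- rownames(gs)[gs$q_value < config$deg$qCut &
                        is.na(gs$degenerate)]
  if (length(deg) < config$network$minModuleSize) {
    stopf("too few stage-associated genes (%d) for network analysis",
          length(deg))
  }
  np <- networkParams(beta = config$network$beta, sign = config$network$sign,
                      cutHeight = config$network$cutHeight,
                      minModuleSize = config$network$minModuleSize)
  modules <- coexpressionModules(dataset, deg, np)
  panel <- selectMarkers(dataset, gs, modules,
                         alpha = config$markers$alpha,
                         panelSize = config$markers$panelSize,
                         ntree = config$markers$ntree, seed = config$seed)
  model <- trainERT(dataset, panel$gene, tau = config$model$tau,
                    ntree = config$model$ntree, seed = config$seed)
  cv <- crossValidate(dataset, panel$gene, k = config$model$cvFolds,
                      ntree = config$model$ntree, seed = config$seed)

  out <- c(out, list(dataset = dataset, genestats = gs, degGenes = deg,
                     modules = modules, panel = panel, model = model,
                     cv = cv))

  if (!is.null(valData)) {
    qc <- qcFilter(valData,
                   minGenesDetected = round(
                     config$qc$minGenesDetectedFrac * nrow(valData)
                   ),
                   minTotal = 0)
    failed <- qc$report$sample_id[!qc$report$pass]
    pred <- predictReceptivity(model, valData, failedSamples = failed)
    pred$outcome <- sampleInfo(valData)$outcome
    out$validation <- list(dataset = valData, predictions = pred,
                           qc = qc$report)
    out$assoc <- tryCatch(outcomeAssociation(pred),
                          error = function(e) e$message)
  }

  if (!is.null(config$outDir)) {
    out$manifest <- writePipelineBundle(out, config)
  }
  out
}

writePipelineBundle <- function(out, config) {
  dir <- config$outDir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeDataset(out$dataset, dir)
  gs <- as.data.frame(out$genestats)
  utils::write.table(
    cbind(gene = rownames(gs), gs), file.path(dir, "genestats.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  mods <- out$modules
  jsonlite::write_json(
    list(labels = as.list(moduleLabels(mods)),
         stage_correlation = as.list(mods@stageCor),
         kWithin = as.list(mods@kWithin), hubs = as.list(hubGenesOf(mods))),
    file.path(dir, "modules.json"), auto_unbox = TRUE, digits = NA
  )
  utils::write.table(out$panel, file.path(dir, "panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(k = out$cv$k, mean = as.list(out$cv$mean), folds = out$cv$folds),
    file.path(dir, "cv.json"), auto_unbox = TRUE, digits = NA
  )
  if (!is.null(out$validation)) {
    utils::write.table(out$validation$predictions,
                       file.path(dir, "predictions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (inherits(out$assoc, "OutcomeTable")) {
      a <- out$assoc
      jsonlite::write_json(
        list(table = unclass(a$table), rates = as.list(a$rates),
             fisher_p = a$fisher$p_value, odds_ratio = a$fisher$odds_ratio,
             or_flag = a$fisher$or_flag, overall_rate = a$overall_rate,
             excluded = a$excluded, n_enrolled = a$n_enrolled),
        file.path(dir, "assoc.json"), auto_unbox = TRUE, digits = NA
      )
    }
  }
  files <- setdiff(list.files(dir, full.names = TRUE),
                   file.path(dir, "manifest.json"))
  manifest <- list(
    package = "fluidERT",
    version = as.character(utils::packageVersion("fluidERT")),
    seed = config$seed,
    config = config[setdiff(names(config), "outDir")],
    files = structure(as.list(unname(tools::md5sum(files))),
                      names = basename(files))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
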