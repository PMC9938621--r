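## Synthetic uterine-fluid cohort generator.
##
## The generative model is the additive log2 decomposition the per-gene
## ANOVA assumes,
##   Y_gij = mu_g + T_gi + S_gj + eps_gij,
## plus per-module latent factors: planted stage-associated genes carry
## i.i.d. normal, centered stage offsets delta_g(s); each planted module m
## carries a stage-independent factor f_m ~ N(0,1) per sample on which its
## members load with per-gene loadings, one member per module getting the
## largest loading and therefore the maximum intramodular connectivity (the
## planted hub). Modules are planted on genes disjoint from the
## stage-associated set so the truth ledger cleanly separates
## "differential" from "co-expressed". Counts, when requested, are
## negative-binomial around the FPKM-inverted expected fragments.

#' Simulation configuration
#'
#' Builds and validates the parameter set for [simulateTrainingCohort()]
#' and [simulateValidationCohort()]. Defaults emulate the study design the
#' pipeline targets: 48 patients sampled at LH+5/7/9 in a natural cycle,
#' 15,000 expressed genes of which 864 are stage-associated, four planted
#' co-expression modules with one hub each, and a 22-sample
#' single-timepoint validation cohort with pregnancy probability 0.78 given
#' a truly receptive endometrium at transfer and 0 otherwise.
#'
#' @param nPatients training patients; each contributes one sample per
#'   stage (LH+5 / LH+7 / LH+9).
#' @param nGenes total genes.
#' @param nDEG planted stage-associated genes.
#' @param stageEffectSD SD of the i.i.d. per-stage offsets of planted DEGs
#'   (log2 units; offsets are centered across the three stages).
#' @param treatmentEffectSD SD of the per-protocol offset (log2 units; 0 by
#'   default since the training cohort is all natural-cycle).
#' @param residualSD residual SD (log2 units).
#' @param baselineLogMean,baselineLogSD distribution of baseline log2 means.
#' @param moduleSizes planted module sizes (disjoint from the DEG set).
#' @param moduleFactorSD scale of member loadings on the module factor.
#' @param hubLoadingBoost multiplier applied to the largest member loading
#'   to create the planted hub.
#' @param nbDispersion negative-binomial dispersion for count emission.
#' @param geneLengthRange transcript length range in bp.
#' @param librarySizeMean expected fragments per library.
#' @param validationN validation cohort size.
#' @param validationStageProbs probabilities of the true stage PR/RE/PO on
#'   transfer day.
#' @param pPregReceptive,pPregDisplaced pregnancy probability given true
#'   receptive / displaced state at transfer.
#' @param seed RNG seed (mandatory; identical config incl. seed gives
#'   byte-identical output).
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nPatients = 48,
                             nGenes = 15000,
                             nDEG = 864,
                             stageEffectSD = 2.0,
                             treatmentEffectSD = 0,
                             residualSD = 1.0,
                             baselineLogMean = 3,
                             baselineLogSD = 1.5,
                             moduleSizes = c(100, 75, 50, 30),
                             moduleFactorSD = 2,
                             hubLoadingBoost = 1.5,
                             nbDispersion = 0.05,
                             geneLengthRange = c(200, 10000),
                             librarySizeMean = 5e6,
                             validationN = 22,
                             validationStageProbs = c(PR = 0.14, RE = 0.86,
                                                      PO = 0),
                             pPregReceptive = 0.78,
                             pPregDisplaced = 0,
                             seed) {
  if (missing(seed)) stopf("configuration error: seed is mandatory")
  cfg <- list(
    nPatients = as.integer(nPatients), samplesPerPatient = 3L,
    nGenes = as.integer(nGenes), nDEG = as.integer(nDEG),
    stageEffectSD = stageEffectSD, treatmentEffectSD = treatmentEffectSD,
    residualSD = residualSD, baselineLogMean = baselineLogMean,
    baselineLogSD = baselineLogSD, moduleSizes = as.integer(moduleSizes),
    moduleFactorSD = moduleFactorSD, hubLoadingBoost = hubLoadingBoost,
    nbDispersion = nbDispersion, geneLengthRange = geneLengthRange,
    librarySizeMean = librarySizeMean,
    validationN = as.integer(validationN),
    validationStageProbs = validationStageProbs,
    pPregReceptive = pPregReceptive, pPregDisplaced = pPregDisplaced,
    seed = as.integer(seed)
  )
  for (f in c("stageEffectSD", "treatmentEffectSD", "residualSD",
              "baselineLogSD", "moduleFactorSD")) {
    if (cfg[[f]] < 0) stopf("configuration error: %s must be >= 0", f)
  }
  if (cfg$nDEG > cfg$nGenes) {
    stopf("configuration error: nDEG exceeds nGenes")
  }
  if (any(cfg$moduleSizes < 1)) {
    stopf("configuration error: moduleSizes must be positive")
  }
  if (sum(cfg$moduleSizes) + cfg$nDEG > cfg$nGenes) {
    stopf("configuration error: moduleSizes + nDEG exceeds nGenes")
  }
  if (any(cfg$validationStageProbs < 0) ||
      abs(sum(cfg$validationStageProbs) - 1) > 1e-8) {
    stopf("configuration error: validationStageProbs must sum to 1")
  }
  for (f in c("pPregReceptive", "pPregDisplaced")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stopf("configuration error: %s must lie in [0, 1]", f)
    }
  }
  structure(cfg, class = "SimulationConfig")
}

## lay out gene roles once per config: module membership, loadings, hubs,
## stage offsets, baselines, lengths. Training and validation emission both
## reuse this shared truth.
simulateTruth <- function(config) {
  G <- config$nGenes
  genes <- sprintf("G%05d", seq_len(G))
  mu <- rnorm(G, config$baselineLogMean, config$baselineLogSD)
  lengths <- round(runif(G, config$geneLengthRange[1],
                         config$geneLengthRange[2]))

  nm <- length(config$moduleSizes)
  moduleNames <- if (nm) paste0("M", seq_len(nm)) else character(0)
  moduleLabelsTrue <- rep("none", G)
  loadings <- rep(0, G)
  hubs <- structure(character(nm), names = moduleNames)
  pos <- 0
  for (m in seq_len(nm)) {
    idx <- pos + seq_len(config$moduleSizes[m])
    pos <- pos + config$moduleSizes[m]
    moduleLabelsTrue[idx] <- moduleNames[m]
    l <- config$moduleFactorSD * runif(length(idx), 0.6, 1.4)
    ihub <- which.max(l)
    l[ihub] <- config$hubLoadingBoost * max(l)
    loadings[idx] <- l
    hubs[m] <- genes[idx[ihub]]
  }

  ## stage-associated genes: the next nDEG genes after the module blocks,
  ## with i.i.d. normal per-stage offsets centered across PR/RE/PO
  degIdx <- pos + seq_len(config$nDEG)
  delta <- matrix(0, G, 3, dimnames = list(genes, STAGES))
  if (config$nDEG > 0) {
    d <- matrix(rnorm(config$nDEG * 3, 0, config$stageEffectSD),
                config$nDEG, 3)
    delta[degIdx, ] <- d - rowMeans(d)
  }

  list(
    genes = genes, mu = mu, geneLengths = lengths, delta = delta,
    moduleLabels = structure(moduleLabelsTrue, names = genes),
    loadings = structure(loadings, names = genes),
    hubIds = hubs, degGeneIds = genes[degIdx]
  )
}

## latent log2 matrix for samples with given stages/protocols
emitLog2 <- function(config, truth, stage, protocol) {
  G <- config$nGenes
  N <- length(stage)
  y <- matrix(rnorm(G * N, 0, config$residualSD), G, N)
  y <- y + truth$mu
  y <- y + truth$delta[, stage, drop = FALSE]
  for (m in seq_along(config$moduleSizes)) {
    idx <- which(truth$moduleLabels == paste0("M", m))
    if (!length(idx)) next
    f <- rnorm(N) # module factor, one draw per sample
    y[idx, ] <- y[idx, ] + truth$loadings[idx] %o% f
  }
  if (config$treatmentEffectSD > 0) {
    prot <- factor(protocol, levels = PROTOCOL_LEVELS)
    toff <- matrix(rnorm(G * nlevels(prot), 0, config$treatmentEffectSD),
                   G, nlevels(prot))
    y <- y + toff[, as.integer(prot), drop = FALSE]
  }
  rownames(y) <- truth$genes
  y
}

## NB counts consistent with a latent log2(FPKM+1) matrix
emitCountsFromLog2 <- function(config, y, geneLens) {
  fpkm <- pmax(2^y - 1, 0)
  lib <- round(config$librarySizeMean * exp(rnorm(ncol(y), 0, 0.05)))
  mu <- sweep(fpkm * geneLens / 1e9, 2, lib, "*")
  matrix(
    rnbinom(length(mu), mu = mu, size = 1 / config$nbDispersion),
    nrow(mu), ncol(mu), dimnames = dimnames(y)
  )
}

#' Simulate the stage-timed training cohort
#'
#' Generates `3 * nPatients` samples labelled PR/RE/PO at days LH+5/7/9
#' (natural cycle) under the additive log2 model described in
#' [simulationConfig()], together with the ground-truth ledger used by
#' parameter-recovery tests.
#'
#' @param config a [simulationConfig()].
#' @param emitCounts also emit negative-binomial fragment counts consistent
#'   with the latent log2 matrix.
#' @return A list with `dataset` (log2-scale
#'   [ReceptivityExperiment-class]), `counts` (counts-scale experiment or
#'   `NULL`) and `truth` (list: `degGeneIds`, per-stage offsets `delta`,
#'   `moduleLabels`, `hubIds`, `loadings`, baseline `mu`, `geneLengths`).
#' @export
simulateTrainingCohort <- function(config, emitCounts = FALSE) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$seed, {
    truth <- simulateTruth(config)
    n <- config$nPatients
    patients <- sprintf("P%03d", seq_len(n))
    stage <- rep(STAGES, times = n)
    patient <- rep(patients, each = 3)
    sid <- paste0(patient, "_", stage)
    protocol <- rep("natural", length(sid))
    y <- emitLog2(config, truth, stage, protocol)
    colnames(y) <- sid
    meta <- data.frame(
      sample_id = sid, patient_id = patient,
      day = unname(STAGE_DAYS[stage]), stage = stage,
      protocol = protocol, outcome = "unknown",
      stringsAsFactors = FALSE
    )
    dataset <- ReceptivityExperiment(y, "log2", meta)
    counts <- NULL
    if (emitCounts) {
      cnt <- emitCountsFromLog2(config, y, truth$geneLengths)
      counts <- ReceptivityExperiment(cnt, "counts", meta,
                                      geneLengths = truth$geneLengths)
    }
    list(dataset = dataset, counts = counts, truth = truth)
  })
}

#' Simulate the single-timepoint validation cohort
#'
#' Emits `validationN` transfer-day samples whose true stage is drawn from
#' `validationStageProbs` and recorded in the returned truth ledger (the
#' dataset's stage column reads `"unknown"`). Pregnancy outcome is
#' Bernoulli with probability `pPregReceptive` when the true stage is RE
#' and `pPregDisplaced` otherwise. Optionally, samples are forced into a
#' library failure (expression zeroed outside a small random subset of
#' genes) to exercise the detection-failure path.
#'
#' @param config the [simulationConfig()] used for training.
#' @param truth the truth ledger from [simulateTrainingCohort()] (aligns
#'   the gene universe).
#' @param nQCFail number of samples forced to fail library QC.
#' @param emitCounts also emit NB fragment counts.
#' @return A list with `dataset`, `counts` and the updated `truth` carrying
#'   `validationStages`, `validationOutcomes` and `validationQCFail`.
#' @export
simulateValidationCohort <- function(config, truth, nQCFail = 0,
                                     emitCounts = FALSE) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!identical(truth$genes, sprintf("G%05d", seq_len(config$nGenes)))) {
    stopf("alignment error: truth gene universe does not match config")
  }
  withSeed(config$seed + 1L, {
    n <- config$validationN
    sid <- sprintf("V%03d", seq_len(n))
    trueStage <- sample(STAGES, n, replace = TRUE,
                        prob = config$validationStageProbs)
    outcome <- ifelse(
      rbinom(n, 1, ifelse(trueStage == "RE", config$pPregReceptive,
                          config$pPregDisplaced)) == 1,
      "pregnant", "not_pregnant"
    )
    protocol <- sample(PROTOCOL_LEVELS, n, replace = TRUE,
                       prob = c(0.4, 0.6))
    y <- emitLog2(config, truth, trueStage, protocol)
    colnames(y) <- sid
    qcFail <- character(0)
    if (nQCFail > 0) {
      fail <- sid[seq_len(min(nQCFail, n))]
      keep <- sample.int(nrow(y), max(1, round(0.05 * nrow(y))))
      y[-keep, fail] <- 0 # mimics a failed library: few genes detected
      qcFail <- fail
    }
    meta <- data.frame(
      sample_id = sid, patient_id = sid, day = "transfer-day",
      stage = "unknown", protocol = protocol, outcome = outcome,
      stringsAsFactors = FALSE
    )
    dataset <- ReceptivityExperiment(y, "log2", meta)
    counts <- NULL
    if (emitCounts) {
      cnt <- emitCountsFromLog2(config, y, truth$geneLengths)
      counts <- ReceptivityExperiment(cnt, "counts", meta,
                                      geneLengths = truth$geneLengths)
    }
    truth$validationStages <- structure(trueStage, names = sid)
    truth$validationOutcomes <- structure(outcome, names = sid)
    truth$validationQCFail <- qcFail
    list(dataset = dataset, counts = counts, truth = truth)
  })
}
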